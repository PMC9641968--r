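#' @importFrom Biostrings readAAStringSet
NULL

# The 20 standard residues, alphabetical by one-letter code. This is the
# canonical state order used for matrices, posterior vectors and the p_*
# columns of state tables.
AA_STATES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue order of the PAML .dat dialect (and of most published
# exchangeability matrices).
AA_PAML <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
              G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
              M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
              S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")

#' Construct a protein alignment
#'
#' A `protein_alignment` is an ordered set of equal-length gapped protein
#' sequences. Sequences are uppercased and the `.` gap dialect is normalised
#' to `-`; any character outside the 20 standard residues, `-` (gap) and `X`
#' (unknown) is rejected.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param seqs Character vector of aligned sequences, same length as `ids`.
#' @return An object of class `protein_alignment`: a list with elements
#'   `ids`, `seqs` (named by id) and `length` (number of columns; columns are
#'   indexed 1-based throughout the package).
#' @export
protein_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) == 0L)
    stop("alignment must contain at least one sequence")
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("sequence identifiers must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (widths[1] < 1L)
    stop("alignment must have at least one column")
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1]][1]
    stop("alignment rows have unequal lengths; first offending id: ", bad)
  }
  ok <- c(AA_STATES, "-", "X")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% ok))
    if (length(bad))
      stop(sprintf("invalid character '%s' at position %d in sequence '%s'",
                   chars[bad[1]], bad[1], ids[i]))
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, length = widths[1]),
            class = "protein_alignment")
}

#' Read an aligned protein FASTA file
#'
#' Records are kept in file order; lowercase letters are uppercased and `.`
#' gaps become `-`. Ragged rows, duplicate identifiers and characters outside
#' the residue alphabet (plus `-`/`X`) are errors.
#'
#' @param path Path to a FASTA file of aligned protein sequences.
#' @return A [protein_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  protein_alignment(ids, as.character(set))
}

#' Write an alignment as FASTA
#'
#' Sequences are wrapped at 60 columns, the canonical width used throughout
#' the package, so `write_fasta(read_fasta(f))` is byte-identical for files
#' in this canonical form.
#'
#' @param aln A [protein_alignment].
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "protein_alignment"))
  con <- file(path, "wb")  # "wb": byte-stable output across platforms
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con, sep = "\n")
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Extract alignment columns
#'
#' @param aln A [protein_alignment].
#' @param columns Integer vector of 1-based column indices.
#' @return A character matrix, rows named by sequence id, one column per
#'   requested alignment column.
#' @export
alignment_columns <- function(aln, columns) {
  stopifnot(inherits(aln, "protein_alignment"))
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > aln$length))
    stop("column index out of range 1..", aln$length)
  m <- matrix("", nrow = length(aln$ids), ncol = length(columns),
              dimnames = list(aln$ids, as.character(columns)))
  for (j in seq_along(columns))
    m[, j] <- substring(aln$seqs, columns[j], columns[j])
  m
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  show <- utils::head(x$ids, 5)
  for (id in show)
    cat(sprintf("  %-20s %s%s\n", id,
                substr(x$seqs[id], 1, 40),
                if (x$length > 40) "..." else ""))
  if (length(x$ids) > 5) cat("  ...\n")
  invisible(x)
}
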