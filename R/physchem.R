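# Physicochemical recoding: residues collapse to broad property categories
# so that radical differences between residue tuples can be told apart from
# conservative ones.

#' Physicochemical recoding scheme
#'
#' The packaged scheme groups the residues as Acidic (E, D), Aliphatic
#' (I, L, M, V), Amine (Q, N), Aromatic (W, Y, F), Basic (K, R), Small
#' Hydroxyl (S, T) and Tiny (A, G). Cys, His and Pro belong to no group and
#' are singleton categories named by their letter, so no unsupported
#' similarity is ever asserted for them.
#'
#' @param path Optional user scheme file (tab-delimited `residue`,
#'   `category`, `display`); defaults to the packaged scheme.
#' @return data.frame of class `physchem_scheme` with one row per residue.
#' @export
physchem_scheme <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "physchem_scheme.tsv", package = "ancsr",
                        mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  need <- c("residue", "category", "display")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scheme is missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(AA_STATES, df$residue)
  if (length(extra))
    stop("scheme does not cover residue(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(df$residue))
    stop("scheme maps a residue twice")
  structure(df[need], class = c("physchem_scheme", "data.frame"))
}

as_tuple <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1]]
  else as.character(x)
}

#' Recode a residue tuple into physicochemical categories
#'
#' @param residues Character vector of one-letter codes, or a single
#'   collapsed string (e.g. `"AATGG"`).
#' @param scheme A [physchem_scheme()]; default packaged scheme.
#' @param display Return display names (`"Tiny"`) instead of snake_case ids
#'   (`"tiny"`).
#' @return Character vector of category names, one per residue. Gaps and
#'   `X` yield `NA` (unscorable), not an error. Residues recoded to a
#'   singleton category (C, H, P) trigger a one-off message.
#' @export
recode <- function(residues, scheme = physchem_scheme(), display = FALSE) {
  r <- as_tuple(residues)
  out <- rep(NA_character_, length(r))
  known <- r %in% scheme$residue
  amb <- r %in% c("-", "X")
  if (any(!known & !amb))
    stop("cannot recode: ", paste(unique(r[!known & !amb]), collapse = ", "))
  col <- if (display) "display" else "category"
  out[known] <- scheme[[col]][match(r[known], scheme$residue)]
  singles <- scheme$residue[scheme$residue == scheme$category]
  hit <- unique(r[known][r[known] %in% singles])
  if (length(hit))
    message("residue(s) ", paste(hit, collapse = ", "),
            " recoded as singleton categor",
            if (length(hit) == 1) "y" else "ies")
  out
}

#' Are two residue tuples physicochemically conservative variants?
#'
#' @param combo_a,combo_b Equal-length residue tuples (vectors or collapsed
#'   strings).
#' @param scheme A [physchem_scheme()].
#' @return `TRUE` iff the recoded category tuples are identical.
#' @export
is_conservative <- function(combo_a, combo_b, scheme = physchem_scheme()) {
  a <- as_tuple(combo_a)
  b <- as_tuple(combo_b)
  if (length(a) != length(b))
    stop("tuples differ in length (", length(a), " vs ", length(b), ")")
  identical(suppressMessages(recode(a, scheme)),
            suppressMessages(recode(b, scheme)))
}

#' Recode every combination in a combination set
#'
#' @param combos A [enumerate_combinations()] result.
#' @param scheme A [physchem_scheme()].
#' @return `combos` with an added `types` column (collapsed category tuple,
#'   `|`-separated snake_case ids).
#' @export
recode_combinations <- function(combos, scheme = physchem_scheme()) {
  stopifnot(inherits(combos, "combination_set"))
  combos$types <- vapply(combos$residues, function(s)
    paste(suppressMessages(recode(s, scheme)), collapse = "|"),
    character(1))
  combos
}
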