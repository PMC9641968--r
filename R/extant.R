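# Comparison of ancestral residue combinations against extant sequence
# diversity: residue tuples at the variable columns are tallied across the
# ingroup, each ancestral combination is classified absent / rare / common
# at the residue and the physicochemical-type level, and pairwise residue
# co-occurrence is reported.

#' Extract extant residue tuples at a set of columns
#'
#' Sequences with a gap or `X` at any requested column cannot yield a
#' complete tuple; they are excluded from the counts and listed in the
#' exclusion report.
#'
#' @param aln A [protein_alignment].
#' @param columns 1-based alignment columns (ascending).
#' @param ingroup_ids Sequence ids to profile (e.g. the nitrogenase ingroup;
#'   outgroup rows are conventionally excluded).
#' @param clade_map Optional named character vector id -> clade tag.
#' @param scheme A [physchem_scheme()] used for type-level tallies.
#' @return Object of class `extant_profile`: list with `tuples` (named
#'   character vector, collapsed residue tuples per scorable sequence),
#'   `counts` (tuple -> occurrences), `type_counts` (category tuple ->
#'   occurrences), `types` (per-sequence category tuples), `excluded`
#'   (ids), `clades`, `columns`.
#' @export
extract_profiles <- function(aln, columns, ingroup_ids, clade_map = NULL,
                             scheme = physchem_scheme()) {
  stopifnot(inherits(aln, "protein_alignment"))
  ingroup_ids <- as.character(ingroup_ids)
  if (!length(ingroup_ids)) stop("ingroup is empty")
  unknown <- setdiff(ingroup_ids, aln$ids)
  if (length(unknown))
    stop("ingroup id(s) not in alignment: ", paste(unknown, collapse = ", "))
  columns <- sort(as.integer(columns))
  m <- alignment_columns(aln, columns)[ingroup_ids, , drop = FALSE]
  bad <- apply(m, 1, function(r) any(r %in% c("-", "X")))
  tuples <- apply(m[!bad, , drop = FALSE], 1, paste, collapse = "")
  types <- vapply(tuples, function(s)
    paste(suppressMessages(recode(s, scheme)), collapse = "|"), character(1))
  clades <- NULL
  if (!is.null(clade_map)) {
    clades <- clade_map[names(tuples)]
    names(clades) <- names(tuples)
  }
  structure(list(tuples = tuples,
                 counts = table(tuples),
                 type_counts = table(types),
                 types = types,
                 excluded = ingroup_ids[bad],
                 clades = clades,
                 columns = columns),
            class = "extant_profile")
}

#' @export
print.extant_profile <- function(x, ...) {
  cat(sprintf("extant_profile: %d scorable sequences (%d excluded) at columns %s\n",
              length(x$tuples), length(x$excluded),
              paste(x$columns, collapse = ", ")))
  cat(sprintf("  %d distinct residue tuples, %d distinct type tuples\n",
              length(x$counts), length(x$type_counts)))
  invisible(x)
}

status_of <- function(count, rare_max) {
  ifelse(count == 0L, "absent", ifelse(count <= rare_max, "rare", "common"))
}

#' Classify ancestral combinations against extant diversity
#'
#' Each combination is looked up in the extant tuple counts (exact residue
#' tuple) and in the recoded category-tuple counts. A combination is
#' `absent` when no extant sequence carries it, `rare` when at most
#' `rare_max` do, and `common` otherwise.
#'
#' @param combos A [enumerate_combinations()] result.
#' @param profile An [extract_profiles()] result over the same columns.
#' @param scheme A [physchem_scheme()].
#' @param rare_max Largest count still called rare (default 2).
#' @return List of class `combination_classification`: `table` (per
#'   combination: rank, residues, types, joint, `residue_status`/`count`,
#'   `type_status`/`type_count`, clades carrying the type), and `summary`
#'   with the named fractions: `n`, `residue_present` (and fraction of the
#'   combination space), `type_absent` (and fraction), `type_present`,
#'   `type_rare_among_present` (and fraction of the type-present count).
#' @export
classify <- function(combos, profile, scheme = physchem_scheme(),
                     rare_max = 2L) {
  stopifnot(inherits(combos, "combination_set"),
            inherits(profile, "extant_profile"))
  cols <- attr(combos, "columns")
  if (!identical(as.integer(cols), as.integer(profile$columns)))
    stop("combination and profile columns differ: ",
         paste(cols, collapse = ","), " vs ",
         paste(profile$columns, collapse = ","))
  if (rare_max < 1L) stop("rare_max must be >= 1")
  combos <- recode_combinations(combos, scheme)
  cnt <- as.integer(profile$counts[combos$residues])
  cnt[is.na(cnt)] <- 0L
  tcnt <- as.integer(profile$type_counts[combos$types])
  tcnt[is.na(tcnt)] <- 0L
  clades_for_type <- function(tt) {
    if (is.null(profile$clades)) return(NA_character_)
    ids <- names(profile$types)[profile$types == tt]
    cl <- unique(stats::na.omit(profile$clades[ids]))
    if (!length(cl)) NA_character_ else paste(sort(cl), collapse = ",")
  }
  tab <- data.frame(rank = combos$rank,
                    residues = combos$residues,
                    types = combos$types,
                    joint = combos$joint,
                    ratio_to_top = combos$ratio_to_top,
                    count = cnt,
                    residue_status = status_of(cnt, rare_max),
                    type_count = tcnt,
                    type_status = status_of(tcnt, rare_max),
                    type_clades = vapply(combos$types, clades_for_type,
                                         character(1)),
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  rp <- sum(tab$count > 0L)
  ta <- sum(tab$type_count == 0L)
  tp <- n - ta
  tr <- sum(tab$type_count >= 1L & tab$type_count <= rare_max)
  summary <- list(n = n,
                  residue_present = rp,
                  residue_present_fraction = rp / n,
                  residue_absent = n - rp,
                  type_absent = ta,
                  type_absent_fraction = ta / n,
                  type_present = tp,
                  type_rare_among_present = tr,
                  type_rare_among_present_fraction =
                    if (tp > 0) tr / tp else NA_real_,
                  rare_max = as.integer(rare_max),
                  n_extant_scored = length(profile$tuples),
                  n_extant_excluded = length(profile$excluded))
  structure(list(table = tab, summary = summary),
            class = "combination_classification")
}

#' @export
print.combination_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("combination_classification: %d combinations vs %d extant sequences\n",
              s$n, s$n_extant_scored))
  cat(sprintf("  residue level: %d/%d present (%.1f%%)\n",
              s$residue_present, s$n, 100 * s$residue_present_fraction))
  cat(sprintf("  type level: %d/%d absent (%.1f%%); rare among present: %d/%d\n",
              s$type_absent, s$n, 100 * s$type_absent_fraction,
              s$type_rare_among_present, s$type_present))
  invisible(x)
}

#' Pairwise residue co-occurrence across columns
#'
#' For every ordered pair of distinct columns and every residue pair drawn
#' from the states of interest (the enumerated combinations when given,
#' otherwise the residues observed in the profile), reports how many extant
#' sequences carry both residues.
#'
#' @param profile An [extract_profiles()] result (>= 2 columns).
#' @param combos Optional [enumerate_combinations()] result restricting the
#'   residues considered per column.
#' @return data.frame: `column_a`, `residue_a`, `column_b`, `residue_b`,
#'   `count`.
#' @export
co_occurrence_report <- function(profile, combos = NULL) {
  stopifnot(inherits(profile, "extant_profile"))
  cols <- profile$columns
  if (length(cols) < 2L) stop("need at least two columns")
  mat <- do.call(rbind, strsplit(unname(profile$tuples), "", fixed = TRUE))
  if (is.null(mat)) mat <- matrix(character(0), 0, length(cols))
  per_col <- if (!is.null(combos)) {
    lapply(attr(combos, "site_states"), function(d) unique(d$residue))
  } else {
    lapply(seq_along(cols), function(j) sort(unique(mat[, j])))
  }
  out <- list()
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (j <= i) next
    for (a in per_col[[i]]) for (b in per_col[[j]]) {
      cnt <- if (nrow(mat)) sum(mat[, i] == a & mat[, j] == b) else 0L
      out[[length(out) + 1L]] <-
        data.frame(column_a = cols[i], residue_a = a,
                   column_b = cols[j], residue_b = b,
                   count = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
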