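# Enumeration of ancestral residue combinations across variable sites.
# Each combination's joint probability is the product of its member
# residues' per-site posteriors (sites are treated independently, as in
# marginal reconstruction); combinations are ranked by joint probability.

#' Enumerate ancestral residue combinations
#'
#' Full cross-product of the listed states at each variable site (ascending
#' alignment column). The joint probability of a combination is the product
#' of its per-site posteriors; combinations are sorted by descending joint,
#' ties broken lexicographically by residue tuple.
#'
#' @param vs A [detect_variable_sites()] result, or a named list (by
#'   column) of data.frames with `residue` and `posterior`.
#' @return data.frame of class `combination_set`: `rank`, `residues`
#'   (collapsed tuple string), `joint`, `ratio_to_top`, one `site_<col>`
#'   residue column and one `p_<col>` posterior column per site. The
#'   per-site state lists are kept as attribute `site_states`.
#' @export
enumerate_combinations <- function(vs) {
  states <- if (inherits(vs, "variable_sites")) variable_site_states(vs)
            else vs[order(as.integer(names(vs)))]
  if (!length(states)) stop("no variable sites to enumerate")
  empty <- vapply(states, function(d) nrow(d) == 0L, logical(1))
  if (any(empty))
    stop("empty state list at site(s): ",
         paste(names(states)[empty], collapse = ", "))
  cols <- names(states)
  grids <- lapply(states, function(d) seq_len(nrow(d)))
  idx <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(d, i) d$residue[i], states, idx, SIMPLIFY = TRUE)
  prb <- mapply(function(d, i) d$posterior[i], states, idx, SIMPLIFY = TRUE)
  res <- matrix(res, ncol = length(cols))
  prb <- matrix(prb, ncol = length(cols))
  joint <- apply(prb, 1, prod)
  tuple <- apply(res, 1, paste, collapse = "")
  ord <- order(-joint, tuple)
  out <- data.frame(rank = seq_along(ord),
                    residues = tuple[ord],
                    joint = joint[ord],
                    ratio_to_top = joint[ord] / max(joint),
                    stringsAsFactors = FALSE)
  rcols <- as.data.frame(res[ord, , drop = FALSE])
  names(rcols) <- paste0("site_", cols)
  pcols <- as.data.frame(prb[ord, , drop = FALSE])
  names(pcols) <- paste0("p_", cols)
  out <- cbind(out, rcols, pcols)
  structure(out, site_states = states, columns = as.integer(cols),
            class = c("combination_set", "data.frame"))
}

#' Summarise an enumerated combination set
#'
#' @param combos A [enumerate_combinations()] result.
#' @return List with `n`, `min_joint`, `max_joint`, `min_joint_pct` (the
#'   minimum joint expressed as a percentage), `min_ratio_to_top`,
#'   `max_ratio_to_top`, `min_ratio_to_top_pct`, and the ranked `table`.
#'   Both the raw joint product and the ratio to the top combination are
#'   reported, since either can serve as a "likelihood ratio" depending on
#'   the chosen normalisation.
#' @export
combination_summary <- function(combos) {
  stopifnot(inherits(combos, "combination_set"), nrow(combos) >= 1L)
  list(n = nrow(combos),
       min_joint = min(combos$joint),
       max_joint = max(combos$joint),
       min_joint_pct = 100 * min(combos$joint),
       min_ratio_to_top = min(combos$ratio_to_top),
       max_ratio_to_top = max(combos$ratio_to_top),
       min_ratio_to_top_pct = 100 * min(combos$ratio_to_top),
       table = as.data.frame(combos))
}

#' Write a combination table
#' @param combos A [enumerate_combinations()] result.
#' @param path Output path (tab-delimited with a `#` provenance header).
#' @return `path`, invisibly.
#' @export
write_combinations <- function(combos, path) {
  stopifnot(inherits(combos, "combination_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ancsr %s combination table; %d combinations over sites %s",
                     as.character(utils::packageVersion("ancsr")),
                     nrow(combos),
                     paste(attr(combos, "columns"), collapse = ",")), con)
  utils::write.table(as.data.frame(combos), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.combination_set <- function(x, ...) {
  cat(sprintf("combination_set: %d combinations over %d sites (%s)\n",
              nrow(x), length(attr(x, "columns")),
              paste(attr(x, "columns"), collapse = ", ")))
  print(utils::head(as.data.frame(x)[c("rank", "residues", "joint",
                                       "ratio_to_top")], 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n")
  invisible(x)
}
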