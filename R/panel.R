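# Site panels: structural annotations keyed by 1-based alignment column,
# mapping to reference-sequence numbering, and detection of ancestrally
# variable sites at a posterior threshold.

#' Construct a site panel
#'
#' @param df data.frame with columns `column` (1-based alignment column,
#'   unique), `reference_label` (e.g. `"alpha-70^Val"`), `role` (free-text
#'   annotation) and `conserved_residue` (one-letter code).
#' @return data.frame of class `site_panel`, sorted by column.
#' @export
site_panel <- function(df) {
  need <- c("column", "reference_label", "role", "conserved_residue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  df$column <- as.integer(df$column)
  if (anyNA(df$column) || any(df$column < 1L))
    stop("panel columns must be positive integers")
  if (anyDuplicated(df$column))
    stop("duplicate panel column(s): ",
         paste(unique(df$column[duplicated(df$column)]), collapse = ", "))
  bad <- !(df$conserved_residue %in% AA_STATES)
  if (any(bad))
    stop("invalid conserved residue: ",
         paste(df$conserved_residue[bad], collapse = ", "))
  df <- df[order(df$column), need]
  rownames(df) <- NULL
  structure(df, class = c("site_panel", "data.frame"))
}

#' Read a tab-delimited site-panel file
#' @param path Panel file; `#` lines are comments.
#' @return A [site_panel].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  site_panel(utils::read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#", quote = "",
                               stringsAsFactors = FALSE))
}

#' The packaged 24-site nitrogenase substrate-channel panel
#'
#' Substrate-channel sites of the nitrogenase D subunit (Azotobacter
#' vinelandii NifD numbering), keyed by alignment column of the curated
#' nitrogenase alignment the package's reference posteriors refer to.
#'
#' @return A [site_panel] with 24 rows.
#' @export
nif_panel <- function() {
  read_panel(system.file("extdata", "nif24_panel.tsv", package = "ancsr",
                         mustWork = TRUE))
}

#' Map alignment columns to reference-sequence residue numbering
#'
#' Counts ungapped positions along the reference row; columns where the
#' reference has a gap map to `NA`.
#'
#' @param aln A [protein_alignment].
#' @param reference_id Id of the reference sequence.
#' @return Integer vector of length `aln$length`: reference position per
#'   alignment column, `NA` at reference gaps. Strictly increasing over
#'   mapped columns.
#' @export
map_alignment_to_reference <- function(aln, reference_id) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!reference_id %in% aln$ids)
    stop("unknown reference id: ", reference_id)
  chars <- strsplit(aln$seqs[[reference_id]], "", fixed = TRUE)[[1]]
  resno <- cumsum(chars != "-")
  resno[chars == "-"] <- NA_integer_
  as.integer(resno)
}

#' Detect ancestrally variable sites within a panel
#'
#' A panel site is variable iff at least two states have posterior strictly
#' greater than `threshold` at the target node. Non-variable sites are
#' retained with their single dominant state, and sub-threshold states are
#' kept (flagged) for reporting but excluded from combination enumeration.
#'
#' @param state A [state_table] containing all panel columns for `node`.
#' @param panel A [site_panel].
#' @param threshold Posterior cutoff (strict `>`; default 0.10).
#' @param node Node id; defaults to the single node present in `state`.
#' @return Object of class `variable_sites`: list with `sites` (per panel
#'   column, a data.frame of `residue`, `posterior`, `listed`, sorted
#'   descending), `variable` (named logical), `threshold`, `node`.
#' @export
detect_variable_sites <- function(state, panel, threshold = 0.10,
                                  node = NULL) {
  stopifnot(inherits(panel, "site_panel"))
  if (!(threshold >= 0 && threshold < 1))
    stop("threshold must be in [0, 1)")
  if (is.null(node)) {
    node <- unique(state$node)
    if (length(node) != 1L)
      stop("state table has several nodes; pass `node`")
  }
  miss <- setdiff(panel$column, state$site[state$node == node])
  if (length(miss))
    stop("panel column(s) missing from state table: ",
         paste(miss, collapse = ", "))
  sites <- lapply(panel$column, function(col) {
    p <- state_probs(state, node, col)
    p <- sort(p[p > 0], decreasing = TRUE)
    data.frame(residue = names(p), posterior = as.numeric(p),
               listed = as.numeric(p) > threshold,
               stringsAsFactors = FALSE)
  })
  names(sites) <- as.character(panel$column)
  variable <- vapply(sites, function(d) sum(d$listed) >= 2L, logical(1))
  structure(list(sites = sites, variable = variable,
                 threshold = threshold, node = node, panel = panel),
            class = "variable_sites")
}

#' Listed states of the variable sites
#'
#' @param vs A [detect_variable_sites()] result.
#' @return Named list (by ascending alignment column, variable sites only)
#'   of data.frames `residue`/`posterior` with posterior above the
#'   detection threshold.
#' @export
variable_site_states <- function(vs) {
  stopifnot(inherits(vs, "variable_sites"))
  cols <- names(vs$variable)[vs$variable]
  out <- lapply(vs$sites[cols], function(d) {
    d <- d[d$listed, c("residue", "posterior")]
    rownames(d) <- NULL
    d
  })
  out[order(as.integer(names(out)))]
}

#' @export
print.variable_sites <- function(x, ...) {
  nv <- sum(x$variable)
  cat(sprintf("variable_sites: %d/%d panel sites variable at P > %g (node %s)\n",
              nv, length(x$variable), x$threshold, x$node))
  for (col in names(x$variable)[x$variable]) {
    d <- x$sites[[col]]
    d <- d[d$listed, ]
    cat(sprintf("  site %s: %s\n", col,
                paste(sprintf("%s %.5f", d$residue, d$posterior),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @export
as.data.frame.variable_sites <- function(x, ...) {
  do.call(rbind, lapply(names(x$sites), function(col) {
    d <- x$sites[[col]]
    cbind(data.frame(column = as.integer(col), variable = x$variable[[col]],
                     row.names = NULL), d)
  }))
}
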