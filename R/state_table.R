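# Per-node, per-site posterior distributions over the 20 residues, in the
# tab-delimited Node/Site/State/p_* dialect written by common ASR tools, so
# real ancestral-state files can be ingested unchanged.

P_COLS <- paste0("p_", AA_STATES)

#' Construct a state table
#'
#' A state table holds, for one or more (node, site) pairs, the marginal
#' posterior probability of each of the 20 residues. Rows whose
#' probabilities sum to 1 within `1e-4` are renormalised (with a message);
#' larger deviations are an error.
#'
#' @param df A data.frame with columns `node`, `site`, `state` (the
#'   most-probable residue; recomputed if missing) and `p_A` ... `p_Y`
#'   (alphabetical one-letter order).
#' @return A data.frame of class `state_table`.
#' @export
state_table <- function(df) {
  names(df) <- sub("^Node$", "node", names(df))
  names(df) <- sub("^Site$", "site", names(df))
  names(df) <- sub("^State$", "state", names(df))
  missing_p <- setdiff(P_COLS, names(df))
  if (length(missing_p))
    stop("missing probability column(s): ", paste(missing_p, collapse = ", "))
  if (!all(c("node", "site") %in% names(df)))
    stop("state table needs 'node' and 'site' columns")
  p <- as.matrix(df[P_COLS])
  if (!is.numeric(p) || anyNA(p))
    stop("non-numeric probability cell in state table")
  if (any(p < 0 | p > 1 + 1e-9))
    stop("probabilities outside [0, 1] in state table")
  s <- rowSums(p)
  off <- abs(s - 1)
  if (any(off > 1e-4))
    stop(sprintf("state-table row %d sums to %.6f (deviation > 1e-4)",
                 which(off > 1e-4)[1], s[which(off > 1e-4)[1]]))
  if (any(off > 1e-9)) {
    message(sum(off > 1e-9), " state-table row(s) renormalised")
    p <- p / s
  }
  df[P_COLS] <- p
  df$site <- as.integer(df$site)
  df$node <- as.character(df$node)
  df$state <- AA_STATES[max.col(p, ties.method = "first")]
  structure(df[c("node", "site", "state", P_COLS)],
            class = c("state_table", "data.frame"))
}

#' Read a tab-delimited ancestral-state file
#'
#' Lines starting with `#` are comments; the header must contain
#' `Node`/`Site`/`State` (case-insensitive on this package's own output) and
#' the 20 probability columns `p_A` ... `p_Y`.
#'
#' @param path Path to a state file.
#' @return A [state_table].
#' @export
read_state_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = TRUE)
  state_table(df)
}

#' Write a state table
#'
#' Emits a `#`-prefixed provenance header followed by the tab-delimited
#' Node/Site/State/p_* dialect; probabilities are printed with 17
#' significant digits so write -> read round trips are exact to well below
#' `1e-12`.
#'
#' @param st A [state_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(st, path) {
  stopifnot(inherits(st, "state_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ancsr %s state table; %d rows; written %s",
                     as.character(utils::packageVersion("ancsr")),
                     nrow(st), format(Sys.time(), "%Y-%m-%d")), con)
  writeLines(paste(c("Node", "Site", "State", P_COLS), collapse = "\t"), con)
  for (i in seq_len(nrow(st))) {
    writeLines(paste(c(st$node[i], st$site[i], st$state[i],
                       sprintf("%.17g", as.numeric(st[i, P_COLS]))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Posterior vector for one (node, site) pair
#'
#' @param st A [state_table].
#' @param node Node id.
#' @param site 1-based alignment column.
#' @return Named numeric vector of length 20 (alphabetical residue order).
#' @export
state_probs <- function(st, node, site) {
  i <- which(st$node == node & st$site == site)
  if (!length(i))
    stop(sprintf("no state-table row for node '%s', site %d", node, site))
  p <- as.numeric(st[i[1], P_COLS])
  names(p) <- AA_STATES
  p
}

#' @export
print.state_table <- function(x, ...) {
  cat(sprintf("state_table: %d rows, %d node(s), sites %d..%d\n",
              nrow(x), length(unique(x$node)), min(x$site), max(x$site)))
  NextMethod()
}
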