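# Likelihood engine: Felsenstein pruning over a rooted tree with a
# rate-category mixture, and marginal ancestral reconstruction via the
# standard inside/outside two-pass algorithm. Underflow is controlled by
# per-(node, site, category) log-scaling; posteriors mix categories by
# their site-specific posterior weight.

leaf_partial <- function(seq, alphabet) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nst <- length(alphabet)
  m <- matrix(0, nst, length(chars))
  amb <- chars %in% c("-", "X")
  m[, amb] <- 1  # missing data: all states equally compatible
  idx <- match(chars[!amb], alphabet)
  if (anyNA(idx))
    stop("sequence character(s) outside the model alphabet: ",
         paste(unique(chars[!amb][is.na(idx)]), collapse = ", "))
  m[cbind(idx, which(!amb))] <- 1
  m
}

# Inside (post-order) pass; optionally the outside (pre-order) pass needed
# for marginal posteriors at internal nodes.
asr_engine <- function(tree, aln, model, need_down = FALSE) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  stopifnot(inherits(aln, "protein_alignment"), inherits(model, "subst_model"))
  tips <- tree$tip.label
  miss <- setdiff(tips, aln$ids)
  if (length(miss))
    stop("leaf without alignment row: ", paste(miss, collapse = ", "))

  nst <- length(model$alphabet)
  S <- aln$length
  cats <- model$categories
  K <- nrow(cats)
  Q <- build_rate_matrix(model)
  tr <- stats::reorder(tree, "postorder")
  E <- nrow(tr$edge)
  ntip <- length(tips)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L

  Pk <- lapply(seq_len(K), function(k)
    lapply(seq_len(E), function(e)
      transition_probs(Q, tr$edge.length[e], cats$rate[k])))

  L <- vector("list", nnode)    # per node: list of K (nst x S) matrices
  scL <- vector("list", nnode)  # per node: K x S log-scale matrix
  for (i in seq_len(ntip)) {
    lp <- leaf_partial(aln$seqs[[tips[i]]], model$alphabet)
    L[[i]] <- rep(list(lp), K)
    scL[[i]] <- matrix(0, K, S)
  }

  rescale <- function(v) {
    for (k in seq_len(K)) {
      m <- apply(L[[v]][[k]], 2, max)
      if (any(m <= 0)) stop("site with zero likelihood at node ", v)
      L[[v]][[k]] <<- L[[v]][[k]] / rep(m, each = nst)
      scL[[v]][k, ] <<- scL[[v]][k, ] + log(m)
    }
  }

  Medge <- vector("list", E)  # per edge: list of K matrices P_e %*% L_child
  done <- logical(nnode)
  done[seq_len(ntip)] <- TRUE
  for (e in seq_len(E)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (!done[ch]) {  # first edge leaving an internal child: finalise it
      rescale(ch)
      done[ch] <- TRUE
    }
    Me <- lapply(seq_len(K), function(k) Pk[[k]][[e]] %*% L[[ch]][[k]])
    Medge[[e]] <- Me
    if (is.null(L[[par]])) {
      L[[par]] <- Me
      scL[[par]] <- scL[[ch]]
    } else {
      for (k in seq_len(K)) L[[par]][[k]] <- L[[par]][[k]] * Me[[k]]
      scL[[par]] <- scL[[par]] + scL[[ch]]
    }
  }
  rescale(root)

  pi <- model$pi
  lw <- matrix(0, K, S)  # log w_k + log P(site | k), unscaled-corrected
  for (k in seq_len(K))
    lw[k, ] <- log(cats$weight[k]) + scL[[root]][k, ] +
      log(colSums(pi * L[[root]][[k]]))
  mx <- apply(lw, 2, max)
  loglik_sites <- mx + log(colSums(exp(lw - rep(mx, each = K))))

  env <- list(tree = tr, L = L, scL = scL, Medge = Medge, Pk = Pk,
              pi = pi, cats = cats, K = K, nst = nst, S = S,
              ntip = ntip, root = root, loglik_sites = loglik_sites,
              alphabet = model$alphabet)

  if (need_down) {
    F <- vector("list", nnode)
    scF <- vector("list", nnode)
    F[[root]] <- rep(list(matrix(pi, nst, S)), K)
    scF[[root]] <- matrix(0, K, S)
    out_edges <- split(seq_len(E), tr$edge[, 1])
    for (e in rev(seq_len(E))) {  # pre-order: parents before children
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (ch <= ntip) next
      sibs <- setdiff(out_edges[[as.character(par)]], e)
      Fch <- vector("list", K)
      scFch <- matrix(0, K, S)
      for (k in seq_len(K)) {
        X <- F[[par]][[k]]
        sc <- scF[[par]][k, ]
        for (se in sibs) {
          X <- X * Medge[[se]][[k]]
          sc <- sc + scL[[tr$edge[se, 2]]][k, ]
        }
        Y <- crossprod(Pk[[k]][[e]], X)
        m <- apply(Y, 2, max)
        m[m <= 0] <- 1
        Fch[[k]] <- Y / rep(m, each = nst)
        scFch[k, ] <- sc + log(m)
      }
      F[[ch]] <- Fch
      scF[[ch]] <- scFch
    }
    env$F <- F
    env$scF <- scF
  }
  env
}

node_posterior <- function(eng, node) {
  K <- eng$K; nst <- eng$nst; S <- eng$S
  num <- matrix(0, nst, S)
  lw <- matrix(0, K, S)
  J <- vector("list", K)
  for (k in seq_len(K)) {
    J[[k]] <- eng$F[[node]][[k]] * eng$L[[node]][[k]]
    lw[k, ] <- log(eng$cats$weight[k]) + eng$scF[[node]][k, ] +
      eng$scL[[node]][k, ]
  }
  mx <- apply(lw, 2, max)
  for (k in seq_len(K))
    num <- num + J[[k]] * rep(exp(lw[k, ] - mx), each = nst)
  post <- num / rep(colSums(num), each = nst)
  rownames(post) <- eng$alphabet
  post
}

resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    if (!is.null(tree$node.label)) {
      i <- match(node, tree$node.label)
      if (!is.na(i)) return(ntip + i)
    }
    i <- match(node, tree$tip.label)
    if (!is.na(i)) return(i)
    stop("unknown node label: ", node)
  }
  node <- as.integer(node)
  if (node < 1L || node > ntip + tree$Nnode)
    stop("node number out of range: ", node)
  node
}

node_id <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  if (!is.null(tree$node.label) && nzchar(tree$node.label[node - ntip]))
    return(tree$node.label[node - ntip])
  paste0("Node", node)
}

#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a reversible model with a rate mixture:
#' `log sum_k w_k sum_x pi_x L_k(x)` at the root. The value is invariant to
#' root placement for reversible models.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param aln A [protein_alignment]; tree leaves must all have rows.
#' @param model A [substitution_model()].
#' @param site Optional 1-based column; default all columns.
#' @return Numeric vector of per-site log-likelihoods (or a scalar when
#'   `site` is given).
#' @export
site_log_likelihood <- function(tree, aln, model, site = NULL) {
  eng <- asr_engine(tree, aln, model, need_down = FALSE)
  if (is.null(site)) return(eng$loglik_sites)
  site <- as.integer(site)
  if (any(site < 1L | site > eng$S)) stop("site out of range 1..", eng$S)
  eng$loglik_sites[site]
}

#' Marginal ancestral reconstruction at one internal node
#'
#' For each site, the posterior probability of each state at `node`,
#' integrating over all other nodes and mixing rate categories by their
#' site-specific posterior weight. Under a reversible model this equals the
#' root-state posterior of the tree re-rooted at `node`, and is invariant to
#' the original root placement.
#'
#' @inheritParams site_log_likelihood
#' @param node Internal node (ape number or node label).
#' @param sites Optional subset of 1-based columns (default: all).
#' @return A [state_table] (for the 20-residue alphabet) with one row per
#'   site, or a plain data.frame for reduced alphabets.
#' @export
marginal_asr <- function(tree, aln, model, node, sites = NULL) {
  nd <- resolve_node(tree, node)
  if (nd <= length(tree$tip.label))
    stop("node ", node, " is a leaf; marginal reconstruction needs an ",
         "internal node")
  eng <- asr_engine(tree, aln, model, need_down = TRUE)
  post <- node_posterior(eng, nd)
  if (is.null(sites)) sites <- seq_len(eng$S)
  sites <- as.integer(sites)
  if (any(sites < 1L | sites > eng$S)) stop("site out of range 1..", eng$S)
  df <- data.frame(node = node_id(tree, nd), site = sites,
                   stringsAsFactors = FALSE)
  pm <- t(post[, sites, drop = FALSE])
  colnames(pm) <- paste0("p_", eng$alphabet)
  df <- cbind(df, as.data.frame(pm))
  rownames(df) <- NULL
  if (identical(eng$alphabet, AA_STATES)) state_table(df) else {
    df$state <- eng$alphabet[max.col(pm, ties.method = "first")]
    df[c("node", "site", "state", paste0("p_", eng$alphabet))]
  }
}

#' Fit a marginal ancestral reconstruction
#'
#' The central fitting function: computes the pruning likelihood of the
#' alignment on the tree under `model` and the marginal state posteriors at
#' a target internal node, returned as a classed fit with `print`,
#' `summary` and `logLik` methods.
#'
#' @inheritParams site_log_likelihood
#' @param node Target internal node (ape number or node label).
#' @return An object of class `asr`: list with `state_table` (per-site
#'   posteriors at `node`), `loglik_sites`, `loglik`, `tree`, `model`,
#'   `node` and `node_label`.
#' @export
asr <- function(aln, tree, model, node) {
  nd <- resolve_node(tree, node)
  if (nd <= length(tree$tip.label))
    stop("target node is a leaf; choose an internal node")
  eng <- asr_engine(tree, aln, model, need_down = TRUE)
  post <- node_posterior(eng, nd)
  df <- data.frame(node = node_id(tree, nd), site = seq_len(eng$S),
                   stringsAsFactors = FALSE)
  pm <- t(post)
  colnames(pm) <- paste0("p_", eng$alphabet)
  df <- cbind(df, as.data.frame(pm))
  st <- if (identical(eng$alphabet, AA_STATES)) state_table(df) else df
  structure(list(state_table = st,
                 loglik_sites = eng$loglik_sites,
                 loglik = sum(eng$loglik_sites),
                 tree = tree, model = model,
                 node = nd, node_label = node_id(tree, nd)),
            class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat(sprintf("Marginal ancestral reconstruction at node '%s'\n",
              x$node_label))
  cat(sprintf("  model: %s, %d rate categor%s\n", x$model$name,
              nrow(x$model$categories),
              if (nrow(x$model$categories) == 1) "y" else "ies"))
  cat(sprintf("  %d sites, log-likelihood %.4f\n",
              length(x$loglik_sites), x$loglik))
  invisible(x)
}

#' @export
summary.asr <- function(object, ...) {
  st <- object$state_table
  pcols <- grep("^p_", names(st))
  pmax_ <- apply(as.matrix(st[pcols]), 1, max)
  out <- list(node = object$node_label, model = object$model$name,
              n_sites = nrow(st), loglik = object$loglik,
              map_sequence = paste(st$state, collapse = ""),
              min_top_posterior = min(pmax_),
              n_confident = sum(pmax_ > 0.9))
  class(out) <- "summary.asr"
  out
}

#' @export
print.summary.asr <- function(x, ...) {
  cat(sprintf("ASR at node '%s' (model %s)\n", x$node, x$model))
  cat(sprintf("  sites: %d; log-likelihood: %.4f\n", x$n_sites, x$loglik))
  cat(sprintf("  MAP sequence: %s\n", x$map_sequence))
  cat(sprintf("  sites with top posterior > 0.9: %d/%d (min top %.4f)\n",
              x$n_confident, x$n_sites, x$min_top_posterior))
  invisible(x)
}

#' @export
logLik.asr <- function(object, ...) {
  structure(object$loglik, df = 0L, nobs = length(object$loglik_sites),
            class = "logLik")
}

#' Full reconstruction pipeline: root, locate ancestor, reconstruct
#'
#' Roots the tree on the outgroup, finds the most recent common ancestor of
#' the ingroup taxa, and runs marginal reconstruction there for all sites.
#'
#' @inheritParams site_log_likelihood
#' @param outgroup Character vector of outgroup tip labels (must form one
#'   side of a bipartition).
#' @param ingroup Character vector of ingroup tip labels whose MRCA is the
#'   target ancestor.
#' @param quiet Suppress progress messages.
#' @return A [state_table] of per-site posteriors at the ancestor.
#' @export
run_asr_pipeline <- function(aln, tree, model, outgroup, ingroup,
                             quiet = FALSE) {
  rooted <- root_on_outgroup(tree, outgroup)
  node <- mrca_node(rooted, ingroup)
  if (node <= length(rooted$tip.label))
    stop("ingroup MRCA is a leaf; supply at least two ingroup taxa")
  fit <- asr(aln, rooted, model, node)
  if (!quiet) {
    message(sprintf("model %s; target node %s (%d ingroup taxa)",
                    model$name, fit$node_label, length(ingroup)))
    message(sprintf("log-likelihood %.4f over %d sites; MAP sequence %s",
                    fit$loglik, length(fit$loglik_sites),
                    paste(fit$state_table$state, collapse = "")))
  }
  fit$state_table
}
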