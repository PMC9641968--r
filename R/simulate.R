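# Sequence simulation along a phylogeny with ground-truth bookkeeping, so
# every analysis stage can be tested end to end against known internal
# states without any external data.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specify a simulation
#'
#' @param n_leaves Ingroup leaf count (>= 2) when no tree is supplied.
#' @param n_sites Number of alignment columns (>= 1).
#' @param model A [substitution_model()]; default LG with 4-category
#'   discrete gamma, shape 1 (a typical level of among-site rate variation
#'   for protein alignments).
#' @param tree Optional user `phylo`; when `NULL` a random topology is
#'   grown by successive random leaf attachment with iid exponential branch
#'   lengths of mean `branch_scale`.
#' @param branch_scale Mean branch length (expected substitutions/site) for
#'   generated trees, and a multiplier applied to supplied trees when
#'   `scale_tree = TRUE`.
#' @param outgroup_size When > 0 and no tree is supplied, a separate
#'   outgroup clade of this many leaves (labelled `og*`) is attached sister
#'   to the ingroup (labelled `in*`), so rooting and MRCA extraction can be
#'   exercised; the ingroup MRCA is then the natural reconstruction target.
#' @param root_seq `"pi"` (draw the root sequence from the equilibrium
#'   frequencies) or a fixed residue string of length `n_sites`.
#' @param slow_columns,fast_columns Columns forced to the slowest / fastest
#'   rate category, emulating conserved panel sites vs. variable sites; all
#'   other columns draw their category from the mixture weights.
#' @param scale_tree Multiply supplied tree branch lengths by
#'   `branch_scale`.
#' @param seed Integer seed; mandatory (every randomised call is
#'   reproducible, and no global RNG state is left behind).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_leaves = 20L, n_sites = 200L,
                            model = load_model("LG",
                                               categories = list(alpha = 1, k = 4)),
                            tree = NULL, branch_scale = 0.3,
                            outgroup_size = 0L, root_seq = "pi",
                            slow_columns = integer(0),
                            fast_columns = integer(0),
                            scale_tree = FALSE, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  n_leaves <- as.integer(n_leaves)
  n_sites <- as.integer(n_sites)
  if (n_leaves < 2L) stop("n_leaves must be >= 2")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (branch_scale <= 0) stop("branch_scale must be positive")
  stopifnot(inherits(model, "subst_model"))
  if (!identical(root_seq, "pi")) {
    root_seq <- toupper(root_seq)
    if (nchar(root_seq) != n_sites)
      stop("fixed root sequence must have n_sites characters")
    if (!all(strsplit(root_seq, "")[[1]] %in% model$alphabet))
      stop("fixed root sequence contains characters outside the alphabet")
  }
  bad <- setdiff(c(slow_columns, fast_columns), seq_len(n_sites))
  if (length(bad)) stop("rate-forced column(s) out of range")
  if (length(intersect(slow_columns, fast_columns)))
    stop("a column cannot be both slow and fast")
  structure(list(n_leaves = n_leaves, n_sites = n_sites, model = model,
                 tree = tree, branch_scale = branch_scale,
                 outgroup_size = as.integer(outgroup_size),
                 root_seq = root_seq,
                 slow_columns = as.integer(slow_columns),
                 fast_columns = as.integer(fast_columns),
                 scale_tree = isTRUE(scale_tree),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

random_tree <- function(n, scale, prefix = "t") {
  tr <- ape::rtree(n, rooted = TRUE, br = stats::rexp, rate = 1 / scale)
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr
}

join_clades <- function(ingroup, outgroup, stem) {
  txt <- paste0("(",
                sub(";$", "", write_newick(outgroup)), ":",
                sprintf("%.17g", stem), ",",
                sub(";$", "", write_newick(ingroup)), ":",
                sprintf("%.17g", stem), ");")
  ape::read.tree(text = txt)
}

#' Simulate an alignment along a phylogeny
#'
#' The root sequence is drawn per the spec's policy; each branch then
#' evolves each site by sampling from the corresponding row of
#' `transition_probs(Q, t, r_site)`. Identical seeds give identical output.
#'
#' @param spec A [simulation_spec()].
#' @return List with `alignment` (a [protein_alignment]), `tree` (rooted
#'   `phylo`) and `truth`: ground-truth bookkeeping holding `states` (a
#'   character matrix of every node's sequence, rows named by tip label /
#'   `Node<k>`), `root` (root sequence string), `site_category` (integer
#'   per column), `ingroup`/`outgroup` tip labels.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    model <- spec$model
    nst <- length(model$alphabet)
    S <- spec$n_sites
    Q <- build_rate_matrix(model)
    cats <- model$categories
    K <- nrow(cats)

    if (is.null(spec$tree)) {
      ing <- random_tree(spec$n_leaves, spec$branch_scale, "in")
      if (spec$outgroup_size > 0L) {
        og <- if (spec$outgroup_size == 1L) {
          structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = "og1",
                         edge.length = stats::rexp(1, 1 / spec$branch_scale),
                         Nnode = 1L), class = "phylo")
        } else random_tree(spec$outgroup_size, spec$branch_scale, "og")
        tree <- join_clades(ing, og, stem = spec$branch_scale)
      } else tree <- ing
    } else {
      tree <- spec$tree
      if (spec$scale_tree) tree$edge.length <- tree$edge.length * spec$branch_scale
    }
    validate_tree(tree)
    if (!ape::is.rooted(tree)) stop("simulation needs a rooted tree")

    site_cat <- sample.int(K, S, replace = TRUE, prob = cats$weight)
    if (length(spec$slow_columns))
      site_cat[spec$slow_columns] <- which.min(cats$rate)
    if (length(spec$fast_columns))
      site_cat[spec$fast_columns] <- which.max(cats$rate)

    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    states <- matrix(NA_integer_, nnode, S)
    states[root, ] <- if (identical(spec$root_seq, "pi"))
      sample.int(nst, S, replace = TRUE, prob = model$pi)
    else match(strsplit(spec$root_seq, "")[[1]], model$alphabet)

    tr <- stats::reorder(tree, "postorder")
    for (e in rev(seq_len(nrow(tr$edge)))) {  # pre-order: parent known
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      len <- tr$edge.length[e]
      for (k in unique(site_cat)) {
        idx <- which(site_cat == k)
        P <- transition_probs(Q, len, cats$rate[k])
        px <- states[par, idx]
        for (x in unique(px)) {
          sub <- idx[px == x]
          states[ch, sub] <- sample.int(nst, length(sub), replace = TRUE,
                                        prob = P[x, ])
        }
      }
    }

    letters_of <- function(v) paste(model$alphabet[v], collapse = "")
    node_ids <- c(tree$tip.label,
                  vapply((ntip + 1L):nnode, function(v) node_id(tree, v),
                         character(1)))
    seqmat <- matrix(model$alphabet[states], nrow = nnode,
                     dimnames = list(node_ids, NULL))
    aln <- protein_alignment(tree$tip.label,
                             apply(seqmat[seq_len(ntip), , drop = FALSE],
                                   1, paste, collapse = ""))
    truth <- list(states = seqmat,
                  root = letters_of(states[root, ]),
                  site_category = site_cat,
                  ingroup = grep("^in", tree$tip.label, value = TRUE),
                  outgroup = grep("^og", tree$tip.label, value = TRUE))
    list(alignment = aln, tree = tree, truth = truth)
  })
}

#' Generate a small extant-diversity fixture
#'
#' Emulates the qualitative structure of extant nitrogenase diversity at
#' five panel columns: one clade fixed on the tuple `LMNGG`, a second fixed
#' on `AINGG`, and a heterogeneous divergent clade drawing residues from
#' per-column frequency profiles. Non-panel columns are invariant. Expected
#' tuple counts are returned as bookkeeping so downstream classification
#' can be tested against known answers.
#'
#' @param seed Integer seed (mandatory).
#' @param n_clade1,n_clade2,n_divergent Sequences per clade.
#' @param profiles Optional named list (one entry per panel column, by
#'   ascending column) of named residue-frequency vectors for the divergent
#'   clade.
#' @return List with `alignment`, `clades` (named vector id -> clade tag),
#'   `columns` (the five panel columns), `profiles`, `tuples` (ground-truth
#'   residue tuple per sequence id, as generated) and `expected_counts`
#'   (tuple -> total count, tallied from the ground truth).
#' @export
make_extant_fixture <- function(seed, n_clade1 = 25L, n_clade2 = 25L,
                                n_divergent = 10L, profiles = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  columns <- c(5L, 10L, 15L, 20L, 25L)
  len <- 30L
  if (is.null(profiles))
    profiles <- list(`5`  = c(A = 0.4, Q = 0.2, L = 0.2, K = 0.2),
                     `10` = c(A = 0.5, M = 0.3, I = 0.2),
                     `15` = c(E = 0.4, T = 0.3, G = 0.2, N = 0.1),
                     `20` = c(G = 0.7, A = 0.3),
                     `25` = c(A = 0.5, G = 0.5))
  if (length(profiles) != 5L)
    stop("profiles must list one frequency vector per panel column")
  with_seed(seed, {
    background <- sample(AA_STATES, len, replace = TRUE)
    base <- function() background
    mk <- function(tuple) {
      s <- base()
      s[columns] <- tuple
      paste(s, collapse = "")
    }
    ids <- c(sprintf("c1_%02d", seq_len(n_clade1)),
             sprintf("c2_%02d", seq_len(n_clade2)),
             sprintf("dv_%02d", seq_len(n_divergent)))
    clades <- stats::setNames(rep(c("clade1", "clade2", "divergent"),
                                  c(n_clade1, n_clade2, n_divergent)), ids)
    tuples <- c(replicate(n_clade1, "LMNGG"),
                replicate(n_clade2, "AINGG"),
                replicate(n_divergent, paste(vapply(profiles, function(p)
                  sample(names(p), 1, prob = p), character(1)),
                  collapse = "")))
    names(tuples) <- ids
    seqs <- vapply(tuples, function(tt)
      mk(strsplit(tt, "", fixed = TRUE)[[1]]), character(1))
    aln <- protein_alignment(ids, seqs)
    list(alignment = aln, clades = clades, columns = columns,
         profiles = profiles, tuples = tuples,
         expected_counts = table(tuples))
  })
}
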