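# Brute-force likelihood/posterior oracle: sums explicitly over all joint
# assignments of states to internal nodes (and over rate categories),
# independently of the pruning recursion it checks.

aa20 <- ancsr:::AA_STATES

# site likelihood by exhaustive enumeration over internal-node states;
# `states` is a named character vector tip label -> residue (single site).
# Internal node ntip+j corresponds to grid column j (ape numbers the root
# of a rooted tree ntip+1).
bf_loglik <- function(tree, states, model) {
  Q <- build_rate_matrix(model)
  cats <- model$categories
  ab <- model$alphabet
  ntip <- length(tree$tip.label)
  grid <- as.matrix(expand.grid(rep(list(seq_along(ab)), tree$Nnode)))
  tip_state <- match(states[tree$tip.label], ab)
  state_of <- function(v) {
    if (v <= ntip) rep(tip_state[v], nrow(grid)) else grid[, v - ntip]
  }
  total <- 0
  for (k in seq_len(nrow(cats))) {
    w <- model$pi[grid[, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_probs(Q, tree$edge.length[e], cats$rate[k])
      w <- w * P[cbind(state_of(tree$edge[e, 1]),
                       state_of(tree$edge[e, 2]))]
    }
    total <- total + cats$weight[k] * sum(w)
  }
  log(total)
}

# posterior at an internal node by the same enumeration
bf_posterior <- function(tree, states, model, node) {
  Q <- build_rate_matrix(model)
  cats <- model$categories
  ab <- model$alphabet
  nst <- length(ab)
  ntip <- length(tree$tip.label)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), tree$Nnode)))
  tip_state <- match(states[tree$tip.label], ab)
  state_of <- function(v) {
    if (v <= ntip) rep(tip_state[v], nrow(grid)) else grid[, v - ntip]
  }
  joint <- numeric(nst)
  for (k in seq_len(nrow(cats))) {
    w <- model$pi[grid[, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_probs(Q, tree$edge.length[e], cats$rate[k])
      w <- w * P[cbind(state_of(tree$edge[e, 1]),
                       state_of(tree$edge[e, 2]))]
    }
    tgt <- grid[, node - ntip]
    joint <- joint + cats$weight[k] *
      vapply(seq_len(nst), function(x) sum(w[tgt == x]), numeric(1))
  }
  joint / sum(joint)
}

read_newick_text <- function(txt) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(txt, tf)
  on.exit(unlink(tf))
  read_newick(tf)
}

# small reversible model on a reduced alphabet (test hook)
toy_model <- function(n = 4, categories = "uniform", seed = 1) {
  set.seed(seed)
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- stats::runif(n * (n - 1) / 2, 0.2, 2)
  S <- S + t(S)
  pi <- stats::runif(n, 0.5, 1.5)
  pi <- pi / sum(pi)
  substitution_model(S, pi, categories = categories,
                     alphabet = LETTERS[seq_len(n)])
}

single_site_aln <- function(states) {
  protein_alignment(names(states), unname(states))
}

lg_uniform <- function() load_model("LG")
lg_gamma <- function() load_model("LG", categories = list(alpha = 1, k = 4))
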