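# Reversible amino-acid substitution models: packaged empirical
# exchangeabilities (PAML lower-triangle .dat dialect), a rate-heterogeneity
# mixture, and transition probabilities via spectral decomposition of the
# symmetrised generator.

#' Read a PAML-style substitution-model file
#'
#' The dialect is the standard lower-triangle text layout: 19 rows of
#' exchangeabilities (residue order A R N D C Q E G H I L K M F P S T W Y V)
#' followed by the 20 equilibrium frequencies.
#'
#' @param path Path to a `.dat` file.
#' @return List with `S` (symmetric 20x20 exchangeability matrix, zero
#'   diagonal, alphabetical residue order) and `pi` (named frequency vector).
#' @export
read_paml_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nums <- scan(path, quiet = TRUE, comment.char = "#")
  if (length(nums) < 210)
    stop("expected at least 210 numbers (190 exchangeabilities + 20 ",
         "frequencies) in ", path)
  ex <- nums[1:190]
  pi <- nums[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_PAML, AA_PAML))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- ex[k]
    k <- k + 1L
  }
  names(pi) <- AA_PAML
  # canonical alphabetical order internally
  S <- S[AA_STATES, AA_STATES]
  pi <- pi[AA_STATES]
  pi <- pi / sum(pi)
  list(S = S, pi = pi)
}

#' Discretised gamma rate categories
#'
#' Equal-probability bins of a mean-one gamma distribution, each represented
#' by its category-mean rate (the conventional discretisation).
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories (>= 1).
#' @return data.frame with columns `weight` and `rate`; weights are `1/k`
#'   and the weighted mean rate is 1 (renormalised exactly).
#' @export
discrete_gamma <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  k <- as.integer(k)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # bin mean of X ~ Gamma(alpha, alpha): uses the shape+1 incomplete gamma
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- diff(cum) * k
  rates <- rates / sum(rates / k)  # exact mean-one normalisation
  data.frame(weight = rep(1 / k, k), rate = rates)
}

#' Explicit rate categories (free-rate style)
#'
#' Accepts externally fitted (weight, rate) pairs, e.g. copied from a
#' maximum-likelihood log; this package never fits them. Rates are rescaled
#' to weighted mean one if they deviate.
#'
#' @param weights Numeric category weights; must sum to 1 within `1e-6`.
#' @param rates Nonnegative category rates.
#' @return data.frame with columns `weight` and `rate`.
#' @export
rate_categories <- function(weights, rates) {
  if (length(weights) != length(rates) || !length(weights))
    stop("weights and rates must be non-empty and of equal length")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("category weights must sum to 1 (got ", sum(weights), ")")
  weights <- weights / sum(weights)
  m <- sum(weights * rates)
  if (m <= 0) stop("mean rate must be positive")
  if (abs(m - 1) > 1e-8) {
    message("rescaling rate categories to weighted mean 1 (was ",
            format(m), ")")
    rates <- rates / m
  }
  data.frame(weight = weights, rate = rates)
}

normalize_categories <- function(categories) {
  if (is.null(categories)) categories <- "uniform"
  if (is.character(categories) && length(categories) == 1 &&
      categories == "uniform")
    return(data.frame(weight = 1, rate = 1))
  if (is.list(categories) && !is.data.frame(categories) &&
      all(c("alpha", "k") %in% names(categories)))
    return(discrete_gamma(categories$alpha, categories$k))
  if (is.data.frame(categories) &&
      all(c("weight", "rate") %in% names(categories)))
    return(rate_categories(categories$weight, categories$rate))
  stop("categories must be \"uniform\", list(alpha=, k=) or a ",
       "data.frame(weight, rate)")
}

#' Construct a substitution model
#'
#' General constructor, also usable with reduced alphabets for testing and
#' simulation on toy state spaces.
#'
#' @param S Symmetric nonnegative exchangeability matrix, zero diagonal.
#' @param pi Positive equilibrium frequencies summing to 1.
#' @param categories Rate mixture: `"uniform"`, `list(alpha=, k=)` for
#'   discrete gamma, or a `data.frame(weight, rate)`.
#' @param name Model name.
#' @param alphabet State labels; defaults to dimnames of `S` or the 20
#'   residues.
#' @return Object of class `subst_model`.
#' @export
substitution_model <- function(S, pi, categories = "uniform",
                               name = "custom", alphabet = NULL) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (is.null(alphabet))
    alphabet <- if (!is.null(rownames(S))) rownames(S) else
      if (n == 20) AA_STATES else as.character(seq_len(n))
  if (ncol(S) != n || length(pi) != n)
    stop("S must be square and pi of matching length")
  if (max(abs(S - t(S))) > 1e-12) stop("S must be symmetric")
  if (any(S < 0)) stop("S must be nonnegative")
  diag(S) <- 0
  if (any(pi <= 0)) stop("all equilibrium frequencies must be positive")
  if (abs(sum(pi) - 1) > 1e-9) {
    if (abs(sum(pi) - 1) > 1e-4)
      stop("equilibrium frequencies must sum to 1")
    pi <- pi / sum(pi)
  }
  dimnames(S) <- list(alphabet, alphabet)
  names(pi) <- alphabet
  cats <- normalize_categories(categories)
  structure(list(name = name, alphabet = alphabet, S = S, pi = pi,
                 categories = cats),
            class = "subst_model")
}

#' Load a packaged (or custom) amino-acid substitution model
#'
#' @param name `"LG"`, `"WAG"` or `"BLOSUM62"` (packaged PAML-style files),
#'   or a path to a custom `.dat` file.
#' @param categories Rate mixture specification; see [substitution_model()].
#' @return Object of class `subst_model`.
#' @export
load_model <- function(name = c("LG", "WAG", "BLOSUM62"),
                       categories = "uniform") {
  if (length(name) == 1 && file.exists(name) &&
      !(toupper(name) %in% c("LG", "WAG", "BLOSUM62"))) {
    mat <- read_paml_matrix(name)
    label <- tools::file_path_sans_ext(basename(name))
  } else {
    name <- toupper(name[1])
    if (!name %in% c("LG", "WAG", "BLOSUM62"))
      stop("unknown model '", name,
           "'; packaged models are LG, WAG, BLOSUM62")
    path <- system.file("extdata", paste0(tolower(name), ".dat"),
                        package = "ancsr", mustWork = TRUE)
    mat <- read_paml_matrix(path)
    label <- name
  }
  substitution_model(mat$S, mat$pi, categories = categories, name = label)
}

#' Build the instantaneous rate matrix Q
#'
#' `Q[i, j] = S[i, j] * pi[j]` off the diagonal; the diagonal makes rows sum
#' to zero and the matrix is rescaled so the mean rate at equilibrium,
#' `-sum(pi * diag(Q))`, is one (branch lengths are then expected
#' substitutions per site). The spectral decomposition of the symmetrised
#' generator is cached on the result for fast transition probabilities.
#'
#' @param model A [substitution_model()].
#' @return Matrix of class `rate_matrix` with attributes `pi` and `eig`.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "subst_model"))
  pi <- model$pi
  Q <- model$S %*% diag(pi)
  dimnames(Q) <- dimnames(model$S)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate model: zero substitution rate")
  Q <- Q / mu
  # reversible Q is similar to the symmetric B = D^{1/2} Q D^{-1/2}
  d <- sqrt(pi)
  B <- (Q * d) / rep(d, each = nrow(Q))  # d_i Q_ij / d_j
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / d        # D^{-1/2} V
  Uinv <- t(eig$vectors * d)  # V' D^{1/2}
  structure(Q, pi = pi, eig = list(values = eig$values, U = U, Uinv = Uinv),
            class = "rate_matrix")
}

#' Transition probabilities P(t) = exp(Q t r)
#'
#' @param Q A [build_rate_matrix()] result.
#' @param t Branch length (>= 0, expected substitutions/site).
#' @param r Rate-category multiplier (>= 0, default 1).
#' @return Stochastic matrix; rows sum to 1 within `1e-9`. Entries a hair
#'   outside `[0, 1]` from floating-point roundoff are clamped.
#' @export
transition_probs <- function(Q, t, r = 1) {
  stopifnot(inherits(Q, "rate_matrix"))
  if (!is.finite(t) || !is.finite(r)) stop("t and r must be finite")
  if (t < 0 || r < 0) stop("t and r must be nonnegative")
  e <- attr(Q, "eig")
  P <- e$U %*% (exp(e$values * t * r) * e$Uinv)
  viol <- max(0, max(-P), max(P - 1))
  if (viol > 1e-8)
    warning("transition probabilities clamped by ", format(viol))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model '%s': %d states, %d rate categor%s\n",
              x$name, length(x$alphabet), nrow(x$categories),
              if (nrow(x$categories) == 1) "y" else "ies"))
  if (nrow(x$categories) > 1) {
    cat("  rates:  ", paste(signif(x$categories$rate, 4), collapse = " "), "\n")
    cat("  weights:", paste(signif(x$categories$weight, 4), collapse = " "), "\n")
  }
  invisible(x)
}
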