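test_that("packaged models satisfy the reversible-model invariants", {
  for (nm in c("LG", "WAG", "BLOSUM62")) {
    m <- load_model(nm)
    expect_equal(max(abs(m$S - t(m$S))), 0)
    expect_true(all(m$S >= 0))
    expect_equal(sum(m$pi), 1, tolerance = 1e-9)
    expect_true(all(m$pi > 0))
    Q <- build_rate_matrix(m)
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    db <- m$pi * Q - t(m$pi * Q)  # pi_i Q_ij - pi_j Q_ji
    expect_lt(max(abs(db)), 1e-10)
    expect_equal(-sum(m$pi * diag(Q)), 1, tolerance = 1e-9)
  }
})

test_that("rate mixtures: uniform, gamma limits, explicit free rates", {
  m <- load_model("LG")
  expect_equal(nrow(m$categories), 1L)
  expect_equal(sum(m$categories$weight * m$categories$rate), 1)

  g <- discrete_gamma(alpha = 1e6, k = 4)
  expect_equal(g$rate, rep(1, 4), tolerance = 1e-3)
  g2 <- discrete_gamma(alpha = 0.5, k = 8)
  expect_equal(sum(g2$weight), 1, tolerance = 1e-12)
  expect_equal(sum(g2$weight * g2$rate), 1, tolerance = 1e-12)
  expect_true(all(diff(g2$rate) > 0))

  fr <- rate_categories(weights = c(0.2, 0.3, 0.5), rates = c(0.1, 0.5, 1.66))
  expect_equal(sum(fr$weight * fr$rate), 1, tolerance = 1e-12)
  expect_error(rate_categories(c(0.5, 0.6), c(1, 1)), "sum to 1")
})

test_that("gamma category means match a Monte Carlo quantile-bin oracle", {
  # equal-probability bins of Gamma(alpha, alpha): compare category means
  # against empirical bin means of a large iid sample
  alpha <- 1
  k <- 4
  g <- discrete_gamma(alpha, k)
  set.seed(404)
  x <- sort(stats::rgamma(2e5, shape = alpha, rate = alpha))
  emp <- colMeans(matrix(x, ncol = k))
  expect_equal(g$rate, unname(emp), tolerance = 0.02)
})

test_that("two-state toy model yields the closed-form generator", {
  m <- substitution_model(S = matrix(c(0, 1, 1, 0), 2),
                          pi = c(0.5, 0.5), alphabet = c("A", "B"))
  Q <- build_rate_matrix(m)
  expect_equal(unclass(Q), matrix(c(-1, 1, 1, -1), 2,
                                  dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)
})

test_that("transition probabilities: identity, ergodic limit, stochasticity", {
  m <- load_model("LG")
  Q <- build_rate_matrix(m)
  expect_equal(unclass(transition_probs(Q, 0)), diag(20), ignore_attr = TRUE,
               tolerance = 1e-12)
  Pinf <- transition_probs(Q, 1e4)
  for (i in c(1, 7, 20))
    expect_equal(unname(Pinf[i, ]), unname(m$pi), tolerance = 1e-6)
  P <- transition_probs(Q, 0.37)
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(P >= 0 & P <= 1))
  expect_error(transition_probs(Q, NaN), "finite")
})

test_that("Chapman-Kolmogorov and stationarity hold across models and rates", {
  set.seed(11)
  for (nm in c("LG", "WAG", "BLOSUM62")) {
    m <- load_model(nm)
    Q <- build_rate_matrix(m)
    for (i in 1:3) {
      t1 <- stats::runif(1, 0, 2)
      t2 <- stats::runif(1, 0, 2)
      r <- stats::runif(1, 0.1, 3)
      lhs <- transition_probs(Q, t1, r) %*% transition_probs(Q, t2, r)
      rhs <- transition_probs(Q, t1 + t2, r)
      expect_lt(max(abs(lhs - rhs)), 1e-8)
      # pi is a left eigenvector of P(t) with eigenvalue 1
      expect_lt(max(abs(m$pi %*% rhs - m$pi)), 1e-8)
    }
  }
})

test_that("model loading validates names and category specs", {
  expect_error(load_model("JTT"), "unknown model")
  expect_error(load_model("LG", categories = data.frame(weight = c(.5, .6),
                                                        rate = c(1, 1))),
               "sum to 1")
  expect_error(substitution_model(matrix(c(0, 1, 2, 0), 2), c(.5, .5)),
               "symmetric")
})
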