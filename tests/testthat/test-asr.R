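test_that("pruning likelihood matches closed forms on degenerate trees", {
  m <- lg_uniform()
  # single leaf: stationarity gives log pi regardless of branch length
  tr1 <- read_newick_text("(a:0.3);")
  expect_equal(site_log_likelihood(tr1, single_site_aln(c(a = "A")), m),
               unname(log(m$pi["A"])), tolerance = 1e-12)
  # two identical leaves joined by zero-length branches
  tr2 <- read_newick_text("(a:0,b:0);")
  expect_equal(site_log_likelihood(tr2, single_site_aln(c(a = "W", b = "W")), m),
               unname(log(m$pi["W"])), tolerance = 1e-12)
  # fully ambiguous partner contributes nothing
  tr3 <- read_newick_text("(a:0.4,b:0.7);")
  expect_equal(site_log_likelihood(tr3, single_site_aln(c(a = "A", b = "X")), m),
               unname(log(m$pi["A"])), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on trees up to 5 leaves", {
  cases <- list(
    list(nwk = "((a:0.1,b:0.3):0.2,c:0.5);",
         st = c(a = "A", b = "G", c = "A")),
    list(nwk = "((a:0.1,b:0.25):0.15,(c:0.3,d:0.05):0.2);",
         st = c(a = "A", b = "A", c = "G", d = "A")),
    list(nwk = "(((a:0.2,b:0.1):0.1,c:0.4):0.3,d:0.6);",
         st = c(a = "L", b = "M", c = "K", d = "L")),
    list(nwk = "(((a:0.2,b:0.1):0.15,(c:0.3,d:0.2):0.1):0.25,e:0.5);",
         st = c(a = "S", b = "T", c = "S", d = "A", e = "G"))
  )
  for (model in list(lg_uniform(), lg_gamma())) {
    for (cs in cases) {
      tr <- read_newick_text(cs$nwk)
      aln <- single_site_aln(cs$st)
      expect_equal(site_log_likelihood(tr, aln, model),
                   bf_loglik(tr, cs$st, model), tolerance = 1e-10)
    }
  }
})

test_that("marginal posteriors match brute-force marginalisation (<= 5 leaves)", {
  cases <- list(
    list(nwk = "((a:0.1,b:0.25):0.15,(c:0.3,d:0.05):0.2);",
         st = c(a = "A", b = "A", c = "G", d = "A"), nodes = c(5, 6, 7)),
    list(nwk = "(((a:0.2,b:0.1):0.15,(c:0.3,d:0.2):0.1):0.25,e:0.5);",
         st = c(a = "S", b = "T", c = "S", d = "A", e = "G"),
         nodes = c(6, 7, 8, 9))
  )
  for (model in list(lg_uniform(), lg_gamma())) {
    for (cs in cases) {
      tr <- read_newick_text(cs$nwk)
      aln <- single_site_aln(cs$st)
      for (nd in cs$nodes) {
        st <- marginal_asr(tr, aln, model, nd, sites = 1)
        ours <- as.numeric(st[1, paste0("p_", aa20)])
        expect_equal(ours, unname(bf_posterior(tr, cs$st, model, nd)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("posterior closed forms: zero branches pin the state, long branches give pi", {
  m <- lg_uniform()
  tr <- read_newick_text("((a:0,b:0):0,(c:0,d:0):0);")
  aln <- single_site_aln(c(a = "H", b = "H", c = "H", d = "H"))
  st <- marginal_asr(tr, aln, m, 6, sites = 1)
  expect_equal(unname(as.numeric(st[1, "p_H"])), 1, tolerance = 1e-12)
  tr2 <- read_newick_text("((a:1e4,b:1e4):1e4,(c:1e4,d:1e4):1e4);")
  st2 <- marginal_asr(tr2, aln, m, 6, sites = 1)
  expect_equal(as.numeric(st2[1, paste0("p_", aa20)]), unname(m$pi),
               tolerance = 1e-6)
})

test_that("log-likelihood is invariant to root placement (reversibility)", {
  for (seed in c(9, 41)) {
    sim <- simulate_alignment(simulation_spec(n_leaves = 7, n_sites = 12,
                                              outgroup_size = 2, seed = seed))
    for (model in list(lg_uniform(), lg_gamma())) {
      ll0 <- site_log_likelihood(sim$tree, sim$alignment, model)
      for (og in list(sim$truth$outgroup, sim$truth$ingroup[1],
                      sim$truth$ingroup[2])) {
        rr <- root_on_outgroup(sim$tree, og)
        expect_equal(site_log_likelihood(rr, sim$alignment, model), ll0,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("marginal posteriors are invariant to the original root placement", {
  sim <- simulate_alignment(simulation_spec(n_leaves = 6, n_sites = 8,
                                            outgroup_size = 2, seed = 77))
  model <- lg_gamma()
  clade <- sim$truth$ingroup
  r1 <- root_on_outgroup(sim$tree, sim$truth$outgroup)
  # rooting on a single outgroup leaf keeps the ingroup clade intact
  r2 <- root_on_outgroup(sim$tree, sim$truth$outgroup[1])
  st1 <- marginal_asr(r1, sim$alignment, model, mrca_node(r1, clade))
  st2 <- marginal_asr(r2, sim$alignment, model, mrca_node(r2, clade))
  expect_equal(as.matrix(st1[ancsr:::P_COLS]), as.matrix(st2[ancsr:::P_COLS]),
               tolerance = 1e-9)
})

test_that("the asr() fit exposes the reconstruction and likelihood", {
  sim <- simulate_alignment(simulation_spec(n_leaves = 5, n_sites = 10,
                                            seed = 13))
  fit <- asr(sim$alignment, sim$tree, lg_gamma(), node = 6)
  expect_s3_class(fit, "asr")
  expect_s3_class(fit$state_table, "state_table")
  expect_equal(nrow(fit$state_table), 10L)
  expect_equal(fit$loglik, sum(fit$loglik_sites))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "Marginal ancestral reconstruction")
  expect_output(print(summary(fit)), "MAP sequence")
  expect_error(asr(sim$alignment, sim$tree, lg_uniform(), node = 1),
               "leaf")
})

test_that("the pipeline wrapper equals a direct marginal_asr call", {
  sim <- simulate_alignment(simulation_spec(n_leaves = 4, n_sites = 6,
                                            outgroup_size = 1, seed = 19))
  model <- lg_uniform()
  st <- run_asr_pipeline(sim$alignment, sim$tree, model,
                         sim$truth$outgroup, sim$truth$ingroup, quiet = TRUE)
  rooted <- root_on_outgroup(sim$tree, sim$truth$outgroup)
  st2 <- marginal_asr(rooted, sim$alignment, model,
                      mrca_node(rooted, sim$truth$ingroup))
  expect_equal(as.matrix(st[ancsr:::P_COLS]), as.matrix(st2[ancsr:::P_COLS]),
               tolerance = 1e-12)
  # posterior rows always normalised
  expect_equal(unname(rowSums(st[ancsr:::P_COLS])), rep(1, nrow(st)),
               tolerance = 1e-9)
})

test_that("engine errors are actionable", {
  tr <- read_newick_text("((a:0.1,b:0.3):0.2,c:0.5);")
  aln <- single_site_aln(c(a = "A", b = "G"))
  expect_error(site_log_likelihood(tr, aln, lg_uniform()),
               "leaf without alignment row: c")
  aln3 <- single_site_aln(c(a = "A", b = "G", c = "A"))
  expect_error(marginal_asr(tr, aln3, lg_uniform(), 1), "leaf")
  un <- read_newick_text("(a:0.1,b:0.2,c:0.3);")
  expect_error(site_log_likelihood(un, aln3, lg_uniform()), "rooted")
})
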