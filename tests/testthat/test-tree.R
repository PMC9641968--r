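test_that("Newick parsing reports leaves, internals and rootedness", {
  tr <- read_newick_text("((a:0.1,b:0.2):0.05,c:0.3);")
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(tr$Nnode, 2L)
  un <- read_newick_text("(a:0.1,b:0.2,c:0.3);")
  expect_false(ape::is.rooted(un))
  expect_equal(un$Nnode, 1L)  # basal trifurcation collapses to one node
})

test_that("malformed Newick input is rejected", {
  tf <- tempfile()
  writeLines("((a:0.1,b:0.2:0.05,c:0.3);", tf)
  expect_error(read_newick(tf), "parenthes|parse")
  writeLines("(a:0.1,b:-0.2,c:0.3);", tf)
  expect_error(read_newick(tf), "negative branch length")
})

test_that("Newick write -> read is topology- and length-identical", {
  for (seed in c(3, 17, 99)) {
    sim <- simulate_alignment(simulation_spec(n_leaves = 12, n_sites = 1,
                                              outgroup_size = 3, seed = seed))
    tr <- sim$tree
    tf <- tempfile(fileext = ".nwk")
    write_newick(tr, tf)
    tr2 <- read_newick(tf)
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
    expect_equal(d1, d2, tolerance = 1e-15)
  }
})

test_that("rooting on an outgroup splits the separating branch equally", {
  tr <- read_newick_text("(a:1,b:1,(c:1,d:1):2);")
  rooted <- root_on_outgroup(tr, "a")
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  sets <- lapply(kids, function(v) sort(node_tips(rooted, v)))
  expect_true(any(vapply(sets, identical, logical(1), "a")))
  expect_true(any(vapply(sets, identical, logical(1), c("b", "c", "d"))))
  lens <- rooted$edge.length[rooted$edge[, 1] == root]
  expect_equal(lens, c(0.5, 0.5))
  expect_equal(tree_length(rooted), tree_length(tr), tolerance = 1e-12)
})

test_that("non-monophyletic outgroups are refused with the violating leaves", {
  tr <- read_newick_text("(a:1,b:1,(c:1,d:1):2);")
  expect_error(root_on_outgroup(tr, c("a", "c")), "not monophyletic")
  expect_error(root_on_outgroup(tr, c("a", "q")), "not in tree.*q")
  expect_error(root_on_outgroup(tr, c("a", "b", "c", "d")), "proper subset")
})

test_that("re-rooting conserves total branch length and the leaf set", {
  for (seed in c(5, 23)) {
    sim <- simulate_alignment(simulation_spec(n_leaves = 8, n_sites = 1,
                                              outgroup_size = 4, seed = seed))
    tr <- sim$tree
    rooted <- root_on_outgroup(tr, sim$truth$outgroup)
    expect_equal(tree_length(rooted), tree_length(tr), tolerance = 1e-12)
    expect_setequal(rooted$tip.label, tr$tip.label)
    root <- length(rooted$tip.label) + 1L
    expect_equal(sum(rooted$edge[, 1] == root), 2L)
  }
})

test_that("MRCA matches a brute-force ancestor-set intersection", {
  expect_equal(mrca_node(read_newick_text("((a:1,b:1):1,c:1);"), "a"), 1L)
  for (seed in c(2, 31)) {
    sim <- simulate_alignment(simulation_spec(n_leaves = 9, n_sites = 1,
                                              seed = seed))
    tr <- sim$tree
    root <- length(tr$tip.label) + 1L
    expect_equal(mrca_node(tr, tr$tip.label), root)
    # brute force: intersect each taxon's ancestor chain, take the deepest
    parent_of <- integer(max(tr$edge))
    parent_of[tr$edge[, 2]] <- tr$edge[, 1]
    chain <- function(tip) {
      v <- match(tip, tr$tip.label)
      anc <- v
      while (v != root) {
        v <- parent_of[v]
        anc <- c(anc, v)
      }
      anc
    }
    set.seed(seed)
    for (i in 1:5) {
      taxa <- sample(tr$tip.label, sample(2:5, 1))
      common <- Reduce(intersect, lapply(taxa, chain))
      expect_equal(mrca_node(tr, taxa), common[1])
    }
  }
  expect_error(mrca_node(read_newick_text("((a:1,b:1):1,c:1);"), "zz"),
               "unknown leaf")
})
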