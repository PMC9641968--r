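test_that("profiles index tuples directly and exclude gapped sequences", {
  aln <- protein_alignment(c("s1", "s2", "s3"),
                           c("ARNDK", "GH--L", "AWNDV"))
  pr <- extract_profiles(aln, c(2, 4), c("s1", "s2", "s3"))
  expect_equal(sort(unname(pr$tuples)), sort(c("RD", "WD")))
  expect_equal(pr$excluded, "s2")  # gap at profiled column 4
  expect_equal(sum(pr$counts), 3L - length(pr$excluded))
})

test_that("gap or X at a profiled column excludes the sequence", {
  aln <- protein_alignment(c("a", "b", "c"), c("A-R", "AXR", "AKR"))
  pr <- extract_profiles(aln, c(1, 2), c("a", "b", "c"))
  expect_setequal(pr$excluded, c("a", "b"))
  expect_equal(unname(pr$tuples), "AK")
  expect_error(extract_profiles(aln, 1, character(0)), "empty")
  expect_error(extract_profiles(aln, 1, "zz"), "not in alignment")
})

test_that("fixture profiles equal the generator's ground-truth bookkeeping", {
  fx <- make_extant_fixture(seed = 101)
  pr <- extract_profiles(fx$alignment, fx$columns, fx$alignment$ids,
                         clade_map = fx$clades)
  expect_equal(length(pr$excluded), 0L)
  truth <- table(fx$tuples)
  expect_equal(sort(names(pr$counts)), sort(names(truth)))
  expect_equal(as.integer(pr$counts[names(truth)]), as.integer(truth))
  # conservation: counts sum to the number of scorable sequences
  expect_equal(sum(pr$counts), length(fx$alignment$ids))
  # determinism
  fx2 <- make_extant_fixture(seed = 101)
  expect_identical(fx$alignment$seqs, fx2$alignment$seqs)
})

test_that("zeroed profile weights never emit the residue", {
  profiles <- list(`5`  = c(A = 1),
                   `10` = c(A = 0.5, M = 0.5),
                   `15` = c(E = 0.5, T = 0.5),
                   `20` = c(A = 1),  # no G possible at the 576-analog
                   `25` = c(A = 0.5, G = 0.5))
  fx <- make_extant_fixture(seed = 11, profiles = profiles)
  dv <- fx$tuples[grep("^dv", names(fx$tuples))]
  expect_true(all(substr(dv, 4, 4) == "A"))
})

test_that("classification follows the absent/rare/common count rules", {
  aln <- protein_alignment(
    c("e1", "e2", "e3", "e4", "e5"),
    c("AATGG", "AATGG", "LMNGG", "LMNGG", "LMNGG"))
  pr <- extract_profiles(aln, 1:5, aln$ids)
  cb <- enumerate_combinations(list(
    `1` = data.frame(residue = c("A", "L"), posterior = c(0.6, 0.4)),
    `2` = data.frame(residue = c("A", "M"), posterior = c(0.7, 0.3)),
    `3` = data.frame(residue = c("T", "N"), posterior = c(0.8, 0.2)),
    `4` = data.frame(residue = "G", posterior = 0.9),
    `5` = data.frame(residue = "G", posterior = 0.9)))
  cls <- classify(cb, pr)
  tab <- cls$table
  expect_equal(tab$residue_status[tab$residues == "AATGG"], "rare")   # 2 copies
  expect_equal(tab$count[tab$residues == "AATGG"], 2L)
  expect_equal(tab$residue_status[tab$residues == "LMNGG"], "common") # 3 copies
  expect_equal(tab$residue_status[tab$residues == "AMTGG"], "absent")
  # exact residue match implies type presence
  expect_true(all(tab$type_status[tab$residue_status != "absent"] != "absent"))
  # type present without residue match: GATGG-type? AATGG type tuple matches
  # LMTGG? recode(LMTGG)=aliphatic|aliphatic|small_hydroxyl|tiny|tiny
  i <- which(tab$residues == "LMTGG")
  expect_equal(tab$residue_status[i], "absent")
  expect_equal(tab$type_status[i], "absent")
  # summary fractions use the documented denominators
  s <- cls$summary
  expect_equal(s$n, nrow(tab))
  expect_equal(s$residue_present_fraction, s$residue_present / s$n)
  expect_equal(s$type_absent_fraction, s$type_absent / s$n)
  expect_equal(s$type_rare_among_present_fraction,
               s$type_rare_among_present / s$type_present)
})

test_that("type-level matches can be common while the residue is absent", {
  # extant AATGG (x10); candidate GGSAA recodes identically to no extant;
  # candidate GGTAA? use GATGG: tiny|tiny|small_hydroxyl|tiny|tiny == AATGG
  aln <- protein_alignment(sprintf("e%02d", 1:10), rep("AATGG", 10))
  pr <- extract_profiles(aln, 1:5, aln$ids)
  cb <- enumerate_combinations(list(
    `1` = data.frame(residue = "G", posterior = 0.5),
    `2` = data.frame(residue = "A", posterior = 0.5),
    `3` = data.frame(residue = "S", posterior = 0.5),
    `4` = data.frame(residue = "G", posterior = 0.5),
    `5` = data.frame(residue = "A", posterior = 0.5)))
  cls <- classify(cb, pr)
  expect_equal(cls$table$residue_status, "absent")
  expect_equal(cls$table$type_status, "common")
  expect_equal(cls$table$type_count, 10L)
})

test_that("an empty profile classifies everything absent at both levels", {
  aln <- protein_alignment(c("a", "b"), c("-A", "-G"))
  pr <- extract_profiles(aln, 1:2, c("a", "b"))
  expect_equal(length(pr$tuples), 0L)
  cb <- enumerate_combinations(list(
    `1` = data.frame(residue = "A", posterior = 0.6),
    `2` = data.frame(residue = "G", posterior = 0.6)))
  cls <- classify(cb, pr)
  expect_true(all(cls$table$residue_status == "absent"))
  expect_true(all(cls$table$type_status == "absent"))
})

test_that("clade tags propagate to matched type tuples", {
  fx <- make_extant_fixture(seed = 31)
  pr <- extract_profiles(fx$alignment, fx$columns, fx$alignment$ids,
                         clade_map = fx$clades)
  cb <- enumerate_combinations(list(
    `5` = data.frame(residue = c("L", "A"), posterior = c(0.5, 0.4)),
    `10` = data.frame(residue = "M", posterior = 0.5),
    `15` = data.frame(residue = "N", posterior = 0.5),
    `20` = data.frame(residue = "G", posterior = 0.9),
    `25` = data.frame(residue = "G", posterior = 0.9)))
  cls <- classify(cb, pr)
  i <- which(cls$table$residues == "LMNGG")
  expect_match(cls$table$type_clades[i], "clade1")
})

test_that("co-occurrence counts equal a direct scan of the tuples", {
  aln <- protein_alignment(c("x", "y"), c("AM", "LA"))
  pr <- extract_profiles(aln, 1:2, c("x", "y"))
  co <- co_occurrence_report(pr)
  row0 <- co[co$residue_a == "A" & co$residue_b == "A", ]
  expect_equal(row0$count, 0L)
  aln2 <- protein_alignment("z", "AA")
  pr2 <- extract_profiles(aln2, 1:2, "z")
  co2 <- co_occurrence_report(pr2)
  expect_equal(co2$count[co2$residue_a == "A" & co2$residue_b == "A"], 1L)

  fx <- make_extant_fixture(seed = 55)
  pr3 <- extract_profiles(fx$alignment, fx$columns, fx$alignment$ids)
  co3 <- co_occurrence_report(pr3)
  mat <- do.call(rbind, strsplit(unname(pr3$tuples), ""))
  for (i in sample(nrow(co3), 10)) {
    a <- match(co3$column_a[i], fx$columns)
    b <- match(co3$column_b[i], fx$columns)
    expect_equal(co3$count[i],
                 sum(mat[, a] == co3$residue_a[i] &
                     mat[, b] == co3$residue_b[i]))
  }
  expect_error(co_occurrence_report(
    extract_profiles(fx$alignment, fx$columns[1], fx$alignment$ids)),
    "two columns")
})
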