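test_that("multiplicity counts occurrences in allele multisets", {
  expect_identical(multiplicity("G", c("G", "G", "G", "T", "T")), 3L)
  expect_identical(multiplicity("A", character(0)), 0L)
  expect_identical(multiplicity("T", c("G", "T")), 1L)
})

test_that("aggregate genotype enumeration matches the multiset coefficient", {
  g <- enumerate_aggregate_genotypes(c("A", "G"), 4)
  expect_identical(g$genotype,
                   c("A/A/A/A", "A/A/A/G", "A/A/G/G", "A/G/G/G", "G/G/G/G"))
  g2 <- enumerate_aggregate_genotypes(c("G", "T"), 5)
  expect_equal(nrow(g2), 6)
  expect_true("G/G/G/T/T" %in% g2$genotype)
  for (k in 1:4) {
    for (cn in 1:8) {
      alleles <- c("A", "C", "G", "TT")[seq_len(k)]
      expect_equal(nrow(enumerate_aggregate_genotypes(alleles, cn)),
                   choose(cn + k - 1, k - 1))
    }
  }
  expect_error(enumerate_aggregate_genotypes(character(0), 2))
  expect_error(enumerate_aggregate_genotypes(c("A", "G"), 0))
})

test_that("aggregate enumeration agrees with ordered-tuple oracle", {
  for (case in list(list(c("A", "C", "G"), 3), list(c("A", "G"), 5),
                    list(c("A", "C", "G", "T"), 4))) {
    got <- enumerate_aggregate_genotypes(case[[1]], case[[2]])$genotype
    expect_setequal(norm_gt_key(got),
                    norm_gt_key(oracle_enum_aggregate(case[[1]], case[[2]])))
  }
})

test_that("paralog genotype enumeration distributes the aggregate multiset", {
  pg <- enumerate_paralog_genotypes(c("A", "A", "A", "G"), c(2, 2))
  expect_setequal(pg$genotype, c("A/A|A/G", "A/G|A/A"))
  expect_equal(nrow(enumerate_paralog_genotypes(rep("A", 4), c(2, 2))), 1)
  expect_error(enumerate_paralog_genotypes(c("A", "G"), c(2, 2)))
})

test_that("paralog enumeration agrees with labelled-assignment oracle", {
  cases <- list(
    list(c("A", "A", "G", "G", "T"), c(3, 2)),
    list(c("A", "A", "A", "G"), c(2, 2)),
    list(c("A", "C", "G"), c(1, 1, 1)),
    list(c("A", "A", "G"), c(0, 3)),
    list(c("A", "G", "G", "T"), c(2, 1, 1))
  )
  for (case in cases) {
    got <- enumerate_paralog_genotypes(case[[1]], case[[2]])$genotype
    expect_setequal(norm_gt_key(got),
                    norm_gt_key(oracle_enum_paralog(case[[1]], case[[2]])))
  }
})

test_that("every paralog genotype flattens back to its aggregate", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    alleles <- sample(c("A", "C", "G", "T"), k)
    n <- sample(2:3, 1)
    pscn <- sample(0:3, n, replace = TRUE)
    if (sum(pscn) == 0) next
    agg <- sort(sample(alleles, sum(pscn), replace = TRUE))
    pgs <- enumerate_paralog_genotypes(agg, pscn)
    for (pc in pgs$per_copy) {
      expect_identical(lengths(pc), as.integer(pscn))
      flat <- sort(unlist(pc))
      expect_identical(flat, agg)
    }
    expect_false(any(duplicated(pgs$genotype)))
  }
})

test_that("exactly one paralog genotype is reference-compatible when all pscn >= 1", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:3, 1)
    pscn <- sample(1:3, n, replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    agg <- unlist(lapply(seq_len(n), function(i) rep(ref[i], pscn[i])))
    pgs <- enumerate_paralog_genotypes(agg, pscn)
    compat <- vapply(pgs$per_copy, reference_compatible, logical(1),
                     ref_alleles = ref)
    expect_equal(sum(compat), 1)
  }
})
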