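test_that("read-pair location probabilities follow the PSV-product rule", {
  # no PSVs covered: location prior only
  expect_equal(locate_read_pair(character(0),
                                matrix(character(0), 0, 2), c(2, 2)),
               c(0.5, 0.5))
  # one PSV, read matches copy 1
  pr <- locate_read_pair("T", matrix(c("T", "C"), 1), c(2, 2))
  expect_equal(pr, c(0.99, 0.01), tolerance = 1e-12)
  # two concordant PSVs
  pr2 <- locate_read_pair(c("T", "G"),
                          matrix(c("T", "C", "G", "A"), 2, byrow = TRUE),
                          c(2, 2))
  expect_equal(pr2[1], 0.99^2 / (0.99^2 + 0.01^2), tolerance = 1e-12)
  # PSV missing from copy 2: epsilon^2 penalty there
  pr3 <- locate_read_pair("T", matrix(c("T", NA), 1), c(2, 2))
  expect_equal(pr3, c(0.99, 0.0001) / (0.99 + 0.0001), tolerance = 1e-12)
  # unequal copy numbers weight the prior
  pr4 <- locate_read_pair(character(0), matrix(character(0), 0, 2), c(3, 1))
  expect_equal(pr4, c(0.75, 0.25))
  # zero-copy locations get zero probability
  pr5 <- locate_read_pair("T", matrix(c("T", "C"), 1), c(2, 0))
  expect_equal(pr5, c(1, 0))
  expect_error(locate_read_pair("T", matrix(c("T", "C"), 1), c(0, 0)))
  # nonduplicated anchor concentrates probability on that copy
  pr6 <- locate_read_pair(character(0), matrix(character(0), 0, 2),
                          c(2, 2), anchored_copy = 1)
  expect_equal(pr6, c(0.99, 0.01), tolerance = 1e-12)
})

test_that("read-pair likelihood mixes per-copy emissions over locations", {
  g <- list(c("A", "G"), c("A", "A"))
  expect_equal(ps_genotype_likelihood(c(1, 0), g, "G"), 0.5,
               tolerance = 1e-12)
  g_all_a <- list(c("A", "A"), c("A", "A"))
  for (split in list(c(0.5, 0.5), c(0.9, 0.1), c(0, 1))) {
    expect_equal(ps_genotype_likelihood(split, g_all_a, "A"), 0.99,
                 tolerance = 1e-12)
  }
  # symmetric genotypes with symmetric locations give identical likelihood
  l1 <- ps_genotype_likelihood(c(0.5, 0.5), list(c("A", "G"), c("A", "A")), "G")
  l2 <- ps_genotype_likelihood(c(0.5, 0.5), list(c("A", "A"), c("A", "G")), "G")
  expect_equal(l1, l2, tolerance = 1e-15)
})

test_that("novel-variant prior penalises each non-reference copy by xi", {
  expect_equal(novel_variant_prior(list(c("A", "A"), c("A", "A")), "A"),
               0.999^2, tolerance = 1e-12)
  expect_equal(novel_variant_prior(list(c("A", "A"), c("A", "G")), "A"),
               0.999 * 0.001, tolerance = 1e-12)
  # hom and het non-reference copies are penalised equally
  expect_equal(novel_variant_prior(list(c("A", "A"), c("G", "G")), "A"),
               novel_variant_prior(list(c("A", "A"), c("A", "G")), "A"))
  expect_equal(novel_variant_prior(list(c("A", "A"), c("A", "A")), "A",
                                   xi = 0), 1)
  expect_equal(novel_variant_prior(list(c("A", "G"), c("A", "A")), "A",
                                   xi = 0), 0)
})

test_that("paralog genotype posterior matches the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:40) {
    n <- 2
    alleles <- c("A", "G")
    pscn <- sample(1:3, n, replace = TRUE)
    agcn <- sum(pscn)
    depths <- setNames(c(rpois(1, 12), rpois(1, 6)), alleles)
    n_reads <- sample(1:12, 1)
    read_pairs <- tibble::tibble(
      allele = sample(alleles, n_reads, replace = TRUE),
      pr = lapply(seq_len(n_reads), function(i) {
        p <- runif(n); p / sum(p)
      }),
      linked = TRUE
    )
    agg <- aggregate_posterior(depths, alleles, agcn)
    vc <- ps_genotype_posterior(read_pairs, agg, pscn,
                                ref_alleles = rep("A", n))
    orc <- oracle_ps_posterior(as.data.frame(read_pairs[, c("allele", "pr")]),
                               depths, alleles, pscn,
                               ref_alleles = rep("A", n))
    got <- tapply(vc$table$posterior, norm_gt_key(vc$table$genotype), sum)
    expect_equal(sum(vc$table$posterior), 1, tolerance = 1e-9)
    for (i in seq_len(nrow(orc))) {
      key <- norm_gt_key(orc$genotype[i])
      expect_equal(unname(got[key]), orc$posterior[i], tolerance = 1e-9)
    }
  }
})

test_that("posterior is invariant to read order and mirror-symmetric without PSV links", {
  set.seed(13)
  alleles <- c("A", "G")
  pscn <- c(2, 2)
  depths <- c(A = 14, G = 7)
  agg <- aggregate_posterior(depths, alleles, 4)
  read_pairs <- tibble::tibble(
    allele = sample(alleles, 10, replace = TRUE, prob = c(0.7, 0.3)),
    pr = replicate(10, c(0.5, 0.5), simplify = FALSE),
    linked = FALSE
  )
  vc <- ps_genotype_posterior(read_pairs, agg, pscn, rep("A", 2))
  vc_rev <- ps_genotype_posterior(read_pairs[10:1, ], agg, pscn, rep("A", 2))
  expect_equal(vc$table$posterior, vc_rev$table$posterior, tolerance = 1e-12)
  expect_false(vc$resolved)
  # mirror symmetry: swapping the two copies leaves the posterior unchanged
  tab <- vc$table
  mirror <- vapply(tab$per_copy, function(pc) {
    paste(rev(vapply(pc, paste, character(1), collapse = "/")),
          collapse = "|")
  }, character(1))
  post_m <- setNames(tab$posterior, tab$genotype)
  expect_true(all(abs(tab$posterior - post_m[mirror]) < 1e-9))
})

test_that("empty read set yields an unresolved call that keeps the aggregate genotype", {
  agg <- aggregate_posterior(c(A = 20, G = 10), c("A", "G"), 4)
  vc <- ps_genotype_posterior(NULL, agg, c(2, 2), rep("A", 2))
  expect_false(vc$resolved)
  expect_true(is.na(vc$map_genotype))
  expect_identical(vc$aggregate$map_genotype, "A/A/A/G")
})

test_that("strand-bias Fisher test flags asymmetric tables and matches the oracle", {
  r <- strand_bias_filter(10, 10, 10, 10)
  expect_equal(r$p_value, 1)
  expect_true(r$pass)
  r2 <- strand_bias_filter(20, 0, 0, 20)
  expect_lt(r2$p_value, 1e-9)
  expect_false(r2$pass)
  expect_true(strand_bias_filter(0, 0, 0, 0)$pass)
  set.seed(3)
  for (rep in 1:60) {
    x <- rpois(4, 6)
    r3 <- strand_bias_filter(x[1], x[2], x[3], x[4])
    expect_equal(r3$p_value, oracle_fisher(x[1], x[3], x[2], x[4]),
                 tolerance = 1e-12)
  }
})
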