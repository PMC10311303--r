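test_that("allele weights follow the length-corrected floored multiplicity rule", {
  expect_equal(allele_weight("G", c("A", "A", "A", "G"), c("A", "G")), 0.25)
  w <- allele_weight("T", c("A", "A", "A", "A"), c("A", "T"))
  expect_equal(w, 0.04 / (0.04 + 4), tolerance = 1e-12)
  expect_equal(allele_weights(c("A", "A"), "A"), c(A = 1))
  expect_equal(sum(allele_weights(c("A", "G", "G"), c("A", "C", "G"))), 1)
  expect_true(all(allele_weights(c("A", "A", "A"), c("A", "C", "G")) > 0))
  expect_error(allele_weights(c("A", "A"), c("A", "ACGTACGT"),
                              mean_read_len = 8))
})

test_that("aggregate likelihood is the multinomial pmf of allelic depths", {
  expect_equal(aggregate_likelihood(c(0, 0), c("A", "A", "A", "G"),
                                    c("A", "G")), 1)
  lik <- aggregate_likelihood(c(22, 8), c("A", "A", "A", "G"), c("A", "G"))
  expect_equal(lik, choose(30, 8) * 0.75^22 * 0.25^8, tolerance = 1e-12)
  lik_ref <- aggregate_likelihood(c(22, 8), rep("A", 4), c("A", "G"),
                                  agcn = 4)
  expect_lt(lik_ref, lik)
})

test_that("aggregate posterior normalises, is uniform on empty data, and picks the right MAP", {
  ap0 <- aggregate_posterior(c(A = 0, G = 0), c("A", "G"), 4)
  expect_equal(ap0$table$posterior, rep(0.2, 5), tolerance = 1e-12)
  ap <- aggregate_posterior(c(A = 22, G = 8), c("A", "G"), 4)
  expect_equal(sum(ap$table$posterior), 1, tolerance = 1e-9)
  expect_identical(ap$map_genotype, "A/A/A/G")
})

test_that("aggregate posterior matches the brute-force oracle on random sites", {
  set.seed(42)
  for (rep in 1:60) {
    s <- random_site()
    ap <- aggregate_posterior(s$depths, s$alleles, s$agcn)
    orc <- oracle_agg_posterior(s$depths[ap$alleles], ap$alleles, s$agcn)
    got <- setNames(ap$table$posterior, norm_gt_key(ap$table$genotype))
    expect_equal(sum(got), 1, tolerance = 1e-9)
    for (g in names(orc)) {
      key <- norm_gt_key(g)
      expect_equal(unname(got[key]), unname(orc[g]), tolerance = 1e-9)
    }
  }
})

test_that("adding an observation of an allele shifts mass towards genotypes richer in it", {
  set.seed(5)
  for (rep in 1:20) {
    s <- random_site(max_alleles = 2)
    a1 <- s$alleles[1]
    ap1 <- aggregate_posterior(s$depths, s$alleles, s$agcn)
    d2 <- s$depths
    d2[a1] <- d2[a1] + 1L
    ap2 <- aggregate_posterior(d2, s$alleles, s$agcn)
    mu <- vapply(strsplit(ap1$table$genotype, "/"), function(g) sum(g == a1),
                 numeric(1))
    # pairwise: posterior ratio high-mu / low-mu never decreases
    for (i in seq_along(mu)) {
      for (j in seq_along(mu)) {
        if (mu[i] > mu[j] && ap1$table$posterior[j] > 0) {
          r1 <- ap1$table$posterior[i] / ap1$table$posterior[j]
          r2 <- ap2$table$posterior[i] / ap2$table$posterior[j]
          expect_gte(r2, r1 * (1 - 1e-12))
        }
      }
    }
  }
})

test_that("deep simulated depths recover the generating genotype", {
  set.seed(99)
  hits <- 0L
  n_trials <- 200L
  for (rep in seq_len(n_trials)) {
    agcn <- sample(2:6, 1)
    alleles <- c("A", "G")
    gt <- sample(0:agcn, 1)  # copies of G
    genotype <- c(rep("A", agcn - gt), rep("G", gt))
    w <- allele_weights(genotype, alleles, agcn = agcn)
    x <- as.vector(rmultinom(1, 500, w))
    ap <- aggregate_posterior(setNames(x, alleles), alleles, agcn)
    if (ap$map_genotype == paste(genotype, collapse = "/")) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.99)
})
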