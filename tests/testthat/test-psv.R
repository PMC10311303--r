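test_that("PSV population prior multiplies per-copy frequency terms", {
  ref <- c("T", "C")
  expect_equal(psv_prior(list(c("T", "T"), c("C", "C")), ref, c(0.95, 0.9)),
               0.95^2 * 0.9^2, tolerance = 1e-12)
  expect_equal(psv_prior(list(c("T", "C"), c("C", "C")), ref, c(0.95, 0.9)),
               0.95 * 0.05 * 0.9^2, tolerance = 1e-12)
  expect_equal(psv_prior(list(c("T", "T"), c("C", "C")), ref, c(1, 1)), 1)
  expect_equal(psv_prior(list(c("T", "C"), c("C", "C")), ref, c(1, 1)), 0)
})

test_that("PSV paralog posterior sums to 1 and renormalises within aggregate classes", {
  pc <- psv_paralog_posterior(c(T = 15, C = 14), c("T", "C"),
                              c(0.95, 0.95), c(2, 2))
  expect_equal(sum(pc$table$posterior), 1, tolerance = 1e-9)
  agg_by_class <- tapply(pc$table$posterior, pc$table$agg_genotype, sum)
  agg <- pc$aggregate$table
  for (g in names(agg_by_class)) {
    expect_equal(unname(agg_by_class[g]),
                 agg$posterior[agg$genotype == g], tolerance = 1e-9)
  }
  expect_error(psv_paralog_posterior(c(T = 10), c("T", "T"), c(0.9, 0.9),
                                     c(2, 2)))
})

test_that("PSV paralog posterior matches the brute-force oracle", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:3, 1)
    bases <- sample(c("A", "C", "G", "T"), n)
    pscn <- sample(1:2, n, replace = TRUE)
    freqs <- runif(n, 0.5, 0.999)
    depths <- setNames(rpois(n, 8), bases)
    pc <- psv_paralog_posterior(depths, bases, freqs, pscn)
    orc <- oracle_psv_posterior(depths, bases, freqs, pscn)
    got <- setNames(pc$table$posterior, norm_gt_key(pc$table$genotype))
    for (i in seq_len(nrow(orc))) {
      key <- norm_gt_key(orc$genotype[i])
      expect_equal(unname(got[key]), orc$posterior[i], tolerance = 1e-9)
    }
  }
})

test_that("informativeness requires high posterior and reference compatibility", {
  # Deep reference-pattern depths: clearly informative.
  pc <- psv_paralog_posterior(c(T = 30, C = 29), c("T", "C"),
                              c(0.95, 0.95), c(2, 2))
  expect_true(pc$reference_compatible)
  expect_true(pc$informative)
  expect_identical(pc$map_genotype, "T/T|C/C")
  # Gene-conversion-like pattern (all reads carry C): not informative.
  pc2 <- psv_paralog_posterior(c(T = 1, C = 58), c("T", "C"),
                               c(0.95, 0.95), c(2, 2))
  expect_false(pc2$informative)
  # Low frequency on one copy undermines confidence even for ref pattern.
  pc3 <- psv_paralog_posterior(c(T = 15, C = 15), c("T", "C"),
                               c(0.55, 0.55), c(2, 2))
  expect_true(pc3$map_posterior < 0.99 || !pc3$reference_compatible)
  expect_false(pc3$informative)
})

test_that("conflict binomial test uses pi = 2e - e^2 and matches direct summation", {
  eps <- 0.01
  expect_equal(2 * eps - eps^2, 0.0199)
  r <- conflict_test(0, 10, epsilon = eps)
  expect_equal(r$p_value, 1)
  expect_false(r$is_conflict)
  r2 <- conflict_test(5, 10, epsilon = eps)
  expect_lt(r2$p_value, 1e-3)
  expect_true(r2$is_conflict)
  expect_equal(r2$p_value, oracle_binom_tail(5, 10, 0.0199),
               tolerance = 1e-12)
  r3 <- conflict_test(2, 2, epsilon = eps)
  expect_true(is.na(r3$p_value))
  expect_false(r3$is_conflict)
})

test_that("greedy conflict pruning removes low-weight conflicted PSVs first", {
  psvs <- tibble::tibble(psv_id = c("a", "b"), min_freq = c(0.99, 0.50),
                         pos = c(1, 2))
  out <- prune_conflicts(psvs, tibble::tibble(psv1 = "a", psv2 = "b"))
  expect_identical(out$retained, c(TRUE, FALSE))
  all_kept <- prune_conflicts(psvs, NULL)
  expect_true(all(all_kept$retained))
})

test_that("greedy pruning always yields an independent set, near the exhaustive optimum", {
  set.seed(31)
  gaps <- numeric(0)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    psvs <- tibble::tibble(psv_id = paste0("p", seq_len(n)),
                           min_freq = runif(n, 0.5, 0.999),
                           pos = seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- runif(nrow(pairs)) < 0.3
    edges <- tibble::tibble(psv1 = psvs$psv_id[pairs[sel, 1]],
                            psv2 = psvs$psv_id[pairs[sel, 2]])
    out <- prune_conflicts(psvs, edges)
    kept <- which(out$retained)
    ei <- match(edges$psv1, psvs$psv_id)
    ej <- match(edges$psv2, psvs$psv_id)
    expect_false(any(ei %in% kept & ej %in% kept))
    best <- oracle_best_independent_set(psvs$min_freq, ei, ej)
    gaps <- c(gaps, best - sum(psvs$min_freq[kept]))
  }
  expect_true(all(gaps >= -1e-9))
  # the greedy heuristic should usually find the optimum on small graphs
  expect_gt(mean(gaps < 1e-9), 0.5)
})

test_that("informativeness is monotone in depth and rejects converted PSVs", {
  set.seed(515)
  sim_frac <- function(n, weights) {
    hits <- vapply(1:500, function(i) {
      x <- as.vector(rmultinom(1, n, weights))
      psv_paralog_posterior(setNames(x, c("T", "C")), c("T", "C"),
                            c(0.95, 0.95), c(2, 2))$informative
    }, logical(1))
    mean(hits)
  }
  # reference-compatible truth (balanced allele weights): the informative
  # fraction grows with pooled depth and clears 95% once the aggregate
  # genotype posterior is sharp (pooled depth 120)
  ref_w <- allele_weights(c("T", "T", "C", "C"), c("C", "T"))
  f60 <- sim_frac(60, ref_w)
  f120 <- sim_frac(120, ref_w)
  expect_gt(f120, f60)
  expect_gte(f120, 0.95)
  # one-directional gene conversion (all haplotypes carry C): essentially
  # never informative
  conv_w <- allele_weights(rep("C", 4), c("C", "T"))
  expect_lte(sim_frac(60, conv_w), 0.01)
})
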