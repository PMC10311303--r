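test_that("locus simulation hits the PSV density target and is deterministic", {
  cfg <- sim_config(seed = 11, copy_length = 10000, similarity = 0.995)
  loc <- simulate_locus(cfg)
  # expected count = length * (1 - similarity) = 50; allow Poisson spread
  expect_gt(nrow(loc$psv_table), 20)
  expect_lt(nrow(loc$psv_table), 90)
  # copies differ exactly at PSV columns
  a <- strsplit(loc$map$seqs[1], "")[[1]]
  b <- strsplit(loc$map$seqs[2], "")[[1]]
  expect_equal(which(a != b) - 1L, sort(loc$psv_table$pos))
  # determinism
  loc2 <- simulate_locus(cfg)
  expect_identical(loc$map$seqs, loc2$map$seqs)
  expect_identical(loc$psv_table, loc2$psv_table)
  # zero PSV density gives identical copies
  loc0 <- simulate_locus(sim_config(seed = 3, copy_length = 2000,
                                    similarity = 1))
  expect_identical(loc0$map$seqs[[1]], loc0$map$seqs[[2]])
  expect_equal(nrow(loc0$psv_table), 0)
})

test_that("sample variants follow the configured type mix and heterozygosity", {
  cfg <- sim_config(seed = 5, copy_length = 50000, variant_rate = 5e-3,
                    similarity = 0.999)
  smp <- simulate_sample(simulate_locus(cfg))
  tr <- smp$truth[!smp$truth$is_psv_site, ]
  expect_gt(nrow(tr), 150)
  mix <- table(tr$type) / nrow(tr)
  expect_equal(unname(mix[["sub"]]), 0.8, tolerance = 0.12)
  expect_lt(abs(mix[["ins"]] - 0.1), 0.07)
  expect_lt(abs(mix[["del"]] - 0.1), 0.07)
  het <- vapply(seq_len(nrow(tr)), function(i) {
    any(vapply(tr$genotypes[[i]], function(g) {
      length(unique(g)) > 1
    }, logical(1)))
  }, logical(1))
  expect_equal(mean(het), 0.615, tolerance = 0.12)
})

test_that("polymorphic PSVs realise non-reference alleles at rate 1 - f", {
  # single PSV with known frequency, many seeds
  set.seed(99)
  nonref <- 0L
  total <- 0L
  for (s in 1:60) {
    cfg <- sim_config(seed = 7000 + s, copy_length = 300,
                      similarity = 0.99, variant_rate = 0)
    loc <- simulate_locus(cfg)
    if (nrow(loc$psv_table) == 0) next
    loc$psv_table$freqs <- lapply(loc$psv_table$freqs, function(f) {
      rep(0.7, length(f))
    })
    smp <- simulate_sample(loc)
    for (k in seq_len(nrow(loc$psv_table))) {
      p <- loc$psv_table$pos[k]
      refs <- loc$psv_table$ref_alleles[[k]]
      row <- smp$truth[smp$truth$pos == p & smp$truth$is_psv_site, ]
      gts <- if (nrow(row)) row$genotypes[[1]] else
        lapply(1:2, function(i) rep(refs[i], 2))
      for (i in 1:2) {
        nonref <- nonref + sum(gts[[i]] != refs[i])
        total <- total + length(gts[[i]])
      }
    }
  }
  expect_gt(total, 300)
  expect_equal(nonref / total, 0.3, tolerance = 0.08)
})

test_that("truth variants and haplotype sequences are mutually consistent", {
  cfg <- sim_config(seed = 21, copy_length = 3000)
  loc <- simulate_locus(cfg)
  smp <- simulate_sample(loc)
  # rebuild each haplotype from the copy reference + realised PSVs + truth
  for (h in seq_len(nrow(smp$haplotypes))) {
    hp <- smp$haplotypes[h, ]
    cm <- hp$copy_map[[1]]
    seq_chars <- strsplit(hp$seq, "")[[1]]
    ref_chars <- strsplit(loc$map$seqs[hp$copy], "")[[1]]
    # every aligned base must equal the reference unless a truth variant or
    # PSV realisation explains it
    aligned <- which(!is.na(cm))
    diffs <- aligned[seq_chars[aligned] != ref_chars[cm[aligned] + 1]]
    for (d in diffs) {
      p <- cm[d]
      explained <- p %in% loc$psv_table$pos || p %in% smp$truth$pos
      expect_true(explained)
    }
  }
})

test_that("simulated reads match their haplotypes at epsilon 0 and hit the depth target", {
  cfg <- sim_config(seed = 31, copy_length = 3000, epsilon = 0)
  b <- simulate_bundle(cfg)
  haps <- b$sample$haplotypes
  for (r in sample(nrow(b$reads), 50)) {
    rd <- b$reads[r, ]
    ci <- match(rd$true_copy, b$locus$map$copy_ids)
    hp <- haps[haps$copy == ci & haps$hap == rd$true_hap, ]
    # without sequencing errors every read is a verbatim haplotype substring
    expect_true(grepl(rd$seq, hp$seq, fixed = TRUE))
  }
  # mean pooled depth ~ depth * sum(pscn) / 2 within 10%
  pp <- pool_reads(b$reads, b$locus$map, min_base_quality = 0)
  inner <- pp$base$pos >= 200 & pp$base$pos < 2800
  mean_cov <- sum(inner) / 2600
  expect_equal(mean_cov, 60, tolerance = 0.1)
})

test_that("read errors occur at the configured rate and truth tags record origin", {
  cfg <- sim_config(seed = 41, copy_length = 3000, epsilon = 0.01,
                    variant_rate = 0, psv_fixed = TRUE)
  b <- simulate_bundle(cfg)
  haps <- b$sample$haplotypes
  n_mismatch <- 0L
  n_bases <- 0L
  for (r in seq_len(nrow(b$reads))) {
    rd <- b$reads[r, ]
    if (!grepl("^[0-9]+M$", rd$cigar)) next
    hrow <- haps[haps$copy == match(rd$true_copy, b$locus$map$copy_ids) &
                   haps$hap == rd$true_hap, ]
    truth_seq <- substr(hrow$seq, rd$pos + 1, rd$pos + nchar(rd$seq))
    a <- strsplit(rd$seq, "")[[1]]
    t <- strsplit(truth_seq, "")[[1]]
    n_mismatch <- n_mismatch + sum(a != t)
    n_bases <- n_bases + length(a)
  }
  expect_equal(n_mismatch / n_bases, 0.01, tolerance = 0.2)
})

test_that("fixed seeds give byte-identical bundles on disk", {
  cfg <- sim_config(seed = 17, copy_length = 1500)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  simulate_bundle(cfg, dir = d1)
  simulate_bundle(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero variant rate with fixed PSVs gives an empty truth set and depth 0 an empty SAM", {
  cfg <- sim_config(seed = 19, copy_length = 1500, variant_rate = 0,
                    psv_fixed = TRUE)
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$sample$truth), 0)
  cfg0 <- sim_config(seed = 19, copy_length = 1500, depth = 0)
  b0 <- simulate_bundle(cfg0)
  expect_equal(nrow(b0$reads), 0)
  d <- file.path(tempdir(), "bundle_d0")
  write_bundle(b0, d)
  sam <- readLines(file.path(d, "reads.sam"))
  expect_true(all(startsWith(sam, "@")))
  unlink(d, recursive = TRUE)
})
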