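ref20 <- "ACGTACGTACGTACGTACGT"
flat_map <- build_homology_map(c(A = ref20, B = ref20))

aln_row <- function(qname, copy, pos, cigar, seq, qual = NULL,
                    strand = "+", is_first = TRUE) {
  tibble::tibble(qname = qname, copy = copy, pos = pos, cigar = cigar,
                 seq = seq,
                 qual = qual %||% strrep("I", nchar(gsub("[0-9]+[DNHP]", "",
                                                         seq))),
                 strand = strand, is_first = is_first)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reads project identically on the representative and through gap-free columns", {
  reads <- dplyr::bind_rows(
    aln_row("a", "A", 2L, "8M", "GTACGTAC"),
    aln_row("b", "B", 2L, "8M", "GTACGTAC"))
  pp <- pool_reads(reads, flat_map)
  expect_equal(nrow(pp$base), 16)
  for (id in 1:2) {
    seg <- pp$base[pp$base$aln_id == id, ]
    expect_equal(seg$pos, 2:9)
    expect_equal(paste(seg$base, collapse = ""), "GTACGTAC")
  }
})

test_that("bases over a copy-specific insertion are unaligned to the representative", {
  map <- build_homology_map(c(A = "ACGT-ACGTACGT", B = "ACGAGACGT--GT"))
  # read on copy B spanning its private insertion at B position 4
  reads <- aln_row("r", "B", 2L, "5M", "GAGAC")
  pp <- pool_reads(reads, map, min_base_quality = 0)
  expect_equal(pp$base$pos, c(2, 3, 4, 5))  # B pos 4 dropped (gap in A)
  expect_equal(pp$base$base, c("G", "A", "A", "C"))
  # read entirely inside the representative gap is dropped with a count
  r2 <- aln_row("q", "B", 4L, "1M", "G")
  pp2 <- pool_reads(r2, map, min_base_quality = 0)
  expect_equal(nrow(pp2$base), 0)
  expect_equal(pp2$n_dropped, 1)
})

test_that("base-quality filtering removes observations below the threshold", {
  quals <- intToUtf8(33 + c(5, 9, 10, 30), multiple = FALSE)
  reads <- aln_row("a", "A", 0L, "4M", "ACGT", qual = quals)
  pp <- pool_reads(reads, flat_map, min_base_quality = 10)
  expect_equal(nrow(pp$base), 2)
  expect_equal(pp$base$qual, c(10L, 30L))
  pp_all <- pool_reads(reads, flat_map, min_base_quality = 0)
  expect_equal(nrow(filter_observations(pp_all, 10)$base), 2)
  expect_equal(nrow(filter_observations(pp_all, 0)$base), 4)
})

test_that("allele observations are extracted for SNVs, insertions and deletions", {
  reads <- dplyr::bind_rows(
    aln_row("snv", "A", 2L, "8M", "GTACATAC"),        # A at ref pos 6
    aln_row("ref1", "B", 2L, "8M", "GTACGTAC"),
    aln_row("ins", "A", 10L, "4M2I4M", "GTACAAGTAC"), # +AA after ref pos 13
    aln_row("ref2", "B", 10L, "8M", "GTACGTAC"),
    aln_row("del", "A", 0L, "4M3D4M", "ACGTTACG"),    # del of ref 4..6
    aln_row("ref3", "B", 0L, "8M", "ACGTACGT"),
    aln_row("part", "B", 3L, "3M", "TAC"))            # partial for the del site
  pp <- pool_reads(reads, flat_map)
  sites <- tibble::tibble(pos = c(6L, 13L, 3L), ref_len = c(1L, 1L, 4L))
  obs <- site_observations(pp, sites)
  o1 <- obs[obs$site_id == 1, ]
  # the deletion read has no aligned base at pos 6 (inside its deletion)
  expect_setequal(paste(o1$qname, o1$allele),
                  c("snv A", "ref1 G", "ref3 G"))
  o2 <- obs[obs$site_id == 2, ]
  expect_setequal(paste(o2$qname, o2$allele), c("ins CAA", "ref2 C"))
  o3 <- obs[obs$site_id == 3, ]
  # the partial read does not span the full reference span and is dropped;
  # the snv read carries its pos-6 substitution inside the span
  expect_setequal(paste(o3$qname, o3$allele),
                  c("del T", "ref3 TACG", "ref1 TACG", "snv TACA"))
})

test_that("mates are collapsed per read pair and allele disagreements dropped", {
  reads <- dplyr::bind_rows(
    aln_row("p1", "A", 2L, "8M", "GTACGTAC", is_first = TRUE),
    aln_row("p1", "A", 2L, "8M", "GTACGTAC", is_first = FALSE,
            strand = "-"),
    aln_row("p2", "A", 2L, "8M", "GTACGTAC", is_first = TRUE),
    aln_row("p2", "A", 2L, "8M", "GTACATAC", is_first = FALSE,
            strand = "-"))
  pp <- pool_reads(reads, flat_map)
  obs <- site_observations(pp, tibble::tibble(pos = 6L, ref_len = 1L))
  expect_equal(obs$qname, "p1")  # p2 mates disagree at the site
  expect_equal(obs$allele, "G")
})

test_that("pooled depth equals the per-copy depth sum and projection round-trips", {
  set.seed(8)
  reads <- dplyr::bind_rows(lapply(1:30, function(i) {
    copy <- sample(c("A", "B"), 1)
    pos <- sample(0:12, 1)
    aln_row(paste0("r", i), copy, pos, "8M",
            substr(ref20, pos + 1, pos + 8))
  }))
  pp <- pool_reads(reads, flat_map)
  cov <- tabulate(pp$base$pos + 1L, nbins = 20)
  cov_by_copy <- lapply(c("A", "B"), function(cp) {
    sub <- pool_reads(reads[reads$copy == cp, ], flat_map)
    tabulate(sub$base$pos + 1L, nbins = 20)
  })
  expect_equal(cov, cov_by_copy[[1]] + cov_by_copy[[2]])
})
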