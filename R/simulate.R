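# Synthetic LCR simulator.
#
# Generates a multi-copy locus (copies differing at PSV columns), a PSV
# table with population reference-allele frequencies, sample haplotypes
# carrying PSV realisations and novel variants, a truth table of variants
# with paralog-specific genotypes, and error-bearing paired-end reads whose
# reported alignment copy emulates ambiguous mapping (reads are assigned
# to the best PSV-matching copy, or a random copy when they cover no PSV).

#' Simulation configuration
#'
#' Defaults correspond to the benchmark conditions the pipeline is
#' validated under: two repeat copies of 10 kb at 0.995 sequence
#' similarity, diploid paralog-specific copy number (2, 2), 30x coverage
#' with 150 bp read pairs, mean fragment 500 bp, 1% sequencing error, one
#' sample variant per kilobase (80% substitutions / 10% insertions / 10%
#' deletions, 61.5% heterozygous).
#'
#' @param n_copies Number of repeat copies.
#' @param copy_length Length of each copy (bp).
#' @param similarity Pairwise sequence similarity target; PSVs are placed
#'   at per-column rate `1 - similarity`.
#' @param psv_fixed If `TRUE` all PSV reference-allele frequencies are
#'   0.9999 (the fixed-PSV scenario); otherwise frequencies are drawn from
#'   `psv_freq_mix`.
#' @param psv_freq_mix Mixture for polymorphic PSV frequencies: with
#'   probability `w[1]` uniform on `[0.9, 1)` ("almost fixed"), else
#'   uniform on `[0.5, 0.9)`.
#' @param variant_rate Per-base sample variant rate (default 1e-3, i.e.
#'   one variant per kilobase on average).
#' @param type_mix Named proportions of substitution / insertion /
#'   deletion variants.
#' @param het_frac Fraction of heterozygous variants.
#' @param pscn Paralog-specific copy numbers of the simulated sample.
#' @param depth Sequencing coverage of a diploid copy (WGS convention);
#'   pooled depth across the locus is about `depth * sum(pscn) / 2`.
#' @param read_length,fragment_mean,fragment_sd Read-pair geometry (bp).
#' @param epsilon Per-base substitution error rate of the simulated reads.
#' @param discard_psv_overlap Drop sample variants whose reference span
#'   overlaps a PSV column.
#' @param seed Mandatory integer seed; all outputs are deterministic in it.
#' @return A list of class `lcr_sim_config`.
#' @export
sim_config <- function(n_copies = 2, copy_length = 10000,
                       similarity = 0.995, psv_fixed = FALSE,
                       psv_freq_mix = c(almost_fixed = 0.7, common = 0.3),
                       variant_rate = 1e-3,
                       type_mix = c(sub = 0.8, ins = 0.1, del = 0.1),
                       het_frac = 0.615, pscn = c(2, 2), depth = 30,
                       read_length = 150, fragment_mean = 500,
                       fragment_sd = 50, epsilon = 0.01,
                       discard_psv_overlap = TRUE, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  stopifnot(n_copies >= 2, length(pscn) == n_copies,
            similarity > 0, similarity <= 1,
            variant_rate >= 0, variant_rate <= 1,
            het_frac >= 0, het_frac <= 1,
            abs(sum(type_mix) - 1) < 1e-9,
            epsilon >= 0, epsilon < 1)
  if (copy_length * (1 - similarity) > copy_length / 3) {
    abort("Similarity target incompatible with copy length.")
  }
  structure(as.list(environment()), class = "lcr_sim_config")
}

#' Simulate an LCR locus: copy sequences, homology map and PSV table
#'
#' Copies are generated from a common ancestral sequence and differ
#' exactly at the generated PSV columns (substitution PSVs, so the copies
#' stay alignment-gap free and coordinates coincide across copies). Each
#' PSV's per-copy reference-allele frequency is recorded in the table.
#'
#' @param config An [sim_config()] object.
#' @param locus_id Locus identifier used in contig names.
#' @return List of class `lcr_locus`: `map` (homology map), `psv_table`
#'   (tibble `psv_id`, `pos`, `ref_alleles`, `freqs`, `min_freq`),
#'   `config`, `locus_id`.
#' @export
simulate_locus <- function(config, locus_id = "locus1") {
  set.seed(config$seed)
  len <- config$copy_length
  n <- config$n_copies
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  psv_pos <- which(runif(len) < 1 - config$similarity) - 1L  # 0-based
  copies <- matrix(rep(anc, n), ncol = n)
  ref_alleles <- vector("list", length(psv_pos))
  for (k in seq_along(psv_pos)) {
    j <- sample(n, 1L)  # copy that deviates from the ancestral base
    old <- anc[psv_pos[k] + 1L]
    copies[psv_pos[k] + 1L, j] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    ref_alleles[[k]] <- copies[psv_pos[k] + 1L, ]
  }
  freqs <- lapply(seq_along(psv_pos), function(k) {
    if (config$psv_fixed) return(rep(0.9999, n))
    vapply(seq_len(n), function(i) {
      if (runif(1) < config$psv_freq_mix[[1L]]) runif(1, 0.9, 1) else runif(1, 0.5, 0.9)
    }, numeric(1))
  })
  seqs <- setNames(apply(copies, 2L, paste, collapse = ""),
                   paste0(locus_id, "_copy", seq_len(n)))
  map <- build_homology_map(seqs)
  psv_table <- tibble(
    psv_id = if (length(psv_pos)) paste0(locus_id, "_psv",
                                         seq_along(psv_pos)) else character(0),
    pos = psv_pos,
    ref_alleles = ref_alleles,
    freqs = freqs,
    min_freq = vapply(freqs, function(f) if (length(f)) min(f) else NA_real_,
                      numeric(1))
  )
  structure(list(map = map, psv_table = psv_table, config = config,
                 locus_id = locus_id),
            class = "lcr_locus")
}

# Geometric-ish indel length in 1..4.
rindel_len <- function(n) pmin(1L + stats::rgeom(n, 0.5), 4L)

#' Simulate a sample: haplotypes and truth variants
#'
#' Realises PSV alleles on every haplotype according to the population
#' reference-allele frequencies, adds novel sample variants (substitutions
#' and short indels) at the configured rate, and returns the haplotype
#' sequences together with a truth table of variants and their
#' paralog-specific genotypes. Variant positions keep a small margin from
#' the locus edges and a minimal spacing so each variant occupies its own
#' site.
#'
#' @param locus An `lcr_locus` from [simulate_locus()].
#' @return List of class `lcr_sample`: `haplotypes` (tibble `copy`, `hap`,
#'   `seq`, `copy_map` list column of per-base 0-based source positions,
#'   `NA` for inserted bases), `truth` (tibble `pos`, `ref`, `alt`,
#'   `type`, `genotypes` list column of per-copy allele vectors,
#'   `is_psv_site`), `locus`.
#' @export
simulate_sample <- function(locus) {
  config <- locus$config
  set.seed(config$seed + 1L)
  map <- locus$map
  n <- config$n_copies
  pscn <- as.integer(config$pscn)
  len <- config$copy_length
  psv_pos <- locus$psv_table$pos

  # --- PSV allele realisation per copy-haplotype
  psv_real <- vector("list", n)  # [[copy]] matrix psv x csi of alleles
  for (i in seq_len(n)) {
    if (pscn[i] == 0L || nrow(locus$psv_table) == 0L) {
      psv_real[[i]] <- matrix(character(0), nrow = nrow(locus$psv_table),
                              ncol = pscn[i])
      next
    }
    m <- matrix("", nrow = nrow(locus$psv_table), ncol = pscn[i])
    for (k in seq_len(nrow(locus$psv_table))) {
      refs <- locus$psv_table$ref_alleles[[k]]
      f <- locus$psv_table$freqs[[k]][i]
      others <- setdiff(unique(refs[!is.na(refs)]), refs[i])
      for (h in seq_len(pscn[i])) {
        m[k, h] <- if (runif(1) < f || length(others) == 0L) refs[i] else
          sample(others, 1L)
      }
    }
    psv_real[[i]] <- m
  }

  # --- novel sample variants, per copy
  margin <- 20L
  ref_chars <- lapply(seq_len(n), function(i) strsplit(map$seqs[i], "")[[1L]])
  variants <- list()
  for (i in seq_len(n)) {
    if (pscn[i] == 0L) next
    cand <- which(runif(len) < config$variant_rate) - 1L
    cand <- cand[cand >= margin & cand < len - margin]
    if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) >= 10L)]
    for (p in cand) {
      type <- sample(names(config$type_mix), 1L, prob = config$type_mix)
      refb <- ref_chars[[i]][p + 1L]
      if (type == "sub") {
        ref <- refb
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        span <- p
      } else if (type == "ins") {
        ins <- paste(sample(c("A", "C", "G", "T"), rindel_len(1L),
                            replace = TRUE), collapse = "")
        ref <- refb
        alt <- paste0(refb, ins)
        span <- p
      } else {
        dl <- rindel_len(1L)
        if (p + dl >= len - margin) next
        ref <- paste(ref_chars[[i]][(p + 1L):(p + 1L + dl)], collapse = "")
        alt <- refb
        span <- p:(p + dl)
      }
      if (config$discard_psv_overlap && any(span %in% psv_pos)) next
      het <- runif(1) < config$het_frac
      haps <- if (het) sample(pscn[i], 1L) else seq_len(pscn[i])
      variants[[length(variants) + 1L]] <-
        list(copy = i, pos = p, ref = ref, alt = alt, type = type,
             het = het, haps = haps)
    }
  }
  # enforce a global minimal spacing so every variant owns its site
  if (length(variants) > 1L) {
    pos_all <- vapply(variants, `[[`, numeric(1), "pos")
    variants <- variants[order(pos_all)]
    pos_all <- sort(pos_all)
    variants <- variants[c(TRUE, diff(pos_all) >= 10L)]
  }

  # --- truth table (novel variants + PSV-site deviations)
  truth_rows <- list()
  for (v in variants) {
    gts <- lapply(seq_len(n), function(i) {
      if (pscn[i] == 0L) return(character(0))
      g <- rep(v$ref, pscn[i])
      if (i == v$copy) g[v$haps] <- v$alt
      g
    })
    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      pos = v$pos, ref = v$ref, alt = v$alt, type = v$type,
      genotypes = list(gts), is_psv_site = FALSE, agg_variant = TRUE)
  }
  for (k in seq_len(nrow(locus$psv_table))) {
    refs <- locus$psv_table$ref_alleles[[k]]
    nonref <- FALSE
    gts <- lapply(seq_len(n), function(i) {
      if (pscn[i] == 0L) return(character(0))
      psv_real[[i]][k, ]
    })
    for (i in seq_len(n)) {
      if (pscn[i] > 0L && !is.na(refs[i]) && any(gts[[i]] != refs[i])) {
        nonref <- TRUE
      }
    }
    if (nonref) {
      p <- locus$psv_table$pos[k]
      alts <- setdiff(unique(c(unlist(gts), refs[!is.na(refs)])),
                      ref_base(map, p))
      ref_agg <- format_gt(allele_order(unlist(lapply(seq_len(n),
        function(i) rep(refs[i], pscn[i])))))
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        pos = p, ref = ref_base(map, p),
        alt = paste(sort(alts), collapse = ","),
        type = "sub", genotypes = list(gts), is_psv_site = TRUE,
        agg_variant = format_gt(allele_order(unlist(gts))) != ref_agg)
    }
  }
  truth <- if (length(truth_rows)) {
    arrange(bind_rows(truth_rows), .data$pos)
  } else {
    tibble(pos = integer(0), ref = character(0), alt = character(0),
           type = character(0), genotypes = list(), is_psv_site = logical(0),
           agg_variant = logical(0))
  }

  # --- haplotype sequences and coordinate maps
  hap_rows <- list()
  for (i in seq_len(n)) {
    for (h in seq_len(pscn[i])) {
      chars <- ref_chars[[i]]
      if (nrow(locus$psv_table) > 0L) {
        chars[psv_pos + 1L] <- psv_real[[i]][, h]
      }
      copy_map <- 0:(len - 1L)
      vs <- Filter(function(v) v$copy == i && h %in% v$haps, variants)
      if (length(vs)) {
        ord <- order(vapply(vs, `[[`, numeric(1), "pos"), decreasing = TRUE)
        for (v in vs[ord]) {
          p <- v$pos
          if (v$type == "sub") {
            chars[p + 1L] <- v$alt
          } else if (v$type == "ins") {
            ins <- strsplit(substr(v$alt, 2L, nchar(v$alt)), "")[[1L]]
            chars <- append(chars, ins, after = p + 1L)
            copy_map <- append(copy_map, rep(NA_integer_, length(ins)),
                               after = p + 1L)
          } else {
            dl <- nchar(v$ref) - 1L
            chars <- chars[-((p + 2L):(p + 1L + dl))]
            copy_map <- copy_map[-((p + 2L):(p + 1L + dl))]
          }
        }
      }
      hap_rows[[length(hap_rows) + 1L]] <- tibble(
        copy = i, hap = h, seq = paste(chars, collapse = ""),
        copy_map = list(copy_map))
    }
  }
  structure(list(haplotypes = bind_rows(hap_rows), truth = truth,
                 locus = locus),
            class = "lcr_sample")
}

# CIGAR string for a read spanning haplotype interval [s, e) (0-based),
# given the haplotype's per-base source-copy positions. Returns list
# (pos, cigar) with pos the 0-based leftmost source position, or NULL if
# the read has no aligned base.
cigar_from_map <- function(copy_map, s, e) {
  v <- copy_map[(s + 1L):e]
  if (all(is.na(v))) return(NULL)
  # fast path: fully aligned, contiguous segment
  if (!anyNA(v) && v[length(v)] - v[1L] == length(v) - 1L) {
    return(list(pos = v[1L], cigar = paste0(length(v), "M")))
  }
  first <- which(!is.na(v))[1L]
  last <- max(which(!is.na(v)))
  ops <- character(0); lens <- integer(0)
  push <- function(op, l) {
    if (l <= 0L) return()
    k <- length(ops)
    if (k > 0L && ops[k] == op) lens[k] <<- lens[k] + l
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- l }
  }
  if (first > 1L) push("S", first - 1L)
  prev <- NA_integer_
  for (t in first:last) {
    if (is.na(v[t])) push("I", 1L)
    else {
      if (!is.na(prev) && v[t] > prev + 1L) push("D", v[t] - prev - 1L)
      push("M", 1L)
      prev <- v[t]
    }
  }
  if (last < length(v)) push("S", length(v) - last)
  list(pos = v[first], cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate paired-end reads from a sample
#'
#' Fragments are sampled uniformly along each haplotype (fragment starts
#' extend past the locus ends so edge coverage does not decay; reads are
#' clipped to the locus). Per-base substitution errors are applied at rate
#' `epsilon`. Each pair's reported alignment copy is the copy whose PSV
#' alleles best match the pair's (possibly erroneous) bases — or a random
#' copy for pairs covering no PSV — emulating ambiguous mapping; the true
#' copy and haplotype are kept in `true_copy` / `true_hap`.
#'
#' @param sample_obj An `lcr_sample` from [simulate_sample()].
#' @return Tibble of alignments compatible with [read_alignments()] output
#'   (`qname`, `copy`, `pos`, `cigar`, `seq`, `qual`, `strand`,
#'   `is_first`) plus `true_copy` and `true_hap`.
#' @export
simulate_reads <- function(sample_obj) {
  locus <- sample_obj$locus
  config <- locus$config
  set.seed(config$seed + 2L)
  map <- locus$map
  rl <- config$read_length
  psv_pos <- locus$psv_table$pos
  psv_mat <- if (nrow(locus$psv_table)) {
    do.call(rbind, locus$psv_table$ref_alleles)
  } else matrix(character(0), 0, config$n_copies)

  empty <- tibble(qname = character(0), copy = character(0),
                  pos = integer(0), cigar = character(0), seq = character(0),
                  qual = character(0), strand = character(0),
                  is_first = logical(0), true_copy = character(0),
                  true_hap = integer(0))
  hap_tabs <- list()
  pair_no <- 0L
  for (hrow in seq_len(nrow(sample_obj$haplotypes))) {
    hp <- sample_obj$haplotypes[hrow, ]
    hap_len <- nchar(hp$seq)
    copy_map <- hp$copy_map[[1L]]
    n_frag <- round(config$depth / 2 * (hap_len + config$fragment_mean) /
                      (2 * rl))
    if (config$depth == 0 || n_frag <= 0L) next
    frag_len <- pmax(2L * rl,
                     round(rnorm(n_frag, config$fragment_mean,
                                 config$fragment_sd)))
    frag_start <- sample.int(hap_len + config$fragment_mean, n_frag,
                             replace = TRUE) - config$fragment_mean - 1L
    pair_id <- pair_no + seq_len(n_frag)
    pair_no <- pair_no + n_frag
    # two mates per fragment, clipped to the haplotype
    s <- c(pmax(0L, frag_start),
           pmax(0L, frag_start + frag_len - rl))
    e <- c(pmin(hap_len, frag_start + rl),
           pmin(hap_len, frag_start + frag_len))
    rd <- tibble(
      pair = rep(pair_id, 2L),
      s = s, e = e,
      strand = rep(c("+", "-"), each = n_frag),
      is_first = rep(c(TRUE, FALSE), each = n_frag))
    rd <- rd[rd$e - rd$s >= 30L, , drop = FALSE]
    if (nrow(rd) == 0L) next
    rd$seq <- substring(hp$seq, rd$s + 1L, rd$e)
    # substitution errors
    if (config$epsilon > 0) {
      n_err <- rbinom(nrow(rd), rd$e - rd$s, config$epsilon)
      for (r in which(n_err > 0L)) {
        pos <- sample.int(rd$e[r] - rd$s[r], n_err[r])
        for (pp in pos) {
          old <- substr(rd$seq[r], pp, pp)
          substr(rd$seq[r], pp, pp) <- sample(setdiff(c("A", "C", "G", "T"),
                                                      old), 1L)
        }
      }
    }
    # alignment against the source copy: fast path for reads not touching
    # an indel-edited region of the haplotype
    irregular <- is.na(copy_map) |
      c(TRUE, diff(copy_map) != 1L | is.na(diff(copy_map)))
    irregular[1L] <- is.na(copy_map[1L])
    cum_irr <- cumsum(irregular)
    plain <- !is.na(copy_map[rd$s + 1L]) &
      cum_irr[rd$e] - cum_irr[rd$s + 1L] == 0L
    rd$pos <- NA_integer_
    rd$cigar <- NA_character_
    rd$pos[plain] <- copy_map[rd$s[plain] + 1L]
    rd$cigar[plain] <- paste0(rd$e[plain] - rd$s[plain], "M")
    for (r in which(!plain)) {
      cg <- cigar_from_map(copy_map, rd$s[r], rd$e[r])
      if (is.null(cg)) next
      rd$pos[r] <- cg$pos
      rd$cigar[r] <- cg$cigar
    }
    rd <- rd[!is.na(rd$pos), , drop = FALSE]
    if (nrow(rd) == 0L) next
    rd$hap_row <- hrow
    hap_tabs[[length(hap_tabs) + 1L]] <- rd
  }
  if (length(hap_tabs) == 0L) return(empty)
  rd <- bind_rows(hap_tabs)

  # reported copy per pair: best PSV match, or random copy with no PSV
  haps <- sample_obj$haplotypes
  rd$true_copy_idx <- haps$copy[rd$hap_row]
  n_pairs_total <- pair_no
  rep_copy <- sample.int(config$n_copies, n_pairs_total, replace = TRUE)
  if (length(psv_pos)) {
    # PSV hits per read (positions in source-copy coordinates; identical
    # across copies since PSVs are substitutions)
    hit_rows <- vector("list", nrow(rd))
    for (r in seq_len(nrow(rd))) {
      cm <- haps$copy_map[[rd$hap_row[r]]]
      seg <- cm[(rd$s[r] + 1L):rd$e[r]]
      hk <- which(!is.na(seg) & seg %in% psv_pos)
      if (length(hk)) {
        hit_rows[[r]] <- tibble(
          pair = rd$pair[r], psv = match(seg[hk], psv_pos),
          base = substring(rd$seq[r], hk, hk))
      }
    }
    hits <- bind_rows(hit_rows)
    if (nrow(hits)) {
      score <- vapply(seq_len(config$n_copies), function(j) {
        as.numeric(hits$base == psv_mat[hits$psv, j])
      }, numeric(nrow(hits)))
      score <- matrix(score, ncol = config$n_copies)
      agg_score <- rowsum(score, hits$pair)
      covered_pairs <- as.integer(rownames(agg_score))
      best <- apply(agg_score, 1L, function(sc) {
        b <- which(sc == max(sc))
        if (length(b) == 1L) b else sample(b, 1L)
      })
      rep_copy[covered_pairs] <- best
    }
  }
  ord <- order(rd$pair, !rd$is_first)
  rd <- rd[ord, , drop = FALSE]
  tibble(
    qname = sprintf("%s_p%06d", locus$locus_id, rd$pair),
    copy = map$copy_ids[rep_copy[rd$pair]],
    pos = rd$pos,
    cigar = rd$cigar,
    seq = rd$seq,
    qual = strrep("?", nchar(rd$seq)),  # Q30
    strand = rd$strand,
    is_first = rd$is_first,
    true_copy = map$copy_ids[rd$true_copy_idx],
    true_hap = haps$hap[rd$hap_row])
}

#' Simulate a complete fixture bundle
#'
#' Runs [simulate_locus()], [simulate_sample()] and [simulate_reads()] and
#' returns everything the caller needs, optionally writing the on-disk
#' bundle (FASTA, SAM, truth VCF, PSV/homology/copy-number TSVs, JSON
#' config echo) with [write_bundle()].
#'
#' @param config An [sim_config()].
#' @param locus_id Locus identifier.
#' @param dir Optional output directory; when given, all files are written.
#' @return List of class `lcr_bundle` with `locus`, `sample`, `reads`,
#'   `profile` (copy-number tibble) and `dir`.
#' @export
simulate_bundle <- function(config, locus_id = "locus1", dir = NULL) {
  locus <- simulate_locus(config, locus_id)
  smp <- simulate_sample(locus)
  reads <- simulate_reads(smp)
  profile <- tibble(
    sample_id = "sim_sample", locus_id = locus_id,
    copy = locus$map$copy_ids,
    pscn = as.integer(config$pscn),
    agcn = sum(as.integer(config$pscn)))
  bundle <- structure(list(locus = locus, sample = smp, reads = reads,
                           profile = profile, dir = dir),
                      class = "lcr_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}
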