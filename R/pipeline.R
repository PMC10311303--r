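# Whole-locus variant calling pipeline: pooling -> aggregate discovery ->
# informative PSV selection -> paralog-specific genotyping -> filters.

#' Pipeline parameters
#'
#' Defaults follow the method's published operating point: base quality
#' cutoff 10, candidate quality >= 1, informativeness threshold 0.99,
#' conflict binomial p < 1e-3 on >= 3 co-covering pairs, strand-bias
#' Fisher p < 0.01, mutation-rate prior 1e-3, recommended output variant
#' quality 21.
#'
#' @param epsilon Per-base sequencing error rate.
#' @param xi Mutation-rate prior for novel variants.
#' @param min_base_quality Minimum base quality of retained observations.
#' @param informative_threshold Posterior needed to call a PSV informative.
#' @param conflict_p,conflict_min_pairs Conflict-test threshold and
#'   minimum co-covering read pairs.
#' @param fet_p Strand-bias Fisher test failure threshold.
#' @param min_candidate_quality Candidate sites below this aggregate
#'   quality are dropped (PSVs are always kept).
#' @param output_quality Variants below this quality are flagged LowQual.
#' @param min_alt_obs Minimum read-pair support to nominate an allele.
#' @param agg_min_posterior Aggregate genotypes below this posterior are
#'   excluded from the paralog genotype space.
#' @param max_alleles Maximum alleles per site (reference and PSV alleles
#'   are always kept).
#' @return List of class `lcr_params`.
#' @export
lcr_params <- function(epsilon = 0.01, xi = 1e-3, min_base_quality = 10,
                       informative_threshold = 0.99, conflict_p = 1e-3,
                       conflict_min_pairs = 3L, fet_p = 0.01,
                       min_candidate_quality = 1, output_quality = 21,
                       min_alt_obs = 2L, agg_min_posterior = 1e-6,
                       max_alleles = 4L) {
  structure(as.list(environment()), class = "lcr_params")
}

empty_calls <- function() {
  tibble(locus_id = character(0), pos = integer(0), ref = character(0),
         alt = character(0), is_psv = logical(0), depth = integer(0),
         ad = list(), agg_genotype = character(0), agg_quality = numeric(0),
         resolved = logical(0), genotype = character(0), per_copy = list(),
         quality = numeric(0), gq = list(), strand_p = numeric(0),
         filter = character(0), variant = logical(0),
         agg_variant = logical(0), n_pairs = integer(0))
}

#' Call variants on one LCR locus
#'
#' Runs the three-step multilocus pipeline on a single locus: (1) pool
#' reads from all repeat copies onto the representative copy and discover
#' candidate sites with the polyploid multinomial model at ploidy =
#' aggregate copy number; (2) identify informative PSVs from population
#' reference-allele frequencies, remove conflicting PSVs via the binomial
#' test and greedy conflict-graph pruning; (3) assign paralog-specific
#' genotypes using read-pair location probabilities, apply the
#' strand-bias and quality filters.
#'
#' @param reads Alignment tibble ([read_alignments()] /
#'   [simulate_reads()]).
#' @param map Homology map of the locus.
#' @param psv_table PSV table (as from [simulate_locus()] or
#'   [read_psv_table()]).
#' @param pscn Paralog-specific copy numbers, in homology-map copy order.
#' @param params An [lcr_params()].
#' @param locus_id Locus identifier for the output.
#' @param extra_sites Optional tibble of externally supplied candidate
#'   sites (columns `pos`, 0-based on the representative copy, and
#'   optionally `ref_len`), merged with the internally discovered
#'   candidates — e.g. candidates lifted from an external caller's VCF.
#' @return Object of class `lcr_callset`: list with `calls` (tibble, one
#'   row per candidate site; rows with `variant == TRUE` are emitted to
#'   VCF), `psv_calls` (annotated PSV tibble), `stats`, `map`, `params`.
#' @export
call_locus <- function(reads, map, psv_table, pscn,
                       params = lcr_params(), locus_id = "locus1",
                       extra_sites = NULL) {
  pscn <- as.integer(pscn)
  stopifnot(length(pscn) == map$n_copies)
  agcn <- sum(pscn)
  if (agcn < 1L) abort("Aggregate copy number must be at least 1.")
  n <- map$n_copies
  eps <- params$epsilon
  empty_psv <- tibble(psv_id = character(0), pos = integer(0),
                      min_freq = numeric(0), map_genotype = character(0),
                      map_posterior = numeric(0), informative = logical(0),
                      retained = logical(0), conflict_p = numeric(0))

  if (is.null(reads) || nrow(reads) == 0L) {
    return(structure(list(calls = empty_calls(), psv_calls = empty_psv,
                          stats = list(n_reads = 0L),
                          map = map, pscn = pscn, params = params,
                          locus_id = locus_id),
                     class = "lcr_callset"))
  }
  pileup <- pool_reads(reads, map, params$min_base_quality)
  rl <- pileup$mean_read_len
  sites <- candidate_positions(pileup, map, psv_table$pos,
                               params$min_alt_obs)
  sites$external <- FALSE
  if (!is.null(extra_sites) && nrow(extra_sites)) {
    if (!"ref_len" %in% names(extra_sites)) extra_sites$ref_len <- 1L
    extra <- extra_sites[!extra_sites$pos %in% sites$pos, , drop = FALSE]
    extra$external <- TRUE
    sites <- arrange(
      bind_rows(sites, extra[, c("pos", "ref_len", "external")]),
      .data$pos)
  }
  obs <- site_observations(pileup, sites)

  psv_idx_of_site <- match(sites$pos, psv_table$pos)
  psv_idx_of_site[sites$ref_len > 1L &
                    !is.na(psv_idx_of_site)] <- NA_integer_

  # --- per-site allele sets, depths, aggregate posteriors
  site_data <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    p <- sites$pos[s]
    L <- sites$ref_len[s]
    ref <- substr(map$seqs[[1L]], p + 1L, p + L)
    o <- obs[obs$site_id == s, , drop = FALSE]
    k <- psv_idx_of_site[s]
    psv_alleles <- if (!is.na(k)) {
      unique(psv_table$ref_alleles[[k]][!is.na(psv_table$ref_alleles[[k]])])
    } else character(0)
    counts <- sort(table(o$allele), decreasing = TRUE)
    # min_alt_obs governs discovery; at externally nominated sites alleles
    # only need the baseline two supporting pairs
    alt_floor <- if (sites$external[s]) min(2L, params$min_alt_obs) else
      params$min_alt_obs
    supported <- names(counts)[counts >= alt_floor]
    protected <- unique(c(ref, psv_alleles))
    extra <- setdiff(supported, protected)
    alleles <- c(protected,
                 head(extra, max(0L, params$max_alleles - length(protected))))
    alleles <- alleles[nchar(alleles) + 1 < rl]
    alleles <- allele_order(alleles)
    o <- o[o$allele %in% alleles, , drop = FALSE]
    depths <- vapply(alleles, function(a) sum(o$allele == a), integer(1))
    agg <- aggregate_posterior(depths, alleles, agcn, rl, eps,
                               ref_allele = ref)
    site_data[[s]] <- list(pos = p, ref = ref, alleles = alleles,
                           depths = depths, obs = o, agg = agg,
                           psv_idx = k)
  }

  is_psv_site <- !is.na(psv_idx_of_site)
  agg_qual <- vapply(site_data, function(d) d$agg$ref_quality, numeric(1))
  is_candidate <- is_psv_site | (!is.na(agg_qual) &
                                   agg_qual >= params$min_candidate_quality)

  # --- step 2: informative PSVs
  psv_sites_idx <- which(is_psv_site)
  psv_calls <- empty_psv
  informative_sites <- integer(0)
  if (length(psv_sites_idx)) {
    prows <- vector("list", length(psv_sites_idx))
    for (ii in seq_along(psv_sites_idx)) {
      s <- psv_sites_idx[ii]
      d <- site_data[[s]]
      k <- d$psv_idx
      refs <- psv_table$ref_alleles[[k]]
      freqs <- psv_table$freqs[[k]]
      usable <- !anyNA(refs) && !anyNA(freqs) &&
        length(unique(refs)) > 1L && all(pscn >= 0L)
      if (usable) {
        pc <- psv_paralog_posterior(
          setNames(d$depths, d$alleles), refs, pmin(freqs, 1 - 1e-9), pscn,
          mean_read_len = rl, epsilon = eps,
          threshold = params$informative_threshold, alleles = d$alleles)
        prows[[ii]] <- tibble(
          psv_id = psv_table$psv_id[k], pos = d$pos,
          min_freq = min(freqs), map_genotype = pc$map_genotype,
          map_posterior = pc$map_posterior, informative = pc$informative,
          site = s)
      } else {
        prows[[ii]] <- tibble(
          psv_id = psv_table$psv_id[k], pos = d$pos,
          min_freq = suppressWarnings(min(freqs, na.rm = TRUE)),
          map_genotype = NA_character_, map_posterior = NA_real_,
          informative = FALSE, site = s)
      }
    }
    psv_calls <- bind_rows(prows)

    # conflict graph among informative PSVs
    inf <- psv_calls[psv_calls$informative, , drop = FALSE]
    edges <- tibble(psv1 = character(0), psv2 = character(0),
                    p_value = numeric(0))
    if (nrow(inf) >= 2L) {
      obs_psv <- bind_rows(lapply(inf$site, function(s) {
        d <- site_data[[s]]
        tibble(qname = d$obs$qname, allele = d$obs$allele, site = s)
      }))
      jj <- inner_join(obs_psv, obs_psv, by = "qname",
                       relationship = "many-to-many",
                       suffix = c("1", "2"))
      jj <- jj[jj$site1 < jj$site2, , drop = FALSE]
      if (nrow(jj)) {
        refs_of <- function(s) {
          psv_table$ref_alleles[[site_data[[s]]$psv_idx]]
        }
        pair_tab <- jj |>
          group_by(.data$site1, .data$site2) |>
          summarise(
            n_total = dplyr::n(),
            n_discordant = {
              r1 <- refs_of(.data$site1[1L]); r2 <- refs_of(.data$site2[1L])
              conc <- vapply(seq_along(.data$allele1), function(t) {
                any(!is.na(r1) & !is.na(r2) &
                      r1 == .data$allele1[t] & r2 == .data$allele2[t])
              }, logical(1))
              sum(!conc)
            }, .groups = "drop")
        ct <- conflict_test(pair_tab$n_discordant, pair_tab$n_total,
                            epsilon = eps, p_threshold = params$conflict_p,
                            min_pairs = params$conflict_min_pairs)
        conf <- which(ct$is_conflict)
        if (length(conf)) {
          edges <- tibble(
            psv1 = psv_calls$psv_id[match(pair_tab$site1[conf],
                                          psv_calls$site)],
            psv2 = psv_calls$psv_id[match(pair_tab$site2[conf],
                                          psv_calls$site)],
            p_value = ct$p_value[conf])
        }
      }
    }
    pruned <- prune_conflicts(
      inf[, c("psv_id", "min_freq", "pos")], edges[, c("psv1", "psv2")])
    psv_calls$retained <- psv_calls$informative &
      psv_calls$psv_id %in% pruned$psv_id[pruned$retained]
    psv_calls$conflict_p <- NA_real_
    if (nrow(edges)) {
      worst <- tapply(edges$p_value, edges$psv1, min)
      psv_calls$conflict_p[match(names(worst), psv_calls$psv_id)] <-
        as.numeric(worst)
    }
    informative_sites <- psv_calls$site[psv_calls$retained]
  }

  # --- read-pair location probabilities (shared across variants)
  pr_default <- pscn / agcn
  pr_by_qname <- new.env(parent = emptyenv())
  if (length(informative_sites)) {
    obs_inf <- bind_rows(lapply(informative_sites, function(s) {
      d <- site_data[[s]]
      tibble(qname = d$obs$qname, allele = d$obs$allele, site = s)
    }))
    if (nrow(obs_inf)) {
      refs_mat_of <- function(sv) {
        do.call(rbind, lapply(sv, function(s) {
          psv_table$ref_alleles[[site_data[[s]]$psv_idx]]
        }))
      }
      for (grp in split(seq_len(nrow(obs_inf)), obs_inf$qname)) {
        qn <- obs_inf$qname[grp[1L]]
        assign(qn, locate_read_pair(
          obs_inf$allele[grp], refs_mat_of(obs_inf$site[grp]), pscn, eps),
          envir = pr_by_qname)
      }
    }
  }

  # --- step 3: paralog-specific genotyping of candidate sites
  call_rows <- vector("list", sum(is_candidate))
  ci <- 0L
  for (s in which(is_candidate)) {
    d <- site_data[[s]]
    k <- d$psv_idx
    site_is_psv <- !is.na(k) && !anyNA(psv_table$ref_alleles[[k]])
    refs_site <- if (site_is_psv) psv_table$ref_alleles[[k]] else
      rep(d$ref, n)
    freqs_site <- if (site_is_psv) pmin(psv_table$freqs[[k]], 1 - 1e-9) else
      NULL
    o <- d$obs
    rp <- NULL
    if (nrow(o)) {
      linked <- vapply(o$qname, function(qn) {
        exists(qn, envir = pr_by_qname, inherits = FALSE)
      }, logical(1))
      rp <- tibble(
        allele = o$allele,
        pr = lapply(seq_len(nrow(o)), function(t) {
          if (linked[t]) get(o$qname[t], envir = pr_by_qname) else
            pr_default
        }),
        linked = linked)
    }
    vc <- ps_genotype_posterior(rp, d$agg, pscn, refs_site,
                                freqs = freqs_site, epsilon = eps,
                                xi = params$xi,
                                agg_min_posterior = params$agg_min_posterior)
    ref_agg <- format_gt(allele_order(
      unlist(lapply(seq_len(n), function(i) rep(refs_site[i], pscn[i])))))
    if (vc$resolved) {
      variant <- !reference_compatible(vc$map_per_copy, refs_site)
      var_alleles <- unique(unlist(vc$map_per_copy))
    } else {
      variant <- d$agg$map_genotype != ref_agg
      var_alleles <- strsplit(d$agg$map_genotype, "/", fixed = TRUE)[[1L]]
    }
    # ALT = every allele involved in the MAP genotype plus any displaced
    # per-copy reference allele (so copy-conversion variants, where a copy
    # carries the representative allele instead of its own, stay encodable)
    alt <- setdiff(unique(c(var_alleles,
                            strsplit(d$agg$map_genotype, "/",
                                     fixed = TRUE)[[1L]],
                            if (variant) refs_site)), d$ref)
    if (length(alt) == 0L || nrow(o) == 0L) variant <- FALSE
    is_alt_obs <- o$allele != d$ref
    fet <- strand_bias_filter(sum(!is_alt_obs & o$strand == "+"),
                              sum(!is_alt_obs & o$strand == "-"),
                              sum(is_alt_obs & o$strand == "+"),
                              sum(is_alt_obs & o$strand == "-"),
                              p_threshold = params$fet_p)
    flags <- c(if (!fet$pass) "StrandBias",
               if (vc$quality < params$output_quality) "LowQual")
    ci <- ci + 1L
    call_rows[[ci]] <- tibble(
      locus_id = locus_id, pos = d$pos, ref = d$ref,
      alt = paste(allele_order(alt), collapse = ","),
      is_psv = site_is_psv, depth = nrow(o),
      ad = list(setNames(d$depths, d$alleles)),
      agg_genotype = d$agg$map_genotype,
      agg_quality = d$agg$ref_quality,
      resolved = vc$resolved,
      genotype = vc$map_genotype,
      per_copy = list(vc$map_per_copy),
      quality = vc$quality,
      gq = list(vc$gq),
      strand_p = fet$p_value,
      filter = if (length(flags)) paste(flags, collapse = ";") else "PASS",
      variant = variant,
      agg_variant = variant && d$agg$map_genotype != ref_agg,
      n_pairs = nrow(o))
  }
  calls <- if (ci) arrange(bind_rows(call_rows), .data$pos) else
    empty_calls()

  stats <- list(
    n_reads = nrow(reads),
    n_pairs_pooled = length(unique(reads$qname)),
    n_dropped = pileup$n_dropped,
    mean_read_len = rl,
    n_sites = nrow(sites),
    n_candidates = sum(is_candidate),
    n_psvs = length(psv_sites_idx),
    n_informative = sum(psv_calls$informative),
    n_retained_informative = length(informative_sites),
    n_variants = sum(calls$variant),
    n_resolved = sum(calls$variant & calls$resolved),
    n_unresolved = sum(calls$variant & !calls$resolved))
  psv_calls$site <- NULL
  structure(list(calls = calls, psv_calls = psv_calls, stats = stats,
                 map = map, pscn = pscn, params = params,
                 locus_id = locus_id),
            class = "lcr_callset")
}

#' @export
print.lcr_callset <- function(x, ...) {
  s <- x$stats
  cat("LCR call set for", x$locus_id, "\n")
  if (!is.null(s$n_pairs_pooled)) {
    cat(sprintf(
      "  %d read pairs pooled; %d candidate sites; %d/%d PSVs informative (%d retained)\n",
      s$n_pairs_pooled, s$n_candidates, s$n_informative, s$n_psvs,
      s$n_retained_informative))
    cat(sprintf("  %d variants (%d resolved, %d unresolved)\n",
                s$n_variants, s$n_resolved, s$n_unresolved))
  } else cat("  no reads\n")
  invisible(x)
}

#' Call variants from a simulation bundle or bundle directory
#'
#' Convenience wrapper: checks locus eligibility from the copy-number
#' profile, then runs [call_locus()] on each callable locus.
#'
#' @param x An `lcr_bundle` or a directory written by [write_bundle()].
#' @param params An [lcr_params()].
#' @param benchmark_mode,extended_copy Passed to [locus_eligibility()].
#' @return List with `callsets` (per callable locus), `manifest`
#'   (eligibility tibble).
#' @export
call_variants <- function(x, params = lcr_params(),
                          benchmark_mode = FALSE, extended_copy = FALSE) {
  if (is.character(x)) {
    dir <- x
    reads <- read_alignments(file.path(dir, "reads.sam"))
    map <- read_homology_map(file.path(dir, "homology_map.tsv"))
    psv_table <- read_psv_table(file.path(dir, "psv_table.tsv"))
    profile <- read_copy_number_profile(file.path(dir, "copy_number.tsv"))
  } else {
    stopifnot(inherits(x, "lcr_bundle"))
    reads <- x$reads
    map <- x$locus$map
    psv_table <- x$locus$psv_table
    profile <- x$profile
  }
  manifest <- locus_eligibility(profile, benchmark_mode, extended_copy)
  callsets <- list()
  for (i in which(manifest$status == "callable")) {
    lid <- manifest$locus_id[i]
    prof <- profile[profile$locus_id == lid, , drop = FALSE]
    pscn <- prof$pscn[match(map$copy_ids, prof$copy)]
    callsets[[lid]] <- call_locus(reads, map, psv_table, pscn, params,
                                  locus_id = lid)
  }
  list(callsets = callsets, manifest = manifest)
}

# trim the longest common suffix shared by ref and all alleles (keeping at
# least one base each) so equivalent indel representations compare equal
normalize_alleles <- function(ref, alleles) {
  all_a <- c(ref, alleles)
  while (all(nchar(all_a) > 1L)) {
    last <- substring(all_a, nchar(all_a), nchar(all_a))
    if (length(unique(last)) != 1L) break
    all_a <- substring(all_a, 1L, nchar(all_a) - 1L)
  }
  list(ref = all_a[1L], alleles = all_a[-1L])
}

norm_gts <- function(ref, gts) {
  lapply(gts, function(g) {
    if (length(g) == 0L) return(g)
    allele_order(normalize_alleles(ref, g)$alleles)
  })
}

#' Evaluate calls against a truth set
#'
#' Genotype-aware matching: a call is an aggregate-level true positive if
#' a truth variant at the same position has the same aggregate genotype
#' (after normalising equivalent indel representations), and a
#' paralog-level true positive if additionally the call is resolved and
#' every per-copy genotype matches the truth. Precision is `NA` when no
#' variants were called.
#'
#' @param calls Calls tibble (rows with `variant == TRUE` are evaluated)
#'   or an `lcr_callset`.
#' @param truth Truth tibble from [simulate_sample()] (or
#'   [write_truth_vcf()] read back).
#' @return Object of class `lcr_eval`: list with `metrics` (tibble over
#'   level x variant type: tp/fp/fn, precision, recall, F1, F0.5),
#'   `concordance` (per-type genotype concordance among resolved matched
#'   calls) and `detail` (per-site join).
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(calls, "lcr_callset")) calls <- calls$calls
  if ("variant" %in% names(calls)) {
    calls <- calls[calls$variant, , drop = FALSE]
  }
  type_of <- function(ref, alt) {
    alts <- unlist(strsplit(alt, ",", fixed = TRUE))
    if (all(nchar(c(ref, alts)) == 1L)) "snv" else "indel"
  }
  calls$vtype <- vapply(seq_len(nrow(calls)),
                        function(i) type_of(calls$ref[i], calls$alt[i]),
                        character(1))
  truth$vtype <- ifelse(truth$type == "sub", "snv", "indel")
  norm_alt_set <- function(ref, alt) {
    alts <- unlist(strsplit(alt, ",", fixed = TRUE))
    alts <- alts[nzchar(alts)]
    if (length(alts) == 0L) return(character(0))
    normalize_alleles(ref, alts)$alleles
  }
  truth$alt_set <- lapply(seq_len(nrow(truth)), function(i) {
    norm_alt_set(truth$ref[i], truth$alt[i])
  })
  truth$pg_key <- vapply(seq_len(nrow(truth)), function(i) {
    format_pg(norm_gts(truth$ref[i], truth$genotypes[[i]]))
  }, character(1))
  calls$alt_set <- lapply(seq_len(nrow(calls)), function(i) {
    norm_alt_set(calls$ref[i], calls$alt[i])
  })
  calls$pg_key <- vapply(seq_len(nrow(calls)), function(i) {
    if (!calls$resolved[i] || is.null(calls$per_copy[[i]]))
      return(NA_character_)
    format_pg(norm_gts(calls$ref[i], calls$per_copy[[i]]))
  }, character(1))

  if (!"locus_id" %in% names(calls)) calls$locus_id <- "L"
  if (!"locus_id" %in% names(truth)) {
    truth$locus_id <- if (nrow(calls)) calls$locus_id[1L] else "L"
  }
  calls$site_key <- paste(calls$locus_id, calls$pos)
  truth$site_key <- paste(truth$locus_id, truth$pos)

  m <- match(calls$site_key, truth$site_key)
  calls$agg_tp <- vapply(seq_len(nrow(calls)), function(i) {
    !is.na(m[i]) &&
      length(intersect(calls$alt_set[[i]], truth$alt_set[[m[i]]])) > 0L
  }, logical(1))
  calls$pg_tp <- calls$agg_tp & !is.na(calls$pg_key) &
    calls$pg_key == truth$pg_key[m]
  calls$matched <- !is.na(m)
  truth$found_agg <- truth$site_key %in% calls$site_key[calls$agg_tp]
  truth$found_pg <- truth$site_key %in% calls$site_key[calls$pg_tp]

  # The aggregate level scores the discovery stage: only sites whose
  # aggregate genotype differs from the reference multiset participate
  # (copy-conversion events with a reference-identical aggregate genotype
  # are paralog-level objects and are invisible to pooled discovery).
  if (!"agg_variant" %in% names(calls)) calls$agg_variant <- TRUE
  if (!"agg_variant" %in% names(truth)) truth$agg_variant <- TRUE
  metric_row <- function(level, vt) {
    cc <- if (vt == "all") calls else calls[calls$vtype == vt, , drop = FALSE]
    tt <- if (vt == "all") truth else truth[truth$vtype == vt, , drop = FALSE]
    if (level == "aggregate") {
      cc <- cc[cc$agg_variant, , drop = FALSE]
      tt <- tt[tt$agg_variant, , drop = FALSE]
    }
    tp_col <- if (level == "aggregate") cc$agg_tp else cc$pg_tp
    found <- if (level == "aggregate") tt$found_agg else tt$found_pg
    tp <- sum(tp_col); fp <- nrow(cc) - tp; fn <- sum(!found)
    prec <- if (nrow(cc)) tp / nrow(cc) else NA_real_
    rec <- if (nrow(tt)) sum(found) / nrow(tt) else NA_real_
    fb <- function(b) {
      if (is.na(prec) || is.na(rec) || prec + rec == 0) return(NA_real_)
      (1 + b^2) * prec * rec / (b^2 * prec + rec)
    }
    tibble(level = level, vtype = vt, tp = tp, fp = fp, fn = fn,
           precision = prec, recall = rec, f1 = fb(1), f0.5 = fb(0.5))
  }
  metrics <- bind_rows(lapply(c("aggregate", "paralog"), function(lv) {
    bind_rows(lapply(c("all", "snv", "indel"), function(vt) {
      metric_row(lv, vt)
    }))
  }))

  resolved_matched <- calls[calls$agg_tp & calls$resolved &
                              !is.na(calls$pg_key), , drop = FALSE]
  mm <- match(resolved_matched$site_key, truth$site_key)
  concord <- bind_rows(lapply(c("all", "snv", "indel"), function(vt) {
    rr <- if (vt == "all") rep(TRUE, nrow(resolved_matched)) else
      resolved_matched$vtype == vt
    n_res <- sum(rr)
    n_conc <- sum(resolved_matched$pg_key[rr] == truth$pg_key[mm][rr])
    tibble(vtype = vt, n_resolved = n_res, n_concordant = n_conc,
           concordance = if (n_res) n_conc / n_res else NA_real_)
  }))
  structure(list(metrics = metrics, concordance = concord,
                 detail = calls, truth = truth),
            class = "lcr_eval")
}

#' @export
print.lcr_eval <- function(x, ...) {
  cat("Variant calling evaluation\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 4)
  cat("\nGenotype concordance among resolved matched calls:\n")
  print(as.data.frame(x$concordance), row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
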