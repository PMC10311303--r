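# Paralog-specific genotyping of candidate variants.
#
# Each read pair covering a variant is probabilistically located on a
# repeat copy using the informative PSVs it covers (and the
# paralog-specific copy numbers as location priors); the per-copy genotype
# posterior then mixes per-location allele emissions over those location
# probabilities.

#' Read-pair location probabilities across repeat copies
#'
#' The probability that repeat copy `i` is the true origin of a read pair,
#' given the informative PSVs the pair covers:
#' `pr(i) ∝ pscn[i] * prod_v P(allele of v on copy i | read)`, where the
#' per-PSV factor is `1 - epsilon` if the read's base matches copy `i`'s
#' allele, `epsilon` if it mismatches, and `epsilon^2` when the PSV is
#' missing from copy `i` (copy shorter than the others). With no PSVs
#' covered the location prior `pscn / sum(pscn)` is returned.
#'
#' @param obs_alleles Character vector of the pair's observed alleles at
#'   the covered informative PSVs (length m, possibly 0).
#' @param psv_alleles m x n character matrix of each PSV's allele on every
#'   repeat copy; `NA` marks a PSV missing from a copy.
#' @param pscn Paralog-specific copy numbers (length n).
#' @param epsilon Per-base error rate.
#' @param anchored_copy Optional copy index to which the pair is anchored
#'   by alignment outside the duplicated region; treated as one
#'   perfectly-matching pseudo-PSV on that copy.
#' @return Numeric vector `pr` of length n, summing to 1; copies with
#'   `pscn == 0` get 0.
#' @export
locate_read_pair <- function(obs_alleles, psv_alleles, pscn, epsilon = 0.01,
                             anchored_copy = NULL) {
  pscn <- as.numeric(pscn)
  n <- length(pscn)
  if (sum(pscn) <= 0) abort("All candidate locations have copy number 0.")
  if (length(obs_alleles) > 0L) {
    psv_alleles <- matrix(psv_alleles, nrow = length(obs_alleles))
    stopifnot(ncol(psv_alleles) == n)
    p <- matrix(epsilon, nrow = length(obs_alleles), ncol = n)
    p[psv_alleles == obs_alleles[row(psv_alleles)]] <- 1 - epsilon
    p[is.na(psv_alleles)] <- epsilon^2
    lw <- colSums(log(p))
  } else {
    lw <- rep(0, n)
  }
  if (!is.null(anchored_copy)) {
    lw <- lw + log(ifelse(seq_len(n) == anchored_copy, 1 - epsilon, epsilon))
  }
  w <- ifelse(pscn > 0, pscn * exp(lw - max(lw[pscn > 0])), 0)
  w / sum(w)
}

#' Likelihood of a read pair under a paralog genotype
#'
#' Mixture over repeat copies of a per-copy allele emission:
#' `P(r | g) = sum_i pr(i)/pscn[i] * ((1-epsilon) * mu(a_r, g_i) +
#' epsilon * (pscn[i] - mu(a_r, g_i)))`, where `a_r` is the read's allele
#' at the variant and `mu` the multiplicity of that allele in copy `i`'s
#' multiset.
#'
#' @param pr Location probabilities from [locate_read_pair()].
#' @param per_copy Paralog genotype: list of per-copy allele vectors.
#' @param allele The read pair's observed allele at the variant.
#' @param epsilon Per-base error rate.
#' @return Probability in (0, 1).
#' @export
ps_genotype_likelihood <- function(pr, per_copy, allele, epsilon = 0.01) {
  stopifnot(length(pr) == length(per_copy))
  p <- 0
  for (i in seq_along(pr)) {
    cs <- length(per_copy[[i]])
    if (cs == 0L || pr[i] == 0) next
    mu <- sum(per_copy[[i]] == allele)
    p <- p + pr[i] / cs * ((1 - epsilon) * mu + epsilon * (cs - mu))
  }
  p
}

#' Prior for a paralog genotype at a novel (non-PSV) variant
#'
#' Each copy is penalised by the mutation rate `xi` if it carries any
#' non-reference allele (homozygous and heterozygous non-reference copies
#' are penalised equally), else contributes `1 - xi`.
#'
#' @param per_copy Paralog genotype: list of per-copy allele vectors.
#' @param ref_allele Reference allele of the variant.
#' @param xi Mutation rate (default 1e-3).
#' @return Prior probability.
#' @export
novel_variant_prior <- function(per_copy, ref_allele, xi = 1e-3) {
  p <- 1
  for (g in per_copy) {
    p <- p * if (sum(g == ref_allele) == length(g)) 1 - xi else xi
  }
  p
}

#' Paralog-specific genotype posterior of a variant
#'
#' Combines read-pair location probabilities and allele observations into
#' a posterior over paralog genotypes:
#' `P(g | R) ∝ p(g) * prod_r P(r | g)`, with `p(g)` the population PSV
#' prior (when `freqs` is given) or the novel-variant prior (otherwise).
#' The genotype space is the union of paralog genotype classes of every
#' aggregate genotype whose aggregate posterior exceeds `agg_min_posterior`.
#'
#' @param read_pairs Tibble with one row per read pair covering the
#'   variant: columns `allele` (observed allele) and `pr` (list column of
#'   location probability vectors); optionally `linked` (logical: pair
#'   covers an informative PSV or a nonduplicated anchor).
#' @param aggregate An `lcr_agg_posterior` for the variant site.
#' @param pscn Paralog-specific copy numbers.
#' @param ref_alleles Per-copy reference alleles (length n; for a novel
#'   variant all equal the representative ref allele).
#' @param freqs Per-copy PSV reference-allele frequencies, or `NULL` for a
#'   novel variant (then the prior uses `xi`).
#' @param epsilon Per-base error rate.
#' @param xi Mutation rate for the novel-variant prior.
#' @param agg_min_posterior Aggregate genotypes below this posterior are
#'   excluded from the genotype space.
#' @return An object of class `lcr_variant_call`: list with `table`
#'   (genotype posteriors), `map_genotype`, `map_per_copy`, `resolved`,
#'   `quality` (Phred of all-reference genotype posterior, capped 1000)
#'   and per-copy `gq`. With no read pairs, or none linked to an
#'   informative PSV/anchor, the call is unresolved: the aggregate MAP is
#'   still reported but `map_genotype` is `NA`.
#' @export
ps_genotype_posterior <- function(read_pairs, aggregate, pscn, ref_alleles,
                                  freqs = NULL, epsilon = 0.01, xi = 1e-3,
                                  agg_min_posterior = 1e-6) {
  pscn <- as.integer(pscn)
  stopifnot(inherits(aggregate, "lcr_agg_posterior"),
            sum(pscn) == aggregate$agcn,
            length(ref_alleles) == length(pscn))
  n_pairs <- if (is.null(read_pairs)) 0L else nrow(read_pairs)
  resolved <- n_pairs > 0L
  if (resolved && "linked" %in% names(read_pairs)) {
    resolved <- any(read_pairs$linked)
  }

  keep <- which(aggregate$table$posterior > agg_min_posterior)
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    g <- keep[j]
    agg_alleles <- counts_to_alleles(aggregate$counts[g, ], aggregate$alleles)
    pgs <- enumerate_paralog_genotypes(agg_alleles, pscn)
    rows[[j]] <- tibble(agg_genotype = aggregate$table$genotype[g],
                        genotype = pgs$genotype, per_copy = pgs$per_copy)
  }
  tab <- bind_rows(rows)
  prior <- if (is.null(freqs)) {
    vapply(tab$per_copy, novel_variant_prior, numeric(1),
           ref_allele = ref_alleles[1L], xi = xi)
  } else {
    vapply(tab$per_copy, psv_prior, numeric(1),
           ref_alleles = ref_alleles, freqs = freqs)
  }
  logpost <- log(prior)
  if (n_pairs > 0L) {
    for (r in seq_len(n_pairs)) {
      pr <- read_pairs$pr[[r]]
      a <- read_pairs$allele[r]
      lik <- vapply(tab$per_copy, ps_genotype_likelihood, numeric(1),
                    pr = pr, allele = a, epsilon = epsilon)
      logpost <- logpost + log(lik)
    }
  }
  if (all(!is.finite(logpost))) logpost[] <- 0  # all priors zero: flat
  post <- exp(logpost - logsumexp(logpost))
  tab$prior <- prior
  tab$posterior <- post

  i_map <- which.max(post)
  ref_pg <- vapply(seq_along(pscn), function(i) {
    format_gt(rep(ref_alleles[i], pscn[i]))
  }, character(1))
  ref_label <- paste(ref_pg, collapse = "|")
  p_ref <- sum(post[tab$genotype == ref_label])
  quality <- phred_cap(p_ref)
  # Per-copy genotype qualities: marginal posterior of the MAP copy genotype.
  gq <- vapply(seq_along(pscn), function(i) {
    map_i <- format_gt(tab$per_copy[[i_map]][[i]])
    marg <- sum(post[vapply(tab$per_copy, function(pc) {
      format_gt(pc[[i]]) == map_i
    }, logical(1))])
    phred_cap(1 - marg)
  }, numeric(1))

  structure(
    list(
      table = tab,
      aggregate = aggregate,
      pscn = pscn,
      ref_alleles = ref_alleles,
      n_read_pairs = n_pairs,
      resolved = resolved,
      map_genotype = if (resolved) tab$genotype[i_map] else NA_character_,
      map_per_copy = if (resolved) tab$per_copy[[i_map]] else NULL,
      map_posterior = if (resolved) post[i_map] else NA_real_,
      quality = quality,
      gq = if (resolved) gq else rep(NA_real_, length(pscn))
    ),
    class = "lcr_variant_call"
  )
}

#' @export
print.lcr_variant_call <- function(x, ...) {
  cat("Paralog-specific variant call (", x$n_read_pairs, " read pairs)\n",
      sep = "")
  cat("Aggregate MAP:", x$aggregate$map_genotype, "\n")
  if (x$resolved) {
    cat("MAP paralog genotype:", x$map_genotype,
        sprintf("(posterior %.4g, QUAL %.1f)\n", x$map_posterior, x$quality))
  } else {
    cat("Unresolved: no read pair links the variant to an informative PSV.\n")
  }
  invisible(x)
}

#' Strand-bias filter (Fisher's exact test)
#'
#' Two-sided Fisher's exact test on the 2x2 table of reference /
#' non-reference allele counts by strand. Variants with `p < p_threshold`
#' (default 0.01) fail the filter. An all-zero table passes (no evidence).
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev Non-negative counts (vectorised).
#' @param p_threshold Failure threshold.
#' @return Tibble with columns `p_value` and `pass`.
#' @export
strand_bias_filter <- function(ref_fwd, ref_rev, alt_fwd, alt_rev,
                               p_threshold = 0.01) {
  stopifnot(all(c(ref_fwd, ref_rev, alt_fwd, alt_rev) >= 0))
  n <- length(ref_fwd)
  p <- vapply(seq_len(n), function(i) {
    m <- matrix(c(ref_fwd[i], ref_rev[i], alt_fwd[i], alt_rev[i]), nrow = 2,
                byrow = TRUE)
    if (sum(m) == 0) return(1)
    fisher.test(m)$p.value
  }, numeric(1))
  tibble(p_value = p, pass = p >= p_threshold)
}
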