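# Aggregate (pooled, polyploid) genotype likelihood model.
#
# Allelic depths pooled across all repeat copies are modelled as a
# multinomial draw whose category probabilities depend on the aggregate
# genotype: each allele's weight is proportional to
#   (mean_read_len - |a| - 1) * max(epsilon * agcn, mu(a, g)),
# so alleles absent from the genotype keep a positive error floor and
# longer alleles are down-weighted by the number of read placements that
# can span them.

#' Allele weights under an aggregate genotype
#'
#' Multinomial category probabilities for the allelic depth model: the
#' weight of allele `a` under aggregate genotype `g` is proportional to
#' `(mean_read_len - nchar(a) - 1) * max(epsilon * agcn, multiplicity(a, g))`,
#' normalised over the full allele set. Weights are strictly positive.
#'
#' @param genotype Character vector of alleles (the aggregate genotype
#'   multiset).
#' @param alleles Full allele set of the site.
#' @param mean_read_len Mean aligned read length; must exceed every allele
#'   length + 1.
#' @param epsilon Per-base error rate in (0, 1).
#' @param agcn Aggregate copy number; defaults to `length(genotype)`.
#' @return Named numeric vector of probabilities over `alleles`, summing
#'   to 1.
#' @export
allele_weights <- function(genotype, alleles, mean_read_len = 150,
                           epsilon = 0.01, agcn = length(genotype)) {
  stopifnot(epsilon > 0, epsilon < 1)
  if (any(mean_read_len <= nchar(alleles) + 1)) {
    abort("`mean_read_len` must exceed every allele length + 1.")
  }
  mu <- vapply(alleles, function(a) sum(genotype == a), numeric(1))
  w <- (mean_read_len - nchar(alleles) - 1) * pmax(epsilon * agcn, mu)
  setNames(w / sum(w), alleles)
}

#' @rdname allele_weights
#' @param allele Single allele whose weight is requested.
#' @export
allele_weight <- function(allele, genotype, alleles, mean_read_len = 150,
                          epsilon = 0.01, agcn = length(genotype)) {
  unname(allele_weights(genotype, alleles, mean_read_len, epsilon, agcn)[allele])
}

#' Multinomial likelihood of pooled allelic depths
#'
#' Probability of the observed allelic depth vector given an aggregate
#' genotype, under the multinomial model with category probabilities from
#' [allele_weights()].
#'
#' @param depths Integer vector of allelic depths, aligned with `alleles`.
#' @param genotype Aggregate genotype (character vector of alleles).
#' @inheritParams allele_weights
#' @param log Return the log likelihood?
#' @return Scalar (log-)likelihood.
#' @export
aggregate_likelihood <- function(depths, genotype, alleles,
                                 mean_read_len = 150, epsilon = 0.01,
                                 agcn = length(genotype), log = FALSE) {
  stopifnot(length(depths) == length(alleles), all(depths >= 0))
  w <- allele_weights(genotype, alleles, mean_read_len, epsilon, agcn)
  ll <- dmultinom(depths, prob = w, log = TRUE)
  if (log) ll else exp(ll)
}

# Fast core: log-likelihoods and normalised log-posteriors for every
# aggregate genotype (uniform prior). `alleles` must be in canonical order.
# Returns list(counts, loglik, logpost, posterior).
agg_posterior_core <- function(depths, alleles, agcn, mean_read_len = 150,
                               epsilon = 0.01) {
  k <- length(alleles)
  cnt <- gt_count_matrix(k, agcn)
  lenw <- mean_read_len - nchar(alleles) - 1
  floor_w <- epsilon * agcn
  n <- sum(depths)
  lgfac <- lgamma(n + 1) - sum(lgamma(depths + 1))
  loglik <- vapply(seq_len(nrow(cnt)), function(i) {
    w <- lenw * pmax(floor_w, cnt[i, ])
    w <- w / sum(w)
    lgfac + sum(depths * log(w))
  }, numeric(1))
  logpost <- loglik - logsumexp(loglik)
  list(counts = cnt, loglik = loglik, logpost = logpost,
       posterior = exp(logpost))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Aggregate genotype posterior at a pooled site
#'
#' Evaluates the multinomial likelihood of the pooled allelic depths for
#' every aggregate genotype of size `agcn` over `alleles`, and converts
#' likelihoods to posteriors with a uniform genotype prior (so the MAP
#' genotype is the maximum-likelihood genotype).
#'
#' @param depths Integer vector of allelic depths, one per allele in
#'   `alleles` (any order; they are re-aligned to canonical allele order).
#' @param alleles Character vector of distinct alleles observed/declared at
#'   the site.
#' @param agcn Aggregate copy number (ploidy of the pooled caller).
#' @inheritParams allele_weights
#' @param ref_allele Optional reference allele on the representative copy;
#'   enables the `ref_quality` field (Phred-scaled posterior probability
#'   that the site is not homozygous reference in aggregate).
#' @return An object of class `lcr_agg_posterior`: list with `table`
#'   (tibble of genotype, loglik, posterior), `map_genotype`,
#'   `map_posterior`, `alleles`, `agcn`, `depths` and `ref_quality`.
#'   [generics::tidy()] returns the genotype table, [generics::glance()] a
#'   one-row summary.
#' @examples
#' aggregate_posterior(c(A = 22, G = 8), c("A", "G"), agcn = 4)
#' @export
aggregate_posterior <- function(depths, alleles, agcn, mean_read_len = 150,
                                epsilon = 0.01, ref_allele = NULL) {
  stopifnot(length(depths) == length(alleles))
  ord <- order(nchar(alleles), alleles, method = "radix")
  alleles <- alleles[ord]
  depths <- as.integer(depths[ord])
  if (any(mean_read_len <= nchar(alleles) + 1)) {
    abort("`mean_read_len` must exceed every allele length + 1.")
  }
  core <- agg_posterior_core(depths, alleles, agcn, mean_read_len, epsilon)
  gts <- vapply(seq_len(nrow(core$counts)), function(i) {
    format_gt(counts_to_alleles(core$counts[i, ], alleles))
  }, character(1))
  i_map <- which.max(core$logpost)
  ref_quality <- NA_real_
  if (!is.null(ref_allele) && ref_allele %in% alleles) {
    i_ref <- which(core$counts[, match(ref_allele, alleles)] == agcn)
    ref_quality <- phred_cap(core$posterior[i_ref])
  }
  structure(
    list(
      table = tibble(genotype = gts, loglik = core$loglik,
                     posterior = core$posterior),
      counts = core$counts,
      alleles = alleles,
      depths = setNames(depths, alleles),
      agcn = agcn,
      epsilon = epsilon,
      mean_read_len = mean_read_len,
      map_genotype = gts[i_map],
      map_index = i_map,
      map_posterior = core$posterior[i_map],
      ref_quality = ref_quality
    ),
    class = "lcr_agg_posterior"
  )
}

# Phred scale of a probability (of being wrong), capped at 1000.
phred_cap <- function(p, cap = 1000) {
  q <- -10 * log10(pmax(p, 10^(-cap / 10)))
  pmin(q, cap)
}

#' @export
print.lcr_agg_posterior <- function(x, ...) {
  cat("Aggregate genotype posterior (agcn = ", x$agcn, ", alleles: ",
      paste(x$alleles, collapse = ","), ")\n", sep = "")
  cat("Depths:", paste(sprintf("%s=%d", names(x$depths), x$depths),
                       collapse = " "), "\n")
  cat("MAP genotype:", x$map_genotype,
      sprintf("(posterior %.4g)\n", x$map_posterior))
  invisible(x)
}
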