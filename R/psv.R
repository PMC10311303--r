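# Informative-PSV identification.
#
# A PSV (paralogous sequence variant) is a paralogous site whose per-copy
# reference alleles differ. Population reference-allele frequencies f_i on
# each copy give a prior over paralog-specific genotypes; combined with the
# aggregate genotype posterior they yield a posterior over paralog
# genotypes. A PSV is "informative" when its MAP paralog genotype is
# reference-compatible with high posterior, so reads covering it can be
# assigned to a repeat copy.

#' Population prior of a paralog-specific genotype at a PSV
#'
#' Product over repeat copies of `f_i` per reference allele carried and
#' `(1 - f_i)` per non-reference allele, where `f_i` is the population
#' frequency of the reference allele on copy `i`.
#'
#' @param per_copy List of per-copy allele vectors (a paralog genotype).
#' @param ref_alleles Per-copy reference alleles of the PSV.
#' @param freqs Per-copy reference-allele frequencies, each in (0, 1].
#' @return Prior probability (not normalised over any genotype set).
#' @examples
#' psv_prior(list(c("T", "T"), c("C", "C")), c("T", "C"), c(0.95, 0.9))
#' @export
psv_prior <- function(per_copy, ref_alleles, freqs) {
  stopifnot(length(per_copy) == length(ref_alleles),
            length(freqs) == length(ref_alleles))
  p <- 1
  for (i in seq_along(per_copy)) {
    mu <- sum(per_copy[[i]] == ref_alleles[i])
    cs <- length(per_copy[[i]])
    p <- p * freqs[i]^mu * (1 - freqs[i])^(cs - mu)
  }
  p
}

#' Paralog-specific genotype posterior at a PSV and informativeness call
#'
#' For every aggregate genotype, the paralog genotype posterior is the
#' aggregate posterior times the population prior renormalised within that
#' aggregate genotype's paralog genotype class. The PSV is flagged
#' informative when the MAP paralog genotype has posterior at or above
#' `threshold` (default 0.99) and is reference-compatible.
#'
#' @param depths Named integer vector of pooled allelic depths over the
#'   PSV's allele set.
#' @param ref_alleles Per-copy reference alleles (must contain at least two
#'   distinct values — otherwise the site is not a PSV).
#' @param freqs Per-copy population reference-allele frequencies in (0, 1).
#' @param pscn Paralog-specific copy numbers per copy.
#' @param mean_read_len,epsilon Passed to [aggregate_posterior()].
#' @param threshold Posterior needed to call the PSV informative.
#' @param alleles Optional full allele set; defaults to the union of
#'   `ref_alleles` and names of `depths`.
#' @return An object of class `lcr_psv_call`: list with `table` (tibble of
#'   aggregate genotype, paralog genotype, prior, posterior),
#'   `map_genotype`, `map_posterior`, `informative`,
#'   `reference_compatible`, and inputs. `tidy()`/`glance()` methods apply.
#' @export
psv_paralog_posterior <- function(depths, ref_alleles, freqs, pscn,
                                  mean_read_len = 150, epsilon = 0.01,
                                  threshold = 0.99, alleles = NULL) {
  if (length(unique(ref_alleles)) < 2L) {
    abort("Site is not a PSV: per-copy reference alleles are identical.")
  }
  stopifnot(all(freqs > 0), all(freqs <= 1),
            length(freqs) == length(ref_alleles),
            length(pscn) == length(ref_alleles))
  pscn <- as.integer(pscn)
  if (is.null(alleles)) {
    alleles <- union(ref_alleles, names(depths))
  }
  alleles <- allele_order(alleles)
  d <- setNames(integer(length(alleles)), alleles)
  d[names(depths)] <- as.integer(depths)
  agcn <- sum(pscn)
  agg <- aggregate_posterior(d, alleles, agcn, mean_read_len, epsilon)

  rows <- vector("list", nrow(agg$table))
  for (g in seq_len(nrow(agg$table))) {
    agg_alleles <- counts_to_alleles(agg$counts[g, ], agg$alleles)
    pgs <- enumerate_paralog_genotypes(agg_alleles, pscn)
    prior <- vapply(pgs$per_copy, psv_prior, numeric(1),
                    ref_alleles = ref_alleles, freqs = freqs)
    z <- sum(prior)
    post <- if (z > 0) agg$table$posterior[g] * prior / z else rep(0, length(prior))
    rows[[g]] <- tibble(
      agg_genotype = agg$table$genotype[g],
      genotype = pgs$genotype,
      per_copy = pgs$per_copy,
      prior = prior,
      posterior = post
    )
  }
  tab <- bind_rows(rows)
  i_map <- which.max(tab$posterior)
  ref_comp <- reference_compatible(tab$per_copy[[i_map]], ref_alleles)
  structure(
    list(
      table = tab,
      aggregate = agg,
      ref_alleles = ref_alleles,
      freqs = freqs,
      min_freq = min(freqs),
      pscn = pscn,
      map_genotype = tab$genotype[i_map],
      map_per_copy = tab$per_copy[[i_map]],
      map_posterior = tab$posterior[i_map],
      reference_compatible = ref_comp,
      informative = ref_comp && tab$posterior[i_map] >= threshold,
      threshold = threshold
    ),
    class = "lcr_psv_call"
  )
}

#' @export
print.lcr_psv_call <- function(x, ...) {
  cat("PSV paralog genotype call (ref: ",
      paste(x$ref_alleles, collapse = "|"),
      ", f = ", paste(format(x$freqs), collapse = ","), ")\n", sep = "")
  cat("MAP genotype:", x$map_genotype,
      sprintf("(posterior %.4g)", x$map_posterior),
      if (x$informative) "[informative]" else "[not informative]", "\n")
  invisible(x)
}

#' Binomial test for a conflicting pair of informative PSVs
#'
#' Read pairs covering two informative PSVs should carry one repeat copy's
#' reference haplotype at both; pairs matching neither copy's reference
#' allele combination are "discordant" and expected only through sequencing
#' error, at rate `pi = 2 * epsilon - epsilon^2` (an error at either site).
#' A one-tailed binomial test on the discordant count flags the pair as
#' conflicting when `p < p_threshold` (default 1e-3). The test requires at
#' least `min_pairs` (default 3) co-covering read pairs.
#'
#' @param n_discordant Number of discordant co-covering read pairs.
#' @param n_total Total co-covering read pairs.
#' @param epsilon Per-base error rate.
#' @param p_threshold Conflict significance threshold.
#' @param min_pairs Minimum co-covering pairs for the test to be performed.
#' @return Tibble with columns `p_value` and `is_conflict` (both `NA`/
#'   `FALSE` when fewer than `min_pairs` pairs are available). Vectorised
#'   over `n_discordant`/`n_total`.
#' @export
conflict_test <- function(n_discordant, n_total, epsilon = 0.01,
                          p_threshold = 1e-3, min_pairs = 3L) {
  stopifnot(all(n_discordant >= 0), all(n_discordant <= n_total))
  pi0 <- 2 * epsilon - epsilon^2
  p <- pbinom(n_discordant - 1, n_total, pi0, lower.tail = FALSE)
  tested <- n_total >= min_pairs
  tibble(
    p_value = ifelse(tested, p, NA_real_),
    is_conflict = tested & p < p_threshold
  )
}

#' Greedy pruning of the PSV conflict graph
#'
#' Keeps a subset of informative PSVs such that no conflict edge remains,
#' aiming to maximise the summed minimal reference-allele frequency
#' (a weighted maximum independent set, NP-complete in general). Greedy
#' heuristic: while edges remain, remove the PSV with the largest
#' `degree * sqrt(1 - min_freq)`; ties are broken towards the smaller
#' `min_freq`, then the lower position.
#'
#' @param psvs Tibble with one row per informative PSV and columns
#'   `psv_id`, `min_freq` and (optionally) `pos` for tie-breaking.
#' @param edges Tibble of conflicting pairs with columns `psv1`, `psv2`
#'   (values of `psv_id`).
#' @return `psvs` with an added logical column `retained`.
#' @export
prune_conflicts <- function(psvs, edges) {
  stopifnot(all(c("psv_id", "min_freq") %in% names(psvs)))
  if (!"pos" %in% names(psvs)) psvs$pos <- seq_len(nrow(psvs))
  keep <- rep(TRUE, nrow(psvs))
  if (nrow(psvs) == 0L || is.null(edges) || nrow(edges) == 0L) {
    psvs$retained <- keep
    return(psvs)
  }
  i1 <- match(edges$psv1, psvs$psv_id)
  i2 <- match(edges$psv2, psvs$psv_id)
  ok <- !is.na(i1) & !is.na(i2) & i1 != i2
  i1 <- i1[ok]; i2 <- i2[ok]
  alive_edge <- rep(TRUE, length(i1))
  repeat {
    deg <- tabulate(c(i1[alive_edge], i2[alive_edge]), nbins = nrow(psvs))
    if (all(deg == 0L)) break
    score <- deg * sqrt(1 - psvs$min_freq)
    score[!keep] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1L) {
      best <- best[order(psvs$min_freq[best], psvs$pos[best],
                         method = "radix")][1L]
    }
    keep[best] <- FALSE
    alive_edge <- alive_edge & i1 != best & i2 != best
  }
  psvs$retained <- keep
  psvs
}
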