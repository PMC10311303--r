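# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for lcrcall result objects
#'
#' `tidy()` returns the per-genotype (or per-call) table of an object;
#' `glance()` a one-row summary.
#'
#' @param x An `lcr_agg_posterior`, `lcr_psv_call`, `lcr_variant_call`,
#'   `lcr_callset` or `lcr_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name lcr_tidiers
NULL

#' @rdname lcr_tidiers
#' @export
tidy.lcr_agg_posterior <- function(x, ...) x$table

#' @rdname lcr_tidiers
#' @export
glance.lcr_agg_posterior <- function(x, ...) {
  tibble(agcn = x$agcn, n_alleles = length(x$alleles),
         n_genotypes = nrow(x$table), depth = sum(x$depths),
         map_genotype = x$map_genotype, map_posterior = x$map_posterior,
         ref_quality = x$ref_quality)
}

#' @rdname lcr_tidiers
#' @export
tidy.lcr_psv_call <- function(x, ...) {
  select(x$table, "agg_genotype", "genotype", "prior", "posterior")
}

#' @rdname lcr_tidiers
#' @export
glance.lcr_psv_call <- function(x, ...) {
  tibble(min_freq = x$min_freq, map_genotype = x$map_genotype,
         map_posterior = x$map_posterior,
         reference_compatible = x$reference_compatible,
         informative = x$informative)
}

#' @rdname lcr_tidiers
#' @export
tidy.lcr_variant_call <- function(x, ...) {
  select(x$table, "agg_genotype", "genotype", "prior", "posterior")
}

#' @rdname lcr_tidiers
#' @export
glance.lcr_variant_call <- function(x, ...) {
  tibble(n_read_pairs = x$n_read_pairs, resolved = x$resolved,
         map_genotype = x$map_genotype, map_posterior = x$map_posterior,
         quality = x$quality)
}

#' @rdname lcr_tidiers
#' @export
tidy.lcr_callset <- function(x, ...) x$calls

#' @rdname lcr_tidiers
#' @export
glance.lcr_callset <- function(x, ...) {
  s <- x$stats
  tibble(locus_id = x$locus_id,
         n_read_pairs = s$n_pairs_pooled %||% 0L,
         n_candidates = s$n_candidates %||% 0L,
         n_psvs = s$n_psvs %||% 0L,
         n_informative = s$n_informative %||% 0L,
         n_retained_informative = s$n_retained_informative %||% 0L,
         n_variants = s$n_variants %||% 0L,
         n_resolved = s$n_resolved %||% 0L)
}

#' @rdname lcr_tidiers
#' @export
tidy.lcr_eval <- function(x, ...) x$metrics

#' @rdname lcr_tidiers
#' @export
glance.lcr_eval <- function(x, ...) {
  m <- x$metrics
  agg <- m[m$level == "aggregate" & m$vtype == "all", ]
  pg <- m[m$level == "paralog" & m$vtype == "all", ]
  conc <- x$concordance[x$concordance$vtype == "all", ]
  tibble(precision_aggregate = agg$precision, recall_aggregate = agg$recall,
         f1_aggregate = agg$f1, precision_paralog = pg$precision,
         recall_paralog = pg$recall, f1_paralog = pg$f1,
         concordance = conc$concordance)
}
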