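# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   facet_wrap labs theme_minimal position_dodge ylim
#' @export
ggplot2::autoplot

#' Plot an aggregate genotype posterior
#'
#' Bar plot of the posterior over aggregate genotypes at a pooled site.
#'
#' @param object An `lcr_agg_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcr_agg_posterior <- function(object, ...) {
  ggplot(object$table, aes(x = .data$genotype, y = .data$posterior)) +
    geom_col(fill = "steelblue") +
    labs(x = "aggregate genotype", y = "posterior probability",
         title = sprintf("Pooled site posterior (agcn = %d, depth = %d)",
                         object$agcn, sum(object$depths))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot evaluation metrics
#'
#' Precision / recall / F-scores by evaluation level and variant type.
#'
#' @param object An `lcr_eval` from [evaluate_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcr_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$vtype, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~.data$level) +
    ylim(0, 1) +
    labs(x = "variant type", y = NULL,
         title = "Variant calling accuracy") +
    theme_minimal()
}

#' Plot per-locus call summary
#'
#' Variant quality along the representative copy, coloured by resolution
#' status and shaped by filter status.
#'
#' @param object An `lcr_callset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcr_callset <- function(object, ...) {
  calls <- object$calls[object$calls$variant, , drop = FALSE]
  ggplot(calls, aes(x = .data$pos, y = .data$quality,
                    colour = .data$resolved,
                    shape = .data$filter == "PASS")) +
    geom_point() +
    labs(x = "position on representative copy (bp)",
         y = "variant quality (Phred)",
         colour = "resolved", shape = "PASS",
         title = sprintf("Variant calls on %s", object$locus_id)) +
    theme_minimal()
}
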