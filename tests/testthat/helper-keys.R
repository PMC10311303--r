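# Normalise genotype string keys (canonical allele order within each
# multiset) so implementation and oracle tables can be joined regardless of
# the order each side used internally.
norm_gt_key <- function(g) {
  vapply(g, function(s) {
    copies <- strsplit(s, "|", fixed = TRUE)[[1]]
    paste(vapply(copies, function(cp) {
      a <- strsplit(cp, "/", fixed = TRUE)[[1]]
      paste(a[order(nchar(a), a, method = "radix")], collapse = "/")
    }, character(1)), collapse = "|")
  }, character(1), USE.NAMES = FALSE)
}
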