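#' @importFrom rlang .data abort
#' @importFrom dplyr mutate filter select arrange bind_rows left_join
#'   inner_join group_by summarise ungroup n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dmultinom pbinom fisher.test rbinom rnorm runif
#'   setNames dhyper rmultinom rpois
#' @importFrom utils head tail
#' @importFrom methods is
NULL

# Canonical allele order: by length, then lexicographic (C locale, radix sort),
# so enumeration order is platform independent.
allele_order <- function(alleles) {
  alleles[order(nchar(alleles), alleles, method = "radix")]
}

#' Multiplicity of an allele in a genotype multiset
#'
#' Counts the number of occurrences of `allele` in the allele multiset
#' `genotype` (the multiplicity function mu(z, Z) used throughout the
#' genotype likelihood model).
#'
#' @param allele Single allele string.
#' @param genotype Character vector representing an allele multiset,
#'   e.g. `c("G","G","G","T","T")`.
#' @return Non-negative integer count.
#' @examples
#' multiplicity("G", c("G", "G", "G", "T", "T"))
#' @export
multiplicity <- function(allele, genotype) {
  stopifnot(is.character(allele), length(allele) == 1L)
  sum(genotype == allele)
}

# All compositions of `total` into `k` non-negative parts, in canonical order:
# part 1 descending, then part 2 descending, ... This makes the corresponding
# sorted allele-index tuples lexicographically increasing.
compositions <- function(k, total) {
  if (k == 1L) return(matrix(as.integer(total), ncol = 1L))
  out <- vector("list", total + 1L)
  for (c1 in total:0) {
    rest <- compositions(k - 1L, total - c1)
    out[[total - c1 + 1L]] <- cbind(as.integer(c1), rest)
  }
  do.call(rbind, out)
}

# Compositions with per-part upper bounds, same canonical order.
bounded_compositions <- function(total, bounds) {
  k <- length(bounds)
  if (k == 1L) {
    if (total <= bounds[1L]) return(matrix(as.integer(total), ncol = 1L))
    return(matrix(integer(0), ncol = 1L))
  }
  hi <- min(total, bounds[1L])
  lo <- max(0L, total - sum(bounds[-1L]))
  if (hi < lo) return(matrix(integer(0), ncol = k))
  parts <- lapply(hi:lo, function(c1) {
    rest <- bounded_compositions(total - c1, bounds[-1L])
    if (nrow(rest) == 0L) return(NULL)
    cbind(as.integer(c1), rest)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) matrix(integer(0), ncol = k) else out
}

# Count matrix of all aggregate genotypes: rows = genotypes, cols = alleles
# (alleles assumed already in canonical order).
gt_count_matrix <- function(n_alleles, agcn) {
  compositions(n_alleles, agcn)
}

counts_to_alleles <- function(counts, alleles) {
  rep(alleles, times = counts)
}

format_gt <- function(alleles) paste(alleles, collapse = "/")

format_pg <- function(per_copy) {
  paste(vapply(per_copy, format_gt, character(1)), collapse = "|")
}

#' Enumerate aggregate genotypes
#'
#' All multisets of `agcn` alleles drawn from `alleles` — the genotype space
#' of a pooled (polyploid) variant site at aggregate copy number `agcn`.
#' The order is canonical and deterministic: alleles are sorted by
#' (length, lexicographic) and genotypes by the lexicographic order of their
#' sorted allele-index tuples. The number of genotypes is
#' `choose(agcn + k - 1, k - 1)` for `k` alleles.
#'
#' @param alleles Character vector of distinct alleles.
#' @param agcn Aggregate copy number (total ploidy across repeat copies).
#' @return Tibble with columns `genotype` (string such as `"A/A/G"`) and
#'   `alleles` (list column of character vectors).
#' @examples
#' enumerate_aggregate_genotypes(c("A", "G"), 4)
#' @export
enumerate_aggregate_genotypes <- function(alleles, agcn) {
  if (length(alleles) == 0L || any(duplicated(alleles))) {
    abort("`alleles` must be a non-empty set of distinct allele strings.")
  }
  if (!is.numeric(agcn) || length(agcn) != 1L || agcn < 1 || agcn != round(agcn)) {
    abort("`agcn` must be a positive integer.")
  }
  alleles <- allele_order(alleles)
  cnt <- gt_count_matrix(length(alleles), as.integer(agcn))
  lst <- lapply(seq_len(nrow(cnt)), function(i) counts_to_alleles(cnt[i, ], alleles))
  tibble(
    genotype = vapply(lst, format_gt, character(1)),
    alleles  = lst
  )
}

# List of paralog genotypes for one aggregate count vector `m` (over alleles)
# and per-copy sizes `pscn`. Each element is an n x k count matrix.
paralog_count_matrices <- function(m, pscn) {
  n <- length(pscn)
  if (n == 1L) {
    return(list(matrix(as.integer(m), nrow = 1L)))
  }
  first <- bounded_compositions(pscn[1L], m)
  out <- list()
  for (i in seq_len(nrow(first))) {
    x <- first[i, ]
    rest <- paralog_count_matrices(m - x, pscn[-1L])
    out <- c(out, lapply(rest, function(r) rbind(as.integer(x), r)))
  }
  out
}

#' Enumerate paralog-specific genotypes of an aggregate genotype
#'
#' All distinct ways of distributing the aggregate allele multiset into
#' per-copy multisets whose sizes are the paralog-specific copy numbers.
#' Every returned genotype flattens back to the input aggregate genotype.
#'
#' @param aggregate Aggregate genotype: character vector of alleles (e.g.
#'   `c("A","A","A","G")`) or a `"A/A/A/G"` string.
#' @param pscn Integer vector of paralog-specific copy numbers, one per
#'   repeat copy; must sum to the aggregate genotype size.
#' @return Tibble with columns `genotype` (string such as `"A/A|A/G"`) and
#'   `per_copy` (list column; each element a list of per-copy character
#'   vectors).
#' @examples
#' enumerate_paralog_genotypes(c("A", "A", "A", "G"), c(2, 2))
#' @export
enumerate_paralog_genotypes <- function(aggregate, pscn) {
  if (is.character(aggregate) && length(aggregate) == 1L && grepl("/", aggregate)) {
    aggregate <- strsplit(aggregate, "/", fixed = TRUE)[[1L]]
  }
  pscn <- as.integer(pscn)
  if (length(aggregate) != sum(pscn)) {
    abort("Aggregate genotype size must equal sum(pscn).")
  }
  alleles <- allele_order(unique(aggregate))
  m <- vapply(alleles, function(a) sum(aggregate == a), integer(1))
  mats <- paralog_count_matrices(m, pscn)
  per_copy <- lapply(mats, function(mat) {
    lapply(seq_len(nrow(mat)), function(i) counts_to_alleles(mat[i, ], alleles))
  })
  tibble(
    genotype = vapply(per_copy, format_pg, character(1)),
    per_copy = per_copy
  )
}

#' Is a paralog genotype reference-compatible?
#'
#' A paralog genotype is reference-compatible when every copy's multiset
#' contains only that copy's reference allele, i.e. the multiplicity of the
#' reference allele on copy i equals the copy's paralog-specific copy number.
#'
#' @param per_copy List of per-copy allele vectors (one element per copy).
#' @param ref_alleles Character vector of per-copy reference alleles.
#' @return Logical scalar.
#' @export
reference_compatible <- function(per_copy, ref_alleles) {
  stopifnot(length(per_copy) == length(ref_alleles))
  all(vapply(seq_along(per_copy), function(i) {
    all(per_copy[[i]] == ref_alleles[i])
  }, logical(1)))
}
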