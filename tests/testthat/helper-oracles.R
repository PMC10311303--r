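# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: genotype spaces are enumerated from ordered tuples /
# labelled assignments, and probabilities are evaluated in linear space with
# direct factorial arithmetic.

# All aggregate genotype multisets as sorted "A/B/C" strings, via ordered
# tuple enumeration collapsed to multisets.
oracle_enum_aggregate <- function(alleles, agcn) {
  grid <- do.call(expand.grid,
                  c(rep(list(alleles), agcn),
                    list(stringsAsFactors = FALSE)))
  keys <- apply(grid, 1L, function(r) paste(sort(unname(r)), collapse = "/"))
  sort(unique(keys))
}

# All paralog genotypes via labelled assignment of aggregate allele
# instances to copies, deduplicated; returns sorted "g1|g2|..." strings
# (each copy multiset sorted with sort()).
oracle_enum_paralog <- function(aggregate, pscn) {
  n <- length(pscn)
  total <- length(aggregate)
  labels <- rep(seq_len(n), times = pscn)
  perms <- unique(combinat_perms(labels))
  keys <- vapply(perms, function(lab) {
    paste(vapply(seq_len(n), function(i) {
      paste(sort(aggregate[lab == i]), collapse = "/")
    }, character(1)), collapse = "|")
  }, character(1))
  sort(unique(keys))
}

# All distinct permutations of a vector (small sizes only).
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    idx <- which(x == v)[1L]
    rest <- combinat_perms(x[-idx])
    out <- c(out, lapply(rest, function(r) c(v, r)))
  }
  out
}

# Direct linear-space aggregate posterior over the oracle genotype space.
# Returns named posterior vector (names = sorted "a/b/.." genotypes).
oracle_agg_posterior <- function(depths, alleles, agcn, mean_read_len = 150,
                                 epsilon = 0.01) {
  gts <- oracle_enum_aggregate(alleles, agcn)
  n <- sum(depths)
  lik <- vapply(gts, function(g) {
    ga <- strsplit(g, "/", fixed = TRUE)[[1]]
    w <- vapply(alleles, function(a) {
      (mean_read_len - nchar(a) - 1) *
        max(epsilon * agcn, sum(ga == a))
    }, numeric(1))
    w <- w / sum(w)
    factorial(n) / prod(factorial(depths)) * prod(w^depths)
  }, numeric(1))
  lik / sum(lik)
}

# Direct PSV paralog posterior (Eqs 4-5) over the oracle enumerations.
# Returns a data.frame with genotype keys and posteriors.
oracle_psv_posterior <- function(depths, ref_alleles, freqs, pscn,
                                 mean_read_len = 150, epsilon = 0.01) {
  alleles <- sort(unique(c(ref_alleles, names(depths))))
  d <- setNames(rep(0L, length(alleles)), alleles)
  d[names(depths)] <- depths
  agcn <- sum(pscn)
  agg <- oracle_agg_posterior(d, alleles, agcn, mean_read_len, epsilon)
  out <- list()
  for (g in names(agg)) {
    ga <- strsplit(g, "/", fixed = TRUE)[[1]]
    pgs <- oracle_enum_paralog(ga, pscn)
    prior <- vapply(pgs, function(pg) {
      copies <- strsplit(strsplit(pg, "|", fixed = TRUE)[[1]], "/",
                         fixed = TRUE)
      p <- 1
      for (i in seq_along(copies)) {
        mu <- sum(copies[[i]] == ref_alleles[i])
        p <- p * freqs[i]^mu * (1 - freqs[i])^(pscn[i] - mu)
      }
      p
    }, numeric(1))
    out[[g]] <- data.frame(agg_genotype = g, genotype = pgs,
                           posterior = agg[[g]] * prior / sum(prior),
                           row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Direct read-set paralog genotype posterior (Eqs 6-9) in linear space.
# read_pairs: data.frame with columns allele and a list column pr.
oracle_ps_posterior <- function(read_pairs, depths, alleles, pscn,
                                ref_alleles, freqs = NULL,
                                mean_read_len = 150, epsilon = 0.01,
                                xi = 1e-3, agg_min_posterior = 1e-6) {
  agcn <- sum(pscn)
  agg <- oracle_agg_posterior(depths, alleles, agcn, mean_read_len, epsilon)
  keep <- names(agg)[agg > agg_min_posterior]
  rows <- list()
  for (g in keep) {
    ga <- strsplit(g, "/", fixed = TRUE)[[1]]
    for (pg in oracle_enum_paralog(ga, pscn)) {
      copies <- strsplit(strsplit(pg, "|", fixed = TRUE)[[1]], "/",
                         fixed = TRUE)
      if (is.null(freqs)) {
        prior <- 1
        for (i in seq_along(copies)) {
          allref <- all(copies[[i]] == ref_alleles[1])
          prior <- prior * if (allref) 1 - xi else xi
        }
      } else {
        prior <- 1
        for (i in seq_along(copies)) {
          mu <- sum(copies[[i]] == ref_alleles[i])
          prior <- prior * freqs[i]^mu * (1 - freqs[i])^(pscn[i] - mu)
        }
      }
      lik <- 1
      if (nrow(read_pairs) > 0) {
        for (r in seq_len(nrow(read_pairs))) {
          pr <- read_pairs$pr[[r]]
          a <- read_pairs$allele[r]
          pread <- 0
          for (i in seq_along(copies)) {
            cs <- pscn[i]
            if (cs == 0 || pr[i] == 0) next
            mu <- sum(copies[[i]] == a)
            pread <- pread + pr[i] / cs *
              ((1 - epsilon) * mu + epsilon * (cs - mu))
          }
          lik <- lik * pread
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(genotype = pg,
                                              weight = prior * lik)
    }
  }
  df <- do.call(rbind, rows)
  df <- aggregate(weight ~ genotype, df, sum)  # same pg under 2 agg classes cannot happen, but safe
  df$posterior <- df$weight / sum(df$weight)
  df
}

# One-tailed binomial upper tail by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum of all
# tables (fixed margins) whose probability does not exceed the observed
# one (standard rule, with the conventional 1e-7 tie tolerance).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  if (sum(c(a, b, c, d)) == 0) return(1)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n2, k), numeric(1))
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exhaustive maximum-weight independent set over all subsets.
oracle_best_independent_set <- function(weights, edges_i, edges_j) {
  n <- length(weights)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(edges_i) > 0) {
      bad <- any(edges_i %in% members & edges_j %in% members)
      if (bad) next
    }
    best <- max(best, sum(weights[members]))
  }
  best
}

# Random allelic-depth instance generator used by several suites.
random_site <- function(max_alleles = 3, max_agcn = 6, max_depth = 40) {
  k <- sample(2:max_alleles, 1)
  bases <- sample(c("A", "C", "G", "T"), k)
  agcn <- sample(2:max_agcn, 1)
  depths <- setNames(rpois(k, lambda = runif(1, 1, max_depth / k)), bases)
  list(alleles = bases, depths = depths, agcn = agcn)
}
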