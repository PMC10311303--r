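# Homology map between repeat copies, derived from a multiple sequence
# alignment (MSA) of the copies' reference sequences. The first copy is
# the representative copy onto which all reads are projected.

#' Build a homology map from a multiple sequence alignment
#'
#' The map records, for every MSA column, the 0-based position of that
#' column in each repeat copy (`NA` where the copy has a gap), plus the
#' inverse position-to-column lookup. The first sequence is the
#' representative copy.
#'
#' @param msa Aligned sequences of the repeat copies: a named character
#'   vector (rows of equal length, `-` for gaps), a
#'   [Biostrings::DNAStringSet], or the path to an aligned FASTA file.
#' @param contigs Optional contig names, one per copy (default: the
#'   sequence names).
#' @return An object of class `lcr_homology_map` with elements `copy_ids`,
#'   `contigs`, `n_copies`, `ncol`, `col2pos` (ncol x n matrix of 0-based
#'   positions or `NA`), `pos2col` (list of per-copy column lookups),
#'   `seqs` (degapped sequences) and `lengths`.
#' @export
build_homology_map <- function(msa, contigs = NULL) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    msa <- Biostrings::readDNAStringSet(msa)
  }
  if (methods::is(msa, "XStringSet")) {
    msa <- setNames(as.character(msa), names(msa))
  }
  stopifnot(is.character(msa), length(msa) >= 2L)
  if (length(unique(nchar(msa))) != 1L) {
    abort("Ragged alignment: all MSA rows must have equal length.")
  }
  if (is.null(names(msa))) names(msa) <- paste0("copy", seq_along(msa))
  n <- length(msa)
  width <- nchar(msa[[1L]])
  rows <- lapply(msa, function(s) strsplit(toupper(s), "")[[1L]])
  col2pos <- matrix(NA_integer_, nrow = width, ncol = n)
  pos2col <- vector("list", n)
  for (i in seq_len(n)) {
    nongap <- rows[[i]] != "-"
    col2pos[nongap, i] <- seq_len(sum(nongap)) - 1L
    pos2col[[i]] <- which(nongap)
  }
  seqs <- vapply(rows, function(r) paste(r[r != "-"], collapse = ""),
                 character(1))
  structure(
    list(
      copy_ids = names(msa),
      contigs = if (is.null(contigs)) names(msa) else contigs,
      n_copies = n,
      ncol = width,
      aln = rows,
      col2pos = col2pos,
      pos2col = pos2col,
      seqs = seqs,
      lengths = nchar(seqs)
    ),
    class = "lcr_homology_map"
  )
}

#' @export
print.lcr_homology_map <- function(x, ...) {
  cat("Homology map:", x$n_copies, "repeat copies,", x$ncol,
      "alignment columns\n")
  cat("Representative copy:", x$copy_ids[1L], sprintf("(%d bp)\n",
                                                      x$lengths[1L]))
  invisible(x)
}

#' Project per-copy positions onto the representative copy
#'
#' @param map An `lcr_homology_map`.
#' @param copy Copy id or index the positions refer to.
#' @param pos Integer vector of 0-based positions on that copy.
#' @return Integer vector of 0-based representative-copy positions; `NA`
#'   where the representative copy has a gap in the aligned column.
#' @export
project_positions <- function(map, copy, pos) {
  j <- if (is.character(copy)) match(copy, map$copy_ids) else as.integer(copy)
  if (is.na(j)) abort("Unknown repeat copy.")
  stopifnot(all(pos >= 0), all(pos < map$lengths[j]))
  cols <- map$pos2col[[j]][pos + 1L]
  map$col2pos[cols, 1L]
}

#' PSV sites of a homology map
#'
#' Columns of the MSA where at least two copies carry different non-gap
#' residues are PSV candidates. Columns where the representative copy has
#' a gap cannot be anchored on the representative and are skipped.
#'
#' @param map An `lcr_homology_map`.
#' @return Tibble with columns `pos` (0-based, representative copy),
#'   `ref_alleles` (list column: per-copy alleles, `NA` for copies gapped
#'   at the column) and `n_alleles`.
#' @export
psv_sites <- function(map) {
  alnm <- do.call(cbind, map$aln)  # ncol x n
  is_base <- alnm != "-"
  differs <- apply(alnm, 1L, function(r) {
    b <- unique(r[r != "-"])
    length(b) > 1L
  })
  keep <- which(differs & is_base[, 1L])
  if (length(keep) == 0L) {
    return(tibble(pos = integer(0), ref_alleles = list(),
                  n_alleles = integer(0)))
  }
  ref_alleles <- lapply(keep, function(cl) {
    a <- alnm[cl, ]
    a[a == "-"] <- NA_character_
    a
  })
  tibble(
    pos = map$col2pos[keep, 1L],
    ref_alleles = ref_alleles,
    n_alleles = vapply(ref_alleles, function(a) {
      length(unique(a[!is.na(a)]))
    }, integer(1))
  )
}
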