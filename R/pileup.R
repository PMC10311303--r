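# Read pooling and pileup construction.
#
# Alignments from every repeat copy are projected through the homology map
# onto the representative copy; per-base observations, insertion and
# deletion events are tabulated for variant discovery and per-site allele
# observation extraction. Mapping quality is ignored throughout: in LCRs
# most reads are assigned low MAPQ precisely because the copies are nearly
# identical, and pooling is designed to use them.

#' Read alignments from a SAM/BAM file into a tibble
#'
#' Thin wrapper over [Rsamtools::scanBam()]; SAM files are converted on
#' the fly. Unmapped reads and secondary/supplementary alignments are
#' dropped; one record per mapped mate is returned.
#'
#' @param path Path to a SAM or BAM file.
#' @return Tibble with columns `qname`, `copy` (contig), `pos` (0-based
#'   leftmost), `cigar`, `seq`, `qual` (string), `strand` (`"+"`/`"-"`),
#'   `is_first` (first mate in pair).
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = prm)[[1L]]
  tibble(
    qname = b$qname,
    copy = as.character(b$rname),
    pos = b$pos - 1L,
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    is_first = bitwAnd(b$flag, 64L) > 0L | bitwAnd(b$flag, 1L) == 0L
  )
}

# Project a tibble of alignments through the homology map into base-level
# tables. Returns list:
#   aln:  per-alignment metadata with projected ref span (rep coords) and
#         aligned length
#   base: one row per aligned (M) base whose column maps to the
#         representative copy: aln_id, pos (rep, 0-based), base, qual
#   ins:  insertion events: aln_id, anchor (rep pos of preceding base), seq
#   del:  deletion events: aln_id, anchor (rep pos of preceding base), len
# Reads lying entirely in representative-copy gaps are dropped and counted.
project_alignments <- function(aln_tbl, map) {
  n_aln <- nrow(aln_tbl)
  copy_idx <- match(aln_tbl$copy, map$copy_ids)
  if (anyNA(copy_idx)) abort("Alignment contig not present in homology map.")

  ops_list <- GenomicAlignments::explodeCigarOps(aln_tbl$cigar)
  lens_list <- GenomicAlignments::explodeCigarOpLengths(aln_tbl$cigar)

  base_rows <- vector("list", n_aln)
  ins_rows <- vector("list", n_aln)
  del_rows <- vector("list", n_aln)
  span_lo <- rep(NA_integer_, n_aln)
  span_hi <- rep(NA_integer_, n_aln)
  dropped <- 0L

  for (k in seq_len(n_aln)) {
    ops <- ops_list[[k]]
    lens <- lens_list[[k]]
    j <- copy_idx[k]
    pos2col <- map$pos2col[[j]]
    rep_of <- map$col2pos[, 1L]
    read_chars <- strsplit(aln_tbl$seq[k], "")[[1L]]
    quals <- utf8ToInt(aln_tbl$qual[k]) - 33L
    q_off <- 0L
    r_off <- aln_tbl$pos[k]
    m_pos <- integer(0); m_idx <- integer(0)
    ins_a <- integer(0); ins_s <- character(0)
    del_a <- integer(0); del_l <- integer(0)
    for (t in seq_along(ops)) {
      op <- ops[t]; len <- lens[t]
      if (op %in% c("M", "=", "X")) {
        cp <- r_off + 0:(len - 1L)
        rp <- rep_of[pos2col[cp + 1L]]
        ok <- !is.na(rp)
        m_pos <- c(m_pos, rp[ok])
        m_idx <- c(m_idx, (q_off + 1:len)[ok])
        q_off <- q_off + len
        r_off <- r_off + len
      } else if (op == "I") {
        if (r_off > 0L) {
          a <- rep_of[pos2col[r_off]]  # copy pos r_off - 1
          if (!is.na(a)) {
            ins_a <- c(ins_a, a)
            ins_s <- c(ins_s, substr(aln_tbl$seq[k], q_off + 1L,
                                     q_off + len))
          }
        }
        q_off <- q_off + len
      } else if (op %in% c("D", "N")) {
        if (op == "D" && r_off > 0L) {
          a <- rep_of[pos2col[r_off]]
          if (!is.na(a)) {
            del_a <- c(del_a, a)
            del_l <- c(del_l, len)
          }
        }
        r_off <- r_off + len
      } else if (op == "S") {
        q_off <- q_off + len
      }  # H/P consume nothing we track
    }
    if (length(m_pos) == 0L) {
      dropped <- dropped + 1L
      next
    }
    span_lo[k] <- min(m_pos)
    span_hi[k] <- max(m_pos, del_a + del_l)
    base_rows[[k]] <- list(aln_id = rep.int(k, length(m_pos)), pos = m_pos,
                           base = read_chars[m_idx], qual = quals[m_idx])
    if (length(ins_a)) {
      ins_rows[[k]] <- list(aln_id = rep.int(k, length(ins_a)),
                            anchor = ins_a, seq = ins_s)
    }
    if (length(del_a)) {
      del_rows[[k]] <- list(aln_id = rep.int(k, length(del_a)),
                            anchor = del_a, len = del_l)
    }
  }
  cat_rows <- function(rows, cols) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) {
      return(as_tibble(setNames(
        lapply(cols, function(cl) vector(cl, 0L)), names(cols))))
    }
    as_tibble(lapply(names(cols), function(nm) {
      unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    }) |> setNames(names(cols)))
  }
  aln <- aln_tbl
  aln$aln_id <- seq_len(n_aln)
  aln$span_lo <- span_lo
  aln$span_hi <- span_hi
  aln <- aln[!is.na(aln$span_lo), , drop = FALSE]
  list(
    aln = as_tibble(aln),
    base = cat_rows(base_rows, c(aln_id = "integer", pos = "integer",
                                 base = "character", qual = "integer")),
    ins = cat_rows(ins_rows, c(aln_id = "integer", anchor = "integer",
                               seq = "character")),
    del = cat_rows(del_rows, c(aln_id = "integer", anchor = "integer",
                               len = "integer")),
    n_dropped = dropped
  )
}

#' Pool reads from all repeat copies onto the representative copy
#'
#' Projects every alignment through the homology map and assembles the
#' pooled pileup: per-base observations, insertion/deletion events and
#' per-alignment projected spans, all in representative-copy coordinates.
#' Observations with base quality below `min_base_quality` are discarded
#' here; partial (non-spanning) allele observations are discarded later at
#' allele extraction.
#'
#' @param aln_tbl Alignment tibble as returned by [read_alignments()].
#' @param map An `lcr_homology_map`.
#' @param min_base_quality Minimum base quality (default 10).
#' @return An object of class `lcr_pileup` (list of tibbles `aln`, `base`,
#'   `ins`, `del`, plus `mean_read_len` and `n_dropped`).
#' @export
pool_reads <- function(aln_tbl, map, min_base_quality = 10) {
  proj <- project_alignments(aln_tbl, map)
  aligned_len <- tabulate(proj$base$aln_id, nbins = max(proj$aln$aln_id, 1L))
  proj$mean_read_len <- if (nrow(proj$aln))
    mean(aligned_len[proj$aln$aln_id]) else NA_real_
  proj$base <- proj$base[proj$base$qual >= min_base_quality, , drop = FALSE]
  proj$min_base_quality <- min_base_quality
  structure(proj, class = "lcr_pileup")
}

#' @export
print.lcr_pileup <- function(x, ...) {
  cat("Pooled pileup:", nrow(x$aln), "alignments,", nrow(x$base),
      "base observations\n")
  cat(sprintf("Mean aligned read length: %.1f; %d read(s) dropped in gaps\n",
              x$mean_read_len, x$n_dropped))
  invisible(x)
}

# Reference allele (single base) of the representative copy at 0-based pos.
ref_base <- function(map, pos) {
  unname(substring(map$seqs[[1L]], pos + 1L, pos + 1L))
}

# Candidate site discovery from a pooled pileup: positions with at least
# `min_alt_obs` non-reference base observations, insertion or deletion
# events, always extended with all PSV positions. Returns a tibble
# pos / ref_len describing each site's reference span.
candidate_positions <- function(pileup, map, psv_pos = integer(0),
                                min_alt_obs = 2L) {
  refc <- strsplit(map$seqs[[1L]], "")[[1L]]
  b <- pileup$base
  mism <- b[b$base != refc[b$pos + 1L], , drop = FALSE]
  snv_tab <- table(paste0(mism$pos, ":", mism$base))
  snv_pos <- unique(as.integer(sub(":.*", "",
                                   names(snv_tab)[snv_tab >= min_alt_obs])))
  ins_tab <- table(paste0(pileup$ins$anchor, ":", pileup$ins$seq))
  ins_keys <- names(ins_tab)[ins_tab >= min_alt_obs]
  ins_pos <- unique(as.integer(sub(":.*", "", ins_keys)))
  del_tab <- table(paste0(pileup$del$anchor, ":", pileup$del$len))
  del_keys <- names(del_tab)[del_tab >= min_alt_obs]
  del_pos <- as.integer(sub(":.*", "", del_keys))
  del_len <- as.integer(sub(".*:", "", del_keys))
  pos <- sort(unique(c(snv_pos, ins_pos, del_pos, psv_pos)))
  if (length(pos) == 0L) {
    return(tibble(pos = integer(0), ref_len = integer(0)))
  }
  ref_len <- rep(1L, length(pos))
  if (length(del_pos)) {
    max_del <- tapply(del_len, del_pos, max)
    idx <- match(as.integer(names(max_del)), pos)
    ref_len[idx] <- pmax(ref_len[idx], as.integer(max_del) + 1L)
  }
  keep <- pos >= 0L & pos + ref_len <= map$lengths[1L]
  tibble(pos = pos[keep], ref_len = ref_len[keep])
}

# Extract per-read-pair allele observations at the given sites.
# sites: tibble with pos, ref_len. Returns tibble site_id, qname, allele,
# qual, strand, copy — one row per read pair (mates collapsed; mates
# disagreeing on the allele are dropped at that site). Single-base sites
# go through a vectorised path; multi-base (deletion-spanning) sites are
# assembled per site.
site_observations <- function(pileup, sites) {
  empty <- tibble(site_id = integer(0), qname = character(0),
                  allele = character(0), qual = integer(0),
                  strand = character(0), copy = character(0))
  if (nrow(sites) == 0L || nrow(pileup$base) == 0L) return(empty)
  b <- pileup$base
  aln <- pileup$aln
  out <- list()

  # --- fast path: ref_len == 1 sites
  s1 <- which(sites$ref_len == 1L)
  if (length(s1)) {
    site_of_pos <- match(b$pos, sites$pos[s1])
    rows <- which(!is.na(site_of_pos))
    if (length(rows)) {
      o <- tibble(site_id = s1[site_of_pos[rows]],
                  aln_id = b$aln_id[rows],
                  allele = b$base[rows],
                  qual = b$qual[rows])
      if (nrow(pileup$ins)) {
        ikey <- paste(pileup$ins$aln_id, pileup$ins$anchor)
        okey <- paste(o$aln_id, sites$pos[o$site_id])
        im <- match(okey, ikey)
        has_ins <- !is.na(im)
        o$allele[has_ins] <- paste0(o$allele[has_ins],
                                    pileup$ins$seq[im[has_ins]])
      }
      out[[length(out) + 1L]] <- o
    }
  }

  # --- general path: multi-base reference spans (deletions)
  for (s in which(sites$ref_len > 1L)) {
    p <- sites$pos[s]
    L <- sites$ref_len[s]
    cover <- aln$aln_id[aln$span_lo <= p & aln$span_hi >= p + L - 1L]
    if (length(cover) == 0L) next
    rows <- which(b$pos >= p & b$pos < p + L & b$aln_id %in% cover)
    if (length(rows) == 0L) next
    piece <- tibble(
      aln_id = b$aln_id[rows],
      key = 2 * as.numeric(b$pos[rows]),
      chunk = b$base[rows],
      qual = b$qual[rows])
    ins <- pileup$ins[pileup$ins$anchor >= p &
                        pileup$ins$anchor <= p + L - 1L &
                        pileup$ins$aln_id %in% cover, , drop = FALSE]
    if (nrow(ins)) {
      piece <- bind_rows(piece, tibble(
        aln_id = ins$aln_id,
        key = 2 * as.numeric(ins$anchor) + 1,
        chunk = ins$seq,
        qual = NA_integer_))
    }
    piece <- piece[order(piece$aln_id, piece$key), , drop = FALSE]
    grp <- match(piece$aln_id, unique(piece$aln_id))
    has_anchor <- tabulate(grp[piece$key == 2 * p], max(grp)) > 0L
    alleles <- vapply(split(piece$chunk, grp), paste, character(1),
                      collapse = "")
    oquals <- vapply(split(piece$qual, grp), function(q) {
      q <- q[!is.na(q)]
      if (length(q)) min(q) else 30L
    }, integer(1))
    keep <- which(has_anchor)
    if (length(keep) == 0L) next
    out[[length(out) + 1L]] <- tibble(
      site_id = s,
      aln_id = unique(piece$aln_id)[keep],
      allele = unname(alleles[keep]),
      qual = unname(oquals[keep]))
  }
  if (length(out) == 0L) return(empty)
  o <- bind_rows(out)
  idx <- match(o$aln_id, aln$aln_id)
  o$qname <- aln$qname[idx]
  o$strand <- aln$strand[idx]
  o$copy <- aln$copy[idx]

  # collapse mates: same allele -> keep best quality; disagreement -> drop
  key <- paste(o$site_id, o$qname)
  ord <- order(key, -o$qual, method = "radix")
  o <- o[ord, , drop = FALSE]
  key <- key[ord]
  grp <- match(key, unique(key))
  first_allele <- o$allele[!duplicated(grp)][grp]
  bad <- unique(grp[o$allele != first_allele])
  keep <- !duplicated(grp) & !(grp %in% bad)
  o <- o[keep, , drop = FALSE]
  o$aln_id <- NULL
  o[, c("site_id", "qname", "allele", "qual", "strand", "copy")]
}

#' Filter pooled observations by base quality
#'
#' Removes base observations below the quality threshold from a pooled
#' pileup (partial allele observations are excluded at allele extraction,
#' where the site span is known).
#'
#' @param pileup An `lcr_pileup`.
#' @param min_base_quality Minimum base quality to retain (default 10).
#' @return The filtered `lcr_pileup`.
#' @export
filter_observations <- function(pileup, min_base_quality = 10) {
  pileup$base <- pileup$base[pileup$base$qual >= min_base_quality, ,
                             drop = FALSE]
  pileup$min_base_quality <- min_base_quality
  pileup
}
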