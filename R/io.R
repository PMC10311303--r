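# On-disk formats: SAM, FASTA, VCF 4.2, tab-separated tables with
# "#"-prefixed headers, JSON config echo. All coordinates are 0-based
# half-open in memory and 1-based in VCF output.

write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, as.character), list(sep = "\t")))
    writeLines(lines, con)
  }
  invisible(path)
}

read_tsv_hash <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = strsplit(header, "\t")[[1L]],
                          colClasses = "character", blank.lines.skip = TRUE)
  as_tibble(df)
}

#' Read a paralog-specific copy number profile
#'
#' Tab-separated with a `#`-prefixed header and columns `sample_id`,
#' `locus_id`, `copy`, `pscn` (non-negative integer or `?` for
#' unavailable) and optionally `agcn`. When `agcn` is present it is
#' cross-checked against the sum of available `pscn`.
#'
#' @param path TSV path.
#' @return Tibble with one row per (sample, locus, copy); `pscn` is `NA`
#'   where unavailable.
#' @export
read_copy_number_profile <- function(path) {
  df <- read_tsv_hash(path)
  need <- c("sample_id", "locus_id", "copy", "pscn")
  if (!all(need %in% names(df))) {
    abort(paste("Copy number profile must have columns:",
                paste(need, collapse = ", ")))
  }
  pscn <- suppressWarnings(as.integer(df$pscn))
  bad <- which(is.na(pscn) & df$pscn != "?")
  if (length(bad)) {
    abort(sprintf("Malformed pscn value %s on line %d of %s",
                  df$pscn[bad[1L]], bad[1L] + 1L, path))
  }
  df$pscn <- pscn
  if ("agcn" %in% names(df)) {
    df$agcn <- as.integer(df$agcn)
    chk <- df |>
      group_by(.data$sample_id, .data$locus_id) |>
      summarise(ok = anyNA(.data$pscn) ||
                  all(.data$agcn == sum(.data$pscn)), .groups = "drop")
    if (!all(chk$ok)) {
      abort("agcn does not equal the sum of pscn for some locus.")
    }
  } else {
    df <- df |>
      group_by(.data$sample_id, .data$locus_id) |>
      mutate(agcn = if (anyNA(.data$pscn)) NA_integer_ else
        sum(.data$pscn)) |>
      ungroup()
  }
  df
}

#' Locus eligibility per copy-number availability
#'
#' A locus is callable when the paralog-specific copy number is available
#' for every copy (or, with `extended_copy = TRUE`, when `agcn` is known
#' so copies with unknown pscn can be merged into one pseudo-copy that
#' receives aggregate genotypes only). In `benchmark_mode`, loci with five
#' or more copies or with any pscn different from 2 are additionally
#' skipped.
#'
#' @param profile Profile tibble for one sample as from
#'   [read_copy_number_profile()].
#' @param benchmark_mode Apply the benchmark filters.
#' @param extended_copy Allow the merged pseudo-copy fallback for loci
#'   with partially unknown pscn.
#' @return Tibble (one row per locus): `locus_id`, `n_copies`, `agcn`,
#'   `status` (`"callable"` or `"skipped"`), `reason`.
#' @export
locus_eligibility <- function(profile, benchmark_mode = FALSE,
                              extended_copy = FALSE) {
  profile |>
    group_by(.data$locus_id) |>
    summarise(
      n_copies = dplyr::n(),
      agcn = .data$agcn[1L],
      n_unknown = sum(is.na(.data$pscn)),
      nonref = any(!is.na(.data$pscn) & .data$pscn != 2L),
      .groups = "drop") |>
    mutate(
      reason = dplyr::case_when(
        .data$n_unknown > 0L & !(extended_copy & !is.na(.data$agcn)) ~
          "pscn_unavailable",
        benchmark_mode & .data$n_copies >= 5L ~ "too_many_copies",
        benchmark_mode & .data$nonref ~ "nonreference_pscn",
        TRUE ~ NA_character_),
      status = ifelse(is.na(.data$reason), "callable", "skipped")) |>
    select("locus_id", "n_copies", "agcn", "status", "reason")
}

#' Merge copies with unknown pscn into an extended pseudo-copy
#'
#' Fallback for loci where the paralog-specific copy number is known for
#' some but not all copies: the unknown copies are merged into one
#' pseudo-copy whose pscn is `agcn - sum(known pscn)`. Variants on the
#' pseudo-copy receive aggregate genotypes only. This is an approximation
#' of calling on extended repeat copies.
#'
#' @param profile Profile tibble for a single locus.
#' @return List with `pscn` (named vector, pseudo-copy last, named
#'   `"extended"`) and `merged_copies` (the copy ids merged).
#' @export
extend_copy_profile <- function(profile) {
  stopifnot(length(unique(profile$locus_id)) == 1L)
  agcn <- profile$agcn[1L]
  if (is.na(agcn)) abort("agcn required for the extended-copy fallback.")
  known <- !is.na(profile$pscn)
  rest <- agcn - sum(profile$pscn[known])
  if (rest < 0L) abort("Known pscn exceed agcn.")
  pscn <- c(setNames(profile$pscn[known], profile$copy[known]),
            extended = as.integer(rest))
  list(pscn = pscn, merged_copies = profile$copy[!known])
}

#' Write / read a PSV table
#'
#' Tab-separated with `#`-header: `psv_id`, `pos` (0-based on the
#' representative copy), `ref_alleles` and `freqs` (comma-joined, one
#' entry per copy in homology-map order; `.` for a copy missing the PSV),
#' `min_freq`.
#'
#' @param psv_table Tibble as in `lcr_locus$psv_table`.
#' @param path File path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_psv_table <- function(psv_table, path) {
  df <- tibble(
    psv_id = psv_table$psv_id,
    pos = psv_table$pos,
    ref_alleles = vapply(psv_table$ref_alleles, function(a) {
      a[is.na(a)] <- "."
      paste(a, collapse = ",")
    }, character(1)),
    freqs = vapply(psv_table$freqs, paste, character(1), collapse = ","),
    min_freq = psv_table$min_freq)
  write_tsv_hash(df, path)
}

#' @rdname write_psv_table
#' @export
read_psv_table <- function(path) {
  df <- read_tsv_hash(path)
  ref_alleles <- lapply(strsplit(df$ref_alleles, ",", fixed = TRUE),
                        function(a) ifelse(a == ".", NA_character_, a))
  freqs <- lapply(strsplit(df$freqs, ",", fixed = TRUE), as.numeric)
  if (any(unlist(freqs) <= 0 | unlist(freqs) > 1)) {
    abort("PSV frequencies must lie in (0, 1].")
  }
  tibble(psv_id = df$psv_id, pos = as.integer(df$pos),
         ref_alleles = ref_alleles, freqs = freqs,
         min_freq = as.numeric(df$min_freq))
}

#' Write / read a homology map
#'
#' Tab-separated with `#`-header: one row per copy with `copy_id`,
#' `contig`, `start`, `end`, `strand` and the copy's aligned (gapped) row
#' of the generating MSA; the reader rebuilds the full column table with
#' [build_homology_map()].
#'
#' @param map An `lcr_homology_map`.
#' @param path File path.
#' @export
write_homology_map <- function(map, path) {
  df <- tibble(
    copy_id = map$copy_ids, contig = map$contigs,
    start = 0L, end = map$lengths, strand = "+",
    aligned_seq = vapply(map$aln, paste, character(1), collapse = ""))
  write_tsv_hash(df, path)
}

#' @rdname write_homology_map
#' @export
read_homology_map <- function(path) {
  df <- read_tsv_hash(path)
  build_homology_map(setNames(df$aligned_seq, df$copy_id),
                     contigs = df$contig)
}

#' Write alignments to a SAM file
#'
#' @param reads Alignment tibble (as produced by [simulate_reads()] or
#'   [read_alignments()]).
#' @param map Homology map providing the `@SQ` header lines.
#' @param path Output path (`.sam`).
#' @export
write_sam <- function(reads, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_len(map$n_copies)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", map$contigs[i], map$lengths[i]),
               con)
  }
  if (nrow(reads)) {
    mate_key <- paste(reads$qname, !reads$is_first)
    self_key <- paste(reads$qname, reads$is_first)
    mate <- match(mate_key, self_key)
    has_mate <- !is.na(mate)
    flag <- 1L +
      ifelse(has_mate, 2L, 8L) +
      ifelse(reads$strand == "-", 16L, 0L) +
      ifelse(has_mate & reads$strand[ifelse(has_mate, mate, 1L)] == "-",
             32L, 0L) +
      ifelse(reads$is_first, 64L, 128L)
    pnext <- ifelse(has_mate, reads$pos[ifelse(has_mate, mate, 1L)] + 1L, 0L)
    opt <- if ("true_copy" %in% names(reads)) {
      paste0("\tXT:Z:", reads$true_copy, "\tXH:i:", reads$true_hap)
    } else ""
    lines <- paste(reads$qname, flag, reads$copy, reads$pos + 1L, 60L,
                   reads$cigar, ifelse(has_mate, "=", "*"), pnext, 0L,
                   reads$seq, reads$qual, sep = "\t")
    writeLines(paste0(lines, opt), con)
  }
  invisible(path)
}

vcf_header <- function(map, sample_id) {
  c("##fileformat=VCFv4.2",
    "##source=lcrcall",
    sprintf("##contig=<ID=%s,length=%d>", map$contigs[1L], map$lengths[1L]),
    sprintf("##lcrcallCopyOrder=%s", paste(map$copy_ids, collapse = ",")),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled read-pair depth\">",
    "##INFO=<ID=PSV,Number=0,Type=Flag,Description=\"Site is a paralogous sequence variant\">",
    "##INFO=<ID=AGGVAR,Number=0,Type=Flag,Description=\"Aggregate genotype differs from the reference allele multiset\">",
    "##FILTER=<ID=StrandBias,Description=\"Fisher exact strand bias p < threshold\">",
    "##FILTER=<ID=LowQual,Description=\"Variant quality below output threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Aggregate genotype on the representative copy (ploidy = aggregate copy number)\">",
    "##FORMAT=<ID=PGT,Number=1,Type=String,Description=\"Paralog-specific genotype: per-copy /-joined allele indices, copies joined by |, . if unresolved\">",
    "##FORMAT=<ID=PGQ,Number=1,Type=String,Description=\"Per-copy genotype qualities joined by |\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Pooled allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

gt_indices <- function(alleles, all_alleles) {
  paste(sort(match(alleles, all_alleles) - 1L), collapse = "/")
}

#' Write calls to a VCF 4.2 file
#'
#' One record per variant on the representative copy (1-based positions).
#' The aggregate genotype is written in `GT` at ploidy = aggregate copy
#' number; the paralog-specific genotype in the custom `PGT` tag as
#' per-copy `/`-joined allele indices with copies joined by `|` (`.` when
#' unresolved), with per-copy Phred qualities in `PGQ`.
#'
#' @param calls Calls tibble from [call_variants()] (rows with
#'   `variant == TRUE` are written), sorted by position.
#' @param map Homology map of the locus.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @export
write_vcf <- function(calls, map, path, sample_id = "sample") {
  calls <- calls[calls$variant, , drop = FALSE]
  if (nrow(calls) && is.unsorted(calls$pos)) {
    abort("Calls must be sorted by representative-copy position.")
  }
  lines <- vcf_header(map, sample_id)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    all_alleles <- c(r$ref, strsplit(r$alt, ",", fixed = TRUE)[[1L]])
    gt <- gt_indices(strsplit(r$agg_genotype, "/", fixed = TRUE)[[1L]],
                     all_alleles)
    if (r$resolved) {
      pgt <- paste(vapply(r$per_copy[[1L]], gt_indices, character(1),
                          all_alleles = all_alleles), collapse = "|")
      pgq <- paste(sprintf("%.0f", r$gq[[1L]]), collapse = "|")
    } else {
      pgt <- "."
      pgq <- "."
    }
    info <- paste0("DP=", r$depth, if (r$is_psv) ";PSV" else "",
                   if (r$agg_variant) ";AGGVAR" else "")
    ad <- paste(r$ad[[1L]][all_alleles], collapse = ",")
    lines <- c(lines, paste(
      map$contigs[1L], r$pos + 1L, ".", r$ref,
      paste(all_alleles[-1L], collapse = ","),
      sprintf("%.6g", r$quality), r$filter, info, "GT:PGT:PGQ:AD",
      paste(gt, pgt, pgq, ad, sep = ":"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf
#' @return `read_vcf()`: tibble with columns `pos` (0-based), `ref`,
#'   `alt`, `quality`, `filter`, `agg_genotype`, `per_copy` (list, `NULL`
#'   rows when unresolved), `gq`, `ad`, `depth`, `is_psv`, `resolved`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!grepl("^##fileformat=VCF", lines[1L])) abort("Not a VCF file.")
  body <- lines[!startsWith(lines, "#")]
  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) abort("Malformed VCF record.")
    all_alleles <- c(f[4L], strsplit(f[5L], ",", fixed = TRUE)[[1L]])
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    smp <- setNames(strsplit(f[10L], ":", fixed = TRUE)[[1L]], fmt)
    dec <- function(idx_str) {
      idx <- as.integer(strsplit(idx_str, "/", fixed = TRUE)[[1L]])
      allele_order(all_alleles[idx + 1L])
    }
    resolved <- smp[["PGT"]] != "."
    per_copy <- if (resolved) {
      lapply(strsplit(smp[["PGT"]], "|", fixed = TRUE)[[1L]], dec)
    } else NULL
    info <- strsplit(f[8L], ";", fixed = TRUE)[[1L]]
    dp <- as.integer(sub("^DP=", "", grep("^DP=", info, value = TRUE)))
    ad <- as.integer(strsplit(smp[["AD"]], ",", fixed = TRUE)[[1L]])
    tibble(
      pos = as.integer(f[2L]) - 1L, ref = f[4L], alt = f[5L],
      quality = as.numeric(f[6L]), filter = f[7L],
      agg_genotype = format_gt(dec(smp[["GT"]])),
      per_copy = list(per_copy),
      gq = list(if (resolved)
        as.numeric(strsplit(smp[["PGQ"]], "|", fixed = TRUE)[[1L]])
        else NULL),
      ad = list(setNames(ad, all_alleles)),
      depth = if (length(dp)) dp else NA_integer_,
      is_psv = "PSV" %in% info,
      agg_variant = "AGGVAR" %in% info,
      resolved = resolved)
  })
  bind_rows(rows)
}

#' Write a truth table as a VCF-like file
#'
#' Truth variants from the simulator with their per-copy genotypes, in
#' the same `PGT` encoding as [write_vcf()].
#'
#' @param truth Truth tibble from [simulate_sample()].
#' @param map Homology map.
#' @param path Output path.
#' @export
write_truth_vcf <- function(truth, map, path) {
  lines <- vcf_header(map, "truth")
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    alts <- strsplit(r$alt, ",", fixed = TRUE)[[1L]]
    all_alleles <- c(r$ref, alts)
    gts <- r$genotypes[[1L]]
    agg <- format_gt(allele_order(unlist(gts)))
    pgt <- paste(vapply(gts, gt_indices, character(1),
                        all_alleles = all_alleles), collapse = "|")
    info <- paste(c(if (r$is_psv_site) "PSV",
                    if (r$agg_variant %||% TRUE) "AGGVAR"), collapse = ";")
    if (!nzchar(info)) info <- "."
    lines <- c(lines, paste(
      map$contigs[1L], r$pos + 1L, ".", r$ref, paste(alts, collapse = ","),
      100, "PASS", info, "GT:PGT",
      paste(gt_indices(unlist(gts), all_alleles), pgt, sep = ":"),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Read a truth VCF back into the simulate_sample() truth shape.
read_truth_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    all_alleles <- c(f[4L], strsplit(f[5L], ",", fixed = TRUE)[[1L]])
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    smp <- setNames(strsplit(f[10L], ":", fixed = TRUE)[[1L]], fmt)
    gts <- lapply(strsplit(smp[["PGT"]], "|", fixed = TRUE)[[1L]],
                  function(s) {
                    idx <- as.integer(strsplit(s, "/", fixed = TRUE)[[1L]])
                    all_alleles[idx + 1L]
                  })
    tibble(pos = as.integer(f[2L]) - 1L, ref = f[4L], alt = f[5L],
           type = if (nchar(f[4L]) == 1L &&
                        all(nchar(all_alleles) == 1L)) "sub" else
                          if (nchar(f[4L]) > 1L) "del" else "ins",
           genotypes = list(gts),
           is_psv_site = "PSV" %in% strsplit(f[8L], ";", fixed = TRUE)[[1L]],
           agg_variant = "AGGVAR" %in% strsplit(f[8L], ";",
                                                fixed = TRUE)[[1L]])
  })
  bind_rows(rows)
}

#' Write a complete simulation bundle to a directory
#'
#' Writes copies FASTA, reads SAM, truth VCF, PSV table, homology map,
#' copy-number profile and a JSON echo of the configuration, plus a
#' `manifest.tsv` listing the files.
#'
#' @param bundle An `lcr_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- bundle$locus$map
  paths <- c(
    fasta = file.path(dir, "copies.fasta"),
    sam = file.path(dir, "reads.sam"),
    truth = file.path(dir, "truth.vcf"),
    psv = file.path(dir, "psv_table.tsv"),
    homology = file.path(dir, "homology_map.tsv"),
    profile = file.path(dir, "copy_number.tsv"),
    config = file.path(dir, "config.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(map$seqs, map$contigs)),
    paths[["fasta"]])
  write_sam(bundle$reads, map, paths[["sam"]])
  write_truth_vcf(bundle$sample$truth, map, paths[["truth"]])
  write_psv_table(bundle$locus$psv_table, paths[["psv"]])
  write_homology_map(map, paths[["homology"]])
  write_tsv_hash(bundle$profile, paths[["profile"]])
  cfg <- bundle$locus$config
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  manifest <- tibble(file = basename(paths), role = names(paths))
  write_tsv_hash(manifest, file.path(dir, "manifest.tsv"))
  invisible(paths)
}
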