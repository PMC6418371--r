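#' Read single-nucleotide variants from a VCF file
#'
#' Reads a VCF 4.x file, splits multi-allelic records into one row per
#' alternate allele, and drops non-SNV alleles (indels, MNVs, symbolic and
#' breakend alleles). The number of dropped alleles is attached as the
#' `n_dropped_non_snv` attribute and reported with a message.
#'
#' Genotypes are recoded per alternate allele: for the k-th alt of a record,
#' a sample carrying two copies of allele k is `hom_alt`, one copy `het`,
#' none `hom_ref`, and any missing allele `missing`. INFO fields declared
#' with `Number=A` (one value per alt, e.g. `AF`) are allele-matched during
#' the split.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param sample_ids optional character vector restricting (and ordering) the
#'   genotype columns kept.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, a `genotypes`
#'   list-column of named character vectors, and an `info` list-column of
#'   named character vectors.
#' @export
read_vcf <- function(path, sample_ids = NULL) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) {
      rlang::abort(paste0("VCF parse error in '", path, "': ", conditionMessage(e)))
    }
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_rec <- length(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- toupper(as.character(rr$REF))
  alt_list <- lapply(rr$ALT, function(a) toupper(as.character(a)))

  gt <- VariantAnnotation::geno(vcf)
  gt_mat <- if ("GT" %in% names(gt)) gt$GT else NULL
  if (!is.null(gt_mat) && !is.null(sample_ids)) {
    missing_samples <- setdiff(sample_ids, colnames(gt_mat))
    if (length(missing_samples) > 0) {
      rlang::abort(paste0("samples not in VCF: ", paste(missing_samples, collapse = ", ")))
    }
    gt_mat <- gt_mat[, sample_ids, drop = FALSE]
  }

  info_df <- VariantAnnotation::info(vcf)
  info_hdr <- VariantAnnotation::info(VariantAnnotation::header(vcf))
  per_alt_keys <- rownames(info_hdr)[info_hdr$Number == "A"]

  is_snv <- function(r, a) {
    nchar(r) == 1 && nchar(a) == 1 &&
      r %in% c("A", "C", "G", "T") && a %in% c("A", "C", "G", "T") && r != a
  }

  rows <- vector("list", n_rec)
  n_dropped <- 0L
  for (i in seq_len(n_rec)) {
    alts <- alt_list[[i]]
    keep <- vapply(alts, function(a) is_snv(ref[i], a), logical(1))
    n_dropped <- n_dropped + sum(!keep)
    if (!any(keep)) next
    sub <- vector("list", sum(keep))
    j <- 0L
    for (k in which(keep)) {
      j <- j + 1L
      geno_k <- if (is.null(gt_mat)) {
        stats::setNames(character(0), character(0))
      } else {
        vapply(gt_mat[i, ], classify_gt, character(1), alt_index = k)
      }
      info_k <- extract_info_strings(info_df, i, k, per_alt_keys)
      sub[[j]] <- tibble::tibble(
        chrom = chrom[i], pos = as.integer(pos[i]),
        ref = ref[i], alt = alts[k],
        genotypes = list(geno_k), info = list(info_k)
      )
    }
    rows[[i]] <- dplyr::bind_rows(sub)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), genotypes = list(), info = list()
    )
  }
  if (n_dropped > 0) {
    message("read_vcf: dropped ", n_dropped, " non-SNV allele(s)")
  }
  attr(out, "n_records") <- n_rec
  attr(out, "n_dropped_non_snv") <- n_dropped
  out
}

# GT string -> {hom_ref, het, hom_alt, missing} for a given alt index
classify_gt <- function(gt, alt_index) {
  if (is.na(gt)) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".") || length(alleles) == 0) return("missing")
  n_alt <- sum(alleles == as.character(alt_index))
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

extract_info_strings <- function(info_df, i, alt_index, per_alt_keys) {
  keys <- colnames(info_df)
  out <- character(0)
  for (key in keys) {
    v <- info_df[[key]][i]
    if (methods::is(v, "List")) v <- v[[1]]
    v <- unlist(v, use.names = FALSE)
    if (length(v) == 0 || all(is.na(v))) next
    if (key %in% per_alt_keys) {
      if (alt_index <= length(v)) v <- v[alt_index] else next
    }
    if (is.logical(v)) v <- tolower(as.character(v))
    out[key] <- paste(format(v, trim = TRUE, scientific = NA), collapse = ",")
  }
  out
}

#' Read gene models from GTF or the minimal transcript TSV dialect
#'
#' The production path is GTF (via rtracklayer); a minimal tab-separated
#' dialect is also accepted so fixtures can be written and inspected by hand.
#' The dialect has one transcript per line with columns
#' `gene_id  transcript_id  chrom  strand  exons  cds`, where `exons` is a
#' comma-separated list of `start-end` intervals (1-based closed, ascending)
#' and `cds` is either `CDS:start-end` or `.` for non-coding models. Lines
#' starting with `#` are comments.
#'
#' Models violating the structural invariants (overlapping or bookended
#' exons, CDS outside the exon union) are rejected individually with a
#' warning; an input yielding no valid model is an error.
#'
#' @param path path to a `.gtf` file or a transcript TSV.
#' @param format `"auto"` (by extension), `"gtf"` or `"tsv"`.
#' @return A gene-model tibble: one row per transcript with columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `exons` (list-column of tibbles with `start`, `end`, ascending),
#'   `cds_start`, `cds_end` (NA for non-coding).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  raw <- if (format == "gtf") read_models_gtf(path) else read_models_tsv(path)
  validated <- purrr::keep(raw, function(m) {
    msg <- check_gene_model(m)
    if (!is.null(msg)) {
      warning("rejecting model ", m$transcript_id, ": ", msg, call. = FALSE)
      FALSE
    } else {
      TRUE
    }
  })
  if (length(validated) == 0) {
    rlang::abort(paste0("no valid gene model parsed from '", path, "'"))
  }
  dplyr::bind_rows(lapply(validated, function(m) {
    tibble::tibble(
      gene_id = m$gene_id, transcript_id = m$transcript_id,
      chrom = m$chrom, strand = m$strand,
      exons = list(m$exons),
      cds_start = m$cds_start, cds_end = m$cds_end
    )
  }))
}

read_models_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) rlang::abort(paste0("GTF parse error in '", path, "': ", conditionMessage(e)))
  )
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0) rlang::abort(paste0("no exon/CDS features in '", path, "'"))
  df <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    gene_id = if (!is.null(gr$gene_id)) gr$gene_id else NA_character_,
    transcript_id = gr$transcript_id
  )
  df <- dplyr::filter(df, !is.na(.data$transcript_id))
  split_df <- split(df, df$transcript_id)
  lapply(split_df, function(d) {
    ex <- dplyr::arrange(dplyr::filter(d, .data$type == "exon"), .data$start)
    cds <- dplyr::filter(d, .data$type == "CDS")
    list(
      gene_id = if (all(is.na(d$gene_id))) d$transcript_id[1] else d$gene_id[!is.na(d$gene_id)][1],
      transcript_id = d$transcript_id[1],
      chrom = d$chrom[1],
      strand = d$strand[1],
      exons = tibble::tibble(start = as.integer(ex$start), end = as.integer(ex$end)),
      cds_start = if (nrow(cds)) as.integer(min(cds$start)) else NA_integer_,
      cds_end = if (nrow(cds)) as.integer(max(cds$end)) else NA_integer_
    )
  })
}

read_models_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) rlang::abort(paste0("no transcript lines in '", path, "'"))
  lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 6) rlang::abort(paste0("bad transcript line (need 6 fields): ", ln))
    iv <- do.call(rbind, lapply(strsplit(f[5], ",", fixed = TRUE)[[1]], function(x) {
      p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
      if (length(p) != 2 || anyNA(p)) rlang::abort(paste0("bad exon interval '", x, "' in: ", ln))
      p
    }))
    cds_start <- NA_integer_
    cds_end <- NA_integer_
    if (f[6] != ".") {
      m <- regmatches(f[6], regexec("^CDS:(\\d+)-(\\d+)$", f[6]))[[1]]
      if (length(m) != 3) rlang::abort(paste0("bad CDS field '", f[6], "' in: ", ln))
      cds_start <- as.integer(m[2])
      cds_end <- as.integer(m[3])
    }
    list(
      gene_id = f[1], transcript_id = f[2], chrom = f[3], strand = f[4],
      exons = tibble::tibble(start = iv[, 1], end = iv[, 2]),
      cds_start = cds_start, cds_end = cds_end
    )
  })
}

# NULL when structurally valid, else a reason string
check_gene_model <- function(m) {
  if (!m$strand %in% c("+", "-")) return("strand must be '+' or '-'")
  ex <- m$exons
  if (nrow(ex) == 0) return("no exons")
  if (any(ex$end < ex$start)) return("exon end < start")
  if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1) return("exons not sorted")
  if (nrow(ex) > 1) {
    # non-overlapping and non-adjacent: every intron >= 1 bp
    if (any(ex$start[-1] <= ex$end[-nrow(ex)] + 1L)) {
      return("exons overlap or are bookended")
    }
  }
  if (!is.na(m$cds_start)) {
    if (is.na(m$cds_end) || m$cds_end < m$cds_start) return("bad CDS bounds")
    in_exon <- function(p) any(p >= ex$start & p <= ex$end)
    if (!in_exon(m$cds_start) || !in_exon(m$cds_end)) {
      return("CDS bounds outside exon union")
    }
  }
  NULL
}

#' Write gene models in the minimal transcript TSV dialect
#'
#' @param models a gene-model tibble as returned by [read_gene_models()].
#' @param path output path.
#' @param header_comment optional comment line (e.g. recording a seed).
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(models, path, header_comment = NULL) {
  lines <- purrr::pmap_chr(models, function(gene_id, transcript_id, chrom, strand,
                                            exons, cds_start, cds_end, ...) {
    ex <- paste(sprintf("%d-%d", exons$start, exons$end), collapse = ",")
    cds <- if (is.na(cds_start)) "." else sprintf("CDS:%d-%d", cds_start, cds_end)
    paste(gene_id, transcript_id, chrom, strand, ex, cds, sep = "\t")
  })
  if (!is.null(header_comment)) lines <- c(paste0("# ", header_comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GTF 2.2
#'
#' Emits one `exon` feature per exon and one `CDS` feature per coding exon
#' segment, which is what the GTF reader consumes back.
#'
#' @inheritParams write_gene_models_tsv
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path, header_comment = NULL) {
  lines <- character(0)
  if (!is.null(header_comment)) lines <- paste0("#!", header_comment)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id, m$transcript_id)
    ex <- m$exons[[1]]
    lines <- c(lines, sprintf(
      "%s\tpaness\texon\t%d\t%d\t.\t%s\t.\t%s",
      m$chrom, ex$start, ex$end, m$strand, attrs
    ))
    if (!is.na(m$cds_start)) {
      cs <- pmax(ex$start, m$cds_start)
      ce <- pmin(ex$end, m$cds_end)
      keep <- cs <= ce
      lines <- c(lines, sprintf(
        "%s\tpaness\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        m$chrom, cs[keep], ce[keep], m$strand, attrs
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

candidate_report_cols <- c(
  "chrom", "pos", "ref", "alt", "maf", "gene_id", "transcript_id", "site_type",
  "strand", "register", "span_start", "span_end", "alt_context",
  "canonical_context", "consensus_score", "dist_to_canonical"
)

#' Write a candidate report TSV
#'
#' Fixed header and a deterministic sort order so that identical runs give
#' byte-identical reports: rows are ordered by
#' (chrom, pos, transcript_id, site_type, register), with
#' `variant_is_first_base` before `variant_is_second_base`.
#'
#' @param rows candidate tibble as produced by [run_paness()].
#' @param path output path.
#' @return The sorted tibble, invisibly.
#' @export
write_candidates <- function(rows, path) {
  if (nrow(rows) == 0) {
    rows <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(candidate_report_cols)), candidate_report_cols
    ))
    rows$pos <- integer(0); rows$maf <- double(0)
    rows$span_start <- integer(0); rows$span_end <- integer(0)
    rows$consensus_score <- double(0); rows$dist_to_canonical <- integer(0)
  } else {
    missing_cols <- setdiff(candidate_report_cols, names(rows))
    if (length(missing_cols) > 0) {
      rlang::abort(paste0("candidate rows missing column(s): ", paste(missing_cols, collapse = ", ")))
    }
    rows <- dplyr::arrange(
      rows[, candidate_report_cols],
      .data$chrom, .data$pos, .data$transcript_id, .data$site_type, .data$register
    )
  }
  readr::write_tsv(rows, path, na = "NA")
  invisible(rows)
}

#' Read back a candidate report TSV
#'
#' @param path path to a file written by [write_candidates()].
#' @return A tibble with the same columns and types.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", maf = "d",
      gene_id = "c", transcript_id = "c", site_type = "c", strand = "c",
      register = "c", span_start = "i", span_end = "i", alt_context = "c",
      canonical_context = "c", consensus_score = "d", dist_to_canonical = "i"
    ),
    na = "NA", progress = FALSE
  )
}
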