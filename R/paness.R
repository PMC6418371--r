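#' Pipeline configuration
#'
#' @param filter a [filter_config()].
#' @param consensus a [consensus_model()].
#' @param margin variants up to this many bp outside a transcript span are
#'   still evaluated against that transcript (deep-intronic and near-gene
#'   sites are the method's point).
#' @param genome_wide if TRUE, evaluate every variant on both strands with no
#'   transcript context; gene fields and canonical-site columns are NA.
#' @param report_flank half-width of the wider human-review window written to
#'   `alt_context` (centred on the variant base, transcribed strand).
#' @param roles optional named vector (`proband`, `mother`, `father`) of
#'   sample IDs, required by the trio command.
#' @return A `paness_config` list.
#' @export
paness_config <- function(filter = filter_config(),
                          consensus = consensus_model(),
                          margin = 100L,
                          genome_wide = FALSE,
                          report_flank = 10L,
                          roles = NULL) {
  stopifnot(inherits(filter, "filter_config"), inherits(consensus, "consensus_model"),
            margin >= 0, report_flank >= 1)
  structure(list(filter = filter, consensus = consensus, margin = as.integer(margin),
                 genome_wide = genome_wide, report_flank = as.integer(report_flank),
                 roles = roles), class = "paness_config")
}

#' Enumerate novel GT/AG dinucleotide creations for a set of SNVs
#'
#' An SNV can only create a dinucleotide it participates in, so exactly two
#' placements are evaluated per variant, both read 5'->3' on the transcribed
#' strand: (variant base, next base downstream in transcription order) and
#' (previous base, variant base). A placement yields a hit when the alternate
#' dinucleotide reads `GT` (donor) or `AG` (acceptor) *and* the reference
#' dinucleotide at the identical placement does not already read the same —
#' novelty is absolute. Placements touching an `N` or falling off the
#' chromosome yield nothing.
#'
#' This is the vectorised production path; [brute_force_oracle()] is the
#' deliberately naive independent implementation used to validate it.
#'
#' @param chrom_seq chromosome sequence (character scalar, plus strand).
#' @param pos integer vector of 1-based variant positions.
#' @param alt character vector of plus-strand alternate bases (same length).
#' @param strand `"+"` or `"-"`: the transcribed strand to read.
#' @return A tibble with columns `pos`, `alt`, `site_type`, `register`,
#'   `span_start`, `span_end`, `ref_dinuc`, `alt_dinuc` (dinucleotides read
#'   on the transcribed strand).
#' @export
scan_creations <- function(chrom_seq, pos, alt, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(length(pos) == length(alt))
  L <- nchar(chrom_seq)
  empty <- tibble::tibble(
    pos = integer(0), alt = character(0), site_type = character(0),
    register = character(0), span_start = integer(0), span_end = integer(0),
    ref_dinuc = character(0), alt_dinuc = character(0)
  )
  if (length(pos) == 0) return(empty)

  ref_base <- substring(chrom_seq, pos, pos)
  out <- list()

  # placement spanning (pos - 1, pos)
  ok <- pos - 1L >= 1L
  if (any(ok)) {
    p <- pos[ok]
    a <- alt[ok]
    rb <- ref_base[ok]
    left <- substring(chrom_seq, p - 1L, p - 1L)
    if (strand == "+") {
      ref_pair <- paste0(left, rb)
      alt_pair <- paste0(left, a)
      register <- "variant_is_second_base"
    } else {
      ref_pair <- paste0(comp_base(rb), comp_base(left))
      alt_pair <- paste0(comp_base(a), comp_base(left))
      register <- "variant_is_first_base"
    }
    out[[1]] <- tibble::new_tibble(list(
      pos = p, alt = a, register = rep(register, length(p)),
      span_start = p - 1L, span_end = p,
      ref_dinuc = ref_pair, alt_dinuc = alt_pair
    ), nrow = length(p))
  }

  # placement spanning (pos, pos + 1)
  ok <- pos + 1L <= L
  if (any(ok)) {
    p <- pos[ok]
    a <- alt[ok]
    rb <- ref_base[ok]
    right <- substring(chrom_seq, p + 1L, p + 1L)
    if (strand == "+") {
      ref_pair <- paste0(rb, right)
      alt_pair <- paste0(a, right)
      register <- "variant_is_first_base"
    } else {
      ref_pair <- paste0(comp_base(right), comp_base(rb))
      alt_pair <- paste0(comp_base(right), comp_base(a))
      register <- "variant_is_second_base"
    }
    out[[2]] <- tibble::new_tibble(list(
      pos = p, alt = a, register = rep(register, length(p)),
      span_start = p, span_end = p + 1L,
      ref_dinuc = ref_pair, alt_dinuc = alt_pair
    ), nrow = length(p))
  }

  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0) return(empty)
  hits$site_type <- dplyr::case_when(
    hits$alt_dinuc == "GT" ~ "donor",
    hits$alt_dinuc == "AG" ~ "acceptor",
    TRUE ~ NA_character_
  )
  hits <- hits[!is.na(hits$site_type) &
                 hits$ref_dinuc != hits$alt_dinuc &
                 !grepl("N", hits$ref_dinuc, fixed = TRUE) &
                 !grepl("N", hits$alt_dinuc, fixed = TRUE), , drop = FALSE]
  dplyr::arrange(
    hits[, c("pos", "alt", "site_type", "register", "span_start", "span_end",
             "ref_dinuc", "alt_dinuc")],
    .data$pos, .data$span_start
  )
}

#' Enumerate splice-site creations for variants against one gene model
#'
#' Applies [scan_creations()] on the transcribed strand of `model` to every
#' variant on the model's chromosome lying within the transcript span plus
#' `margin`. At most two candidates per (variant, transcript) can result.
#'
#' @param variants variant tibble (chrom, pos, ref, alt, ...).
#' @param genome a [genome_seq()].
#' @param model one row of a gene-model tibble.
#' @param margin bp of slack around the transcript span.
#' @return Candidate tibble with variant identity, `gene_id`,
#'   `transcript_id`, `strand`, and the [scan_creations()] columns.
#' @export
enumerate_creations <- function(variants, genome, model, margin = 100L) {
  ex <- model$exons[[1]]
  span <- c(min(ex$start) - margin, max(ex$end) + margin)
  v <- variants[variants$chrom == model$chrom &
                  variants$pos >= span[1] & variants$pos <= span[2], , drop = FALSE]
  if (nrow(v) == 0) {
    return(tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0), alt = character(0),
      gene_id = character(0), transcript_id = character(0), strand = character(0),
      site_type = character(0), register = character(0),
      span_start = integer(0), span_end = integer(0),
      ref_dinuc = character(0), alt_dinuc = character(0)
    ))
  }
  hits <- scan_creations(genome[[model$chrom]], v$pos, v$alt, model$strand)
  if (nrow(hits) == 0) hits$ref <- character(0) else {
    hits$ref <- v$ref[match(paste(hits$pos, hits$alt), paste(v$pos, v$alt))]
  }
  tibble::tibble(
    chrom = model$chrom, pos = hits$pos, ref = hits$ref, alt = hits$alt,
    gene_id = model$gene_id, transcript_id = model$transcript_id,
    strand = model$strand, site_type = hits$site_type, register = hits$register,
    span_start = hits$span_start, span_end = hits$span_end,
    ref_dinuc = hits$ref_dinuc, alt_dinuc = hits$alt_dinuc
  )
}

#' Canonical essential splice sites of a gene model
#'
#' Every internal exon junction contributes one donor (first two intron
#' bases, transcription order) and one acceptor (last two intron bases).
#' Single-exon models have none.
#'
#' @param model one row of a gene-model tibble.
#' @return Tibble with `site_type`, `span_start`, `span_end` (genomic span of
#'   the essential dinucleotide) and `tpos`, a strand-aware coordinate that
#'   increases in transcription order (used for signed distances).
#' @export
canonical_sites <- function(model) {
  ex <- model$exons[[1]]
  n <- nrow(ex)
  empty <- tibble::tibble(site_type = character(0), span_start = integer(0),
                          span_end = integer(0), tpos = double(0))
  if (n < 2) return(empty)
  if (model$strand == "+") {
    donors <- tibble::tibble(site_type = "donor",
                             span_start = ex$end[-n] + 1L, span_end = ex$end[-n] + 2L)
    acceptors <- tibble::tibble(site_type = "acceptor",
                                span_start = ex$start[-1] - 2L, span_end = ex$start[-1] - 1L)
  } else {
    # transcription order runs high -> low genomic coordinate
    donors <- tibble::tibble(site_type = "donor",
                             span_start = ex$start[-1] - 2L, span_end = ex$start[-1] - 1L)
    acceptors <- tibble::tibble(site_type = "acceptor",
                                span_start = ex$end[-n] + 1L, span_end = ex$end[-n] + 2L)
  }
  sites <- dplyr::bind_rows(donors, acceptors)
  sites$tpos <- site_tpos(sites$span_start, sites$span_end, model$strand)
  sites
}

# transcription-order coordinate of a dinucleotide span
site_tpos <- function(span_start, span_end, strand) {
  if (strand == "+") as.double(span_start) else -as.double(span_end)
}

#' Nearest canonical site of the same type
#'
#' Signed distance in transcription order between a candidate dinucleotide
#' and the model's canonical sites of the same `site_type`: negative means
#' the candidate lies upstream (5') of the canonical site. Ties in |distance|
#' are broken towards the upstream canonical site. Models with fewer than two
#' exons have no canonical sites and return an NA triple.
#'
#' @param candidate one candidate row (needs `site_type`, `span_start`,
#'   `span_end`).
#' @param model the matching gene-model row.
#' @return A list with `span_start`, `span_end`, `distance` (NA triple when
#'   no canonical site of that type exists).
#' @export
nearest_canonical_site <- function(candidate, model) {
  sites <- canonical_sites(model)
  sites <- sites[sites$site_type == candidate$site_type, , drop = FALSE]
  if (nrow(sites) == 0) {
    return(list(span_start = NA_integer_, span_end = NA_integer_, distance = NA_integer_))
  }
  t_cand <- site_tpos(candidate$span_start, candidate$span_end, model$strand)
  d <- t_cand - sites$tpos
  best <- order(abs(d), -d)[1]  # min |d|, ties to the upstream (5') site (d > 0)
  list(span_start = sites$span_start[best], span_end = sites$span_end[best],
       distance = as.integer(d[best]))
}

# Transcribed-strand consensus-length window anchored on a dinucleotide span.
# alt (plus-strand base) substituted at alt_pos when inside the window.
# Returns NA if the window leaves the chromosome.
site_context <- function(genome, chrom, span_start, strand, site_type, consensus,
                         alt_pos = NULL, alt = NULL) {
  m <- consensus[[site_type]]
  span_end <- span_start + 1L
  if (strand == "+") {
    a <- span_start - m$upstream
    b <- span_end + m$downstream
  } else {
    a <- span_start - m$downstream
    b <- span_end + m$upstream
  }
  if (a < 1 || b > nchar(genome[[chrom]])) return(NA_character_)
  s <- substr(genome[[chrom]], a, b)
  if (!is.null(alt) && !is.null(alt_pos) && alt_pos >= a && alt_pos <= b) {
    substr(s, alt_pos - a + 1L, alt_pos - a + 1L) <- alt
  }
  if (strand == "-") s <- revcomp(s)
  s
}

#' Run the full splice-site creation scan
#'
#' Composition of the pipeline: (read VCF ->) annotate MAF -> MAF gate ->
#' per overlapping transcript, enumerate novel GT/AG creations -> locate the
#' nearest canonical site of the same type -> score the alternate context
#' against the splice-site consensus. A variant overlapping no transcript
#' yields no rows unless `config$genome_wide` is set, in which case both
#' strands are evaluated without transcript context and gene fields are NA.
#' Candidates whose context window leaves the chromosome are skipped and
#' counted; no single bad record aborts the run.
#'
#' @param variants variant tibble from [read_vcf()], or a path to a VCF file.
#' @param genome a [genome_seq()] (or path to a FASTA file).
#' @param models gene-model tibble from [read_gene_models()] (ignored in
#'   genome-wide mode; may be NULL there).
#' @param config a [paness_config()].
#' @param freq_source optional [frequency_source()]; when NULL an existing
#'   `maf` column is used, else MAF is NA throughout.
#' @return A `paness_scan` object: list with `candidates` (the report
#'   tibble), and `summary` (stage counts). Use [generics::tidy()] /
#'   [generics::glance()] to extract them as tibbles.
#' @export
run_paness <- function(variants, genome, models = NULL, config = paness_config(),
                       freq_source = NULL) {
  if (is.character(variants)) variants <- read_vcf(variants)
  if (is.character(genome)) genome <- read_genome(genome)
  n_records <- attr(variants, "n_records") %||% nrow(variants)
  n_dropped <- attr(variants, "n_dropped_non_snv") %||% 0L

  if (!is.null(freq_source)) {
    variants <- annotate_maf(variants, freq_source)
  } else if (!"maf" %in% names(variants)) {
    variants$maf <- NA_real_
  }
  low <- filter_by_maf(variants, config$filter)

  cand <- if (config$genome_wide) {
    genome_wide_candidates(low, genome)
  } else {
    if (is.null(models)) rlang::abort("gene models required unless genome_wide = TRUE")
    dplyr::bind_rows(lapply(seq_len(nrow(models)), function(i) {
      enumerate_creations(low, genome, models[i, ], margin = config$margin)
    }))
  }

  n_skipped_context <- 0L
  rows <- if (nrow(cand) == 0) empty_report() else {
    scored <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
      ci <- cand[i, ]
      near <- if (config$genome_wide) {
        list(span_start = NA_integer_, span_end = NA_integer_, distance = NA_integer_)
      } else {
        nearest_canonical_site(ci, models[models$transcript_id == ci$transcript_id, ][1, ])
      }
      ctx <- site_context(genome, ci$chrom, ci$span_start, ci$strand, ci$site_type,
                          config$consensus, alt_pos = ci$pos, alt = ci$alt)
      wide <- tryCatch(
        transcribed_strand_window(genome, ci$chrom, ci$pos, config$report_flank,
                                  ci$strand, alt = ci$alt),
        error = function(e) NA_character_
      )
      if (is.na(ctx) || is.na(wide)) {
        n_skipped_context <<- n_skipped_context + 1L
        return(NULL)
      }
      canon_ctx <- if (is.na(near$span_start)) NA_character_ else {
        site_context(genome, ci$chrom, near$span_start, ci$strand, ci$site_type,
                     config$consensus)
      }
      tibble::tibble(
        chrom = ci$chrom, pos = ci$pos, ref = ci$ref, alt = ci$alt,
        maf = low$maf[match(paste(ci$chrom, ci$pos, ci$ref, ci$alt),
                            paste(low$chrom, low$pos, low$ref, low$alt))],
        gene_id = ci$gene_id, transcript_id = ci$transcript_id,
        site_type = ci$site_type, strand = ci$strand, register = ci$register,
        span_start = ci$span_start, span_end = ci$span_end,
        alt_context = wide, canonical_context = canon_ctx,
        consensus_score = consensus_similarity(ctx, ci$site_type, config$consensus),
        dist_to_canonical = near$distance
      )
    })
    if (is.null(scored) || nrow(scored) == 0) empty_report() else scored
  }
  rows <- dplyr::arrange(rows, .data$chrom, .data$pos, .data$transcript_id,
                         .data$site_type, .data$register)

  structure(list(
    candidates = rows,
    variants_kept = low,
    summary = list(
      n_records = n_records,
      n_dropped_non_snv = n_dropped,
      n_snvs = nrow(variants),
      n_low_maf = nrow(low),
      n_candidates = nrow(rows),
      n_variants_with_candidates =
        length(unique(paste(rows$chrom, rows$pos, rows$ref, rows$alt))),
      n_genes = length(unique(stats::na.omit(rows$gene_id))),
      n_skipped_context = n_skipped_context
    )
  ), class = "paness_scan")
}

genome_wide_candidates <- function(variants, genome) {
  dplyr::bind_rows(lapply(split(variants, variants$chrom), function(v) {
    chrom <- v$chrom[1]
    if (is.null(genome[[chrom]])) return(NULL)
    dplyr::bind_rows(lapply(c("+", "-"), function(st) {
      hits <- scan_creations(genome[[chrom]], v$pos, v$alt, st)
      if (nrow(hits) == 0) return(NULL)
      hits$ref <- v$ref[match(paste(hits$pos, hits$alt), paste(v$pos, v$alt))]
      tibble::tibble(
        chrom = chrom, pos = hits$pos, ref = hits$ref, alt = hits$alt,
        gene_id = NA_character_, transcript_id = NA_character_,
        strand = st, site_type = hits$site_type, register = hits$register,
        span_start = hits$span_start, span_end = hits$span_end,
        ref_dinuc = hits$ref_dinuc, alt_dinuc = hits$alt_dinuc
      )
    }))
  }))
}

empty_report <- function() {
  tibble::tibble(
    chrom = character(0), pos = integer(0), ref = character(0), alt = character(0),
    maf = double(0), gene_id = character(0), transcript_id = character(0),
    site_type = character(0), strand = character(0), register = character(0),
    span_start = integer(0), span_end = integer(0), alt_context = character(0),
    canonical_context = character(0), consensus_score = double(0),
    dist_to_canonical = integer(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
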