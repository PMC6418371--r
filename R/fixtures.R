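# run code under a fixed seed without disturbing the caller's RNG state
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a reproducible random genome
#'
#' @param seed integer seed; fixed seed gives a byte-identical genome.
#' @param length chromosome length in bp (>= 1000).
#' @param gc target G+C fraction in (0, 1).
#' @param chrom chromosome name.
#' @return A [genome_seq()] with one chromosome.
#' @export
generate_genome <- function(seed, length = 10000L, gc = 0.5, chrom = "chr1") {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  with_fixed_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome_seq(stats::setNames(list(paste(bases, collapse = "")), chrom))
  })
}

random_codons <- function(n) {
  non_stop <- names(codon_table)[codon_table != "*"]
  sample(non_stop, n, replace = TRUE)
}

# map a transcript coordinate to genomic, over exons in transcription order
tx_to_genomic <- function(ex_tx, strand, tpos) {
  off <- 0L
  for (i in seq_len(nrow(ex_tx))) {
    len <- ex_tx$end[i] - ex_tx$start[i] + 1L
    if (tpos <= off + len) {
      within <- tpos - off - 1L
      return(if (strand == "+") ex_tx$start[i] + within else ex_tx$end[i] - within)
    }
    off <- off + len
  }
  NA_integer_
}

#' Generate synthetic gene models and write them into a genome
#'
#' Places `n_transcripts` non-overlapping transcripts (mixed strands, 2-8
#' exons each) on the genome, writing each transcript's exonic sequence and
#' canonical `GT`/`AG` intron ends into the chromosome so that every model
#' is canonical by construction. Each model carries a valid CDS: `ATG`
#' start, in-frame stop, length a multiple of 3, no internal stop codon.
#' Transcripts are separated by at least 300 bp so that a transcript-margin
#' of up to 100 bp never makes a variant ambiguous between models.
#'
#' @param genome a [genome_seq()] to place models on (its sequence is
#'   modified and returned).
#' @param n_transcripts number of transcripts to place.
#' @param seed integer seed.
#' @return A list with `genome` (modified) and `models` (gene-model tibble).
#' @export
generate_gene_models <- function(genome, n_transcripts, seed) {
  with_fixed_seed(seed, {
    chrom <- names(genome)[1]
    L <- nchar(genome[[chrom]])
    seq_chr <- genome[[chrom]]
    models <- list()
    cursor <- 150L
    for (t in seq_len(n_transcripts)) {
      n_exons <- sample(2:8, 1)
      exon_lens <- sample(60:160, n_exons, replace = TRUE)
      intron_lens <- sample(80:150, n_exons - 1, replace = TRUE)
      span <- sum(exon_lens) + sum(intron_lens)
      if (cursor + span + 150L > L) {
        if (length(models) == 0) {
          rlang::abort("genome too short for the requested gene models")
        }
        warning("genome exhausted after ", length(models), " of ", n_transcripts,
                " transcripts", call. = FALSE)
        break
      }
      strand <- sample(c("+", "-"), 1)
      # transcript sequence: 5' UTR + CDS + 3' UTR, then cut into exons
      total <- sum(exon_lens)
      utr5 <- sample(10:30, 1)
      n_codons <- (total - utr5 - sample(10:30, 1)) %/% 3L - 1L
      if (n_codons < 5L) n_codons <- 5L
      cds <- paste(c("ATG", random_codons(n_codons - 1L), sample(c("TAA", "TAG", "TGA"), 1)),
                   collapse = "")
      utr3 <- total - utr5 - nchar(cds)
      if (utr3 < 3L) rlang::abort("internal: exon lengths too small for CDS")
      tx_seq <- paste0(
        paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
        cds,
        paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = "")
      )
      # genomic exon intervals, ascending
      starts <- integer(n_exons)
      g <- cursor
      for (i in seq_len(n_exons)) {
        starts[i] <- g
        g <- g + exon_lens[i] + if (i < n_exons) intron_lens[i] else 0L
      }
      ends <- starts + exon_lens - 1L
      # write exon sequence: exon index in transcription order
      tx_off <- 0L
      order_idx <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
      for (i in order_idx) {
        piece <- substr(tx_seq, tx_off + 1L, tx_off + exon_lens[i])
        if (strand == "-") piece <- revcomp(piece)
        substr(seq_chr, starts[i], ends[i]) <- piece
        tx_off <- tx_off + exon_lens[i]
      }
      # introns: random fill, then canonical GT/AG on the transcribed strand
      for (i in seq_len(n_exons - 1L)) {
        a <- ends[i] + 1L
        b <- starts[i + 1L] - 1L
        substr(seq_chr, a, b) <- paste(
          sample(c("A", "C", "G", "T"), b - a + 1L, replace = TRUE), collapse = "")
        if (strand == "+") {
          substr(seq_chr, a, a + 1L) <- "GT"
          substr(seq_chr, b - 1L, b) <- "AG"
        } else {
          substr(seq_chr, a, a + 1L) <- "CT"   # reads AG on the minus strand
          substr(seq_chr, b - 1L, b) <- "AC"   # reads GT on the minus strand
        }
      }
      ex_tx <- {
        ex <- tibble::tibble(start = starts, end = ends)
        if (strand == "-") ex[rev(seq_len(n_exons)), ] else ex
      }
      cds_g1 <- tx_to_genomic(ex_tx, strand, utr5 + 1L)
      cds_g2 <- tx_to_genomic(ex_tx, strand, utr5 + nchar(cds))
      models[[t]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", t),
        transcript_id = sprintf("tx%03d", t),
        chrom = chrom, strand = strand,
        exons = list(tibble::tibble(start = starts, end = ends)),
        cds_start = min(cds_g1, cds_g2), cds_end = max(cds_g1, cds_g2)
      )
      cursor <- g + 300L
    }
    genome[[chrom]] <- seq_chr
    list(genome = genome_seq(genome), models = dplyr::bind_rows(models))
  })
}

#' Brute-force splice-creation oracle
#'
#' Independent, deliberately naive check used to validate the vectorised
#' scanner: builds the *entire* alternate chromosome string, reverse
#' complements the whole string when the transcribed strand is minus, and
#' inspects the two dinucleotide placements containing the variant base in
#' the transcribed string, reporting `GT`/`AG` gains relative to the
#' reference string at the same placement. Unlike [scan_creations()] it
#' never reasons locally about complements or registers; everything falls
#' out of whole-string coordinates.
#'
#' @param genome a [genome_seq()].
#' @param chrom,pos,ref,alt the SNV (plus-strand alleles).
#' @param strand transcribed strand to read, `"+"` or `"-"`.
#' @return Tibble with `site_type`, `register`, `span_start`, `span_end`
#'   (genomic span of the created dinucleotide).
#' @export
brute_force_oracle <- function(genome, chrom, pos, ref, alt, strand = "+") {
  L <- nchar(genome[[chrom]])
  stopifnot(pos >= 1, pos <= L)
  ref_str <- genome[[chrom]]
  if (substr(ref_str, pos, pos) != ref) {
    rlang::abort(sprintf("reference mismatch at %s:%d", chrom, pos))
  }
  alt_str <- paste0(substr(ref_str, 1L, pos - 1L), alt,
                    substr(ref_str, pos + 1L, L))
  if (strand == "-") {
    ref_t <- stringi::stri_reverse(chartr("ACGTN", "TGCAN", ref_str))
    alt_t <- stringi::stri_reverse(chartr("ACGTN", "TGCAN", alt_str))
    pt <- L - pos + 1L
  } else {
    ref_t <- ref_str
    alt_t <- alt_str
    pt <- pos
  }
  site_type <- character(0)
  register <- character(0)
  span_start <- integer(0)
  span_end <- integer(0)
  for (a in c(pt - 1L, pt)) {
    if (a < 1L || a + 1L > L) next
    pair_alt <- substr(alt_t, a, a + 1L)
    pair_ref <- substr(ref_t, a, a + 1L)
    if (!pair_alt %in% c("GT", "AG")) next
    if (pair_ref == pair_alt) next
    if (grepl("N", pair_ref, fixed = TRUE) || grepl("N", pair_alt, fixed = TRUE)) next
    # genomic span of transcribed-string positions (a, a+1)
    span <- if (strand == "-") c(L - (a + 1L) + 1L, L - a + 1L) else c(a, a + 1L)
    site_type <- c(site_type, if (pair_alt == "GT") "donor" else "acceptor")
    register <- c(register,
                  if (a == pt) "variant_is_first_base" else "variant_is_second_base")
    span_start <- c(span_start, span[1])
    span_end <- c(span_end, span[2])
  }
  o <- order(span_start)
  tibble::new_tibble(list(site_type = site_type[o], register = register[o],
                          span_start = span_start[o], span_end = span_end[o]),
                     nrow = length(o))
}

trio_gt_patterns <- list(
  recessive = c(proband = "hom_alt", mother = "het", father = "het"),
  dominant_de_novo = c(proband = "het", mother = "hom_ref", father = "hom_ref"),
  none_a = c(proband = "het", mother = "het", father = "het"),
  none_b = c(proband = "hom_alt", mother = "hom_alt", father = "het"),
  none_c = c(proband = "hom_ref", mother = "het", father = "het")
)

#' Plant splice-creating and null variants with ground truth
#'
#' Creation variants are SNVs verified *at plant time* by
#' [brute_force_oracle()] to create at least one novel GT/AG on the
#' transcribed strand of their transcript; null variants verifiably create
#' none. All creation and null variants carry AF at or below 0.001 (or no AF
#' record); an optional extra set of "common" creation variants carries
#' AF > 0.001 to exercise the MAF gate. Trio genotypes follow the planted
#' inheritance label (recessive: proband 1/1, parents 0/1; de novo dominant:
#' proband 0/1, parents 0/0; the remainder get patterns that match neither
#' model).
#'
#' @param genome a [genome_seq()] (after [generate_gene_models()]).
#' @param models gene-model tibble.
#' @param n_creations number of low-frequency creation variants.
#' @param n_nulls number of low-frequency variants creating nothing.
#' @param seed integer seed.
#' @param n_recessive how many creations get the autosomal-recessive trio
#'   pattern.
#' @param n_dominant how many creations get the de novo dominant pattern.
#' @param n_common_creations extra creation variants with AF > 0.001, which
#'   the MAF gate must remove.
#' @return A list with `variants` (tibble: chrom, pos, ref, alt, af, kind,
#'   inheritance, genotypes list-column) and `truth` (tibble: one row per
#'   variant, `expected` list-column of expected candidates with
#'   `site_type`, `register`, `span_start`, `span_end`, `transcript_id`,
#'   and `expected_n`).
#' @export
plant_variants <- function(genome, models, n_creations, n_nulls, seed,
                           n_recessive = 5L, n_dominant = 0L,
                           n_common_creations = 0L) {
  stopifnot(n_recessive + n_dominant <= n_creations)
  with_fixed_seed(seed, {
    used <- new.env(parent = emptyenv())
    pick_site <- function(want_creation) {
      for (attempt in seq_len(20000L)) {
        mi <- sample(nrow(models), 1)
        m <- models[mi, ]
        ex <- m$exons[[1]]
        lo <- min(ex$start) - 80L
        hi <- max(ex$end) + 80L
        pos <- sample(lo:hi, 1)
        key <- paste(m$chrom, pos)
        if (!is.null(used[[key]])) next
        ref <- substr(genome[[m$chrom]], pos, pos)
        if (!ref %in% c("A", "C", "G", "T")) next
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        hits <- brute_force_oracle(genome, m$chrom, pos, ref, alt, m$strand)
        ok <- if (want_creation) nrow(hits) > 0 else nrow(hits) == 0
        if (!ok) next
        used[[key]] <- TRUE
        hits$transcript_id <- rep(m$transcript_id, nrow(hits))
        return(list(chrom = m$chrom, pos = pos, ref = ref, alt = alt,
                    transcript_id = m$transcript_id, expected = hits))
      }
      rlang::abort("could not place a variant after bounded retries")
    }

    inh_labels <- c(rep("recessive", n_recessive), rep("dominant_de_novo", n_dominant),
                    rep("none", n_creations - n_recessive - n_dominant))
    inh_labels <- sample(inh_labels)

    build <- function(n, kind, inh, af_fun) {
      purrr::map2_dfr(seq_len(n), inh[seq_len(n)], function(i, label) {
        s <- pick_site(kind %in% c("creation", "common_creation"))
        pat <- switch(label,
          recessive = trio_gt_patterns$recessive,
          dominant_de_novo = trio_gt_patterns$dominant_de_novo,
          trio_gt_patterns[[sample(c("none_a", "none_b", "none_c"), 1)]]
        )
        tibble::tibble(
          chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
          af = af_fun(), kind = kind, inheritance = label,
          transcript_id = s$transcript_id,
          genotypes = list(pat), expected = list(s$expected)
        )
      })
    }

    low_af <- function() if (stats::runif(1) < 0.3) NA_real_ else stats::runif(1, 1e-6, 0.001)
    high_af <- function() stats::runif(1, 0.002, 0.5)

    creations <- if (n_creations > 0) build(n_creations, "creation", inh_labels, low_af) else NULL
    nulls <- if (n_nulls > 0) {
      build(n_nulls, "null", rep("none", n_nulls),
            function() if (stats::runif(1) < 0.25) high_af() else low_af())
    } else NULL
    commons <- if (n_common_creations > 0) {
      build(n_common_creations, "common_creation",
            rep("none", n_common_creations), high_af)
    } else NULL

    variants <- dplyr::arrange(dplyr::bind_rows(creations, nulls, commons),
                               .data$chrom, .data$pos)
    truth <- dplyr::mutate(
      variants[, c("chrom", "pos", "ref", "alt", "af", "kind", "inheritance",
                   "transcript_id", "expected")],
      expected_n = purrr::map_int(.data$expected, nrow)
    )
    list(variants = variants, truth = truth)
  })
}

#' Write a planted trio as a multi-sample VCF 4.2
#'
#' Sample order is fixed (proband, mother, father). AF is written as an
#' INFO field with `Number=A`; variants with no AF record carry no AF key.
#'
#' @param variants `variants` tibble from [plant_variants()].
#' @param genome the [genome_seq()] (for contig header lines).
#' @param path output path.
#' @param samples sample names for (proband, mother, father).
#' @param seed_comment optional seed note placed in the header.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, genome, path,
                           samples = c("1406-1", "1406-2", "1406-3"),
                           seed_comment = NULL) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(seed_comment)) paste0("##paness_seed=", seed_comment),
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s,length=%d>", names(genome), seq_lengths(genome)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  body <- purrr::pmap_chr(
    variants[, c("chrom", "pos", "ref", "alt", "af", "genotypes")],
    function(chrom, pos, ref, alt, af, genotypes) {
      info <- if (is.na(af)) "." else sprintf("AF=%.8g", af)
      paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT",
              gt_code[genotypes[c("proband", "mother", "father")]]), collapse = "\t")
    }
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a truth table as TSV
#'
#' One line per (variant, expected candidate); variants expecting no
#' candidate get a single line with NA candidate fields.
#'
#' @param truth `truth` tibble from [plant_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  flat <- purrr::pmap_dfr(
    truth[, c("chrom", "pos", "ref", "alt", "af", "kind", "inheritance",
              "transcript_id", "expected", "expected_n")],
    function(chrom, pos, ref, alt, af, kind, inheritance, transcript_id,
             expected, expected_n) {
      base <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             af = af, kind = kind, inheritance = inheritance,
                             expected_n = expected_n)
      if (nrow(expected) == 0) {
        dplyr::mutate(base, site_type = NA_character_, register = NA_character_,
                      span_start = NA_integer_, span_end = NA_integer_,
                      transcript_id = NA_character_)
      } else {
        dplyr::bind_cols(base[rep(1, nrow(expected)), ],
                         expected[, c("site_type", "register", "span_start",
                                      "span_end", "transcript_id")])
      }
    }
  )
  readr::write_tsv(flat, path, na = "NA")
  invisible(path)
}

#' Synthetic worked-example transcript (SERCA1-like)
#'
#' A hand-constructed, fully synthetic plus-strand transcript that mirrors
#' the published worked example's arithmetic without any external download:
#' 13 exons; exon 11 is 103 bp ending at coding position 1287; the reference
#' base there is `G` inside a `GAG` (Glu) codon, so the G>A change at the
#' exon's last base is synonymous on the unspliced transcript
#' (p.(Glu429=)) while creating a novel `AG` acceptor dinucleotide across
#' the exon 11 donor junction; and skipping exon 11 shifts the frame at
#' residue 396 (Leu>Pro) with a stop at position 23 of the new frame,
#' p.(Leu396ProfsTer23), far enough upstream of the last junction to flag
#' nonsense-mediated decay. It is a stand-in built from these published
#' constraints, not the RefSeq transcript.
#'
#' @return A list with `genome` (one synthetic chromosome), `models`
#'   (one-row gene-model tibble), `variant` (tibble with the G>A variant,
#'   AF 8.1e-06, trio genotypes 1/1, 0/1, 0/1), and `expected` (a list of
#'   the values the pipeline should reproduce).
#' @export
synthetic_worked_example <- function() {
  # reference CDS, codon by codon
  codons <- c(
    "ATG", rep("CAC", 393),          # 1, 2..394
    "CTG",                            # 395: Leu, split 2+1 across exons 10|11
    "CTG",                            # 396: Leu, first residue altered by the skip
    rep("CAC", 32),                   # 397..428
    "GAG"                             # 429: Glu, ends at coding position 1287
  )
  # exon 12 coding sequence (e1..e216); the shifted frame after the skip
  # reads (e2,e3,e4) = CCA (Pro) at residue 396 and hits TAA at offset 23
  e <- rep("A", 216)
  e[1:4] <- c("A", "C", "C", "A")
  e[68:70] <- c("T", "A", "A")       # premature stop in the shifted frame
  e[214:216] <- c("T", "A", "A")     # reference stop codon (codon 501)
  cds <- paste0(paste(codons, collapse = ""), paste(e, collapse = ""))
  stopifnot(nchar(cds) == 1503)

  utr5 <- strrep("CT", 25)                     # 50 bp
  utr3a <- strrep("C", 34)                     # 3' UTR tail of exon 12
  utr3b <- strrep("CT", 100)                   # exon 13, non-coding
  tx <- paste0(utr5, cds, utr3a, utr3b)
  exon_lens <- c(168L, rep(118L, 8L), 122L, 103L, 250L, 200L)
  stopifnot(sum(exon_lens) == nchar(tx))

  intron_len <- 150L
  pad <- 100L
  starts <- integer(13)
  g <- pad + 1L
  for (i in 1:13) {
    starts[i] <- g
    g <- g + exon_lens[i] + intron_len
  }
  ends <- starts + exon_lens - 1L
  chrom_len <- ends[13] + pad
  chrom <- rep("C", chrom_len)
  off <- 0L
  for (i in 1:13) {
    piece <- substr(tx, off + 1L, off + exon_lens[i])
    chrom[starts[i]:ends[i]] <- strsplit(piece, "", fixed = TRUE)[[1]]
    off <- off + exon_lens[i]
  }
  for (i in 1:12) {
    a <- ends[i] + 1L
    b <- starts[i + 1L] - 1L
    chrom[a:b] <- rep("A", b - a + 1L)
    chrom[a:(a + 1L)] <- c("G", "T")
    chrom[(b - 1L):b] <- c("A", "G")
  }
  genome <- genome_seq(list(chrS = paste(chrom, collapse = "")))

  cds_start_g <- starts[1] + 50L
  cds_end_g <- starts[12] + 216L - 1L
  models <- tibble::tibble(
    gene_id = "ATP2A1_like", transcript_id = "ATP2A1_like_tx1",
    chrom = "chrS", strand = "+",
    exons = list(tibble::tibble(start = starts, end = ends)),
    cds_start = cds_start_g, cds_end = cds_end_g
  )

  var_pos <- ends[11]   # last base of exon 11 = coding position 1287
  variant <- tibble::tibble(
    chrom = "chrS", pos = var_pos, ref = "G", alt = "A",
    af = 8.1e-06,
    genotypes = list(c(proband = "hom_alt", mother = "het", father = "het"))
  )
  list(
    genome = genome, models = models, variant = variant,
    expected = list(
      site_type = "acceptor",
      register = "variant_is_first_base",
      span_start = var_pos, span_end = var_pos + 1L,
      donor_junction_span = c(var_pos + 1L, var_pos + 2L),
      exon_index = 11L, exon_length = 103L,
      hgvs_p = "p.(Leu396ProfsTer23)",
      nmd_flag = TRUE,
      synonymous_codon = "Glu429="
    )
  )
}
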