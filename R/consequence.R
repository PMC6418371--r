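# Standard genetic code, 1-letter codes; "*" = stop
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

aa_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Ter"
)

aa3 <- function(x) {
  unname(aa_three[strsplit(x, "", fixed = TRUE)[[1]]])
}

# exons in transcription order (exon 1 = 5'-most in transcription)
exons_tx_order <- function(model) {
  ex <- model$exons[[1]]
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Splice a transcript, optionally skipping one exon
#'
#' Concatenates exon sequences in transcription order (minus-strand models
#' are reverse-complemented) and extracts the coding sequence. For an
#' unskipped transcript the CDS runs from the start codon to the annotated
#' stop and must be a multiple of 3; for a skipped transcript it runs from
#' the start codon to the transcript 3' end, since a frameshift can move the
#' stop downstream of the annotated one.
#'
#' @param genome a [genome_seq()].
#' @param model one row of a gene-model tibble; must have CDS bounds.
#' @param skip_exon optional 1-based exon index in transcription order to
#'   omit. Skipping the exon containing the start codon is an error.
#' @return A list with `mrna`, `cds` and `cds_tx_start` (1-based position of
#'   the first CDS base within `mrna`).
#' @export
splice_transcript <- function(genome, model, skip_exon = NULL) {
  if (is.na(model$cds_start)) rlang::abort("model has no CDS bounds")
  ex <- exons_tx_order(model)
  n <- nrow(ex)
  # genomic position of the first CDS base in transcription order
  cds_first_g <- if (model$strand == "+") model$cds_start else model$cds_end
  cds_last_g <- if (model$strand == "+") model$cds_end else model$cds_start
  if (!is.null(skip_exon)) {
    if (skip_exon < 1 || skip_exon > n) rlang::abort("skip_exon out of range")
    sk <- ex[skip_exon, ]
    if (cds_first_g >= sk$start && cds_first_g <= sk$end) {
      rlang::abort("skipping the exon containing the start codon is not supported")
    }
    ex <- ex[-skip_exon, , drop = FALSE]
  }
  seqs <- purrr::map2_chr(ex$start, ex$end, function(s, e) {
    s0 <- get_seq(genome, model$chrom, s, e)
    if (model$strand == "-") revcomp(s0) else s0
  })
  mrna <- paste(seqs, collapse = "")
  # transcript coordinate of a genomic position over the (possibly reduced) exon set
  txc <- function(gpos) {
    off <- 0L
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- ex$end[i]
      if (gpos >= s && gpos <= e) {
        within <- if (model$strand == "+") gpos - s else e - gpos
        return(off + within + 1L)
      }
      off <- off + (e - s + 1L)
    }
    NA_integer_
  }
  t1 <- txc(cds_first_g)
  if (is.na(t1)) rlang::abort("CDS start not contained in the exon set")
  if (is.null(skip_exon)) {
    t2 <- txc(cds_last_g)
    if (is.na(t2)) rlang::abort("CDS end not contained in the exon set")
    cds <- substr(mrna, t1, t2)
    if (nchar(cds) %% 3 != 0) {
      rlang::abort(sprintf("CDS of %s has length %d, not a multiple of 3",
                           model$transcript_id, nchar(cds)))
    }
  } else {
    cds <- substr(mrna, t1, nchar(mrna))
  }
  list(mrna = mrna, cds = cds, cds_tx_start = t1)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at the first stop codon. A trailing partial codon is
#' ignored but flagged, as is a sequence that runs out without reaching a
#' stop.
#'
#' @param cds character scalar over `A/C/G/T`, length >= 3.
#' @return A list with `protein` (1-letter codes, stop excluded),
#'   `stop_reached` and `partial_codon` flags.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) rlang::abort("coding sequence shorter than one codon")
  if (grepl("[^ACGT]", cds)) rlang::abort("coding sequence contains non-ACGT characters")
  n_codon <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aas <- unname(codon_table[codons])
  stop_i <- which(aas == "*")
  if (length(stop_i) > 0) {
    list(protein = paste(aas[seq_len(stop_i[1] - 1L)], collapse = ""),
         stop_reached = TRUE,
         partial_codon = FALSE)
  } else {
    list(protein = paste(aas, collapse = ""),
         stop_reached = FALSE,
         partial_codon = nchar(cds) %% 3L != 0L)
  }
}

#' Predict the protein consequence of skipping one exon
#'
#' Compares the reference translation with the translation of the transcript
#' lacking `exon_index` (transcription order). Only the coding portion of
#' the exon counts toward frame arithmetic: skipping a wholly non-coding
#' exon is "no protein change", and a coding length that is a multiple of 3
#' preserves the frame. Frameshifts are reported in HGVS `fsTer` notation,
#' counting the first altered residue as position 1, so `Ter23` places the
#' new stop at position 23 of the shifted frame; a frameshift whose first
#' shifted codon is itself a stop is reported as a nonsense change
#' `p.(XnnnTer)`. In-frame skips are reported as deletions
#' `p.(Xnnn_Ymmmdel)` (or `delins` when the junction codon changes).
#'
#' A nonsense-mediated-decay flag is set when the predicted stop lies at
#' least 50 nt upstream of the last exon-exon junction of the skipped
#' transcript.
#'
#' @param genome a [genome_seq()].
#' @param model one row of a gene-model tibble with CDS bounds.
#' @param exon_index 1-based exon index in transcription order.
#' @return An `exon_skip` object; see [tidy.exon_skip()] for the tabular
#'   form.
#' @export
predict_exon_skip <- function(genome, model, exon_index) {
  ex <- exons_tx_order(model)
  n <- nrow(ex)
  if (exon_index < 1 || exon_index > n) {
    rlang::abort(sprintf("exon %d out of range (transcript has %d exons)", exon_index, n))
  }
  sk <- ex[exon_index, ]
  exon_len <- sk$end - sk$start + 1L
  coding_len <- max(0L, min(sk$end, model$cds_end) - max(sk$start, model$cds_start) + 1L)

  res <- list(
    transcript_id = model$transcript_id,
    exon_index = as.integer(exon_index),
    exon_length = as.integer(exon_len),
    coding_length = as.integer(coding_len),
    frame_preserving = coding_len %% 3L == 0L,
    first_altered_residue = NA_integer_,
    ref_residue = NA_character_,
    novel_residue = NA_character_,
    stop_offset = NA_integer_,
    hgvs_p = NA_character_,
    nmd_flag = NA,
    protein_ref = NA_character_,
    protein_alt = NA_character_,
    stop_reached_alt = NA
  )

  if (coding_len == 0L) {
    res$hgvs_p <- "p.(=)"
    res$nmd_flag <- FALSE
    return(structure(res, class = "exon_skip"))
  }

  ref <- splice_transcript(genome, model)
  alt <- splice_transcript(genome, model, skip_exon = exon_index)
  tr_ref <- translate_cds(ref$cds)
  tr_alt <- translate_cds(alt$cds)
  P <- tr_ref$protein
  Q <- tr_alt$protein
  res$protein_ref <- P
  res$protein_alt <- Q
  res$stop_reached_alt <- tr_alt$stop_reached

  # first residue where the two translations differ
  np <- nchar(P); nq <- nchar(Q)
  nmin <- min(np, nq)
  pv <- strsplit(P, "", fixed = TRUE)[[1]]
  qv <- strsplit(Q, "", fixed = TRUE)[[1]]
  diff_i <- which(pv[seq_len(nmin)] != qv[seq_len(nmin)])
  i <- if (length(diff_i) > 0) diff_i[1] else nmin + 1L

  if (!res$frame_preserving) {
    res$first_altered_residue <- as.integer(i)
    res$ref_residue <- if (i <= np) pv[i] else "*"
    if (i > nq) {
      # the first shifted codon is already a stop: nonsense, not fsTer
      res$novel_residue <- "*"
      res$stop_offset <- 1L
      res$hgvs_p <- sprintf("p.(%s%dTer)", aa_three[[res$ref_residue]], i)
    } else {
      res$novel_residue <- qv[i]
      if (tr_alt$stop_reached) {
        res$stop_offset <- as.integer(nq + 1L - i + 1L)
        res$hgvs_p <- sprintf("p.(%s%d%sfsTer%d)", aa_three[[res$ref_residue]], i,
                              aa_three[[res$novel_residue]], res$stop_offset)
      } else {
        res$hgvs_p <- sprintf("p.(%s%d%sfsTer?)", aa_three[[res$ref_residue]], i,
                              aa_three[[res$novel_residue]])
      }
    }
  } else {
    # in-frame: align by common prefix/suffix, report the excised stretch
    a <- i - 1L
    b <- 0L
    while (b < nmin - a && pv[np - b] == qv[nq - b]) b <- b + 1L
    del_from <- a + 1L
    del_to <- np - b
    ins <- if (nq - b >= a + 1L) qv[seq(a + 1L, nq - b)] else character(0)
    if (del_to < del_from) {
      res$hgvs_p <- "p.(=)"
    } else {
      res$first_altered_residue <- as.integer(del_from)
      res$ref_residue <- pv[del_from]
      range_str <- if (del_to == del_from) {
        sprintf("%s%d", aa_three[[pv[del_from]]], del_from)
      } else {
        sprintf("%s%d_%s%d", aa_three[[pv[del_from]]], del_from,
                aa_three[[pv[del_to]]], del_to)
      }
      res$hgvs_p <- if (length(ins) == 0) {
        sprintf("p.(%sdel)", range_str)
      } else {
        sprintf("p.(%sdelins%s)", range_str,
                paste(unname(aa_three[ins]), collapse = ""))
      }
    }
  }

  # NMD heuristic: premature stop >= 50 nt upstream of the last junction
  res$nmd_flag <- FALSE
  ex_alt <- ex[-exon_index, , drop = FALSE]
  if (tr_alt$stop_reached && nrow(ex_alt) >= 2) {
    lens <- ex_alt$end - ex_alt$start + 1L
    last_junction <- sum(lens[-length(lens)])
    stop_end <- alt$cds_tx_start + 3L * (nq + 1L) - 1L
    res$nmd_flag <- (last_junction - stop_end) >= 50L
  }
  structure(res, class = "exon_skip")
}

#' Parse an HGVS p. frameshift / deletion string back into its parts
#'
#' The inverse of the formatting used by [predict_exon_skip()]; used in
#' round-trip checks.
#'
#' @param hgvs_p a string like `"p.(Leu396ProfsTer23)"`.
#' @return A list with `ref_residue`, `position`, `novel_residue`,
#'   `stop_offset` (fsTer form) or `kind = "del"/"delins"/"ter"/"silent"`.
#' @export
parse_hgvs_p <- function(hgvs_p) {
  three_to_one <- stats::setNames(names(aa_three), unname(aa_three))
  m <- regmatches(hgvs_p, regexec(
    "^p\\.\\(([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})fsTer(\\d+|\\?)\\)$", hgvs_p))[[1]]
  if (length(m) == 5) {
    return(list(kind = "fs",
                ref_residue = three_to_one[[m[2]]],
                position = as.integer(m[3]),
                novel_residue = three_to_one[[m[4]]],
                stop_offset = if (m[5] == "?") NA_integer_ else as.integer(m[5])))
  }
  m <- regmatches(hgvs_p, regexec("^p\\.\\(([A-Z][a-z]{2})(\\d+)Ter\\)$", hgvs_p))[[1]]
  if (length(m) == 3) {
    return(list(kind = "ter", ref_residue = three_to_one[[m[2]]],
                position = as.integer(m[3]), novel_residue = "*", stop_offset = 1L))
  }
  if (hgvs_p == "p.(=)") return(list(kind = "silent"))
  if (grepl("delins", hgvs_p, fixed = TRUE)) return(list(kind = "delins"))
  if (grepl("del\\)$", hgvs_p)) return(list(kind = "del"))
  rlang::abort(paste0("unrecognised HGVS p. string: ", hgvs_p))
}

#' Write one exon-skip consequence row as TSV
#'
#' @param x an `exon_skip` object (or list of them).
#' @param path output path.
#' @return The tibble written, invisibly.
#' @export
write_consequence <- function(x, path) {
  if (inherits(x, "exon_skip")) x <- list(x)
  tab <- dplyr::bind_rows(lapply(x, tidy.exon_skip))
  readr::write_tsv(tab, path, na = "NA")
  invisible(tab)
}
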