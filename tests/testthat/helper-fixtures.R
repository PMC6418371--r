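# shared fixture cache: built once per test run, reused across files
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small planted universe used by several files
small_universe <- function() {
  cached_fixture("small_universe", function() {
    g0 <- generate_genome(101, 20000)
    gm <- generate_gene_models(g0, 8, 102)
    planted <- plant_variants(gm$genome, gm$models, n_creations = 15, n_nulls = 15,
                              seed = 103, n_recessive = 4, n_dominant = 2,
                              n_common_creations = 3)
    list(genome = gm$genome, models = gm$models, planted = planted)
  })
}

comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

# reverse-complement + coordinate-mirror of a whole fixture universe
mirror_universe <- function(genome, models, variants = NULL) {
  lens <- seq_lengths(genome)
  genome2 <- genome_seq(lapply(names(genome), function(ch) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome[[ch]])))
  }) |> stats::setNames(names(genome)))
  models2 <- models
  for (i in seq_len(nrow(models))) {
    L <- lens[[models$chrom[i]]]
    ex <- models$exons[[i]]
    ex2 <- tibble::tibble(start = L - ex$end + 1L, end = L - ex$start + 1L)
    models2$exons[[i]] <- dplyr::arrange(ex2, start)
    models2$strand[i] <- if (models$strand[i] == "+") "-" else "+"
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    models2$cds_start[i] <- if (is.na(ce)) NA_integer_ else L - ce + 1L
    models2$cds_end[i] <- if (is.na(cs)) NA_integer_ else L - cs + 1L
  }
  variants2 <- NULL
  if (!is.null(variants)) {
    variants2 <- variants
    L <- lens[variants$chrom]
    variants2$pos <- as.integer(L - variants$pos + 1L)
    variants2$ref <- comp_chr(variants$ref)
    variants2$alt <- comp_chr(variants$alt)
  }
  list(genome = genome2, models = models2, variants = variants2,
       mirror_span = function(chrom, s, e) {
         L <- lens[[chrom]]
         c(L - e + 1L, L - s + 1L)
       })
}

# independent exon-skip oracle: per-base coordinate bookkeeping plus
# Biostrings translation; shares no splicing or translation code with the
# package implementation
oracle_exon_skip <- function(genome, model, exon_index) {
  ex <- model$exons[[1]]
  n_ex <- nrow(ex)
  gpos <- unlist(Map(seq.int, ex$start, ex$end))
  bases <- strsplit(genome[[model$chrom]], "", fixed = TRUE)[[1]][gpos]
  exid <- rep(seq_len(n_ex), ex$end - ex$start + 1L)
  if (model$strand == "-") {
    ord <- rev(seq_along(gpos))
    gpos <- gpos[ord]
    bases <- comp_chr(bases[ord])
    exid <- (n_ex + 1L) - exid[ord]
  }
  cds5 <- if (model$strand == "+") model$cds_start else model$cds_end
  cds3 <- if (model$strand == "+") model$cds_end else model$cds_start
  translate_bs <- function(b) {
    s <- paste(b, collapse = "")
    s <- substr(s, 1, 3L * (nchar(s) %/% 3L))
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    stop_at <- regexpr("*", p, fixed = TRUE)
    if (stop_at > 0) {
      list(protein = substr(p, 1, stop_at - 1), stop_reached = TRUE)
    } else {
      list(protein = p, stop_reached = FALSE)
    }
  }
  i1 <- which(gpos == cds5); i2 <- which(gpos == cds3)
  ref <- translate_bs(bases[i1:i2])
  keep <- exid != exon_index
  basesA <- bases[keep]; gposA <- gpos[keep]
  i1A <- which(gposA == cds5)
  alt <- translate_bs(basesA[i1A:length(basesA)])
  coding_len <- sum(gpos[exid == exon_index] >= model$cds_start &
                      gpos[exid == exon_index] <= model$cds_end)
  pv <- strsplit(ref$protein, "", fixed = TRUE)[[1]]
  qv <- strsplit(alt$protein, "", fixed = TRUE)[[1]]
  nmin <- min(length(pv), length(qv))
  d <- which(pv[seq_len(nmin)] != qv[seq_len(nmin)])
  first_diff <- if (length(d)) d[1] else nmin + 1L
  list(
    coding_len = coding_len,
    frame_preserving = coding_len %% 3L == 0L,
    protein_ref = ref$protein,
    protein_alt = alt$protein,
    alt_stop_reached = alt$stop_reached,
    first_diff = first_diff,
    # fsTer numbering: first altered residue = 1, stop occupies the offset
    stop_offset = if (alt$stop_reached) length(qv) + 2L - first_diff else NA_integer_
  )
}

make_variant_tbl <- function(chrom, pos, ref, alt, maf = NA_real_,
                             genotypes = NULL, info = NULL) {
  n <- length(pos)
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    genotypes = if (is.null(genotypes)) rep(list(character(0)), n) else genotypes,
    info = if (is.null(info)) rep(list(character(0)), n) else info,
    maf = rep_len(maf, n)
  )
}
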