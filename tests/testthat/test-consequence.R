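# toy 3-exon plus-strand model and its minus-strand mirror twin; the CDS is
# ATG GCA GCA CTG GTG CAG CAT AGC TAA cut across the three exons
toy_pair <- function() {
  exon1 <- "TTTTATGGCAGC"   # 4 bp UTR + ATG GCA GC
  exon2 <- "ACTGGTGCAGCA"   # fully coding, 12 bp (in-frame to skip)
  exon3 <- "TAGCTAACCCCC"   # ...TAA stop at coding 25-27, then 3' UTR
  chrom <- paste0(
    strrep("A", 9), exon1, strrep("C", 18), exon2, strrep("C", 18), exon3,
    strrep("A", 9)
  )
  g <- genome_seq(c(chr1 = chrom))
  m <- tibble::tibble(
    gene_id = "g1", transcript_id = "t_plus", chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = c(10L, 40L, 70L), end = c(21L, 51L, 81L))),
    cds_start = 14L, cds_end = 76L
  )
  L <- nchar(chrom)
  g2 <- genome_seq(c(chr1 = revcomp(chrom)))
  ex <- m$exons[[1]]
  m2 <- tibble::tibble(
    gene_id = "g1", transcript_id = "t_minus", chrom = "chr1", strand = "-",
    exons = list(tibble::tibble(start = rev(L - ex$end + 1L), end = rev(L - ex$start + 1L))),
    cds_start = L - 76L + 1L, cds_end = L - 14L + 1L
  )
  list(genome = g, model = m, genome_m = g2, model_m = m2)
}

test_that("splice_transcript concatenates exons in transcription order", {
  tp <- toy_pair()
  full <- splice_transcript(tp$genome, tp$model[1, ])
  expect_equal(full$mrna, paste0("TTTTATGGCAGC", "ACTGGTGCAGCA",
                                 "TAGCTAACCCCC"))
  expect_equal(full$cds_tx_start, 5L)
  expect_equal(full$cds, "ATGGCAGCACTGGTGCAGCATAGCTAA")
  expect_equal(nchar(full$cds) %% 3, 0)

  skipped <- splice_transcript(tp$genome, tp$model[1, ], skip_exon = 2)
  expect_equal(skipped$mrna, paste0("TTTTATGGCAGC", "TAGCTAACCCCC"))

  # the minus-strand mirror model yields the identical mRNA
  mirrored <- splice_transcript(tp$genome_m, tp$model_m[1, ])
  expect_equal(mirrored$mrna, full$mrna)
  expect_equal(splice_transcript(tp$genome_m, tp$model_m[1, ], skip_exon = 2)$mrna,
               skipped$mrna)

  expect_error(splice_transcript(tp$genome, tp$model[1, ], skip_exon = 1),
               "start codon")
  expect_error(splice_transcript(tp$genome, tp$model[1, ], skip_exon = 9),
               "out of range")
})

test_that("translation follows the standard code and flags odd endings", {
  expect_equal(translate_cds("ATGGAATAA"),
               list(protein = "ME", stop_reached = TRUE, partial_codon = FALSE))
  expect_equal(translate_cds("ATGAAA"),
               list(protein = "MK", stop_reached = FALSE, partial_codon = FALSE))
  expect_true(translate_cds("ATGAAAA")$partial_codon)
  expect_error(translate_cds("AT"), "shorter")
  expect_error(translate_cds("ATGNAA"), "non-ACGT")

  # random 300-mers against the independent Biostrings codon table
  set.seed(33)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    ours <- translate_cds(s)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    stop_at <- regexpr("*", bs, fixed = TRUE)
    bs_protein <- if (stop_at > 0) substr(bs, 1, stop_at - 1) else bs
    expect_equal(ours$protein, bs_protein)
    expect_equal(ours$stop_reached, stop_at > 0)
  }
})

test_that("skipping a frameshifting exon gives fsTer notation and an NMD call", {
  we <- synthetic_worked_example()
  cons <- predict_exon_skip(we$genome, we$models[1, ], 11)
  expect_equal(cons$exon_length, 103L)
  expect_false(cons$frame_preserving)
  expect_equal(cons$first_altered_residue, 396L)
  expect_equal(cons$ref_residue, "L")
  expect_equal(cons$novel_residue, "P")
  expect_equal(cons$stop_offset, 23L)
  expect_equal(cons$hgvs_p, "p.(Leu396ProfsTer23)")
  expect_true(cons$nmd_flag)

  # the same variant is synonymous without the skip: codon 429 Glu stays Glu
  g2 <- we$genome
  s <- g2[["chrS"]]
  substr(s, we$variant$pos, we$variant$pos) <- "A"
  g2 <- genome_seq(stats::setNames(list(s), "chrS"))
  ref_protein <- translate_cds(splice_transcript(we$genome, we$models[1, ])$cds)
  alt_protein <- translate_cds(splice_transcript(g2, we$models[1, ])$cds)
  expect_equal(ref_protein$protein, alt_protein$protein)
  expect_equal(substr(ref_protein$protein, 429, 429), "E")
})

test_that("a 102 bp exon (103 minus one) skips in frame with del notation", {
  # plus-strand model whose exon 2 is 102 bp and fully coding
  set.seed(44)
  filler <- function(n) paste(rep("GCA", n), collapse = "")  # Ala runs
  exon1 <- paste0("TTTT", "ATG", filler(4))                  # UTR + M + 4 Ala
  exon2 <- paste0("CAT", filler(33))                         # His + 33 Ala = 102 bp
  exon3 <- paste0(filler(4), "TAA", "CCCC")
  chrom <- paste0(strrep("A", 10), exon1, strrep("T", 20), exon2,
                  strrep("T", 20), exon3, strrep("A", 10))
  s1 <- 11L; e1 <- s1 + nchar(exon1) - 1L
  s2 <- e1 + 21L; e2 <- s2 + nchar(exon2) - 1L
  s3 <- e2 + 21L; e3 <- s3 + nchar(exon3) - 1L
  g <- genome_seq(c(chr1 = chrom))
  m <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = c(s1, s2, s3), end = c(e1, e2, e3))),
    cds_start = s1 + 4L, cds_end = s3 + nchar(filler(4)) + 2L
  )
  cons <- predict_exon_skip(g, m[1, ], 2)
  expect_true(cons$frame_preserving)
  expect_equal(cons$coding_length, 102L)
  # His6..Ala39 excised: 34 residues = 102 bp
  expect_equal(cons$hgvs_p, "p.(His6_Ala39del)")
  expect_false(cons$nmd_flag)
})

test_that("skipping a wholly non-coding exon is no protein change", {
  # exon 1 is pure 5' UTR; start codon in exon 2
  exon1 <- "TTTTTTTT"
  exon2 <- paste0("ATG", "GCAGCA")
  exon3 <- paste0("GCAGCA", "TAA", "CC")
  chrom <- paste0("AAAA", exon1, strrep("C", 15), exon2, strrep("C", 15),
                  exon3, "AAAA")
  s1 <- 5L; e1 <- s1 + nchar(exon1) - 1L
  s2 <- e1 + 16L; e2 <- s2 + nchar(exon2) - 1L
  s3 <- e2 + 16L; e3 <- s3 + nchar(exon3) - 1L
  g <- genome_seq(c(chr1 = chrom))
  m <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = c(s1, s2, s3), end = c(e1, e2, e3))),
    cds_start = s2, cds_end = s3 + 8L
  )
  cons <- predict_exon_skip(g, m[1, ], 1)
  expect_equal(cons$hgvs_p, "p.(=)")
  expect_equal(cons$coding_length, 0L)
  expect_true(cons$frame_preserving)
})

test_that("exon-skip predictions agree with the translate-and-diff oracle", {
  u <- small_universe()
  set.seed(55)
  n_checked <- 0
  for (rep in 1:40) {
    mi <- sample(nrow(u$models), 1)
    m <- u$models[mi, ]
    n_ex <- nrow(m$exons[[1]])
    ei <- sample(seq_len(n_ex), 1)
    ok <- tryCatch({
      cons <- predict_exon_skip(u$genome, m, ei)
      TRUE
    }, error = function(e) FALSE)   # start-codon exon skips are rejected
    if (!ok) next
    o <- oracle_exon_skip(u$genome, m, ei)
    expect_equal(cons$coding_length, o$coding_len)
    expect_equal(cons$frame_preserving, o$frame_preserving)
    if (cons$coding_length == 0) next
    expect_equal(cons$protein_ref, o$protein_ref)
    expect_equal(cons$protein_alt, o$protein_alt)
    if (!cons$frame_preserving && o$alt_stop_reached &&
        o$first_diff <= nchar(o$protein_alt)) {
      expect_equal(cons$first_altered_residue, o$first_diff)
      expect_equal(cons$stop_offset, o$stop_offset)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("frame preservation is exactly coding length mod 3 over the fixture set", {
  u <- small_universe()
  for (i in seq_len(nrow(u$models))) {
    m <- u$models[i, ]
    for (ei in seq_len(nrow(m$exons[[1]]))) {
      cons <- tryCatch(predict_exon_skip(u$genome, m, ei),
                       error = function(e) NULL)
      if (is.null(cons)) next
      expect_identical(cons$frame_preserving, cons$coding_length %% 3L == 0L)
    }
  }
})

test_that("HGVS p. strings round-trip through the parser", {
  we <- synthetic_worked_example()
  cons <- predict_exon_skip(we$genome, we$models[1, ], 11)
  p <- parse_hgvs_p(cons$hgvs_p)
  expect_equal(p$kind, "fs")
  expect_equal(p$ref_residue, cons$ref_residue)
  expect_equal(p$position, cons$first_altered_residue)
  expect_equal(p$novel_residue, cons$novel_residue)
  expect_equal(p$stop_offset, cons$stop_offset)
  expect_equal(parse_hgvs_p("p.(Gln12Ter)"),
               list(kind = "ter", ref_residue = "Q", position = 12L,
                    novel_residue = "*", stop_offset = 1L))
  expect_equal(parse_hgvs_p("p.(=)")$kind, "silent")
  expect_equal(parse_hgvs_p("p.(His6_Ala39del)")$kind, "del")
  expect_error(parse_hgvs_p("gibberish"), "unrecognised")
})

test_that("consequence rows serialise with the report columns", {
  we <- synthetic_worked_example()
  cons <- predict_exon_skip(we$genome, we$models[1, ], 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_consequence(cons, path)
  expect_true(all(c("transcript_id", "exon", "exon_len", "frame_preserving",
                    "hgvs_p", "nmd_flag") %in% names(tab)))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$hgvs_p, "p.(Leu396ProfsTer23)")
  expect_true(back$nmd_flag)
})
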