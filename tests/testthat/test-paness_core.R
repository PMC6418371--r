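test_that("transcribed-strand windows substitute the alt and respect strand", {
  g <- genome_seq(c(chr1 = "CAGGT"))
  expect_equal(transcribed_strand_window(g, "chr1", 3, 2, "+", alt = "A"), "CAAGT")
  # minus strand: reverse complement of the substituted window
  expect_equal(transcribed_strand_window(g, "chr1", 3, 2, "-", alt = "A"),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString("CAAGT"))))
  expect_error(transcribed_strand_window(g, "chr1", 5, 2, "+"), "bounds")
  expect_error(transcribed_strand_window(g, "chr1", 1, 2, "+"), "bounds")
})

test_that("revcomp agrees with the Biostrings oracle on random sequences", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:60, 1), TRUE), collapse = "")
    expect_equal(revcomp(s),
                 as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("creation scanning finds the junction acceptor of the worked example shape", {
  # exon ends ...GAG | GTAAGA... : G>A at the exon-final base turns the
  # (exon-final, intron-first) pair GG into AG - an acceptor, variant first
  g_seq <- "CCGAGGTAAGACC"
  hits <- scan_creations(g_seq, 5L, "A", "+")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_type, "acceptor")
  expect_equal(hits$register, "variant_is_first_base")
  expect_equal(c(hits$span_start, hits$span_end), c(5L, 6L))
  expect_equal(hits$ref_dinuc, "GG")

  # T>C with neighbours A_G creates neither GT nor AG
  expect_equal(nrow(scan_creations("AAATGAA", 4L, "C", "+")), 0L)

  # ref pair GA, A>T gives GT: emitted; but if the ref pair is already GT
  # the same placement is suppressed (novelty is absolute)
  expect_equal(scan_creations("GGAC", 3L, "T", "+")$site_type, "donor")
  expect_equal(nrow(scan_creations("GGTC", 3L, "T", "+")), 0L)  # ref==alt impossible, use alt at other base
  expect_equal(nrow(scan_creations("AGTC", 1L, "G", "+")[
    scan_creations("AGTC", 1L, "G", "+")$span_start == 1, ]), 0L)
})

test_that("all donor-creating SNVs of a hand-worked 20-mer are found", {
  s <- "GATTACAGATTACAGGTCCA"
  # hand enumeration (1-based; register = which base of the new GT is the
  # variant): pos 2 A>G before T(3); pos 2 A>T after G(1); pos 3 T>G before
  # T(4); pos 9 A>G before T(10); pos 9 A>T after G(8); pos 10 T>G before
  # T(11); pos 16 G>T after G(15). pos 17 never qualifies: the ref pair at
  # (16,17) is already GT.
  expected <- tibble::tribble(
    ~pos, ~alt, ~register,                ~span_start,
    2L,  "G",  "variant_is_first_base",  2L,
    2L,  "T",  "variant_is_second_base", 1L,
    3L,  "G",  "variant_is_first_base",  3L,
    9L,  "G",  "variant_is_first_base",  9L,
    9L,  "T",  "variant_is_second_base", 8L,
    10L, "G",  "variant_is_first_base",  10L,
    16L, "T",  "variant_is_second_base", 15L
  )
  ref <- strsplit(s, "")[[1]]
  pos <- integer(0); alt <- character(0)
  for (b in c("A", "C", "G", "T")) {
    sel <- which(ref != b)
    pos <- c(pos, sel); alt <- c(alt, rep(b, length(sel)))
  }
  hits <- scan_creations(s, pos, alt, "+")
  donors <- dplyr::arrange(hits[hits$site_type == "donor",
                                c("pos", "alt", "register", "span_start")],
                           pos, alt)
  expect_equal(donors, dplyr::arrange(expected, pos, alt))

  # and the naive oracle agrees placement by placement
  g <- genome_seq(c(chr1 = s))
  for (i in seq_along(pos)) {
    o <- brute_force_oracle(g, "chr1", pos[i], ref[pos[i]], alt[i], "+")
    h <- hits[hits$pos == pos[i] & hits$alt == alt[i], ]
    expect_equal(nrow(o), nrow(h))
  }
})

test_that("scanner and brute-force oracle agree on every SNV of a 2 kb genome", {
  g <- generate_genome(202, 2000)
  chrom <- g[["chr1"]]
  ref <- strsplit(chrom, "")[[1]]
  pos <- integer(0); alt <- character(0)
  for (b in c("A", "C", "G", "T")) {
    sel <- which(ref != b)
    pos <- c(pos, sel); alt <- c(alt, rep(b, length(sel)))
  }
  for (st in c("+", "-")) {
    hits <- scan_creations(chrom, pos, alt, st)
    scan_keys <- sort(paste(hits$pos, hits$alt, hits$site_type, hits$register,
                            hits$span_start, hits$span_end))
    okeys <- vector("list", length(pos))
    for (i in seq_along(pos)) {
      o <- brute_force_oracle(g, "chr1", pos[i], ref[pos[i]], alt[i], st)
      if (nrow(o)) {
        okeys[[i]] <- paste(pos[i], alt[i], o$site_type, o$register,
                            o$span_start, o$span_end)
      }
    }
    expect_identical(scan_keys, sort(unlist(okeys)), label = paste("strand", st))
  }
})

test_that("placements touching N yield no candidate", {
  expect_equal(nrow(scan_creations("ANAC", 3L, "G", "+")), 0L)
  g <- genome_seq(c(chr1 = "ANAC"))
  expect_equal(nrow(brute_force_oracle(g, "chr1", 3, "A", "G", "+")), 0L)
})

test_that("canonical sites and signed distances are strand-aware", {
  # plus strand, 3 exons: donors after exons 1,2; acceptors before exons 2,3
  m <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = c(11L, 61L, 111L), end = c(30L, 80L, 130L))),
    cds_start = 11L, cds_end = 130L
  )
  cs <- canonical_sites(m[1, ])
  expect_equal(cs$span_start[cs$site_type == "donor"], c(31L, 81L))
  expect_equal(cs$span_start[cs$site_type == "acceptor"], c(59L, 109L))

  # mirrored minus-strand model: same junction structure read the other way
  m2 <- m
  m2$strand <- "-"
  cs2 <- canonical_sites(m2[1, ])
  expect_equal(cs2$span_start[cs2$site_type == "donor"], c(59L, 109L))
  expect_equal(cs2$span_start[cs2$site_type == "acceptor"], c(31L, 81L))

  # candidate at the first donor junction itself: distance 0
  cand <- tibble::tibble(site_type = "donor", span_start = 31L, span_end = 32L)
  near <- nearest_canonical_site(cand, m[1, ])
  expect_equal(near$distance, 0L)

  # single-exon model: no canonical sites, NA triple
  m1 <- m
  m1$exons <- list(tibble::tibble(start = 11L, end = 130L))
  expect_true(is.na(nearest_canonical_site(cand, m1[1, ])$distance))

  # equidistant candidate: tie broken towards the upstream (5') site,
  # giving a positive signed distance
  mid <- tibble::tibble(site_type = "donor", span_start = 56L, span_end = 57L)
  d1 <- 56L - 31L; d2 <- 56L - 81L
  stopifnot(abs(d1) == abs(d2))
  tie <- nearest_canonical_site(mid, m[1, ])
  expect_equal(tie$span_start, 31L)
  expect_equal(tie$distance, 25L)

  # downstream candidates get negative distances on the minus strand too
  cand_m <- tibble::tibble(site_type = "donor", span_start = 50L, span_end = 51L)
  near_m <- nearest_canonical_site(cand_m, m2[1, ])
  expect_equal(near_m$span_start, 59L)
  expect_equal(near_m$distance, 59L + 1L - (50L + 1L))  # tpos = -span_end
})

test_that("consensus similarity is a weighted IUPAC match with unit maximum", {
  cm <- consensus_model()
  expect_equal(consensus_similarity("CAGGTAAGT", "donor", cm), 1.0)
  expect_equal(consensus_similarity("AAGGTGAGT", "donor", cm), 1.0)  # M,R degenerate
  # all-T context: only the essential T (0.25) and the extended T (0.5/7),
  # plus no other position admits T
  expect_equal(consensus_similarity(strrep("T", 9), "donor", cm), 0.25 + 0.5 / 7)
  # acceptor: all-C matches the 12 Y, the N and the 14th-position Y (14
  # extended positions) but not A, G or the exonic G
  expect_equal(consensus_similarity(strrep("C", 17), "acceptor", cm), 14 * 0.5 / 15)
  expect_equal(consensus_similarity(paste0(strrep("C", 13), "CAGG"), "acceptor", cm), 1.0)
  expect_error(consensus_similarity("CAGGT", "donor", cm), "length")
  expect_true(is.na(consensus_similarity("CAGGTANGT", "donor", cm)))

  # property: scores always in [0,1]; 1 only on full-consensus contexts
  set.seed(9)
  for (i in 1:200) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    sc <- consensus_similarity(ctx, "donor", cm)
    expect_true(sc >= 0 && sc <= 1)
    if (sc == 1) {
      expect_true(grepl("^[AC]AGGT[AG]AGT$", ctx))
    }
  }
  expect_error(consensus_model(essential_weight = 0.01), "largest")
})

test_that("the scan composes: worked-example fixture yields one acceptor row", {
  we <- synthetic_worked_example()
  scan <- run_paness(dplyr::mutate(we$variant, maf = af), we$genome, we$models)
  cand <- tidy(scan)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$site_type, "acceptor")
  expect_equal(cand$register, "variant_is_first_base")
  expect_equal(c(cand$span_start, cand$span_end),
               c(we$expected$span_start, we$expected$span_end))
  expect_equal(cand$maf, 8.1e-06)
  expect_equal(cand$gene_id, "ATP2A1_like")
  # the created AG sits right at the exon 11 donor junction
  expect_equal(cand$span_end, we$expected$donor_junction_span[1])
  expect_true(cand$consensus_score >= 0 && cand$consensus_score <= 1)
})

test_that("an empty variant set gives an empty report and zero counts", {
  we <- synthetic_worked_example()
  empty <- we$variant[0, ]
  scan <- run_paness(dplyr::mutate(empty, maf = double(0)), we$genome, we$models)
  expect_equal(nrow(tidy(scan)), 0L)
  expect_equal(glance(scan)$n_candidates, 0L)
  expect_equal(glance(scan)$n_low_maf, 0L)
})

test_that("genome-wide mode evaluates both strands without transcript context", {
  # enough flanking sequence that the consensus context windows fit
  g <- genome_seq(c(chr1 = paste0(strrep("CA", 15), "CCGAGGTAAGACC", strrep("CA", 15))))
  p <- 30L + 5L
  v <- make_variant_tbl("chr1", p, "G", "A", maf = 1e-4)
  cfg <- paness_config(genome_wide = TRUE, report_flank = 2L)
  scan <- run_paness(v, g, NULL, cfg)
  cand <- tidy(scan)
  oracle_rows <- dplyr::bind_rows(
    dplyr::mutate(brute_force_oracle(g, "chr1", p, "G", "A", "+"), strand = "+"),
    dplyr::mutate(brute_force_oracle(g, "chr1", p, "G", "A", "-"), strand = "-")
  )
  expect_gte(nrow(cand), 1L)
  expect_equal(nrow(cand), nrow(oracle_rows))
  expect_true(all(is.na(cand$gene_id)))
  expect_true(all(is.na(cand$dist_to_canonical)))
})

test_that("no emitted candidate ever recreates its reference dinucleotide", {
  u <- small_universe()
  for (i in seq_len(nrow(u$models))) {
    m <- u$models[i, ]
    cand <- enumerate_creations(u$planted$variants, u$genome, m)
    if (nrow(cand) == 0) next
    expect_true(all(cand$ref_dinuc != cand$alt_dinuc))
    expect_true(all(cand$alt_dinuc %in% c("GT", "AG")))
    expect_true(all(cand$pos >= cand$span_start & cand$pos <= cand$span_end))
  }
})
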