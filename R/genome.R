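#' Genome sequence container
#'
#' A `genome_seq` is a named list of uppercase chromosome strings over the
#' alphabet `A/C/G/T/N`. It is deliberately plain (character vectors, not an
#' external pointer) so that fixture genomes can be built, mutated and
#' compared cheaply in tests; FASTA I/O goes through Biostrings.
#'
#' @param seqs named character vector or list of chromosome sequences.
#' @return An object of class `genome_seq`.
#' @examples
#' g <- genome_seq(c(chr1 = "ACGTACGT"))
#' get_seq(g, "chr1", 2, 5)
#' @export
genome_seq <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    rlang::abort("all chromosomes must be named")
  }
  seqs <- lapply(seqs, function(s) toupper(as.character(s)))
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    rlang::abort(paste0(
      "chromosome(s) contain characters outside {A,C,G,T,N}: ",
      paste(names(seqs)[bad], collapse = ", ")
    ))
  }
  structure(seqs, class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x), " chromosome(s)\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a [genome_seq()].
#' @return Named integer vector of lengths.
#' @export
seq_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Extract a subsequence, with strict bounds checking
#'
#' Queries outside chromosome bounds are an error, never silently clipped:
#' a splice-context window that falls off the end of a contig must surface
#' at the pipeline level, not return a shortened string.
#'
#' @param genome a [genome_seq()].
#' @param chrom chromosome name.
#' @param start,end 1-based closed genomic coordinates.
#' @return Character scalar, the requested sequence on the plus strand.
#' @export
get_seq <- function(genome, chrom, start, end) {
  s <- genome[[chrom]]
  if (is.null(s)) rlang::abort(paste0("unknown chromosome: ", chrom))
  if (start < 1 || end > nchar(s) || start > end) {
    rlang::abort(sprintf(
      "query %s:%d-%d outside chromosome bounds (1-%d)", chrom, start, end, nchar(s)
    ))
  }
  substr(s, start, end)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over `A/C/G/T/N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Read a reference genome from FASTA
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return A [genome_seq()].
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the identifier
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome_seq(stats::setNames(as.list(as.character(ss)), names(ss)))
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_seq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Sequence window around a position, read on the transcribed strand
#'
#' Returns the `2 * flank + 1` window centred on `pos`. For minus-strand
#' transcripts the window is reverse-complemented so it reads 5'->3' in
#' transcription order. When `alt` is given, the centre base is substituted
#' before any reverse complementing, i.e. `alt` is the plus-strand allele as
#' written in a VCF.
#'
#' @param genome a [genome_seq()].
#' @param chrom chromosome name.
#' @param pos 1-based position of the centre base.
#' @param flank number of bases on each side (>= 1).
#' @param strand `"+"` or `"-"`, the transcribed strand.
#' @param alt optional plus-strand substitute base for the centre position.
#' @return Character scalar of length `2 * flank + 1`.
#' @export
transcribed_strand_window <- function(genome, chrom, pos, flank, strand = "+",
                                      alt = NULL) {
  stopifnot(flank >= 1)
  strand <- match.arg(strand, c("+", "-"))
  s <- get_seq(genome, chrom, pos - flank, pos + flank)
  if (!is.null(alt)) {
    alt <- toupper(alt)
    if (!alt %in% c("A", "C", "G", "T")) rlang::abort("alt must be a single base")
    substr(s, flank + 1L, flank + 1L) <- alt
  }
  if (strand == "-") s <- revcomp(s)
  s
}
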