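# IUPAC nucleotide classes used for consensus matching
iupac_classes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_match <- function(base, code) {
  cls <- iupac_classes[[code]]
  if (is.null(cls)) rlang::abort(paste0("unknown IUPAC code: ", code))
  base %in% cls
}

#' Splice-site consensus model
#'
#' The classical mammalian consensus around the essential dinucleotides:
#' donor `MAG|GTRAGT` (exon positions -3..-1, then intron +1..+6, the `GT`
#' being essential) and acceptor `YYYYYYYYYYYYNYAG|G` (a 12-base
#' polypyrimidine tract, branch-distal `N`, `Y`, the essential `AG`, and the
#' first exonic base). Similarity scoring weights the two essential positions
#' at `essential_weight` each; the remaining weight is spread uniformly over
#' the extended positions, so weights sum to 1 per site type and a
#' full-consensus context scores exactly 1.
#'
#' @param donor IUPAC consensus for donor sites, junction implied; default
#'   `"MAGGTRAGT"` with the essential `GT` at positions 4-5.
#' @param acceptor IUPAC consensus for acceptor sites; default
#'   `"YYYYYYYYYYYYNYAGG"` with the essential `AG` at positions 15-16.
#' @param donor_essential,acceptor_essential integer positions (length 2) of
#'   the essential dinucleotide within each consensus.
#' @param essential_weight weight of each essential position; must exceed the
#'   per-position extended weight.
#' @return A `consensus_model` list with per-position weight vectors.
#' @export
consensus_model <- function(donor = "MAGGTRAGT",
                            acceptor = "YYYYYYYYYYYYNYAGG",
                            donor_essential = c(4L, 5L),
                            acceptor_essential = c(15L, 16L),
                            essential_weight = 0.25) {
  build <- function(consensus, essential, expected_dinuc) {
    L <- nchar(consensus)
    if (any(essential < 1 | essential > L) || length(essential) != 2) {
      rlang::abort("essential positions must be two positions inside the consensus")
    }
    din <- substr(consensus, essential[1], essential[2])
    if (din != expected_dinuc) {
      rlang::abort(paste0("essential positions must read '", expected_dinuc, "', got '", din, "'"))
    }
    w <- rep((1 - 2 * essential_weight) / (L - 2), L)
    w[essential] <- essential_weight
    if (essential_weight <= max(w[-essential])) {
      rlang::abort("essential positions must carry the largest weights")
    }
    list(consensus = consensus, essential = essential, weights = w,
         upstream = essential[1] - 1L, downstream = L - essential[2])
  }
  structure(list(
    donor = build(donor, donor_essential, "GT"),
    acceptor = build(acceptor, acceptor_essential, "AG")
  ), class = "consensus_model")
}

#' Weighted consensus similarity of a splice-site context
#'
#' The weighted fraction of positions whose base belongs to the IUPAC class
#' of the consensus at that position. Returns 1 exactly when every position
#' matches; contributions at zero-weight positions (none by default) are
#' ignored by construction.
#'
#' @param context transcribed-strand sequence, same length as the consensus
#'   for `site_type`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param model a [consensus_model()].
#' @return Numeric scalar in `[0, 1]`; `NA` if the context contains `N` or is
#'   itself `NA`.
#' @export
consensus_similarity <- function(context, site_type = c("donor", "acceptor"),
                                 model = consensus_model()) {
  site_type <- match.arg(site_type)
  m <- model[[site_type]]
  if (is.na(context)) return(NA_real_)
  if (nchar(context) != nchar(m$consensus)) {
    rlang::abort(sprintf(
      "context length %d does not match %s consensus length %d",
      nchar(context), site_type, nchar(m$consensus)
    ))
  }
  bases <- strsplit(context, "", fixed = TRUE)[[1]]
  if (any(bases == "N")) return(NA_real_)
  codes <- strsplit(m$consensus, "", fixed = TRUE)[[1]]
  hits <- mapply(iupac_match, bases, codes)
  sum(m$weights[hits])
}
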