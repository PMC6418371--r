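#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Candidate rows of a scan as a tibble
#'
#' @param x a `paness_scan` object from [run_paness()].
#' @param ... unused.
#' @return The candidate report tibble, one row per
#'   (variant, transcript, placement).
#' @method tidy paness_scan
#' @export
tidy.paness_scan <- function(x, ...) {
  x$candidates
}

#' One-row summary of a scan
#'
#' @param x a `paness_scan` object.
#' @param ... unused.
#' @return A one-row tibble of the stage counts (records read, SNVs kept,
#'   low-MAF kept, candidate rows, candidate-bearing variants, genes).
#' @method glance paness_scan
#' @export
glance.paness_scan <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' @export
print.paness_scan <- function(x, ...) {
  s <- x$summary
  cat("<paness_scan>\n")
  cat("  records: ", s$n_records, " (", s$n_dropped_non_snv, " non-SNV allele(s) dropped)\n", sep = "")
  cat("  SNVs kept: ", s$n_snvs, "; low-MAF: ", s$n_low_maf, "\n", sep = "")
  cat("  candidates: ", s$n_candidates, " row(s) over ",
      s$n_variants_with_candidates, " variant(s), ", s$n_genes, " gene(s)\n", sep = "")
  if (s$n_skipped_context > 0) {
    cat("  skipped (context off chromosome): ", s$n_skipped_context, "\n", sep = "")
  }
  invisible(x)
}

#' Plot consensus-score distributions of scan candidates
#'
#' Histogram of the consensus similarity of candidate sites, split by site
#' type and coloured by the register of the variant base within the new
#' dinucleotide.
#'
#' @param object a `paness_scan` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot paness_scan
#' @export
autoplot.paness_scan <- function(object, ...) {
  d <- object$candidates
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no candidates") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$consensus_score, fill = .data$register)) +
    ggplot2::geom_histogram(bins = 20, position = "stack") +
    ggplot2::facet_wrap(~site_type) +
    ggplot2::labs(x = "consensus similarity", y = "candidates",
                  title = "Novel essential splice-site candidates") +
    ggplot2::theme_minimal()
}

#' Distance of candidates to their nearest canonical site
#'
#' @param scan a `paness_scan` object.
#' @return A ggplot object; candidates without transcript context are
#'   omitted.
#' @export
plot_candidate_distances <- function(scan) {
  d <- dplyr::filter(scan$candidates, !is.na(.data$dist_to_canonical))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dist_to_canonical, y = .data$consensus_score,
                                  colour = .data$site_type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "signed distance to nearest canonical site (bp, transcription order)",
                  y = "consensus similarity") +
    ggplot2::theme_minimal()
}

#' Exon-skip consequence as a one-row tibble
#'
#' @param x an `exon_skip` object from [predict_exon_skip()].
#' @param ... unused.
#' @return A one-row tibble with the report columns (`transcript_id`,
#'   `exon`, `exon_len`, `coding_len`, `frame_preserving`, `hgvs_p`,
#'   `nmd_flag`) plus the altered-residue details.
#' @method tidy exon_skip
#' @export
tidy.exon_skip <- function(x, ...) {
  tibble::tibble(
    transcript_id = x$transcript_id,
    exon = x$exon_index,
    exon_len = x$exon_length,
    coding_len = x$coding_length,
    frame_preserving = x$frame_preserving,
    first_altered_residue = x$first_altered_residue,
    ref_residue = x$ref_residue,
    novel_residue = x$novel_residue,
    stop_offset = x$stop_offset,
    hgvs_p = x$hgvs_p,
    nmd_flag = x$nmd_flag
  )
}

#' @export
print.exon_skip <- function(x, ...) {
  cat("<exon_skip> ", x$transcript_id, " exon ", x$exon_index,
      " (", x$exon_length, " bp, ", x$coding_length, " coding)\n", sep = "")
  cat("  ", if (x$frame_preserving) "in-frame" else "frameshift", ": ", x$hgvs_p, "\n", sep = "")
  cat("  NMD flag: ", x$nmd_flag, "\n", sep = "")
  invisible(x)
}
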