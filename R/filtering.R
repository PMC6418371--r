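#' Describe where allele frequencies come from
#'
#' Frequencies are consumed, never computed: either from a per-alt INFO field
#' of the VCF itself (`info_key`), or from an external frequency table
#' (chrom, pos, ref, alt, af). An allele absent from the source gets `NA`,
#' never 0 — "never observed" is not the same statement as "observed at
#' frequency zero", and the two are treated differently by the MAF gate.
#'
#' @param info_key name of the INFO field carrying the allele frequency
#'   (used when `table` is NULL).
#' @param table optional tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `af` (frequencies in `[0, 1]`).
#' @return A `frequency_source` list.
#' @export
frequency_source <- function(info_key = "AF", table = NULL) {
  if (!is.null(table)) {
    need <- c("chrom", "pos", "ref", "alt", "af")
    if (!all(need %in% names(table))) {
      rlang::abort("frequency table needs columns chrom, pos, ref, alt, af")
    }
    if (any(!is.na(table$af) & (table$af < 0 | table$af > 1))) {
      rlang::abort("allele frequencies must lie in [0, 1]")
    }
    structure(list(mode = "table", table = table), class = "frequency_source")
  } else {
    structure(list(mode = "info_field", info_key = info_key), class = "frequency_source")
  }
}

#' Read an external allele-frequency table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return A [frequency_source()] in table mode.
#' @export
read_freq_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(chrom = "c", pos = "i", ref = "c", alt = "c", af = "d"),
    na = c("NA", "."), comment = "#", progress = FALSE
  )
  frequency_source(table = tab)
}

#' Attach minor allele frequencies to variants
#'
#' @param variants variant tibble from [read_vcf()].
#' @param source a [frequency_source()].
#' @return `variants` with a numeric `maf` column (`NA` when the allele is
#'   absent from the source).
#' @export
annotate_maf <- function(variants, source) {
  stopifnot(inherits(source, "frequency_source"))
  if (nrow(variants) == 0) {
    variants$maf <- double(0)
    return(variants)
  }
  if (source$mode == "table") {
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    tab_key <- paste(source$table$chrom, source$table$pos, source$table$ref, source$table$alt)
    variants$maf <- source$table$af[match(key, tab_key)]
  } else {
    variants$maf <- purrr::map2_dbl(
      variants$info, seq_len(nrow(variants)),
      function(info, i) {
        raw <- if (source$info_key %in% names(info)) info[[source$info_key]] else NA
        if (is.null(raw) || is.na(raw)) return(NA_real_)
        af <- suppressWarnings(as.numeric(raw))
        if (is.na(af)) {
          rlang::abort(sprintf(
            "unparseable frequency '%s' for variant %s:%d %s>%s",
            raw, variants$chrom[i], variants$pos[i], variants$ref[i], variants$alt[i]
          ))
        }
        af
      }
    )
  }
  bad <- !is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1)
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "allele frequency outside [0,1] for variant %s:%d %s>%s",
      variants$chrom[i], variants$pos[i], variants$ref[i], variants$alt[i]
    ))
  }
  variants
}

#' Filtering configuration
#'
#' Defaults encode a deliberately liberal rare-variant screen: MAF at most
#' 0.001 (boundary kept), alleles never seen in the reference database kept,
#' no inheritance model, no effect-class or score filtering.
#'
#' @param maf_threshold keep variants with `maf <= maf_threshold`. Must lie
#'   in (0, 1).
#' @param maf_comparator `"le"` (default) or `"lt"`.
#' @param maf_missing_passes keep variants with `NA` MAF? An allele absent
#'   from a large reference database is rarer than any threshold in use, so
#'   the default is TRUE.
#' @param inheritance_model one of `"none"`, `"autosomal_recessive"`,
#'   `"autosomal_dominant_de_novo"`.
#' @param effect_classes_kept character vector of effect classes considered
#'   potentially pathogenic (e.g. nonsense, frameshift, essential_splice,
#'   missense), or NULL for no effect filter.
#' @param effect_key INFO key holding the effect class annotation.
#' @param score_thresholds named list, one entry per annotation key, each a
#'   `list(cmp = , value = )` with `cmp` in lt/le/gt/ge/eq. A variant lacking
#'   the annotation is never excluded by it (liberal screening).
#' @param strict_missing_genotypes if TRUE a missing genotype fails
#'   inheritance classification; default FALSE treats it as non-matching.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.001,
                          maf_comparator = c("le", "lt"),
                          maf_missing_passes = TRUE,
                          inheritance_model = c("none", "autosomal_recessive",
                                                "autosomal_dominant_de_novo"),
                          effect_classes_kept = NULL,
                          effect_key = "EFFECT",
                          score_thresholds = list(),
                          strict_missing_genotypes = FALSE) {
  maf_comparator <- match.arg(maf_comparator)
  inheritance_model <- match.arg(inheritance_model)
  if (!(maf_threshold > 0 && maf_threshold < 1)) {
    rlang::abort("maf_threshold must lie in (0, 1)")
  }
  for (key in names(score_thresholds)) {
    th <- score_thresholds[[key]]
    if (!is.list(th) || is.null(th$cmp) || is.null(th$value) ||
        !th$cmp %in% c("lt", "le", "gt", "ge", "eq")) {
      rlang::abort(paste0(
        "score_thresholds[['", key, "']] must be list(cmp = one of lt/le/gt/ge/eq, value = )"
      ))
    }
  }
  structure(list(
    maf_threshold = maf_threshold,
    maf_comparator = maf_comparator,
    maf_missing_passes = maf_missing_passes,
    inheritance_model = inheritance_model,
    effect_classes_kept = effect_classes_kept,
    effect_key = effect_key,
    score_thresholds = score_thresholds,
    strict_missing_genotypes = strict_missing_genotypes
  ), class = "filter_config")
}

#' Keep low-frequency variants
#'
#' @param variants variant tibble with a `maf` column (see [annotate_maf()]).
#' @param config a [filter_config()].
#' @return The subset of `variants` passing the MAF gate.
#' @export
filter_by_maf <- function(variants, config = filter_config()) {
  if (!"maf" %in% names(variants)) {
    rlang::abort("variants lack a 'maf' column; run annotate_maf() first")
  }
  cmp <- if (config$maf_comparator == "le") `<=` else `<`
  keep <- ifelse(
    is.na(variants$maf),
    config$maf_missing_passes,
    cmp(variants$maf, config$maf_threshold)
  )
  variants[keep, , drop = FALSE]
}

#' Classify trio genotype patterns
#'
#' Tests each variant's genotypes against a Mendelian model:
#' `autosomal_recessive` is true iff the proband is homozygous alternate and
#' both parents are heterozygous carriers; `autosomal_dominant_de_novo` iff
#' the proband is heterozygous and both parents homozygous reference. With
#' `strict = FALSE` (default) a missing genotype simply fails the pattern;
#' with `strict = TRUE` it raises an error.
#'
#' @param variants variant tibble from [read_vcf()].
#' @param roles named character vector mapping `proband`, `mother`, `father`
#'   to sample IDs in the VCF.
#' @param model `"autosomal_recessive"` or `"autosomal_dominant_de_novo"`.
#' @param strict how to treat missing genotypes (see above).
#' @return Logical vector, one element per variant.
#' @export
classify_inheritance <- function(variants, roles,
                                 model = c("autosomal_recessive",
                                           "autosomal_dominant_de_novo"),
                                 strict = FALSE) {
  model <- match.arg(model)
  need <- c("proband", "mother", "father")
  if (!all(need %in% names(roles))) {
    rlang::abort("roles must name proband, mother and father sample IDs")
  }
  vapply(seq_len(nrow(variants)), function(i) {
    g <- variants$genotypes[[i]]
    gt <- vapply(need, function(role) {
      sid <- roles[[role]]
      if (!sid %in% names(g)) {
        rlang::abort(paste0("sample '", sid, "' (", role, ") has no genotype for variant ",
                            variants$chrom[i], ":", variants$pos[i]))
      }
      g[[sid]]
    }, character(1))
    if (any(gt == "missing")) {
      if (strict) {
        rlang::abort(paste0("missing genotype at ", variants$chrom[i], ":", variants$pos[i]))
      }
      return(FALSE)
    }
    switch(model,
      autosomal_recessive =
        gt[["proband"]] == "hom_alt" && gt[["mother"]] == "het" && gt[["father"]] == "het",
      autosomal_dominant_de_novo =
        gt[["proband"]] == "het" && gt[["mother"]] == "hom_ref" && gt[["father"]] == "hom_ref"
    )
  }, logical(1))
}

cmp_fun <- function(cmp) {
  switch(cmp, lt = `<`, le = `<=`, gt = `>`, ge = `>=`, eq = `==`,
         rlang::abort(paste0("unknown comparator: ", cmp)))
}

#' Apply effect-class and annotation-score screens
#'
#' The conjunction of (a) membership of the variant's annotated effect class
#' in `effect_classes_kept` and (b) every configured score threshold. The
#' screen is deliberately liberal: a variant lacking the effect or score
#' annotation is never excluded by that predicate, and an empty config is the
#' identity.
#'
#' @param variants variant tibble from [read_vcf()].
#' @param config a [filter_config()].
#' @return The subset of `variants` passing all configured screens.
#' @export
apply_standard_filters <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    info <- variants$info[[i]]
    if (!is.null(config$effect_classes_kept)) {
      eff <- if (config$effect_key %in% names(info)) info[[config$effect_key]] else NA
      if (!is.null(eff) && !is.na(eff) && !eff %in% config$effect_classes_kept) {
        keep[i] <- FALSE
        next
      }
    }
    for (key in names(config$score_thresholds)) {
      raw <- if (key %in% names(info)) info[[key]] else NA
      if (is.null(raw) || is.na(raw)) next  # absent annotation never excludes
      val <- suppressWarnings(as.numeric(raw))
      if (is.na(val)) next
      th <- config$score_thresholds[[key]]
      if (!cmp_fun(th$cmp)(val, th$value)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  variants[keep, , drop = FALSE]
}
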