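# Pipeline configuration and the all-in-one runner composing
# quantitation -> DE calling -> profiles/clustering -> enrichment ->
# fermentation stoichiometry.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis.  The defaults are
#' the standard operating point of the method: spectra qualify at
#' log(e) <= -2.0, the intensity filter keeps spectra whose corrected
#' two-channel sum exceeds 20000 (strict), zero-denominator spectra get
#' the sentinel ratio 10, quantitation requires at least 3 contributing
#' spectra at p <= 0.01, fold-change calls use >= 1.2 (up) and <= 0.83
#' (down), pathways are significant at raw p <= 0.05, and profiles are
#' cut into 6 clusters.
#'
#' @param log_e_max Spectrum score threshold (log10 expectation value).
#' @param intensity_sum_min Strict lower bound on the corrected
#'   numerator+denominator intensity of a spectrum used for a protein
#'   median.
#' @param sentinel_ratio Ratio assigned to zero-denominator ("Divide 0")
#'   spectra.
#' @param min_psm Minimum intensity-passing spectra per protein and
#'   comparison.
#' @param p_max Significance level of the quantitation gate.
#' @param up_threshold,down_threshold Fold-change thresholds for DE calls.
#' @param enrich_p Raw significance threshold of pathway enrichment.
#' @param k_clusters Number of profile clusters.
#' @param test Location test for spectrum log-ratios: `"wilcoxon"`
#'   (default) or `"t"`.
#' @param comparisons Character vector of reporter-channel comparisons;
#'   default stress channels against the 114 control.
#' @param channel_conditions Named numeric vector mapping channels to
#'   conditions (mM); first entry is the control.
#' @param normalize Apply summed-intensity normalization (default TRUE).
#' @param seed Integer seed for any stochastic downstream step.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(log_e_max = -2.0,
                            intensity_sum_min = 20000,
                            sentinel_ratio = 10,
                            min_psm = 3L,
                            p_max = 0.01,
                            up_threshold = 1.2,
                            down_threshold = 0.83,
                            enrich_p = 0.05,
                            k_clusters = 6L,
                            test = c("wilcoxon", "t"),
                            comparisons = c("115/114", "116/114", "117/114"),
                            channel_conditions = c("114" = 0, "115" = 50,
                                                   "116" = 100, "117" = 200),
                            normalize = TRUE,
                            seed = 1L) {
  cfg <- list(log_e_max = log_e_max,
              intensity_sum_min = intensity_sum_min,
              sentinel_ratio = sentinel_ratio,
              min_psm = as.integer(min_psm),
              p_max = p_max,
              up_threshold = up_threshold,
              down_threshold = down_threshold,
              enrich_p = enrich_p,
              k_clusters = as.integer(k_clusters),
              test = match.arg(test),
              comparisons = comparisons,
              channel_conditions = channel_conditions,
              normalize = isTRUE(normalize),
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

#' @noRd
validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    if (!is.list(cfg)) stop_config("config must come from pipeline_config()")
  }
  if (!(cfg$down_threshold < 1 && 1 < cfg$up_threshold))
    stop_config("thresholds must satisfy down_threshold < 1 < up_threshold")
  if (cfg$intensity_sum_min < 0) stop_config("intensity_sum_min must be >= 0")
  if (cfg$sentinel_ratio <= 0) stop_config("sentinel_ratio must be > 0")
  if (cfg$min_psm < 1L) stop_config("min_psm must be >= 1")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop_config("p_max must lie in (0, 1]")
  if (cfg$enrich_p <= 0 || cfg$enrich_p > 1) stop_config("enrich_p must lie in (0, 1]")
  if (cfg$k_clusters < 1L) stop_config("k_clusters must be >= 1")
  lapply(cfg$comparisons, comparison_channels)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes quantitation, DE calling, the Venn and COG summaries, profile
#' construction with z-scoring and clustering, per-comparison pathway
#' enrichment, and (when yields are supplied) fermentation stoichiometry.
#' The run report records record counts at every filter stage, mirroring
#' the way such experiments are reported (spectra in, qualifying,
#' intensity-passing, proteins quantified, DE per condition).
#'
#' @param psm A PSM `data.frame`.
#' @param annotation Optional [annotation_map()] for COG tallies and
#'   enrichment.
#' @param fermentation Optional fermentation yield `data.frame`.
#' @param purity A 4x4 purity matrix.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written there as TSV.
#' @return A list with `quants`, `de`, `venn`, `cog_tally`, `profile`,
#'   `zmatrix`, `clusters`, `enrichment` (per comparison), `stoichiometry`
#'   and `report`.
#' @export
run_pipeline <- function(psm, annotation = NULL, fermentation = NULL,
                         purity = default_purity_matrix(),
                         config = pipeline_config(), out_dir = NULL) {
  config <- validate_pipeline_config(config)
  quants <- quantify_proteins(psm, purity = purity, config = config)
  de <- call_de(quants, up_threshold = config$up_threshold,
                down_threshold = config$down_threshold)

  sets <- lapply(config$comparisons, function(cmp) de_accessions(de, cmp))
  cond <- config$channel_conditions
  names(sets) <- vapply(config$comparisons, function(cmp) {
    num <- comparison_channels(cmp)[["num"]]
    if (num %in% names(cond)) paste0(cond[[num]], "mM") else cmp
  }, "")
  venn <- if (length(sets) == 3L) venn_counts(sets) else NULL

  tally <- if (!is.null(annotation)) cog_tally(de, annotation) else NULL

  de_union <- de_accessions(de)
  profile <- zmat <- clusters <- NULL
  if (length(de_union) >= 2L) {
    profile <- build_profile(quants, de_union,
                             channel_conditions = config$channel_conditions)
    zmat <- zscore_rows(profile)
    k <- min(config$k_clusters, nrow(zmat))
    clusters <- cluster_rows(zmat, k = k)
  }

  enrichment <- NULL
  if (!is.null(annotation) && length(annotation$pathways)) {
    background <- unique(quants$protein_acc[quants$status == "quantified"])
    enrichment <- lapply(config$comparisons, function(cmp) {
      q <- intersect(de_accessions(de, cmp), background)
      enrich(q, background, annotation, p_max = config$enrich_p)
    })
    names(enrichment) <- config$comparisons
  }

  stoich <- if (!is.null(fermentation))
    summarize_stoichiometry(fermentation) else NULL

  counts <- attr(quants, "counts")
  report <- list(
    n_spectra = counts$n_spectra,
    n_qualifying = counts$n_qualifying,
    n_intensity_pass = counts$n_intensity_pass,
    n_proteins = length(unique(quants$protein_acc)),
    n_quantified = counts$n_quantified,
    n_de = vapply(config$comparisons, function(cmp)
      length(de_accessions(de, cmp)), 0L),
    n_de_union = length(de_union),
    config = config
  )

  result <- list(quants = quants, de = de, venn = venn, cog_tally = tally,
                 profile = profile, zmatrix = zmat, clusters = clusters,
                 enrichment = enrichment, stoichiometry = stoich,
                 report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_table(quants, file.path(out_dir, "proteins.tsv"))
    write_tsv(de, file.path(out_dir, "de.tsv"))
    if (!is.null(venn))
      write_tsv(data.frame(region = names(venn$regions),
                           count = as.integer(venn$regions),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "venn.tsv"))
    if (!is.null(tally))
      write_tsv(data.frame(cog = names(tally), count = as.integer(tally),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "cog_tally.tsv"))
    if (!is.null(clusters))
      write_tsv(data.frame(protein_acc = names(clusters$cluster),
                           cluster = as.integer(clusters$cluster),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "clusters.tsv"))
    if (!is.null(enrichment))
      for (cmp in names(enrichment))
        write_tsv(enrichment[[cmp]],
                  file.path(out_dir, paste0("enrichment_",
                                            gsub("/", "_vs_", cmp), ".tsv")))
    if (!is.null(stoich))
      write_tsv(stoich, file.path(out_dir, "stoichiometry.tsv"))
  }
  result
}
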