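# Synthetic 4-plex PSM generator with planted ground truth.  Emulates the
# data structure of a two-channel-pair ethanol-stress design: channel 114
# carries the 0 mM control and 115/116/117 the 50/100/200 mM conditions.

#' Configuration of the synthetic 4-plex generator
#'
#' Defines every condition of a simulated experiment: the number of
#' proteins, spectra per protein, planted log2 fold changes for the three
#' stress-vs-control comparisons, per-spectrum multiplicative noise,
#' reporter base-intensity distribution, the reagent purity matrix, and
#' the rates of the defects real tables contain (spectra with a zero
#' channel, low-quality scores, missing labels, off-database peptides,
#' sub-threshold intensities).
#'
#' @param n_proteins Number of simulated proteins.
#' @param psm_per_protein Integer vector `c(min, max)` of the uniform
#'   spectra-per-protein distribution (a single value fixes the count).
#' @param true_log2_fc Either `NULL` (plant fold changes with
#'   `de_fraction` and `de_log2fc`, half up / half down) or an
#'   `n_proteins` x 3 matrix of per-protein log2 fold changes for
#'   comparisons 115/114, 116/114, 117/114.
#' @param de_fraction Fraction of proteins planted as differentially
#'   expressed when `true_log2_fc` is `NULL`.
#' @param de_log2fc Magnitude of the planted |log2 fold change|.
#' @param noise_sd_log2 SD of the per-spectrum Gaussian noise on the log2
#'   ratio of each stress channel (0 = noise-free).
#' @param base_meanlog,base_sdlog Parameters of the log-normal channel-114
#'   base intensity.
#' @param purity 4x4 purity matrix mixed into the spectra (identity =
#'   no cross-over).
#' @param frac_zero_channel Probability a spectrum has one randomly chosen
#'   channel zeroed (detector dropout).
#' @param frac_low_quality Probability a spectrum's log(e) exceeds -2.0.
#' @param frac_unlabeled Probability a spectrum is unlabeled.
#' @param frac_offdb Probability a spectrum's peptide falls outside the
#'   target database.
#' @param frac_low_intensity Probability a spectrum is rescaled so every
#'   pairwise channel sum falls below `intensity_sum_min`.
#' @param intensity_sum_min Intensity-filter threshold the low-intensity
#'   defect is defined against.
#' @param balance_loading If `TRUE` (default), rescale protein spectra so
#'   that the summed qualifying intensity is identical across channels,
#'   emulating equal protein loading per channel — the condition under
#'   which summed-intensity normalization returns planted ratios exactly.
#'   Requires planted effects in both directions (or none); if infeasible
#'   the step is skipped with a warning.
#' @param up_threshold,down_threshold Fold-change thresholds used to
#'   derive the ground-truth DE labels.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_proteins = 500,
                             psm_per_protein = c(8, 32),
                             true_log2_fc = NULL,
                             de_fraction = 0.2,
                             de_log2fc = log2(1.6),
                             noise_sd_log2 = 0.25,
                             base_meanlog = log(6e4),
                             base_sdlog = 0.8,
                             purity = default_purity_matrix(),
                             frac_zero_channel = 0.02,
                             frac_low_quality = 0.05,
                             frac_unlabeled = 0.03,
                             frac_offdb = 0.03,
                             frac_low_intensity = 0.05,
                             intensity_sum_min = 20000,
                             balance_loading = TRUE,
                             up_threshold = 1.2,
                             down_threshold = 0.83,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              psm_per_protein = as.integer(rep(psm_per_protein, length.out = 2L)),
              true_log2_fc = true_log2_fc, de_fraction = de_fraction,
              de_log2fc = de_log2fc, noise_sd_log2 = noise_sd_log2,
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              purity = purity,
              frac_zero_channel = frac_zero_channel,
              frac_low_quality = frac_low_quality,
              frac_unlabeled = frac_unlabeled,
              frac_offdb = frac_offdb,
              frac_low_intensity = frac_low_intensity,
              intensity_sum_min = intensity_sum_min,
              balance_loading = isTRUE(balance_loading),
              up_threshold = up_threshold, down_threshold = down_threshold,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  if (cfg$n_proteins < 1L) stop_validation("n_proteins must be >= 1")
  if (any(cfg$psm_per_protein < 1L) ||
      cfg$psm_per_protein[1L] > cfg$psm_per_protein[2L])
    stop_validation("psm_per_protein must be c(min, max) with 1 <= min <= max")
  if (cfg$noise_sd_log2 < 0) stop_validation("noise_sd_log2 must be >= 0")
  probs <- c(cfg$frac_zero_channel, cfg$frac_low_quality, cfg$frac_unlabeled,
             cfg$frac_offdb, cfg$frac_low_intensity, cfg$de_fraction)
  if (any(probs < 0 | probs > 1))
    stop_validation("defect fractions and de_fraction must lie in [0, 1]")
  if (!is.null(cfg$true_log2_fc)) {
    fc <- as.matrix(cfg$true_log2_fc)
    if (nrow(fc) != cfg$n_proteins || ncol(fc) != 3L)
      stop_validation("true_log2_fc must be an n_proteins x 3 matrix")
    if (any(!is.finite(fc))) stop_validation("true_log2_fc must be finite")
    cfg$true_log2_fc <- fc
  }
  validate_purity_matrix(cfg$purity)
  if (!(cfg$down_threshold < 1 && 1 < cfg$up_threshold))
    stop_config("thresholds must satisfy down < 1 < up")
  structure(cfg, class = "synthetic_config")
}

#' @noRd
plant_fold_changes <- function(n, de_fraction, de_log2fc) {
  fc <- matrix(0, n, 3L)
  n_de <- round(n * de_fraction)
  if (n_de > 0L) {
    de_idx <- seq_len(n_de)  # which proteins are DE is not informative
    sign <- rep(c(1, -1), length.out = n_de)
    fc[de_idx, ] <- sign * de_log2fc
  }
  fc
}

# Per-protein rescaling t (t > 0, close to 1) such that the summed
# qualifying intensity becomes equal across channels:
# sum_p t_p * d_pc = 0 for every stress channel c, where d_pc is protein
# p's summed (channel c - channel 114) qualifying intensity.  The
# correction minimises sum_p w_p (t_p - 1)^2 with w_p the protein's total
# intensity, so the relative adjustment of a protein is proportional to
# its own channel imbalance (roughly ratio - 1), never to its abundance.
#' @noRd
loading_balance_factors <- function(D, w) {
  if (all(abs(D) < 1e-12)) return(rep(1, nrow(D)))
  qrD <- qr(D)
  Dr <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
  Wi <- Dr / w
  t <- drop(1 - Wi %*% solve(crossprod(Dr, Wi), colSums(Dr)))
  if (any(t <= 0)) return(NULL)
  t
}

#' Generate a synthetic 4-plex PSM table with ground truth
#'
#' Intensities are produced by (1) drawing a log-normal channel-114 base
#' intensity per spectrum, (2) multiplying by the protein's true ratio
#' times `2^N(0, noise_sd_log2^2)` for each stress channel, (3) applying
#' defects (zero channel, low-intensity rescaling), (4) optionally
#' balancing channel loading, (5) mixing the channels through the purity
#' matrix, and (6) assigning quality/label/database flags.  Generation is
#' a pure function of the configuration (including its seed).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `psm` (a PSM `data.frame`) and `truth`, a
#'   list holding `proteins` (per protein and comparison: `true_log2_fc`,
#'   `true_ratio`, and the DE label `de_truth` implied by the thresholds),
#'   `spectra` (pre-leakage intensities), and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  accs <- sprintf("P%04d", seq_len(n))
  fc <- if (is.null(cfg$true_log2_fc))
    plant_fold_changes(n, cfg$de_fraction, cfg$de_log2fc) else cfg$true_log2_fc
  ratio <- 2^fc

  n_psm <- if (cfg$psm_per_protein[1L] == cfg$psm_per_protein[2L])
    rep(cfg$psm_per_protein[1L], n)
  else
    sample(cfg$psm_per_protein[1L]:cfg$psm_per_protein[2L], n, replace = TRUE)
  p_of <- rep(seq_len(n), n_psm)
  S <- length(p_of)

  base <- stats::rlnorm(S, cfg$base_meanlog, cfg$base_sdlog)
  I <- matrix(0, S, 4L, dimnames = list(NULL, CHANNELS))
  I[, 1L] <- base
  for (c in 2:4) {
    noise <- if (cfg$noise_sd_log2 > 0)
      2^stats::rnorm(S, 0, cfg$noise_sd_log2) else 1
    I[, c] <- base * ratio[p_of, c - 1L] * noise
  }

  # quality/label/database flags
  low_q <- stats::runif(S) < cfg$frac_low_quality
  log_e <- ifelse(low_q, stats::runif(S, -1.9, -0.1), stats::runif(S, -8, -2))
  has_label <- stats::runif(S) >= cfg$frac_unlabeled
  in_db <- stats::runif(S) >= cfg$frac_offdb

  # defects acting on the true (pre-leakage) signal
  zero_hit <- stats::runif(S) < cfg$frac_zero_channel
  zero_channel <- sample.int(4L, S, replace = TRUE)
  I[cbind(which(zero_hit), zero_channel[zero_hit])] <- 0
  low_int <- stats::runif(S) < cfg$frac_low_intensity
  if (any(low_int)) {
    pair_max <- apply(I[low_int, 2:4, drop = FALSE] + I[low_int, 1L], 1L, max)
    target <- stats::runif(sum(low_int), 0.2, 0.9) * cfg$intensity_sum_min
    scale <- ifelse(pair_max > 0, target / pair_max, 1)
    I[low_int, ] <- I[low_int, , drop = FALSE] * scale
  }

  if (cfg$balance_loading) {
    qual <- has_label & in_db & log_e <= -2.0
    diff <- I[qual, 2:4, drop = FALSE] - I[qual, 1L]
    D <- rowsum(diff, group = p_of[qual], reorder = TRUE)
    w <- rowsum(rowSums(I[qual, , drop = FALSE]), group = p_of[qual],
                reorder = TRUE)[, 1L]
    w[w <= 0] <- 1
    t_p <- loading_balance_factors(D, w)
    if (is.null(t_p)) {
      warning("channel loading could not be balanced (e.g. one-sided ",
              "planted effects); normalization factors will differ from 1")
    } else {
      scale_p <- rep(1, n)
      scale_p[as.integer(rownames(D))] <- t_p
      I <- I * scale_p[p_of]
    }
  }

  pre_leakage <- I
  obs <- t(cfg$purity %*% t(I))
  colnames(obs) <- CHANNELS

  peptide <- vapply(sample.int(13L, S, replace = TRUE) + 7L, function(len)
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                   "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
          collapse = ""), "")

  psm <- data.frame(
    spectrum_id = sprintf("S%06d", seq_len(S)),
    peptide = peptide,
    protein_acc = accs[p_of],
    log_e = log_e,
    has_label = has_label,
    in_target_db = in_db,
    stringsAsFactors = FALSE
  )
  for (c in 1:4) psm[[INTENSITY_COLUMNS[c]]] <- obs[, c]

  comparisons <- paste(CHANNELS[2:4], CHANNELS[1L], sep = "/")
  truth_proteins <- data.frame(
    protein_acc = rep(accs, each = 3L),
    comparison = rep(comparisons, n),
    true_log2_fc = as.vector(t(fc)),
    true_ratio = as.vector(t(ratio)),
    stringsAsFactors = FALSE
  )
  truth_proteins$de_truth <- ifelse(
    truth_proteins$true_ratio >= cfg$up_threshold, "up",
    ifelse(truth_proteins$true_ratio <= cfg$down_threshold, "down", "none"))

  spectra <- data.frame(spectrum_id = psm$spectrum_id, stringsAsFactors = FALSE)
  for (c in 1:4) spectra[[paste0("t", CHANNELS[c])]] <- pre_leakage[, c]

  list(psm = psm,
       truth = list(proteins = truth_proteins, spectra = spectra, config = cfg))
}

#' Generate a synthetic annotation map with a planted enriched pathway
#'
#' Assigns each protein a COG category and one to three pathway
#' memberships uniformly at random; about 10 percent of proteins are left
#' without a COG hit.  A planted enrichment specification forces a chosen
#' pathway to contain a given protein set (typically differentially
#' expressed proteins) within a fixed pathway size, so the hypergeometric
#' enrichment stage has a known positive.
#'
#' @param accessions Character vector of protein accessions (or a count,
#'   expanded to `P0001..`).
#' @param n_pathways Number of pathway identifiers (`pw01..`).
#' @param planted Optional list with elements `pathway_id`, `proteins`
#'   (members to force into it) and `size` (its total size,
#'   `>= length(proteins)`).
#' @param seed Integer seed.
#' @return An [annotation_map()].
#' @export
generate_annotation <- function(accessions, n_pathways = 20, planted = NULL,
                                seed = 1L) {
  if (is.numeric(accessions) && length(accessions) == 1L)
    accessions <- sprintf("P%04d", seq_len(accessions))
  set.seed(as.integer(seed))
  n <- length(accessions)
  pw_ids <- sprintf("pw%02d", seq_len(n_pathways))

  cog_letters <- setdiff(COG_CATEGORIES, "no_hit")
  annotated <- stats::runif(n) >= 0.1
  cog <- sample(cog_letters, sum(annotated), replace = TRUE)
  names(cog) <- accessions[annotated]

  pathways <- lapply(seq_len(n), function(i)
    sample(pw_ids, sample.int(min(3L, n_pathways), 1L)))
  names(pathways) <- accessions

  if (!is.null(planted)) {
    if (!all(c("pathway_id", "proteins", "size") %in% names(planted)))
      stop_validation("planted spec needs pathway_id, proteins and size")
    if (length(planted$proteins) > planted$size)
      stop_validation("planted overlap larger than the pathway size")
    if (!all(planted$proteins %in% accessions))
      stop_validation("planted proteins must be among the accessions")
    filler <- setdiff(accessions, planted$proteins)
    members <- c(planted$proteins,
                 sample(filler, planted$size - length(planted$proteins)))
    pathways <- lapply(pathways, function(p) setdiff(p, planted$pathway_id))
    for (acc in members)
      pathways[[acc]] <- c(pathways[[acc]], planted$pathway_id)
    # setdiff may have emptied a non-member's set; give it a replacement
    empty <- names(pathways)[lengths(pathways) == 0L]
    for (acc in empty)
      pathways[[acc]] <- sample(setdiff(pw_ids, planted$pathway_id), 1L)
  }
  annotation_map(cog = cog, pathways = pathways)
}
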