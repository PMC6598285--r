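# Spectrum-to-protein quantitation: isotope cross-over correction,
# qualification, normalization, ratio computation with the Divide-0
# sentinel, intensity-filtered median protein ratios, and the
# PSM-count/significance gate.

#' Default reporter-ion purity matrix
#'
#' Isobaric reagent certificates report, per channel, the fraction of
#' signal leaking into neighbouring mass windows.  Reagent lots differ and
#' the correct matrix is the one supplied with the kit; this default is a
#' typical 4-plex profile (93 percent on the diagonal, 6 percent at +1 Da,
#' 1 percent at -1 Da, edge channels losing the remainder outside the four
#' measured windows) intended for simulation and as a placeholder until a
#' lot-specific matrix is supplied.
#'
#' @return A 4x4 matrix `P` with `P[r, c]` the fraction of channel `c`'s
#'   true signal observed in channel `r`; columns sum to at most 1.
#' @seealso [correct_isotope_crossover()], [read_purity_matrix()]
#' @export
default_purity_matrix <- function() {
  P <- diag(0.93, 4)
  P[cbind(2:4, 1:3)] <- 0.06  # +1 Da leakage
  P[cbind(1:3, 2:4)] <- 0.01  # -1 Da leakage
  dimnames(P) <- list(CHANNELS, CHANNELS)
  P
}

#' @noRd
validate_purity_matrix <- function(purity) {
  if (!is.matrix(purity) || !identical(dim(purity), c(4L, 4L)))
    stop_config("purity matrix must be 4x4")
  if (any(!is.finite(purity)) || any(purity < 0))
    stop_config("purity matrix entries must be finite and >= 0")
  if (any(diag(purity) < 0.8))
    stop_config("purity matrix diagonal entries must be >= 0.8")
  if (any(colSums(purity) > 1 + 1e-8))
    stop_config("purity matrix columns must sum to <= 1")
  if (rcond(purity) < .Machine$double.eps * 1e3)
    stop_config("purity matrix is singular or near-singular")
  invisible(purity)
}

# Exact non-negative least squares for a 4-variable system by support
# enumeration: the optimal NNLS support is one of the 16 channel subsets,
# and on its support the NNLS solution equals the unconstrained
# least-squares fit, so trying every subset and keeping the feasible fit
# with the smallest residual is exact, deterministic, and cheap.
#' @noRd
nnls4 <- function(A, b) {
  best_x <- rep(0, 4L)
  best_r <- sum(b^2)
  for (m in seq_len(15L)) {
    S <- which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
    As <- A[, S, drop = FALSE]
    x <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(x) || any(x < 0)) next
    r <- sum((b - As %*% x)^2)
    if (r < best_r * (1 - 1e-12)) {
      best_r <- r
      best_x <- rep(0, 4L)
      best_x[S] <- x
    }
  }
  best_x
}

#' Correct reporter intensities for isotope cross-over
#'
#' Recovers the true per-channel signal `T` from observed intensities
#' `O = P T`, where `P` is the reagent purity matrix.  The unconstrained
#' linear solve is used when it is already non-negative; otherwise the
#' non-negative least-squares solution minimising `||P T - O||` subject to
#' `T >= 0` is taken (computed exactly by support enumeration), so noisy
#' spectra can never acquire negative intensities.
#'
#' @param intensities Numeric vector of 4 observed intensities, or an
#'   n x 4 matrix (rows are spectra) in channel order 114..117.
#' @param purity A 4x4 purity matrix; see [default_purity_matrix()].
#' @return Corrected intensities with the same shape as the input.
#' @export
correct_isotope_crossover <- function(intensities, purity = default_purity_matrix()) {
  validate_purity_matrix(purity)
  vec_in <- is.null(dim(intensities))
  X <- if (vec_in) matrix(intensities, nrow = 1L) else as.matrix(intensities)
  if (ncol(X) != 4L)
    stop_validation("intensities must have exactly 4 channels")
  if (any(!is.finite(X)) || any(X < 0))
    stop_validation("intensities must be finite and >= 0")
  Tmat <- t(solve(purity, t(X)))
  # material negativity triggers the constrained solve; numerical dust is
  # clamped below
  tol <- -1e-9 * pmax(apply(abs(Tmat), 1L, max), 1)
  neg <- which(apply(Tmat < tol, 1L, any))
  for (i in neg)
    Tmat[i, ] <- nnls4(purity, X[i, ])
  Tmat[Tmat < 0] <- 0
  colnames(Tmat) <- CHANNELS
  if (vec_in) Tmat[1L, ] else Tmat
}

#' Spectrum qualification
#'
#' A spectrum qualifies for quantitation when its peptide carries the
#' 4-plex label, maps to the target protein database, and its search score
#' satisfies log(e) <= `log_e_max` (boundary inclusive).
#'
#' @param psm A PSM `data.frame`.
#' @param log_e_max Score threshold on log10 of the expectation value
#'   (default -2.0).
#' @return Logical vector, one element per PSM.
#' @export
passes_spectrum_criteria <- function(psm, log_e_max = -2.0) {
  psm$has_label & psm$in_target_db & psm$log_e <= log_e_max
}

#' @noRd
comparison_channels <- function(comparison) {
  parts <- strsplit(comparison, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(parts %in% CHANNELS))
    stop_config("comparison must look like '115/114' using channels 114..117")
  c(num = parts[1L], den = parts[2L])
}

#' Summed-intensity normalization factor
#'
#' The per-comparison normalization factor is the ratio of summed
#' corrected reporter intensity (numerator channel over denominator
#' channel) across all qualifying spectra; dividing spectrum ratios by it
#' sets the post-normalization summed-intensity ratio to exactly 1, so a
#' global loading difference between channels cancels.
#'
#' @param corrected n x 4 matrix of corrected intensities of the
#'   qualifying spectra (channel order 114..117).
#' @param comparison Comparison label such as `"115/114"`.
#' @return A positive scalar.
#' @export
normalization_factor <- function(corrected, comparison) {
  ch <- comparison_channels(comparison)
  corrected <- rbind(corrected)
  num_sum <- sum(corrected[, match(ch["num"], CHANNELS)])
  den_sum <- sum(corrected[, match(ch["den"], CHANNELS)])
  if (nrow(corrected) == 0L || den_sum <= 0)
    stop_validation("normalization requires at least one qualifying spectrum ",
                    "with positive denominator-channel intensity")
  num_sum / den_sum
}

#' Per-spectrum normalized ratios
#'
#' Computes raw and normalized reporter ratios for one comparison.
#' A zero denominator with positive numerator is the "Divide 0" case: the
#' spectrum is kept and its normalized ratio is set to the sentinel value
#' (10 by default, not rescaled by the normalization factor, since the
#' sentinel is a final placeholder rather than a measurement).  Spectra
#' with both channels zero carry no ratio information and are dropped.
#'
#' @param corrected n x 4 matrix of corrected intensities (channel order
#'   114..117), with `spectrum_id`s as row names if available.
#' @param comparison Comparison label such as `"115/114"`.
#' @param norm Positive normalization factor; see [normalization_factor()].
#' @param sentinel Ratio assigned to zero-denominator spectra (default 10).
#' @param spectrum_id,protein_acc Optional identifier vectors carried
#'   through to the output.
#' @return A `data.frame` with columns `spectrum_id`, `protein_acc`,
#'   `comparison`, `raw_ratio` (NA for sentinel rows), `normalized_ratio`,
#'   `is_sentinel` and `channel_sum` (corrected numerator + denominator
#'   intensity, the statistic of the intensity filter).
#' @export
spectrum_ratios <- function(corrected, comparison, norm, sentinel = 10,
                            spectrum_id = NULL, protein_acc = NULL) {
  if (!is.numeric(norm) || length(norm) != 1L || !is.finite(norm) || norm <= 0)
    stop_validation("normalization factor must be a positive scalar")
  ch <- comparison_channels(comparison)
  corrected <- rbind(corrected)
  n <- nrow(corrected)
  num <- corrected[, match(ch["num"], CHANNELS)]
  den <- corrected[, match(ch["den"], CHANNELS)]
  if (is.null(spectrum_id)) spectrum_id <- rownames(corrected)
  if (is.null(spectrum_id)) spectrum_id <- as.character(seq_len(n))
  if (is.null(protein_acc)) protein_acc <- rep(NA_character_, n)
  keep <- num > 0 | den > 0
  num <- num[keep]; den <- den[keep]
  is_sentinel <- den == 0
  raw <- ifelse(is_sentinel, NA_real_, num / den)
  data.frame(
    spectrum_id = spectrum_id[keep],
    protein_acc = protein_acc[keep],
    comparison = comparison,
    raw_ratio = raw,
    normalized_ratio = ifelse(is_sentinel, sentinel, raw / norm),
    is_sentinel = is_sentinel,
    channel_sum = num + den,
    stringsAsFactors = FALSE
  )
}

#' Intensity-filtered median protein ratio
#'
#' The protein-level ratio for one comparison is the median of the
#' normalized spectrum ratios over spectra whose corrected
#' numerator+denominator intensity sum is strictly greater than
#' `intensity_sum_min`; `n` counts those spectra.  With an even count the
#' median is the midpoint of the two central values; with no passing
#' spectra no ratio exists and `median` is `NA`.
#'
#' @param ratios A `data.frame` from [spectrum_ratios()] restricted to one
#'   protein and comparison.
#' @param intensity_sum_min Intensity filter threshold (default 20000,
#'   strict).
#' @return A list with elements `median` and `n`.
#' @export
protein_median_ratio <- function(ratios, intensity_sum_min = 20000) {
  pass <- ratios$channel_sum > intensity_sum_min
  x <- ratios$normalized_ratio[pass]
  list(median = if (length(x)) stats::median(x) else NA_real_,
       n = length(x))
}

#' One-sample location test of spectrum log-ratios
#'
#' Two-sided p-value for the null that the log2 normalized spectrum ratios
#' of a protein are centred at 0.  The default is the Wilcoxon signed-rank
#' test (exact null distribution when n <= 25 and there are no ties among
#' non-zero values; the tie-corrected normal approximation otherwise); a
#' one-sample t-test may be selected instead.  Exact zeros are dropped, as
#' usual for the signed-rank statistic; an empty or all-zero sample gives
#' p = 1 by convention, since it carries no evidence of a shift.
#'
#' @param log2_ratios Numeric vector of log2 normalized spectrum ratios
#'   (sentinel spectra must be excluded by the caller).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A p-value in `[0, 1]`.
#' @export
protein_p_value <- function(log2_ratios, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  x <- log2_ratios[is.finite(log2_ratios)]
  if (test == "wilcoxon") {
    x <- x[x != 0]
    if (length(x) == 0L) return(1)
    p <- suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
  } else {
    if (length(x) < 2L || stats::sd(x) == 0)
      return(if (all(x == 0) || length(x) < 2L) 1 else 0)
    p <- stats::t.test(x, mu = 0)$p.value
  }
  min(1, max(0, p))
}

#' Spectrum-to-protein quantitation pipeline
#'
#' Runs the full quantitation chain for every comparison in the
#' configuration: isotope cross-over correction, spectrum qualification,
#' summed-intensity normalization, per-spectrum ratios with the Divide-0
#' sentinel, intensity-filtered median protein ratios, the one-sample
#' location test, and the quantitation gate (`n_psm >= min_psm` and
#' `p <= p_max`).  Sentinel spectra count towards the median and `n_psm`
#' (when they pass the intensity filter) but are excluded from the
#' location test, which only makes sense on measured ratios.
#'
#' @param psm A PSM `data.frame`; see [read_psm_table()].
#' @param purity A 4x4 purity matrix.
#' @param config A [pipeline_config()].
#' @return A `data.frame` of class `"protein_quant"`, one row per protein
#'   per comparison: `protein_acc`, `comparison`, `median_ratio`, `n_psm`,
#'   `p_value`, `status` (`quantified`, `insufficient_psm` or
#'   `not_significant`).  Stage counts (spectra in, qualifying,
#'   intensity-passing, proteins quantified) are attached as attribute
#'   `"counts"`.
#' @export
quantify_proteins <- function(psm, purity = default_purity_matrix(),
                              config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  validate_psm_table(psm)
  if (nrow(psm) == 0L) {
    out <- data.frame(protein_acc = character(), comparison = character(),
                      median_ratio = numeric(), n_psm = integer(),
                      p_value = numeric(), status = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("protein_quant", "data.frame")
    return(out)
  }
  identity_purity <- isTRUE(all.equal(unname(purity), diag(4), tolerance = 0))
  corrected <- if (identity_purity) {
    validate_purity_matrix(purity)
    as.matrix(psm[INTENSITY_COLUMNS])
  } else {
    correct_isotope_crossover(as.matrix(psm[INTENSITY_COLUMNS]), purity)
  }
  colnames(corrected) <- CHANNELS
  qual <- passes_spectrum_criteria(psm, config$log_e_max)
  proteins <- sort(unique(psm$protein_acc))
  counts <- list(n_spectra = nrow(psm), n_qualifying = sum(qual),
                 n_intensity_pass = integer(0), n_quantified = integer(0))

  per_comparison <- lapply(config$comparisons, function(cmp) {
    norm <- if (config$normalize)
      normalization_factor(corrected[qual, , drop = FALSE], cmp) else 1
    sr <- spectrum_ratios(corrected[qual, , drop = FALSE], cmp, norm,
                          sentinel = config$sentinel_ratio,
                          spectrum_id = psm$spectrum_id[qual],
                          protein_acc = psm$protein_acc[qual])
    pass <- sr$channel_sum > config$intensity_sum_min
    counts$n_intensity_pass[[cmp]] <<- sum(pass)
    srp <- sr[pass, , drop = FALSE]
    grp <- split(seq_len(nrow(srp)), factor(srp$protein_acc, levels = proteins))
    med <- vapply(grp, function(i)
      if (length(i)) stats::median(srp$normalized_ratio[i]) else NA_real_, 0)
    n <- lengths(grp)
    pv <- vapply(grp, function(i) {
      x <- srp$normalized_ratio[i][!srp$is_sentinel[i]]
      protein_p_value(log2(x), test = config$test)
    }, 0)
    status <- ifelse(n < config$min_psm, "insufficient_psm",
                     ifelse(pv <= config$p_max, "quantified", "not_significant"))
    counts$n_quantified[[cmp]] <<- sum(status == "quantified")
    data.frame(protein_acc = proteins, comparison = cmp,
               median_ratio = unname(med), n_psm = unname(as.integer(n)),
               p_value = unname(pv), status = unname(status),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_comparison)
  out <- out[order(out$protein_acc, out$comparison), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("protein_quant", "data.frame")
  out
}
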