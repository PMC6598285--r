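# Quantitation chain: correction, qualification, normalization, ratios,
# medians, p-values, and the composed pipeline.

test_that("isotope correction is the identity under identity purity and on zeros", {
  expect_equal(correct_isotope_crossover(c(100, 200, 300, 400), diag(4)),
               c(100, 200, 300, 400), ignore_attr = TRUE)
  expect_equal(correct_isotope_crossover(c(0, 0, 0, 0)),
               c(0, 0, 0, 0), ignore_attr = TRUE)
})

test_that("forward mixing then correction recovers true intensities", {
  P <- default_purity_matrix()
  expect_equal(correct_isotope_crossover(as.vector(P %*% c(1000, 500, 0, 200)), P),
               c(1000, 500, 0, 200), tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(4)
  for (i in 1:100) {
    truth <- runif(4, 0, 1e5) * rbinom(4, 1, 0.7)
    rec <- correct_isotope_crossover(as.vector(P %*% truth), P)
    expect_true(all(abs(rec - truth) <= 1e-6 * pmax(truth, 1)))
  }
})

test_that("correction clamps noisy spectra to the non-negative optimum", {
  P <- default_purity_matrix()
  # observation incompatible with any non-negative signal in channel 114
  obs <- c(5, 10000, 9000, 8000)
  rec <- correct_isotope_crossover(obs, P)
  expect_true(all(rec >= 0))
  # NNLS optimality: residual no worse than a dense grid of clamps
  res <- sum((as.vector(P %*% rec) - obs)^2)
  unc <- solve(P, obs)
  res_clamped <- sum((as.vector(P %*% pmax(unc, 0)) - obs)^2)
  expect_lte(res, res_clamped + 1e-9)
})

test_that("singular or implausible purity matrices are configuration errors", {
  expect_error(correct_isotope_crossover(1:4, matrix(0.85, 4, 4)),
               class = "plexquant_config_error")
  bad <- default_purity_matrix(); bad[1, 1] <- 0.79
  expect_error(correct_isotope_crossover(1:4, bad),
               class = "plexquant_config_error")
})

test_that("spectrum qualification is a conjunction with inclusive score boundary", {
  psm <- make_psm(4, log_e = c(-2.0, -4, -1.5, -4),
                  has_label = c(TRUE, FALSE, TRUE, TRUE),
                  in_target_db = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(passes_spectrum_criteria(psm), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("normalization factor is the summed-intensity ratio over qualifying spectra", {
  corrected <- rbind(c(1e4, 2e4, 0, 0), c(9.9e5, 1.98e6, 0, 0))
  expect_equal(normalization_factor(corrected, "115/114"), 2.0)
  # equal sums in both channels -> 1
  eq <- rbind(c(5e4, 3e4, 0, 0), c(1e4, 3e4, 0, 0))
  expect_equal(normalization_factor(eq, "115/114"), 1.0)
  # a non-qualifying spectrum contributes nothing: the caller filters it out,
  # so the factor over the remaining rows is unchanged
  expect_equal(normalization_factor(corrected[1, , drop = FALSE], "115/114"), 2.0)
  expect_error(normalization_factor(rbind(c(0, 10, 0, 0)), "115/114"),
               class = "plexquant_validation_error")
})

test_that("spectrum ratios implement the Divide-0 sentinel and drop 0/0", {
  corrected <- rbind(c(0, 3000, 0, 0),      # sentinel
                     c(1500, 3000, 0, 0),   # ratio 2
                     c(0, 0, 5, 5))         # both zero -> dropped
  sr <- spectrum_ratios(corrected, "115/114", norm = 1)
  expect_equal(nrow(sr), 2L)
  expect_true(sr$is_sentinel[1])
  expect_equal(sr$normalized_ratio[1], 10)
  expect_equal(sr$raw_ratio[2], 2)
  expect_equal(sr$channel_sum, c(3000, 4500))
  # normalization rescales measured ratios but never the sentinel
  sr2 <- spectrum_ratios(corrected, "115/114", norm = 2)
  expect_equal(sr2$normalized_ratio, c(10, 1))
})

test_that("median protein ratio applies the strict intensity filter", {
  ratios <- data.frame(normalized_ratio = c(0.5, 1, 2, 4, 8),
                       channel_sum = rep(30000, 5))
  expect_equal(protein_median_ratio(ratios), list(median = 2, n = 5L))
  ratios$channel_sum[5] <- 15000
  expect_equal(protein_median_ratio(ratios), list(median = 1.5, n = 4L))
  # boundary is strict
  ratios$channel_sum <- rep(20000, 5)
  expect_equal(protein_median_ratio(ratios)$n, 0L)
  one <- data.frame(normalized_ratio = 3.3, channel_sum = 25000)
  expect_equal(protein_median_ratio(one), list(median = 3.3, n = 1L))
})

test_that("signed-rank p-values match the exact null and its conventions", {
  # 8 strictly positive values: two-sided exact p = 2 / 2^8
  expect_equal(protein_p_value(c(0.31, 0.45, 0.52, 0.63, 0.71, 0.84, 0.9, 1.0)),
               2 / 2^8)
  expect_equal(protein_p_value(rep(0, 6)), 1)
  expect_equal(protein_p_value(c(-0.4, 0.4)), 1)
  expect_equal(protein_p_value(numeric(0)), 1)
  # t-test alternative
  expect_lt(protein_p_value(c(0.5, 0.52, 0.48, 0.51), test = "t"), 0.01)
  expect_equal(protein_p_value(rep(0, 4), test = "t"), 1)
})

test_that("quantify_proteins composes the stages and gates quantitation", {
  # protein A: 10 spectra at planted ratio 2 vs 114 in channel 115,
  # protein B: only 2 passing spectra -> insufficient_psm
  psm <- rbind(
    make_psm(10, spectrum_id = sprintf("A%02d", 1:10), protein_acc = "PA",
             i114 = 2e4, i115 = 4e4, i116 = 2e4, i117 = 2e4),
    make_psm(2, spectrum_id = sprintf("B%02d", 1:2), protein_acc = "PB",
             i114 = 2e4, i115 = 1e4, i116 = 2e4, i117 = 2e4))
  cfg <- pipeline_config(normalize = FALSE)
  q <- quantify_proteins(psm, purity = diag(4), config = cfg)
  a115 <- q[q$protein_acc == "PA" & q$comparison == "115/114", ]
  expect_equal(a115$median_ratio, 2)
  expect_equal(a115$n_psm, 10L)
  expect_equal(a115$status, "quantified")
  b115 <- q[q$protein_acc == "PB" & q$comparison == "115/114", ]
  expect_equal(b115$status, "insufficient_psm")
  expect_equal(b115$n_psm, 2L)

  expect_equal(nrow(quantify_proteins(make_psm(0))), 0L)
})

test_that("stage counts are attached and monotone through the filters", {
  d <- generate_dataset(synthetic_config(n_proteins = 40, seed = 12))
  q <- quantify_proteins(d$psm, purity = default_purity_matrix())
  counts <- attr(q, "counts")
  expect_lte(counts$n_qualifying, counts$n_spectra)
  expect_true(all(counts$n_intensity_pass <= counts$n_qualifying))
  expect_true(all(counts$n_quantified <= length(unique(d$psm$protein_acc))))
})

test_that("normalization makes summed ratios 1 and absorbs global channel scaling", {
  d <- generate_dataset(synthetic_config(n_proteins = 30, seed = 8,
                                         balance_loading = FALSE))
  psm <- d$psm
  cfg <- pipeline_config()
  corrected <- correct_isotope_crossover(
    as.matrix(psm[paste0("i", c(114, 115, 116, 117))]))
  qual <- passes_spectrum_criteria(psm)
  for (cmp in cfg$comparisons) {
    norm <- normalization_factor(corrected[qual, ], cmp)
    sr <- spectrum_ratios(corrected[qual, ], cmp, norm)
    num_ch <- sub("/.*", "", cmp)
    num <- corrected[qual, match(num_ch, c("114", "115", "116", "117"))]
    den <- corrected[qual, 1]
    expect_equal(sum(num / norm) / sum(den), 1, tolerance = 1e-9)
  }
  # scaling the numerator channel by c > 0 leaves every normalized
  # spectrum ratio unchanged: the normalization factor absorbs c
  inten <- as.matrix(psm[paste0("i", c(114, 115, 116, 117))])
  scaled <- inten
  scaled[, 2] <- scaled[, 2] * 3.7
  n1 <- normalization_factor(inten[qual, ], "115/114")
  n2 <- normalization_factor(scaled[qual, ], "115/114")
  expect_equal(n2, 3.7 * n1, tolerance = 1e-12)
  r1 <- spectrum_ratios(inten[qual, ], "115/114", n1)
  r2 <- spectrum_ratios(scaled[qual, ], "115/114", n2)
  expect_equal(r2$normalized_ratio, r1$normalized_ratio, tolerance = 1e-9)
  # and with the intensity filter out of play, protein medians agree too
  cfg0 <- pipeline_config(intensity_sum_min = 0)
  psm2 <- psm
  psm2$i115 <- psm2$i115 * 3.7
  q1 <- quantify_proteins(psm, purity = diag(4), config = cfg0)
  q2 <- quantify_proteins(psm2, purity = diag(4), config = cfg0)
  sel <- q1$comparison == "115/114" & !is.na(q1$median_ratio)
  expect_equal(q2$median_ratio[sel], q1$median_ratio[sel], tolerance = 1e-9)
})

test_that("no emitted ratio is NaN, infinite, or non-positive", {
  d <- generate_dataset(synthetic_config(n_proteins = 60, seed = 21,
                                         frac_zero_channel = 0.15))
  q <- quantify_proteins(d$psm)
  ok <- is.na(q$median_ratio) | (is.finite(q$median_ratio) & q$median_ratio > 0)
  expect_true(all(ok))
  expect_true(all(q$p_value >= 0 & q$p_value <= 1))
  expect_true(all(q$status[q$n_psm < 3] == "insufficient_psm"))
  expect_true(all(q$p_value[q$status == "quantified"] <= 0.01))
})
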