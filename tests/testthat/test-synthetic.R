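# Generator: determinism, noise-free limit, defect rates, ground truth.

test_that("generation is a pure function of the seed", {
  cfg <- synthetic_config(n_proteins = 20, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$psm, d2$psm)
  expect_identical(d1$truth$proteins, d2$truth$proteins)
  d3 <- generate_dataset(synthetic_config(n_proteins = 20, seed = 100))
  expect_false(identical(d1$psm$i114, d3$psm$i114))
})

test_that("noise-free identity-purity spectra carry planted ratios exactly", {
  fc <- matrix(0, 4, 3)
  fc[1, ] <- 1  # ratio 2 in all three comparisons
  fc[2, ] <- -1
  cfg <- synthetic_config(n_proteins = 4, psm_per_protein = c(6, 6),
                          true_log2_fc = fc, noise_sd_log2 = 0,
                          purity = diag(4), frac_zero_channel = 0,
                          frac_low_quality = 0, frac_unlabeled = 0,
                          frac_offdb = 0, frac_low_intensity = 0, seed = 5)
  d <- generate_dataset(cfg)
  p1 <- d$psm[d$psm$protein_acc == "P0001", ]
  expect_equal(p1$i115 / p1$i114, rep(2, 6))
  expect_equal(p1$i117 / p1$i114, rep(2, 6))
  null_p <- d$psm[d$psm$protein_acc == "P0003", ]
  expect_equal(null_p$i116 / null_p$i114, rep(1, 6))
})

test_that("zero-channel defect rate matches its binomial expectation", {
  cfg <- synthetic_config(n_proteins = 250, psm_per_protein = c(20, 20),
                          de_fraction = 0, noise_sd_log2 = 0.1,
                          purity = diag(4), frac_zero_channel = 0.1,
                          frac_low_quality = 0, frac_unlabeled = 0,
                          frac_offdb = 0, frac_low_intensity = 0, seed = 17)
  d <- generate_dataset(cfg)
  inten <- as.matrix(d$psm[paste0("i", c(114, 115, 116, 117))])
  frac <- mean(apply(inten == 0, 1, any))
  n <- nrow(inten)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("quality, label and database flag rates match their settings", {
  cfg <- synthetic_config(n_proteins = 250, psm_per_protein = c(20, 20),
                          de_fraction = 0, frac_low_quality = 0.2,
                          frac_unlabeled = 0.15, frac_offdb = 0.1, seed = 23)
  d <- generate_dataset(cfg)
  n <- nrow(d$psm)
  expect_lt(abs(mean(d$psm$log_e > -2) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(mean(!d$psm$has_label) - 0.15), 3 * sqrt(0.15 * 0.85 / n))
  expect_lt(abs(mean(!d$psm$in_target_db) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("low-intensity defect pushes every pairwise channel sum below the filter", {
  cfg <- synthetic_config(n_proteins = 50, psm_per_protein = c(10, 10),
                          de_fraction = 0, noise_sd_log2 = 0,
                          purity = diag(4), frac_zero_channel = 0,
                          frac_low_quality = 0, frac_unlabeled = 0,
                          frac_offdb = 0, frac_low_intensity = 0.3,
                          balance_loading = FALSE, seed = 31)
  d <- generate_dataset(cfg)
  inten <- as.matrix(d$psm[paste0("i", c(114, 115, 116, 117))])
  pair_max <- pmax(inten[, 2] + inten[, 1], inten[, 3] + inten[, 1],
                   inten[, 4] + inten[, 1])
  frac_low <- mean(pair_max < 20000)
  expect_lt(abs(frac_low - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(inten)))
})

test_that("ground-truth DE labels are consistent with ratios and thresholds", {
  d <- generate_dataset(synthetic_config(n_proteins = 100, seed = 7))
  tp <- d$truth$proteins
  expect_identical(tp$de_truth,
                   ifelse(tp$true_ratio >= 1.2, "up",
                          ifelse(tp$true_ratio <= 0.83, "down", "none")))
  expect_equal(tp$true_ratio, 2^tp$true_log2_fc)
})

test_that("balanced loading equalizes qualifying channel sums exactly", {
  cfg <- recovery_config(seed = 3)
  d <- generate_dataset(cfg)
  inten <- as.matrix(d$psm[paste0("i", c(114, 115, 116, 117))])
  sums <- colSums(inten)
  expect_equal(unname(sums[2:4] / sums[1]), rep(1, 3), tolerance = 1e-9)
})

test_that("purity mixing spreads signal into neighbour channels", {
  fc <- matrix(0, 2, 3)
  cfg <- synthetic_config(n_proteins = 2, psm_per_protein = c(5, 5),
                          true_log2_fc = fc, noise_sd_log2 = 0,
                          frac_zero_channel = 0, frac_low_quality = 0,
                          frac_unlabeled = 0, frac_offdb = 0,
                          frac_low_intensity = 0, seed = 2)
  d <- generate_dataset(cfg)
  pre <- as.matrix(d$truth$spectra[paste0("t", c(114, 115, 116, 117))])
  obs <- as.matrix(d$psm[paste0("i", c(114, 115, 116, 117))])
  expect_equal(obs, pre %*% t(default_purity_matrix()),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_proteins = 0), class = "plexquant_validation_error")
  expect_error(synthetic_config(noise_sd_log2 = -1), class = "plexquant_validation_error")
  expect_error(synthetic_config(frac_unlabeled = 1.5), class = "plexquant_validation_error")
  expect_error(synthetic_config(n_proteins = 5, true_log2_fc = matrix(0, 4, 3)),
               class = "plexquant_validation_error")
})

test_that("planted annotation over-represents the chosen pathway deterministically", {
  de <- sprintf("P%04d", 1:8)
  ann1 <- generate_annotation(200, n_pathways = 15,
                              planted = list(pathway_id = "pw01",
                                             proteins = de, size = 10),
                              seed = 13)
  ann2 <- generate_annotation(200, n_pathways = 15,
                              planted = list(pathway_id = "pw01",
                                             proteins = de, size = 10),
                              seed = 13)
  expect_identical(ann1$pathways, ann2$pathways)
  members <- names(ann1$pathways)[vapply(ann1$pathways, function(p)
    "pw01" %in% p, TRUE)]
  expect_length(members, 10)
  expect_true(all(de %in% members))
  expect_true(all(lengths(ann1$pathways) > 0))

  expect_error(generate_annotation(200, planted = list(pathway_id = "pw01",
                                                       proteins = de, size = 5)),
               class = "plexquant_validation_error")
})

test_that("a single all-encompassing pathway is never enriched", {
  accs <- sprintf("P%04d", 1:30)
  ann <- annotation_map(pathways = setNames(rep(list("pw01"), 30), accs))
  res <- enrich(accs[1:10], accs, ann)
  expect_equal(res$p, 1)
})
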