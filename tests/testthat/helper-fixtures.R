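# Shared fixture builders.  Everything is generated in code; no data files.

# A minimal PSM data.frame; intensity defaults are large enough to pass the
# 20,000 intensity filter.
make_psm <- function(n = 1, spectrum_id = sprintf("S%03d", seq_len(n)),
                     protein_acc = "P0001", log_e = -4,
                     has_label = TRUE, in_target_db = TRUE,
                     i114 = 3e4, i115 = 3e4, i116 = 3e4, i117 = 3e4) {
  r <- function(x) rep(x, length.out = n)
  data.frame(spectrum_id = spectrum_id,
             peptide = r(strrep("ACDEFK", 2)),
             protein_acc = r(protein_acc),
             log_e = r(log_e), has_label = r(has_label),
             in_target_db = r(in_target_db),
             i114 = r(i114), i115 = r(i115), i116 = r(i116), i117 = r(i117),
             stringsAsFactors = FALSE)
}

# Noise-free, defect-free generator config with identity purity and a
# balanced two-sided planted design (n_up proteins at +log2fc, n_up at
# -log2fc, the rest null).
clean_config <- function(n_proteins = 30, n_up = 4, log2fc = 1,
                         psm = 10, seed = 42, ...) {
  fc <- matrix(0, n_proteins, 3)
  if (n_up > 0) {
    fc[seq_len(n_up), ] <- log2fc
    fc[n_up + seq_len(n_up), ] <- -log2fc
  }
  synthetic_config(n_proteins = n_proteins, psm_per_protein = c(psm, psm),
                   true_log2_fc = fc, noise_sd_log2 = 0, purity = diag(4),
                   frac_zero_channel = 0, frac_low_quality = 0,
                   frac_unlabeled = 0, frac_offdb = 0, frac_low_intensity = 0,
                   seed = seed, ...)
}

# The stochastic parameter-recovery config: 500 proteins, 20 PSMs each,
# noise SD 0.25 log2 units, 20% of proteins at |FC| = 1.6, identity purity,
# no defects.
recovery_config <- function(seed) {
  synthetic_config(n_proteins = 500, psm_per_protein = c(20, 20),
                   de_fraction = 0.2, de_log2fc = log2(1.6),
                   noise_sd_log2 = 0.25, purity = diag(4),
                   frac_zero_channel = 0, frac_low_quality = 0,
                   frac_unlabeled = 0, frac_offdb = 0, frac_low_intensity = 0,
                   seed = seed)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws; independent oracle for enrich().
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "annotated" ones
  mean(hits >= k)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual / expected - 1)), tol))
}
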