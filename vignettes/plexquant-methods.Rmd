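---
title: "Quantitation model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitation model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexquant)
```

## The problem

In a 4-plex isobaric labelling (iTRAQ) experiment, four protein samples are
labelled with chemically identical tags, pooled, and fragmented together.
Each tag releases a reporter ion at m/z 114, 115, 116 or 117, and the
relative intensities of the four reporters in one MS/MS spectrum encode the
relative abundance of that peptide across the four samples.  plexquant
implements the complete path from a table of peptide-spectrum matches
(PSMs) with reporter intensities to protein-level fold changes and
differential-expression calls, together with downstream profile clustering,
pathway enrichment, and fermentation end-product stoichiometry for
ethanol-stress experiments on H~2~/ethanol co-producing fermenters.

The intended design places the unstressed control in channel 114 and
increasing ethanol stress (50, 100, 200 mM) in channels 115-117, so the
three informative comparisons are 115/114, 116/114 and 117/114.  All
channel pairs can be requested through `pipeline_config(comparisons = ...)`;
the stress-versus-control set is the default because a control-referenced
design is what the Venn-style DE summaries presuppose.

## The quantitation chain

For each spectrum with observed reporter vector $O$:

1. **Isotope cross-over correction.**  Reagent isotope impurities leak a
   known fraction of each channel's signal into neighbouring mass windows.
   With purity matrix $P$ (entry $P_{rc}$ = fraction of channel $c$
   observed in window $r$), the true signal satisfies $O = P T$.  We solve
   the non-negative least-squares problem $\min_{T \ge 0} \|P T - O\|_2$.
   The unconstrained solve is used whenever it is already non-negative;
   materially negative solutions (possible on noisy or partially zero
   spectra) are replaced by the exact NNLS optimum, found by enumerating
   all 15 non-empty channel supports — for a 4-variable system this
   support enumeration is exact, deterministic and costs microseconds.
   Manufacturers never publish a universal matrix (values are lot
   specific), so `default_purity_matrix()` ships a typical certificate
   profile (0.93 diagonal, 0.06 at +1 Da, 0.01 at −1 Da) and every entry
   point accepts a user matrix.

2. **Qualification.**  A spectrum enters quantitation only if the peptide
   carries the 4-plex label, maps to the target proteome, and has search
   score $\log_{10}(e) \le -2.0$ (boundary inclusive).

3. **Normalization.**  The factor for a comparison is the ratio of summed
   corrected intensities (numerator channel over denominator channel)
   across all qualifying spectra.  Dividing each spectrum ratio by it makes
   the post-normalization summed-intensity ratio exactly 1, cancelling
   global loading differences between channels.  Correction precedes
   normalization because leakage distorts channel sums; computing the
   factor on corrected intensities keeps the two effects orthogonal.

4. **Spectrum ratios and the Divide-0 sentinel.**  The raw ratio is
   $I_{num}/I_{den}$.  A zero denominator with positive numerator (a
   protein absent from the reference channel) is kept with the sentinel
   normalized ratio 10 — a deliberate placeholder, assigned after (and
   instead of) normalization, because a placeholder is not a measurement
   to be rescaled.  Spectra with both channels zero carry no information
   and are dropped.

5. **Protein ratios.**  The protein-level ratio is the median of its
   normalized spectrum ratios over spectra whose corrected
   numerator+denominator sum strictly exceeds 20,000 counts; the strict
   boundary follows the filter's definition.  `n_psm` counts these
   spectra, sentinels included.

6. **Quantitation gate.**  A protein is reported `quantified` for a
   comparison when `n_psm >= 3` and a two-sided one-sample location test
   of its log2 normalized spectrum ratios against 0 gives $p \le 0.01$.
   The default test is the Wilcoxon signed-rank (exact null for $n \le
   25$ without ties; tie-corrected normal approximation otherwise), chosen
   for robustness to the occasional outlier ratio; a one-sample t-test is
   selectable via `pipeline_config(test = "t")`.  Sentinel ratios are
   excluded from the test — they are imputations — but counted in
   `n_psm` when they pass the intensity filter.  Conventions for
   degenerate inputs: an empty or all-zero sample gives $p = 1$ (no
   evidence of shift can never pass the gate).

Differential expression is then a pure thresholding step: `up` if the
median ratio is $\ge 1.2$, `down` if $\le 0.83$, both boundaries
inclusive; proteins failing the gate are explicitly `none` so that
set-level summaries (Venn regions, COG tallies) see explicit absence.

Note a consequence of gating quantitation on $p \le 0.01$: proteins whose
abundance genuinely does not change rarely reach `quantified` status, so
the `quantified` background used for enrichment is enriched for proteins
with real shifts.  This mirrors the published procedure; users wanting a
wider background can pass one explicitly to `enrich()`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `log_e_max` | −2.0 | log10 e-value | spectrum qualification |
| `intensity_sum_min` | 20,000 | counts | strict two-channel intensity filter |
| `sentinel_ratio` | 10 | ratio | Divide-0 placeholder |
| `min_psm` | 3 | spectra | quantitation gate |
| `p_max` | 0.01 | probability | quantitation gate |
| `up_threshold` / `down_threshold` | 1.2 / 0.83 | fold change | DE calls |
| `enrich_p` | 0.05 | probability | raw enrichment significance |
| `k_clusters` | 6 | clusters | profile dendrogram cut |

All are fields of `pipeline_config()` and validated up front (for example
`down_threshold < 1 < up_threshold` is rejected before any computation).

## Profiles, clustering, enrichment

Profiles are built on log2 median ratios versus control (control column
identically 0; a comparison without a quantified ratio is imputed as 0 and
flagged).  Rows are z-scored with the sample SD ($n-1$) so that 0 marks a
protein's own average abundance; constant rows map to all-zero rather than
NaN.  z-scores are computed on log ratios, not raw ratios, so up- and
down-regulation are treated symmetrically.  Clustering is agglomerative
with Euclidean distance and average linkage, cut to exactly `k` clusters
(default 6); distance, linkage and `k` are exposed because "six major
clusters" is a presentation choice, not a property of the algorithm.

Enrichment uses the upper-tail hypergeometric probability
$p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$
with the quantified proteins as the default background.  Raw $p \le 0.05$
defines "significant" for fidelity with the original procedure;
Benjamini-Hochberg adjusted values are always reported alongside so the
multiplicity cost is visible.

## Fermentation stoichiometry

Endogenous ethanol is the measured total minus the exogenously added mass
(1 mM ethanol ≡ 46.07 mg/L); small negative differences (a fully
recovered spike measured with noise) clamp to 0, gross inconsistencies
raise an error.  Molar ratios use 46.07 g/mol (ethanol) and 60.05 g/mol
(acetic acid); the ethanol weight percentage is taken over the two liquid
end-products.  These constants are named package exports because every
printed ratio in this literature depends on them.

```{r}
ctrl <- 4030.4 / 1.301  # endogenous control yield implied by a 30.1% rise
yields <- data.frame(
  condition_mM = c(0, 200), h2_mL_L = c(1888.6, 837),
  ethanol_total_mg_L = c(ctrl, ctrl * 1.274 + 200 * M_ETHANOL),
  acetate_mg_L = c(1767.7, 160.6))
summarize_stoichiometry(yields)[, c("condition_mM", "molar_ratio",
                                    "ethanol_weight_pct", "fold_vs_control")]
```

## What the generator emulates — and what it does not

`generate_dataset()` produces PSM tables whose every downstream property
is known: per-protein fold changes (by default 20% of proteins at
|FC| = 1.6, half up and half down, matching the magnitude the DE
thresholds are designed to detect), log-normal base intensities
(median 60,000 counts, log-SD 0.8, so a realistic minority of spectra
fall near the 20,000 intensity filter), multiplicative log-normal
reporter noise (default SD 0.25 log2 units, a typical spectrum-to-spectrum
spread for reporter ratios), purity-matrix leakage, and the defect classes
a real search output contains: spectra with a zero channel (2%),
low-quality scores (5%), unlabeled peptides (3%), off-database peptides
(3%), and deliberately sub-threshold intensities (5%).  Defects are
applied to the true signal before purity mixing, because leakage happens
in the instrument after the sample state is fixed.  One RNG stream seeded
once makes whole tables reproducible.

**Channel-loading balance.**  Summed-intensity normalization recovers
planted ratios exactly only when the summed qualifying intensity is equal
across channels — precisely the equal-loading assumption that justifies
the normalization in the first place.  The generator therefore finishes
(by default) with a `balance_loading` step: a minimal per-protein
rescaling, weighted by protein abundance, that equalises the qualifying
channel sums without touching any spectrum's ratios.  The adjustment is
proportional to each protein's own channel imbalance, is exactly 1 for
null proteins in the noise-free case, and is infeasible only for
one-sided designs (all planted changes in the same direction), where the
generator warns and skips it.  With balancing off, recovered ratios are
shifted by the intensity-weighted mean spectrum ratio — a bias of a few
percent under the default mixed design, which is exactly what
normalization would face on such a sample in reality.

The generator does **not** simulate chromatography, peptide detectability,
missed cleavages, shared peptides (each PSM carries one accession),
ratio compression from co-isolation interference, or between-replicate
biological variance.  Passing tests on synthetic data therefore
demonstrate the correctness of the arithmetic chain and the operating
characteristics of the thresholds under the stated noise model — not
performance on any particular instrument's output.

## Numerical and design choices

- **NNLS by support enumeration** (not an iterative active-set solver):
  for 4 variables the enumeration is exact and immune to the
  iteration-limit failures iterative solvers exhibit on exact-fit
  boundary spectra.
- **Strict inequalities** where the definitions state them
  (`channel_sum > 20000`), inclusive elsewhere (`log_e <= -2`,
  `ratio >= 1.2`, `ratio <= 0.83`, `p <= 0.01`, `p <= 0.05`).
- **Even-count medians** are midpoints of the two central values
  (`stats::median`).
- **Ties in clustering** are resolved by `stats::hclust`'s deterministic
  merge order, so results are reproducible for a fixed row order, and
  cluster membership is invariant under row permutation up to relabelling.
- **Degenerate inputs**: empty PSM tables quantify to empty tables;
  proteins with no intensity-passing spectra are reported with status
  `insufficient_psm` and an NA ratio rather than dropped silently;
  all-zero spectra are dropped at the ratio stage.

## Problem sizes used by the test suite

The suite exercises exactness on 100-protein noise-free tables
(10 spectra per protein — at least 8 identically-signed spectra are
needed for the tie-corrected signed-rank test to clear $p \le 0.01$ in the
zero-noise limit), the stochastic operating characteristics on ten
500-protein × 20-spectra datasets at noise SD 0.25 (mean DE recall and
false-positive rate among null proteins), and enrichment p-values against
exhaustive draw enumeration for backgrounds up to $N = 12$.  These sizes
were chosen as the smallest at which each property is sharply testable.

## Known limitations

- Protein inference is out of scope: each PSM carries a single accession.
- No FDR estimation at the PSM level and no multiple-testing correction
  at the DE step (the adjusted enrichment p-values are reported but raw
  values define significance), matching the procedure this package
  reproduces.
- The default purity matrix is a plausible stand-in, not a measured
  certificate; quantitative work should supply the lot-specific matrix.
- The sentinel ratio 10 biases medians upward for proteins with many
  reference-channel dropouts; this is inherent to the sentinel rule.
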