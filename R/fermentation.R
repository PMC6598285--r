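# Fermentation end-product stoichiometry: endogenous ethanol after
# deducting exogenous additions, ethanol:acetate molar ratios, ethanol
# weight percentage of liquid end-products, and fold changes vs control.
# Molar masses: ethanol 46.07 g/mol, acetic acid 60.05 g/mol, so 1 mM
# exogenous ethanol corresponds to 46.07 mg/L.

#' Endogenous ethanol yield
#'
#' Ethanol produced by the culture itself: the measured total minus the
#' mass of the exogenously added ethanol (`exogenous_mM` x 46.07 mg/L per
#' mM).  Small negative results (measurement noise around a fully
#' recovered spike) clamp to 0; results more negative than `rel_tol`
#' times the exogenous mass indicate inconsistent inputs and raise an
#' error.
#'
#' @param total_mg_L Measured total ethanol, mg/L.
#' @param exogenous_mM Exogenously added ethanol, mM.
#' @param rel_tol Relative tolerance for the clamp (default 0.02).
#' @return Endogenous ethanol, mg/L.
#' @export
endogenous_ethanol <- function(total_mg_L, exogenous_mM, rel_tol = 0.02) {
  exo_mg_L <- exogenous_mM * M_ETHANOL
  out <- total_mg_L - exo_mg_L
  floor_mg_L <- -rel_tol * pmax(exo_mg_L, 1)
  if (any(out < floor_mg_L))
    stop_validation("total ethanol is well below the exogenous addition; ",
                    "inputs are inconsistent")
  pmax(out, 0)
}

#' Ethanol to acetic acid molar ratio
#'
#' @param ethanol_mg_L Ethanol, mg/L.
#' @param acetate_mg_L Acetic acid, mg/L; must be positive.
#' @return `(ethanol / 46.07) / (acetate / 60.05)`.
#' @export
molar_ratio <- function(ethanol_mg_L, acetate_mg_L) {
  if (any(acetate_mg_L <= 0))
    stop_validation("molar ratio is undefined for zero acetate")
  (ethanol_mg_L / M_ETHANOL) / (acetate_mg_L / M_ACETATE)
}

#' Ethanol weight percentage of liquid end-products
#'
#' @param ethanol_mg_L Ethanol, mg/L.
#' @param acetate_mg_L Acetic acid, mg/L.
#' @return `100 * ethanol / (ethanol + acetate)` (w/w percent).
#' @export
weight_percent_ethanol <- function(ethanol_mg_L, acetate_mg_L) {
  total <- ethanol_mg_L + acetate_mg_L
  if (any(total <= 0))
    stop_validation("weight percentage is undefined when both products are 0")
  100 * ethanol_mg_L / total
}

#' Summarise fermentation stoichiometry per condition
#'
#' Derives, for every condition, the endogenous ethanol yield, molar
#' amounts, the ethanol:acetate molar ratio, the ethanol weight
#' percentage of liquid end-products, and the fold change of the molar
#' ratio versus the control condition.
#'
#' @param records Fermentation `data.frame`; see
#'   [read_fermentation_table()].
#' @param control_mM Which `condition_mM` is the control (default 0).
#' @param rel_tol Passed to [endogenous_ethanol()].
#' @return A `data.frame` with one row per condition: `condition_mM`,
#'   `ethanol_endog_mg_L`, `ethanol_mM`, `acetate_mM`, `molar_ratio`,
#'   `ethanol_weight_pct`, `fold_vs_control`.
#' @export
summarize_stoichiometry <- function(records, control_mM = 0, rel_tol = 0.02) {
  if (!control_mM %in% records$condition_mM)
    stop_validation("control condition ", control_mM, " mM is missing")
  endog <- endogenous_ethanol(records$ethanol_total_mg_L,
                              records$condition_mM, rel_tol = rel_tol)
  out <- data.frame(
    condition_mM = records$condition_mM,
    ethanol_endog_mg_L = endog,
    ethanol_mM = endog / M_ETHANOL,
    acetate_mM = records$acetate_mg_L / M_ACETATE,
    molar_ratio = molar_ratio(endog, records$acetate_mg_L),
    ethanol_weight_pct = weight_percent_ethanol(endog, records$acetate_mg_L),
    stringsAsFactors = FALSE
  )
  control_ratio <- out$molar_ratio[match(control_mM, out$condition_mM)]
  out$fold_vs_control <- out$molar_ratio / control_ratio
  out[order(out$condition_mM), , drop = FALSE]
}
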