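# Standard bolus calculator (the hybrid-system baseline) with guideline
# therapy parameters and Gaussian carbohydrate misestimation.

#' Derive therapy parameters from total daily insulin
#'
#' Guideline rules: CR = 500/TDI (g/U), CF = 1800/TDI (mg/dL per U),
#' target glucose 120 mg/dL. Any component can be overridden.
#'
#' @param tdi total daily insulin (U), > 0
#' @param CR,CF,BG_T overrides of the derived values
#' @return object of class \code{therapy_params}
#' @export
derive_therapy <- function(tdi, CR = 500 / tdi, CF = 1800 / tdi,
                           BG_T = 120) {
  stopifnot(tdi > 0, CR > 0, CF > 0, BG_T > 0)
  structure(list(CR = CR, CF = CF, BG_T = BG_T, TDI = tdi),
            class = "therapy_params")
}

#' Standard bolus calculator
#'
#' \deqn{u = CHO/CR + (BG_k - BG_T)/CF - \widehat{IOB}} clamped at zero.
#'
#' @param cho announced carbohydrates (g), >= 0
#' @param bg_k CGM at bolus time (mg/dL)
#' @param therapy \code{therapy_params}
#' @param iob_hat estimated insulin on board (U)
#' @return bolus (U), >= 0
#' @export
standard_bolus <- function(cho, bg_k, therapy, iob_hat = 0) {
  stopifnot(cho >= 0)
  max(0, cho / therapy$CR + (bg_k - therapy$BG_T) / therapy$CF - iob_hat)
}

#' Gaussian carbohydrate misestimation
#'
#' Returns \code{true_cho * (1 + e)} with \code{e ~ N(mu, sigma)}, redrawn
#' until the result is positive. The default 20\% CV reflects typical adult
#' misestimation.
#'
#' @param true_cho true carbohydrate mass (g), > 0
#' @param mu,sigma error mean and standard deviation (fractional)
#' @return misestimated CHO (g), > 0
#' @export
misestimate_cho <- function(true_cho, mu = 0, sigma = 0.2) {
  stopifnot(true_cho > 0, sigma >= 0)
  for (i in 1:100) {
    out <- true_cho * (1 + stats::rnorm(1, mu, sigma))
    if (out > 0) return(out)
  }
  true_cho * 0.01  # pathological parameters; keep the contract
}
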