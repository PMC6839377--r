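#' Compare a measured dose grid against a planned one
#'
#' One front door over the comparison engines. Builds the lower-dose-
#' threshold mask from the planned dose sampled at the measured positions,
#' then dispatches to gamma evaluation ([gamma_map()]), the MADD normalized
#' dose difference ([ndd_map()]) or divide-and-conquer regional gamma
#' ([dnc_evaluate()]).
#'
#' For `technique = "dnc"` the dose criterion `dd` must be one of the
#' tabulated base criteria (1, 2, 3, 5) and the lower dose threshold is
#' fixed at 10% by the region definitions; `ldt` is ignored.
#'
#' @param reference the planned [dose_grid()] (fine resolution).
#' @param evaluated the measured [dose_grid()] (coarse resolution).
#' @param technique one of `"gamma_global"`, `"gamma_local"`, `"madd_box"`,
#'   `"madd_gamma"`, `"dnc"`.
#' @param dd dose-difference criterion in percent.
#' @param dta distance-to-agreement criterion in mm.
#' @param ldt lower dose threshold in percent of the planned maximum.
#' @param search gamma search mode; see [gamma_map()].
#' @param dnc_normalization normalization for D&C regional gamma.
#' @return a `dose_comparison` (or `dnc_result`).
#' @examples
#' spec <- plan_spec()
#' ref <- generate_plan(spec, seed = 7)
#' meas <- sample_detector(inject_errors(ref, error_model(), seed = 7))
#' compare_dose(ref, meas, "gamma_global", dd = 3, dta = 3, ldt = 10)
#' @export
compare_dose <- function(reference, evaluated,
                         technique = c("gamma_global", "gamma_local",
                                       "madd_box", "madd_gamma", "dnc"),
                         dd = 3, dta = 3, ldt = 10,
                         search = c("optimized", "exhaustive"),
                         dnc_normalization = c("local", "global")) {
  technique <- match.arg(technique)
  search <- match.arg(search)
  if (technique == "dnc") {
    return(dnc_evaluate(reference, evaluated, dnc_criteria(dd, dta),
                        normalization = match.arg(dnc_normalization),
                        search = search))
  }
  mask <- comparison_mask(reference, evaluated, ldt)
  if (technique %in% c("gamma_global", "gamma_local")) {
    norm <- sub("gamma_", "", technique)
    gamma_map(reference, evaluated, criteria_pair(dd, dta, norm), mask,
              search = search)
  } else {
    mode <- sub("madd_", "", technique)
    madd <- madd_map(reference, evaluated, criteria_pair(dd, dta, "global"),
                     mode = mode)
    ndd_map(reference, evaluated, madd, mask)
  }
}
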