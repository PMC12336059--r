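#' Davis-type BOLD forward-model parameters
#'
#' `alpha` is the flow/volume power-law exponent and `beta` the exponent
#' capturing field strength and voxel-size effects on the extravascular
#' signal; `cbv0` is baseline venous blood volume (fraction) and `k` a
#' lumped proportionality constant, unidentifiable from CVR data alone and
#' fixed at 1 unless calibrated.  Defaults `alpha = 0.38`, `beta = 1.5` are
#' the conventional 3 T values, not study-specific estimates.
#'
#' @param alpha Power-law exponent (unitless).
#' @param beta Field/voxel exponent (unitless).
#' @param cbv0 Baseline venous CBV fraction.
#' @param k Proportionality constant.
#' @return A `davis_params` list.
#' @export
davis_params <- function(alpha = 0.38, beta = 1.5, cbv0 = 0.05, k = 1) {
  stopifnot(cbv0 > 0, k > 0)
  structure(list(alpha = alpha, beta = beta, cbv0 = cbv0, k = k),
            class = "davis_params")
}

#' Baseline/hypercapnia hemodynamic state
#'
#' @param cbf0 Room-air CBF, ml/100 g/min.
#' @param cbf_hc Hypercapnic CBF, ml/100 g/min.
#' @param yv0 Baseline venous oxygenation, fraction; sets the baseline
#'   deoxyhemoglobin level `dhb0 = 1 - yv0` unless `dhb0` is supplied.
#' @param delta_etco2 EtCO2 change driving the response, mmHg.
#' @param dhb0 Baseline deoxyhemoglobin (proportional units); overrides
#'   `1 - yv0` when given.
#' @return A `hemo_state` list.
#' @export
hemo_state <- function(cbf0, cbf_hc, yv0 = NULL, delta_etco2 = NA_real_,
                       dhb0 = NULL) {
  if (cbf0 <= 0 || cbf_hc <= 0) stop("CBF values must be positive", call. = FALSE)
  if (is.null(dhb0)) {
    if (is.null(yv0)) stop("supply yv0 or dhb0", call. = FALSE)
    if (yv0 <= 0 || yv0 >= 1) stop("yv0 must be in (0, 1)", call. = FALSE)
    dhb0 <- 1 - yv0
  }
  if (dhb0 <= 0) stop("dhb0 must be positive", call. = FALSE)
  structure(list(cbf0 = cbf0, cbf_hc = cbf_hc, yv0 = yv0, dhb0 = dhb0,
                 delta_etco2 = delta_etco2),
            class = "hemo_state")
}

#' Fractional hypercapnic BOLD response (Davis-type model)
#'
#' `dBOLD/BOLD0 = k * cbv0 * dhb0^beta * (1 - (cbf_hc/cbf0)^(alpha - beta))`.
#' With `alpha < beta` the response is positive for a flow increase and
#' monotone increasing in the flow ratio.
#'
#' @param state A [hemo_state()].
#' @param p A [davis_params()].
#' @return Fractional BOLD signal change (unitless).
#' @export
bold_response <- function(state, p = davis_params()) {
  r <- state$cbf_hc / state$cbf0
  p$k * p$cbv0 * state$dhb0^p$beta * (1 - r^(p$alpha - p$beta))
}

#' Predicted BOLD-CVR from a hemodynamic state
#'
#' @param state A [hemo_state()] with `delta_etco2` set.
#' @param p A [davis_params()].
#' @return Predicted BOLD-CVR in %/mmHg.
#' @export
predicted_bold_cvr <- function(state, p = davis_params()) {
  if (!is.finite(state$delta_etco2) || state$delta_etco2 <= 0)
    stop("delta_etco2 must be positive", call. = FALSE)
  bold_response(state, p) * 100 / state$delta_etco2
}

#' How basal-oxygenation shifts attenuate the BOLD-CVR change
#'
#' Compares the percent change (pre - post, positive = reduction) of
#' CBF-CVR and of the model-predicted BOLD-CVR between two states.  When
#' the post state combines a weaker fractional CBF response with a lower
#' baseline venous oxygenation (more deoxyhemoglobin), the rise in `dhb0`
#' counteracts part -- or all -- of the flow-driven BOLD-CVR loss, so the
#' signed BOLD-CVR reduction is strictly smaller than the CBF-CVR
#' reduction.
#'
#' @param pre,post [hemo_state()]s with `delta_etco2` set.
#' @param p A [davis_params()].
#' @return List with `cbf_cvr_change` and `bold_cvr_change`, both in
#'   percent (positive = reduction), plus the per-state CVR values.
#' @export
attenuation_analysis <- function(pre, post, p = davis_params()) {
  cbf_cvr <- function(s) ((s$cbf_hc / s$cbf0 - 1) * 100) / s$delta_etco2
  cvr_pre <- cbf_cvr(pre); cvr_post <- cbf_cvr(post)
  b_pre <- predicted_bold_cvr(pre, p); b_post <- predicted_bold_cvr(post, p)
  list(
    cbf_cvr_change = (cvr_pre - cvr_post) / cvr_pre * 100,
    bold_cvr_change = (b_pre - b_post) / b_pre * 100,
    cbf_cvr = c(pre = cvr_pre, post = cvr_post),
    bold_cvr = c(pre = b_pre, post = b_post)
  )
}
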