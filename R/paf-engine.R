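#' Population attributable fraction for a categorical exposure
#'
#' Computes
#' `PAF = (sum(P_i RR_i) - sum(P*_i RR_i)) / sum(P_i RR_i)`,
#' where `P_i` are the observed level proportions and `P*` is the
#' counterfactual that places the whole population at the
#' theoretical-minimum-risk level (so `sum(P*_i RR_i) = 1` because the TMREL
#' relative risk is 1). Algebraically this equals `1 - 1/sum(P_i RR_i)`.
#'
#' @param dist an [exposure_distribution()].
#' @param rr a categorical [relative_risk_set()] whose levels align with
#'   `dist$levels`.
#' @return PAF as a fraction in `(-Inf, 1)`. Negative values (net-protective
#'   exposure patterns) are returned as-is with a warning, never clamped.
#' @export
#' @examples
#' d <- exposure_distribution("x", "men", c("low", "high"), c(0.5, 0.5))
#' r <- relative_risk_set("x", "site", "men", "categorical",
#'                        rr = c(1, 2), levels = c("low", "high"))
#' paf_categorical(d, r) # 1/3
paf_categorical <- function(dist, rr) {
  if (!inherits(dist, "exposure_distribution")) {
    abort_paf("`dist` must be an exposure_distribution")
  }
  if (!inherits(rr, "relative_risk_set") || rr$form != "categorical") {
    abort_paf("`rr` must be a categorical relative_risk_set")
  }
  if (!identical(dist$levels, rr$levels)) {
    abort_paf("levels of distribution (%s) and RR set (%s) are not aligned",
              paste(dist$levels, collapse = ","),
              paste(rr$levels, collapse = ","))
  }
  if (dist$tmrel_level != rr$tmrel_level) {
    abort_paf("TMREL level of distribution and RR set disagree")
  }
  observed <- sum(dist$proportions * rr$rr)
  pstar <- replace(numeric(length(dist$levels)), dist$tmrel_level, 1)
  counterfactual <- sum(pstar * rr$rr) # = 1 by the TMREL constraint
  paf <- (observed - counterfactual) / observed
  if (paf < -1e-12) {
    warning(sprintf("negative PAF (%.4f) for %s/%s: exposure pattern is net protective",
                    paf, dist$exposure_id, rr$cancer_site), call. = FALSE)
  }
  paf
}

#' Population attributable fraction for a continuous exposure (BMI)
#'
#' Computes
#' `PAF = (int RR(x) P(x) dx - int RR(x) P*(x) dx) / int RR(x) P(x) dx`,
#' where `P` is the observed BMI density `Normal(mean, sd)`, `P*` the
#' counterfactual `Normal(cf_mean, cf_sd)` (default mean 22 kg/m², sd 1), and
#' `RR(x)` a [dose_response_model()]. Both densities are truncated to the
#' integration range and renormalised; the integrals are evaluated by
#' Gauss-Legendre quadrature.
#'
#' @param dist a [continuous_distribution()].
#' @param model a [dose_response_model()].
#' @param range integration range in kg/m², default `c(10, 60)` (covers
#'   plausible adult BMI).
#' @param nodes number of Gauss-Legendre nodes, default 512.
#' @return PAF as a fraction in `(-Inf, 1)`; negative values warn as for
#'   [paf_categorical()].
#' @export
paf_continuous <- function(dist, model, range = c(10, 60), nodes = 512) {
  if (!inherits(dist, "continuous_distribution")) {
    abort_paf("`dist` must be a continuous_distribution")
  }
  if (!inherits(model, "dose_response_model")) {
    abort_paf("`model` must be a dose_response_model")
  }
  # RR(x) is identically 1 below the TMREL and smooth above it; integrating
  # across the kink would spoil Gauss-Legendre convergence, so the
  # below-TMREL mass enters analytically and quadrature covers only the
  # smooth upper piece
  split <- min(max(model$tmrel, range[1]), range[2])
  gl <- pracma::gaussLegendre(nodes, split, range[2])
  rrx <- rr_at_dose(gl$x, model)
  if (any(!is.finite(rrx))) {
    abort_paf(paste0("dose-response is non-finite on the integration range; ",
                     "set `cap_dose` to saturate extreme relative risks"))
  }
  expected_rr <- function(m, s) {
    z <- pnorm(range[2], m, s) - pnorm(range[1], m, s)
    if (z <= 0) abort_paf("density has no mass on the integration range")
    mass_below <- pnorm(split, m, s) - pnorm(range[1], m, s)
    (mass_below + sum(gl$w * rrx * dnorm(gl$x, m, s))) / z
  }
  observed <- expected_rr(dist$mean, dist$sd)
  counterfactual <- expected_rr(dist$cf_mean, dist$cf_sd)
  paf <- (observed - counterfactual) / observed
  if (paf < -1e-12) {
    warning(sprintf("negative PAF (%.4f) for %s: observed BMI below counterfactual",
                    paf, dist$exposure_id), call. = FALSE)
  }
  paf
}

#' Combine PAFs across independent risk factors
#'
#' Under the assumption that risk factors act independently (no statistical
#' interaction), the combined fraction is
#' `1 - prod(1 - PAF_i)`. The result is order-invariant and, for
#' non-negative inputs, at least as large as every component yet always
#' below 1.
#'
#' @param pafs numeric vector of fractions, each `< 1`.
#' @return combined PAF as a fraction.
#' @export
#' @examples
#' combine_pafs(c(0.5, 0.5)) # 0.75
combine_pafs <- function(pafs) {
  assert_number(pafs, "pafs")
  if (length(pafs) == 0) abort_paf("`pafs` must contain at least one value")
  if (any(pafs >= 1)) abort_paf("every PAF must be < 1")
  1 - prod(1 - pafs)
}
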