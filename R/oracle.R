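# Ground-truth oracle arithmetic, coded independently of the PAF engine.
#
# These functions recompute the attributable-fraction quantities along a
# different implementation path (explicit accumulation loops; adaptive
# quadrature instead of fixed Gauss-Legendre) so that generator ground truth
# and engine output can be cross-checked without sharing code.

#' Oracle: categorical PAF from raw vectors
#'
#' Independent re-derivation of the categorical attributable fraction from
#' bare proportion and relative-risk vectors, used to cross-check
#' [paf_categorical()] and to label synthetic ground truth.
#'
#' @param proportions level proportions summing to 1.
#' @param rr level relative risks; `rr[tmrel_level]` must be 1.
#' @param tmrel_level index of the theoretical-minimum-risk level.
#' @return PAF fraction.
#' @export
oracle_paf_categorical <- function(proportions, rr, tmrel_level = 1L) {
  stopifnot(length(proportions) == length(rr),
            abs(sum(proportions) - 1) < 1e-9,
            abs(rr[tmrel_level] - 1) < 1e-12)
  num_obs <- 0
  num_cf <- 0
  for (i in seq_along(rr)) {
    num_obs <- num_obs + proportions[i] * rr[i]
    num_cf <- num_cf + (if (i == tmrel_level) 1 else 0) * rr[i]
  }
  (num_obs - num_cf) / num_obs
}

#' Oracle: continuous PAF by adaptive quadrature
#'
#' Independent evaluation of the continuous attributable fraction using
#' `stats::integrate()` over the truncated normal densities, used to
#' cross-check [paf_continuous()]'s fixed-node Gauss-Legendre result.
#'
#' @param mean,sd observed BMI mean and sd.
#' @param model a [dose_response_model()].
#' @param cf_mean,cf_sd counterfactual mean and sd.
#' @param range truncation range, matching the engine default.
#' @return PAF fraction.
#' @export
oracle_paf_continuous <- function(mean, sd, model, cf_mean = 22, cf_sd = 1,
                                  range = c(10, 60)) {
  split <- min(max(model$tmrel, range[1]), range[2])
  expected_rr <- function(m, s) {
    mass <- pnorm(range[2], m, s) - pnorm(range[1], m, s)
    upper <- integrate(function(x) rr_at_dose(x, model) * dnorm(x, m, s),
                       split, range[2], rel.tol = 1e-11,
                       subdivisions = 500L)$value
    (pnorm(split, m, s) - pnorm(range[1], m, s) + upper) / mass
  }
  obs <- expected_rr(mean, sd)
  cf <- expected_rr(cf_mean, cf_sd)
  (obs - cf) / obs
}

#' Oracle: combined PAF by sequential complement multiplication
#'
#' @param pafs numeric vector of fractions `< 1`.
#' @return combined PAF fraction.
#' @export
oracle_combined_paf <- function(pafs) {
  stopifnot(all(pafs < 1))
  surviving <- 1
  for (p in pafs) surviving <- surviving * (1 - p)
  1 - surviving
}
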