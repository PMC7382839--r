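#' Categorical exposure distribution
#'
#' Holds the level proportions of one categorical lifestyle exposure for one
#' sex, together with the index of the theoretical-minimum-risk exposure level
#' (TMREL) — the counterfactual level to which the whole population is shifted
#' when a population attributable fraction is computed.
#'
#' @param exposure_id character scalar identifying the exposure
#'   (e.g. `"smoking"`, `"alcohol"`).
#' @param sex `"men"` or `"women"`.
#' @param levels character vector of ordered level labels.
#' @param proportions numeric vector of level proportions; must sum to 1
#'   within `1e-9`.
#' @param tmrel_level integer index into `levels` marking the TMREL.
#' @return An object of class `exposure_distribution`.
#' @export
#' @examples
#' exposure_distribution("smoking", "men",
#'   levels = c("never", "former", "current"),
#'   proportions = c(0.377, 0.289, 0.334), tmrel_level = 1)
exposure_distribution <- function(exposure_id, sex, levels, proportions,
                                  tmrel_level = 1L) {
  stopifnot(is.character(exposure_id), length(exposure_id) == 1)
  sex <- match.arg(sex, c("men", "women"))
  if (length(levels) != length(proportions)) {
    abort_paf("`levels` and `proportions` must have equal length")
  }
  assert_number(proportions, "proportions", lower = 0, upper = 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort_paf("proportions for exposure '%s' (%s) sum to %.6f, not 1",
              exposure_id, sex, sum(proportions))
  }
  tmrel_level <- as.integer(tmrel_level)
  if (tmrel_level < 1L || tmrel_level > length(levels)) {
    abort_paf("`tmrel_level` must index into `levels`")
  }
  structure(
    list(exposure_id = exposure_id, sex = sex,
         levels = as.character(levels), proportions = as.numeric(proportions),
         tmrel_level = tmrel_level),
    class = "exposure_distribution"
  )
}

#' @export
print.exposure_distribution <- function(x, ...) {
  cat(sprintf("<exposure_distribution> %s (%s)\n", x$exposure_id, x$sex))
  lab <- ifelse(seq_along(x$levels) == x$tmrel_level,
                paste0(x$levels, " [TMREL]"), x$levels)
  for (i in seq_along(lab)) {
    cat(sprintf("  %-28s %6.1f%%\n", lab[i], 100 * x$proportions[i]))
  }
  invisible(x)
}

#' Continuous exposure distribution (BMI)
#'
#' The observed body-mass-index distribution for one sex, summarised as a
#' normal mean and standard deviation, paired with the counterfactual
#' theoretical-minimum-risk distribution (default mean 22 kg/m², sd 1 kg/m²).
#'
#' @param exposure_id character scalar, conventionally `"high_bmi"`.
#' @param sex `"men"` or `"women"`.
#' @param mean,sd observed BMI mean and standard deviation in kg/m²; `sd > 0`.
#' @param cf_mean,cf_sd counterfactual mean and sd in kg/m²; `cf_sd > 0`.
#' @return An object of class `continuous_distribution`.
#' @export
continuous_distribution <- function(exposure_id = "high_bmi", sex,
                                    mean, sd, cf_mean = 22, cf_sd = 1) {
  sex <- match.arg(sex, c("men", "women"))
  assert_number(mean, "mean", lower = 0)
  if (!is.numeric(sd) || sd <= 0) abort_paf("`sd` must be > 0")
  if (!is.numeric(cf_sd) || cf_sd <= 0) abort_paf("`cf_sd` must be > 0")
  structure(
    list(exposure_id = exposure_id, sex = sex,
         mean = as.numeric(mean), sd = as.numeric(sd),
         cf_mean = as.numeric(cf_mean), cf_sd = as.numeric(cf_sd)),
    class = "continuous_distribution"
  )
}

#' @export
print.continuous_distribution <- function(x, ...) {
  cat(sprintf("<continuous_distribution> %s (%s)\n", x$exposure_id, x$sex))
  cat(sprintf("  observed:       mean %.2f, sd %.2f kg/m2\n", x$mean, x$sd))
  cat(sprintf("  counterfactual: mean %.2f, sd %.2f kg/m2\n",
              x$cf_mean, x$cf_sd))
  invisible(x)
}

#' Relative-risk set for one exposure-cancer-sex pair
#'
#' Either a vector of level-specific relative risks aligned with an
#' [exposure_distribution()]'s levels (`form = "categorical"`, RR forced to 1
#' at the TMREL level), or a per-unit relative risk for a continuous exposure
#' (`form = "per_unit"`, RR per 1 kg/m² BMI increase) to be expanded through a
#' dose-response model.
#'
#' @param exposure_id,cancer_site,sex identifiers; `sex` is `"men"` or
#'   `"women"`.
#' @param form `"categorical"` or `"per_unit"`.
#' @param rr for `"categorical"`: numeric vector of relative risks, one per
#'   exposure level. Ignored for `"per_unit"`.
#' @param levels character vector of level labels matching `rr` (categorical
#'   form only).
#' @param tmrel_level index of the TMREL level; `rr[tmrel_level]` must be 1.
#' @param rr_per_unit relative risk per unit dose (per-unit form only).
#' @param model_id dose-response model id for the per-unit form; see
#'   [dose_response_model()].
#' @return An object of class `relative_risk_set`.
#' @export
relative_risk_set <- function(exposure_id, cancer_site, sex,
                              form = c("categorical", "per_unit"),
                              rr = NULL, levels = NULL, tmrel_level = 1L,
                              rr_per_unit = NULL, model_id = "log_linear") {
  form <- match.arg(form)
  sex <- match.arg(sex, c("men", "women"))
  if (form == "categorical") {
    if (is.null(rr)) abort_paf("categorical form requires `rr`")
    assert_number(rr, "rr")
    if (any(rr <= 0)) abort_paf("all relative risks must be > 0")
    if (is.null(levels)) levels <- paste0("level_", seq_along(rr))
    if (length(levels) != length(rr)) {
      abort_paf("`levels` and `rr` must have equal length")
    }
    tmrel_level <- as.integer(tmrel_level)
    if (abs(rr[tmrel_level] - 1) > 1e-12) {
      abort_paf("RR at the TMREL level must equal 1 (got %.4f)",
                rr[tmrel_level])
    }
  } else {
    if (is.null(rr_per_unit)) abort_paf("per_unit form requires `rr_per_unit`")
    assert_number(rr_per_unit, "rr_per_unit", lower = 0)
    if (rr_per_unit < 1) {
      warning(sprintf(
        "rr_per_unit = %.4f < 1 for %s/%s: protective dose-response",
        rr_per_unit, exposure_id, cancer_site), call. = FALSE)
    }
  }
  structure(
    list(exposure_id = exposure_id, cancer_site = cancer_site, sex = sex,
         form = form, rr = if (form == "categorical") as.numeric(rr),
         levels = if (form == "categorical") as.character(levels),
         tmrel_level = if (form == "categorical") tmrel_level,
         rr_per_unit = if (form == "per_unit") as.numeric(rr_per_unit),
         model_id = if (form == "per_unit") model_id),
    class = "relative_risk_set"
  )
}

#' @export
print.relative_risk_set <- function(x, ...) {
  cat(sprintf("<relative_risk_set> %s -> %s (%s, %s)\n",
              x$exposure_id, x$cancer_site, x$sex, x$form))
  if (x$form == "categorical") {
    cat("  RR:", paste(sprintf("%s=%.3f", x$levels, x$rr), collapse = ", "),
        "\n")
  } else {
    cat(sprintf("  RR per unit: %.4f (%s)\n", x$rr_per_unit, x$model_id))
  }
  invisible(x)
}
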