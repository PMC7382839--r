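#' Canonical exposure level sets
#'
#' Ordered level labels for each categorical lifestyle exposure, TMREL
#' (theoretical-minimum-risk exposure level) first. These labels align the
#' survey derivation, the bundled prevalence fixture, and relative-risk sets.
#'
#' @param exposure_id optional exposure id; if given, returns that exposure's
#'   level vector, otherwise the full named list.
#' @return A named list of character vectors, or one character vector.
#' @export
#' @examples
#' exposure_levels("smoking")
exposure_levels <- function(exposure_id = NULL) {
  lv <- list(
    alcohol           = c("abstainer", "light", "moderate", "heavy"),
    fruit_veg         = c("ge400", "300_399", "200_299", "100_199", "0_99"),
    fruit             = c("ge250", "200_249", "150_199", "100_149", "50_99",
                          "0_49"),
    physical_activity = c("ge8000", "4000_7999", "600_3999", "lt600"),
    passive_smoking   = c("no", "yes"),
    smoking           = c("never", "former", "current")
  )
  if (is.null(exposure_id)) return(lv)
  if (!exposure_id %in% names(lv)) {
    abort_paf("unknown categorical exposure '%s'", exposure_id)
  }
  lv[[exposure_id]]
}

#' MET values by activity domain
#'
#' Metabolic equivalents of task assigned to each Global Physical Activity
#' Questionnaire (GPAQ) domain when scoring activity volume: 4 for active
#' transport (walking and cycling), 3.8/7.8 for moderate/vigorous occupational
#' activity, and 3/6 for moderate/vigorous recreational activity.
#'
#' @return Named numeric vector of MET multipliers.
#' @export
met_values <- function() {
  c(transport = 4, occupational_moderate = 3.8, occupational_vigorous = 7.8,
    recreational_moderate = 3, recreational_vigorous = 6)
}

#' Grams of pure alcohol per day
#'
#' One standard drink (beer, glass of wine, or shot of spirits) is assumed to
#' contain 12.5 g of pure alcohol.
#'
#' @param drinks_per_day non-negative number of drinks on a regular day.
#' @return grams of pure alcohol per day (vectorised).
#' @export
#' @examples
#' grams_alcohol_per_day(4) # 50 g/day, the heavy-drinking threshold
grams_alcohol_per_day <- function(drinks_per_day) {
  assert_number(drinks_per_day, "drinks_per_day", lower = 0)
  drinks_per_day * 12.5
}

#' Categorize daily alcohol intake
#'
#' Bands partition `[0, Inf)`: abstainer exactly 0 g/day (the TMREL), light
#' `(0, 12.5]`, moderate `(12.5, 50)`, heavy `[50, Inf)`. The published band
#' labels ("1-12.5", "12.6-49.9") leave small gaps on the gram scale; the
#' half-open convention here covers them while keeping every printed cutpoint
#' in its printed band. Intakes in `(0, 1)` g/day, unassigned by the printed
#' labels, fall in the light band.
#'
#' @param g_per_day non-negative grams of pure alcohol per day.
#' @return factor with levels `exposure_levels("alcohol")` (vectorised).
#' @export
categorize_alcohol <- function(g_per_day) {
  assert_number(g_per_day, "g_per_day", lower = 0)
  lv <- exposure_levels("alcohol")
  lab <- ifelse(g_per_day == 0, "abstainer",
         ifelse(g_per_day <= 12.5, "light",
         ifelse(g_per_day < 50, "moderate", "heavy")))
  factor(lab, levels = lv)
}

#' Average grams of fruit and/or vegetables per day
#'
#' Consumption is reported as servings per day on days when eaten and the
#' number of eating days per week; one serving is 80 g. The weekly average is
#' `servings_per_day * 80 * days_per_week / 7`.
#'
#' @param servings_per_day non-negative servings on an eating day.
#' @param days_per_week eating days per week, in `[0, 7]`.
#' @return grams per day, averaged over the week (vectorised).
#' @export
#' @examples
#' fruit_veg_grams_per_day(5, 7) # 400 g/day, the TMREL band floor
fruit_veg_grams_per_day <- function(servings_per_day, days_per_week) {
  assert_number(servings_per_day, "servings_per_day", lower = 0)
  assert_number(days_per_week, "days_per_week", lower = 0, upper = 7)
  servings_per_day * 80 * days_per_week / 7
}

#' Categorize combined fruit-and-vegetable intake
#'
#' Left-closed 100 g bands: `[400, Inf)` (TMREL), `[300, 400)`, `[200, 300)`,
#' `[100, 200)`, `[0, 100)`.
#'
#' @param g_per_day non-negative grams per day.
#' @return factor with levels `exposure_levels("fruit_veg")` (vectorised).
#' @export
categorize_fruit_veg <- function(g_per_day) {
  assert_number(g_per_day, "g_per_day", lower = 0)
  canonical_bands(g_per_day, c(0, 100, 200, 300, 400, Inf), "fruit_veg")
}

#' Categorize fruit-only intake
#'
#' Left-closed 50 g bands: `[250, Inf)` (TMREL), `[200, 250)`, `[150, 200)`,
#' `[100, 150)`, `[50, 100)`, `[0, 50)`.
#'
#' @param g_per_day non-negative grams per day.
#' @return factor with levels `exposure_levels("fruit")` (vectorised).
#' @export
categorize_fruit <- function(g_per_day) {
  assert_number(g_per_day, "g_per_day", lower = 0)
  canonical_bands(g_per_day, c(0, 50, 100, 150, 200, 250, Inf), "fruit")
}

#' Total physical activity in MET-minutes per week
#'
#' Sums `MET(domain) * minutes_per_day * days_per_week` over GPAQ activity
#' items. Domains and their MET multipliers are those of [met_values()].
#'
#' @param items data frame with columns `domain`, `days_per_week`
#'   (in `[0, 7]`) and `minutes_per_day` (non-negative): one row per reported
#'   activity of one respondent.
#' @return MET-minutes per week (scalar).
#' @export
#' @examples
#' met_minutes_per_week(data.frame(
#'   domain = "transport", days_per_week = 5, minutes_per_day = 30)) # 600
met_minutes_per_week <- function(items) {
  if (nrow(items) == 0) return(0)
  mets <- met_values()
  unknown <- setdiff(unique(items$domain), names(mets))
  if (length(unknown) > 0) {
    abort_paf("unknown activity domain(s): %s",
              paste(unknown, collapse = ", "))
  }
  assert_number(items$days_per_week, "days_per_week", lower = 0, upper = 7)
  assert_number(items$minutes_per_day, "minutes_per_day", lower = 0)
  sum(mets[items$domain] * items$minutes_per_day * items$days_per_week)
}

#' Categorize physical activity volume
#'
#' Left-closed bands in MET-min/week: `[8000, Inf)` (TMREL), `[4000, 8000)`,
#' `[600, 4000)`, `[0, 600)`.
#'
#' @param met_min_per_week non-negative MET-minutes per week.
#' @return factor with levels `exposure_levels("physical_activity")`
#'   (vectorised).
#' @export
categorize_activity <- function(met_min_per_week) {
  assert_number(met_min_per_week, "met_min_per_week", lower = 0)
  canonical_bands(met_min_per_week, c(0, 600, 4000, 8000, Inf),
                  "physical_activity")
}

# left-closed banding relabelled into canonical TMREL-first level order
canonical_bands <- function(x, breaks, exposure_id) {
  lv <- exposure_levels(exposure_id)
  factor(as.character(
    cut(x, breaks = breaks, right = FALSE, labels = rev(lv))), levels = lv)
}

# wide activity columns carried by a survey record tibble
activity_columns <- function() {
  doms <- names(met_values())
  c(paste0(doms, "_days"), paste0(doms, "_min_per_day"))
}

# vectorised MET-min/week over wide survey columns
survey_met_minutes <- function(records) {
  mets <- met_values()
  total <- rep(0, nrow(records))
  for (d in names(mets)) {
    total <- total +
      mets[[d]] * records[[paste0(d, "_days")]] *
      records[[paste0(d, "_min_per_day")]]
  }
  total
}

# derive one record set's categorized exposure (factor), or BMI values
derive_exposure <- function(records, exposure_id) {
  switch(exposure_id,
    alcohol = categorize_alcohol(
      grams_alcohol_per_day(records$drinks_per_day)),
    fruit_veg = categorize_fruit_veg(fruit_veg_grams_per_day(
      records$fv_servings_per_day, records$fv_days_per_week)),
    fruit = categorize_fruit(fruit_veg_grams_per_day(
      records$fruit_servings_per_day, records$fruit_days_per_week)),
    physical_activity = categorize_activity(survey_met_minutes(records)),
    smoking = factor(records$smoking_status,
                     levels = exposure_levels("smoking")),
    passive_smoking = factor(records$home_smoke_exposure,
                             levels = exposure_levels("passive_smoking")),
    high_bmi = records$weight / records$height^2,
    abort_paf("unknown exposure '%s'", exposure_id)
  )
}

#' Estimate exposure prevalence from survey records
#'
#' Computes survey-weighted level proportions (or, for BMI, the weighted mean
#' and standard deviation of weight/height²) by sex. Weights are normalised
#' within sex, so prevalence is invariant to uniform weight rescaling.
#' Passive smoking is defined among never-smokers only; records of former and
#' current smokers are excluded from that exposure's denominator.
#'
#' @param records tibble of survey records as produced by [generate_survey()]
#'   or read from CSV; see that function for the column layout. Must contain
#'   `sex` and `survey_weight`.
#' @param exposure_id one of `"alcohol"`, `"fruit_veg"`, `"fruit"`,
#'   `"physical_activity"`, `"smoking"`, `"passive_smoking"`, `"high_bmi"`.
#' @return Named list (by sex present in `records`) of
#'   [exposure_distribution()] objects, or [continuous_distribution()] for
#'   `"high_bmi"`.
#' @export
estimate_prevalence <- function(records, exposure_id) {
  if (nrow(records) == 0) abort_paf("no survey records supplied")
  if (any(records$survey_weight <= 0)) {
    abort_paf("survey weights must be positive")
  }
  if (exposure_id == "passive_smoking") {
    records <- records[records$smoking_status == "never", , drop = FALSE]
    if (nrow(records) == 0) {
      abort_paf("passive smoking is defined among never-smokers only; none found")
    }
  }
  out <- list()
  for (s in intersect(c("men", "women"), unique(records$sex))) {
    rec <- records[records$sex == s, , drop = FALSE]
    w <- rec$survey_weight / sum(rec$survey_weight)
    if (exposure_id == "high_bmi") {
      bmi <- derive_exposure(rec, "high_bmi")
      m <- sum(w * bmi)
      out[[s]] <- continuous_distribution(
        sex = s, mean = m, sd = sqrt(sum(w * (bmi - m)^2)))
    } else {
      cat_ <- derive_exposure(rec, exposure_id)
      if (anyNA(cat_)) abort_paf("unresolvable exposure values in records")
      prop <- vapply(levels(cat_), function(l) sum(w[cat_ == l]), numeric(1))
      out[[s]] <- exposure_distribution(
        exposure_id, s, levels = levels(cat_),
        proportions = prop / sum(prop), tmrel_level = 1L)
    }
  }
  out
}
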