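#' Path to a bundled fixture
#'
#' The package ships the published Chilean 2018 tables as plain CSV under
#' `extdata`: `table1_prevalence.csv` (exposure level proportions by sex),
#' `table1_bmi_synthetic_sd.csv` (BMI means with synthetic stand-in sds —
#' the source tables print confidence intervals of the mean, not population
#' sds), `table2_cases.csv` / `table3_deaths.csv` (per-exposure PAF columns
#' and totals), `occurrence_totals.csv`, `subtype_splits.csv` and
#' `site_exposure_map.csv`.
#'
#' @param name fixture file name.
#' @return absolute path to the installed fixture.
#' @export
#' @examples
#' paf_fixture_path("table2_cases.csv")
paf_fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "pafburden")
  if (p == "") abort_paf("no bundled fixture named '%s'", name)
  p
}

read_checked_csv <- function(path, required, col_types) {
  if (!file.exists(path)) abort_paf("file not found: %s", path)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort_paf("%s: missing column(s) %s", basename(path),
              paste(missing_cols, collapse = ", "))
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read a categorical prevalence table
#'
#' Expects columns `exposure`, `sex`, `level`, `level_order`, `proportion`,
#' `is_tmrel`. Within each exposure/sex stratum the proportions must sum to 1
#' within `tol` (published tables carry 0.1-percentage-point rounding, so
#' sums of 0.999 occur); they are renormalised to sum exactly to 1.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @param tol allowed deviation of each stratum's proportion sum from 1.
#' @return Named list (by exposure) of named lists (by sex) of
#'   [exposure_distribution()] objects.
#' @export
read_prevalence_table <- function(path = paf_fixture_path("table1_prevalence.csv"),
                                  tol = 0.005) {
  df <- read_checked_csv(
    path, c("exposure", "sex", "level", "level_order", "proportion",
            "is_tmrel"),
    readr::cols(exposure = "c", sex = "c", level = "c", level_order = "i",
                proportion = "d", is_tmrel = "i"))
  if (any(df$proportion < 0 | df$proportion > 1)) {
    abort_paf("proportions must lie in [0, 1]")
  }
  out <- list()
  for (ex in unique(df$exposure)) {
    out[[ex]] <- list()
    for (s in unique(df$sex[df$exposure == ex])) {
      sub <- df[df$exposure == ex & df$sex == s, ]
      sub <- sub[order(sub$level_order), ]
      tot <- sum(sub$proportion)
      if (abs(tot - 1) > tol) {
        abort_paf("proportions for %s (%s) sum to %.4f", ex, s, tot)
      }
      tm <- which(sub$is_tmrel == 1)
      if (length(tm) != 1) {
        abort_paf("%s (%s): exactly one level must be flagged TMREL", ex, s)
      }
      out[[ex]][[s]] <- exposure_distribution(
        ex, s, levels = sub$level, proportions = sub$proportion / tot,
        tmrel_level = tm)
    }
  }
  out
}

#' Read the continuous BMI distribution table
#'
#' Expects columns `exposure`, `sex`, `mean`, `sd`, `cf_mean`, `cf_sd`. The
#' bundled fixture's sds are synthetic stand-ins (flagged by its
#' `sd_source` column): the source tables print confidence intervals of the
#' mean, not population standard deviations.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return Named list (by sex) of [continuous_distribution()] objects.
#' @export
read_bmi_table <- function(path = paf_fixture_path("table1_bmi_synthetic_sd.csv")) {
  df <- read_checked_csv(
    path, c("exposure", "sex", "mean", "sd", "cf_mean", "cf_sd"),
    readr::cols_only(exposure = "c", sex = "c", mean = "d", sd = "d",
                     cf_mean = "d", cf_sd = "d"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[df$sex[i]]] <- continuous_distribution(
      df$exposure[i], df$sex[i], mean = df$mean[i], sd = df$sd[i],
      cf_mean = df$cf_mean[i], cf_sd = df$cf_sd[i])
  }
  out
}

#' Read a printed PAF table (reproduction-path input)
#'
#' Expects columns `exposure`, `site`, `sex`, `total`, `paf_percent`
#' (an `attributable` column, if present, is carried through). PAFs are in
#' percent as printed; totals are non-negative counts.
#'
#' @param path CSV path, e.g. `paf_fixture_path("table2_cases.csv")`.
#' @return tibble.
#' @export
read_paf_table <- function(path) {
  df <- read_checked_csv(
    path, c("exposure", "site", "sex", "total", "paf_percent"),
    readr::cols(exposure = "c", sex = "c", site = "c", total = "d",
                paf_percent = "d", .default = "d"))
  if (any(df$total < 0)) abort_paf("`total` must be non-negative")
  if (any(df$paf_percent >= 100)) abort_paf("`paf_percent` must be < 100")
  if (!all(df$sex %in% c("men", "women", "both"))) {
    abort_paf("`sex` must be men, women or both")
  }
  df
}

#' Read occurrence totals (cases and deaths per site and sex)
#'
#' Expects columns `site`, `sex`, `cases`, `deaths` with non-negative integer
#' counts; an `all_sites` row carries the all-cancer denominators.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return tibble.
#' @export
read_occurrence <- function(path = paf_fixture_path("occurrence_totals.csv")) {
  df <- read_checked_csv(
    path, c("site", "sex", "cases", "deaths"),
    readr::cols(site = "c", sex = "c", cases = "d", deaths = "d"))
  if (any(df$cases < 0 | df$deaths < 0)) {
    abort_paf("occurrence counts must be non-negative")
  }
  if (any(df$cases != round(df$cases) | df$deaths != round(df$deaths))) {
    abort_paf("occurrence counts must be integers")
  }
  df
}

#' Read subtype splits
#'
#' Expects columns `site`, `sex`, `subtype`, `fraction`,
#' `applies_to_exposure`; fractions lie in `[0, 1]` and sum to at most 1
#' within each site/sex.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return tibble.
#' @export
read_subtype_splits <- function(path = paf_fixture_path("subtype_splits.csv")) {
  df <- read_checked_csv(
    path, c("site", "sex", "subtype", "fraction", "applies_to_exposure"),
    readr::cols(site = "c", sex = "c", subtype = "c", fraction = "d",
                applies_to_exposure = "c"))
  if (any(df$fraction < 0 | df$fraction > 1)) {
    abort_paf("subtype fractions must lie in [0, 1]")
  }
  sums <- tapply(df$fraction, paste(df$site, df$sex), sum)
  if (any(sums > 1 + 1e-9)) {
    abort_paf("subtype fractions exceed 1 for: %s",
              paste(names(sums)[sums > 1 + 1e-9], collapse = ", "))
  }
  df
}

#' Read the exposure-to-site eligibility map
#'
#' Expects columns `exposure`, `site`, `sex_restriction` (empty when the pair
#' applies to both sexes).
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return tibble.
#' @export
read_site_exposure_map <- function(path = paf_fixture_path("site_exposure_map.csv")) {
  read_checked_csv(
    path, c("exposure", "site"),
    readr::cols(exposure = "c", site = "c", sex_restriction = "c"))
}

#' Read individual-level survey records
#'
#' Expects the column layout written by [generate_survey()]: `sex`, `age`,
#' `drinks_per_day`, `weight`, `height`, `fruit_servings_per_day`,
#' `fruit_days_per_week`, `fv_servings_per_day`, `fv_days_per_week`, the ten
#' wide GPAQ activity columns (`<domain>_days`, `<domain>_min_per_day` for
#' each domain of [met_values()]), `smoking_status`, `home_smoke_exposure`
#' and `survey_weight`.
#'
#' @param path CSV path.
#' @return tibble of survey records.
#' @export
read_survey_records <- function(path) {
  req <- c("sex", "drinks_per_day", "weight", "height",
           "fruit_servings_per_day", "fruit_days_per_week",
           "fv_servings_per_day", "fv_days_per_week", activity_columns(),
           "smoking_status", "home_smoke_exposure", "survey_weight")
  df <- read_checked_csv(path, req, readr::cols(
    sex = "c", smoking_status = "c", home_smoke_exposure = "c",
    .default = "d"))
  if (any(df$height <= 0) || any(df$weight <= 0)) {
    abort_paf("height and weight must be positive")
  }
  df
}

#' Write an attribution result to CSV and JSON
#'
#' Writes the four component tables as tidy CSV plus one JSON file holding
#' the full result at unrounded precision; [read_attribution()] reads the
#' JSON back into an equal object.
#'
#' @param result an `attribution_result`.
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_attribution <- function(result, dir) {
  if (!inherits(result, "attribution_result")) {
    abort_paf("`result` must be an attribution_result")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("by_site", "combined", "by_exposure", "overall")) {
    p <- file.path(dir, paste0("attribution_", nm, ".csv"))
    readr::write_csv(result[[nm]], p)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "attribution.json")
  jsonlite::write_json(
    list(by_site = result$by_site, combined = result$combined,
         by_exposure = result$by_exposure, overall = result$overall,
         all_total = result$all_total),
    jp, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(c(paths, jp))
}

#' Read an attribution result back from JSON
#'
#' @param dir directory previously written by [write_attribution()].
#' @return an `attribution_result`.
#' @export
read_attribution <- function(dir) {
  jp <- file.path(dir, "attribution.json")
  if (!file.exists(jp)) abort_paf("no attribution.json under %s", dir)
  raw <- jsonlite::read_json(jp, simplifyVector = TRUE)
  structure(
    list(by_site = tibble::as_tibble(raw$by_site),
         combined = tibble::as_tibble(raw$combined),
         by_exposure = tibble::as_tibble(raw$by_exposure),
         overall = tibble::as_tibble(raw$overall),
         all_total = raw$all_total),
    class = "attribution_result"
  )
}

#' Presentation table in the published layout
#'
#' Rounds an attribution result's per-exposure/site rows for display: PAFs to
#' 0.1 percentage point and attributable counts to integers, both half away
#' from zero. Internal tables keep unrounded values.
#'
#' @param result an `attribution_result`.
#' @return tibble with columns `exposure`, `site`, `sex`, `total`,
#'   `paf_percent`, `attributable`.
#' @export
presentation_table <- function(result) {
  if (!inherits(result, "attribution_result")) {
    abort_paf("`result` must be an attribution_result")
  }
  result$by_site |>
    dplyr::mutate(paf_percent = round_half_away(100 * .data$paf, 1),
                  attributable = round_half_away(.data$attributable)) |>
    dplyr::select(dplyr::all_of(c("exposure", "site", "sex", "total",
                                  "paf_percent", "attributable")))
}
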