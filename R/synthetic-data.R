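# gram/MET sampling windows used to back-generate raw survey items so that
# the derivation operations reproduce the intended category exactly
band_windows <- list(
  alcohol = list(abstainer = c(0, 0), light = c(0.5, 12.5),
                 moderate = c(13, 49.5), heavy = c(50, 150)),
  fruit_veg = list(ge400 = c(400, 800), `300_399` = c(300, 399.5),
                   `200_299` = c(200, 299.5), `100_199` = c(100, 199.5),
                   `0_99` = c(0, 99.5)),
  fruit = list(ge250 = c(250, 500), `200_249` = c(200, 249.5),
               `150_199` = c(150, 199.5), `100_149` = c(100, 149.5),
               `50_99` = c(50, 99.5), `0_49` = c(0, 49.5)),
  physical_activity = list(ge8000 = c(8000, 16000),
                           `4000_7999` = c(4000, 7999),
                           `600_3999` = c(600, 3999), lt600 = c(0, 599))
)

#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter the generator draws from. The defaults are the
#' study conditions the package emulates: level proportions and BMI
#' mean/sd from the bundled published prevalence fixture, the
#' exposure-to-site roster from the bundled eligibility map, relative risks
#' log-uniform in plausible meta-analytic ranges, and occurrence counts at
#' the scale of national site-level registries.
#'
#' @param seed integer seed; identical seeds give identical outputs.
#' @param n_per_sex number of survey records per sex.
#' @param proportions named list (exposure -> sex -> proportion vector,
#'   TMREL first) for the categorical exposures.
#' @param bmi named list (sex -> `c(mean, sd)`), kg/m².
#' @param rr_range log-uniform range for categorical non-TMREL relative
#'   risks.
#' @param rr_per_unit_range log-uniform range for the BMI per-unit relative
#'   risk.
#' @param roster tibble with columns `exposure`, `site`, `sex_restriction`
#'   listing the exposure-cancer pairs to emulate.
#' @param occurrence_mean Poisson mean of site/sex case counts.
#' @param death_rate thinning probability turning cases into deaths.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_per_sex = 5000L,
                             proportions = NULL, bmi = NULL,
                             rr_range = c(1.2, 3.0),
                             rr_per_unit_range = c(1.02, 1.15),
                             roster = NULL,
                             occurrence_mean = 1000, death_rate = 0.5) {
  seed <- as.integer(seed)
  if (is.null(proportions)) {
    prev <- read_prevalence_table()
    proportions <- lapply(prev, function(by_sex) {
      lapply(by_sex, function(d) setNames(d$proportions, d$levels))
    })
  }
  for (ex in names(proportions)) {
    for (s in names(proportions[[ex]])) {
      p <- proportions[[ex]][[s]]
      if (abs(sum(p) - 1) > 1e-9) {
        abort_paf("generator proportions for %s (%s) do not sum to 1", ex, s)
      }
      if (length(p) == 0) abort_paf("exposure %s has zero levels", ex)
    }
  }
  if (is.null(bmi)) {
    bt <- read_bmi_table()
    bmi <- lapply(bt, function(d) c(mean = d$mean, sd = d$sd))
  }
  if (is.null(roster)) roster <- read_site_exposure_map()
  structure(
    list(seed = seed, n_per_sex = as.integer(n_per_sex),
         proportions = proportions, bmi = bmi, rr_range = rr_range,
         rr_per_unit_range = rr_per_unit_range, roster = roster,
         occurrence_mean = occurrence_mean, death_rate = death_rate),
    class = "generator_config"
  )
}

sample_in_window <- function(bands, windows) {
  lo <- vapply(windows, `[`, numeric(1), 1)
  hi <- vapply(windows, `[`, numeric(1), 2)
  runif(length(bands), lo[bands], hi[bands])
}

#' Generate synthetic survey records with known prevalence
#'
#' Draws per-record exposure levels from the configured proportions and
#' back-generates the raw questionnaire items (drinks/day, servings and
#' days/week, GPAQ minutes, weight and height) so that the derivation
#' operations reproduce the sampled category exactly. BMI is drawn
#' `Normal(mean, sd)` and realised through height and weight. Passive
#' smoking is sampled for every record but is defined (and estimated) among
#' never-smokers only. Survey weights are uniform on `[0.5, 1.5]`,
#' independent of all exposures.
#'
#' @param config a [generator_config()].
#' @return list with `records` (tibble, one row per respondent) and `truth`
#'   (the generating prevalence parameters, for parameter-recovery checks).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pr <- config$proportions
  rows <- list()
  for (s in c("men", "women")) {
    n <- config$n_per_sex
    draw_level <- function(ex) {
      p <- pr[[ex]][[s]]
      sample(names(p), n, replace = TRUE, prob = p)
    }
    alcohol <- draw_level("alcohol")
    fruit <- draw_level("fruit")
    fv <- draw_level("fruit_veg")
    pa <- draw_level("physical_activity")
    smoking <- draw_level("smoking")
    passive <- draw_level("passive_smoking")

    g_alc <- sample_in_window(alcohol, band_windows$alcohol)
    g_fruit <- sample_in_window(fruit, band_windows$fruit)
    g_fv <- sample_in_window(fv, band_windows$fruit_veg)
    met <- sample_in_window(pa, band_windows$physical_activity)

    height <- rnorm(n, if (s == "men") 1.71 else 1.60,
                    if (s == "men") 0.07 else 0.06)
    bmi <- rnorm(n, config$bmi[[s]]["mean"], config$bmi[[s]]["sd"])

    rec <- tibble::tibble(
      sex = s, age = sample(20:80, n, replace = TRUE),
      drinks_per_day = g_alc / 12.5,
      weight = bmi * height^2, height = height,
      fruit_servings_per_day = g_fruit / 80, fruit_days_per_week = 7,
      fv_servings_per_day = g_fv / 80, fv_days_per_week = 7,
      smoking_status = smoking, home_smoke_exposure = passive,
      survey_weight = runif(n, 0.5, 1.5))

    # realise the MET volume through one randomly chosen GPAQ domain
    mets <- met_values()
    domain <- sample(names(mets), n, replace = TRUE)
    days <- sample(3:7, n, replace = TRUE)
    for (d in names(mets)) {
      on_d <- domain == d & met > 0
      rec[[paste0(d, "_days")]] <- ifelse(on_d, days, 0)
      rec[[paste0(d, "_min_per_day")]] <-
        ifelse(on_d, met / (mets[[d]] * days), 0)
    }
    rows[[s]] <- rec
  }
  list(records = dplyr::bind_rows(rows),
       truth = list(proportions = pr, bmi = config$bmi))
}

#' Generate relative-risk sets for the configured roster
#'
#' For every exposure-site-sex triple in the roster, draws level relative
#' risks log-uniform in `rr_range`, sorted non-decreasing across the ordered
#' exposure levels with RR fixed at 1 for the TMREL level; for the continuous
#' BMI exposure draws a per-unit RR log-uniform in `rr_per_unit_range`.
#'
#' @param config a [generator_config()].
#' @return list of [relative_risk_set()] objects.
#' @export
generate_rr_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  log_unif <- function(k, range) exp(runif(k, log(range[1]), log(range[2])))
  out <- list()
  for (i in seq_len(nrow(config$roster))) {
    ex <- config$roster$exposure[i]
    site <- config$roster$site[i]
    restrict <- config$roster$sex_restriction[i]
    sexes <- if (!is.na(restrict) && nzchar(restrict)) restrict
             else c("men", "women")
    for (s in sexes) {
      out[[length(out) + 1]] <- if (ex == "high_bmi") {
        relative_risk_set(ex, site, s, "per_unit",
                          rr_per_unit = log_unif(1,
                            config$rr_per_unit_range))
      } else {
        lv <- exposure_levels(ex)
        rr <- c(1, sort(log_unif(length(lv) - 1, config$rr_range)))
        relative_risk_set(ex, site, s, "categorical", rr = rr, levels = lv,
                          tmrel_level = 1L)
      }
    }
  }
  out
}

#' Generate occurrence counts
#'
#' Poisson case counts per roster site and sex; deaths are obtained by
#' binomial thinning of cases at `death_rate`, which guarantees
#' `deaths <= cases` in every stratum.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `site`, `sex`, `cases`, `deaths`, plus an
#'   `all_sites` row holding the summed denominators.
#' @export
generate_occurrence <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  strata <- unique(config$roster[, c("site", "sex_restriction")])
  # one row per site; restricted sites occur for one sex only
  sites <- unique(strata$site)
  rows <- list()
  for (site in sites) {
    restrict <- strata$sex_restriction[strata$site == site]
    restrict <- restrict[!is.na(restrict) & nzchar(restrict)]
    sexes <- if (length(restrict) > 0) unique(restrict) else c("men", "women")
    for (s in sexes) {
      cases <- rpois(1, config$occurrence_mean)
      deaths <- rbinom(1, cases, config$death_rate)
      rows[[length(rows) + 1]] <- tibble::tibble(
        site = site, sex = s, cases = cases, deaths = deaths)
    }
  }
  occ <- dplyr::bind_rows(rows)
  dplyr::bind_rows(occ, tibble::tibble(
    site = "all_sites", sex = "both", cases = sum(occ$cases),
    deaths = sum(occ$deaths)))
}

#' Ground-truth PAFs for generated relative risks
#'
#' Computes the analytically true PAF of every generated relative-risk set
#' from the generator's own parameters, through the independently coded
#' oracle arithmetic (see [oracle_paf_categorical()],
#' [oracle_paf_continuous()]), plus the true combined PAF per site and sex.
#'
#' @param config a [generator_config()].
#' @param rr_sets output of [generate_rr_table()].
#' @return list with `by_pair` (tibble: `exposure`, `site`, `sex`,
#'   `true_paf`) and `combined` (tibble: `site`, `sex`, `true_paf`).
#' @export
ground_truth_pafs <- function(config, rr_sets) {
  rows <- lapply(rr_sets, function(rr) {
    true_paf <- if (rr$form == "categorical") {
      p <- config$proportions[[rr$exposure_id]][[rr$sex]]
      oracle_paf_categorical(unname(p), rr$rr, rr$tmrel_level)
    } else {
      b <- config$bmi[[rr$sex]]
      oracle_paf_continuous(b["mean"], b["sd"],
                            dose_response_model("log_linear",
                                                rr$rr_per_unit))
    }
    tibble::tibble(exposure = rr$exposure_id, site = rr$cancer_site,
                   sex = rr$sex, true_paf = true_paf)
  })
  by_pair <- dplyr::bind_rows(rows)
  combined <- by_pair |>
    dplyr::group_by(.data$site, .data$sex) |>
    dplyr::summarise(true_paf = oracle_combined_paf(.data$true_paf),
                     .groups = "drop")
  list(by_pair = by_pair, combined = combined)
}
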