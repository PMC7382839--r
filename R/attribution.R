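#' Restrict a subtype-specific PAF to the whole cancer site
#'
#' When a risk factor acts only on a subtype of a site (high BMI on cardia
#' stomach cancer, alcohol on oesophageal squamous cell carcinoma), the PAF
#' estimated against the subtype applies to only `fraction` of the site's
#' counts. The site-level PAF reported against the whole-site total is then
#' `fraction * paf_subtype`.
#'
#' @param paf_subtype PAF estimated for the subtype, a fraction `< 1`.
#' @param fraction share of the site's counts belonging to the subtype, in
#'   `[0, 1]`.
#' @return site-level PAF (fraction).
#' @export
#' @examples
#' apply_subtype_restriction(0.20, 0.32) # cardia stomach in men
apply_subtype_restriction <- function(paf_subtype, fraction) {
  assert_number(paf_subtype, "paf_subtype", upper = 1)
  assert_number(fraction, "fraction", lower = 0, upper = 1)
  fraction * paf_subtype
}

#' Attributable count
#'
#' The unrounded product `paf * total`. Presentation tables round half away
#' from zero via [round_half_away()]; all internal arithmetic keeps the
#' unrounded value.
#'
#' @param paf fraction (may be negative for protective patterns).
#' @param total non-negative occurrence count.
#' @return unrounded attributable count (vectorised).
#' @export
attributable_count <- function(paf, total) {
  assert_number(total, "total", lower = 0)
  paf * total
}

#' Combine per-exposure PAFs within one cancer site and sex
#'
#' Applies the independence combination `1 - prod(1 - PAF_i)` to the
#' site-level per-exposure PAFs of one site/sex stratum and converts the
#' result to an attributable count against the site total.
#'
#' @param paf_table tibble with columns `exposure`, `site`, `sex`, `paf`
#'   (fractions) and `total`; all rows must share one site, sex and total.
#' @return one-row tibble with columns `site`, `sex`, `paf`, `total`,
#'   `attributable`.
#' @export
combine_within_site <- function(paf_table) {
  if (nrow(paf_table) == 0) abort_paf("empty PAF table")
  if (length(unique(paf_table$site)) != 1 ||
      length(unique(paf_table$sex)) != 1) {
    abort_paf("`paf_table` must contain a single site/sex stratum")
  }
  total <- unique(paf_table$total)
  if (length(total) != 1) {
    abort_paf("inconsistent totals within site/sex stratum")
  }
  paf <- combine_pafs(paf_table$paf)
  tibble::tibble(site = paf_table$site[1], sex = paf_table$sex[1],
                 paf = paf, total = total,
                 attributable = attributable_count(paf, total))
}

# both-sex rows from sex-specific rows: pooled attributable over pooled totals
pool_sexes <- function(df, group_cols) {
  df |>
    dplyr::filter(.data$sex %in% c("men", "women")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(total = sum(.data$total),
                     attributable = sum(.data$attributable),
                     .groups = "drop") |>
    dplyr::mutate(sex = "both", paf = .data$attributable / .data$total)
}

#' Aggregate per-exposure site PAFs into a full attribution result
#'
#' Takes a long table of site-level per-exposure PAFs by sex and produces the
#' complete burden surface: per-exposure/site rows with pooled both-sex
#' values, combined-risk-factor rows per site (independence combination
#' within each sex, then pooled), per-exposure attributable totals, and the
#' overall proportion of occurrence attributable to the combined factors.
#' Pooled ("both") PAFs are always derived from sex-specific attributable
#' counts divided by pooled totals, never by combining pooled PAFs.
#'
#' @param paf_table tibble with columns `exposure`, `site`, `sex`
#'   (`"men"`/`"women"`), `total`, `paf` (fractions). A `measure` column is
#'   carried through if present.
#' @param all_total optional all-cancer occurrence denominator used for
#'   per-exposure and overall shares.
#' @return An object of class `attribution_result`: a list of tibbles
#'   `by_site` (per exposure/site/sex, including pooled rows), `combined`
#'   (combined factors per site/sex), `by_exposure` (attributable totals and
#'   shares per exposure/sex) and `overall` (combined attributable and share
#'   per sex and pooled).
#' @export
aggregate_attribution <- function(paf_table, all_total = NULL) {
  req <- c("exposure", "site", "sex", "total", "paf")
  missing_cols <- setdiff(req, names(paf_table))
  if (length(missing_cols) > 0) {
    abort_paf("`paf_table` lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  if (!all(paf_table$sex %in% c("men", "women"))) {
    abort_paf("`paf_table` sex must be 'men' or 'women'; pooled rows are derived")
  }
  if (anyDuplicated(paf_table[c("exposure", "site", "sex")]) > 0) {
    abort_paf("duplicate exposure/site/sex rows in `paf_table`")
  }

  by_sex <- paf_table |>
    dplyr::mutate(attributable = attributable_count(.data$paf, .data$total))

  by_site <- dplyr::bind_rows(
    by_sex,
    pool_sexes(by_sex, c("exposure", "site"))
  ) |>
    dplyr::select(dplyr::all_of(c("exposure", "site", "sex", "paf", "total",
                                  "attributable"))) |>
    dplyr::arrange(.data$exposure, .data$site, .data$sex)

  combined_sex <- if (nrow(by_sex) == 0) {
    tibble::tibble(site = character(0), sex = character(0),
                   paf = numeric(0), total = numeric(0),
                   attributable = numeric(0))
  } else {
    by_sex |>
      dplyr::group_by(.data$site, .data$sex) |>
      dplyr::group_modify(~ combine_within_site(
        dplyr::mutate(.x, site = .y$site, sex = .y$sex))[
          c("paf", "total", "attributable")]) |>
      dplyr::ungroup()
  }
  combined <- dplyr::bind_rows(
    combined_sex,
    pool_sexes(combined_sex, "site")
  ) |>
    dplyr::select(dplyr::all_of(c("site", "sex", "paf", "total",
                                  "attributable"))) |>
    dplyr::arrange(.data$site, .data$sex)

  exposure_sex <- by_sex |>
    dplyr::group_by(.data$exposure, .data$sex) |>
    dplyr::summarise(attributable = sum(.data$attributable),
                     total = sum(.data$total), .groups = "drop")
  by_exposure <- dplyr::bind_rows(
    exposure_sex |> dplyr::mutate(paf = .data$attributable / .data$total),
    pool_sexes(exposure_sex |>
                 dplyr::mutate(paf = .data$attributable / .data$total),
               "exposure")
  ) |>
    dplyr::select(dplyr::all_of(c("exposure", "sex", "attributable"))) |>
    dplyr::arrange(.data$exposure, .data$sex)

  overall_sex <- combined_sex |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(attributable = sum(.data$attributable),
                     site_total = sum(.data$total), .groups = "drop")
  overall <- dplyr::bind_rows(
    overall_sex,
    tibble::tibble(sex = "both",
                   attributable = sum(overall_sex$attributable),
                   site_total = sum(overall_sex$site_total))
  )

  if (!is.null(all_total)) {
    by_exposure$share <- by_exposure$attributable / all_total
    overall$share <- overall$attributable / all_total
  }

  structure(
    list(by_site = by_site, combined = combined, by_exposure = by_exposure,
         overall = overall, all_total = all_total),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result>\n")
  cat(sprintf("  %d exposure-site-sex rows, %d sites\n",
              nrow(x$by_site), length(unique(x$by_site$site))))
  ov <- x$overall[x$overall$sex == "both", ]
  if (nrow(ov) == 1) {
    cat(sprintf("  combined attributable (both sexes): %d",
                round_half_away(ov$attributable)))
    if (!is.null(x$all_total)) {
      cat(sprintf(" of %d (%.1f%%)", x$all_total, 100 * ov$share))
    }
    cat("\n")
  }
  invisible(x)
}

#' Reproduce the published burden surface from a printed PAF table
#'
#' The reproduction path: consumes a per-exposure/site/sex PAF table as
#' printed (PAFs in percent, with site totals) together with occurrence
#' totals, and regenerates the whole attribution surface — pooled both-sex
#' rows, combined per-site PAFs, per-exposure attributable totals and the
#' overall attributable proportion — without needing relative-risk inputs.
#'
#' @param paf_table tibble with columns `exposure`, `site`, `sex`, `total`,
#'   `paf_percent` (as read by [read_paf_table()]); `"both"` rows, if
#'   present, are dropped and re-derived from the sex-specific rows.
#' @param occurrence optional occurrence tibble (columns `site`, `sex`,
#'   `cases`, `deaths`) used to validate site totals and to supply the
#'   all-cancer denominator from its `all_sites` row.
#' @param measure `"cases"` or `"deaths"`; selects the occurrence column used
#'   for validation and the denominator.
#' @return An `attribution_result`; see [aggregate_attribution()].
#' @export
reproduce_from_paf_table <- function(paf_table, occurrence = NULL,
                                     measure = c("cases", "deaths")) {
  measure <- match.arg(measure)
  tab <- paf_table |>
    dplyr::filter(.data$sex %in% c("men", "women")) |>
    dplyr::mutate(paf = .data$paf_percent / 100) |>
    dplyr::select(dplyr::all_of(c("exposure", "site", "sex", "total", "paf")))

  all_total <- NULL
  if (!is.null(occurrence)) {
    occ <- occurrence |>
      dplyr::mutate(total = .data[[measure]]) |>
      dplyr::select(dplyr::all_of(c("site", "sex", "total")))
    missing_sites <- setdiff(unique(tab$site),
                             occ$site[occ$site != "all_sites"])
    if (length(missing_sites) > 0) {
      abort_paf("site(s) in PAF table absent from occurrence: %s",
                paste(missing_sites, collapse = ", "))
    }
    chk <- dplyr::inner_join(tab, occ, by = c("site", "sex"),
                             suffix = c("", ".occ"))
    bad <- chk[chk$total != chk$total.occ &
                 !(chk$site == "prostate" & measure == "cases"), ]
    if (nrow(bad) > 0) {
      abort_paf("PAF-table totals disagree with occurrence for: %s",
                paste(unique(paste(bad$site, bad$sex)), collapse = "; "))
    }
    all_row <- occurrence[occurrence$site == "all_sites", ]
    if (nrow(all_row) == 1) all_total <- all_row[[measure]]
  }
  aggregate_attribution(tab, all_total = all_total)
}

#' Compute attribution from prevalence and relative risks
#'
#' The first-principles path: for every supplied relative-risk set, computes
#' the PAF from the matching exposure distribution ([paf_categorical()] for
#' categorical sets, [paf_continuous()] through a [dose_response_model()] for
#' per-unit sets), applies any subtype restriction, converts to attributable
#' counts against the occurrence totals, and aggregates.
#'
#' Two published special rules are honoured: subtype fractions multiply the
#' subtype PAF down to the site level (see [apply_subtype_restriction()]),
#' and for prostate cancer incidence the exposed pool of "advanced" cases is
#' taken equal to prostate deaths, with the resulting count reported against
#' the whole-site case total.
#'
#' @param prevalence named list: for each exposure id, the output of
#'   [estimate_prevalence()] (a list of per-sex distributions).
#' @param rr_sets list of [relative_risk_set()] objects.
#' @param occurrence tibble with columns `site`, `sex`, `cases`, `deaths`.
#' @param subtype_splits optional tibble with columns `site`, `sex`,
#'   `fraction`, `applies_to_exposure` (as read by [read_subtype_splits()]).
#' @param site_exposure_map optional tibble with columns `exposure`, `site`;
#'   RR sets for pairs outside the map are skipped with a warning.
#' @param measure `"cases"` or `"deaths"`.
#' @param model_args list of extra arguments for [dose_response_model()]
#'   applied to per-unit RR sets (e.g. `tmrel`, `cap_dose`).
#' @return An `attribution_result`; see [aggregate_attribution()].
#' @export
compute_attribution <- function(prevalence, rr_sets, occurrence,
                                subtype_splits = NULL,
                                site_exposure_map = NULL,
                                measure = c("cases", "deaths"),
                                model_args = list()) {
  measure <- match.arg(measure)
  rows <- list()
  for (rr in rr_sets) {
    if (!inherits(rr, "relative_risk_set")) {
      abort_paf("`rr_sets` must contain relative_risk_set objects")
    }
    if (!is.null(site_exposure_map) &&
        !any(site_exposure_map$exposure == rr$exposure_id &
             site_exposure_map$site == rr$cancer_site)) {
      warning(sprintf("skipping %s/%s: pair not in the site-exposure map",
                      rr$exposure_id, rr$cancer_site), call. = FALSE)
      next
    }
    dist <- prevalence[[rr$exposure_id]][[rr$sex]]
    if (is.null(dist)) {
      abort_paf("no %s prevalence for exposure '%s'", rr$sex, rr$exposure_id)
    }
    paf <- if (rr$form == "categorical") {
      paf_categorical(dist, rr)
    } else {
      model <- do.call(dose_response_model,
                       c(list(model_id = rr$model_id %||% "log_linear",
                              rr_per_unit = rr$rr_per_unit), model_args))
      paf_continuous(dist, model)
    }
    if (!is.null(subtype_splits)) {
      sp <- subtype_splits[
        !is.na(subtype_splits$applies_to_exposure) &
          subtype_splits$applies_to_exposure == rr$exposure_id &
          subtype_splits$site == rr$cancer_site &
          subtype_splits$sex == rr$sex, ]
      if (nrow(sp) == 1) paf <- apply_subtype_restriction(paf, sp$fraction)
    }
    occ <- occurrence[occurrence$site == rr$cancer_site &
                        occurrence$sex == rr$sex, ]
    if (nrow(occ) != 1) {
      abort_paf("site '%s' (%s) absent from occurrence", rr$cancer_site,
                rr$sex)
    }
    total <- occ[[measure]]
    # advanced prostate: exposed case pool equals prostate deaths, reported
    # against the whole-site case total
    if (rr$cancer_site == "prostate" && measure == "cases") {
      paf <- paf * occ$deaths / total
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      exposure = rr$exposure_id, site = rr$cancer_site, sex = rr$sex,
      total = total, paf = paf)
  }
  if (length(rows) == 0) abort_paf("no usable relative-risk sets")
  all_total <- NULL
  all_row <- occurrence[occurrence$site == "all_sites", ]
  if (nrow(all_row) == 1) all_total <- all_row[[measure]]
  aggregate_attribution(dplyr::bind_rows(rows), all_total = all_total)
}
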