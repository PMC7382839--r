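# build exact exposure/continuous distributions straight from a generator
# config (no survey sampling), for analytic parameter-recovery checks
prevalence_from_config <- function(config) {
  prev <- lapply(names(config$proportions), function(ex) {
    lapply(config$proportions[[ex]], function(p) {
      exposure_distribution(ex, sex = "men", levels = names(p),
                            proportions = unname(p), tmrel_level = 1L)
    })
  })
  names(prev) <- names(config$proportions)
  for (ex in names(prev)) {
    for (s in names(prev[[ex]])) prev[[ex]][[s]]$sex <- s
  }
  prev$high_bmi <- lapply(names(config$bmi), function(s) {
    continuous_distribution(sex = s, mean = config$bmi[[s]]["mean"],
                            sd = config$bmi[[s]]["sd"])
  })
  names(prev$high_bmi) <- names(config$bmi)
  prev
}

# Monte-Carlo estimate of the continuous PAF with a delta-method standard
# error; the independent stochastic check on the quadrature engine
mc_paf_continuous <- function(mean, sd, model, cf_mean = 22, cf_sd = 1,
                              n = 1e6, range = c(10, 60)) {
  draw_trunc <- function(m, s) {
    x <- rnorm(n, m, s)
    while (any(bad <- x < range[1] | x > range[2])) {
      x[bad] <- rnorm(sum(bad), m, s)
    }
    x
  }
  a <- rr_at_dose(draw_trunc(mean, sd), model)
  b <- rr_at_dose(draw_trunc(cf_mean, cf_sd), model)
  ma <- mean(a); mb <- mean(b)
  paf <- (ma - mb) / ma
  # var(1 - B/A) by the delta method, A and B independent
  se <- (mb / ma) * sqrt(var(a) / n / ma^2 + var(b) / n / mb^2)
  list(paf = paf, se = se)
}
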