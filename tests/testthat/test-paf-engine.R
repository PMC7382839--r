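make_cat_pair <- function(p, rr, levels = paste0("l", seq_along(p))) {
  list(
    dist = exposure_distribution("x", "men", levels, p, tmrel_level = 1L),
    rr = relative_risk_set("x", "site", "men", "categorical", rr = rr,
                           levels = levels, tmrel_level = 1L))
}

test_that("categorical PAF matches the counterfactual-shift definition", {
  # population already at the TMREL
  pr <- make_cat_pair(c(1, 0), c(1, 5))
  expect_equal(paf_categorical(pr$dist, pr$rr), 0)
  # null relative risks
  pr <- make_cat_pair(c(0.2, 0.3, 0.5), c(1, 1, 1))
  expect_equal(paf_categorical(pr$dist, pr$rr), 0)
  # closed-form hand computation (1.5 - 1)/1.5
  pr <- make_cat_pair(c(0.5, 0.5), c(1, 2))
  expect_equal(paf_categorical(pr$dist, pr$rr), 1 / 3, tolerance = 1e-12)

  # misaligned levels and invalid RRs fail loudly
  d <- exposure_distribution("x", "men", c("a", "b"), c(0.5, 0.5))
  r <- relative_risk_set("x", "s", "men", "categorical", rr = c(1, 2),
                         levels = c("a", "c"))
  expect_error(paf_categorical(d, r), "not aligned")
  expect_error(relative_risk_set("x", "s", "men", "categorical",
                                 rr = c(1, -2), levels = c("a", "b")),
               "> 0")
  expect_error(relative_risk_set("x", "s", "men", "categorical",
                                 rr = c(1.2, 2), levels = c("a", "b")),
               "TMREL")
})

test_that("categorical PAF equals 1 - 1/sum(P*RR) and the independent oracle", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    rr <- c(1, exp(runif(k - 1, 0, 1.5)))
    pr <- make_cat_pair(p, rr)
    paf <- paf_categorical(pr$dist, pr$rr)
    expect_equal(paf, 1 - 1 / sum(p * rr), tolerance = 1e-12)
    expect_equal(paf, oracle_paf_categorical(p, rr), tolerance = 1e-12)
  }
})

test_that("categorical PAF is invariant to merging levels with equal RR and monotone in risk mass", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  rr <- c(1, 2, 2, 3)
  merged <- make_cat_pair(c(0.4, 0.5, 0.1), c(1, 2, 3))
  full <- make_cat_pair(p, rr)
  expect_equal(paf_categorical(full$dist, full$rr),
               paf_categorical(merged$dist, merged$rr), tolerance = 1e-12)

  # moving mass from TMREL to an RR > 1 level increases the PAF
  shifted <- make_cat_pair(c(0.3, 0.4, 0.2, 0.1), rr)
  expect_gt(paf_categorical(shifted$dist, shifted$rr),
            paf_categorical(full$dist, full$rr))
})

test_that("dose-response RR is 1 at and below the TMREL and follows the model above", {
  m <- dose_response_model("log_linear", rr_per_unit = 1.05)
  expect_equal(rr_at_dose(22, m), 1)
  expect_equal(rr_at_dose(18, m), 1)
  expect_equal(rr_at_dose(32, m), 1.05^10, tolerance = 1e-12)

  capped <- dose_response_model("log_linear", 1.05, cap_dose = 30)
  expect_equal(rr_at_dose(45, capped), 1.05^8, tolerance = 1e-12)

  ll <- dose_response_model("log_logit", rr_per_unit = 1.08)
  x <- seq(10, 60, by = 0.25)
  rr <- rr_at_dose(x, ll)
  expect_equal(rr_at_dose(22, ll), 1)
  expect_true(all(rr[x <= 22] == 1))
  expect_true(all(diff(rr) >= -1e-12)) # non-decreasing
  expect_true(all(is.finite(rr)))
  # saturation: log-logit stays below the unbounded log-linear curve far
  # above the TMREL
  expect_lt(rr_at_dose(60, ll),
            rr_at_dose(60, dose_response_model("log_linear", 1.08)))

  expect_error(dose_response_model("quadratic", 1.05), "arg")
})

test_that("continuous PAF vanishes under a flat dose-response or a null shift", {
  dist <- continuous_distribution(sex = "men", mean = 28.42, sd = 4.5)
  flat <- dose_response_model("log_linear", rr_per_unit = 1)
  expect_equal(paf_continuous(dist, flat), 0, tolerance = 1e-12)

  at_cf <- continuous_distribution(sex = "men", mean = 22, sd = 1)
  m <- dose_response_model("log_linear", 1.10)
  expect_equal(paf_continuous(at_cf, m), 0, tolerance = 1e-12)
})

test_that("continuous PAF agrees with a 10^6-draw Monte-Carlo oracle", {
  set.seed(99)
  params <- list(
    list(mean = 28.42, sd = 4, rr = 1.10, model = "log_linear"),
    list(mean = 29.62, sd = 5, rr = 1.05, model = "log_linear"),
    list(mean = 26, sd = 3, rr = 1.08, model = "log_logit"))
  for (p in params) {
    m <- dose_response_model(p$model, rr_per_unit = p$rr)
    dist <- continuous_distribution(sex = "men", mean = p$mean, sd = p$sd)
    quad <- paf_continuous(dist, m)
    mc <- mc_paf_continuous(p$mean, p$sd, m)
    expect_lt(abs(quad - mc$paf), 3 * mc$se)
  }
})

test_that("continuous PAF is stable to quadrature grid refinement", {
  dist <- continuous_distribution(sex = "women", mean = 29.62, sd = 5)
  m <- dose_response_model("log_linear", 1.10)
  expect_equal(paf_continuous(dist, m, nodes = 512),
               paf_continuous(dist, m, nodes = 2048), tolerance = 1e-8)
  expect_equal(paf_continuous(dist, m, nodes = 512),
               oracle_paf_continuous(29.62, 5, m), tolerance = 1e-8)
})

test_that("combined PAF obeys the independence identities", {
  # men's lung combination: smoking, low fruits, passive smoking
  expect_equal(combine_pafs(c(0.907, 0.143, 0.022)), 0.92205242,
               tolerance = 1e-8)
  expect_equal(combine_pafs(0.4), 0.4)
  expect_equal(combine_pafs(c(0.5, 0.5)), 0.75)
  # two-factor inclusion-exclusion
  expect_equal(combine_pafs(c(0.3, 0.2)), 0.3 + 0.2 - 0.3 * 0.2)
  # commutative and associative
  p <- c(0.1, 0.25, 0.6)
  expect_equal(combine_pafs(p), combine_pafs(rev(p)))
  expect_equal(combine_pafs(c(combine_pafs(p[1:2]), p[3])), combine_pafs(p))
  expect_equal(combine_pafs(p), oracle_combined_paf(p))
  # dominates every component, stays below 1
  expect_gte(combine_pafs(p), max(p))
  expect_lt(combine_pafs(c(0.999, 0.999)), 1)
  expect_error(combine_pafs(c(0.5, 1)), "< 1")
})
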