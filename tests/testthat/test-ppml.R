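make_panel <- function(seed, n_tract = 30L, n_year = 5L, beta = c(0.05, -0.1),
                       fe_sd = 0.3, zero_tracts = 0L, singleton_tracts = 0L) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_tract))
  dt <- data.table::CJ(tract_id = ids, year = 2000L + seq_len(n_year) - 1L)
  dt[, x1 := rnorm(.N)]
  dt[, x2 := rnorm(.N)]
  a <- stats::setNames(rnorm(n_tract, 0, fe_sd), ids)
  g <- stats::setNames(rnorm(n_year, 0, fe_sd), as.character(sort(unique(dt$year))))
  dt[, y := rpois(.N, exp(0.5 + beta[1] * x1 + beta[2] * x2 +
                          a[tract_id] + g[as.character(year)]))]
  if (zero_tracts > 0L) dt[tract_id %in% ids[seq_len(zero_tracts)], y := 0L]
  if (singleton_tracts > 0L) {
    singles <- ids[n_tract - seq_len(singleton_tracts) + 1L]
    dt <- dt[!(tract_id %in% singles & year > 2000L)]
  }
  dt[]
}

test_that("singleton and separated observations drop to a fixed point", {
  dt <- make_panel(601, n_tract = 20L, n_year = 6L,
                   zero_tracts = 3L, singleton_tracts = 2L)
  red <- drop_singletons_separated(dt, "y", c("tract_id", "year"))
  expect_equal(red$n_singletons, 2L)        # 2 tracts observed once
  expect_equal(red$n_separated, 18L)        # 3 all-zero tracts x 6 years
  expect_equal(nrow(red$data), nrow(dt) - 20L)
  # no all-zero or singleton groups remain
  expect_true(all(red$data[, .N, by = tract_id]$N > 1L))
  expect_true(all(red$data[, .(az = all(y == 0)), by = tract_id]$az == FALSE))

  # a clean panel is untouched
  clean <- make_panel(602, n_tract = 10L, n_year = 4L)
  clean[y == 0, y := 1L]
  red2 <- drop_singletons_separated(clean, "y", c("tract_id", "year"))
  expect_equal(red2$n_singletons + red2$n_separated, 0L)
  expect_error(
    drop_singletons_separated(data.table::data.table(tract_id = "a",
                                                     year = 1L, y = 0),
                              "y", c("tract_id", "year")),
    "no identifying variation")
})

test_that("intercept-only PPML gives the closed-form log mean", {
  set.seed(603)
  dt <- data.table::data.table(y = rpois(200, 4), tract_id = "x", year = 1L)
  fit <- fit_ppml_hdfe(dt, "y", character(0), fe = NULL, cluster = NULL)
  expect_equal(unname(coef(fit)), log(mean(dt$y)), tolerance = 1e-8)
})

test_that("HDFE PPML matches the explicit-dummy glm oracle to 1e-6", {
  for (seed in c(611, 612, 613)) {
    dt <- make_panel(seed, n_tract = 30L, n_year = 5L, zero_tracts = 1L)
    fit <- fit_ppml_hdfe(dt, "y", c("x1", "x2"))
    oracle <- glm_ppml_oracle(dt, "y", c("x1", "x2"))
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
    expect_equal(fit$n_obs, nrow(dt) - fit$n_singletons_dropped -
                   fit$n_separated_dropped)
  }
})

test_that("deviance trace is non-increasing after the first step", {
  dt <- make_panel(614, n_tract = 40L, n_year = 8L)
  fit <- fit_ppml_hdfe(dt, "y", c("x1", "x2"))
  tr <- fit$deviance_trace
  expect_true(all(diff(tr[-1]) <= abs(tr[-c(1, length(tr))]) * 1e-9 + 1e-8))
})

test_that("adding-up: residuals sum to ~0 within every absorbed FE group", {
  dt <- make_panel(615, n_tract = 25L, n_year = 6L)
  fit <- fit_ppml_hdfe(dt, "y", c("x1", "x2"))
  resid <- fit$data$y - fit$fitted
  scale <- mean(fit$fitted)
  by_tract <- tapply(resid, fit$data$tract_id, sum)
  by_year <- tapply(resid, fit$data$year, sum)
  expect_lt(max(abs(by_tract)) / scale, 1e-6)
  expect_lt(max(abs(by_year)) / scale, 1e-6)
})

test_that("outcome scaling leaves slope estimates unchanged", {
  dt <- make_panel(616)
  f1 <- fit_ppml_hdfe(dt, "y", c("x1", "x2"))
  dt[, y := y * 73.5]
  f2 <- fit_ppml_hdfe(dt, "y", c("x1", "x2"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
})

test_that("one cluster per observation equals an independent HC oracle", {
  dt <- make_panel(621, n_tract = 15L, n_year = 5L)
  dt <- drop_singletons_separated(dt, "y", c("tract_id", "year"))$data
  dt[, rid := as.character(.I)]
  fit <- fit_ppml_hdfe(dt, "y", c("x1", "x2"), cluster = "rid", drop = FALSE)
  fit_hc <- fit_ppml_hdfe(dt, "y", c("x1", "x2"), cluster = NULL,
                          drop = FALSE)
  expect_equal(fit$se, fit_hc$se, tolerance = 1e-10)

  # oracle: full-dummy design sandwich, X-block of the partitioned inverse
  X <- cbind(dt$x1, dt$x2,
             stats::model.matrix(~ factor(tract_id) + factor(year), dt))
  mu <- fit$fitted
  B <- solve(crossprod(X, mu * X))
  sc <- (dt$y - mu) * X
  n <- nrow(dt)
  V <- (n / (n - 1)) * (B %*% crossprod(sc) %*% B)[1:2, 1:2]
  expect_equal(unname(fit$se), unname(sqrt(diag(V))), tolerance = 1e-6)
})

test_that("duplicating every cluster leaves estimates and SEs unchanged", {
  dt <- make_panel(622, n_tract = 12L, n_year = 5L)
  dt <- drop_singletons_separated(dt, "y", c("tract_id", "year"))$data
  f1 <- fit_ppml_hdfe(dt, "y", c("x1", "x2"), drop = FALSE)
  dup <- data.table::rbindlist(list(dt, dt))
  f2 <- fit_ppml_hdfe(dup, "y", c("x1", "x2"), drop = FALSE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  # bread halves, meat quadruples with the same G: the sandwich is invariant
  expect_equal(f1$se, f2$se, tolerance = 1e-6)
  expect_true(all(f2$se >= f1$se * (1 - 1e-6)))
})

test_that("clustered CIs cover under within-tract serial correlation", {
  # AR(1) multiplicative errors inside tracts; 95% CI coverage in [90, 99]%
  covered <- logical(200)
  set.seed(631)
  for (r in seq_len(200)) {
    n_tract <- 40L; n_year <- 6L
    ids <- sprintf("T%02d", 1:n_tract)
    dt <- data.table::CJ(tract_id = ids, year = 1:n_year)
    dt[, x := rnorm(.N)]
    u <- replicate(n_tract, {
      e <- rnorm(n_year, 0, 0.4)
      as.vector(stats::filter(e, 0.7, method = "recursive"))
    })
    dt[order(tract_id, year), u := as.vector(u)]
    dt[, y := rpois(.N, exp(1 + 0.3 * x + u))]
    fit <- tryCatch(
      fit_ppml_hdfe(dt, "y", "x", fe = c("tract_id", "year")),
      error = function(e) NULL)
    if (is.null(fit)) next
    ci <- coef(fit)[["x"]] + c(-1, 1) * 1.959964 * fit$se[["x"]]
    covered[r] <- ci[1] <= 0.3 && 0.3 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("collinear regressors are dropped with a warning", {
  dt <- make_panel(641)
  dt[, x3 := 2 * x1 - x2]
  expect_warning(fit <- fit_ppml_hdfe(dt, "y", c("x1", "x2", "x3")),
                 "collinear")
  expect_named(coef(fit), c("x1", "x2"))
  expect_identical(fit$dropped_collinear, "x3")
})

test_that("model suite runs the full grid with honest bookkeeping", {
  w <- small_world(seed = 51, n_rows = 8, n_cols = 8, years = 2000:2009)
  suite <- run_model_suite(w$panel, w$attrs)
  # 2 outcomes x {race, hispanic} x {all, metro, nonmetro} + 2 x 2 SVI fits
  expect_equal(length(unique(suite$model_id)), 16L)
  expect_true(all(suite$se > 0))
  # metro + nonmetro pre-drop rows partition the full sample
  tot <- function(mid) {
    s <- suite[model_id == mid][1]
    s$n_obs + s$n_singletons + s$n_separated
  }
  expect_equal(tot("mrfei.race.metro") + tot("mrfei.race.nonmetro"),
               tot("mrfei.race.all"))
})

test_that("suite recovers a planted negative Asian effect on mRFEI", {
  # effect large enough to be identifiable from within-tract drift at this
  # scale; the sign, not the magnitude, is what the suite must recover
  w <- small_world(seed = 52, n_rows = 20, n_cols = 20, years = 2000:2019,
                   beta_true = c(pct_white = 0.003, pct_black = 0,
                                 pct_asian = -0.05))
  suite <- run_model_suite(w$panel, w$attrs, outcomes = "mrfei")
  est <- suite[model_id == "mrfei.race.all" & term == "pct_asian"]
  expect_lt(est$estimate, 0)
  expect_lt(est$z, -1)  # clearly on the negative side, not just noise
})
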