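test_that("mRFEI definition, endpoints and degenerate tract", {
  expect_equal(compute_mrfei(2, 6), 25)
  expect_equal(compute_mrfei(0, 7), 0)
  expect_equal(compute_mrfei(7, 0), 100)
  expect_equal(compute_mrfei(0, 0), 0)
  expect_error(compute_mrfei(-1, 2), "non-negative")
  # denominator policy: intermediate outlets excluded by default
  expect_equal(compute_mrfei(2, 6, n_intermediate = 92), 25)
  expect_equal(compute_mrfei(2, 6, 2, denominator = "all"), 20)
})

test_that("mRFEI monotonicity and range over random counts", {
  set.seed(401)
  for (r in 1:200) {
    h <- rpois(1, 3); u <- rpois(1, 5)
    m <- compute_mrfei(h, u)
    expect_true(m >= 0 && m <= 100)
    # an extra unhealthy outlet never increases the score
    expect_lte(compute_mrfei(h, u + 1), m)
    # intermediate outlets never move the default score
    expect_equal(compute_mrfei(h, u, n_intermediate = rpois(1, 4)), m)
  }
})

test_that("HHI on percentage shares: worked values", {
  expect_equal(compute_hhi(c(100, 100, 100, 100)), 2500)
  expect_equal(compute_hhi(42), 10000)
  # shares 25,15,15,10,10,10,10,5 -> 625+225+225+100+100+100+100+25 = 1500
  expect_equal(compute_hhi(c(25, 15, 15, 10, 10, 10, 10, 5)), 1500)
  expect_equal(compute_hhi(numeric(0)), 0)
  expect_error(compute_hhi(c(10, 0)), "positive")
  expect_error(compute_hhi(c(10, -3)), "positive")
})

test_that("HHI invariants: scale invariance, 10000/k, merger monotonicity", {
  set.seed(402)
  for (r in 1:50) {
    k <- sample(2:12, 1)
    s <- rlnorm(k, 12, 1)
    h <- compute_hhi(s)
    expect_equal(compute_hhi(s * runif(1, 0.1, 50)), h, tolerance = 1e-12)
    expect_equal(compute_hhi(rep(runif(1, 1, 9), k)), 10000 / k,
                 tolerance = 1e-9)
    # merging two firms never decreases concentration
    idx <- sample(k, 2)
    merged <- c(sum(s[idx]), s[-idx])
    expect_gte(compute_hhi(merged), h - 1e-9)
  }
})

test_that("HHI bands follow the 1500/2500 boundaries", {
  expect_equal(hhi_band(1499.9), "COMPETITIVE")
  expect_equal(hhi_band(1500), "MODERATE")
  expect_equal(hhi_band(2000), "MODERATE")
  expect_equal(hhi_band(2500), "HIGH")     # "2500 or greater"
  expect_equal(hhi_band(10000), "HIGH")
  expect_equal(hhi_band(0, no_outlets = TRUE), "EMPTY")
  expect_error(hhi_band(10001), "\\[0, 10000\\]")
  expect_error(hhi_band(-1), "\\[0, 10000\\]")
})

test_that("USDA food-desert classifier applies both conditions", {
  # all thresholds exactly at their boundaries
  expect_true(classify_food_desert(20.0, 0.9, 500, 1000))
  # low-income test fails on both branches
  expect_false(classify_food_desert(5, 0.81, 900, 1000))
  # 499 < 500 persons even though the share is 83% >= 33%
  expect_false(classify_food_desert(40, 0.5, 499, 600))
  # income branch alone suffices
  expect_true(classify_food_desert(5, 0.80, 400, 1000) == FALSE)
  expect_true(classify_food_desert(5, 0.80, 500, 1200))
  # share below 33%
  expect_false(classify_food_desert(25, 0.5, 500, 2000))
  expect_error(classify_food_desert(10, 1, 10, 0), "population")
  expect_error(classify_food_desert(10, 0, 10, 100), "income_ratio")
  expect_error(classify_food_desert(10, 1, 200, 100), "exceed")
})

test_that("indices panel is balanced, zero-filled and matches brute force", {
  w <- small_world(seed = 21, n_rows = 4, n_cols = 4, years = 2000:2009)
  panel <- w$panel
  expect_equal(nrow(panel), 16L * 10L)
  expect_identical(
    names(panel),
    c("tract_id", "year", "n_healthy", "n_intermediate", "n_unhealthy",
      "mrfei", "hhi", "hhi_band", "no_outlets"))

  # independent tabulation of tier counts from the raw classified table
  cls <- w$classified[category != "NON_FOOD"]
  for (r in sample(nrow(panel), 40)) {
    row <- panel[r]
    sub <- cls[tract_id == row$tract_id & year == row$year]
    expect_equal(row$n_healthy, sum(sub$tier == "HEALTHY"))
    expect_equal(row$n_unhealthy, sum(sub$tier == "UNHEALTHY"))
    expect_equal(row$n_intermediate, sum(sub$tier == "INTERMEDIATE"))
    if (nrow(sub)) expect_equal(row$hhi, compute_hhi(sub$sales))
  }
  expect_identical(panel$no_outlets,
                   panel$n_healthy + panel$n_intermediate +
                     panel$n_unhealthy == 0L)
  expect_true(all(panel[no_outlets == TRUE, hhi_band] == "EMPTY"))
})

test_that("tract with outlets in one year still fills the whole grid", {
  est <- data.table::data.table(
    establishment_id = c("A", "B"), tract_id = "T1", year = 2005L,
    naics = c("445110", "722513"), name = c("Big Grocer", "Quick Bites"),
    employees = c(12L, 6L), sales = c(2e6, 4e5))
  cls <- classify_establishments(est)
  panel <- build_indices_panel(cls, years = 2000:2009)
  expect_equal(nrow(panel), 10L)
  expect_equal(sum(panel$no_outlets), 9L)
  expect_equal(panel[year == 2005, mrfei], 50)
  expect_equal(panel[year == 2005, hhi],
               compute_hhi(c(2e6, 4e5)))
})

test_that("duplicate establishment ids within a tract-year are rejected", {
  est <- data.table::data.table(
    establishment_id = c("A", "A"), tract_id = "T1", year = 2005L,
    naics = "445110", name = "Dup", employees = 10L, sales = 1e6)
  cls <- classify_establishments(est)
  expect_error(build_indices_panel(cls), "duplicate establishment_id")
})

test_that("NON_FOOD records never affect counts or HHI", {
  est <- data.table::data.table(
    establishment_id = c("A", "B", "C"), tract_id = "T1", year = 2000L,
    naics = c("445110", "811111", "452319"),
    name = c("Grocer", "Garage", "Bargain Barn"),
    employees = c(10L, 3L, 8L), sales = c(1e6, 9e9, 9e9))
  panel <- build_indices_panel(classify_establishments(est))
  expect_equal(panel$n_healthy, 1L)
  expect_equal(panel$n_unhealthy, 0L)
  expect_equal(panel$hhi, 10000)
})
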