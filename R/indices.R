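#' Modified Retail Food Environment Index (mRFEI)
#'
#' `mRFEI = 100 * healthy / (healthy + unhealthy)`: the percentage of a
#' tract's in-scope food retailers that are healthy, out of healthy plus
#' unhealthy retailers. Intermediate-tier outlets (full-service restaurants)
#' are excluded from the denominator under the default policy, following the
#' CDC's healthy / (healthy + less-healthy) convention; set
#' `denominator = "all"` to include them. Low values flag food
#' deserts/swamps, high values food oases.
#'
#' @param n_healthy,n_unhealthy non-negative outlet counts (vectorised).
#' @param n_intermediate intermediate-tier counts, used only under
#'   `denominator = "all"`.
#' @param denominator `"healthy_unhealthy"` (default) or `"all"`.
#' @return numeric in \[0, 100\]; 0 when the denominator is empty (callers
#'   should consult the `no_outlets` flag from [build_indices_panel()]).
#' @examples
#' compute_mrfei(2, 6)  # 25
#' @export
compute_mrfei <- function(n_healthy, n_unhealthy, n_intermediate = 0,
                          denominator = c("healthy_unhealthy", "all")) {
  denominator <- match.arg(denominator)
  if (any(n_healthy < 0) || any(n_unhealthy < 0) || any(n_intermediate < 0))
    stop("outlet counts must be non-negative", call. = FALSE)
  den <- n_healthy + n_unhealthy +
    if (denominator == "all") n_intermediate else 0
  ifelse(den > 0, 100 * n_healthy / den, 0)
}

#' Herfindahl-Hirschman Index from firm sales
#'
#' Sum of squared percentage market shares: 10000 for a monopoly, 10000/k
#' for k equal firms, 0 (with an empty market) for no firms.
#'
#' @param sales numeric vector of positive firm sales in one market.
#' @return HHI in points, `(0, 10000]`, or 0 for an empty market.
#' @examples
#' compute_hhi(c(100, 100, 100, 100))  # 2500
#' @export
compute_hhi <- function(sales) {
  if (length(sales) == 0L) return(0)
  if (any(!is.finite(sales)) || any(sales <= 0))
    stop("all sales must be positive and finite", call. = FALSE)
  shares <- 100 * sales / sum(sales)
  # guard the monopoly boundary against floating-point overshoot
  min(sum(shares^2), 10000)
}

#' HHI concentration band
#'
#' Department-of-Justice banding: below 1500 points is competitive,
#' 1500-2500 moderately concentrated, and 2500 or greater highly
#' concentrated (the "or greater" wording assigns the 2500 boundary to
#' HIGH). Empty markets are banded `EMPTY`.
#'
#' @param hhi numeric HHI in \[0, 10000\] (vectorised).
#' @param no_outlets logical, marks empty markets.
#' @return character vector in `{"COMPETITIVE","MODERATE","HIGH","EMPTY"}`.
#' @export
hhi_band <- function(hhi, no_outlets = FALSE) {
  if (any(!is.finite(hhi)) || any(hhi < 0) || any(hhi > 10000))
    stop("hhi must lie in [0, 10000]", call. = FALSE)
  band <- ifelse(hhi >= 2500, "HIGH",
          ifelse(hhi >= 1500, "MODERATE", "COMPETITIVE"))
  band[rep_len(no_outlets, length(hhi))] <- "EMPTY"
  band
}

#' USDA food-desert classifier
#'
#' A tract is a food desert iff it is both a low-income community (poverty
#' rate of 20% or greater, OR median family income at or below 80% of the
#' area median) and a low-access community (at least 500 persons AND at
#' least 33% of the population living more than one mile from a
#' supermarket).
#'
#' @param poverty_rate percentage in \[0, 100\].
#' @param income_ratio tract median family income / area median (> 0).
#' @param persons_low_access residents beyond one mile from a supermarket.
#' @param population tract population (> 0).
#' @return logical (vectorised).
#' @export
classify_food_desert <- function(poverty_rate, income_ratio,
                                 persons_low_access, population) {
  if (any(population <= 0))
    stop("population must be positive", call. = FALSE)
  if (any(income_ratio <= 0))
    stop("income_ratio must be positive", call. = FALSE)
  if (any(persons_low_access > population))
    stop("persons_low_access cannot exceed population", call. = FALSE)
  low_income <- poverty_rate >= 20 | income_ratio <= 0.80
  low_access <- persons_low_access >= 500 &
    persons_low_access / population >= 0.33
  low_income & low_access
}

#' Build the balanced tract-year indices panel
#'
#' Aggregates a classified establishment table to one row per tract x year
#' on the full year grid: tier counts, mRFEI, sales-share HHI over in-scope
#' food categories (firm = establishment), HHI band, and a `no_outlets`
#' flag. Tract-years with no in-scope outlet are kept, zero-filled and
#' flagged — the panel stays balanced so the Poisson estimator can consume
#' the zeros. `NON_FOOD` records never enter counts or sales shares.
#'
#' @param classified establishment table with `category`/`tier` columns
#'   (see [classify_establishments()]); must contain `tract_id`, `year`,
#'   `establishment_id`, `sales`.
#' @param years integer year grid (default: range observed in the data).
#' @param tract_ids tract universe (default: tracts observed in the data).
#' @param mrfei_denominator forwarded to [compute_mrfei()].
#' @return `data.table` with columns `tract_id`, `year`, `n_healthy`,
#'   `n_intermediate`, `n_unhealthy`, `mrfei`, `hhi`, `hhi_band`,
#'   `no_outlets`.
#' @export
build_indices_panel <- function(classified,
                                years = NULL, tract_ids = NULL,
                                mrfei_denominator = "healthy_unhealthy") {
  est <- as.data.table(classified)
  need <- c("establishment_id", "tract_id", "year", "sales", "category", "tier")
  miss <- setdiff(need, names(est))
  if (length(miss))
    stop("classified table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- est[, .N, by = .(tract_id, year, establishment_id)][N > 1]
  if (nrow(dup))
    stop("duplicate establishment_id within tract-year, e.g. ",
         dup$establishment_id[1], " in tract ", dup$tract_id[1], " year ",
         dup$year[1], call. = FALSE)
  if (is.null(years)) years <- seq(min(est$year), max(est$year))
  if (is.null(tract_ids)) tract_ids <- sort(unique(est$tract_id))

  scope <- est[category != "NON_FOOD"]
  counts <- scope[, .(
    n_healthy = sum(tier == "HEALTHY"),
    n_intermediate = sum(tier == "INTERMEDIATE"),
    n_unhealthy = sum(tier == "UNHEALTHY"),
    hhi = compute_hhi(sales)
  ), by = .(tract_id, year)]

  grid <- CJ(tract_id = tract_ids, year = as.integer(years), sorted = TRUE)
  panel <- merge(grid, counts, by = c("tract_id", "year"), all.x = TRUE)
  for (col in c("n_healthy", "n_intermediate", "n_unhealthy"))
    set(panel, which(is.na(panel[[col]])), col, 0L)
  panel[is.na(hhi), hhi := 0]
  panel[, no_outlets := n_healthy + n_intermediate + n_unhealthy == 0L]
  panel[, mrfei := compute_mrfei(n_healthy, n_unhealthy, n_intermediate,
                                 denominator = mrfei_denominator)]
  panel[, hhi_band := hhi_band(hhi, no_outlets)]
  setcolorder(panel, c("tract_id", "year", "n_healthy", "n_intermediate",
                       "n_unhealthy", "mrfei", "hhi", "hhi_band",
                       "no_outlets"))
  panel[]
}
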