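#' Configuration for the synthetic registry generator
#'
#' Bundles every knob of the synthetic world: lattice size, year range,
#' ground-truth coefficients linking tract attributes to healthy-outlet
#' intensity, fixed-effect dispersions, per-category baseline outlet rates,
#' and an optional planted spatial cluster of healthy outlets.
#'
#' Defaults describe a stylised US tract panel over 2000-2019: mean outlet
#' rates chosen so a typical tract-year holds a handful of food outlets
#' (supermarkets rarer than convenience stores and limited-service
#' restaurants), a positive White and negative Asian ground-truth effect on
#' healthy-outlet intensity per percentage point, and modest tract/year
#' log-intensity dispersion.
#'
#' @param n_rows,n_cols lattice dimensions (tracts = `n_rows * n_cols`).
#' @param years integer vector of calendar years (inclusive grid).
#' @param seed root RNG seed; per-table child seeds are derived from it.
#' @param beta_true named numeric: log-scale coefficient per percentage point
#'   of each tract attribute on outlet intensity.
#' @param beta_scope `"healthy"` (default) applies `beta_true` to
#'   healthy-tier categories only, so the coefficients move mRFEI in the
#'   same direction; `"all"` scales every food category alike.
#' @param fe_sd_tract,fe_sd_year standard deviations of tract and year
#'   log-intensity effects.
#' @param category_base_rates named numeric, baseline expected outlet count
#'   per tract-year for each category (upper-snake-case tokens; must include
#'   only known categories, see [outlet_categories()]).
#' @param metro_fraction proportion of tracts flagged metropolitan.
#' @param cluster_spec optional list `(center_row, center_col, radius,
#'   multiplier)`: tracts whose cell centres lie within `radius` cells
#'   (Euclidean) of the centre get healthy-category intensity multiplied by
#'   `multiplier`.
#' @param small_grocery_prob probability a grocery-coded establishment draws
#'   the small (< 5 employees) employment mode, exercising the
#'   reclassification rule.
#' @param nondollar_name_frac fraction of NAICS 452319 establishments given
#'   a name without the token "dollar", exercising the name filter.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_rows = 10L, n_cols = 10L,
                         years = 2000:2019,
                         seed = 20260911L,
                         beta_true = c(pct_white = 0.003, pct_black = 0,
                                       pct_asian = -0.006, pct_hispanic = 0),
                         beta_scope = c("healthy", "all"),
                         fe_sd_tract = 0.25, fe_sd_year = 0.1,
                         category_base_rates = c(
                           SUPERMARKET_GROCERY = 1.2,
                           FRUIT_VEG_MARKET = 0.4,
                           SUPERCENTRE = 0.2,
                           CONVENIENCE = 2.2,
                           DOLLAR = 0.6,
                           FULL_SERVICE_RESTAURANT = 2.0,
                           LIMITED_SERVICE_RESTAURANT = 2.6,
                           NON_FOOD = 3.0),
                         metro_fraction = 0.6,
                         cluster_spec = NULL,
                         small_grocery_prob = 0.3,
                         nondollar_name_frac = 0.25) {
  beta_scope <- match.arg(beta_scope)
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop("lattice dimensions must be >= 1", call. = FALSE)
  if (length(years) == 0L) stop("`years` must be non-empty", call. = FALSE)
  if (any(category_base_rates <= 0))
    stop("all category base rates must be > 0", call. = FALSE)
  known <- c(outlet_categories(), "NON_FOOD")
  bad <- setdiff(names(category_base_rates), known)
  if (length(bad))
    stop("unknown category in base rates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (metro_fraction < 0 || metro_fraction > 1)
    stop("`metro_fraction` must lie in [0, 1]", call. = FALSE)
  if (!is.null(cluster_spec)) {
    need <- c("center_row", "center_col", "radius", "multiplier")
    if (!all(need %in% names(cluster_spec)))
      stop("`cluster_spec` needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (cluster_spec$multiplier <= 0)
      stop("cluster multiplier must be > 0", call. = FALSE)
  }
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    years = as.integer(sort(unique(years))), seed = as.integer(seed),
    beta_true = beta_true, beta_scope = beta_scope,
    fe_sd_tract = fe_sd_tract, fe_sd_year = fe_sd_year,
    category_base_rates = category_base_rates,
    metro_fraction = metro_fraction, cluster_spec = cluster_spec,
    small_grocery_prob = small_grocery_prob,
    nondollar_name_frac = nondollar_name_frac
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_rows, "x", x$n_cols, "lattice,",
      length(x$years), "years (", min(x$years), "-", max(x$years), "), seed",
      x$seed, "\n")
  invisible(x)
}
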