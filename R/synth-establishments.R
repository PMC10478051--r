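# category -> NAICS code used when emitting synthetic records
synth_naics_map <- function() {
  m <- naics_category_map()
  c(stats::setNames(names(m), unname(m)), NON_FOOD = "811111")
}

#' Generate a synthetic establishment registry
#'
#' For every tract-year and outlet category, an establishment count is drawn
#' Poisson with log-mean
#' `log(base rate) + sum(beta_true * attributes) + tract effect + year effect`,
#' plus `log(multiplier)` for healthy-tier categories inside the planted
#' cluster (if configured). With the default `beta_scope = "healthy"` the
#' ground-truth coefficients shift only healthy-category intensity, so they
#' propagate to mRFEI with the same sign and are recoverable by regressing
#' the healthy-outlet count on the attributes.
#'
#' Establishment attributes exercise every downstream rule: grocery-coded
#' stores draw a bimodal employee distribution (a `small_grocery_prob` mass
#' below five employees triggers the corner-store reclassification), a
#' `nondollar_name_frac` share of NAICS 452319 records get names without the
#' token "dollar" (triggering the name filter), and sales are lognormal with
#' category-specific medians and sdlog 0.8, giving heavy-tailed,
#' non-degenerate HHI variation.
#'
#' @param config a [synth_config()].
#' @param attrs attribute panel from [generate_attributes()].
#' @param geoms tract geometries; required when `config$cluster_spec` is set
#'   (cluster membership is Euclidean centroid distance in cells).
#' @return `data.table` with columns `establishment_id`, `tract_id`, `year`,
#'   `naics`, `name`, `employees`, `sales`.
#' @export
generate_establishments <- function(config, attrs, geoms = NULL) {
  stopifnot(inherits(config, "synth_config"))
  rates <- config$category_base_rates
  healthy_cats <- c("SUPERMARKET_GROCERY", "FRUIT_VEG_MARKET", "SUPERCENTRE")

  cells <- CJ(tract_id = unique(attrs$tract_id), year = config$years,
              category = names(rates), sorted = TRUE)
  cells <- merge(cells, attrs, by = c("tract_id", "year"))

  # ground-truth attribute effects (log scale, per percentage point)
  beta <- config$beta_true
  unknown <- setdiff(names(beta), names(attrs))
  if (length(unknown))
    stop("beta_true names not in attribute panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  xb <- rep(0, nrow(cells))
  for (v in names(beta)) xb <- xb + beta[[v]] * cells[[v]]
  scope <- if (config$beta_scope == "healthy")
    cells$category %in% healthy_cats else cells$category != "NON_FOOD"
  cells[, lambda := rates[category] * exp(xb * scope)]

  with_seed(child_seed(config$seed, "establishments"), {
    ids <- unique(attrs$tract_id)
    fe_tract <- stats::setNames(rnorm(length(ids), 0, config$fe_sd_tract), ids)
    fe_year <- stats::setNames(rnorm(length(config$years), 0, config$fe_sd_year),
                               as.character(config$years))
    cells[, lambda := lambda * exp(fe_tract[tract_id] +
                                   fe_year[as.character(year)])]

    if (!is.null(config$cluster_spec)) {
      if (is.null(geoms))
        stop("`geoms` required when cluster_spec is set", call. = FALSE)
      cs <- config$cluster_spec
      cx <- cs$center_col - 0.5; cy <- cs$center_row - 0.5
      d <- sqrt((geoms$centroid_x - cx)^2 + (geoms$centroid_y - cy)^2)
      inside <- geoms$tract_id[d <= cs$radius]
      cells[tract_id %chin% inside & category %in% healthy_cats,
            lambda := lambda * cs$multiplier]
    }

    cells[, n_outlets := rpois(.N, lambda)]
    est <- cells[n_outlets > 0,
                 .(tract_id = rep(tract_id, n_outlets),
                   year = rep(year, n_outlets),
                   category = rep(category, n_outlets))]
    if (nrow(est) == 0L)
      return(data.table(establishment_id = character(), tract_id = character(),
                        year = integer(), naics = character(),
                        name = character(), employees = integer(),
                        sales = numeric()))
    setorder(est, tract_id, year, category)
    est[, establishment_id := sprintf("E%08d", .I)]
    est[, naics := synth_naics_map()[category]]

    n <- nrow(est)
    # employees: category-typical; grocery bimodal so the corner-store rule
    # bites on a known expected fraction
    emp <- integer(n)
    draw <- function(mask, fun) if (any(mask)) emp[mask] <<- fun(sum(mask))
    draw(est$category == "SUPERMARKET_GROCERY", function(k) {
      small <- runif(k) < config$small_grocery_prob
      ifelse(small, sample(0:4, k, replace = TRUE), 20L + rpois(k, 15))
    })
    draw(est$category == "FRUIT_VEG_MARKET",
         function(k) 1L + rpois(k, 3))
    draw(est$category == "SUPERCENTRE", function(k) 80L + rpois(k, 60))
    draw(est$category == "CONVENIENCE",
         function(k) sample(1:8, k, replace = TRUE))
    draw(est$category == "DOLLAR", function(k) 4L + rpois(k, 6))
    draw(est$category == "FULL_SERVICE_RESTAURANT",
         function(k) 8L + rpois(k, 10))
    draw(est$category == "LIMITED_SERVICE_RESTAURANT",
         function(k) 5L + rpois(k, 8))
    draw(est$category == "NON_FOOD", function(k) 1L + rpois(k, 5))
    est[, employees := emp]

    sales_meanlog <- c(SUPERMARKET_GROCERY = log(2e6),
                       FRUIT_VEG_MARKET = log(3e5),
                       SUPERCENTRE = log(2e7),
                       CONVENIENCE = log(4e5),
                       DOLLAR = log(1e6),
                       FULL_SERVICE_RESTAURANT = log(8e5),
                       LIMITED_SERVICE_RESTAURANT = log(6e5),
                       NON_FOOD = log(5e5))
    est[, sales := rlnorm(.N, sales_meanlog[category], 0.8)]

    # names: dollar-category records carry the token "Dollar" except for a
    # planted non-dollar fraction that the name filter must reject
    nm <- character(n)
    generic <- c("Market", "Foods", "Corner Shop", "Eatery", "Diner",
                 "Services", "Outfitters", "Depot")
    nm <- paste0(sample(c("Oak", "Main St", "Riverside", "Sunset", "Union",
                          "Liberty", "Cedar", "Summit"), n, replace = TRUE),
                 " ", sample(generic, n, replace = TRUE),
                 " #", seq_len(n))
    is_dollar <- est$category == "DOLLAR"
    if (any(is_dollar)) {
      k <- sum(is_dollar)
      nondollar <- runif(k) < config$nondollar_name_frac
      dn <- ifelse(nondollar,
                   paste0("Big Bargain Mart #", which(is_dollar)),
                   paste0(sample(c("Family Dollar", "Dollar Tree",
                                   "Dollar Depot", "Super Dollar"),
                                 k, replace = TRUE),
                          " #", which(is_dollar)))
      nm[is_dollar] <- dn
    }
    est[, name := nm]
    est[, category := NULL]
    setcolorder(est, c("establishment_id", "tract_id", "year", "naics",
                       "name", "employees", "sales"))
    est[]
  })
}

#' Generate a full synthetic bundle
#'
#' Convenience wrapper running [generate_lattice()],
#' [generate_attributes()] and [generate_establishments()] and optionally
#' writing `tracts.geojson`, `tract_attributes.csv`, `establishments.csv`.
#'
#' @param config a [synth_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with `geoms`, `attrs`, `establishments` (and `files` when
#'   `outdir` given).
#' @export
simulate_registry <- function(config, outdir = NULL) {
  geoms <- generate_lattice(config)
  attrs <- generate_attributes(config, geoms)
  est <- generate_establishments(config, attrs, geoms)
  out <- list(geoms = geoms, attrs = attrs, establishments = est)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(outdir, c("tracts.geojson", "tract_attributes.csv",
                                 "establishments.csv"))
    write_tracts_geojson(geoms, files[1])
    fwrite(attrs, files[2])
    fwrite(est, files[3])
    out$files <- files
  }
  out
}
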