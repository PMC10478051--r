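#' Generate a synthetic tract-year attribute panel
#'
#' Emulates the Census/ACS/SVI side of the analysis. Race shares (White,
#' Black, Asian, other) are drawn per tract from a Dirichlet composition and
#' given small tract-specific *linear* drifts over years (clipped only
#' through the drift slope, so each trajectory is exactly linear); Hispanic
#' share is an independent ethnicity axis. Poverty is tied linearly to the
#' minority share plus tract noise, so race coefficients are identified
#' within tract. SVI sub-themes are rank-normalised transforms of
#' poverty/minority attributes, so higher minority share implies a higher
#' minority-status-and-language score by construction.
#'
#' @param config a [synth_config()].
#' @param geoms tract geometries from [generate_lattice()] (or GeoJSON read
#'   back); defines the tract set.
#' @return `data.table`, one row per tract-year, columns `tract_id`, `year`,
#'   `pct_white`, `pct_black`, `pct_asian`, `pct_hispanic`, `population`,
#'   `pct_bachelor`, `poverty_rate`, `metro`, `svi_overall`, `svi_ses`,
#'   `svi_household`, `svi_minority_language`, `svi_housing_transport`.
#' @export
generate_attributes <- function(config, geoms) {
  stopifnot(inherits(config, "synth_config"), inherits(geoms, "tract_geoms"))
  ids <- geoms$tract_id
  n <- length(ids)
  yrs <- config$years
  span <- max(yrs) - min(yrs)

  with_seed(child_seed(config$seed, "attributes"), {
    # Dirichlet(8, 1.5, 0.8, 0.7) race composition, in percent
    g <- matrix(rgamma(n * 4L, shape = rep(c(8, 1.5, 0.8, 0.7), each = n)),
                nrow = n)
    shares <- 100 * g / rowSums(g)
    w0 <- shares[, 1]; b0 <- shares[, 2]; a0 <- shares[, 3]

    # tract-specific linear drift slopes (pp/year), jointly scaled so that
    # every share stays in (0.5, 99) and the race sum stays below 99.5 over
    # the full span -- trajectories remain exactly linear
    sw <- rnorm(n, 0, 0.3); sb <- rnorm(n, 0, 0.15); sa <- rnorm(n, 0, 0.1)
    scl <- rep(1, n)
    if (span > 0) {
      bound <- function(v0, s, lo = 0.5, hi = 99) {
        lim <- ifelse(s > 0, (hi - v0) / (s * span),
               ifelse(s < 0, (lo - v0) / (s * span), Inf))
        pmax(lim, 0)
      }
      ssum <- sw + sb + sa
      scl <- pmin(1, bound(w0, sw), bound(b0, sb), bound(a0, sa),
                  bound(w0 + b0 + a0, ssum, hi = 99.5))
    }
    sw <- sw * scl; sb <- sb * scl; sa <- sa * scl

    h0 <- 100 * rbeta(n, 2, 6)
    sh <- rnorm(n, 0, 0.2)
    if (span > 0) {
      lim_h <- ifelse(sh > 0, (99 - h0) / (sh * span),
               ifelse(sh < 0, (0.5 - h0) / (sh * span), Inf))
      sh <- sh * pmin(1, pmax(lim_h, 0))
    }

    pop0 <- rlnorm(n, log(4000), 0.35)
    growth <- rnorm(n, 0.005, 0.01)
    bach0 <- 100 * rbeta(n, 2.5, 4.5)
    sbach <- rnorm(n, 0.15, 0.1)
    pov_noise <- rnorm(n, 0, 4)
    metro_flag <- rbinom(n, 1L, config$metro_fraction) == 1L

    panel <- CJ(tract_id = ids, year = yrs, sorted = TRUE)
    idx <- match(panel$tract_id, ids)
    t_rel <- panel$year - min(yrs)
    panel[, pct_white := w0[idx] + sw[idx] * t_rel]
    panel[, pct_black := b0[idx] + sb[idx] * t_rel]
    panel[, pct_asian := a0[idx] + sa[idx] * t_rel]
    panel[, pct_hispanic := h0[idx] + sh[idx] * t_rel]
    panel[, population := pmax(50L, as.integer(round(
      pop0[idx] * (1 + growth[idx])^t_rel)))]
    panel[, pct_bachelor := pmin(99, pmax(0.5, bach0[idx] + sbach[idx] * t_rel))]
    # tract-year noise keeps poverty from being collinear with the race
    # shares once tract fixed effects are absorbed
    panel[, poverty_rate := pmin(70, pmax(0.5,
      5 + 0.25 * (100 - pct_white) + pov_noise[idx] + rnorm(.N, 0, 1.5)))]
    panel[, metro := metro_flag[idx]]

    # SVI: within-year rank-normalised scores in [0, 1]
    rank01 <- function(v) (frank(v, ties.method = "average") - 0.5) / length(v)
    panel[, `:=`(
      svi_ses = rank01(poverty_rate + rnorm(.N, 0, 2)),
      svi_household = rank01(0.3 * poverty_rate + rnorm(.N, 0, 5)),
      svi_minority_language = rank01(
        (100 - pct_white) + 0.5 * pct_hispanic + rnorm(.N, 0, 3)),
      svi_housing_transport = rank01(
        0.3 * (100 - pct_white) + rnorm(.N, 0, 6))
    ), by = year]
    panel[, svi_overall := rank01(
      svi_ses + svi_household + svi_minority_language + svi_housing_transport),
      by = year]
    panel[]
  })
}
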