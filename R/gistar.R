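# two-sided standard-normal critical values, fixed to six decimals for
# bit-stable confidence binning
GI_CRIT <- c(`90` = 1.644854, `95` = 1.959964, `99` = 2.575829)

#' Getis-Ord Gi* statistic
#'
#' For each tract i (self included in its own neighbourhood):
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar X W_i}
#'   {S \sqrt{(n \sum_j w_{ij}^2 - W_i^2)/(n-1)}}}
#' with \eqn{W_i = \sum_j w_{ij}}, \eqn{\bar X} the global mean and
#' \eqn{S = \sqrt{\sum_j x_j^2/n - \bar X^2}}. Large positive z marks a hot
#' spot (cluster of high values), large negative a cold spot.
#'
#' @param values numeric vector aligned to `weights$ids`.
#' @param weights a `spatial_weights` object ([build_weights()]).
#' @return numeric z-score per tract.
#' @export
gi_star <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$ids)
  if (length(values) != n)
    stop("`values` length (", length(values),
         ") does not match weights (", n, ")", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values in the score field", call. = FALSE)
  xbar <- mean(values)
  # algebraically sum(x^2)/n - xbar^2, computed in centred form so that
  # near-constant fields do not cancel catastrophically
  s2 <- sum((values - xbar)^2) / n
  if (s2 <= 0)
    stop("degenerate field: constant values, Gi* undefined", call. = FALSE)
  S <- sqrt(s2)
  # a field constant up to floating-point noise carries no spatial signal:
  # standardising rounding error would manufacture spurious clusters
  if (S < 1e-10 * (abs(xbar) + S))
    return(numeric(n))
  vapply(seq_len(n), function(i) {
    w <- weights$weights[[i]]
    nb <- weights$neighbours[[i]]
    Wi <- sum(w)
    num <- sum(w * values[nb]) - xbar * Wi
    den <- S * sqrt((n * sum(w^2) - Wi^2) / (n - 1))
    num / den
  }, numeric(1))
}

#' Signed confidence bin from a Gi* z-score
#'
#' Two-sided normal binning at the 90/95/99% confidence levels:
#' |z| >= 2.575829 gives |bin| 3, >= 1.959964 gives 2, >= 1.644854 gives 1,
#' else 0; the sign of the bin is the sign of z (hot positive, cold
#' negative).
#'
#' @param z numeric z-score(s).
#' @return integer bin(s) in `{-3,...,3}`.
#' @export
bin_confidence <- function(z) {
  if (any(!is.finite(z)))
    stop("non-finite z-score", call. = FALSE)
  mag <- ifelse(abs(z) >= GI_CRIT["99"], 3L,
         ifelse(abs(z) >= GI_CRIT["95"], 2L,
         ifelse(abs(z) >= GI_CRIT["90"], 1L, 0L)))
  as.integer(sign(z) * mag)
}

#' Per-year hot-spot analysis of an indices panel
#'
#' Runs Gi* on one value column (default mRFEI) of the tract-year indices
#' panel for each requested year. HHI is accepted but is typically
#' uninformative when many tract-years carry null/zero HHI.
#'
#' @param panel indices panel ([build_indices_panel()]) or any tract-year
#'   table containing `value` as a column.
#' @param weights a `spatial_weights` whose `ids` define the tract set.
#' @param value column to analyse (`"mrfei"` or `"hhi"`).
#' @param years years to analyse (default: all in `panel`).
#' @param fdr if `TRUE`, bins are recomputed from Benjamini-Hochberg
#'   adjusted p-values (sensitivity mode; default off, matching raw
#'   confidence bins).
#' @return `data.table` with `tract_id`, `year`, `gi_z`, `p_value`, `bin`.
#' @export
hotspot_panel <- function(panel, weights, value = "mrfei", years = NULL,
                          fdr = FALSE) {
  panel <- as.data.table(panel)
  if (!value %in% names(panel))
    stop("value column not in panel: ", value, call. = FALSE)
  if (is.null(years)) years <- sort(unique(panel$year))
  out <- lapply(years, function(yr) {
    slice <- panel[year == yr]
    m <- match(weights$ids, slice$tract_id)
    if (anyNA(m))
      stop("panel year ", yr, " missing tract(s): ",
           paste(head(weights$ids[is.na(m)], 5L), collapse = ", "),
           call. = FALSE)
    x <- slice[[value]][m]
    z <- gi_star(x, weights)
    p <- 2 * pnorm(-abs(z))
    b <- if (fdr) {
      padj <- stats::p.adjust(p, method = "BH")
      mag <- ifelse(padj <= 0.01, 3L, ifelse(padj <= 0.05, 2L,
             ifelse(padj <= 0.10, 1L, 0L)))
      as.integer(sign(z) * mag)
    } else bin_confidence(z)
    data.table(tract_id = weights$ids, year = yr, gi_z = z, p_value = p,
               bin = b)
  })
  rbindlist(out)
}

#' Cross-year cluster transitions
#'
#' Compares the first and last analysed year of a hot-spot result table and
#' labels each tract's transition: `stable-hot`, `stable-cold`, `cold->hot`,
#' `hot->cold`, `emerging-hot`, `emerging-cold` or `none`. Also tallies hot
#' (bin > 0) and cold (bin < 0) tract counts per year.
#'
#' @param hotspots output of [hotspot_panel()] covering >= 2 years on one
#'   tract set.
#' @return list with `transitions` (per-tract table: `tract_id`,
#'   `first_bin`, `last_bin`, `transition`) and `counts_by_year`
#'   (`year`, `n_hot`, `n_cold`).
#' @export
compare_years <- function(hotspots) {
  hs <- as.data.table(hotspots)
  yrs <- sort(unique(hs$year))
  if (length(yrs) < 2L)
    stop("need >= 2 years of hot-spot results", call. = FALSE)
  sets <- hs[, .(ids = list(sort(tract_id))), by = year]
  if (length(unique(sets$ids)) != 1L)
    stop("tract sets differ across years", call. = FALSE)
  first <- hs[year == yrs[1], .(tract_id, first_bin = bin)]
  last <- hs[year == yrs[length(yrs)], .(tract_id, last_bin = bin)]
  tr <- merge(first, last, by = "tract_id")
  lab <- function(f, l) {
    if (f < 0 && l > 0) "cold->hot"
    else if (f > 0 && l < 0) "hot->cold"
    else if (f > 0 && l > 0) "stable-hot"
    else if (f < 0 && l < 0) "stable-cold"
    else if (f == 0 && l > 0) "emerging-hot"
    else if (f == 0 && l < 0) "emerging-cold"
    else "none"
  }
  tr[, transition := mapply(lab, first_bin, last_bin)]
  counts <- hs[, .(n_hot = sum(bin > 0), n_cold = sum(bin < 0)), by = year]
  setorder(counts, year)
  list(transitions = tr[], counts_by_year = counts[])
}
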