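library(data.table)

# Independent Gi* oracle: literal double-loop evaluation of the formula.
naive_gi_star <- function(values, weights) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wij <- numeric(n)
    nb <- weights$neighbours[[i]]
    wij[nb] <- weights$weights[[i]]
    num <- 0; Wi <- 0; S1 <- 0
    for (j in seq_len(n)) {
      num <- num + wij[j] * values[j]
      Wi <- Wi + wij[j]
      S1 <- S1 + wij[j]^2
    }
    z[i] <- (num - xbar * Wi) / (S * sqrt((n * S1 - Wi^2) / (n - 1)))
  }
  z
}

# Brute-force queen adjacency oracle for a unit lattice: two cells are queen
# neighbours iff both row and column indices differ by at most one.
lattice_queen_oracle <- function(geoms) {
  rc <- data.table(row = as.integer(substr(geoms$tract_id, 1, 3)),
                   col = as.integer(substr(geoms$tract_id, 4, 6)))
  n <- nrow(rc)
  lapply(seq_len(n), function(i)
    which(abs(rc$row - rc$row[i]) <= 1L & abs(rc$col - rc$col[i]) <= 1L))
}

# Explicit-dummy Poisson pseudo-ML oracle via stats::glm.
glm_ppml_oracle <- function(data, outcome, regressors,
                            fe = c("tract_id", "year")) {
  red <- drop_singletons_separated(data, outcome, fe)$data
  fml <- stats::as.formula(paste(
    outcome, "~", paste(regressors, collapse = " + "), "+",
    paste(sprintf("factor(%s)", fe), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = red, family = stats::poisson()))
  stats::coef(fit)[regressors]
}

# Small synthetic world shared by several test files.
small_world <- function(seed = 42L, n_rows = 6L, n_cols = 6L,
                        years = 2000:2004, ...) {
  cfg <- synth_config(n_rows = n_rows, n_cols = n_cols, years = years,
                      seed = seed, ...)
  b <- simulate_registry(cfg)
  b$classified <- classify_establishments(b$establishments)
  b$panel <- build_indices_panel(b$classified, years = cfg$years,
                                 tract_ids = b$geoms$tract_id)
  b$joined <- merge(b$panel, b$attrs, by = c("tract_id", "year"))
  b$config <- cfg
  b
}

# Polygon area by the shoelace formula (lattice cells should all be 1).
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
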