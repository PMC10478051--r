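#' Drop singleton and separated observations
#'
#' Iteratively removes, until a fixed point: (a) observations alone in a
#' fixed-effect group after earlier removals (singletons, which carry no
#' identifying variation), and (b) entire fixed-effect groups whose outcome
#' is all zero (perfectly separated under the log link — the group's
#' intercept diverges to -Inf).
#'
#' @param data panel `data.table`/data.frame.
#' @param outcome outcome column name (non-negative).
#' @param fe character vector of fixed-effect column names.
#' @return list with `data` (reduced `data.table`), `n_singletons`,
#'   `n_separated`.
#' @export
drop_singletons_separated <- function(data, outcome, fe) {
  dt <- as.data.table(data)
  n_singletons <- 0L
  n_separated <- 0L
  repeat {
    n_before <- nrow(dt)
    for (f in fe) {
      keep <- dt[, .N, by = f][N > 1L][[f]]
      drop_n <- nrow(dt) - sum(dt[[f]] %in% keep)
      if (drop_n > 0L) {
        n_singletons <- n_singletons + drop_n
        dt <- dt[dt[[f]] %in% keep]
      }
    }
    for (f in fe) {
      y <- dt[[outcome]]
      allzero <- dt[, .(az = all(get(outcome) == 0)), by = f][az == TRUE][[f]]
      drop_n <- sum(dt[[f]] %in% allzero)
      if (drop_n > 0L) {
        n_separated <- n_separated + drop_n
        dt <- dt[!dt[[f]] %in% allzero]
      }
    }
    if (nrow(dt) == n_before) break
  }
  if (nrow(dt) == 0L)
    stop("no identifying variation: empty panel after singleton/separation ",
         "dropping", call. = FALSE)
  list(data = dt, n_singletons = n_singletons, n_separated = n_separated)
}

# Weighted two-way within-demeaning by alternating projections.
# M: numeric matrix; w: weights; groups: list of integer group-id vectors.
# Iterates full sweeps until the largest entry change < tol.
demean_hdfe <- function(M, w, groups, tol = 1e-10, max_sweeps = 10000L) {
  if (length(groups) == 0L) return(M)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (g in groups) {
      wm <- rowsum(M * w, g, reorder = FALSE) /
        as.vector(rowsum(w, g, reorder = FALSE))
      adj <- wm[match(g, rownames(wm)), , drop = FALSE]
      M <- M - adj
      delta <- max(delta, max(abs(adj)))
    }
    if (delta < tol || length(groups) == 1L) break
  }
  M
}

#' Two-way fixed-effects Poisson pseudo-maximum-likelihood
#'
#' Fits `E[y | x] = exp(x'beta + alpha_i + gamma_t)` by iteratively
#' re-weighted least squares with the fixed effects absorbed from the
#' working response and regressors by weighted alternating projections
#' (within-transformation iterated to an inner tolerance). The outcome only
#' needs to be non-negative — mRFEI and HHI are continuous, which the
#' pseudo-likelihood permits. Deviance is monitored with step-halving, the
#' standard guard against the convergence issues of separated/ill-scaled
#' Poisson fits. Standard errors are cluster-robust (sandwich with
#' cluster-summed scores and a G/(G-1) small-sample factor).
#'
#' @param data panel table.
#' @param outcome name of the non-negative outcome column.
#' @param regressors character vector of regressor column names.
#' @param fe character vector of fixed-effect columns (default tract and
#'   year); `NULL` fits with an explicit intercept instead.
#' @param cluster cluster column for the sandwich (default first FE);
#'   `NULL` for one-cluster-per-observation (HC) errors.
#' @param drop run [drop_singletons_separated()] first (default `TRUE` when
#'   `fe` is non-empty).
#' @param tol relative-deviance outer convergence tolerance.
#' @param proj_tol inner alternating-projection tolerance.
#' @param max_iter maximum outer IRLS iterations.
#' @return object of class `ppml_fit`: `coefficients`, `se`, `z`, `vcov`,
#'   `n_obs`, `n_singletons_dropped`, `n_separated_dropped`, `deviance`,
#'   `pseudo_r2`, `iterations`, `converged`, `fitted`, `data` (the rows
#'   used), plus bookkeeping on dropped collinear regressors.
#' @export
fit_ppml_hdfe <- function(data, outcome, regressors,
                          fe = c("tract_id", "year"), cluster = fe[1],
                          drop = length(fe) > 0, tol = 1e-9,
                          proj_tol = 1e-10, max_iter = 200L) {
  dt <- as.data.table(data)
  miss <- setdiff(c(outcome, regressors, fe, cluster), names(dt))
  if (length(miss))
    stop("panel missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_singletons <- 0L; n_separated <- 0L
  if (drop && length(fe)) {
    red <- drop_singletons_separated(dt, outcome, fe)
    dt <- red$data
    n_singletons <- red$n_singletons
    n_separated <- red$n_separated
  }
  y <- as.numeric(dt[[outcome]])
  if (any(!is.finite(y)) || any(y < 0))
    stop("outcome must be finite and non-negative", call. = FALSE)

  if (length(fe)) {
    X <- as.matrix(dt[, ..regressors])
    groups <- lapply(fe, function(f) as.integer(factor(dt[[f]])))
  } else {
    X <- matrix(1, nrow(dt), 1L, dimnames = list(NULL, "(Intercept)"))
    if (length(regressors)) X <- cbind(X, as.matrix(dt[, ..regressors]))
    groups <- list()
  }
  if (any(!is.finite(X))) stop("non-finite regressor values", call. = FALSE)
  n <- length(y); k <- ncol(X)

  dev_fun <- function(mu)
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))

  mu <- (y + mean(y)) / 2
  eta <- log(mu)
  dev <- dev_fun(mu)
  dropped_collinear <- character(0)
  keep <- seq_len(k)
  converged <- FALSE
  iter <- 0L
  dev_trace <- numeric(0)

  for (iter in seq_len(max_iter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    Xd <- demean_hdfe(X[, keep, drop = FALSE], w, groups, tol = proj_tol)
    zd <- demean_hdfe(cbind(z), w, groups, tol = proj_tol)[, 1]

    if (iter == 1L) {
      qrx <- qr(sqrt(w) * Xd)
      if (qrx$rank < length(keep)) {
        bad <- qrx$pivot[seq.int(qrx$rank + 1L, length(keep))]
        dropped_collinear <- colnames(X)[keep][bad]
        warning("dropping collinear regressor(s): ",
                paste(dropped_collinear, collapse = ", "), call. = FALSE)
        keep <- keep[-bad]
        Xd <- demean_hdfe(X[, keep, drop = FALSE], w, groups, tol = proj_tol)
      }
    }

    XtWX <- crossprod(Xd, w * Xd)
    beta <- solve(XtWX, crossprod(Xd, w * zd))
    # FWL: the full WLS residual equals the demeaned-regression residual
    eta_new <- z - (zd - as.vector(Xd %*% beta))
    mu_new <- exp(eta_new)
    dev_new <- dev_fun(mu_new)

    # step-halving guard: the near-saturated start has lower deviance than
    # any fitted model, so the first step is exempt from the monotonicity
    # check (only non-finite deviance is halved there)
    halvings <- 0L
    while ((!is.finite(dev_new) ||
            (iter > 1L && dev_new > dev * (1 + 1e-10) + 1e-8)) &&
           halvings < 30L) {
      eta_new <- (eta_new + eta) / 2
      mu_new <- exp(eta_new)
      dev_new <- dev_fun(mu_new)
      halvings <- halvings + 1L
    }
    done <- iter > 1L && is.finite(dev) &&
      abs(dev_new - dev) / (0.1 + abs(dev_new)) < tol
    eta <- eta_new; mu <- mu_new; dev <- dev_new
    dev_trace <- c(dev_trace, dev)
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stop("PPML did not converge in ", max_iter,
         " iterations (deviance ", signif(dev, 8), ")", call. = FALSE)

  # final absorbed regressors and sandwich pieces at the converged weights
  w <- mu
  Xd <- demean_hdfe(X[, keep, drop = FALSE], w, groups, tol = proj_tol)
  bread <- solve(crossprod(Xd, w * Xd))
  scores <- (y - mu) * Xd

  if (is.null(cluster)) {
    cl_ids <- seq_len(n)
  } else {
    cl_ids <- as.integer(factor(dt[[cluster]]))
  }
  G <- length(unique(cl_ids))
  if (G < 2L) stop("need at least two clusters", call. = FALSE)
  meat <- crossprod(rowsum(scores, cl_ids, reorder = FALSE))
  V <- (G / (G - 1)) * bread %*% meat %*% bread

  beta <- as.vector(solve(crossprod(Xd, w * Xd),
                          crossprod(Xd, w * demean_hdfe(cbind(log(mu) +
                            (y - mu) / mu), w, groups, tol = proj_tol)[, 1])))
  names(beta) <- colnames(X)[keep]
  se <- sqrt(diag(V))
  names(se) <- names(beta)
  separated_fit <- sum(mu < 1e-12)

  structure(list(
    coefficients = beta, se = se, z = beta / se, vcov = V,
    n_obs = n, n_singletons_dropped = n_singletons,
    n_separated_dropped = n_separated,
    n_near_separated_fitted = separated_fit,
    deviance = dev, deviance_trace = dev_trace,
    pseudo_r2 = suppressWarnings(cor(y, mu))^2,
    iterations = iter, converged = converged,
    fitted = mu, outcome = outcome,
    dropped_collinear = dropped_collinear,
    n_clusters = G, data = dt
  ), class = "ppml_fit")
}

#' @export
print.ppml_fit <- function(x, ...) {
  cat("Two-way FE Poisson pseudo-ML fit\n")
  cat("  outcome:", x$outcome, " n_obs:", x$n_obs,
      " clusters:", x$n_clusters, "\n")
  cat("  dropped: ", x$n_singletons_dropped, " singleton, ",
      x$n_separated_dropped, " separated obs\n", sep = "")
  cat("  deviance:", signif(x$deviance, 6),
      " pseudo-R2:", round(x$pseudo_r2, 4),
      " iterations:", x$iterations, "\n\n")
  tab <- data.frame(estimate = x$coefficients, cluster_se = x$se,
                    z = x$z, p = 2 * pnorm(-abs(x$z)))
  print(signif(tab, 4))
  invisible(x)
}

#' @export
coef.ppml_fit <- function(object, ...) object$coefficients

#' @export
vcov.ppml_fit <- function(object, ...) object$vcov

#' Run the full model grid
#'
#' Fits the study's model grid on a joined indices + attributes panel:
#' outcomes {mrfei, hhi} x models {race (White/Black/Asian), Hispanic} x
#' subsets {all, metro, non-metro} — twelve baseline fits — plus SVI
#' robustness fits {overall score, four sub-theme scores} per outcome on the
#' full sample (four fits). Controls everywhere: log population, % bachelor,
#' poverty rate. All fits use tract and year fixed effects and
#' tract-clustered standard errors.
#'
#' @param indices tract-year indices panel ([build_indices_panel()]).
#' @param attrs tract-year attribute panel.
#' @param outcomes outcomes to fit.
#' @param ... forwarded to [fit_ppml_hdfe()].
#' @return tidy `data.table`: `model_id`, `outcome`, `model`, `subset`,
#'   `term`, `estimate`, `se`, `z`, `p`, `n_obs`, `n_singletons`,
#'   `n_separated`.
#' @export
run_model_suite <- function(indices, attrs, outcomes = c("mrfei", "hhi"),
                            ...) {
  panel <- merge(as.data.table(indices), as.data.table(attrs),
                 by = c("tract_id", "year"))
  if (nrow(panel) == 0L) stop("empty join of indices and attributes",
                              call. = FALSE)
  panel[, log_population := log(population)]
  controls <- c("log_population", "pct_bachelor", "poverty_rate")
  models <- list(
    race = c("pct_white", "pct_black", "pct_asian"),
    hispanic = "pct_hispanic",
    svi_overall = "svi_overall",
    svi_subthemes = c("svi_ses", "svi_household", "svi_minority_language",
                      "svi_housing_transport"))
  grid <- rbind(
    CJ(outcome = outcomes, model = c("race", "hispanic"),
       subset = c("all", "metro", "nonmetro")),
    CJ(outcome = outcomes, model = c("svi_overall", "svi_subthemes"),
       subset = "all"))
  res <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r]
    sub <- switch(g$subset,
                  all = panel,
                  metro = panel[metro == TRUE],
                  nonmetro = panel[metro == FALSE])
    mid <- paste(g$outcome, g$model, g$subset, sep = ".")
    if (nrow(sub) == 0L) {
      warning("subset ", g$subset, " has no rows; skipping ", mid,
              call. = FALSE)
      next
    }
    fit <- tryCatch(
      fit_ppml_hdfe(sub, outcome = g$outcome,
                    regressors = c(models[[g$model]], controls), ...),
      error = function(e) {
        warning("model ", mid, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    res[[r]] <- data.table(
      model_id = mid, outcome = g$outcome, model = g$model,
      subset = g$subset, term = names(fit$coefficients),
      estimate = unname(fit$coefficients), se = unname(fit$se),
      z = unname(fit$z), p = 2 * pnorm(-abs(unname(fit$z))),
      n_obs = fit$n_obs, n_singletons = fit$n_singletons_dropped,
      n_separated = fit$n_separated_dropped)
  }
  rbindlist(res)
}
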