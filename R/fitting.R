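#' Fitting configuration
#'
#' Bundles everything the estimator needs: the start vector, box bounds,
#' optimizer tolerances, the frame-sampling mode, and the multistart policy.
#' The default start (K1 = 1.0, k2 = 1.0, k3 = 0.01, k4 = 0.01, fA = 0.25,
#' vB = 0.01) reflects population empirical values for liver FDG kinetics.
#' Default bounds keep the rate constants in \[0, 10\] /min and the fractions
#' in \[0, 1\]; they are deliberately permissive and configurable, and
#' `at_bound` flags in the result expose any clipping.
#'
#' @param initial_theta A [kinetic_params()] start vector.
#' @param lower,upper Named numeric bounds for (K1, k2, k3, k4, fA, vB).
#' @param max_iterations Maximum optimizer iterations per start.
#' @param ftol,gtol Relative function- and gradient-convergence tolerances.
#' @param sampling `"frame_average"` or `"midpoint"` frame reduction.
#' @param multistart Number of starts. Start 1 is `initial_theta`; starts 2-5
#'   re-use it with the arterial fraction moved across \{0, 0.5, 0.75, 1\}
#'   (deterministic — the likelihood surface has distinct basins along fA);
#'   any further starts are drawn from `seed` inside a physiological start
#'   region. Starts stop early once a run reaches `stop_wrss`.
#' @param seed Integer seed controlling the random starts (configs with
#'   `multistart <= 5` use no randomness at all).
#' @param stop_wrss WRSS below which a fit is treated as numerically perfect
#'   and remaining starts are skipped (only ever reached on noise-free data).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(initial_theta = kinetic_params(1.0, 1.0, 0.01, 0.01, 0.25, 0.01),
                       lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, fA = 0, vB = 0),
                       upper = c(K1 = 10, k2 = 10, k3 = 10, k4 = 10, fA = 1, vB = 1),
                       max_iterations = 500,
                       ftol = 1e-12, gtol = 1e-12,
                       sampling = c("frame_average", "midpoint"),
                       multistart = 5, seed = 1L, stop_wrss = 1e-22) {
  sampling <- match.arg(sampling)
  initial_theta <- as_kinetic_params(initial_theta)
  pn <- c("K1", "k2", "k3", "k4", "fA", "vB")
  lower <- lower[pn]; upper <- upper[pn]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower > upper)) {
    abort("bounds must be named over K1..vB with lower <= upper")
  }
  th <- unclass(initial_theta)
  if (any(th < lower) || any(th > upper)) {
    abort("initial theta must lie inside the bounds")
  }
  stopifnot(multistart >= 1, max_iterations >= 1)
  structure(list(initial_theta = initial_theta, lower = lower, upper = upper,
                 max_iterations = max_iterations, ftol = ftol, gtol = gtol,
                 sampling = sampling, multistart = multistart,
                 seed = as.integer(seed), stop_wrss = stop_wrss),
            class = "fit_config")
}

#' Weighted residual sum of squares
#'
#' The fitting objective: `WRSS(theta) = sum_i w_i (C_meas(t_i) -
#' C_T(t_i; theta))^2` with uniform frame weights `w_i = 1/N` (so the weights
#' sum to one and a constant residual of `delta` scores `delta^2`).
#'
#' @param measured A tidy TAC tibble holding exactly one measured curve.
#' @param inputs An input-function tibble (`time_min`, `c_ha`, `c_pv`).
#' @param theta A [kinetic_params()] vector.
#' @param sampling Frame-reduction mode for the model prediction.
#' @return The scalar WRSS.
#' @export
wrss <- function(measured, inputs, theta,
                 sampling = c("frame_average", "midpoint")) {
  sampling <- match.arg(sampling)
  theta <- as_kinetic_params(theta)
  sched <- tac_schedule(measured)
  y <- dplyr::arrange(measured, .data$frame_start_s)$value
  if (length(y) == 0) abort("measured TAC has no frames")
  if (length(y) != nrow(sched)) {
    abort("measured must contain exactly one curve")
  }
  pred <- predict_frames(unclass(theta), inputs$time_min, inputs$c_ha,
                         inputs$c_pv, sched, sampling)
  mean((y - pred)^2)
}

#' Corrected Akaike information criterion for a fit
#'
#' Small-sample Gaussian-likelihood form
#' `AICc = N log(WRSS) + 2p + 2p(p+1)/(N - p - 1)`, with p the number of
#' fitted kinetic parameters (6; the residual variance is not counted).
#' Smaller is better; the correction term requires `N > p + 1`.
#'
#' @param wrss_value Positive weighted residual sum of squares.
#' @param n_frames Number of frames N.
#' @param n_params Number of fitted parameters p (default 6).
#' @return The AICc score.
#' @examples
#' aicc(1, 50)  # 12 + 84/43 = 13.9535
#' @export
aicc <- function(wrss_value, n_frames, n_params = 6) {
  if (!is.finite(wrss_value) || wrss_value <= 0) {
    abort("wrss_value must be a positive number")
  }
  if (n_frames <= n_params + 1) {
    abort("AICc undefined: need n_frames > n_params + 1")
  }
  n_frames * log(wrss_value) + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_frames - n_params - 1)
}

#' Start points for the multistart policy
#'
#' Start 1 is the configured initial theta; starts 2-5 sweep its arterial
#' fraction over 0, 0.5, 0.75, 1 (tissue classes differ mainly in fA, and the
#' WRSS surface has separate basins along it); further starts are seeded
#' uniform draws over a physiological region (K1, k2 in \[0, 3\] /min, k3 in
#' \[0, 0.5\], k4 in \[0, 0.2\], fA in \[0, 1\], vB in \[0, 0.2\]),
#' intersected with the configured bounds.
#' @noRd
multistart_points <- function(config) {
  starts <- list(unclass(config$initial_theta))
  fa_grid <- c(0, 0.5, 0.75, 1)
  n_grid <- min(config$multistart - 1, length(fa_grid))
  for (k in seq_len(max(n_grid, 0))) {
    st <- unclass(config$initial_theta)
    st[["fA"]] <- min(max(fa_grid[k], config$lower[["fA"]]),
                      config$upper[["fA"]])
    starts[[length(starts) + 1]] <- st
  }
  n_rand <- config$multistart - length(starts)
  if (n_rand > 0) {
    region_hi <- pmin(c(K1 = 3, k2 = 3, k3 = 0.5, k4 = 0.2, fA = 1, vB = 0.2),
                      config$upper)
    u <- local({
      set.seed(config$seed)
      matrix(runif(n_rand * 6), ncol = 6)
    })
    for (k in seq_len(n_rand)) {
      starts[[length(starts) + 1]] <-
        config$lower + u[k, ] * (region_hi - config$lower)
    }
  }
  starts
}

#' Fit the dual-input two-tissue model to one measured TAC
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box bounds) on
#' the uniform-weight WRSS objective, from the configured start(s). With
#' `multistart > 1`, additional in-bounds starts are drawn deterministically
#' from the config seed and the best solution is kept (ties broken by lowest
#' WRSS, then lowest Ki, then start order). The result is fully deterministic
#' given data and config.
#'
#' @inheritParams wrss
#' @param config A [fit_config()].
#' @return An object of class `"tac_fit"` with the estimated parameters, Ki,
#'   WRSS, AICc, convergence diagnostics and per-parameter `at_bound` flags.
#'   Use [tidy()] / [glance()] to extract tibbles, [autoplot()] to inspect the
#'   fit.
#' @export
fit_tac <- function(measured, inputs, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  sched <- tac_schedule(measured)
  meas <- dplyr::arrange(measured, .data$frame_start_s)
  y <- meas$value
  if (length(y) != nrow(sched)) abort("measured must contain exactly one curve")
  if (any(!is.finite(y))) abort("measured TAC contains non-finite values")
  if (max(frame_ends_s(sched)) / 60 > max(inputs$time_min) + 1e-9) {
    abort("schedule extends beyond the input-function time grid")
  }
  n <- length(y)
  sw <- 1 / sqrt(n)
  t <- inputs$time_min; c_ha <- inputs$c_ha; c_pv <- inputs$c_pv

  resid_fn <- function(par) {
    r <- sw * (y - predict_frames(par, t, c_ha, c_pv, sched, config$sampling))
    if (any(!is.finite(r))) abort("non-finite residuals during fitting")
    r
  }

  starts <- multistart_points(config)

  one_start <- function(st) {
    run_lm <- function(p0) tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, lower = config$lower, upper = config$upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = config$ftol, gtol = config$gtol, ptol = config$ftol,
          maxiter = config$max_iterations, maxfev = 100 * (6 + 1) *
            config$max_iterations))),
      error = function(e) e)
    fit <- run_lm(st)
    if (inherits(fit, "error")) {
      if (grepl("non-finite residuals", conditionMessage(fit))) stop(fit)
      return(list(par = st, wrss = sum(resid_fn(st)^2), converged = FALSE,
                  n_iter = NA_integer_))
    }
    # restarting resets the damping and often dives further down a flat valley
    for (r in 1:2) {
      refit <- run_lm(fit$par)
      if (inherits(refit, "error") || refit$deviance >= fit$deviance) break
      fit <- refit
    }
    list(par = setNames(fit$par, names(config$lower)),
         wrss = fit$deviance,
         converged = fit$info %in% 1:4,
         n_iter = fit$niter)
  }

  runs <- list()
  for (st in starts) {
    runs[[length(runs) + 1]] <- one_start(st)
    if (runs[[length(runs)]]$wrss < config$stop_wrss) break
  }

  ki <- purrr::map_dbl(runs, ~ net_influx_Ki(.x$par))
  ord <- order(purrr::map_dbl(runs, "wrss"), ki, seq_along(runs))
  best <- runs[[ord[1]]]

  theta_hat <- as_kinetic_params(best$par)
  tol_b <- 1e-9 * pmax(1, abs(config$upper))
  at_bound <- (unclass(theta_hat) - config$lower <= tol_b) |
    (config$upper - unclass(theta_hat) <= tol_b)
  fitted_vals <- predict_frames(unclass(theta_hat), t, c_ha, c_pv, sched,
                                config$sampling)
  w <- best$wrss
  structure(list(
    theta = theta_hat,
    Ki = net_influx_Ki(theta_hat),
    wrss = w,
    aicc = if (w > 0) aicc(w, n, 6) else -Inf,
    n_frames = n,
    converged = best$converged,
    n_iterations = best$n_iter,
    at_bound = setNames(at_bound, names(config$lower)),
    voi_label = meas$voi_label[1],
    measure = meas$measure[1],
    measured = meas,
    fitted = fitted_vals,
    inputs = inputs,
    config = config
  ), class = "tac_fit")
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> %s (%s), %d frames\n", x$voi_label, x$measure,
              x$n_frames))
  th <- unclass(x$theta)
  cat(sprintf("  K1=%.4f k2=%.4f k3=%.4f k4=%.4f fA=%.4f vB=%.4f\n",
              th[1], th[2], th[3], th[4], th[5], th[6]))
  cat(sprintf("  Ki=%.5f  WRSS=%.5g  AICc=%.2f  converged=%s (%s iter)\n",
              x$Ki, x$wrss, x$aicc, x$converged, x$n_iterations))
  invisible(x)
}

#' Tidy a fitted TAC model
#'
#' @param x A `"tac_fit"` object.
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter (term, estimate, at_bound);
#'   `glance()` gives a one-row model summary (Ki, wrss, aicc, n_frames,
#'   converged, n_iterations, voi_label, measure).
#' @method tidy tac_fit
#' @export
tidy.tac_fit <- function(x, ...) {
  tibble::tibble(term = names(unclass(x$theta)),
                 estimate = as.numeric(unclass(x$theta)),
                 at_bound = as.logical(x$at_bound))
}

#' @rdname tidy.tac_fit
#' @method glance tac_fit
#' @export
glance.tac_fit <- function(x, ...) {
  tibble::tibble(voi_label = x$voi_label, measure = x$measure,
                 K1 = x$theta[["K1"]], k2 = x$theta[["k2"]],
                 k3 = x$theta[["k3"]], k4 = x$theta[["k4"]],
                 fA = x$theta[["fA"]], vB = x$theta[["vB"]],
                 Ki = x$Ki, wrss = x$wrss, aicc = x$aicc,
                 n_frames = x$n_frames, converged = x$converged,
                 n_iterations = as.integer(x$n_iterations))
}

#' Fit every tissue curve in a TAC table
#'
#' Convenience wrapper mapping [fit_tac()] over the (voi_label, measure)
#' curves of a tidy TAC table against one shared input-function pair,
#' returning one glance row per curve.
#'
#' @param tacs A tidy TAC tibble.
#' @param inputs Input-function tibble used for every curve.
#' @param vois Optional character vector restricting the VOIs fitted
#'   (default: everything except "aorta" and "portal_vein").
#' @param measures Measures to fit (default both, where present).
#' @param config A [fit_config()].
#' @return A tibble with one row per fitted curve (see [glance.tac_fit()]).
#' @export
fit_tacs <- function(tacs, inputs, vois = NULL,
                     measures = c("mean", "max"), config = fit_config()) {
  if (is.null(vois)) {
    vois <- setdiff(unique(tacs$voi_label), c("aorta", "portal_vein"))
  }
  todo <- dplyr::distinct(
    dplyr::filter(tacs, .data$voi_label %in% vois,
                  .data$measure %in% measures),
    .data$voi_label, .data$measure)
  purrr::pmap_dfr(todo, function(voi_label, measure) {
    cur <- dplyr::filter(tacs, .data$voi_label == .env$voi_label,
                         .data$measure == .env$measure)
    glance(fit_tac(cur, inputs, config))
  })
}
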