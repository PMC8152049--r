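#' Fine time grid for continuous-time curves
#'
#' Input functions and model curves are evaluated on a fine, piecewise-uniform
#' grid in minutes: a short step through the bolus phase and a coarser step
#' afterwards. The default (0.5 s up to 3 min, 1 s thereafter, spanning
#' 0-60 min) resolves the arterial peak while keeping the convolution cheap.
#'
#' @param t_end_min End of the grid in minutes.
#' @param fast_until_min End of the finely sampled bolus window, minutes.
#' @param fast_step_s,slow_step_s Grid steps in seconds for the two regimes.
#' @return Increasing numeric vector of times in minutes, starting at 0.
#' @export
fine_time_grid <- function(t_end_min = 60, fast_until_min = 3,
                           fast_step_s = 0.5, slow_step_s = 1) {
  stopifnot(t_end_min > 0, fast_step_s > 0, slow_step_s > 0)
  fast_until_min <- min(fast_until_min, t_end_min)
  g1 <- seq(0, fast_until_min, by = fast_step_s / 60)
  g2 <- if (t_end_min > fast_until_min) {
    seq(fast_until_min, t_end_min, by = slow_step_s / 60)
  } else numeric(0)
  sort(unique(c(g1, g2, t_end_min)))
}

#' Feng-type arterial input model
#'
#' Parametric tri-exponential bolus widely used to describe arterial FDG
#' concentration after a venous injection:
#' \deqn{C_A(t) = (A_1 s - A_2 - A_3) e^{-\lambda_1 s} + A_2 e^{-\lambda_2 s}
#'   + A_3 e^{-\lambda_3 s}, \quad s = t - \tau,}
#' zero for `t <= tau` and clipped at zero. Defaults give a bolus peaking
#' around 20 SUV at ~0.75 min and decaying to ~2 SUV by 60 min — a
#' generator convention for a typical descending-aorta curve in SUV units.
#'
#' @param tau Appearance delay after injection, minutes.
#' @param A1 Slope term, SUV/min; `A2`, `A3` amplitudes in SUV.
#' @param lambda1,lambda2,lambda3 Decay rates, 1/min; all must be positive.
#' @return A named list of class `"feng_params"`.
#' @export
feng_params <- function(tau = 0.5, A1 = 180, A2 = 2, A3 = 3.6,
                        lambda1 = 4, lambda2 = 0.12, lambda3 = 0.01) {
  if (any(c(lambda1, lambda2, lambda3) <= 0)) {
    abort("Feng decay rates lambda must be strictly positive")
  }
  structure(list(tau = tau, A1 = A1, A2 = A2, A3 = A3,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "feng_params")
}

#' Evaluate the arterial input model on a time grid
#'
#' @param model A [feng_params()] object.
#' @param time_min Numeric vector of times in minutes.
#' @return Numeric vector of arterial concentration (SUV), zero before the
#'   delay and never negative.
#' @export
arterial_curve <- function(model, time_min) {
  stopifnot(inherits(model, "feng_params"))
  s <- time_min - model$tau
  c_a <- with(model, (A1 * s - A2 - A3) * exp(-lambda1 * s) +
                A2 * exp(-lambda2 * s) + A3 * exp(-lambda3 * s))
  c_a[s <= 0] <- 0
  pmax(c_a, 0)
}

#' Dispersed portal-vein curve from an arterial curve
#'
#' The portal-vein input is modelled as the arterial curve convolved with a
#' single-exponential dispersion kernel \eqn{(1/\beta) e^{-t/\beta}}: a
#' delayed, smoothed, lower-peak version of the arterial bolus with the same
#' total area over an infinite horizon. Used only to simulate; fitting always
#' takes the portal curve as measured.
#'
#' @param time_min Increasing time grid, minutes.
#' @param c_ha Arterial concentration on `time_min`.
#' @param beta Dispersion time constant in minutes (> 0).
#' @return Portal-vein concentration on the same grid.
#' @export
portal_from_arterial <- function(time_min, c_ha, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    abort("dispersion constant beta must be a positive scalar (minutes)")
  }
  expconv_cpp(1 / beta, time_min, c_ha) / beta
}

#' Build a continuous-time dual input-function pair
#'
#' Evaluates the arterial model on a fine grid and derives the portal-vein
#' curve by exponential dispersion, returning the tibble all kinetic
#' computations consume.
#'
#' @param arterial A [feng_params()] model.
#' @param beta Portal dispersion constant, minutes.
#' @param time_min Fine time grid in minutes (see [fine_time_grid()]).
#' @return A tibble with columns `time_min`, `c_ha`, `c_pv`.
#' @export
input_functions <- function(arterial = feng_params(), beta = 0.5,
                            time_min = fine_time_grid()) {
  c_ha <- arterial_curve(arterial, time_min)
  tibble::tibble(
    time_min = time_min,
    c_ha = c_ha,
    c_pv = portal_from_arterial(time_min, c_ha, beta)
  )
}

#' Reconstruct continuous input functions from measured blood TACs
#'
#' Image-derived input functions arrive as frame-sampled TACs over the aorta
#' and portal-vein VOIs. This helper places each frame value at its frame
#' midpoint, anchors the curve at (0, 0) (pre-injection), and interpolates
#' linearly onto a fine grid, clipping at zero. The last frame value is held
#' beyond the final midpoint.
#'
#' @param tacs A tidy TAC tibble containing both blood curves (SUVmean).
#' @param arterial_voi,portal_voi VOI labels of the aorta and portal-vein
#'   curves.
#' @param time_min Fine output grid, minutes.
#' @return A tibble with columns `time_min`, `c_ha`, `c_pv`.
#' @export
input_pair_from_tacs <- function(tacs, arterial_voi = "aorta",
                                 portal_voi = "portal_vein",
                                 time_min = NULL) {
  sched <- tac_schedule(tacs)
  if (is.null(time_min)) {
    time_min <- fine_time_grid(t_end_min = max(frame_ends_s(sched)) / 60)
  }
  mid <- frame_midpoints(sched)
  interp_one <- function(voi) {
    v <- tac_values(tacs, voi, "mean")
    y <- approx(c(0, mid), c(0, v), xout = time_min, rule = 2)$y
    pmax(y, 0)
  }
  tibble::tibble(
    time_min = time_min,
    c_ha = interp_one(arterial_voi),
    c_pv = interp_one(portal_voi)
  )
}
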