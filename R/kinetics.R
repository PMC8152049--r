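#' Kinetic parameter vectors
#'
#' The estimated quantity is the vector theta = (K1, k2, k3, k4, fA, vB):
#' K1 (ml/min/ml) the FDG delivery rate from blood to hepatic tissue, k2
#' (1/min) the clearance rate back to blood, k3 (1/min) the hexokinase
#' phosphorylation rate, k4 (1/min) the phosphatase dephosphorylation rate,
#' fA the fraction of liver blood inflow supplied by the hepatic artery, and
#' vB the fractional blood volume in the tissue signal.
#'
#' @param K1,k2,k3,k4 Non-negative rate constants (K1 in ml/min/ml, the
#'   others in 1/min).
#' @param fA,vB Unitless fractions in \[0, 1\].
#' @return A named numeric vector of class `"kinetic_params"`.
#' @export
kinetic_params <- function(K1, k2, k3, k4, fA, vB) {
  theta <- c(K1 = unname(K1), k2 = unname(k2), k3 = unname(k3),
             k4 = unname(k4), fA = unname(fA), vB = unname(vB))
  if (any(!is.finite(theta))) abort("kinetic parameters must be finite")
  if (any(theta[c("K1", "k2", "k3", "k4")] < 0)) {
    abort("rate constants K1, k2, k3, k4 must be non-negative")
  }
  if (fA < 0 || fA > 1) abort("fA must lie in [0, 1]")
  if (vB < 0 || vB > 1) abort("vB must lie in [0, 1]")
  structure(theta, class = "kinetic_params")
}

as_kinetic_params <- function(x) {
  x <- unlist(x)[c("K1", "k2", "k3", "k4", "fA", "vB")]
  kinetic_params(x[["K1"]], x[["k2"]], x[["k3"]], x[["k4"]],
                 x[["fA"]], x[["vB"]])
}

#' Net influx rate constant Ki
#'
#' The macro (metabolic) rate constant Ki = K1 * k3 / (k2 + k3): the steady
#' trapping rate of FDG into the phosphorylated pool. By convention Ki = 0
#' when k2 + k3 = 0 (no exchange at all); when k2 = 0 and k3 > 0 every
#' delivered tracer molecule is eventually trapped and Ki = K1.
#'
#' @param theta A [kinetic_params()] vector (or anything coercible).
#' @return Ki in ml/min/ml.
#' @examples
#' net_influx_Ki(kinetic_params(1.0, 1.0, 0.01, 0.01, 0.25, 0.01))  # 0.009901
#' @export
net_influx_Ki <- function(theta) {
  theta <- as_kinetic_params(theta)
  denom <- theta[["k2"]] + theta[["k3"]]
  if (denom == 0) return(0)
  unname(theta[["K1"]] * theta[["k3"]] / denom)
}

#' Mix the dual blood input into a plasma input
#'
#' The plasma input feeding the tissue is the flow-weighted mixture of the
#' hepatic-artery and portal-vein concentrations,
#' `C_P(t) = fA * C_HA(t) + (1 - fA) * C_PV(t)`.
#'
#' @param inputs A tibble with columns `time_min`, `c_ha`, `c_pv` (see
#'   [input_functions()]).
#' @param fA Arterial supply fraction in \[0, 1\].
#' @return The input tibble with a `c_p` column appended.
#' @export
dual_input <- function(inputs, fA) {
  if (!all(c("time_min", "c_ha", "c_pv") %in% names(inputs))) {
    abort("inputs must have columns time_min, c_ha, c_pv")
  }
  if (!is.numeric(fA) || length(fA) != 1 || fA < 0 || fA > 1) {
    abort("fA must be a scalar in [0, 1]")
  }
  dplyr::mutate(inputs, c_p = fA * .data$c_ha + (1 - fA) * .data$c_pv)
}

#' Tissue response of the reversible two-tissue compartment model
#'
#' Solves the linear system
#' \deqn{dC_F/dt = K_1 C_P - (k_2 + k_3) C_F + k_4 C_M, \qquad
#'       dC_M/dt = k_3 C_F - k_4 C_M,}
#' with zero initial conditions, via the closed-form biexponential impulse
#' response convolved with `C_P`. The eigenvalues are
#' \eqn{\alpha_{1,2} = [(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}]/2};
#' the near-degenerate case \eqn{\alpha_1 \approx \alpha_2} switches to the
#' \eqn{t e^{-\alpha t}} limit form to avoid catastrophic cancellation.
#' Convolutions are exact for a piecewise-linear `C_P` on the grid.
#'
#' @param cp A tibble with columns `time_min` and `c_p` (e.g. from
#'   [dual_input()]).
#' @param theta A [kinetic_params()] vector; `fA` is not used here (the mixing
#'   happens upstream), `vB` is not used (it enters the output equation).
#' @return The input tibble with `c_f` and `c_m` columns appended.
#' @export
tissue_response <- function(cp, theta) {
  if (!all(c("time_min", "c_p") %in% names(cp))) {
    abort("cp must have columns time_min and c_p")
  }
  theta <- as_kinetic_params(theta)
  resp <- tissue_conv_core(cp$time_min, cp$c_p, theta[["K1"]], theta[["k2"]],
                           theta[["k3"]], theta[["k4"]])
  dplyr::mutate(cp, c_f = resp$c_f, c_m = resp$c_m)
}

#' Closed-form biexponential tissue solution on plain vectors
#' @noRd
tissue_conv_core <- function(t, f, K1, k2, k3, k4) {
  a <- k2 + k3 + k4
  disc <- a * a - 4 * k2 * k4
  sq <- sqrt(max(disc, 0))
  a1 <- (a - sq) / 2
  a2 <- (a + sq) / 2

  if (sq > 1e-7 * max(1, a)) {
    e1 <- expconv_cpp(a1, t, f)
    e2 <- expconv_cpp(a2, t, f)
    c_f <- K1 / (a2 - a1) * ((k4 - a1) * e1 + (a2 - k4) * e2)
    c_m <- K1 * k3 / (a2 - a1) * (e1 - e2)
  } else {
    # repeated eigenvalue alpha = a/2: impulse response has a t*exp(-alpha t)
    # term; (t e^{-at}) * f = t (e^{-at} * f) - e^{-at} * (t f)
    al <- a / 2
    e0 <- expconv_cpp(al, t, f)
    te <- t * e0 - expconv_cpp(al, t, t * f)
    c_f <- K1 * (e0 + (k4 - al) * te)
    c_m <- K1 * k3 * te
  }
  list(c_f = pmax(c_f, 0), c_m = pmax(c_m, 0))
}

#' Frame-sampled model output on plain vectors (optimizer fast path)
#' @noRd
predict_frames <- function(par, t, c_ha, c_pv, schedule, sampling) {
  c_p <- par[[5]] * c_ha + (1 - par[[5]]) * c_pv
  resp <- tissue_conv_core(t, c_p, par[[1]], par[[2]], par[[3]], par[[4]])
  c_t <- par[[6]] * c_p + resp$c_f + resp$c_m
  frame_reduce(t, c_t, schedule, sampling)
}

#' Full model curves including the total tissue output
#'
#' Forms the plasma input, solves the tissue system, and appends the model
#' output `C_T(t) = vB * C_P(t) + C_F(t) + C_M(t)` — the collective signal of
#' capillary blood and the two tissue compartments.
#'
#' @inheritParams dual_input
#' @inheritParams tissue_response
#' @return A tibble with columns `time_min`, `c_ha`, `c_pv`, `c_p`, `c_f`,
#'   `c_m`, `c_t`.
#' @export
model_curves <- function(inputs, theta) {
  theta <- as_kinetic_params(theta)
  out <- tissue_response(dual_input(inputs, theta[["fA"]]), theta)
  dplyr::mutate(out, c_t = theta[["vB"]] * .data$c_p + .data$c_f + .data$c_m)
}

#' Frame-sampled model prediction
#'
#' Reduces the continuous model output to the acquisition frames, either as
#' the mean over each frame interval (`"frame_average"`, the default: PET
#' frames record time-integrated counts) or as the value at the frame midpoint
#' (`"midpoint"`, for sensitivity analysis).
#'
#' @inheritParams model_curves
#' @param schedule A frame-schedule tibble; must be covered by the input grid.
#' @param sampling `"frame_average"` or `"midpoint"`.
#' @param voi_label Label attached to the predicted curve.
#' @return A tidy TAC tibble with measure `"mean"`.
#' @export
model_tac <- function(inputs, theta, schedule = default_frame_schedule(),
                      sampling = c("frame_average", "midpoint"),
                      voi_label = "model") {
  sampling <- match.arg(sampling)
  validate_schedule(schedule)
  if (max(frame_ends_s(schedule)) / 60 > max(inputs$time_min) + 1e-9) {
    abort("schedule extends beyond the input-function time grid")
  }
  curves <- model_curves(inputs, theta)
  vals <- frame_reduce(curves$time_min, curves$c_t, schedule, sampling)
  tac_tibble(schedule, vals, voi_label = voi_label, measure = "mean")
}

#' Reduce a fine-grid curve to per-frame values
#' @noRd
frame_reduce <- function(time_min, values, schedule, sampling) {
  if (sampling == "midpoint") {
    return(approx(time_min, values, xout = frame_midpoints(schedule))$y)
  }
  # frame average via the cumulative trapezoidal integral, interpolated at
  # the frame boundaries
  n <- length(time_min)
  cum <- cumsum(c(0, diff(time_min) * (values[-1] + values[-n]) / 2))
  bounds_min <- c(schedule$frame_start_s, max(frame_ends_s(schedule))) / 60
  cum_b <- approx(time_min, cum, xout = bounds_min)$y
  diff(cum_b) / (schedule$frame_duration_s / 60)
}
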