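# Shared small objects for the test suite. Everything is built in code; the
# coarse grid keeps convolution-based tests fast while the default grid is
# exercised where the schedule demands it.

test_grid <- function(t_end = 60) fine_time_grid(t_end_min = t_end)

test_inputs <- function() input_functions()

# a short 10-frame schedule for cheap tests (total 10 min)
short_schedule <- function() {
  frame_schedule(c(rep(10, 3), rep(30, 3), rep(120, 4)))
}

# independent numerical oracle: solve the compartment ODEs with a generic
# stiff integrator on the same plasma-input interpolant
ode_tissue_oracle <- function(cp_tbl, K1, k2, k3, k4,
                              rtol = 1e-10, atol = 1e-12) {
  cpf <- stats::approxfun(cp_tbl$time_min, cp_tbl$c_p, rule = 2)
  deriv <- function(t, y, p) {
    list(c(K1 * cpf(t) - (k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  out <- deSolve::lsoda(c(0, 0), cp_tbl$time_min, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  list(c_f = out[, 2], c_m = out[, 3])
}

as_theta_row <- function(row) {
  kinetic_params(row$K1, row$k2, row$k3, row$k4, row$fA, row$vB)
}

expect_curves_close <- function(a, b, rel_tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(a))
  expect_lt(max(abs(a - b)) / scale, rel_tol)
}
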