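test_that("dual input mixing is the convex combination of the two vessels", {
  inp <- tibble::tibble(time_min = c(0, 1, 2),
                        c_ha = c(0, 4, 2), c_pv = c(0, 2, 1))
  expect_equal(dual_input(inp, 0)$c_p, inp$c_pv)
  expect_equal(dual_input(inp, 1)$c_p, inp$c_ha)
  expect_equal(dual_input(inp, 0.25)$c_p[2], 2.5)
  expect_error(dual_input(inp, 1.2), "0, 1")
  expect_error(dual_input(inp[, 1:2], 0.5), "c_pv")
})

test_that("net influx rate follows its closed-form identities", {
  expect_equal(net_influx_Ki(kinetic_params(0.5, 1.0, 0, 0, 0.5, 0)), 0)
  expect_equal(net_influx_Ki(kinetic_params(0.5, 0, 0.1, 0, 0.5, 0)), 0.5)
  expect_equal(net_influx_Ki(kinetic_params(1.0, 1.0, 0.01, 0.01, 0.25, 0.01)),
               0.01 / 1.01)
  # k2 = k3 = 0 returns 0 by convention
  expect_equal(net_influx_Ki(kinetic_params(0.5, 0, 0, 0, 0.5, 0)), 0)
})

test_that("tissue response reproduces analytic limits", {
  t <- seq(0, 10, by = 1 / 120)
  cp <- tibble::tibble(time_min = t, c_p = rep(1, length(t)))
  # pure integrator: K1=1, all other rates 0 -> C_F = t, C_M = 0
  r <- tissue_response(cp, kinetic_params(1, 0, 0, 0, 0, 0))
  expect_curves_close(r$c_f, t, 1e-9)
  expect_equal(r$c_m, rep(0, length(t)))
  # one-tissue limit k3 = k4 = 0 with step input:
  # C_F = (K1/k2)(1 - exp(-k2 t)), C_M = 0
  r1 <- tissue_response(cp, kinetic_params(0.8, 1.3, 0, 0, 0, 0))
  expect_curves_close(r1$c_f, 0.8 / 1.3 * (1 - exp(-1.3 * t)), 1e-6)
  expect_equal(r1$c_m, rep(0, length(t)))
  expect_error(tissue_response(cp, kinetic_params(-1, 1, 0, 0, 0, 0)),
               "non-negative")
})

test_that("degenerate equal-eigenvalue case stays finite and correct", {
  inp <- test_inputs()
  cp <- dual_input(inp, 0.5)
  # k3 = 0, k2 = k4 gives a repeated eigenvalue exactly
  th <- kinetic_params(1.0, 0.4, 0, 0.4, 0.5, 0.01)
  r <- tissue_response(cp, th)
  expect_true(all(is.finite(r$c_f)), all(is.finite(r$c_m)))
  oracle <- ode_tissue_oracle(cp, 1.0, 0.4, 0, 0.4)
  expect_curves_close(r$c_f, oracle$c_f, 1e-6)
})

test_that("closed-form solution matches the ODE oracle on random draws", {
  inp <- test_inputs()
  cp <- dual_input(inp, 0.3)
  set.seed(42)
  for (i in 1:8) {
    K1 <- runif(1, 0.05, 2.5); k2 <- runif(1, 0.05, 2.5)
    k3 <- runif(1, 0, 0.5); k4 <- runif(1, 0, 0.2)
    r <- tissue_response(cp, kinetic_params(K1, k2, k3, k4, 0.3, 0.01))
    o <- ode_tissue_oracle(cp, K1, k2, k3, k4)
    scale <- max(r$c_f + r$c_m)
    expect_curves_close(r$c_f, o$c_f, 1e-6, scale = scale)
    expect_curves_close(r$c_m, o$c_m, 1e-6, scale = scale)
  }
})

test_that("tissue response is linear and superposable in the input", {
  inp <- test_inputs()
  th <- kinetic_params(0.9, 0.7, 0.08, 0.01, 0.4, 0.02)
  cp1 <- dual_input(inp, 0.2)
  cp2 <- dual_input(inp, 0.9)
  r1 <- tissue_response(cp1, th)
  r2 <- tissue_response(cp2, th)
  for (a in c(0.5, 2, 7)) {
    rs <- tissue_response(dplyr::mutate(cp1, c_p = a * c_p), th)
    expect_curves_close(rs$c_f, a * r1$c_f, 1e-12)
    expect_curves_close(rs$c_m, a * r1$c_m, 1e-12)
  }
  rsum <- tissue_response(tibble::tibble(time_min = cp1$time_min,
                                         c_p = cp1$c_p + cp2$c_p), th)
  expect_curves_close(rsum$c_f, r1$c_f + r2$c_f, 1e-12)
  expect_curves_close(rsum$c_m, r1$c_m + r2$c_m, 1e-12)
})

test_that("with no dephosphorylation the metabolite pool never shrinks", {
  inp <- test_inputs()
  cp <- dual_input(inp, 0.6)
  r <- tissue_response(cp, kinetic_params(0.5, 0.6, 0.15, 0, 0.6, 0))
  expect_true(all(diff(r$c_m) > -1e-12))
})

test_that("model output identity C_T = vB C_P + C_F + C_M holds pointwise", {
  inp <- test_inputs()
  th <- kinetic_params(0.6, 0.8, 0.1, 0.02, 0.7, 0.04)
  m <- model_curves(inp, th)
  expect_curves_close(m$c_t, 0.04 * m$c_p + m$c_f + m$c_m, 1e-12)
})

test_that("frame reduction honours degenerate parameter limits", {
  inp <- test_inputs()
  sched <- default_frame_schedule()
  # vB = 0: output is the frame-reduced tissue signal alone
  th0 <- kinetic_params(0.6, 0.8, 0.1, 0.02, 0.7, 0)
  m <- model_curves(inp, th0)
  expect_equal(model_tac(inp, th0, sched)$value,
               liverkin:::frame_reduce(m$time_min, m$c_f + m$c_m, sched,
                                       "frame_average"))
  # K1 = 0, vB = 1: pure blood signal
  thb <- kinetic_params(0, 0, 0, 0, 0.5, 1)
  cp <- dual_input(inp, 0.5)
  expect_equal(model_tac(inp, thb, sched)$value,
               liverkin:::frame_reduce(cp$time_min, cp$c_p, sched,
                                       "frame_average"))
})

test_that("frame-average and midpoint sampling agree on smooth late frames", {
  inp <- test_inputs()
  sched <- default_frame_schedule()
  th <- kinetic_params(0.6, 0.8, 0.1, 0.02, 0.7, 0.03)
  fa <- model_tac(inp, th, sched, sampling = "frame_average")$value
  mp <- model_tac(inp, th, sched, sampling = "midpoint")$value
  late <- sched$frame_duration_s >= 60
  expect_lt(max(abs(fa[late] - mp[late]) / fa[late]), 0.02)
})

test_that("schedules beyond the input grid are rejected", {
  inp <- input_functions(time_min = fine_time_grid(t_end_min = 30))
  expect_error(model_tac(inp, kinetic_params(1, 1, 0, 0, 0.5, 0)),
               "beyond")
})
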