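test_that("arterial bolus model matches its closed forms", {
  t <- seq(0, 10, by = 0.005)
  m <- feng_params(tau = 0.5)
  ca <- arterial_curve(m, t)
  expect_true(all(ca[t <= 0.5] == 0))
  expect_true(all(ca >= 0))
  # single-term model: A1 (t - tau) exp(-l1 (t - tau)), peak at tau + 1/l1
  m1 <- feng_params(tau = 0.5, A1 = 100, A2 = 0, A3 = 0, lambda1 = 4)
  c1 <- arterial_curve(m1, t)
  s <- pmax(t - 0.5, 0)
  expect_equal(c1, 100 * s * exp(-4 * s))
  expect_equal(t[which.max(c1)], 0.5 + 1 / 4, tolerance = 0.01)
  expect_error(feng_params(lambda1 = -1), "positive")
})

test_that("portal dispersion delays, smooths and preserves the step limit", {
  grid <- test_grid()
  ca <- arterial_curve(feng_params(), grid)
  # tiny beta: kernel approaches a delta, PV approaches HA
  pv0 <- portal_from_arterial(grid, ca, 1e-4)
  expect_lt(max(abs(pv0 - ca)) / max(ca), 0.02)
  # beta = 0.5: lower, later peak
  pv <- portal_from_arterial(grid, ca, 0.5)
  expect_lt(max(pv), max(ca))
  expect_gt(grid[which.max(pv)], grid[which.max(ca)])
  expect_true(all(pv >= 0))
  # step response: constant input a gives a (1 - exp(-t / beta))
  a <- 3.7
  pvs <- portal_from_arterial(grid, rep(a, length(grid)), 0.5)
  expect_curves_close(pvs, a * (1 - exp(-grid / 0.5)), 1e-9)
  expect_error(portal_from_arterial(grid, ca, 0), "positive")
})

test_that("population priors hold the class statistics and sample correctly", {
  pr <- population_prior("reference")
  expect_equal(pr$mean[pr$term == "K1"], 1.66)
  expect_equal(pr$sd[pr$term == "fA"], 0.14)
  # degenerate sd returns the mean exactly
  pr0 <- dplyr::mutate(pr, sd = 0)
  expect_equal(unname(unlist(sample_params(pr0, 3)[2, 1:6])),
               pr0$mean)
  # fixed seed reproduces the draw sequence
  set.seed(123); d1 <- sample_params(pr, 5)
  set.seed(123); d2 <- sample_params(pr, 5)
  expect_identical(d1, d2)
  # draws respect truncation
  set.seed(9); d <- sample_params(population_prior("lesion_HCC"), 500)
  expect_true(all(d$fA >= 0 & d$fA <= 1))
  expect_true(all(d$k3 >= 0))
})

test_that("Monte-Carlo mean of reference K1 draws matches the prior", {
  set.seed(2024)
  d <- sample_params(population_prior("reference"), 1e4)
  se <- 0.61 / sqrt(1e4)
  expect_lt(abs(mean(d$K1) - 1.66), 3 * se + 0.0061)
})

test_that("simulated noise follows the frame-duration law", {
  sched <- default_frame_schedule()
  nm <- noise_model(scale = 0.05)
  # same activity: short early frames noisier than long late frames
  sig <- noise_sd(nm, rep(2, 50), sched)
  expect_gt(sig[1], sig[50])
  expect_equal(sig[1] / sig[50], sqrt(300 / 5))
  # suvmax mode inflates by the multiplier
  nmx <- noise_model(scale = 0.05, mode = "suvmax_like", multiplier = 2.5)
  expect_equal(noise_sd(nmx, rep(2, 50), sched), 2.5 * sig)
  # zero scale reproduces the clean model TAC exactly
  inp <- test_inputs()
  th <- kinetic_params(0.6, 0.8, 0.1, 0.02, 0.7, 0.03)
  expect_equal(simulate_tac(inp, th, noise = noise_model(scale = 0))$value,
               model_tac(inp, th)$value)
})

test_that("empirical residual spread matches the nominal sigma", {
  sched <- short_schedule()
  inp <- input_functions(time_min = fine_time_grid(t_end_min = 10))
  th <- kinetic_params(0.6, 0.8, 0.1, 0.02, 0.7, 0.03)
  clean <- model_tac(inp, th, sched)$value
  nm <- noise_model(scale = 0.05)
  sig <- noise_sd(nm, clean, sched)
  set.seed(31)
  reps <- replicate(1000, simulate_tac(inp, th, sched, nm)$value[5])
  expect_equal(sd(reps), sig[5], tolerance = 0.05)
})

test_that("cohort simulation produces the advertised structure", {
  co <- simulate_cohort(3, 2, 1, seed = 4)
  expect_identical(nrow(co$truth), 6L)
  expect_identical(nrow(co$subjects), 3L)
  # 6 tissue VOIs x 2 measures + 2 blood curves x 3 subjects
  counts <- dplyr::count(co$tacs, voi_label, measure)
  expect_identical(nrow(counts), 6L * 2L + 3L * 2L)
  expect_setequal(unique(co$truth$tissue_class),
                  c("reference", "lesion_HCC", "lesion_ICC"))
  # blood curves are SUVmean by construction
  expect_true(all(counts$measure[grepl("aorta|portal", counts$voi_label)] ==
                    "mean"))
  # portal is a delayed smoothed arterial in every subject
  for (s in 1:3) {
    inp <- subject_inputs(co$subjects[s, ])
    expect_gt(inp$time_min[which.max(inp$c_pv)],
              inp$time_min[which.max(inp$c_ha)])
    expect_true(all(inp$c_ha >= 0 & inp$c_pv >= 0))
    expect_equal(inp$c_ha[1], 0)
    expect_equal(inp$c_pv[1], 0)
  }
})

test_that("cohort generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(2, 1, 1, seed = 11), d1)
  write_cohort(simulate_cohort(2, 1, 1, seed = 11), d2)
  for (f in c("tacs.csv", "truth.csv", "subjects.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seed, different data
  d3 <- withr::local_tempdir()
  write_cohort(simulate_cohort(2, 1, 1, seed = 12), d3)
  expect_false(identical(readLines(file.path(d1, "tacs.csv")),
                         readLines(file.path(d3, "tacs.csv"))))
})

test_that("an empty cohort still writes valid files", {
  co <- simulate_cohort(0, 0, 0, seed = 1)
  expect_identical(nrow(co$truth), 0L)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, c("tacs.csv", "truth.csv",
                                             "subjects.csv")))))
})
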