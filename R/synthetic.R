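#' Population priors for kinetic parameters
#'
#' Per-class (mean, sd) summaries of the six kinetic parameters used as
#' ground-truth distributions by the simulator. The shipped defaults are the
#' SUVmean-based population statistics for healthy liver tissue
#' (`"reference"`), HCC lesions and ICC lesions; draws are truncated to the
#' fitting bounds (see [sample_params()]).
#'
#' @param tissue_class One of `"reference"`, `"lesion_HCC"`, `"lesion_ICC"`.
#' @return A tibble with columns `tissue_class`, `term`, `mean`, `sd`.
#' @export
population_prior <- function(tissue_class = c("reference", "lesion_HCC",
                                              "lesion_ICC")) {
  tissue_class <- match.arg(tissue_class)
  pn <- c("K1", "k2", "k3", "k4", "fA", "vB")
  stats <- switch(tissue_class,
    reference  = list(mean = c(1.66, 1.18, 0.001, 0.043, 0.09, 0.005),
                      sd   = c(0.61, 0.50, 0.002, 0.048, 0.14, 0.015)),
    lesion_HCC = list(mean = c(0.39, 0.59, 0.145, 0.015, 0.79, 0.015),
                      sd   = c(0.19, 0.38, 0.150, 0.016, 0.27, 0.017)),
    lesion_ICC = list(mean = c(0.69, 0.74, 0.058, 0.006, 0.47, 0.017),
                      sd   = c(0.43, 0.35, 0.047, 0.011, 0.33, 0.023)))
  tibble::tibble(tissue_class = tissue_class, term = pn,
                 mean = stats$mean, sd = stats$sd)
}

#' Draw ground-truth kinetic parameters from a population prior
#'
#' Independent truncated-normal draws per parameter (inverse-CDF method), with
#' truncation at the supplied bounds so every simulated truth is reachable by
#' the fitter; a prior sd of 0 returns the (clipped) mean exactly. Uses the
#' current RNG state — seed upstream for reproducibility.
#'
#' @param prior A prior tibble from [population_prior()] (or the same shape).
#' @param n Number of parameter vectors to draw.
#' @param lower,upper Named truncation bounds (default: the fitting bounds).
#' @return A tibble with `n` rows and columns `K1`, `k2`, `k3`, `k4`, `fA`,
#'   `vB`, `Ki`.
#' @export
sample_params <- function(prior, n = 1,
                          lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, fA = 0, vB = 0),
                          upper = c(K1 = 10, k2 = 10, k3 = 10, k4 = 10, fA = 1, vB = 1)) {
  stopifnot(all(c("term", "mean", "sd") %in% names(prior)))
  draws <- purrr::map_dfc(seq_len(nrow(prior)), function(i) {
    term <- prior$term[i]; mu <- prior$mean[i]; s <- prior$sd[i]
    a <- lower[[term]]; b <- upper[[term]]
    x <- if (s <= 0) {
      rep(min(max(mu, a), b), n)
    } else {
      fa <- pnorm((a - mu) / s); fb <- pnorm((b - mu) / s)
      if (fb - fa < 1e-12) rep(min(max(mu, a), b), n)
      else mu + s * qnorm(fa + runif(n) * (fb - fa))
    }
    tibble::tibble(!!term := pmin(pmax(x, a), b))
  })
  dplyr::mutate(draws, Ki = purrr::pmap_dbl(draws, function(K1, k2, k3, k4, fA, vB) {
    net_influx_Ki(kinetic_params(K1, k2, k3, k4, fA, vB))
  }))
}

#' Frame-duration-dependent measurement noise
#'
#' Emulates count-statistics noise on frame-averaged SUV values: the per-frame
#' standard deviation is
#' `sigma_i = c * sqrt(max(C_T(t_i), eps) / dt_i)` with `dt_i` the frame
#' duration in minutes, so short early frames are noisier than long late
#' frames at similar activity. SUVmax-like curves use the same model with the
#' scale inflated by `multiplier` (maxima over a VOI are intrinsically
#' noisier than means).
#'
#' @param scale Base noise scale `c` (unitless; 0 disables noise).
#' @param mode `"suvmean_like"` or `"suvmax_like"`.
#' @param multiplier SUVmax inflation factor m > 1.
#' @param floor Activity floor `eps` (SUV) preventing zero variance
#'   pre-bolus.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(scale = 0.05, mode = c("suvmean_like", "suvmax_like"),
                        multiplier = 2.5, floor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(scale >= 0, multiplier > 1, floor > 0)
  structure(list(scale = scale, mode = mode, multiplier = multiplier,
                 floor = floor), class = "noise_model")
}

#' Per-frame noise standard deviations implied by a noise model
#'
#' @param noise A [noise_model()].
#' @param ct_frames Noise-free frame values (SUV).
#' @param schedule The frame schedule.
#' @return Numeric vector of per-frame standard deviations.
#' @export
noise_sd <- function(noise, ct_frames, schedule) {
  stopifnot(inherits(noise, "noise_model"))
  c_eff <- noise$scale * if (noise$mode == "suvmax_like") noise$multiplier else 1
  dt_min <- schedule$frame_duration_s / 60
  c_eff * sqrt(pmax(ct_frames, noise$floor) / dt_min)
}

#' Simulate one noisy measured TAC
#'
#' Forward-models the frame-averaged tissue curve for a ground-truth theta and
#' adds independent Gaussian noise with frame-duration-dependent standard
#' deviation. With `scale = 0` the output equals [model_tac()] exactly. The
#' measure tag follows the noise mode (`"mean"` for suvmean-like, `"max"` for
#' suvmax-like). Uses the current RNG state.
#'
#' @inheritParams model_tac
#' @param noise A [noise_model()].
#' @return A tidy TAC tibble (values may undershoot zero at high noise, as
#'   real noisy measurements do).
#' @export
simulate_tac <- function(inputs, theta, schedule = default_frame_schedule(),
                         noise = noise_model(), voi_label = "sim") {
  stopifnot(inherits(noise, "noise_model"))
  clean <- model_tac(inputs, theta, schedule, sampling = "frame_average",
                     voi_label = voi_label)
  sig <- noise_sd(noise, clean$value, schedule)
  vals <- clean$value + rnorm(nrow(schedule), 0, sig)
  tac <- tac_tibble(schedule, vals, voi_label = voi_label,
                    measure = if (noise$mode == "suvmax_like") "max" else "mean")
  tac
}

#' Cohort simulation settings
#'
#' @param arterial Baseline [feng_params()] arterial model.
#' @param beta Portal dispersion constant, minutes.
#' @param subject_jitter_sd Log-normal sd applied per subject to the arterial
#'   amplitudes and to beta (inter-subject input variability).
#' @param noise_scale,noise_multiplier Noise model settings (see
#'   [noise_model()]).
#' @param schedule Frame schedule for all simulated TACs.
#' @param time_min Fine simulation grid, minutes.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(arterial = feng_params(), beta = 0.5,
                          subject_jitter_sd = 0.1,
                          noise_scale = 0.05, noise_multiplier = 2.5,
                          schedule = default_frame_schedule(),
                          time_min = fine_time_grid()) {
  validate_schedule(schedule)
  structure(list(arterial = arterial, beta = beta,
                 subject_jitter_sd = subject_jitter_sd,
                 noise_scale = noise_scale,
                 noise_multiplier = noise_multiplier,
                 schedule = schedule, time_min = time_min),
            class = "cohort_config")
}

#' Simulate a full dynamic-PET liver cohort
#'
#' Generates a study-sized cohort: one subject per reference VOI (defaults
#' mirror the study: 24 reference VOIs, 13 HCC and 25 ICC lesions, 62 tissue
#' VOIs in all), each subject with its own jittered arterial input and
#' dispersed portal input; per-VOI ground-truth parameters drawn from the
#' class priors; and, for every tissue VOI, a paired suvmean-like and
#' suvmax-like noisy TAC. Blood input TACs (noise-free, frame-averaged,
#' SUVmean) are included per subject. Lesions are assigned to subjects
#' round-robin.
#'
#' @param n_ref,n_hcc,n_icc VOI counts per tissue class.
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @return A list of class `"liver_cohort"`: `tacs` (tidy TAC tibble),
#'   `truth` (per-VOI ground truth with subject and tissue class),
#'   `subjects` (per-subject input-model parameters), `config`, `seed`.
#' @export
simulate_cohort <- function(n_ref = 24, n_hcc = 13, n_icc = 25,
                            config = cohort_config(), seed = 7L) {
  stopifnot(inherits(config, "cohort_config"),
            n_ref >= 0, n_hcc >= 0, n_icc >= 0)
  set.seed(as.integer(seed))
  n_sub <- max(n_ref, if (n_hcc + n_icc > 0) 1L else 0L)

  # per-subject input models
  subjects <- purrr::map_dfr(seq_len(n_sub), function(i) {
    j <- exp(rnorm(4, 0, config$subject_jitter_sd))
    tibble::tibble(subject = i, tau = config$arterial$tau,
                   A1 = config$arterial$A1 * j[1],
                   A2 = config$arterial$A2 * j[2],
                   A3 = config$arterial$A3 * j[3],
                   lambda1 = config$arterial$lambda1,
                   lambda2 = config$arterial$lambda2,
                   lambda3 = config$arterial$lambda3,
                   beta = config$beta * j[4])
  })

  voi_plan <- tibble::tibble(
    voi_label = c(sprintf("ref%02d", seq_len(n_ref)),
                  sprintf("hcc%02d", seq_len(n_hcc)),
                  sprintf("icc%02d", seq_len(n_icc))),
    tissue_class = rep(c("reference", "lesion_HCC", "lesion_ICC"),
                       c(n_ref, n_hcc, n_icc)))
  if (nrow(voi_plan) > 0) {
    voi_plan$subject <- c(seq_len(n_ref),
                          rep_len(seq_len(n_sub), n_hcc + n_icc))
  } else {
    voi_plan$subject <- integer(0)
  }

  truth <- purrr::map_dfr(seq_len(nrow(voi_plan)), function(i) {
    draw <- sample_params(population_prior(voi_plan$tissue_class[i]), 1)
    dplyr::bind_cols(voi_plan[i, ], draw)
  })

  nm_mean <- noise_model(config$noise_scale, "suvmean_like",
                         config$noise_multiplier)
  nm_max <- noise_model(config$noise_scale, "suvmax_like",
                        config$noise_multiplier)

  tac_list <- list()
  for (s in seq_len(n_sub)) {
    inputs <- subject_inputs(subjects[s, ], config$time_min)
    tac_list[[length(tac_list) + 1]] <-
      tac_tibble(config$schedule,
                 frame_reduce(inputs$time_min, inputs$c_ha, config$schedule,
                              "frame_average"),
                 voi_label = sprintf("s%02d_aorta", s), measure = "mean")
    tac_list[[length(tac_list) + 1]] <-
      tac_tibble(config$schedule,
                 frame_reduce(inputs$time_min, inputs$c_pv, config$schedule,
                              "frame_average"),
                 voi_label = sprintf("s%02d_portal_vein", s), measure = "mean")
    vois <- truth[truth$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(vois))) {
      theta <- as_kinetic_params(vois[i, c("K1", "k2", "k3", "k4", "fA", "vB")])
      tac_list[[length(tac_list) + 1]] <-
        simulate_tac(inputs, theta, config$schedule, nm_mean,
                     voi_label = vois$voi_label[i])
      tac_list[[length(tac_list) + 1]] <-
        simulate_tac(inputs, theta, config$schedule, nm_max,
                     voi_label = vois$voi_label[i])
    }
  }
  tacs <- if (length(tac_list) > 0) dplyr::bind_rows(tac_list) else
    tibble::tibble(frame_start_s = numeric(0), frame_duration_s = numeric(0),
                   voi_label = character(0), measure = character(0),
                   value = numeric(0))

  structure(list(tacs = tacs, truth = truth, subjects = subjects,
                 config = config, seed = as.integer(seed)),
            class = "liver_cohort")
}

#' Continuous input pair for one simulated subject
#'
#' @param subject_row One row of a cohort's `subjects` table.
#' @param time_min Fine time grid, minutes.
#' @return An input tibble (`time_min`, `c_ha`, `c_pv`).
#' @export
subject_inputs <- function(subject_row, time_min = fine_time_grid()) {
  m <- feng_params(tau = subject_row$tau, A1 = subject_row$A1,
                   A2 = subject_row$A2, A3 = subject_row$A3,
                   lambda1 = subject_row$lambda1,
                   lambda2 = subject_row$lambda2,
                   lambda3 = subject_row$lambda3)
  input_functions(m, beta = subject_row$beta, time_min = time_min)
}

#' Fit every tissue TAC of a simulated cohort
#'
#' Fits each tissue VOI against its own subject's (exact, continuous) input
#' pair and returns one row per fitted curve, joined with the tissue class
#' and ground truth for downstream comparison tables.
#'
#' @param cohort A `"liver_cohort"` from [simulate_cohort()].
#' @param measures Which measures to fit (`"mean"`, `"max"` or both).
#' @param config A [fit_config()].
#' @return A tibble of glance rows plus `tissue_class`, `subject`, and
#'   ground-truth columns prefixed `true_`.
#' @export
fit_cohort <- function(cohort, measures = "mean", config = fit_config()) {
  stopifnot(inherits(cohort, "liver_cohort"))
  res <- purrr::map_dfr(unique(cohort$truth$subject), function(s) {
    inputs <- subject_inputs(cohort$subjects[cohort$subjects$subject == s, ],
                             cohort$config$time_min)
    vois <- cohort$truth$voi_label[cohort$truth$subject == s]
    fit_tacs(cohort$tacs, inputs, vois = vois, measures = measures,
             config = config)
  })
  truth <- dplyr::rename_with(cohort$truth,
                              ~ paste0("true_", .x),
                              dplyr::all_of(c("K1", "k2", "k3", "k4",
                                              "fA", "vB", "Ki")))
  dplyr::left_join(res, truth, by = "voi_label")
}

#' Write a simulated cohort to a directory
#'
#' Emits `tacs.csv` (the wide TAC format of [write_tacs()]), `truth.csv`,
#' `subjects.csv` and a YAML config snapshot recording the generator
#' settings, seed and package version.
#'
#' @param cohort A `"liver_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "liver_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(cohort$tacs) > 0) {
    write_tacs(cohort$tacs, file.path(dir, "tacs.csv"))
  } else {
    sched <- cohort$config$schedule
    readr::write_csv(sched, file.path(dir, "tacs.csv"), progress = FALSE)
  }
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), progress = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   progress = FALSE)
  snap <- list(seed = cohort$seed,
               package_version = as.character(utils::packageVersion("liverkin")),
               noise_scale = cohort$config$noise_scale,
               noise_multiplier = cohort$config$noise_multiplier,
               beta = cohort$config$beta,
               subject_jitter_sd = cohort$config$subject_jitter_sd,
               n_frames = nrow(cohort$config$schedule))
  yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  invisible(dir)
}
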