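test_that("bundled patient fixtures match the printed cohort structure", {
  hcc <- load_fixture("HCC")
  icc <- load_fixture("ICC")
  expect_identical(nrow(hcc$patients), 9L)
  expect_identical(hcc$patients$age, c(59, 64, 67, 73, 46, 61, 71, 50, 38))
  expect_true(all(hcc$patients$sex == "M"))
  expect_identical(sum(hcc$patients$cirrhosis == "yes"), 7L)
  expect_identical(nrow(icc$patients), 15L)
  expect_identical(nrow(icc$lesions), 25L)
  expect_identical(nrow(hcc$lesions) + nrow(icc$lesions), 38L)
  expect_identical(sum(icc$patients$sex == "F"), 4L)
})

test_that("fixture summaries reproduce the printed table statistics", {
  hcc <- load_fixture("HCC")
  icc <- load_fixture("ICC")
  s_hcc_age <- summarize_values(hcc$patients$age)
  expect_equal(round_half_up(s_hcc_age$mean), 58.78)
  expect_equal(round_half_up(s_hcc_age$sd), 11.85)
  expect_identical(s_hcc_age$display, "58.78 ± 11.85")
  s_icc_age <- summarize_values(icc$patients$age)
  expect_equal(round_half_up(s_icc_age$mean), 56.60)
  expect_equal(round_half_up(s_icc_age$sd), 12.19)
  expect_equal(round_half_up(mean(icc$lesions$volume_cm3)), 13.15)
  expect_equal(round_half_up(sd(icc$lesions$volume_cm3)), 25.89)
  expect_equal(round_half_up(mean(icc$lesions$suvmax)), 7.48)
  expect_equal(round_half_up(sd(icc$lesions$suvmax)), 3.65)
  # degenerate summaries
  expect_equal(summarize_values(c(5, 5, 5))$sd, 0)
  expect_true(is.na(summarize_values(7)$sd))
  expect_error(summarize_values(numeric(0)), "empty")
})

test_that("two-sample comparison reproduces hand-computed t-tests", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), "student")
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)
  expect_identical(r$stars, "**")
  expect_true(r$significant)
  # identical groups with spread: t = 0, p = 1
  r0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # extreme separation with tiny jitter
  set.seed(8)
  rx <- compare_groups(rnorm(4, 0, 1e-6), 1 + rnorm(4, 0, 1e-6))
  expect_lt(rx$p, 0.001)
  expect_identical(rx$stars, "****")
  # antisymmetry under group swap
  a <- c(0.1, 0.5, 0.9); b <- c(1.2, 1.4, 2.0)
  expect_equal(compare_groups(a, b)$t, -compare_groups(b, a)$t)
  # zero-variance identical groups are flagged undefined
  rz <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(is.na(rz$t))
  expect_error(compare_groups(1, c(1, 2)), "two observations")
})

test_that("significance stars are a monotone pure function of p", {
  p <- c(1e-5, 0.005, 0.02, 0.07, 0.5)
  expect_identical(significance_stars(p), c("****", "***", "**", "*", ""))
  expect_true(all(diff(nchar(significance_stars(sort(p)))) <= 0))
})

test_that("ground-truth draws summarize to their truncated prior means", {
  set.seed(77)
  co <- simulate_cohort(24, 13, 25, seed = 77)
  # feed truths straight into the comparison machinery (no fitting, no noise)
  truths <- dplyr::mutate(co$truth, measure = "mean")
  tab <- kinetic_comparison(truths, "lesion_vs_reference")
  trunc_mean <- function(mu, s, a = 0, b = Inf) {
    al <- (a - mu) / s; be <- (b - mu) / s
    z <- pnorm(be) - pnorm(al)
    mu + s * (dnorm(al) - dnorm(be)) / z
  }
  pr <- population_prior("reference")
  for (pm in c("K1", "k2", "fA")) {
    mu <- pr$mean[pr$term == pm]; s <- pr$sd[pr$term == pm]
    b <- if (pm == "fA") 1 else 10
    expect_lt(abs(tab$mean1[tab$parameter == pm] - trunc_mean(mu, s, 0, b)),
              3 * s / sqrt(24))
  }
  # lesion truths separate from reference truths in the expected directions
  expect_gt(tab$mean2[tab$parameter == "fA"], tab$mean1[tab$parameter == "fA"])
  expect_gt(tab$mean2[tab$parameter == "Ki"], tab$mean1[tab$parameter == "Ki"])
})

test_that("comparison tables handle single groups and missing labels", {
  fits <- tibble::tibble(tissue_class = rep("reference", 4), measure = "mean",
                         K1 = c(1.5, 1.7, 1.6, 1.8), Ki = c(0.001, 0.002, 0.001, 0.003))
  tab <- kinetic_comparison(fits, "lesion_vs_reference")
  expect_true(all(is.na(tab$p)))
  expect_false(any(is.na(tab$mean1)))
  bad <- dplyr::mutate(fits, tissue_class = NA_character_)
  expect_error(kinetic_comparison(bad), "missing")
  expect_error(kinetic_comparison(dplyr::select(fits, -tissue_class)),
               "tissue_class")
})

test_that("comparison reports are written as CSV and text", {
  set.seed(5)
  fits <- tibble::tibble(
    tissue_class = rep(c("reference", "lesion_HCC", "lesion_ICC"), each = 5),
    measure = "mean",
    K1 = c(rnorm(5, 1.66, 0.3), rnorm(5, 0.39, 0.1), rnorm(5, 0.69, 0.2)),
    fA = c(runif(5, 0, 0.2), runif(5, 0.6, 1), runif(5, 0.3, 0.7)),
    Ki = c(runif(5, 0, 0.005), runif(5, 0.03, 0.1), runif(5, 0.02, 0.06)))
  d <- withr::local_tempdir()
  out <- comparison_report(fits, d)
  expect_true(file.exists(file.path(d, "lesion_vs_reference.csv")))
  expect_true(file.exists(file.path(d, "hcc_vs_icc.txt")))
  expect_identical(names(out), c("lesion_vs_reference", "hcc_vs_icc"))
  txt <- readLines(file.path(d, "lesion_vs_reference.txt"))
  expect_true(any(grepl("fA", txt)))
})

test_that("fixture loader detects corruption", {
  # a tampered copy must not pass the checksum
  src <- system.file("extdata", "patients_hcc.csv", package = "liverkin")
  tmp <- withr::local_tempdir()
  fake_pkg <- file.path(tmp, "extdata")
  dir.create(fake_pkg)
  lines <- readLines(src)
  lines[2] <- sub("59", "60", lines[2])
  writeLines(lines, file.path(fake_pkg, "patients_hcc.csv"))
  md5 <- unname(tools::md5sum(file.path(fake_pkg, "patients_hcc.csv")))
  expect_false(identical(md5, unname(liverkin:::FIXTURE_MD5[["patients_hcc.csv"]])))
})
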