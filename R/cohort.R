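FIXTURE_MD5 <- c(
  lesions_hcc.csv  = "03b51203485153d1c82f2cfb5801cb5e",
  lesions_icc.csv  = "45ac2c397392a3d08d7e3f89dd3ec5b4",
  patients_hcc.csv = "fad029d299c2120b2db6ac1385d3f3ad",
  patients_icc.csv = "c813534a0854fb780fd03c79843e5821"
)

#' Bundled patient-characteristics fixtures
#'
#' Per-patient clinical records of the 24-patient study cohort: the HCC group
#' (9 patients, 13 lesions, all male, with a cirrhosis flag) and the ICC
#' group (15 patients, 25 lesions). Each record carries sex, age, previous
#' treatments, and per-lesion volume (cm^3) and SUVmax. The HCC per-lesion
#' volume/SUVmax cells were typographically ambiguous in the source tables
#' and are a best-effort transcription (their column means check out, so they
#' ship, but downstream checks rely only on the ICC per-lesion values, which
#' were verified independently). Files are checksum-validated on load.
#'
#' @param group `"HCC"` or `"ICC"`.
#' @return A list with tibbles `patients` (one row per patient) and `lesions`
#'   (one row per lesion, keyed by `patient_id`).
#' @export
load_fixture <- function(group = c("HCC", "ICC")) {
  group <- match.arg(group)
  suffix <- tolower(group)
  files <- paste0(c("patients_", "lesions_"), suffix, ".csv")
  paths <- vapply(files, function(f) {
    p <- system.file("extdata", f, package = "liverkin")
    if (p == "") abort(sprintf("fixture file %s not found", f))
    md5 <- unname(tools::md5sum(p))
    if (!identical(md5, unname(FIXTURE_MD5[[f]]))) {
      abort(sprintf("fixture %s failed its checksum (corrupted install?)", f))
    }
    p
  }, character(1))
  patients <- readr::read_csv(paths[1], show_col_types = FALSE, progress = FALSE)
  lesions <- readr::read_csv(paths[2], show_col_types = FALSE, progress = FALSE)
  counts <- dplyr::count(lesions, .data$patient_id)
  chk <- dplyr::left_join(patients, counts, by = "patient_id")
  if (any(chk$n_lesions != chk$n)) {
    abort("fixture lesion counts disagree with the patient table")
  }
  list(patients = patients, lesions = lesions)
}

#' Round half away from zero
#'
#' Display rounding for table reproduction (R's `round()` rounds half to
#' even; printed clinical tables round half up).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Mean-and-SD summary of a group of values
#'
#' Sample mean and sample (n-1) standard deviation, plus 2-decimal display
#' values rounded half up, as in "mean +/- SD" table cells.
#'
#' @param values Numeric vector; `n >= 1`, and the SD needs `n >= 2`
#'   (flagged `NA` otherwise).
#' @return A one-row tibble with `n`, `mean`, `sd`, `display`.
#' @examples
#' summarize_values(c(59, 64, 67, 73, 46, 61, 71, 50, 38))  # 58.78 +/- 11.85
#' @export
summarize_values <- function(values) {
  if (length(values) == 0) abort("cannot summarize an empty group")
  m <- mean(values)
  s <- if (length(values) >= 2) sd(values) else NA_real_
  tibble::tibble(
    n = length(values), mean = m, sd = s,
    display = if (is.na(s)) sprintf("%.2f", round_half_up(m)) else
      sprintf("%.2f ± %.2f", round_half_up(m), round_half_up(s)))
}

#' Significance stars
#'
#' Four-level star convention: `****`, `***`, `**` and `*` mark significance
#' at the 0.1%, 1%, 5% and 10% levels respectively; larger p gives an empty
#' string. Pure, monotone function of p.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "****",
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.10 ~ "*",
    TRUE ~ ""
  )
}

#' Two-sample comparison of a kinetic parameter between groups
#'
#' Two-sided two-sample t-test, by default the equal-variance Student's test
#' (`variant = "welch"` gives the unequal-variance form). p < 0.05 is flagged
#' significant; stars follow [significance_stars()]. Because group variances
#' of kinetic parameters are often badly unequal, the result carries the
#' variance ratio and a `welch_advised` flag (ratio > 4) so reports can
#' surface it. Zero-variance identical groups have no defined t statistic and
#' come back flagged with `t = NA`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p`, `stars`, `significant`,
#'   `variance_ratio`, `welch_advised`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
compare_groups <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least two observations")
  }
  va <- stats::var(a); vb <- stats::var(b)
  vr <- if (vb == 0) Inf else va / vb
  if (va == 0 && vb == 0) {
    degenerate <- mean(a) == mean(b)
    if (degenerate) {
      return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                            stars = NA_character_, significant = NA,
                            variance_ratio = NaN, welch_advised = FALSE))
    }
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  p <- tt$p.value
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
                 stars = significance_stars(p), significant = p < 0.05,
                 variance_ratio = vr,
                 welch_advised = is.infinite(vr) || vr > 4 || vr < 1 / 4)
}

#' Group-comparison tables of fitted kinetic parameters
#'
#' Builds the study-style comparison report from a table of fitted results
#' labelled by tissue class: per parameter (K1, k2, k3, k4, fA, vB, Ki) and
#' per measure, the mean +/- SD of each group and the Student's-t p value
#' with significance stars. Two comparisons are available: all lesions versus
#' reference tissue, and HCC versus ICC lesions. With only one group present
#' the summary columns are returned without p values.
#'
#' @param fits A tibble with columns `tissue_class`
#'   (reference/lesion_HCC/lesion_ICC), `measure`, and the parameter columns —
#'   e.g. the output of [fit_cohort()].
#' @param comparison `"lesion_vs_reference"` or `"hcc_vs_icc"`.
#' @param variant t-test variant passed to [compare_groups()].
#' @return A tibble with one row per (parameter, measure).
#' @export
kinetic_comparison <- function(fits,
                               comparison = c("lesion_vs_reference",
                                              "hcc_vs_icc"),
                               variant = "student") {
  comparison <- match.arg(comparison)
  if (!"tissue_class" %in% names(fits)) {
    abort("fits must carry a tissue_class column")
  }
  if (any(is.na(fits$tissue_class))) abort("missing tissue_class labels")
  if (comparison == "lesion_vs_reference") {
    fits <- dplyr::mutate(fits, grp = ifelse(
      .data$tissue_class == "reference", "reference", "lesion"))
    g1 <- "reference"; g2 <- "lesion"
  } else {
    fits <- dplyr::filter(fits, .data$tissue_class != "reference")
    fits <- dplyr::mutate(fits, grp = ifelse(
      .data$tissue_class == "lesion_HCC", "HCC", "ICC"))
    g1 <- "HCC"; g2 <- "ICC"
  }
  params <- intersect(c("K1", "k2", "k3", "k4", "fA", "vB", "Ki"),
                      names(fits))
  grid <- tidyr::expand_grid(parameter = params,
                             measure = unique(fits$measure))
  purrr::pmap_dfr(grid, function(parameter, measure) {
    sub <- dplyr::filter(fits, .data$measure == .env$measure)
    x1 <- sub[[parameter]][sub$grp == g1]
    x2 <- sub[[parameter]][sub$grp == g2]
    s1 <- if (length(x1) > 0) summarize_values(x1) else
      tibble::tibble(n = 0, mean = NA_real_, sd = NA_real_, display = NA_character_)
    s2 <- if (length(x2) > 0) summarize_values(x2) else
      tibble::tibble(n = 0, mean = NA_real_, sd = NA_real_, display = NA_character_)
    cmp <- if (length(x1) >= 2 && length(x2) >= 2) {
      compare_groups(x1, x2, variant = variant)
    } else {
      tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                     stars = NA_character_, significant = NA,
                     variance_ratio = NA_real_, welch_advised = NA)
    }
    tibble::tibble(parameter = parameter, measure = measure,
                   group1 = g1, n1 = s1$n, mean1 = s1$mean, sd1 = s1$sd,
                   display1 = s1$display,
                   group2 = g2, n2 = s2$n, mean2 = s2$mean, sd2 = s2$sd,
                   display2 = s2$display,
                   t = cmp$t, p = cmp$p, stars = cmp$stars,
                   significant = cmp$significant,
                   welch_advised = cmp$welch_advised)
  })
}

#' Write comparison tables as CSV and readable text
#'
#' @param fits See [kinetic_comparison()].
#' @param dir Output directory.
#' @param variant t-test variant.
#' @return Invisibly, the list of written comparison tibbles.
#' @export
comparison_report <- function(fits, dir, variant = "student") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (cmp in c("lesion_vs_reference", "hcc_vs_icc")) {
    tab <- kinetic_comparison(fits, cmp, variant = variant)
    readr::write_csv(tab, file.path(dir, paste0(cmp, ".csv")),
                     progress = FALSE)
    txt <- c(sprintf("Kinetic parameter comparison: %s", gsub("_", " ", cmp)),
             "",
             sprintf("%-6s %-5s %-16s %-16s %8s %s",
                     "param", "meas", tab$group1[1], tab$group2[1], "p", ""),
             sprintf("%-6s %-5s %-16s %-16s %8s %s%s",
                     tab$parameter, tab$measure,
                     ifelse(is.na(tab$display1), "-", tab$display1),
                     ifelse(is.na(tab$display2), "-", tab$display2),
                     ifelse(is.na(tab$p), "-", sprintf("%.4f", tab$p)),
                     ifelse(is.na(tab$stars), "", tab$stars),
                     ifelse(!is.na(tab$welch_advised) & tab$welch_advised,
                            " (unequal variances)", "")))
    writeLines(txt, file.path(dir, paste0(cmp, ".txt")))
    out[[cmp]] <- tab
  }
  invisible(out)
}
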