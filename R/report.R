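#' End-to-end analysis of a trial table
#'
#' Chains the full pipeline over a (simulated or imported) cohort:
#' psychometric fits per group x orientation, per-participant SDT
#' summaries, Monte Carlo permutation tests of the effects of interest,
#' lapse rates on the extreme lengths, and the mischievous-sentence probe.
#'
#' The permutation battery mirrors the design's questions: the
#' within-participant orientation effect on d-prime (the inversion effect)
#' and on median reaction time; the between-group flip-type effect on beta
#' (mirror vs upside-down underestimation bias); and the flip-type by
#' orientation interaction on underestimation-lapse difference scores.
#'
#' @param trials A trial table with responses.
#' @param n_iter Permutation iterations per test.
#' @param seed Integer seed driving all permutation randomness.
#' @param reference_length Reference word count.
#' @return An object of class `sentlen_report`: a list of tibbles `fits`,
#'   `sdt`, `permutations`, `lapses`, `mischievous`, plus `meta`.
#' @export
#' @examples
#' trials <- simulate_cohort(design_config(n_per_group = 4),
#'                           observer_params(), seed = 1)
#' rep <- analyze_cohort(trials, n_iter = 200, seed = 1)
#' rep$permutations
analyze_cohort <- function(trials, n_iter = 10000, seed = 1L,
                           reference_length = 17) {
  ana <- analysis_trials(trials)
  if (nrow(ana) == 0) {
    stop("analyze_cohort: no analysis-phase trials", call. = FALSE)
  }

  fits <- fit_cohort_psychometrics(trials,
                                   reference_length = reference_length)
  sdt <- sdt_by_participant(trials, reference_length = reference_length)
  lapses <- lapse_rates(trials)
  mischief <- mischievous_analysis(trials)

  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, 4))

  wide <- function(tbl, value_col) {
    tbl |>
      dplyr::select(dplyr::all_of(c("participant_id", "flip_type",
                                    "orientation", value_col))) |>
      tidyr::pivot_wider(names_from = "orientation",
                         values_from = dplyr::all_of(value_col)) |>
      dplyr::filter(!is.na(.data$standard), !is.na(.data$flipped))
  }

  sdt_wide <- wide(sdt, "d_prime")
  dprime_orientation <- perm_test_within(
    sdt_wide$standard, sdt_wide$flipped, n_iter = n_iter, seed = seeds[1])

  beta_by_p <- sdt |>
    dplyr::group_by(.data$participant_id, .data$flip_type) |>
    dplyr::summarise(beta = median(.data$beta), .groups = "drop")
  beta_fliptype <- perm_test_between(
    beta_by_p$beta[beta_by_p$flip_type == "mirror"],
    beta_by_p$beta[beta_by_p$flip_type == "upside_down"],
    n_iter = n_iter, seed = seeds[2])

  lapse_wide <- wide(lapses, "underestimate_lapse_rate") |>
    dplyr::mutate(diff = .data$flipped - .data$standard)
  lapse_interaction <- perm_test_interaction(
    lapse_wide$diff[lapse_wide$flip_type == "mirror"],
    lapse_wide$diff[lapse_wide$flip_type == "upside_down"],
    n_iter = n_iter, seed = seeds[3])

  rt_by_cell <- ana |>
    dplyr::group_by(.data$participant_id, .data$flip_type,
                    .data$orientation) |>
    dplyr::summarise(rt_median = median(.data$rt_seconds),
                     .groups = "drop")
  rt_wide <- wide(rt_by_cell, "rt_median")
  rt_orientation <- perm_test_within(
    rt_wide$flipped, rt_wide$standard, n_iter = n_iter, seed = seeds[4])

  permutations <- dplyr::bind_rows(
    dplyr::mutate(tidy(dprime_orientation),
                  effect = "d_prime: standard - flipped", .before = 1),
    dplyr::mutate(tidy(beta_fliptype),
                  effect = "beta: mirror - upside_down", .before = 1),
    dplyr::mutate(tidy(lapse_interaction),
                  effect = "underestimate lapse diff: mirror - upside_down",
                  .before = 1),
    dplyr::mutate(tidy(rt_orientation),
                  effect = "rt median: flipped - standard", .before = 1)
  )

  structure(
    list(
      fits = fits,
      sdt = sdt,
      permutations = permutations,
      lapses = lapses,
      mischievous = mischief,
      meta = list(
        seed = seed,
        n_iter = n_iter,
        n_participants = dplyr::n_distinct(ana$participant_id),
        n_analysis_trials = nrow(ana),
        reference_length = reference_length,
        package_version = as.character(utils::packageVersion("sentlen"))
      )
    ),
    class = "sentlen_report"
  )
}

#' @export
print.sentlen_report <- function(x, ...) {
  cat("Sentence-length perception analysis report\n")
  cat(sprintf("  %d participants, %d analysis trials (seed %d)\n",
              x$meta$n_participants, x$meta$n_analysis_trials, x$meta$seed))
  jnd <- x$fits$jnd[x$fits$ok]
  if (length(jnd) > 0) {
    cat(sprintf("  group JNDs: %.2f-%.2f words (Weber %.1f-%.1f%%)\n",
                min(jnd), max(jnd),
                100 * min(x$fits$weber_fraction, na.rm = TRUE),
                100 * max(x$fits$weber_fraction, na.rm = TRUE)))
  }
  cat(sprintf("  median d' = %.3f, median beta = %.3f\n",
              median(x$sdt$d_prime), median(x$sdt$beta)))
  cat("  permutation tests:\n")
  for (i in seq_len(nrow(x$permutations))) {
    row <- x$permutations[i, ]
    cat(sprintf("    %-48s diff = %8.4f  p = %.4f%s\n", row$effect,
                row$observed_diff, row$p_value,
                if (row$significant) " *" else ""))
  }
  invisible(x)
}

#' @export
glance.sentlen_report <- function(x, ...) {
  tibble::tibble(
    n_participants = x$meta$n_participants,
    n_analysis_trials = x$meta$n_analysis_trials,
    median_d_prime = median(x$sdt$d_prime),
    median_beta = median(x$sdt$beta),
    min_jnd = min(x$fits$jnd[x$fits$ok]),
    max_jnd = max(x$fits$jnd[x$fits$ok]),
    seed = x$meta$seed
  )
}

#' Write a report bundle to disk
#'
#' Emits the result tables as CSV files (`fits.csv`, `sdt.csv`,
#' `permutations.csv`, `lapses.csv`, `mischievous.csv`) plus a
#' `summary.json` with run metadata, into `dir`.
#'
#' @param report A [analyze_cohort()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sentlen_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("fits", "sdt", "permutations", "lapses", "mischievous")
  files <- character(0)
  for (tbl in tables) {
    path <- file.path(dir, paste0(tbl, ".csv"))
    readr::write_csv(report[[tbl]], path, progress = FALSE)
    files <- c(files, path)
  }
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    c(report$meta, as.list(glance(report))),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(files, json_path))
}

#' Audit the package's numerical conventions against worked anchors
#'
#' Recomputes every desk-scale worked example that pins down the package's
#' conventions -- the half-SD d-prime/beta scale, the extreme-rate
#' correction, the omega-squared denominator, the phi-based sample size,
#' the Weber-fraction arithmetic, the chance band, and the schedule counts
#' -- and compares each against its expected value at the printed
#' precision. Running the audit with a perturbed convention (unit-SD z, or
#' the printed-precedence omega-squared denominator) must break the
#' corresponding anchors; this guards against silent convention drift.
#'
#' @param beta_convention `"half_sd"` (the package convention) or
#'   `"unit_sd"` (deliberate fault).
#' @param omega_reading `"worked_value"` or `"printed_precedence"`
#'   (deliberate fault).
#' @return A tibble with `anchor`, `expected`, `computed`, `pass`.
#' @export
#' @examples
#' all(audit_anchors()$pass)
audit_anchors <- function(beta_convention = c("half_sd", "unit_sd"),
                          omega_reading = c("worked_value",
                                            "printed_precedence")) {
  beta_convention <- match.arg(beta_convention)
  omega_reading <- match.arg(omega_reading)
  z_scale <- if (beta_convention == "half_sd") 0.5 else 1

  ow <- omega_squared(9.37, 2, 17, reading = omega_reading)
  ss <- sample_size(0.1975, 2.3)
  band <- chance_band(22)
  sched <- generate_schedule("audit", design_config(), rng_seed = 1)
  ana <- sched[sched$phase == "analysis", ]

  anchors <- tibble::tribble(
    ~anchor, ~expected, ~computed, ~digits,
    "d_prime at unbiased 75% correct", 0.67, d_prime(0.75, 0.25), 2,
    "beta at hit 0.784 / fa 0.041", 1.351,
      beta_criterion(0.784, 0.041, z_scale = z_scale), 3,
    "beta at symmetric 9.6% rates", 1.0,
      beta_criterion(0.904, 0.096, z_scale = z_scale), 3,
    "corrected perfect hit rate (34.5/35)", 34.5 / 35,
      corrected_rates(35, 35, 0, 35)$hit_rate, 6,
    "corrected zero fa rate (0.5/35)", 0.5 / 35,
      corrected_rates(35, 35, 0, 35)$fa_rate, 6,
    "omega^2 from F = 9.37, a = 2, n = 17", 0.1975, ow, 4,
    "sample size n_exact from phi = 2.3", 21.49, ss$n_exact, 2,
    "sample size rounded up", 22, ss$n_rounded, 0,
    "Weber fraction of JND 1.60 (%)", 9.41,
      100 * weber_fraction(1.60, 17), 2,
    "Weber fraction of JND 1.81 (%)", 10.65,
      100 * weber_fraction(1.81, 17), 2,
    "chance band lower at n = 22", 0.32, band[["lower"]], 2,
    "chance band upper at n = 22", 0.68, band[["upper"]], 2,
    "analysis trials per participant", 140, nrow(ana), 0,
    "analysis trials per orientation", 70,
      sum(ana$orientation == "standard"), 0
  )
  anchors |>
    dplyr::mutate(pass = abs(.data$computed - .data$expected) <=
                    10^(-.data$digits) / 2 + 1e-12) |>
    dplyr::select(-"digits")
}
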