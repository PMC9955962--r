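#' Two-parameter sigmoid psychometric function
#'
#' `1 / (1 + exp(-K * (x - Xo)))`: `K` sets the slope (per word) and `Xo`
#' the midpoint (the point of subjective equality) on the relative-length
#' axis `x = length_words - reference_length`.
#'
#' @param x Relative sentence length, words.
#' @param K Slope parameter, per word. Positive for a rising curve.
#' @param Xo Midpoint, words.
#' @return Probability of a "more" response, in (0, 1).
#' @export
#' @examples
#' sigmoid(0, K = 0.7, Xo = 0)     # 0.5 at the midpoint
#' sigmoid(log(3) / 0.7, 0.7, 0)   # 0.75 one JND above
sigmoid <- function(x, K, Xo) {
  1 / (1 + exp(-K * (x - Xo)))
}

#' Just-noticeable difference from the sigmoid slope
#'
#' Half the change in relative length needed to move the "more" response
#' rate from 0.25 to 0.75 on the fitted sigmoid, which is `ln(3) / K`.
#'
#' @param K Sigmoid slope, per word; must be positive.
#' @return JND in words.
#' @export
#' @examples
#' jnd_from_slope(log(3))  # 1 word by construction
jnd_from_slope <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("jnd_from_slope: K must be positive and finite", call. = FALSE)
  }
  log(3) / K
}

#' Weber fraction
#'
#' The JND expressed as a proportion of the reference magnitude; a
#' scale-free index of discrimination precision.
#'
#' @param jnd JND in words; positive.
#' @param reference_length Reference magnitude, words; positive.
#' @return JND / reference, a proportion.
#' @export
#' @examples
#' weber_fraction(1.60, 17)  # 0.0941
weber_fraction <- function(jnd, reference_length = 17) {
  if (any(jnd <= 0) || any(reference_length <= 0)) {
    stop("weber_fraction: inputs must be positive", call. = FALSE)
  }
  jnd / reference_length
}

#' Aggregate "more" response proportions per sentence length
#'
#' Computes, for each grouping cell and orientation, the proportion of
#' "more" responses at every analysis sentence length, with trial counts
#' and the relative-length abscissa. Cells with no trials at a design
#' length are reported with `NA` proportions, never as zero.
#'
#' @param trials A trial table; only analysis-phase rows are used.
#' @param by Character vector of grouping columns (besides `orientation`).
#'   Use `"participant_id"` for per-participant curves.
#' @param reference_length Reference word count for the relative axis.
#' @return A tibble with the grouping columns plus `orientation`,
#'   `length_words`, `x_rel`, `n_trials`, `prop_more`.
#' @export
#' @examples
#' trials <- simulate_cohort(design_config(n_per_group = 2),
#'                           observer_params(), seed = 1)
#' group_proportions(trials)
group_proportions <- function(trials,
                              by = c("flip_type", "sample_id"),
                              reference_length = 17) {
  ana <- analysis_trials(trials)
  lengths_present <- sort(unique(ana$length_words))
  ana |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "orientation",
                                                  "length_words")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      prop_more = mean(.data$response == "more"),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c(by, "orientation"))),
      length_words = lengths_present
    ) |>
    dplyr::mutate(x_rel = .data$length_words - reference_length) |>
    dplyr::relocate("x_rel", .after = "length_words")
}

#' Fit the sigmoid psychometric function by least squares
#'
#' Minimises the sum of squared residuals between observed "more"
#' proportions and [sigmoid()] predictions over `(K, Xo)`, using bounded
#' L-BFGS-B from a 3 x 3 multi-start grid (`Xo` in {-2, 0, 2}, `K` in
#' {0.3, 0.7, 1.5}); ties are broken by smallest SSE, then smallest `K`.
#' Proportions of exactly 0 or 1 enter the least squares untransformed.
#' Flat or non-monotone data that drive `K` to the lower bound are flagged
#' as fit failures rather than returned silently.
#'
#' @param points A data frame with columns `x_rel` (relative length, words)
#'   and `prop_more` (observed proportion in `[0, 1]`); rows with `NA`
#'   proportions are dropped. At least 4 distinct abscissa values required.
#' @param reference_length Reference word count, used for the Weber
#'   fraction.
#' @return An object of class `psychometric_fit`: a list with `K`, `Xo`,
#'   `sse`, `pearson_r`, `var_explained`, `jnd`, `weber_fraction`, `pse`,
#'   `ok` (logical fit-success flag) and the fitted `points`.
#' @export
#' @examples
#' pts <- tibble::tibble(x_rel = c(-7:-1, 1:7),
#'                       prop_more = sigmoid(c(-7:-1, 1:7), 0.7, 0.2))
#' fit <- fit_psychometric(pts)
#' c(fit$K, fit$Xo, fit$jnd)
fit_psychometric <- function(points, reference_length = 17) {
  stopifnot(is.data.frame(points),
            all(c("x_rel", "prop_more") %in% names(points)))
  pts <- points |>
    dplyr::filter(!is.na(.data$prop_more)) |>
    dplyr::select("x_rel", "prop_more")
  if (length(unique(pts$x_rel)) < 4) {
    stop("fit_psychometric: need at least 4 distinct abscissa values",
         call. = FALSE)
  }
  if (any(pts$prop_more < 0 | pts$prop_more > 1)) {
    stop("fit_psychometric: proportions must lie in [0, 1]", call. = FALSE)
  }

  x <- pts$x_rel
  p <- pts$prop_more
  sse_fun <- function(par) sum((sigmoid(x, par[1], par[2]) - p)^2)

  starts <- tidyr::expand_grid(K = c(0.3, 0.7, 1.5), Xo = c(-2, 0, 2))
  fits <- purrr::pmap(starts, function(K, Xo) {
    optim(c(K, Xo), sse_fun, method = "L-BFGS-B",
          lower = c(1e-6, min(x) - diff(range(x))),
          upper = c(1e3, max(x) + diff(range(x))),
          control = list(factr = 1e1, pgtol = 0, maxit = 500))
  })
  sses <- vapply(fits, function(f) f$value, numeric(1))
  ks <- vapply(fits, function(f) f$par[1], numeric(1))
  best <- fits[[order(sses, ks)[1]]]

  K <- best$par[1]
  Xo <- best$par[2]
  fitted <- sigmoid(x, K, Xo)
  r <- suppressWarnings(cor(fitted, p))
  # a fit fails when the slope collapses to a bound (flat or reversed data)
  # or the correlation is undefined; optimiser stalls at machine-precision
  # SSE are not failures
  ok <- is.finite(K) && K > 1e-3 && K < 1e3 - 1e-6 && is.finite(r)

  structure(
    list(
      K = K,
      Xo = Xo,
      sse = best$value,
      pearson_r = if (is.finite(r)) r else NA_real_,
      var_explained = if (is.finite(r)) r^2 else NA_real_,
      jnd = if (ok) jnd_from_slope(K) else NA_real_,
      weber_fraction = if (ok) weber_fraction(log(3) / K, reference_length)
                       else NA_real_,
      pse = Xo,
      ok = ok,
      reference_length = reference_length,
      points = tibble::as_tibble(pts)
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Sigmoid psychometric fit",
      if (!x$ok) "(FIT FAILURE)" else "", "\n")
  cat(sprintf("  K = %.4f /word, Xo (PSE) = %.4f words\n", x$K, x$Xo))
  if (x$ok) {
    cat(sprintf("  JND = %.3f words, Weber fraction = %.2f%%\n",
                x$jnd, 100 * x$weber_fraction))
  }
  cat(sprintf("  SSE = %.3g, r = %.4f, var explained = %.1f%%\n",
              x$sse, x$pearson_r, 100 * x$var_explained))
  invisible(x)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K", "Xo"),
    estimate = c(x$K, x$Xo)
  )
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, Xo = x$Xo, sse = x$sse, pearson_r = x$pearson_r,
    var_explained = x$var_explained, jnd = x$jnd,
    weber_fraction = x$weber_fraction, pse = x$pse, ok = x$ok
  )
}

#' Fit psychometric functions for every cell of a cohort
#'
#' Convenience wrapper chaining [group_proportions()] and
#' [fit_psychometric()] over each grouping cell and orientation; the
#' default grouping reproduces one curve per group x orientation, fitted to
#' the cell's mean proportions.
#'
#' @inheritParams group_proportions
#' @return A tibble with the grouping columns, `orientation`, and one
#'   column per [glance.psychometric_fit()] field.
#' @export
#' @examples
#' trials <- simulate_cohort(design_config(n_per_group = 2),
#'                           observer_params(), seed = 1)
#' fit_cohort_psychometrics(trials)
fit_cohort_psychometrics <- function(trials,
                                     by = c("flip_type", "sample_id"),
                                     reference_length = 17) {
  group_proportions(trials, by = by, reference_length = reference_length) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "orientation")))) |>
    dplyr::group_modify(function(cell, key) {
      glance(fit_psychometric(cell, reference_length = reference_length))
    }) |>
    dplyr::ungroup()
}
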