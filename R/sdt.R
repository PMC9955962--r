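#' Extreme-rate corrections for SDT proportions
#'
#' z-transforms need rates strictly inside (0, 1), so perfect cells are
#' nudged half a trial inward: a count of 0 becomes 0.5 / n and a count of
#' n becomes (n - 0.5) / n. With the default 35-trial cells this is the
#' familiar 0.5/35 and 34.5/35 rule, generalised to any cell size.
#'
#' @param hits,false_alarms Response counts.
#' @param n_signal,n_noise Cell sizes (trials with more / fewer words than
#'   the reference).
#' @return A list with `hit_rate` and `fa_rate`, both in (0, 1).
#' @export
#' @examples
#' corrected_rates(35, 35, 0, 35)  # 34.5/35 and 0.5/35
corrected_rates <- function(hits, n_signal, false_alarms, n_noise) {
  if (any(n_signal <= 0) || any(n_noise <= 0)) {
    stop("corrected_rates: cell sizes must be positive", call. = FALSE)
  }
  if (any(hits < 0) || any(hits > n_signal) ||
      any(false_alarms < 0) || any(false_alarms > n_noise)) {
    stop("corrected_rates: counts must lie within their cell sizes",
         call. = FALSE)
  }
  correct_one <- function(k, n) pmin(pmax(k, 0.5), n - 0.5) / n
  list(
    hit_rate = correct_one(hits, n_signal),
    fa_rate = correct_one(false_alarms, n_noise)
  )
}

#' Half-scaled z-score
#'
#' The z-transform used throughout: the unit-normal quantile scaled by the
#' convention that the z-distribution's SD is 0.5, i.e.
#' `0.5 * qnorm(p)`.
#'
#' @param p Proportion strictly inside (0, 1).
#' @return Half-scaled z-score.
#' @export
#' @examples
#' z_half(0.75)  # 0.3373
z_half <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("z_half: p must lie strictly in (0, 1)", call. = FALSE)
  }
  0.5 * qnorm(p)
}

#' Sensitivity d-prime under the half-SD convention
#'
#' `d' = z_half(hit_rate) - z_half(fa_rate)`. On this scale, unbiased 75%
#' correct performance corresponds to d' = 0.67.
#'
#' @param hit_rate,fa_rate Corrected rates in (0, 1).
#' @return d-prime.
#' @export
#' @examples
#' d_prime(0.75, 0.25)  # 0.674
d_prime <- function(hit_rate, fa_rate) {
  z_half(hit_rate) - z_half(fa_rate)
}

#' Criterion beta as a likelihood ratio
#'
#' The ratio of unit-normal densities evaluated at the half-scaled
#' z-scores of the hit and false-alarm rates:
#' `dnorm(z_half(hit)) / dnorm(z_half(fa))`. Beta above 1 indicates an
#' underestimation bias (a conservative "more" criterion); below 1, an
#' overestimation bias. Symmetric rates (`fa = 1 - hit`) force beta = 1
#' exactly.
#'
#' The density is evaluated *at the half-scaled z-scores*; this is the
#' convention pinned down by the worked anchor beta = 1.351 at hit 0.784 /
#' false alarm 0.041, and it is guarded by [audit_anchors()]. Passing
#' `z_scale = 1` reproduces the conventional unit-SD beta instead.
#'
#' @param hit_rate,fa_rate Corrected rates in (0, 1).
#' @param z_scale Scale of the z-transform; 0.5 is the package convention.
#' @return Beta, a positive real.
#' @export
#' @examples
#' beta_criterion(0.784, 0.041)  # 1.351
#' beta_criterion(0.904, 0.096)  # exactly 1
beta_criterion <- function(hit_rate, fa_rate, z_scale = 0.5) {
  if (any(hit_rate <= 0) || any(hit_rate >= 1) ||
      any(fa_rate <= 0) || any(fa_rate >= 1)) {
    stop("beta_criterion: rates must lie strictly in (0, 1)", call. = FALSE)
  }
  zh <- z_scale * qnorm(hit_rate)
  zf <- z_scale * qnorm(fa_rate)
  dnorm(zh) / dnorm(zf)
}

#' Convert between unbiased percent correct and d-prime
#'
#' For an unbiased responder (`fa = 1 - hit`) under the half-SD
#' convention, d-prime collapses to the unit-normal quantile of percent
#' correct: `d' = qnorm(pc)`. The two functions are exact inverses.
#'
#' @param pc Proportion correct in (0, 1).
#' @param d d-prime.
#' @return `pc_unbiased_to_dprime()` returns d-prime;
#'   `dprime_to_pc_unbiased()` returns proportion correct.
#' @export
#' @examples
#' pc_unbiased_to_dprime(0.75)   # 0.674
#' dprime_to_pc_unbiased(0.674)  # 0.75
pc_unbiased_to_dprime <- function(pc) {
  if (any(pc <= 0) || any(pc >= 1)) {
    stop("pc_unbiased_to_dprime: pc must lie strictly in (0, 1)",
         call. = FALSE)
  }
  qnorm(pc)
}

#' @rdname pc_unbiased_to_dprime
#' @export
dprime_to_pc_unbiased <- function(d) {
  pnorm(d)
}

#' Per-participant SDT summaries
#'
#' Tallies hits ("more" responses to sentences longer than the reference)
#' and false alarms ("more" responses to shorter sentences) separately for
#' each participant and orientation, applies the extreme-rate correction,
#' and computes d-prime and beta. Participants missing a signal or noise
#' cell in either orientation are dropped with a warning naming them.
#'
#' @param trials A trial table; only analysis-phase rows are used.
#' @param reference_length Word count splitting signal from noise trials.
#' @return A tibble with one row per participant x orientation: counts,
#'   corrected rates, `z_hits`, `z_fa`, `d_prime`, `beta`.
#' @export
#' @examples
#' trials <- simulate_cohort(design_config(n_per_group = 2),
#'                           observer_params(), seed = 1)
#' sdt_by_participant(trials)
sdt_by_participant <- function(trials, reference_length = 17) {
  ana <- analysis_trials(trials)
  out <- ana |>
    dplyr::filter(.data$length_words != reference_length) |>
    dplyr::group_by(.data$participant_id, .data$flip_type,
                    .data$sample_id, .data$orientation) |>
    dplyr::summarise(
      n_signal = sum(.data$length_words > reference_length),
      n_noise = sum(.data$length_words < reference_length),
      hits = sum(.data$length_words > reference_length &
                   .data$response == "more"),
      false_alarms = sum(.data$length_words < reference_length &
                           .data$response == "more"),
      .groups = "drop"
    )

  incomplete <- out |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      bad = dplyr::n() < 2 || any(.data$n_signal == 0 | .data$n_noise == 0),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$bad)
  if (nrow(incomplete) > 0) {
    warning("sdt_by_participant: dropping participants with missing cells: ",
            paste(incomplete$participant_id, collapse = ", "),
            call. = FALSE)
    out <- dplyr::filter(out,
                         !.data$participant_id %in% incomplete$participant_id)
  }

  rates <- corrected_rates(out$hits, out$n_signal,
                           out$false_alarms, out$n_noise)
  out |>
    dplyr::mutate(
      misses = .data$n_signal - .data$hits,
      correct_rejections = .data$n_noise - .data$false_alarms,
      hit_rate = rates$hit_rate,
      fa_rate = rates$fa_rate,
      z_hits = z_half(.data$hit_rate),
      z_fa = z_half(.data$fa_rate),
      d_prime = .data$z_hits - .data$z_fa,
      beta = beta_criterion(.data$hit_rate, .data$fa_rate)
    ) |>
    dplyr::relocate("misses", .after = "hits")
}
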