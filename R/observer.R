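#' Generative model of one participant
#'
#' An observer judges "more or fewer than 17 words" through one of two
#' strategies. A *word-counting* observer compares a noisy percept of the
#' true word count -- Normal with mean equal to the count and SD
#' proportional to it (`word_noise_cv`, scalar variability as in approximate
#' number system accounts) -- against `word_criterion` words. A
#' *line-counting* observer compares a noisy percept of the page's occupied
#' line extent -- Normal with SD `line_noise_sd` -- against `line_criterion`
#' lines, exploiting the heuristic that a 17-word sentence spans about 1.5
#' text lines. Either criterion can be shifted per (flip type, orientation)
#' cell: a positive shift produces more "fewer" responses, i.e. an
#' underestimation bias. With probability `lapse_rate` the observer instead
#' guesses uniformly at random regardless of the stimulus. Reaction times
#' are log-normal with the configured median, independent of stimulus and
#' condition.
#'
#' The defaults describe a line-counting observer whose fitted
#' just-noticeable difference is about 1.6 words (Weber fraction ~9%), with
#' a +0.3-line criterion shift confined to the (mirror, flipped) cell sized
#' so the expected underestimation-lapse rate on 23/24-word trials is about
#' 10%.
#'
#' @param strategy `"line_count"` or `"word_count"`.
#' @param word_noise_cv Weber coefficient of the word-count percept
#'   (SD = cv x true count).
#' @param line_noise_sd SD of the occupied-line percept, in lines.
#' @param word_criterion Decision criterion in words.
#' @param line_criterion Decision criterion in lines.
#' @param criterion_shift Named numeric of per-cell criterion shifts, names
#'   `"<flip_type>.<orientation>"`; entries not supplied default to 0.
#'   Units follow the strategy (lines or words).
#' @param lapse_rate Probability of a uniform random response, in `[0, 1)`.
#' @param rt_median_seconds Median reaction time, seconds.
#' @param rt_log_sd SD of log reaction time.
#' @return An object of class `observer_params` (a named list).
#' @export
#' @examples
#' obs <- observer_params()
#' obs$strategy
observer_params <- function(strategy = c("line_count", "word_count"),
                            word_noise_cv = 0.14,
                            line_noise_sd = 0.21,
                            word_criterion = 17,
                            line_criterion = 1.5,
                            criterion_shift = c(mirror.flipped = 0.3),
                            lapse_rate = 0.01,
                            rt_median_seconds = 0.35,
                            rt_log_sd = 0.35) {
  strategy <- match.arg(strategy)
  stopifnot(
    is.numeric(word_noise_cv), word_noise_cv > 0,
    is.numeric(line_noise_sd), line_noise_sd > 0,
    is.numeric(word_criterion), is.numeric(line_criterion),
    is.numeric(lapse_rate), lapse_rate >= 0, lapse_rate < 1,
    is.numeric(rt_median_seconds), rt_median_seconds > 0,
    is.numeric(rt_log_sd), rt_log_sd > 0
  )
  cells <- c("mirror.standard", "mirror.flipped",
             "upside_down.standard", "upside_down.flipped")
  shift <- setNames(numeric(4), cells)
  if (length(criterion_shift) > 0) {
    if (is.null(names(criterion_shift)) ||
        !all(names(criterion_shift) %in% cells)) {
      stop("observer_params: `criterion_shift` names must be among: ",
           paste(cells, collapse = ", "), call. = FALSE)
    }
    shift[names(criterion_shift)] <- criterion_shift
  }
  structure(
    list(
      strategy = strategy,
      word_noise_cv = word_noise_cv,
      line_noise_sd = line_noise_sd,
      word_criterion = word_criterion,
      line_criterion = line_criterion,
      criterion_shift = shift,
      lapse_rate = lapse_rate,
      rt_median_seconds = rt_median_seconds,
      rt_log_sd = rt_log_sd
    ),
    class = "observer_params"
  )
}

# Vectorised decision core. `noise_scale` multiplies the observer's noise
# parameter per trial (participant heterogeneity). Assumes the RNG state is
# already set by the caller.
simulate_decision <- function(trials, params, noise_scale = 1) {
  n <- nrow(trials)
  shift <- params$criterion_shift[paste(trials$flip_type,
                                        trials$orientation, sep = ".")]
  if (params$strategy == "word_count") {
    signal <- rnorm(n, trials$length_words,
                    params$word_noise_cv * noise_scale * trials$length_words)
    criterion <- params$word_criterion + shift
  } else {
    signal <- rnorm(n, trials$occupied_lines,
                    params$line_noise_sd * noise_scale)
    criterion <- params$line_criterion + shift
  }
  response <- ifelse(signal > criterion, "more", "fewer")
  lapse <- runif(n) < params$lapse_rate
  if (any(lapse)) {
    response[lapse] <- sample(c("more", "fewer"), sum(lapse), replace = TRUE)
  }
  response
}

#' Fill responses into trial stubs
#'
#' Applies the observer's decision rule to every practice- and
#' analysis-phase row of a schedule (demonstration trials are passive and
#' stay `NA`), recomputes correctness from the true word count, and draws
#' log-normal reaction times.
#'
#' @param trials Trial stubs, e.g. from [generate_schedule()].
#' @param params An [observer_params()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @param reference_length Word count defining the correct response.
#' @return The trial table with `response`, `correct`, `rt_seconds` filled.
#' @export
#' @examples
#' sched <- generate_schedule("p01", design_config(), rng_seed = 1)
#' done <- simulate_responses(sched, observer_params(), seed = 2)
#' mean(done$correct[done$phase == "analysis"])
simulate_responses <- function(trials, params, seed = 1L,
                               reference_length = 17) {
  stopifnot(inherits(params, "observer_params"))
  validate_trials(trials, allow_empty = TRUE)
  active <- trials$phase %in% c("practice", "analysis")
  withr::with_seed(seed, {
    response <- simulate_decision(trials[active, ], params)
    rt <- rlnorm(sum(active), log(params$rt_median_seconds), params$rt_log_sd)
  })
  trials$response[active] <- response
  trials$rt_seconds[active] <- rt
  trials$correct[active] <-
    (trials$response[active] == "more") ==
    (trials$length_words[active] > reference_length)
  trials
}

#' Simulate a full 2 x 2 cohort
#'
#' Builds seeded schedules and responses for all four groups (mirror and
#' upside-down flip types, each with replication samples 1 and 2),
#' `n_per_group` participants each. Optional per-participant heterogeneity
#' multiplies the observer's noise parameter by a seeded uniform factor in
#' `1 +/- participant_jitter`.
#'
#' @param config A [design_config()].
#' @param params_by_group Either a single [observer_params()] applied to all
#'   groups, or a named list with entries `"mirror"` and `"upside_down"`.
#' @param seed Integer seed; the whole table is deterministic given the seed.
#' @param participant_jitter Half-width of the multiplicative noise jitter
#'   across participants (0 disables heterogeneity).
#' @return The canonical trial table for all participants and phases.
#' @export
#' @examples
#' cfg <- design_config(n_per_group = 2)
#' trials <- simulate_cohort(cfg, observer_params(), seed = 1)
#' nrow(dplyr::filter(trials, phase == "analysis"))
simulate_cohort <- function(config = design_config(),
                            params_by_group = observer_params(),
                            seed = 1L,
                            participant_jitter = 0.2) {
  stopifnot(inherits(config, "design_config"))
  if (inherits(params_by_group, "observer_params")) {
    params_by_group <- list(mirror = params_by_group,
                            upside_down = params_by_group)
  }
  missing_groups <- setdiff(c("mirror", "upside_down"), names(params_by_group))
  if (length(missing_groups) > 0) {
    stop("simulate_cohort: missing observer parameters for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }

  participants <- tidyr::expand_grid(
    flip_type = c("mirror", "upside_down"),
    sample_id = c(1L, 2L),
    idx = seq_len(config$n_per_group)
  ) |>
    dplyr::mutate(
      participant_id = sprintf(
        "%s%d_p%02d",
        ifelse(.data$flip_type == "mirror", "M", "U"),
        .data$sample_id, .data$idx
      )
    )

  stim <- generate_stimulus_set(config)
  withr::with_seed(seed, {
    sched_seeds <- sample.int(.Machine$integer.max - 1L,
                              nrow(participants))
    resp_seed <- sample.int(.Machine$integer.max - 1L, 1)
    jitter <- runif(nrow(participants),
                    1 - participant_jitter, 1 + participant_jitter)
  })

  trials <- purrr::pmap(
    list(participants$participant_id, participants$flip_type,
         participants$sample_id, sched_seeds),
    function(pid, ft, sid, s1) {
      generate_schedule(pid, config, rng_seed = s1,
                        flip_type = ft, sample_id = sid,
                        stimulus_set = stim)
    }
  ) |>
    dplyr::bind_rows()

  # one vectorised response pass over all participants; noise scaled by
  # each participant's heterogeneity factor
  p_index <- match(trials$participant_id, participants$participant_id)
  active <- trials$phase %in% c("practice", "analysis")
  for (ft in c("mirror", "upside_down")) {
    rows <- active & trials$flip_type == ft
    params <- params_by_group[[ft]]
    withr::with_seed(resp_seed + (ft == "mirror"), {
      response <- simulate_decision(trials[rows, ], params,
                                    noise_scale = jitter[p_index[rows]])
      rt <- rlnorm(sum(rows), log(params$rt_median_seconds),
                   params$rt_log_sd)
    })
    trials$response[rows] <- response
    trials$rt_seconds[rows] <- rt
  }
  trials$correct[active] <-
    (trials$response[active] == "more") ==
    (trials$length_words[active] > config$reference_length)
  trials
}

#' Closed-form response curve implied by an observer
#'
#' Returns the exact probability of a "more" response at each sentence
#' length under the observer's decision rule and lapse mixture:
#' `lambda/2 + (1 - lambda) * Phi((signal - criterion - shift) / sd)`.
#' For line-counting observers the probability is averaged over the
#' exemplars' occupied-line extents at each length (including the
#' mischievous page when a stimulus set is supplied), matching what a
#' simulated cohort actually experiences.
#'
#' @param params An [observer_params()].
#' @param flip_type,orientation The condition whose criterion shift applies.
#' @param lengths Word counts at which to evaluate the curve.
#' @param config A [design_config()] supplying the layout model.
#' @param stimulus_set Optional tibble from [generate_stimulus_set()]; when
#'   omitted, occupied extents are taken as `length / words_per_line`
#'   without jitter.
#' @return A tibble with columns `length_words` and `p_more`.
#' @export
#' @examples
#' predicted_response_curve(observer_params(), "mirror", "standard",
#'                          lengths = c(10, 17, 24))
predicted_response_curve <- function(params,
                                     flip_type = "mirror",
                                     orientation = "standard",
                                     lengths = c(10:16, 18:24),
                                     config = design_config(),
                                     stimulus_set = NULL) {
  stopifnot(inherits(params, "observer_params"), length(lengths) > 0)
  flip_type <- match.arg(flip_type, c("mirror", "upside_down"))
  orientation <- match.arg(orientation, c("standard", "flipped"))
  shift <- params$criterion_shift[paste(flip_type, orientation, sep = ".")]
  lam <- params$lapse_rate

  p_more <- vapply(lengths, function(L) {
    if (params$strategy == "word_count") {
      p <- pnorm((L - params$word_criterion - shift) /
                   (params$word_noise_cv * L))
    } else {
      if (is.null(stimulus_set)) {
        occ <- L / config$words_per_line
      } else {
        occ <- stimulus_set$occupied_lines[stimulus_set$length_words == L]
        if (length(occ) == 0) occ <- L / config$words_per_line
      }
      p <- mean(pnorm((occ - params$line_criterion - shift) /
                        params$line_noise_sd))
    }
    lam / 2 + (1 - lam) * p
  }, numeric(1))

  tibble::tibble(length_words = as.numeric(lengths), p_more = p_more)
}
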