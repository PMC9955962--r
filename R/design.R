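#' Experimental design configuration
#'
#' Bundles the constants of the sentence-length judgement design: a 2 x 2
#' mixed factorial (flip type between groups, text orientation within
#' participant) in which each participant judges whether a bolded target
#' sentence contains more or fewer than `reference_length` words.
#'
#' The default design has 22 participants per group, 14 analysis lengths
#' (10--24 words excluding the 17-word reference), 5 exemplar pages per
#' length, and both orientations of every exemplar, i.e. 5 x 14 x 2 = 140
#' analysis trials per participant.
#'
#' @param n_per_group Participants per group (4 groups: mirror/upside-down
#'   crossed with replication samples 1 and 2).
#' @param lengths Integer word counts used on analysis trials. Must exclude
#'   `reference_length`.
#' @param exemplars_per_length Unique text pages per sentence length.
#' @param reference_length The comparison length (words) participants judge
#'   against.
#' @param words_per_line Average words per text line in the page layout; the
#'   default encodes "a 17-word sentence spans ~1.5 lines".
#' @param line_criterion Occupied-line extent corresponding to the reference
#'   length (lines).
#' @param jitter_range Half-width (lines) of the uniform start-offset jitter
#'   applied to each exemplar's occupied extent.
#' @param mischievous_occupied Occupied-line extent assigned to the
#'   mischievous stimulus: a 16-word sentence laid out to touch three text
#'   lines.
#' @param n_demo Passive demonstration trials (reference-length stimuli).
#' @param n_practice Practice trials (10- or 24-word stimuli).
#' @param seed Integer seed fixing the stimulus-layout jitter.
#'
#' @return An object of class `design_config` (a named list).
#' @export
#' @examples
#' cfg <- design_config()
#' cfg$n_per_group
design_config <- function(n_per_group = 22,
                          lengths = c(10:16, 18:24),
                          exemplars_per_length = 5,
                          reference_length = 17,
                          words_per_line = 17 / 1.5,
                          line_criterion = 1.5,
                          jitter_range = 0.15,
                          mischievous_occupied = 2.5,
                          n_demo = 10,
                          n_practice = 20,
                          seed = 1L) {
  stopifnot(
    is.numeric(n_per_group), length(n_per_group) == 1,
    is.numeric(lengths), length(lengths) >= 4,
    is.numeric(exemplars_per_length), length(exemplars_per_length) == 1,
    is.numeric(reference_length), length(reference_length) == 1,
    is.numeric(words_per_line), is.numeric(line_criterion),
    is.numeric(jitter_range), is.numeric(mischievous_occupied),
    is.numeric(seed)
  )
  if (n_per_group < 1 || exemplars_per_length < 1 ||
      words_per_line <= 0 || line_criterion <= 0 ||
      mischievous_occupied <= 0 || jitter_range < 0 ||
      n_demo < 0 || n_practice < 0) {
    stop("design_config: counts and layout parameters must be positive",
         call. = FALSE)
  }
  lengths <- sort(unique(as.integer(lengths)))
  if (reference_length %in% lengths) {
    stop("design_config: `reference_length` must be excluded from analysis `lengths`",
         call. = FALSE)
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      lengths = lengths,
      exemplars_per_length = as.integer(exemplars_per_length),
      reference_length = as.integer(reference_length),
      words_per_line = words_per_line,
      line_criterion = line_criterion,
      jitter_range = jitter_range,
      mischievous_occupied = mischievous_occupied,
      n_demo = as.integer(n_demo),
      n_practice = as.integer(n_practice),
      seed = as.integer(seed)
    ),
    class = "design_config"
  )
}

#' Generate the stimulus set of unique text pages
#'
#' Builds one row per unique text page: `exemplars_per_length` exemplars at
#' every length from the analysis lengths plus the reference length (the
#' reference-length exemplars appear on demonstration trials only). Each
#' stimulus carries its nominal line span (text lines touched) and an
#' occupied-line extent equal to `length_words / words_per_line` plus a
#' seeded per-exemplar start-offset jitter. Exactly one 16-word exemplar is
#' flagged mischievous: it nominally spans three lines and gets the
#' configured `mischievous_occupied` extent, so observers judging length by
#' counting lines misread it as long.
#'
#' @param config A [design_config()].
#' @return A tibble with columns `length_words`, `exemplar_id`,
#'   `nominal_line_span`, `occupied_lines`, `mischievous`.
#' @export
#' @examples
#' stim <- generate_stimulus_set(design_config())
#' nrow(stim)           # 75 unique pages
#' sum(stim$mischievous)  # exactly one
generate_stimulus_set <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  all_lengths <- sort(unique(c(config$lengths, config$reference_length)))
  stim <- tidyr::expand_grid(
    length_words = all_lengths,
    exemplar_id = seq_len(config$exemplars_per_length)
  )
  withr::with_seed(config$seed, {
    jitter <- runif(nrow(stim), -config$jitter_range, config$jitter_range)
  })
  stim <- stim |>
    dplyr::mutate(
      mischievous = .data$length_words == 16L &
        .data$exemplar_id == config$exemplars_per_length,
      nominal_line_span = dplyr::if_else(
        .data$mischievous, 3L,
        as.integer(ceiling(.data$length_words / config$words_per_line))
      ),
      occupied_lines = dplyr::if_else(
        .data$mischievous,
        config$mischievous_occupied,
        .data$length_words / config$words_per_line + jitter
      )
    ) |>
    dplyr::select("length_words", "exemplar_id", "nominal_line_span",
                  "occupied_lines", "mischievous")
  stim
}

#' Generate one participant's trial schedule
#'
#' Produces response-less trial stubs for the three phases: `n_demo` passive
#' demonstration trials (reference-length stimuli; first half standard, then
#' flipped), a practice block of 10- and 24-word stimuli, and the analysis
#' phase in which every (length, exemplar, orientation) triple appears
#' exactly once in a seeded random interleaving.
#'
#' @param participant_id Identifier stored on every row.
#' @param config A [design_config()].
#' @param rng_seed Integer seed for the trial-order randomisation.
#' @param flip_type `"mirror"` or `"upside_down"` (the participant's group).
#' @param sample_id Replication sample, `1` or `2`.
#' @param stimulus_set Optional precomputed [generate_stimulus_set()] result
#'   for `config`; supplying it avoids regenerating the set when scheduling
#'   many participants.
#' @return A tibble of trial stubs in canonical column order with `response`,
#'   `correct` and `rt_seconds` set to `NA`.
#' @export
#' @examples
#' sched <- generate_schedule("p01", design_config(), rng_seed = 7)
#' table(sched$phase)
generate_schedule <- function(participant_id, config = design_config(),
                              rng_seed = 1L, flip_type = "mirror",
                              sample_id = 1L, stimulus_set = NULL) {
  stopifnot(inherits(config, "design_config"))
  flip_type <- match.arg(flip_type, c("mirror", "upside_down"))
  stim <- if (is.null(stimulus_set)) generate_stimulus_set(config)
          else stimulus_set
  skey <- stim$length_words * 1000L + stim$exemplar_id

  # demo: reference-length exemplars, first half standard then flipped
  demo_idx <- rep(which(stim$length_words == config$reference_length),
                  length.out = config$n_demo)
  demo_or <- rep(c("standard", "flipped"),
                 each = ceiling(config$n_demo / 2))[seq_len(config$n_demo)]

  # practice: the two extreme lengths, both orientations, cycling exemplars
  ext <- range(config$lengths)
  cell_len <- c(ext, ext)
  cell_or <- rep(c("standard", "flipped"), each = 2)
  pr_cell <- rep(seq_len(4), length.out = config$n_practice)
  pr_ex <- rep_len(seq_len(config$exemplars_per_length), config$n_practice)
  pr_idx <- match(cell_len[pr_cell] * 1000L + pr_ex, skey)
  pr_or <- cell_or[pr_cell]

  # analysis: every (length, exemplar, orientation) exactly once
  an_grid <- expand.grid(
    exemplar_id = seq_len(config$exemplars_per_length),
    length_words = config$lengths,
    orientation = c("standard", "flipped"),
    stringsAsFactors = FALSE
  )
  an_idx <- match(an_grid$length_words * 1000L + an_grid$exemplar_id, skey)
  an_or <- an_grid$orientation

  withr::with_seed(rng_seed, {
    pr_ord <- sample.int(length(pr_idx))
    an_ord <- sample.int(length(an_idx))
  })

  idx <- c(demo_idx, pr_idx[pr_ord], an_idx[an_ord])
  n <- length(idx)
  tibble::tibble(
    participant_id = rep(as.character(participant_id), n),
    flip_type = rep(flip_type, n),
    sample_id = rep(as.integer(sample_id), n),
    phase = rep(c("demo", "practice", "analysis"),
                c(config$n_demo, length(pr_idx), length(an_idx))),
    trial_index = seq_len(n),
    orientation = c(demo_or, pr_or[pr_ord], an_or[an_ord]),
    length_words = stim$length_words[idx],
    exemplar_id = stim$exemplar_id[idx],
    nominal_line_span = stim$nominal_line_span[idx],
    occupied_lines = stim$occupied_lines[idx],
    mischievous = stim$mischievous[idx],
    response = NA_character_,
    correct = NA,
    rt_seconds = NA_real_
  )
}

# Canonical column order of the trial table.
trial_table_columns <- function() {
  c("participant_id", "flip_type", "sample_id", "phase", "trial_index",
    "orientation", "length_words", "exemplar_id", "nominal_line_span",
    "occupied_lines", "mischievous", "response", "correct", "rt_seconds")
}
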