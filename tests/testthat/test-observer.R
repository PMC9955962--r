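test_that("decision rule hits its noiseless and guessing limits", {
  # vanishing word noise: a 24-word sentence is always judged "more"
  obs <- observer_params(strategy = "word_count", word_noise_cv = 1e-9,
                         lapse_rate = 0)
  trials <- manual_trials(function(L) rep("more", length(L)), n_each = 20,
                          lengths = c(10, 24))
  long <- dplyr::filter(trials, length_words == 24)
  out <- simulate_responses(long, obs, seed = 1)
  expect_true(all(out$response == "more"))
  short <- dplyr::filter(trials, length_words == 10)
  out <- simulate_responses(short, obs, seed = 1)
  expect_true(all(out$response == "fewer"))

  # near-total lapsing: accuracy collapses to chance on any stimulus
  lapser <- observer_params(strategy = "word_count", lapse_rate = 0.999)
  out <- simulate_responses(
    manual_trials(function(L) rep("more", length(L)), n_each = 400,
                  lengths = c(24)),
    lapser, seed = 2
  )
  expect_gt(mean(out$correct), 0.42)
  expect_lt(mean(out$correct), 0.58)
})

test_that("line-counting observers are fooled by the mischievous page", {
  # closed form: P(more) = Phi((2.5 - 1.5) / 0.3) = 0.9996 on a page that
  # holds only 16 words
  obs <- observer_params(strategy = "line_count", line_noise_sd = 0.3,
                         lapse_rate = 0, criterion_shift = c())
  misch <- manual_trials(function(L) rep("more", length(L)), n_each = 1,
                         lengths = 16)[rep(1, 20000), ]
  misch$occupied_lines <- 2.5
  out <- simulate_responses(misch, obs, seed = 3)
  expect_equal(mean(out$response == "more"), pnorm((2.5 - 1.5) / 0.3),
               tolerance = 0.005)
  expect_equal(mean(out$correct), 1 - pnorm((2.5 - 1.5) / 0.3),
               tolerance = 0.005)
})

test_that("predicted response curve matches its closed form and asymptotes", {
  obs <- observer_params(strategy = "word_count", word_noise_cv = 0.09,
                         word_criterion = 17, lapse_rate = 0,
                         criterion_shift = c())
  curve <- predicted_response_curve(obs, lengths = c(17, 20))
  expect_equal(curve$p_more[1], 0.5)
  expect_equal(curve$p_more[2], pnorm(3 / 1.8), tolerance = 1e-10)
  expect_equal(curve$p_more[2], 0.952, tolerance = 1e-3)

  # lapse mixture asymptote: lambda / 2 + (1 - lambda)
  lapsy <- observer_params(strategy = "word_count", word_noise_cv = 0.01,
                           lapse_rate = 0.2, criterion_shift = c())
  far <- predicted_response_curve(lapsy, lengths = 24)
  expect_equal(far$p_more, 0.9, tolerance = 1e-6)

  # monotone nondecreasing in length for zero lapse, positive noise
  for (strat in c("word_count", "line_count")) {
    crv <- predicted_response_curve(
      observer_params(strategy = strat, lapse_rate = 0),
      lengths = 10:24
    )
    expect_true(all(diff(crv$p_more) >= 0))
  }
})

test_that("simulated frequencies converge to the analytic curve", {
  cfg <- design_config()
  stim <- generate_stimulus_set(cfg)
  obs <- observer_params(criterion_shift = c())
  n_cell <- 10000
  lengths <- c(12, 15, 16, 19, 23)
  trials <- manual_trials(function(L) rep("more", length(L)), n_each = 1,
                          lengths = lengths)
  trials <- trials[rep(seq_len(nrow(trials)), each = n_cell / 10), ]
  # use the design's occupied extents, averaging over exemplars
  trials$exemplar_id <- rep_len(1:5, nrow(trials))
  trials$occupied_lines <- stim$occupied_lines[
    match(trials$length_words * 1000 + trials$exemplar_id,
          stim$length_words * 1000 + stim$exemplar_id)]
  out <- simulate_responses(trials, obs, seed = 11)
  emp <- dplyr::summarise(
    dplyr::group_by(out, length_words),
    p = mean(response == "more"), n = dplyr::n(), .groups = "drop"
  )
  pred <- predicted_response_curve(obs, lengths = sort(lengths),
                                   config = cfg, stimulus_set = stim)
  se <- sqrt(pred$p_more * (1 - pred$p_more) / emp$n)
  expect_true(all(abs(emp$p - pred$p_more) <= 3 * pmax(se, 1e-4)))
})

test_that("cohort simulation is deterministic and matches the design counts", {
  trials <- small_cohort()
  cfg <- design_config(n_per_group = 2)
  expect_equal(dplyr::n_distinct(trials$participant_id), 8)
  expect_equal(sum(trials$phase == "analysis"), 8 * 140)
  expect_identical(trials,
                   simulate_cohort(cfg, observer_params(), seed = 101))
  expect_error(simulate_cohort(cfg, list(mirror = observer_params())),
               "upside_down")
})

test_that("a mirror-flipped criterion shift raises long-sentence miss rates", {
  shift <- 0.25
  obs <- observer_params(criterion_shift = c(mirror.flipped = shift))
  trials <- simulate_cohort(design_config(n_per_group = 11), obs, seed = 5,
                            participant_jitter = 0)
  long_flipped <- dplyr::filter(trials, phase == "analysis",
                                orientation == "flipped",
                                length_words %in% c(23, 24))
  miss <- dplyr::summarise(
    dplyr::group_by(long_flipped, flip_type),
    rate = mean(response == "fewer"), .groups = "drop"
  )
  miss_mirror <- miss$rate[miss$flip_type == "mirror"]
  miss_upside <- miss$rate[miss$flip_type == "upside_down"]
  expect_gt(miss_mirror, miss_upside)

  # brute-force oracle of the decision rule at 10^6 draws per condition
  oracle_miss <- function(sh) {
    withr::with_seed(99, {
      occ <- rep(dplyr::distinct(long_flipped, length_words,
                                 exemplar_id, occupied_lines)$occupied_lines,
                 length.out = 1e6)
      percept <- rnorm(1e6, occ, obs$line_noise_sd)
      lapse <- runif(1e6) < obs$lapse_rate
      fewer <- percept <= obs$line_criterion + sh
      fewer[lapse] <- runif(sum(lapse)) < 0.5
      mean(fewer)
    })
  }
  expect_lt(abs(miss_mirror - oracle_miss(shift)), 0.03)
  expect_lt(abs(miss_upside - oracle_miss(0)), 0.02)
})
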