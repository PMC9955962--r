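design_x <- c(10:16, 18:24) - 17

test_that("sigmoid evaluates its defining identities", {
  expect_equal(sigmoid(0, 0.7, 0), 0.5)
  expect_equal(sigmoid(2, 1, 0), 0.8807971, tolerance = 1e-7)
  expect_equal(sigmoid(log(3) / 0.7, 0.7, 0), 0.75)
  expect_equal(sigmoid(5, 0.7, 5), 0.5)
})

test_that("noiseless sigmoid data are recovered to high precision", {
  pts <- tibble::tibble(x_rel = design_x,
                        prop_more = sigmoid(design_x, 0.7, 0.2))
  fit <- fit_psychometric(pts)
  expect_true(fit$ok)
  expect_equal(fit$K, 0.7, tolerance = 1e-4)
  expect_equal(fit$Xo, 0.2, tolerance = 1e-4)
  expect_equal(fit$var_explained, 1, tolerance = 1e-8)
  # the fitted curve passes through its own PSE and JND points exactly
  expect_equal(sigmoid(fit$pse, fit$K, fit$Xo), 0.5)
  expect_equal(sigmoid(fit$pse + fit$jnd, fit$K, fit$Xo), 0.75)
})

test_that("flat data are flagged as a fit failure, not returned silently", {
  pts <- tibble::tibble(x_rel = design_x, prop_more = 0.5)
  fit <- fit_psychometric(pts)
  expect_false(fit$ok)
  expect_true(is.na(fit$jnd))
})

test_that("fit_psychometric rejects malformed input", {
  expect_error(fit_psychometric(tibble::tibble(x_rel = 1:3,
                                               prop_more = c(0, .5, 1))),
               "4 distinct")
  expect_error(fit_psychometric(tibble::tibble(x_rel = design_x,
                                               prop_more = 1.5)),
               "\\[0, 1\\]")
})

test_that("least squares matches an exhaustive grid search on noisy data", {
  withr::with_seed(42, {
    true_p <- sigmoid(design_x, 0.65, 0.3)
    obs_p <- rbinom(length(design_x), 110, true_p) / 110
  })
  fit <- fit_psychometric(tibble::tibble(x_rel = design_x,
                                         prop_more = obs_p))
  grid <- grid_search_sse(design_x, obs_p)
  expect_lte(fit$sse, grid$sse + 1e-6)
  expect_equal(fit$K, grid$K, tolerance = 0.01)
})

test_that("JND and Weber arithmetic follow their definitions", {
  expect_equal(jnd_from_slope(log(3)), 1)
  expect_equal(jnd_from_slope(0.718), 1.530, tolerance = 1e-3)
  ks <- seq(0.2, 5, by = 0.2)
  expect_true(all(diff(jnd_from_slope(ks)) < 0))
  expect_error(jnd_from_slope(0), "positive")

  expect_equal(weber_fraction(1.60, 17), 0.0941, tolerance = 1e-3)
  expect_equal(weber_fraction(1.81, 17), 0.1065, tolerance = 1e-3)
  expect_equal(weber_fraction(17, 17), 1)
  expect_error(weber_fraction(-1, 17), "positive")
})

test_that("group proportions aggregate responses per cell and length", {
  all_more <- manual_trials(function(L) rep("more", length(L)))
  props <- group_proportions(all_more)
  expect_true(all(props$prop_more == 1))
  expect_true(all(props$n_trials == 5))
  expect_equal(sort(unique(props$x_rel)), design_x)

  # an unfilled design length is reported as missing, not zero
  dropped <- dplyr::filter(all_more, length_words != 12 |
                             orientation != "flipped")
  props2 <- group_proportions(dropped)
  gap <- dplyr::filter(props2, length_words == 12, orientation == "flipped")
  expect_true(is.na(gap$prop_more))

  # cohort frequencies sit on the analytic curve within binomial error
  cfg <- design_config(n_per_group = 11)
  obs <- observer_params(criterion_shift = c())
  trials <- simulate_cohort(cfg, obs, seed = 8, participant_jitter = 0)
  props3 <- group_proportions(trials, by = character(0))
  pred <- predicted_response_curve(obs, lengths = cfg$lengths, config = cfg,
                                   stimulus_set = generate_stimulus_set(cfg))
  joined <- dplyr::inner_join(props3, pred, by = "length_words")
  se <- sqrt(pmax(joined$p_more * (1 - joined$p_more), 1e-4) /
               joined$n_trials)
  expect_true(all(abs(joined$prop_more - joined$p_more) <= 4 * se))
})

test_that("tidy and glance expose the fitted parameters", {
  pts <- tibble::tibble(x_rel = design_x,
                        prop_more = sigmoid(design_x, 0.7, 0))
  fit <- fit_psychometric(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("K", "Xo"))
  gl <- glance(fit)
  expect_equal(gl$jnd, log(3) / gl$K)
  expect_equal(gl$weber_fraction, gl$jnd / 17)

  fits <- fit_cohort_psychometrics(small_cohort())
  expect_equal(nrow(fits), 8)
  expect_true(all(c("flip_type", "sample_id", "orientation", "K", "jnd",
                    "weber_fraction", "pse", "var_explained", "ok")
                  %in% names(fits)))
})
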