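test_that("exact binomial tails match enumeration and the complement identity", {
  expect_equal(binomial_tail(0, 20), 1)
  expect_equal(binomial_tail(18, 20), 211 / 1048576)
  expect_equal(binomial_tail(10, 20), 1 - pbinom(9, 20, 0.5))
  expect_error(binomial_tail(-1, 20), "require")
  expect_error(binomial_tail(21, 20), "require")

  # Pascal-triangle oracle for all n up to 60
  for (n in c(20, 35, 47, 60)) {
    row <- 1
    for (i in seq_len(n)) row <- c(0, row) + c(row, 0)  # choose(n, 0:n)
    tails <- rev(cumsum(rev(row))) / 2^n
    expect_equal(binomial_tail(0:n, rep(n, n + 1)), tails,
                 tolerance = 1e-12)
  }
})

test_that("practice stopping rule finds the 18-of-20 threshold", {
  expect_equal(practice_threshold(20), 18L)
  expect_true(practice_criterion_met(20, 20))
  expect_true(practice_criterion_met(18, 20))
  expect_false(practice_criterion_met(17, 20))
  expect_error(practice_threshold(19), "\\[20, 60\\]")
  expect_error(practice_criterion_met(10, 61), "\\[20, 60\\]")
  # required accuracy relaxes with more evidence: the ratio trends down,
  # with local upticks bounded by the one-trial integer granularity
  ns <- 20:60
  ratio <- practice_threshold(ns) / ns
  expect_lt(ratio[length(ratio)], ratio[1])
  expect_true(all(diff(ratio) <= 1 / ns[-1]))
  expect_true(all(diff(practice_threshold(ns)) >= 0))
})

test_that("inclusion criterion separates the percentage and exact rules", {
  expect_true(inclusion_criterion(88, 140))
  expect_false(inclusion_criterion(70, 140))
  expect_false(inclusion_criterion(70, 140, "exact_binomial"))
  # the exact rule is one trial stricter at n = 140
  expect_false(inclusion_criterion(88, 140, "exact_binomial"))
  expect_true(inclusion_criterion(89, 140, "exact_binomial"))
  expect_error(inclusion_criterion(150, 140), "range")
})

test_that("chance band reproduces (0.32, 0.68) and its exact counterpart", {
  expect_equal(chance_band(22), c(lower = 0.32, upper = 0.68))
  wide_n <- chance_band(1e6, digits = NULL)
  expect_equal(unname(wide_n), c(0.5, 0.5), tolerance = 1e-2)

  # exact mode equals brute-force enumeration at n = 22
  exact <- chance_band(22, mode = "exact")
  probs <- sapply(0:22, function(k) choose(22, k) / 2^22)
  k_low <- max(which(cumsum(probs) < 0.05)) - 1
  k_high <- min(which(rev(cumsum(rev(probs))) < 0.05)) - 1
  expect_equal(exact, c(lower = k_low / 22, upper = k_high / 22))

  # exact thresholds bracket the normal approximation within 2/n
  for (n in c(20, 22, 40, 60)) {
    na <- chance_band(n, digits = NULL)
    ex <- chance_band(n, mode = "exact")
    expect_lt(abs(ex[["lower"]] - na[["lower"]]), 2 / n)
    expect_lt(abs(ex[["upper"]] - na[["upper"]]), 2 / n)
  }
})

test_that("lapse rates are computed on the extreme lengths only", {
  perfect <- manual_trials(function(L) ifelse(L > 17, "more", "fewer"))
  lp <- lapse_rates(perfect)
  expect_equal(lp$underestimate_lapse_rate, c(0, 0))
  expect_equal(lp$overestimate_lapse_rate, c(0, 0))
  expect_equal(lp$n_long, c(10, 10))
  expect_equal(lp$n_short, c(10, 10))

  # two misses among the ten long-extreme trials = 0.2
  two_miss <- perfect
  idx <- which(two_miss$length_words == 24 &
                 two_miss$orientation == "standard")[1:2]
  two_miss$response[idx] <- "fewer"
  two_miss$correct[idx] <- FALSE
  lp2 <- lapse_rates(two_miss)
  std <- dplyr::filter(lp2, orientation == "standard")
  expect_equal(std$underestimate_lapse_rate, 0.2)
  expect_equal(std$overestimate_lapse_rate, 0)

  # default design: every participant contributes 10 trials per extreme
  lp3 <- lapse_rates(small_cohort())
  expect_true(all(lp3$n_long == 10))
  expect_true(all(lp3$n_short == 10))
})

test_that("the mischievous probe separates line counters from word counters", {
  all_fewer <- purrr::map_dfr(1:22, function(i) {
    dplyr::mutate(manual_trials(function(L) rep("fewer", length(L))),
                  participant_id = sprintf("p%02d", i))
  })
  ma <- mischievous_analysis(all_fewer)
  expect_true(all(ma$error_rate == 0))
  expect_true(all(ma$band == "below"))

  cfg <- design_config(n_per_group = 11)
  liners <- simulate_cohort(
    cfg, observer_params(strategy = "line_count", criterion_shift = c()),
    seed = 21)
  ml <- mischievous_analysis(liners)
  expect_true(all(ml$band[ml$mischievous] == "above"))
  expect_true(all(ml$error_rate[ml$mischievous] >
                    max(ml$error_rate[!ml$mischievous])))

  worders <- simulate_cohort(
    cfg, observer_params(strategy = "word_count", word_noise_cv = 0.09,
                         criterion_shift = c()),
    seed = 22)
  mw <- mischievous_analysis(worders)
  expect_true(all(mw$band[mw$mischievous] != "above"))
})

test_that("omega-squared reproduces the worked value and its orderings", {
  expect_equal(round(omega_squared(9.37, 2, 17), 4), 0.1975)
  expect_equal(
    round(omega_squared(9.37, 2, 17, reading = "printed_precedence"), 4),
    0.2023)
  expect_equal(omega_squared(1, 2, 17), 0)
  expect_equal(omega_squared(5, 2, 20), 4 / 44)
  expect_warning(expect_equal(omega_squared(0.5, 2, 17), 0), "F < 1")
  expect_error(omega_squared(-2, 2, 17), "positive")
  # strictly increasing in F, decreasing in n
  expect_true(all(diff(sapply(c(2, 5, 9, 15),
                              function(f) omega_squared(f, 2, 17))) > 0))
  expect_true(all(diff(sapply(c(10, 17, 30),
                              function(n) omega_squared(9.37, 2, n))) < 0))
})

test_that("phi-based sample size reproduces 21.49 rounded to 22", {
  ss <- sample_size(0.1975, 2.3)
  expect_equal(ss$n_exact, 21.49, tolerance = 5e-3)
  expect_equal(ss$n_rounded, 22)
  expect_equal(sample_size(0.5, 2.3)$n_exact, 5.29)
  expect_lt(sample_size(0.999, 2.3)$n_exact, 0.01)
  expect_error(sample_size(0, 2.3), "require")
  expect_error(sample_size(0.5, -1), "require")
})
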