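# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small 2-per-group cohort with the default observer, for structural tests.
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(
    design_config(n_per_group = 2), observer_params(), seed = 101
  ))
}

# Full default cohort (88 participants) with the default line-counting
# observer and its (mirror, flipped) criterion shift.
default_cohort <- function() {
  cached("default_cohort", simulate_cohort(
    design_config(), observer_params(), seed = 2024
  ))
}

# A trial table with hand-assigned responses: one participant, analysis
# phase only, `n_each` trials at each design length per orientation.
manual_trials <- function(responder, n_each = 5, participant_id = "p1",
                          flip_type = "mirror", lengths = c(10:16, 18:24)) {
  grid <- expand.grid(
    length_words = lengths,
    rep = seq_len(n_each),
    orientation = c("standard", "flipped"),
    stringsAsFactors = FALSE
  )
  response <- responder(grid$length_words)
  tibble::tibble(
    participant_id = participant_id,
    flip_type = flip_type,
    sample_id = 1L,
    phase = "analysis",
    trial_index = seq_len(nrow(grid)),
    orientation = grid$orientation,
    length_words = as.integer(grid$length_words),
    exemplar_id = as.integer(grid$rep),
    nominal_line_span = as.integer(ceiling(grid$length_words / (17 / 1.5))),
    occupied_lines = grid$length_words / (17 / 1.5),
    mischievous = grid$length_words == 16L & grid$rep == n_each,
    response = response,
    correct = (response == "more") == (grid$length_words > 17),
    rt_seconds = 0.35
  )
}

# Exhaustive two-stage grid search for the sigmoid least squares: coarse
# pass at step `step1`, refined pass at step `step2` around the coarse
# minimum. Independent of fit_psychometric().
grid_search_sse <- function(x, p, K_lim = c(0.05, 5), Xo_lim = c(-5, 5),
                            step1 = 0.01, step2 = 0.001) {
  scan <- function(Ks, Xos) {
    best <- list(sse = Inf)
    for (K in Ks) {
      preds <- 1 / (1 + exp(-K * outer(x, Xos, "-")))
      sses <- colSums((preds - p)^2)
      i <- which.min(sses)
      if (sses[i] < best$sse) best <- list(sse = sses[i], K = K, Xo = Xos[i])
    }
    best
  }
  coarse <- scan(seq(K_lim[1], K_lim[2], by = step1),
                 seq(Xo_lim[1], Xo_lim[2], by = step1))
  scan(seq(max(K_lim[1], coarse$K - 2 * step1),
           min(K_lim[2], coarse$K + 2 * step1), by = step2),
       seq(max(Xo_lim[1], coarse$Xo - 2 * step1),
           min(Xo_lim[2], coarse$Xo + 2 * step1), by = step2))
}
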