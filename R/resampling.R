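# Shared constructor for permutation-test results.
new_perm_test <- function(mode, observed_diff, sim_diffs, n_iter, seed,
                          alternative) {
  effective <- if (alternative == "two_sided") abs(sim_diffs) else sim_diffs
  observed_eff <- if (alternative == "two_sided") abs(observed_diff)
                  else observed_diff
  p <- (sum(effective >= observed_eff) + 1) / (n_iter + 1)
  perc95 <- unname(quantile(effective, 0.95))
  structure(
    list(
      mode = mode,
      observed_diff = observed_diff,
      n_iter = n_iter,
      p_value = p,
      percentile_95 = perc95,
      significant = observed_eff >= perc95,
      alternative = alternative,
      seed = seed
    ),
    class = "perm_test"
  )
}

#' Monte Carlo permutation test of a between-group median difference
#'
#' The observed statistic is `median(a) - median(b)`. The null distribution
#' is built by pooling both samples and reshuffling them into groups of the
#' original sizes `n_iter` times (default 10,000). The one-sided p-value is
#' the plus-one-corrected proportion of simulated differences at least as
#' large as the observed one, and the effect is flagged significant when
#' the observed difference reaches the 95th percentile of the null.
#'
#' @param a,b Numeric samples; non-empty.
#' @param n_iter Number of reshuffles.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param alternative `"greater"` (the directional criterion, default) or
#'   `"two_sided"` (absolute differences).
#' @return An object of class `perm_test` with fields `observed_diff`,
#'   `n_iter`, `p_value`, `percentile_95`, `significant`, `seed`, `mode`.
#' @export
#' @examples
#' r <- perm_test_between(rnorm(20, 1), rnorm(20, 0), n_iter = 999, seed = 1)
#' r$p_value
perm_test_between <- function(a, b, n_iter = 10000, seed = 1L,
                              alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0 || anyNA(a) || anyNA(b)) {
    stop("perm_test_between: samples must be non-empty and free of NAs",
         call. = FALSE)
  }
  observed <- median(a) - median(b)
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  withr::with_seed(seed, {
    idx <- vapply(seq_len(n_iter), function(i) sample.int(n),
                  integer(n))
  })
  perm <- matrix(pooled[idx], nrow = n)
  sims <- matrixStats::colMedians(perm[seq_len(na), , drop = FALSE]) -
    matrixStats::colMedians(perm[-seq_len(na), , drop = FALSE])
  new_perm_test("between", observed, sims, n_iter, seed, alternative)
}

#' Permutation test of a within-participant median difference
#'
#' For paired (standard, flipped) values the observed statistic is
#' `median(standard) - median(flipped)`. Exchangeability under the null is
#' imposed by independently swapping each participant's pair with
#' probability 1/2 on every iteration (the sign-flip construction for
#' paired designs); p-value and significance criterion as in
#' [perm_test_between()].
#'
#' @param standard,flipped Paired numeric vectors of equal length (>= 2),
#'   one value per participant.
#' @inheritParams perm_test_between
#' @return A `perm_test` object with `mode = "within"`.
#' @export
#' @examples
#' s <- rnorm(12, 1); f <- s - 0.5
#' perm_test_within(s, f, n_iter = 999, seed = 1)$p_value
perm_test_within <- function(standard, flipped, n_iter = 10000, seed = 1L,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  standard <- as.numeric(standard); flipped <- as.numeric(flipped)
  if (length(standard) != length(flipped)) {
    stop("perm_test_within: pairs are incomplete (unequal lengths)",
         call. = FALSE)
  }
  if (length(standard) < 2 || anyNA(standard) || anyNA(flipped)) {
    stop("perm_test_within: need >= 2 complete pairs without NAs",
         call. = FALSE)
  }
  n <- length(standard)
  observed <- median(standard) - median(flipped)
  withr::with_seed(seed, {
    swap <- matrix(runif(n * n_iter) < 0.5, nrow = n)
  })
  s_mat <- matrix(standard, nrow = n, ncol = n_iter)
  f_mat <- matrix(flipped, nrow = n, ncol = n_iter)
  tmp <- s_mat[swap]
  s_mat[swap] <- f_mat[swap]
  f_mat[swap] <- tmp
  sims <- matrixStats::colMedians(s_mat) - matrixStats::colMedians(f_mat)
  new_perm_test("within", observed, sims, n_iter, seed, alternative)
}

#' Permutation test of a 2 x 2 interaction
#'
#' Takes per-participant within-participant difference scores (flipped
#' minus standard, say) from two groups and applies the between-group
#' shuffle of [perm_test_between()] to them: a between-participant
#' permutation of within-participant contrasts.
#'
#' @param diffs_a,diffs_b Per-participant difference scores by group.
#' @inheritParams perm_test_between
#' @return A `perm_test` object with `mode = "interaction"`.
#' @export
#' @examples
#' perm_test_interaction(rnorm(10, 0.5), rnorm(10), n_iter = 999,
#'                       seed = 1)$p_value
perm_test_interaction <- function(diffs_a, diffs_b, n_iter = 10000,
                                  seed = 1L,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  res <- perm_test_between(diffs_a, diffs_b, n_iter = n_iter, seed = seed,
                           alternative = alternative)
  res$mode <- "interaction"
  res
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo permutation test (%s, %s)\n", x$mode, x$alternative))
  cat(sprintf(
    "  observed median difference = %.4f\n  null 95th percentile = %.4f\n",
    x$observed_diff, x$percentile_95))
  cat(sprintf("  p = %.4f over %d iterations (seed %d)%s\n",
              x$p_value, x$n_iter, x$seed,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    observed_diff = x$observed_diff,
    n_iter = x$n_iter,
    p_value = x$p_value,
    percentile_95 = x$percentile_95,
    significant = x$significant,
    seed = x$seed
  )
}
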