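#' Plot a fitted psychometric function
#'
#' Observed "more" proportions with the fitted sigmoid overlaid on the
#' relative-length axis.
#'
#' @param object A [fit_psychometric()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x_rel = seq(min(object$points$x_rel), max(object$points$x_rel),
                length.out = 200)
  )
  grid$p <- sigmoid(grid$x_rel, object$K, object$Xo)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x_rel, y = .data$prop_more)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(
      x = "Relative sentence length (words)",
      y = "P(\"more than 17 words\")",
      title = sprintf("JND = %.2f words, PSE = %.2f words",
                      object$jnd, object$pse)
    ) +
    ggplot2::theme_minimal()
}

#' Group psychometric curves for a cohort
#'
#' One panel per group (flip type x sample), observed mean proportions and
#' fitted sigmoids coloured by orientation.
#'
#' @param trials A trial table.
#' @param reference_length Reference word count.
#' @return A ggplot object.
#' @export
plot_group_psychometrics <- function(trials, reference_length = 17) {
  props <- group_proportions(trials, reference_length = reference_length)
  fits <- fit_cohort_psychometrics(trials,
                                   reference_length = reference_length)
  grid <- fits |>
    dplyr::filter(.data$ok) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      flip_type = .data$flip_type, sample_id = .data$sample_id,
      orientation = .data$orientation,
      x_rel = seq(min(props$x_rel), max(props$x_rel), length.out = 120),
      p = sigmoid(seq(min(props$x_rel), max(props$x_rel),
                      length.out = 120), .data$K, .data$Xo)
    )
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$x_rel, y = .data$prop_more,
                               colour = .data$orientation)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$sample_id),
      cols = ggplot2::vars(.data$flip_type),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "Relative sentence length (words)",
                  y = "P(\"more than 17 words\")") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-participant SDT statistics
#'
#' d-prime or beta per condition cell, echoing the standard presentation
#' of precision and bias results.
#'
#' @param sdt A [sdt_by_participant()] table.
#' @param stat `"d_prime"` or `"beta"`.
#' @return A ggplot object.
#' @export
plot_sdt <- function(sdt, stat = c("d_prime", "beta")) {
  stat <- match.arg(stat)
  p <- ggplot2::ggplot(
    sdt,
    ggplot2::aes(x = .data$flip_type, y = .data[[stat]],
                 fill = .data$orientation)
  ) +
    ggplot2::geom_boxplot(notch = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = stat) +
    ggplot2::theme_minimal()
  if (stat == "beta") {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed")
  }
  p
}
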