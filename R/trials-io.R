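#' Read and write the canonical trial table
#'
#' The canonical on-disk format is a UTF-8 comma-separated table with one
#' header row and exactly these columns, in this order: `participant_id`,
#' `flip_type`, `sample_id`, `phase`, `trial_index`, `orientation`,
#' `length_words`, `exemplar_id`, `nominal_line_span`, `occupied_lines`,
#' `mischievous`, `response`, `correct`, `rt_seconds`. Reaction times are in
#' seconds as decimals. Writing then reading reproduces every field exactly.
#'
#' @param path File path.
#' @param trials A trial-table tibble (e.g. from [simulate_cohort()]).
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   invisibly returns `trials`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' sched <- generate_schedule("p01", design_config(), rng_seed = 1)
#' write_trials(sched, tf)
#' identical(read_trials(tf)$length_words, sched$length_words)
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop("read_trials: file not found: ", path, call. = FALSE)
  }
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  missing_cols <- setdiff(trial_table_columns(), header)
  if (length(missing_cols) > 0) {
    stop("read_trials: file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      flip_type = readr::col_character(),
      sample_id = readr::col_integer(),
      phase = readr::col_character(),
      trial_index = readr::col_integer(),
      orientation = readr::col_character(),
      length_words = readr::col_integer(),
      exemplar_id = readr::col_integer(),
      nominal_line_span = readr::col_integer(),
      occupied_lines = readr::col_double(),
      mischievous = readr::col_logical(),
      response = readr::col_character(),
      correct = readr::col_logical(),
      rt_seconds = readr::col_double()
    ),
    progress = FALSE,
    show_col_types = FALSE,
    lazy = FALSE
  ))
  problems <- readr::problems(trials)
  if (nrow(problems) > 0) {
    p1 <- problems[1, ]
    stop(sprintf(
      "read_trials: parse error at row %d, column %d: expected %s, got '%s'",
      p1$row, p1$col, p1$expected, p1$actual
    ), call. = FALSE)
  }
  validate_trials(trials, allow_empty = TRUE)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, allow_empty = TRUE)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(trials)
}

# Structural validation of a trial table: canonical columns, legal enum
# values, positive RTs. Errors name the offending row and column.
validate_trials <- function(trials, allow_empty = FALSE) {
  missing_cols <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) {
    if (allow_empty) return(invisible(trials))
    stop("trial table is empty", call. = FALSE)
  }
  check_enum <- function(col, allowed, na_ok = FALSE) {
    x <- trials[[col]]
    bad <- !(x %in% allowed) & !(na_ok & is.na(x))
    if (any(bad)) {
      stop(sprintf(
        "trial table: invalid value '%s' in column '%s' at row %d",
        x[which(bad)[1]], col, which(bad)[1]
      ), call. = FALSE)
    }
  }
  check_enum("flip_type", c("mirror", "upside_down"))
  check_enum("sample_id", c(1L, 2L))
  check_enum("phase", c("demo", "practice", "analysis"))
  check_enum("orientation", c("standard", "flipped"))
  check_enum("response", c("more", "fewer"), na_ok = TRUE)
  bad_rt <- which(!is.na(trials$rt_seconds) & trials$rt_seconds <= 0)
  if (length(bad_rt) > 0) {
    stop(sprintf(
      "trial table: non-positive rt_seconds at row %d", bad_rt[1]
    ), call. = FALSE)
  }
  invisible(trials)
}

# Analysis-phase rows only, validated. Used by every analysis operation so
# demo and practice trials never leak into statistics.
analysis_trials <- function(trials) {
  validate_trials(trials, allow_empty = TRUE)
  dplyr::filter(trials, .data$phase == "analysis")
}
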