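# AB-design series container and CSV input/output.
#
# Conventions: timepoints are 0-based integer week indices; the
# intervention onset (and the model's change point) is the 0-based index
# of the FIRST intervention-phase observation, so phase A occupies
# positions [0, onset) and phase B positions [onset, n). Both phases must
# hold at least `min_per_phase` observations (default 3, the model's
# applicability rule).

#' Construct a validated AB-design outcome series
#'
#' @param values Numeric outcome scores, one per assessment occasion.
#' @param intervention_onset 0-based index of the first intervention-phase
#'   observation (the designed phase split, not the estimated change point).
#' @param timepoints Strictly increasing integer week indices; defaults to
#'   `0:(n-1)` (a complete weekly series).
#' @param label Outcome name (e.g. `"total"`, `"adl"`, `"bpsd"`, `"cog"`).
#' @param min_per_phase Minimum observations required in each phase.
#' @return Object of class `ab_series` with fields `week`, `score`,
#'   `onset`, `label`.
#' @export
ab_series <- function(values, intervention_onset,
                      timepoints = seq_along(values) - 1L,
                      label = "score", min_per_phase = 3L) {
  values <- as.numeric(values)
  timepoints <- as.integer(timepoints)
  onset <- as.integer(intervention_onset)
  n <- length(values)
  if (n != length(timepoints)) {
    stop("values and timepoints differ in length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("series values must be finite and non-missing", call. = FALSE)
  }
  if (anyNA(timepoints) || any(diff(timepoints) <= 0L)) {
    stop("timepoints must be strictly increasing integers", call. = FALSE)
  }
  if (onset < min_per_phase || n - onset < min_per_phase) {
    stop(sprintf(
      "insufficient phase length: onset %d leaves %d pre- and %d post-onset observations (need >= %d each)",
      onset, onset, n - onset, min_per_phase), call. = FALSE)
  }
  structure(
    list(week = timepoints, score = values, onset = onset,
         label = as.character(label)),
    class = "ab_series"
  )
}

#' @export
print.ab_series <- function(x, ...) {
  n <- length(x$score)
  cat(sprintf("AB series '%s': %d observations, intervention onset at index %d\n",
              x$label, n, x$onset))
  cat(sprintf("  phase A (n=%d): mean %.2f | phase B (n=%d): mean %.2f\n",
              x$onset, mean(phase_a(x)), n - x$onset, mean(phase_b(x))))
  invisible(x)
}

#' @export
length.ab_series <- function(x) length(x$score)

#' Phase A / phase B observations of an AB series
#' @param series An `ab_series`.
#' @return Numeric vector of the phase's outcome values.
#' @export
phase_a <- function(series) series$score[seq_len(series$onset)]

#' @rdname phase_a
#' @export
phase_b <- function(series) series$score[(series$onset + 1L):length(series$score)]

#' Is a series complete (consecutive weekly observations)?
#' @param series An `ab_series`.
#' @return Logical scalar.
#' @export
is_complete <- function(series) all(diff(series$week) == 1L)

#' Read an AB-design series from CSV
#'
#' Accepts the minimal dialect `week,score` (any single outcome column
#' name) or the extended dialect `week,adl,bpsd,cog,total`, in which case
#' `outcome_label` selects the outcome and `total == adl + bpsd + cog` is
#' enforced row-wise. Gaps in the week index are rejected unless
#' `allow_gaps = TRUE`; missing values are always an error (never
#' imputed).
#'
#' @param path CSV file path (header row, comma-separated, UTF-8).
#' @param onset_index 0-based index of the first intervention-phase
#'   observation.
#' @param outcome_label Column to read as the outcome; defaults to the
#'   second column.
#' @param allow_gaps Accept non-consecutive week indices (the AR(1)
#'   likelihood then uses exact gap-length decay); off by default.
#' @param min_per_phase Minimum observations per phase.
#' @return An [ab_series()].
#' @export
read_series_csv <- function(path, onset_index, outcome_label = NULL,
                            allow_gaps = FALSE, min_per_phase = 3L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"week" %in% names(df)) {
    stop("CSV must have a 'week' column", call. = FALSE)
  }
  extended <- all(c("adl", "bpsd", "cog", "total") %in% names(df))
  if (is.null(outcome_label)) {
    outcome_label <- setdiff(names(df), "week")[1L]
  }
  if (!outcome_label %in% names(df)) {
    stop("no column '", outcome_label, "' in ", path, call. = FALSE)
  }
  wk <- df$week
  y <- df[[outcome_label]]
  if (anyNA(wk) || anyNA(y)) {
    stop("unparseable or missing cells in ", path,
         " (missing rows are reported, not imputed)", call. = FALSE)
  }
  if (any(wk != round(wk)) || any(diff(wk) <= 0)) {
    stop("non-monotone or non-integer week indices in ", path, call. = FALSE)
  }
  if (extended) {
    bad <- which(df$total != df$adl + df$bpsd + df$cog)
    if (length(bad)) {
      stop("row ", bad[1L], ": total != adl + bpsd + cog", call. = FALSE)
    }
  }
  if (!allow_gaps && any(diff(wk) != 1)) {
    gap <- which(diff(wk) != 1)[1L]
    stop(sprintf("missing week(s) between %d and %d (set allow_gaps = TRUE to accept)",
                 wk[gap], wk[gap + 1L]), call. = FALSE)
  }
  ab_series(y, onset_index, timepoints = wk, label = outcome_label,
            min_per_phase = min_per_phase)
}

#' Write an AB-design series to CSV
#'
#' Emits the minimal dialect with the series' own label as the outcome
#' column name; `read_series_csv()` round-trips it losslessly.
#'
#' @param series An `ab_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- data.frame(week = series$week, score = series$score)
  names(df)[2L] <- series$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
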