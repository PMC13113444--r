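# Gait-cycle resampling and waveform agreement statistics.

#' Resample a time series onto the 101-point gait-cycle grid
#'
#' Each pair of consecutive foot-strike events delimits one gait cycle;
#' the signal is linearly interpolated onto 0, 1, ..., 100% of that cycle
#' and, when the events delimit several cycles, the cycles are averaged
#' pointwise.
#'
#' @param time Sample times (strictly increasing).
#' @param values Signal values at `time`.
#' @param events Foot-strike times (>= 2), each inside the sampled range.
#' @return Numeric vector of length 101.
#' @export
resample_to_cycle <- function(time, values, events) {
  stopifnot(length(time) == length(values))
  if (length(events) < 2L)
    stop("need at least 2 foot-strike events to delimit a cycle")
  events <- sort(events)
  if (events[1] < time[1] - 1e-9 ||
      events[length(events)] > time[length(time)] + 1e-9)
    stop("events must lie within the sampled time range")
  grid <- seq(0, 1, length.out = 101L)
  ncyc <- length(events) - 1L
  acc <- numeric(101L)
  for (c in seq_len(ncyc)) {
    t0 <- events[c]; t1 <- events[c + 1L]
    acc <- acc + stats::approx(time, values, xout = t0 + grid * (t1 - t0),
                               rule = 2)$y
  }
  acc / ncyc
}

#' Pearson correlation between two waveforms
#'
#' Standard product-moment correlation, used to compare normalized force
#' waveforms of non-pathological gait against reference curves.
#'
#' @param a,b Numeric series of equal length (>= 3), neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  .check_corr_args(a, b)
  stats::cor(a, b, method = "pearson")
}

#' Spearman rank correlation between two waveforms
#'
#' Pearson correlation of the rank-transformed series (average ranks for
#' ties). Preferred over Pearson for pathological (stroke) gait, where
#' extreme force values make a linear association measure unstable.
#'
#' @inheritParams pearson_r
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  .check_corr_args(a, b)
  stats::cor(a, b, method = "spearman")
}

.check_corr_args <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 samples")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("series must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation is undefined for a constant series")
}

#' Classify correlation strength
#'
#' Maps the absolute value of a correlation coefficient to a qualitative
#' band. Defaults: `|r| >= 0.8` strong, `0.5 <= |r| < 0.8` moderate,
#' `|r| < 0.5` weak; a coefficient exactly at a cut point takes the higher
#' band. The cut points are configurable because conventions differ
#' between fields.
#'
#' @param coefficient Correlation coefficient in `[-1, 1]`; vectorized.
#' @param cuts Length-2 increasing numeric: the weak/moderate and
#'   moderate/strong cut points on `|r|`.
#' @return Character vector: `"weak"`, `"moderate"` or `"strong"`.
#' @export
classify_strength <- function(coefficient, cuts = c(0.5, 0.8)) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2])
  if (any(!is.finite(coefficient)) || any(abs(coefficient) > 1))
    stop("coefficient must lie in [-1, 1]")
  a <- abs(coefficient)
  ifelse(a >= cuts[2], "strong", ifelse(a >= cuts[1], "moderate", "weak"))
}

#' Compare estimated force profiles against reference waveforms
#'
#' Correlates each muscle's estimated series with its reference series on
#' the shared 101-point cycle grid and classifies the strength of
#' agreement.
#'
#' @param estimated Named list of numeric series (one per muscle), or a
#'   list of [force_profile()]s (the active series is used).
#' @param reference Named list of numeric series on the same grid.
#' @param method `"pearson"` or `"spearman"`.
#' @param condition Free-form label stored in the report.
#' @return A `comparison_report` data.frame with columns `muscle`,
#'   `coefficient`, `method`, `condition`, `strength`.
#' @export
compare_profiles <- function(estimated, reference,
                             method = c("pearson", "spearman"),
                             condition = "") {
  method <- match.arg(method)
  fun <- if (method == "pearson") pearson_r else spearman_rho
  series <- lapply(estimated, function(e)
    if (inherits(e, "force_profile")) e$active else e)
  muscles <- names(series)
  if (is.null(muscles)) stop("estimated profiles must be named by muscle")
  missing <- setdiff(muscles, names(reference))
  if (length(missing))
    stop("no reference waveform for: ", paste(missing, collapse = ", "))
  r <- vapply(muscles, function(m) fun(series[[m]], reference[[m]]),
              numeric(1))
  out <- data.frame(muscle = muscles, coefficient = unname(r),
                    method = method, condition = condition,
                    strength = classify_strength(unname(r)),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Waveform comparison (%s%s)\n", x$method[1],
              if (nzchar(x$condition[1])) paste0(", ", x$condition[1]) else ""))
  df <- as.data.frame(x)
  df$coefficient <- sprintf("%.3f", df$coefficient)
  print(df[, c("muscle", "coefficient", "strength")], row.names = FALSE)
  invisible(x)
}
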