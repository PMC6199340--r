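#' Running lag-1 autocorrelations over a sliding window
#'
#' Slides a window of `window` consecutive occasions across the series
#' (step 1) and, per variable, computes the Pearson correlation between the
#' window's values and their lag-1 counterparts (`window - 1` lagged
#' pairs). Each window is indexed by the median of the occasions it covers:
#' if a change point is present, the window whose median sits at the change
#' point holds an equal number of occasions from both phases, which
#' maximizes the chance of detecting the shift.
#'
#' @param data Series data frame (see [series_vars()]); rows must already be
#'   consecutive and complete (apply [lag1_filter()] first for beep data
#'   with gaps).
#' @param window Window size in occasions, at least 3. The default of 25
#'   gives running autocorrelations that are noisy enough to react quickly
#'   yet stable enough to segment.
#' @return A tibble of class `running_stats` with columns `window` (start
#'   index), `t` (median occasion) and one autocorrelation column per
#'   variable; `n - window + 1` rows. The window size is kept in the
#'   `window_size` attribute.
#' @export
running_autocorrelations <- function(data, window = 25) {
  if (window < 3) stop("`window` must be at least 3", call. = FALSE)
  X <- series_matrix(data)
  n <- nrow(X)
  if (n < window) stop("series shorter than the window", call. = FALSE)
  P <- cpp_running_autocor(X, as.integer(window))
  if (anyNA(P)) {
    bad <- which(is.na(P), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("autocorrelation undefined in window %d for variable ",
                        "'%s' (constant lagged segment)"),
                 bad[1], series_vars(data)[bad[2]]), call. = FALSE)
  }
  t_raw <- series_time(data)
  w <- n - window + 1L
  centers <- vapply(seq_len(w),
                    function(s) median(t_raw[s:(s + window - 1L)]), numeric(1))
  colnames(P) <- series_vars(data)
  out <- tibble::as_tibble(P)
  out <- dplyr::bind_cols(tibble::tibble(window = seq_len(w), t = centers), out)
  attr(out, "window_size") <- as.integer(window)
  class(out) <- c("running_stats", class(out))
  out
}

# Matrix of autocorrelation vectors from a running_stats tibble (or any
# matrix-like input, for the low-level kernel functions).
stats_matrix <- function(P) {
  if (is.matrix(P)) return(P)
  series_matrix(P)
}

#' Keep only occasions whose lag-1 counterpart exists on the same day
#'
#' Experience-sampling series have unequal gaps: beeps can be missed and
#' nights separate the last beep of a day from the first of the next. For
#' lag-1 modeling, a row is only usable if the immediately preceding beep
#' (same day, beep number minus one) was observed. This filter retains
#' exactly those rows; in particular the first beep of every day is dropped
#' (overnight lags are considerably longer than within-day ones).
#'
#' @param data Series data frame with numeric `day` and `beep` columns.
#' @return The filtered tibble, rows in original order.
#' @export
lag1_filter <- function(data) {
  if (!all(c("day", "beep") %in% names(data))) {
    stop("`lag1_filter()` needs `day` and `beep` columns", call. = FALSE)
  }
  key <- paste(data$day, data$beep)
  pred <- paste(data$day, data$beep - 1)
  tibble::as_tibble(data[pred %in% key, , drop = FALSE])
}

#' Replace per-variable outliers beyond three standard deviations
#'
#' For each variable separately, scores further than three standard
#' deviations from the variable's mean are replaced by the most extreme
#' score of the same tail that stays within the threshold. Mean and
#' standard deviation are computed once on the original column (a single
#' replacement pass, not iterated), so the range of a column never
#' increases. Constant columns are left untouched.
#'
#' @param data Series data frame.
#' @return The winsorized tibble.
#' @export
winsorize_3sd <- function(data) {
  out <- tibble::as_tibble(data)
  for (v in series_vars(out)) {
    x <- out[[v]]
    m <- mean(x)
    s <- sd(x)
    if (!is.finite(s) || s == 0) next
    lo <- m - 3 * s
    hi <- m + 3 * s
    inside <- x >= lo & x <= hi
    if (!any(inside)) next
    x[x > hi] <- max(x[inside])
    x[x < lo] <- min(x[inside])
    out[[v]] <- x
  }
  out
}
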