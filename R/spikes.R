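#' Detect spikes by threshold crossing
#'
#' A spike is the first sample of each upward crossing
#' (`V[k-1] < threshold <= V[k]`); crossings closer than 2 ms are merged into a
#' single event (a refractory guard against noisy re-crossings).
#'
#' @param V_mV Voltage trace (finite numeric vector).
#' @param time_ms Matching time axis; alternatively pass a `sim_result` as the
#'   first argument and leave `time_ms` missing.
#' @param threshold_mV Detection threshold in mV (default -55).
#' @param merge_ms Merge window for successive crossings (default 2).
#' @return A `spike_train`: `spike_times_ms` (strictly increasing),
#'   `threshold_mV`, `span_ms = c(t0, t1)`.
#' @export
detect_spikes <- function(V_mV, time_ms = NULL, threshold_mV = -55,
                          merge_ms = 2) {
  if (inherits(V_mV, "sim_result")) {
    time_ms <- V_mV$time_ms
    V_mV <- V_mV$V_mV
  }
  stopifnot(is.numeric(V_mV), all(is.finite(V_mV)),
            length(V_mV) == length(time_ms))
  up <- which(V_mV[-1] >= threshold_mV & V_mV[-length(V_mV)] < threshold_mV) + 1L
  times <- time_ms[up]
  if (length(times) > 1L) {
    # merge runs: a crossing is kept only if >= merge_ms after the last kept one
    out <- numeric(0)
    last <- -Inf
    for (tm in times) {
      if (tm - last >= merge_ms) {
        out <- c(out, tm)
        last <- tm
      }
    }
    times <- out
  }
  # the record spans [t0, t0 + n*dt): each sample owns one dt-wide bin
  dt <- time_ms[2] - time_ms[1]
  spike_train(times,
              span_ms = c(time_ms[1], time_ms[1] + length(V_mV) * dt),
              threshold_mV = threshold_mV)
}

#' Construct a spike train
#'
#' @param spike_times_ms Strictly increasing spike times within `span_ms`.
#' @param span_ms Record span `c(t0, t1)` in ms.
#' @param threshold_mV Detection threshold the times came from.
#' @return A `spike_train` object.
#' @export
spike_train <- function(spike_times_ms, span_ms, threshold_mV = -55) {
  spike_times_ms <- as.numeric(spike_times_ms)
  if (is.unsorted(spike_times_ms, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(spike_times_ms) &&
      (min(spike_times_ms) < span_ms[1] || max(spike_times_ms) > span_ms[2]))
    stop("spike times must lie within the record span")
  structure(list(spike_times_ms = spike_times_ms, span_ms = span_ms,
                 threshold_mV = threshold_mV),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in [%.6g, %.6g] ms (threshold %.4g mV)\n",
              length(x$spike_times_ms), x$span_ms[1], x$span_ms[2],
              x$threshold_mV))
  invisible(x)
}

#' Binary firing-rate series r(t)
#'
#' Each sample containing a spike takes the value `1 / dt` (dt in seconds), all
#' others are zero, so that `sum(r) * dt` equals the spike count.
#'
#' @param train A [spike_train()].
#' @param dt_ms Bin width in ms; must divide the record span.
#' @return A `rate_series`: `dt_ms`, `values` (1/s), `t0_ms`.
#' @export
rate_series <- function(train, dt_ms) {
  stopifnot(inherits(train, "spike_train"), dt_ms > 0)
  span <- diff(train$span_ms)
  n <- round(span / dt_ms)
  if (abs(span - n * dt_ms) > 1e-6 * dt_ms)
    stop("dt_ms must divide the record span")
  idx <- pmin(floor((train$spike_times_ms - train$span_ms[1]) / dt_ms) + 1L, n)
  if (anyDuplicated(idx))
    stop("two spikes fall into one rate bin; decrease dt_ms")
  values <- numeric(n)
  values[idx] <- 1000 / dt_ms
  structure(list(dt_ms = dt_ms, values = values, t0_ms = train$span_ms[1]),
            class = "rate_series")
}

#' Coefficient of variation of interspike intervals
#'
#' `SD(ISI) / mean(ISI)` with the population-SD convention (divide by n). For a
#' list of trains the ISIs are pooled across trials before the ratio is taken;
#' set `per_trial = TRUE` to instead average per-trial CVs.
#'
#' @param train A [spike_train()] or a list of them.
#' @param per_trial If `TRUE` and `train` is a list, return the mean of
#'   per-trial CVs instead of the pooled-ISI CV.
#' @return The CV (dimensionless).
#' @export
isi_cv <- function(train, per_trial = FALSE) {
  isis_of <- function(tr) diff(tr$spike_times_ms)
  if (inherits(train, "spike_train")) {
    isis <- isis_of(train)
    if (length(isis) < 2L) stop("need at least 2 ISIs for a CV")
    return(pop_cv(isis))
  }
  stopifnot(is.list(train))
  if (per_trial) {
    cvs <- vapply(train, function(tr) isi_cv(tr), 0)
    return(mean(cvs))
  }
  isis <- unlist(lapply(train, isis_of))
  if (length(isis) < 2L) stop("need at least 2 ISIs for a CV")
  pop_cv(isis)
}

pop_cv <- function(x) {
  m <- mean(x)
  if (m == 0) stop("degenerate sample: zero mean")
  sqrt(mean((x - m)^2)) / m
}

#' Two-sample test for equality of coefficients of variation
#'
#' Asymptotic chi-square test of H0: CV_a = CV_b (Feltz & Miller 1996). The
#' statistic pools the per-sample CVs weighted by degrees of freedom and is
#' referred to a chi-square distribution with 1 df; the reported p-value is
#' two-sided by construction.
#'
#' @param isis_a,isis_b Numeric samples (e.g. interspike intervals), each with
#'   at least 5 values and nonzero mean and variance.
#' @return List with `statistic`, `p_value`, `cv_a`, `cv_b`.
#' @export
cv_test <- function(isis_a, isis_b) {
  check <- function(x, lab) {
    if (length(x) < 5L) stop(sprintf("sample %s: need >= 5 values", lab))
    if (mean(x) == 0) stop(sprintf("sample %s: zero mean", lab))
    if (all(x == x[1])) stop(sprintf("sample %s: zero variance", lab))
  }
  check(isis_a, "a"); check(isis_b, "b")
  cvs <- c(pop_cv(isis_a), pop_cv(isis_b))
  nu <- c(length(isis_a) - 1, length(isis_b) - 1)
  if (identical(isis_a, isis_b))
    return(list(statistic = 0, p_value = 1, cv_a = cvs[1], cv_b = cvs[2]))
  cp <- sum(nu * cvs) / sum(nu)
  stat <- sum(nu * (cvs - cp)^2) / (cp^2 * (0.5 + cp^2))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       cv_a = cvs[1], cv_b = cvs[2])
}

#' Write / read spike trains as single-column text
#'
#' @param train A [spike_train()].
#' @param path File path.
#' @export
write_spikes <- function(train, path) {
  hdr <- c("# fdgscape spike train",
           sprintf("# span_ms=%.17g,%.17g threshold_mV=%.17g",
                   train$span_ms[1], train$span_ms[2], train$threshold_mV),
           "spike_time_ms")
  writeLines(c(hdr, sprintf("%.17g", train$spike_times_ms)), path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# span_ms=", lines, value = TRUE)[1]
  span <- as.numeric(strsplit(sub("^# span_ms=([^ ]+) .*", "\\1", meta),
                              ",")[[1]])
  thr <- as.numeric(sub(".*threshold_mV=", "", meta))
  body <- lines[!startsWith(lines, "#")]
  times <- as.numeric(body[-1]) # drop column-name row
  spike_train(times[!is.na(times)], span_ms = span, threshold_mV = thr)
}
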