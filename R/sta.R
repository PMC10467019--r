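#' Spikes with an uncontaminated pre-spike window
#'
#' Keeps spikes that have (a) no earlier spike within `window_ms` before them
#' and (b) at least `window_ms` of recorded data before them, so every
#' surviving spike owns a complete, spike-free pre-window.
#'
#' @param train A [spike_train()].
#' @param window_ms Pre-spike window length (> 0), e.g. 30, 100 or 200.
#' @return A `spike_train` (possibly empty) with the surviving spikes.
#' @export
isolated_spikes <- function(train, window_ms) {
  stopifnot(inherits(train, "spike_train"), window_ms > 0)
  tms <- train$spike_times_ms
  keep <- vapply(seq_along(tms), function(i) {
    if (tms[i] - train$span_ms[1] < window_ms) return(FALSE)
    if (i == 1L) return(TRUE)
    tms[i] - tms[i - 1L] >= window_ms
  }, TRUE)
  spike_train(tms[keep], span_ms = train$span_ms,
              threshold_mV = train$threshold_mV)
}

#' Spike-triggered average of a signal
#'
#' Averages `signal` over the `[t_spike - window_ms, t_spike]` window of every
#' isolated spike (the detection sample is the inclusive right edge). For
#' multi-trial input (lists of signals and trains) each trial's spike-average
#' is computed first and trials are combined with equal weight; the SD band is
#' across trials. For a single trial the SD is across spikes.
#'
#' Samples may be masked (`NA` in the signal): they are excluded and each lag
#' is renormalized by its count of defined contributions.
#'
#' @param signal Numeric vector on the `dt_ms` grid starting at the train's
#'   span start, or a list of such vectors (one per trial).
#' @param train A [spike_train()] or list of them (matching `signal`).
#' @param window_ms Pre-spike window length.
#' @param dt_ms Sample interval of `signal`.
#' @return An `sta_result`: `lag_ms` (from `-window_ms` to 0), `mean`, `sd`,
#'   `n_spikes`, `n_trials`, `window_ms`, `dt_ms`.
#' @export
sta_signal <- function(signal, train, window_ms, dt_ms) {
  if (inherits(train, "spike_train")) {
    signal <- list(signal)
    train <- list(train)
  }
  stopifnot(length(signal) == length(train), length(train) >= 1L)
  w <- as.integer(round(window_ms / dt_ms))
  trial_stats <- lapply(seq_along(train), function(i) {
    iso <- isolated_spikes(train[[i]], window_ms)
    tms <- iso$spike_times_ms
    if (length(tms) == 0L) return(NULL)
    x <- signal[[i]]
    t0 <- train[[i]]$span_ms[1]
    segs <- vapply(tms, function(tt) {
      k <- as.integer(round((tt - t0) / dt_ms)) + 1L
      x[seq.int(k - w, k)]
    }, numeric(w + 1L))
    cnt <- rowSums(!is.na(segs))
    mu <- rowSums(segs, na.rm = TRUE) / ifelse(cnt > 0, cnt, NA_real_)
    list(mean = mu, segs = segs, n = length(tms))
  })
  ok <- !vapply(trial_stats, is.null, TRUE)
  if (!any(ok))
    stop(sprintf("no isolated spikes for the %g ms window", window_ms))
  trial_stats <- trial_stats[ok]
  M <- vapply(trial_stats, `[[`, numeric(w + 1L), "mean")
  n_spk <- sum(vapply(trial_stats, `[[`, 0L, "n"))
  if (length(trial_stats) > 1L) {
    mu <- rowMeans(M, na.rm = TRUE)
    sdv <- apply(M, 1, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2L) 0 else sqrt(mean((z - mean(z))^2))
    })
  } else {
    segs <- trial_stats[[1]]$segs
    mu <- M[, 1]
    sdv <- apply(segs, 1, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2L) 0 else sqrt(mean((z - mean(z))^2))
    })
  }
  structure(
    list(lag_ms = seq(-w, 0) * dt_ms, mean = mu, sd = sdv,
         n_spikes = n_spk, n_trials = length(trial_stats),
         window_ms = window_ms, dt_ms = dt_ms),
    class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(
    "<sta_result> %g ms window @ %g ms, %d spikes over %d trial(s), mean range [%.4g, %.4g]\n",
    x$window_ms, x$dt_ms, x$n_spikes, x$n_trials, min(x$mean), max(x$mean)))
  invisible(x)
}

#' Spike-triggered averages of percentage contributions, per channel
#'
#' Applies [sta_signal()] to each channel's percentage-contribution trace.
#' Each channel is averaged in its dominant class over the collected windows
#' (the class carrying more of its defined samples); samples where the channel
#' carries the opposite class, or where the class total is undefined, are
#' masked and the average renormalized by the defined count. Channels that are
#' never defined in any window yield an error entry rather than failing the
#' whole map.
#'
#' @param pc A [percent_contributions()] result or list of them (one per
#'   trial).
#' @param train A [spike_train()] or list of them (matching `pc`).
#' @param window_ms Pre-spike window length.
#' @return Named list: per channel either an `sta_result` (with attributes
#'   `class` = `"inward"`/`"outward"` and `flipped`) or a character error
#'   message.
#' @export
sta_contributions <- function(pc, train, window_ms) {
  if (inherits(pc, "percent_contribution")) {
    pc <- list(pc)
    train <- list(train)
  }
  stopifnot(length(pc) == length(train))
  channels <- pc[[1]]$channels
  dt <- diff(pc[[1]]$time_ms[1:2])
  w <- as.integer(round(window_ms / dt))
  # collect per-trial window masks of in/out presence to pick the dominant class
  counts <- sapply(channels, function(ch) c(inward = 0, outward = 0))
  win_idx <- lapply(seq_along(pc), function(i) {
    iso <- isolated_spikes(train[[i]], window_ms)
    t0 <- train[[i]]$span_ms[1]
    lapply(iso$spike_times_ms, function(tt) {
      k <- as.integer(round((tt - t0) / dt)) + 1L
      seq.int(k - w, k)
    })
  })
  for (i in seq_along(pc)) {
    idx <- unlist(win_idx[[i]])
    if (!length(idx)) next
    for (j in seq_along(channels)) {
      counts["inward", j] <- counts["inward", j] +
        sum(pc[[i]]$pct_in[idx, j] > 0, na.rm = TRUE)
      counts["outward", j] <- counts["outward", j] +
        sum(pc[[i]]$pct_out[idx, j] > 0, na.rm = TRUE)
    }
  }
  out <- vector("list", length(channels))
  names(out) <- channels
  for (j in seq_along(channels)) {
    ch <- channels[j]
    if (counts["inward", j] + counts["outward", j] == 0) {
      out[[j]] <- sprintf("channel '%s' never defined in any window", ch)
      next
    }
    dom <- if (counts["inward", j] >= counts["outward", j]) "inward" else "outward"
    sigs <- lapply(seq_along(pc), function(i) {
      p <- pc[[i]]
      x <- if (dom == "inward") p$pct_in[, j] else p$pct_out[, j]
      opp <- if (dom == "inward") p$pct_out[, j] else p$pct_in[, j]
      x[!is.na(opp) & opp > 0] <- NA_real_ # opposite-class samples masked
      x
    })
    res <- tryCatch(sta_signal(sigs, train, window_ms, dt),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "sta_result")) {
      attr(res, "class_label") <- dom
      attr(res, "flipped") <- all(counts[, j] > 0)
    }
    out[[j]] <- res
  }
  out
}

#' Monotonicity of a processed spike-triggered average
#'
#' Normalizes the STA trace by its window maximum (outward polarity) or
#' minimum (inward polarity), smooths with a centered 5-point moving average
#' whose windows shrink at the edges, takes the per-step difference quotient,
#' and reports the proportions of negative (decreasing), positive
#' (increasing) and exactly-zero (flat) steps.
#'
#' @param sta An `sta_result` (or a bare numeric trace plus `dt_ms`).
#' @param polarity `"inward"` or `"outward"`: selects the normalizing
#'   extremum.
#' @param span Moving-average span (odd, default 5).
#' @param dt_ms Required only when `sta` is a bare numeric vector.
#' @return A `monotonicity_result`: `fraction_increasing`,
#'   `fraction_decreasing`, `fraction_flat`, `polarity`, `span`, `processed`
#'   (the smoothed normalized trace) and `diff_quotient`.
#' @export
monotonicity <- function(sta, polarity = c("inward", "outward"), span = 5L,
                         dt_ms = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(sta, "sta_result")) {
    x <- sta$mean
    dt_ms <- sta$dt_ms
  } else {
    x <- as.numeric(sta)
    if (is.null(dt_ms)) stop("dt_ms required for a bare trace")
  }
  if (all(x == 0)) stop("all-zero trace: nothing to normalize")
  if (length(x) < span) stop("trace shorter than the smoothing span")
  norm <- if (polarity == "outward") max(x) else min(x)
  if (norm == 0) stop("normalizing extremum is zero")
  proc <- moving_average(x / norm, span)
  d <- diff(proc) / dt_ms
  structure(
    list(fraction_increasing = mean(d > 0),
         fraction_decreasing = mean(d < 0),
         fraction_flat = mean(d == 0),
         polarity = polarity, span = span,
         processed = proc, diff_quotient = d),
    class = "monotonicity_result")
}

# centered moving average with shrinking (always-centered, odd) edge windows:
# y[1] = x[1], y[2] = mean(x[1:3]), y[3] = mean(x[1:5]), ... and symmetrically
moving_average <- function(x, span = 5L) {
  n <- length(x)
  half <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, 0)
}

#' @export
print.monotonicity_result <- function(x, ...) {
  cat(sprintf(
    "<monotonicity_result> %s: %.2f%% decreasing, %.2f%% increasing, %.2f%% flat (span %d)\n",
    x$polarity, 100 * x$fraction_decreasing, 100 * x$fraction_increasing,
    100 * x$fraction_flat, x$span))
  invisible(x)
}

#' Write an STA result as delimited text / a monotonicity result as JSON
#'
#' @param sta An `sta_result`.
#' @param path File path.
#' @export
write_sta <- function(sta, path) {
  hdr <- c("# fdgscape spike-triggered average",
           sprintf("# window_ms=%g dt_ms=%g n_spikes=%d n_trials=%d",
                   sta$window_ms, sta$dt_ms, sta$n_spikes, sta$n_trials),
           "lag_ms\tmean\tsd")
  writeLines(c(hdr, sprintf("%.17g\t%.17g\t%.17g", sta$lag_ms, sta$mean,
                            sta$sd)), path)
  invisible(path)
}

#' @rdname write_sta
#' @param mono A `monotonicity_result`.
#' @param channel Channel label recorded in the JSON.
#' @export
write_monotonicity <- function(mono, path, channel = "") {
  jsonlite::write_json(
    list(channel = channel, polarity = mono$polarity, span = mono$span,
         fraction_increasing = mono$fraction_increasing,
         fraction_decreasing = mono$fraction_decreasing,
         fraction_flat = mono$fraction_flat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
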