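#' Specification of a frozen-noise current stimulus
#'
#' A stimulus is zero-mean Gaussian white noise on the integration grid,
#' convolved with a square kernel of width `pulse_width_ms` (unit area),
#' rescaled so its sample standard deviation equals `sigma_nA`, and offset by a
#' tonic DC current `dc_nA`. The same spec always regenerates the same samples
#' ("frozen" noise).
#'
#' @param duration_ms Record duration in ms (default 2500).
#' @param dt_ms Sample interval in ms.
#' @param sigma_nA Target SD of the noise component in nA (default 0.04).
#' @param pulse_width_ms Width of the square smoothing kernel in ms (default 3).
#' @param dc_nA Tonic offset in nA.
#' @param seed Integer seed; identical specs give bitwise-identical traces.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(duration_ms = 2500, dt_ms = 0.025, sigma_nA = 0.04,
                          pulse_width_ms = 3, dc_nA = 0, seed = 1L) {
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("invalid spec: duration_ms must be > 0")
  if (!is.numeric(dt_ms) || dt_ms <= 0)
    stop("invalid spec: dt_ms must be > 0")
  if (sigma_nA < 0) stop("invalid spec: sigma_nA must be >= 0")
  if (pulse_width_ms < dt_ms)
    stop("invalid spec: pulse_width_ms must be >= dt_ms")
  structure(
    list(duration_ms = duration_ms, dt_ms = dt_ms, sigma_nA = sigma_nA,
         pulse_width_ms = pulse_width_ms, dc_nA = dc_nA,
         seed = as.integer(seed)),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %.6g ms @ dt %.6g ms | sigma %.4g nA, kernel %.3g ms, dc %.4g nA, seed %d\n",
    x$duration_ms, x$dt_ms, x$sigma_nA, x$pulse_width_ms, x$dc_nA, x$seed))
  invisible(x)
}

n_samples <- function(spec) as.integer(round(spec$duration_ms / spec$dt_ms))

#' Generate a frozen white-noise current trace
#'
#' Draws i.i.d. Gaussian samples on the `dt_ms` grid, convolves with a unit-area
#' square kernel of width `pulse_width_ms`, rescales so the sample SD of the
#' result equals `sigma_nA` exactly, and adds `dc_nA`. Convolution edges are
#' trimmed by regenerating one kernel width of extra samples, so every returned
#' sample sees a full kernel.
#'
#' @param spec A [stimulus_spec()].
#' @return A `stimulus_trace`: list with `spec`, `time_ms` and `samples` (nA).
#' @export
make_frozen_noise <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- n_samples(spec)
  kn <- max(1L, as.integer(round(spec$pulse_width_ms / spec$dt_ms)))
  x <- if (spec$sigma_nA > 0) {
    raw <- withr_seed(spec$seed, stats::rnorm(n + kn - 1L))
    kernel <- rep(1 / kn, kn) # unit area
    sm <- as.numeric(stats::filter(raw, kernel, method = "convolution",
                                   sides = 1))
    sm <- sm[kn:(n + kn - 1L)] # full-kernel samples only
    sdev <- sqrt(mean((sm - mean(sm))^2))
    sm * (spec$sigma_nA / sdev)
  } else {
    numeric(n)
  }
  structure(
    list(spec = spec,
         time_ms = seq(0, by = spec$dt_ms, length.out = n),
         samples = x + spec$dc_nA),
    class = "stimulus_trace")
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %d samples, mean %.4g nA, sd %.4g nA\n",
              length(x$samples), mean(x$samples), stats::sd(x$samples)))
  print(x$spec)
  invisible(x)
}

#' Calibrate the DC shift to a target spike count
#'
#' Bisects on the tonic offset `dc_nA` so that a simulation of `model` driven by
#' the frozen noise of `base_spec` (same seed, same noise component) produces a
#' spike count inside `target_spikes`. Assumes the count is nondecreasing in dc
#' over `dc_bounds`; a violated bracket raises an error rather than returning a
#' silent answer. Ties break toward the smallest dc found in range.
#'
#' @param model A [model_params()] object.
#' @param base_spec A [stimulus_spec()]; its `dc_nA` is ignored.
#' @param target_spikes Integer range `c(lo, hi)` (default `c(12, 15)`).
#' @param dc_bounds Numeric `c(lo, hi)` bracketing a solution, in nA.
#' @param threshold_mV Spike-detection threshold (default -55).
#' @param max_iter Bisection iterations before giving up (default 40).
#' @return The calibrated dc in nA, with attribute `spike_count`.
#' @export
calibrate_dc <- function(model, base_spec, target_spikes = c(12L, 15L),
                         dc_bounds = c(-0.7, 1.2), threshold_mV = -55,
                         max_iter = 40L) {
  stopifnot(length(target_spikes) == 2L, target_spikes[1] <= target_spikes[2])
  count_at <- function(dc) {
    sp <- base_spec
    sp$dc_nA <- dc
    # an over- or under-driven model can diverge numerically; read the
    # divergence direction as "far too many" or "no" spikes so the bisection
    # backs away from the offending dc
    tryCatch({
      sim <- simulate_neuron(model, make_frozen_noise(sp))
      length(detect_spikes(sim$V_mV, sim$time_ms, threshold_mV)$spike_times_ms)
    }, error = function(e) {
      msg <- conditionMessage(e)
      if (!grepl("integration failure", msg)) stop(e)
      v <- suppressWarnings(as.numeric(sub(".*V = ([-0-9.]+).*", "\\1", msg)))
      if (!is.na(v) && v < 0) 0L else Inf
    })
  }
  lo <- dc_bounds[1]; hi <- dc_bounds[2]
  c_lo <- count_at(lo); c_hi <- count_at(hi)
  if (c_hi < c_lo)
    stop(sprintf(
      "calibration failure: spike count not nondecreasing in dc (%s at %.4g nA, %s at %.4g nA)",
      c_lo, lo, c_hi, hi))
  in_range <- function(ct) ct >= target_spikes[1] && ct <= target_spikes[2]
  done <- function(dc, ct) structure(dc, spike_count = ct)
  if (in_range(c_lo)) return(done(lo, c_lo))
  if (c_lo > target_spikes[2] || c_hi < target_spikes[1])
    stop(sprintf(
      "calibration failure: target [%d, %d] not bracketed (counts %s at %.4g nA, %s at %.4g nA)",
      target_spikes[1], target_spikes[2], c_lo, lo, c_hi, hi))
  best <- if (in_range(c_hi)) done(hi, c_hi) else NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    c_mid <- count_at(mid)
    if (in_range(c_mid) && (is.null(best) || mid < as.numeric(best)))
      best <- done(mid, c_mid)
    if (c_mid < target_spikes[1]) lo <- mid else hi <- mid
    # once a solution is known, keep shrinking toward its lower edge briefly
    if (!is.null(best) && (hi - lo) < 1e-4) return(best)
  }
  if (!is.null(best)) return(best)
  stop(sprintf(
    "calibration failure after %d iterations: counts %s at %.4g nA, %s at %.4g nA",
    max_iter, count_at(dc_bounds[1]), dc_bounds[1], count_at(dc_bounds[2]),
    dc_bounds[2]))
}

#' Write / read a stimulus trace as delimited text
#'
#' Two columns (`time_ms`, `I_nA`) with the generating spec in `#` header
#' comments, so a written stimulus is fully regenerable and round-trips.
#'
#' @param trace A `stimulus_trace`.
#' @param path File path.
#' @return `read_stimulus` returns a `stimulus_trace`.
#' @export
write_stimulus <- function(trace, path) {
  stopifnot(inherits(trace, "stimulus_trace"))
  s <- trace$spec
  hdr <- c(
    "# fdgscape stimulus trace",
    sprintf("# duration_ms=%.17g dt_ms=%.17g sigma_nA=%.17g pulse_width_ms=%.17g dc_nA=%.17g seed=%d",
            s$duration_ms, s$dt_ms, s$sigma_nA, s$pulse_width_ms, s$dc_nA,
            s$seed),
    "time_ms\tI_nA")
  body <- sprintf("%.17g\t%.17g", trace$time_ms, trace$samples)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# .*duration_ms=", lines, value = TRUE)
  kv <- strsplit(strsplit(sub("^# ", "", meta[1]), " ")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  spec <- stimulus_spec(
    duration_ms = as.numeric(vals["duration_ms"]),
    dt_ms = as.numeric(vals["dt_ms"]),
    sigma_nA = as.numeric(vals["sigma_nA"]),
    pulse_width_ms = as.numeric(vals["pulse_width_ms"]),
    dc_nA = as.numeric(vals["dc_nA"]),
    seed = as.integer(as.numeric(vals["seed"])))
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                           sep = "\t")
  structure(list(spec = spec, time_ms = dat$time_ms, samples = dat$I_nA),
            class = "stimulus_trace")
}
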