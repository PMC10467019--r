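#' The standard 1-30 Hz analysis grid
#'
#' Frequencies 1.0, 1.2, ..., 30.0 Hz (146 points, 0.2 Hz steps).
#' @return Numeric vector of length 146.
#' @export
fdg_grid <- function() seq(1, 30, by = 0.2)

new_fdg_curve <- function(freqs, gains, normalized = FALSE,
                          provenance = list()) {
  stopifnot(length(freqs) == length(gains), all(gains >= -1e-12))
  structure(list(freqs_Hz = freqs, gains = pmax(gains, 0),
                 normalized = normalized, provenance = provenance),
            class = "fdg_curve")
}

#' @export
print.fdg_curve <- function(x, ...) {
  pk <- x$freqs_Hz[which.max(x$gains)]
  cat(sprintf("<fdg_curve>%s %d freqs [%g, %g] Hz, max gain %.4g at %.1f Hz\n",
              if (x$normalized) " (normalized)" else "", length(x$freqs_Hz),
              min(x$freqs_Hz), max(x$freqs_Hz), max(x$gains), pk))
  invisible(x)
}

# zero-padded length: smallest multiple of 5 s worth of samples >= n,
# so that native FFT bins land exactly on the 0.2 Hz grid
pad_length <- function(n, dt_ms) {
  for (k in 1:50) {
    np <- round(5000 * k / dt_ms)
    if (abs(np * dt_ms - 5000 * k) > 1e-6)
      stop("dt_ms must divide 5000 ms for exact 0.2 Hz frequency bins")
    if (np >= n) return(np)
  }
  stop("record too long to pad onto the 0.2 Hz grid")
}

fdg_spectra <- function(stim, train) {
  dt <- stim$spec$dt_ms
  n <- length(stim$samples)
  if (n * dt < 1000)
    stop("record shorter than 1 s: insufficient frequency resolution")
  if (length(train$spike_times_ms) == 0L)
    stop("no spikes: cannot estimate a gain")
  r <- rate_series(train, dt)
  if (length(r$values) != n)
    stop("stimulus and spike train must share the record span")
  np <- pad_length(n, dt)
  s0 <- stim$samples - mean(stim$samples)
  S <- stats::fft(c(s0, numeric(np - n)))
  R <- stats::fft(c(r$values, numeric(np - n)))
  list(S = S, R = R, np = np, dt = dt)
}

#' Frequency-dependent gain of a spike train
#'
#' Estimates `G(f) = |C_sr(f)| / |C_ss(f)|`, the magnitude of the stimulus to
#' firing-rate transfer function, on the 1-30 Hz grid at 0.2 Hz steps. The
#' firing-rate series r(t) is built at the stimulus sampling interval; the
#' stimulus is mean-subtracted (removing the DC shift so it cannot leak into
#' the 1 Hz bin after padding) while r(t) is not; correlations use the biased
#' (divide-by-N) convention, computed via FFT on records zero-padded to a
#' multiple of 5 s so native bins land exactly on the grid.
#'
#' Single-realization cross-spectral estimates are inconsistent (the
#' periodogram has 100% pointwise variance and a sparse spike train
#' contributes a broadband incoherent floor), so both spectra are regularized
#' before the ratio is taken. The complex cross-spectrum `C_sr` is smoothed
#' across frequency with a Gaussian kernel (`num_smooth_hz`, the kernel SD;
#' default 0.6 Hz), which averages down the incoherent floor while leaving
#' the smooth coherent transfer function intact. The autospectrum denominator
#' is smoothed with bandwidth `den_smooth_hz`; the default `Inf` replaces it
#' with its mean over the 1-30 Hz band -- for the near-white stimuli this
#' method is built around, the true autospectrum varies by under 3% across
#' the band, so this is the lowest-variance choice. `den_smooth_hz = 0`
#' divides by the raw periodogram and `num_smooth_hz = 0` disables numerator
#' smoothing (together: the literal single-realization formula).
#'
#' @param stim A `stimulus_trace`.
#' @param train A [spike_train()] covering the same record span.
#' @param num_smooth_hz Gaussian SD (Hz) for cross-spectrum smoothing
#'   (default 0.6; 0 disables).
#' @param den_smooth_hz Denominator smoothing bandwidth in Hz (default `Inf`
#'   = band mean).
#' @return An `fdg_curve` with gains in (spikes/s)/nA.
#' @export
compute_fdg <- function(stim, train, num_smooth_hz = 0.6,
                        den_smooth_hz = Inf) {
  sp <- fdg_spectra(stim, train)
  df <- 1000 / (sp$np * sp$dt)
  freqs <- fdg_grid()
  idx <- round(freqs / df) + 1L
  stopifnot(max(abs((idx - 1L) * df - freqs)) < 1e-9)
  Csr_all <- Conj(sp$S) * sp$R / sp$np
  num <- smooth_numerator(Csr_all, idx, df, num_smooth_hz)
  Css_all <- Mod(sp$S)^2 / sp$np
  den <- smooth_denominator(Css_all, idx, df, freqs, den_smooth_hz)
  new_fdg_curve(freqs, num / den,
                provenance = list(n_spikes = length(train$spike_times_ms),
                                  seed = stim$spec$seed,
                                  dc_nA = stim$spec$dc_nA))
}

smooth_numerator <- function(Csr_all, idx, df, num_smooth_hz) {
  if (num_smooth_hz == 0) return(Mod(Csr_all[idx]))
  half <- length(Csr_all) %/% 2
  hw <- max(1L, as.integer(ceiling(3 * num_smooth_hz / df)))
  vapply(idx, function(i) {
    sel <- seq.int(max(2L, i - hw), min(half, i + hw))
    w <- exp(-0.5 * (((sel - i) * df) / num_smooth_hz)^2)
    Mod(sum(w * Csr_all[sel]) / sum(w))
  }, 0)
}

smooth_denominator <- function(Css_all, idx, df, freqs, den_smooth_hz) {
  if (is.infinite(den_smooth_hz)) return(rep(mean(Css_all[idx]), length(idx)))
  if (den_smooth_hz == 0) return(Css_all[idx])
  ext <- as.integer(ceiling(3 * den_smooth_hz / df))
  lo <- max(2L, min(idx) - ext)
  hi <- min(length(Css_all) %/% 2, max(idx) + ext)
  fr <- (seq(lo, hi) - 1) * df
  seg <- Css_all[lo:hi]
  vapply(freqs, function(ff) {
    w <- exp(-0.5 * ((fr - ff) / den_smooth_hz)^2)
    sum(w * seg) / sum(w)
  }, 0)
}

#' Lag- and frequency-domain correlation estimates
#'
#' Returns the biased stimulus-response cross-correlation `c_sr(tau)` and
#' stimulus autocorrelation `c_ss(tau)` together with their Fourier
#' transforms, on the zero-padded lag/frequency axes used by [compute_fdg()].
#'
#' @inheritParams compute_fdg
#' @param max_lag_ms Trim the returned lag axis to `[-max_lag_ms, max_lag_ms]`
#'   (default 500; the full circular axis is rarely useful to inspect).
#' @return A `spectral_estimate` list: `lags_ms`, `c_sr`, `c_ss`, `freqs_Hz`,
#'   `C_sr` (complex), `C_ss` (complex).
#' @export
spectral_estimate <- function(stim, train, max_lag_ms = 500) {
  sp <- fdg_spectra(stim, train)
  np <- sp$np
  Csr_full <- Conj(sp$S) * sp$R / np
  Css_full <- (Mod(sp$S)^2 + 0i) / np
  csr <- Re(stats::fft(Csr_full, inverse = TRUE)) / np
  css <- Re(stats::fft(Css_full, inverse = TRUE)) / np
  kmax <- min(np %/% 2, round(max_lag_ms / sp$dt))
  ord <- c(seq.int(np - kmax + 1L, np), 1L, seq.int(2L, kmax + 1L))
  lags <- seq.int(-kmax, kmax) * sp$dt
  df <- 1000 / (np * sp$dt)
  freqs <- fdg_grid()
  idx <- round(freqs / df) + 1L
  structure(list(lags_ms = lags, c_sr = csr[ord], c_ss = css[ord],
                 freqs_Hz = freqs, C_sr = Csr_full[idx], C_ss = Css_full[idx]),
            class = "spectral_estimate")
}

#' Average an ensemble of FDG curves (multi-noise-realisation design)
#'
#' Pointwise mean of non-normalized single-trial curves, the averaging rule
#' for a deterministic model probed with many distinct noise realisations.
#'
#' @param ensemble An `fdg_ensemble` or list of `fdg_curve`s on one grid.
#' @return An `fdg_curve`.
#' @export
average_fdg_insilico <- function(ensemble) {
  curves <- as_curve_list(ensemble)
  grid <- shared_grid(curves)
  g <- rowMeans(vapply(curves, `[[`, numeric(length(grid)), "gains"))
  new_fdg_curve(grid, g, normalized = all_normalized(curves),
                provenance = list(n_curves = length(curves)))
}

as_curve_list <- function(x) {
  if (inherits(x, "fdg_ensemble")) return(x$curves)
  if (inherits(x, "fdg_curve")) return(list(x))
  stopifnot(is.list(x), length(x) >= 1L,
            all(vapply(x, inherits, TRUE, "fdg_curve")))
  x
}

shared_grid <- function(curves) {
  grid <- curves[[1]]$freqs_Hz
  for (cv in curves)
    if (!isTRUE(all.equal(cv$freqs_Hz, grid)))
      stop("curves must share an identical frequency grid")
  grid
}

all_normalized <- function(curves)
  all(vapply(curves, `[[`, TRUE, "normalized"))

#' Min-max normalize an FDG curve over its grid
#'
#' `(x - min) / (max - min)`; a constant curve is degenerate and errors.
#'
#' @param curve An `fdg_curve`.
#' @return The normalized `fdg_curve` (min 0, max 1 on the grid).
#' @export
normalize_fdg <- function(curve) {
  stopifnot(inherits(curve, "fdg_curve"))
  rng <- range(curve$gains)
  if (diff(rng) <= 0) stop("degenerate curve: constant over the grid")
  curve$gains <- (curve$gains - rng[1]) / diff(rng)
  curve$normalized <- TRUE
  curve
}

#' Average FDG curves with the per-neuron (average-of-averages) dialect
#'
#' For recorded neurons each probed repeatedly with one frozen stimulus:
#' average each neuron's trial curves first, optionally min-max normalize each
#' per-neuron mean, then average across neurons with equal neuron weight.
#'
#' @param curves_by_neuron Named list: one list of `fdg_curve`s per neuron.
#' @param normalize_first Normalize each per-neuron mean before the
#'   cross-neuron average (default `FALSE`).
#' @return An `fdg_curve`.
#' @export
average_fdg_invitro <- function(curves_by_neuron, normalize_first = FALSE) {
  stopifnot(is.list(curves_by_neuron), length(curves_by_neuron) >= 1L)
  per_neuron <- lapply(seq_along(curves_by_neuron), function(i) {
    cv <- average_fdg_insilico(curves_by_neuron[[i]])
    if (normalize_first) {
      cv <- tryCatch(normalize_fdg(cv), error = function(e) {
        id <- names(curves_by_neuron)[i]
        stop(sprintf("neuron %s: %s",
                     if (is.null(id) || id == "") i else id,
                     conditionMessage(e)))
      })
    }
    cv
  })
  average_fdg_insilico(per_neuron)
}

#' Across-trial variability of an FDG ensemble
#'
#' Pointwise across-curve SD (population convention), averaged over a band
#' (`mean_sd`), plus the band maximum of the pointwise SD/mean ratio
#' (`max_cv`).
#'
#' @param ensemble List of >= 2 `fdg_curve`s on one grid, or an
#'   `fdg_ensemble`.
#' @param band_Hz Frequency band `c(lo, hi)` (default the full grid).
#' @return List with `mean_sd` and `max_cv`.
#' @export
fdg_variability <- function(ensemble, band_Hz = c(1, 30)) {
  curves <- as_curve_list(ensemble)
  if (length(curves) < 2L) stop("need >= 2 curves")
  grid <- shared_grid(curves)
  if (band_Hz[1] < min(grid) || band_Hz[2] > max(grid))
    stop("band outside the frequency grid")
  sel <- grid >= band_Hz[1] & grid <= band_Hz[2]
  G <- vapply(curves, `[[`, numeric(length(grid)), "gains")[sel, , drop = FALSE]
  mu <- rowMeans(G)
  sd_pt <- sqrt(rowMeans((G - mu)^2))
  list(mean_sd = mean(sd_pt), max_cv = max(sd_pt / mu))
}

#' Local maxima of an FDG curve above a prominence threshold
#'
#' A grid point is a peak if strictly greater than both neighbours; its
#' prominence is its height minus the higher of the two valley minima found
#' walking outward until terrain exceeding the peak (or the grid edge) is
#' reached.
#'
#' @param curve An `fdg_curve`.
#' @param min_prominence Minimum prominence, in the curve's gain units
#'   (default 0).
#' @return Numeric vector of peak frequencies (Hz), sorted, possibly empty.
#' @export
find_fdg_peaks <- function(curve, min_prominence = 0) {
  g <- curve$gains
  f <- curve$freqs_Hz
  n <- length(g)
  peaks <- 1L + which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n])
  keep <- vapply(peaks, function(i) {
    h <- g[i]
    left <- if (i > 1) g[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) g[seq.int(i + 1, n)] else numeric(0)
    valley <- function(side) {
      higher <- which(side >= h)
      if (length(higher)) min(side[seq_len(min(higher))]) else min(side, h)
    }
    v_l <- valley(rev(left))
    v_r <- valley(right)
    (h - max(v_l, v_r)) >= min_prominence
  }, TRUE)
  f[peaks[keep]]
}

#' Pointwise comparison of two FDG ensembles
#'
#' Per-frequency two-sample Welch t-test with Bonferroni correction over the
#' grid; returns the frequencies whose corrected p-value is below `alpha`.
#'
#' @param ensemble_a,ensemble_b Lists of >= 2 `fdg_curve`s on one grid.
#' @param alpha Familywise significance level (default 0.05).
#' @return Numeric vector of significant frequencies (Hz), possibly empty.
#' @export
compare_pointwise <- function(ensemble_a, ensemble_b, alpha = 0.05) {
  a <- as_curve_list(ensemble_a)
  b <- as_curve_list(ensemble_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 curves per ensemble")
  grid <- shared_grid(c(a, b))
  Ga <- vapply(a, `[[`, numeric(length(grid)), "gains")
  Gb <- vapply(b, `[[`, numeric(length(grid)), "gains")
  p <- vapply(seq_along(grid), function(i) {
    xa <- Ga[i, ]; xb <- Gb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb)$p.value
  }, 0)
  grid[stats::p.adjust(p, method = "bonferroni") < alpha]
}

#' Bundle FDG curves into a labelled ensemble
#'
#' @param curves List of `fdg_curve`s on one shared grid.
#' @param condition Condition label.
#' @return An `fdg_ensemble`.
#' @export
fdg_ensemble <- function(curves, condition = "") {
  curves <- as_curve_list(curves)
  shared_grid(curves)
  structure(list(curves = curves, condition = condition),
            class = "fdg_ensemble")
}

#' @export
print.fdg_ensemble <- function(x, ...) {
  cat(sprintf("<fdg_ensemble> '%s': %d curves on %d-point grid\n",
              x$condition, length(x$curves), length(x$curves[[1]]$freqs_Hz)))
  invisible(x)
}

#' Write / read an FDG curve as two-column delimited text
#'
#' @param curve An `fdg_curve`.
#' @param path File path.
#' @export
write_fdg <- function(curve, path) {
  hdr <- c("# fdgscape FDG curve",
           sprintf("# normalized=%s", curve$normalized),
           "freq_Hz\tgain")
  writeLines(c(hdr, sprintf("%.17g\t%.17g", curve$freqs_Hz, curve$gains)),
             path)
  invisible(path)
}

#' @rdname write_fdg
#' @export
read_fdg <- function(path) {
  lines <- readLines(path)
  norm <- any(grepl("^# normalized=TRUE", lines))
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  new_fdg_curve(dat$freq_Hz, dat$gain, normalized = norm)
}
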