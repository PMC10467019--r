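# Shared fixture builders. Everything is generated in code; tests that need
# simulation use short records and the coarsest dt the integrator accepts.

leak_only_model <- function(g = 0.01, e = -70) {
  model_params(list(channel_spec("leak", gbar = g, e_rev = e)),
               capacitance_nF = 0.1, v_init_mV = e)
}

# a stimulus trace with externally supplied samples (bypasses the generator)
raw_stimulus <- function(samples, dt_ms = 0.5, dc_nA = 0, seed = 1L) {
  n <- length(samples)
  spec <- stimulus_spec(duration_ms = n * dt_ms, dt_ms = dt_ms,
                        sigma_nA = 0, pulse_width_ms = dt_ms, dc_nA = dc_nA,
                        seed = seed)
  structure(list(spec = spec,
                 time_ms = seq(0, by = dt_ms, length.out = n),
                 samples = samples),
            class = "stimulus_trace")
}

# smoothed Gaussian noise matching the frozen-noise construction
test_noise <- function(n, dt_ms, sigma, kernel_ms = 3) {
  kn <- max(1L, round(kernel_ms / dt_ms))
  raw <- rnorm(n + kn - 1L)
  sm <- as.numeric(stats::filter(raw, rep(1 / kn, kn), sides = 1))
  sm <- sm[kn:(n + kn - 1L)]
  sm * sigma / sqrt(mean((sm - mean(sm))^2))
}

# spikes locked to the upward zero crossings of a pure sinusoid at f0 (Hz),
# plus the matching noisy stimulus; used by the phase-locked gain checks
locked_case <- function(f0, duration_ms = 2500, dt_ms = 0.1, amp = 1,
                        sigma = 0.05, seed = 1) {
  set.seed(seed)
  n <- round(duration_ms / dt_ms)
  t_s <- (0:(n - 1)) * dt_ms / 1000
  s <- amp * sin(2 * pi * f0 * t_s) + test_noise(n, dt_ms, sigma)
  tk <- seq(1000 / f0, duration_ms - 1e-9, by = 1000 / f0)
  list(stim = raw_stimulus(s, dt_ms),
       train = spike_train(tk, span_ms = c(0, duration_ms)))
}

# direct-DFT oracle for compute_fdg: same formulas, summation instead of FFT
fdg_oracle <- function(stim, train, num_smooth_hz = 0.6) {
  dt <- stim$spec$dt_ms
  n <- length(stim$samples)
  r <- numeric(n)
  idx <- pmin(floor((train$spike_times_ms - train$span_ms[1]) / dt) + 1L, n)
  r[idx] <- 1 / (dt / 1000)
  np <- n
  k <- 1L
  while (np * dt < 5000 * k || abs(np * dt - 5000 * k) > 1e-6) {
    np <- round(5000 * k / dt)
    if (np >= n) break
    k <- k + 1L
  }
  s0 <- stim$samples - mean(stim$samples)
  df <- 1000 / (np * dt)
  freqs <- fdg_grid()
  i0 <- round(freqs / df) + 1L
  hw <- max(1L, as.integer(ceiling(3 * num_smooth_hz / df)))
  bins <- sort(unique(unlist(lapply(i0, function(i)
    seq.int(max(2L, i - hw), min(np %/% 2, i + hw))))))
  tt <- 0:(n - 1) # only the first n samples are nonzero after padding
  Sb <- vapply(bins, function(b)
    sum(s0 * exp(-2i * pi * (b - 1) * tt / np)), 0i)
  Rb <- vapply(bins, function(b)
    sum(r * exp(-2i * pi * (b - 1) * tt / np)), 0i)
  names(Sb) <- names(Rb) <- bins
  Csr <- Conj(Sb) * Rb / np
  num <- vapply(i0, function(i) {
    sel <- seq.int(max(2L, i - hw), min(np %/% 2, i + hw))
    w <- exp(-0.5 * (((sel - i) * df) / num_smooth_hz)^2)
    Mod(sum(w * Csr[as.character(sel)]) / sum(w))
  }, 0)
  Sg <- vapply(i0, function(b)
    sum(s0 * exp(-2i * pi * (b - 1) * tt / np)), 0i)
  den <- mean(Mod(Sg)^2 / np)
  new_fdg_curve <- get("new_fdg_curve", asNamespace("fdgscape"))
  new_fdg_curve(freqs, num / den)
}

# synthetic fdg_curve from a gain vector
toy_curve <- function(gains, normalized = FALSE) {
  structure(list(freqs_Hz = fdg_grid(), gains = gains,
                 normalized = normalized, provenance = list()),
            class = "fdg_curve")
}

# short human-like simulation shared across tests (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- human_like_model()
      dc <- calibrate_dc(m, stimulus_spec(seed = 1), dc_bounds = c(-0.3, 1.2))
      stim <- make_frozen_noise(stimulus_spec(seed = 1,
                                              dc_nA = as.numeric(dc)))
      cache <<- list(model = m, dc = as.numeric(dc), stim = stim,
                     sim = simulate_neuron(m, stim))
    }
    cache
  }
})
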