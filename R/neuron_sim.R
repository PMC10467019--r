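#' Ionic-channel specification
#'
#' Describes one Hodgkin-Huxley-style conductance: a maximal conductance
#' `gbar` (uS), reversal potential `e_rev` (mV) and up to two first-order
#' gates. Gate steady states are Boltzmann functions
#' `x_inf(V) = 1 / (1 + exp((half - V) / slope))` -- a positive `slope` opens
#' the gate with depolarisation, a negative `slope` with hyperpolarisation
#' (inverted activation, as for the h-current). Voltage-dependent time
#' constants are bell-shaped:
#' `tau(V) = base + amp * exp(-((V - center) / width)^2)` (ms).
#'
#' @param name Channel label (unique within a model).
#' @param gbar Maximal conductance in uS (>= 0).
#' @param e_rev Reversal potential in mV.
#' @param act Activation gate: list with `half`, `slope`, `p` (gate power) and
#'   `tau = c(base, amp, center, width)`; `NULL` for an ohmic (leak) channel.
#' @param inact Optional inactivation gate, same shape, power 1.
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(name, gbar, e_rev, act = NULL, inact = NULL) {
  stopifnot(is.character(name), length(name) == 1L, gbar >= 0)
  check_gate <- function(g, what) {
    if (is.null(g)) return(NULL)
    stopifnot(all(c("half", "slope", "tau") %in% names(g)))
    if (g$slope == 0) stop(sprintf("%s gate of '%s': slope must be nonzero",
                                   what, name))
    g$p <- as.integer(if (is.null(g$p)) 1L else g$p)
    g$tau <- as.numeric(g$tau)
    stopifnot(length(g$tau) == 4L)
    vgrid <- seq(-120, 60, by = 1)
    taus <- g$tau[1] + g$tau[2] * exp(-((vgrid - g$tau[3]) / g$tau[4])^2)
    if (any(taus <= 0))
      stop(sprintf("%s gate of '%s': tau(V) must be > 0 on [-120, 60] mV",
                   what, name))
    g
  }
  structure(list(name = name, gbar = gbar, e_rev = e_rev,
                 act = check_gate(act, "activation"),
                 inact = check_gate(inact, "inactivation")),
            class = "channel_spec")
}

#' Single-compartment model parameters
#'
#' @param channels List of [channel_spec()] objects; exactly one must be named
#'   `"leak"` and names must be unique.
#' @param capacitance_nF Membrane capacitance in nF (> 0).
#' @param v_init_mV Initial voltage (default -70).
#' @param species_preset Label recording which preset built the model
#'   (`"human_like"`, `"rodent_like"` or `"custom"`).
#' @return A `model_params` object.
#' @seealso [human_like_model()], [rodent_like_model()], [scale_channel()]
#' @export
model_params <- function(channels, capacitance_nF = 0.15, v_init_mV = -70,
                         species_preset = "custom") {
  stopifnot(capacitance_nF > 0, length(channels) >= 1L)
  nms <- vapply(channels, function(ch) ch$name, "")
  if (anyDuplicated(nms)) stop("channel names must be unique")
  if (sum(nms == "leak") != 1L)
    stop("exactly one channel must be named 'leak'")
  names(channels) <- nms
  structure(list(capacitance_nF = capacitance_nF, channels = channels,
                 v_init_mV = v_init_mV, species_preset = species_preset),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s preset, C = %.3g nF, %d channels: %s\n",
              x$species_preset, x$capacitance_nF, length(x$channels),
              paste(sprintf("%s(%.4g uS)", names(x$channels),
                            vapply(x$channels, `[[`, 0, "gbar")),
                    collapse = ", ")))
  invisible(x)
}

#' Built-in single-compartment presets
#'
#' A minimal five-conductance neuron generating sodium/potassium spiking plus
#' a slow subthreshold h-current resonance: leak (E = -85 mV), transient
#' sodium (m^3 h, E = +55 mV, with slow recovery from inactivation providing a
#' ~40 ms relative refractory period), fast delayed-rectifier potassium (n^4,
#' E = -85 mV), a slow-inactivating potassium current (E = -85 mV, availability
#' recovering over hundreds of ms, which produces cluster/gap firing under
#' noisy drive), and a hyperpolarization-activated cation current Ih (single
#' inverted-activation gate, E = -45 mV, half-activation -72 mV, slope 7 mV).
#' The two presets differ only in the h-current time constant, which peaks
#' near the subthreshold operating range: ~340 ms for `human_like_model()`,
#' ~34 ms for `rodent_like_model()` (a tenfold kinetic contrast). All
#' parameter values are implementation defaults of this synthetic stand-in,
#' not measurements.
#'
#' @param g_ih Maximal h-conductance in uS (default 0.16).
#' @return A [model_params()] object.
#' @export
human_like_model <- function(g_ih = 0.16) {
  base_model(g_ih, tau_h = c(20, 320, -75, 25), preset = "human_like")
}

#' @rdname human_like_model
#' @export
rodent_like_model <- function(g_ih = 0.16) {
  base_model(g_ih, tau_h = c(2, 32, -75, 25), preset = "rodent_like")
}

base_model <- function(g_ih, tau_h, preset) {
  model_params(
    channels = list(
      channel_spec("leak", gbar = 0.003, e_rev = -85),
      channel_spec("NaT", gbar = 5.0, e_rev = 55,
                   act = list(half = -48, slope = 4.5, p = 3L,
                              tau = c(0.04, 0.08, -48, 20)),
                   inact = list(half = -64, slope = -4.5, p = 1L,
                                tau = c(2, 40, -68, 16))),
      channel_spec("Kfast", gbar = 2.5, e_rev = -85,
                   act = list(half = -34, slope = 6, p = 4L,
                              tau = c(0.5, 2.2, -45, 25))),
      channel_spec("Kslow", gbar = 0.15, e_rev = -85,
                   act = list(half = -50, slope = 6, p = 1L,
                              tau = c(5, 10, -50, 20)),
                   inact = list(half = -70, slope = -7, p = 1L,
                                tau = c(300, 700, -70, 40))),
      channel_spec("Ih", gbar = g_ih, e_rev = -45,
                   act = list(half = -72, slope = -7, p = 1L,
                              tau = tau_h))),
    capacitance_nF = 0.15, v_init_mV = -70, species_preset = preset)
}

#' Scale a channel's maximal conductance
#'
#' @param params A [model_params()].
#' @param name Channel name.
#' @param factor Nonnegative multiplier for `gbar`.
#' @return A copy of `params` with `gbar[name]` scaled.
#' @export
scale_channel <- function(params, name, factor) {
  stopifnot(inherits(params, "model_params"), factor >= 0)
  if (!name %in% names(params$channels))
    stop(sprintf("unknown channel '%s'", name))
  params$channels[[name]]$gbar <- params$channels[[name]]$gbar * factor
  params
}

channels_for_core <- function(params) {
  lapply(unname(params$channels), function(ch)
    list(gbar = ch$gbar, e_rev = ch$e_rev, act = ch$act, inact = ch$inact))
}

#' Simulate the model neuron under a current-clamp stimulus
#'
#' Integrates `C dV/dt = I_inj - sum_c gbar_c m^p h (V - E_c)` with
#' exponential-Euler gate updates and a forward-Euler voltage update, after a
#' settling period at the stimulus DC that is discarded from the returned
#' record. Currents use the convention positive = outward, so the per-step
#' balance `C dV/dt + sum_c I_c = I_inj` holds exactly (forward difference).
#'
#' @param params A [model_params()].
#' @param stim A `stimulus_trace` with `dt_ms <= 0.05`.
#' @param settle_ms Settling period simulated before the record at constant
#'   `dc_nA` and discarded (default 200).
#' @return A `sim_result`: `time_ms`, `V_mV`, matrix `I_nA` (one column per
#'   channel, nA, positive outward), `I_inj_nA`, `dt_ms`, `params`.
#' @export
simulate_neuron <- function(params, stim, settle_ms = 200) {
  stopifnot(inherits(params, "model_params"), inherits(stim, "stimulus_trace"))
  dt <- stim$spec$dt_ms
  if (dt > 0.05) stop("stimulus dt_ms must be <= 0.05 ms for integration")
  n_settle <- as.integer(round(settle_ms / dt))
  i_inj <- c(rep(stim$spec$dc_nA, n_settle), stim$samples)
  out <- .simulate_core(i_inj, dt, params$capacitance_nF, params$v_init_mV,
                        channels_for_core(params))
  keep <- seq.int(n_settle + 1L, length(i_inj))
  I <- out$I[keep, , drop = FALSE]
  colnames(I) <- names(params$channels)
  structure(
    list(time_ms = stim$time_ms, V_mV = out$V[keep], I_nA = I,
         I_inj_nA = stim$samples, dt_ms = dt, params = params,
         stim_spec = stim$spec),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  nsp <- length(detect_spikes(x$V_mV, x$time_ms)$spike_times_ms)
  cat(sprintf(
    "<sim_result> %.6g ms @ dt %.4g ms, V in [%.1f, %.1f] mV, %d spikes (-55 mV), currents: %s\n",
    utils::tail(x$time_ms, 1) + x$dt_ms, x$dt_ms, min(x$V_mV), max(x$V_mV),
    nsp, paste(colnames(x$I_nA), collapse = ", ")))
  invisible(x)
}

#' Passive and excitability fingerprints of a model
#'
#' Resting potential from a zero-input run; input resistance from the steady
#' voltage deflection to a -0.01 nA step; sag ratio
#' `(V_min - V_steady) / (V_min - V_rest)` from a -0.1 nA, 1 s step; rheobase by
#' bisection on 1 s tonic steps to the first spike.
#'
#' @param params A [model_params()].
#' @param dt_ms Integration step (default 0.025).
#' @return List with `rmp_mV`, `input_resistance_MOhm`, `sag_ratio`,
#'   `rheobase_nA`.
#' @export
intrinsic_properties <- function(params, dt_ms = 0.025) {
  run <- function(dc, dur) {
    sp <- stimulus_spec(duration_ms = dur, dt_ms = dt_ms, sigma_nA = 0,
                        pulse_width_ms = dt_ms, dc_nA = dc)
    simulate_neuron(params, make_frozen_noise(sp), settle_ms = 0)
  }
  rest <- run(0, 5000)
  tailseg <- function(sim, frac = 0.1) {
    n <- length(sim$V_mV)
    sim$V_mV[seq.int(n - as.integer(n * frac) + 1L, n)]
  }
  vr_tail <- tailseg(rest)
  if (diff(range(vr_tail)) > 0.05)
    stop("model does not settle to rest within 5 s (oscillatory?)")
  rmp <- mean(vr_tail)
  # input resistance: steady DV to a small hyperpolarising step, settled state
  small <- run(-0.01, 5000)
  r_in <- (mean(tailseg(small)) - rmp) / (-0.01) # mV / nA = MOhm
  # sag: -0.1 nA for 1 s from rest
  sag_sim <- run(-0.1, 1000)
  v_min <- min(sag_sim$V_mV)
  v_steady <- mean(sag_sim$V_mV[seq.int(
    length(sag_sim$V_mV) - as.integer(100 / dt_ms), length(sag_sim$V_mV))])
  sag <- if (abs(v_min - rmp) < 1e-9) 0 else (v_min - v_steady) / (v_min - rmp)
  # rheobase: smallest 1 s tonic step evoking >= 1 spike
  spikes_at <- function(dc) {
    sim <- run(dc, 1000)
    length(detect_spikes(sim$V_mV, sim$time_ms)$spike_times_ms)
  }
  lo <- 0; hi <- 1
  if (spikes_at(hi) == 0) {
    rheo <- NA_real_
  } else {
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (spikes_at(mid) >= 1) hi <- mid else lo <- mid
    }
    rheo <- hi
  }
  list(rmp_mV = rmp, input_resistance_MOhm = r_in, sag_ratio = sag,
       rheobase_nA = rheo)
}
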