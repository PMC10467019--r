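#' Configuration for a multi-trial frozen-noise experiment
#'
#' One condition = one model (a preset plus channel scalings) probed with
#' `n_trials` distinct noise realisations sharing the same statistics; trial i
#' uses seed `base_seed + i`, so conditions built from the same `base_seed`
#' see identical noise (a paired design isolating the conductance effect).
#'
#' @param model A [model_params()] object.
#' @param n_trials Number of noise realisations (default 30).
#' @param base_seed Base seed; trial i uses `base_seed + i`.
#' @param stim Stimulus template, a [stimulus_spec()]; its `dc_nA` and `seed`
#'   are overridden per the dc policy and trial index.
#' @param dc DC policy: `"calibrate"` (bisect to `target_spikes` on the first
#'   trial's noise) or a fixed value in nA.
#' @param dc_bounds Bracket for the calibration bisection in nA
#'   (default `c(-0.7, 1.2)`).
#' @param target_spikes Calibration target range (default `c(12, 15)`).
#' @param ih_scale Scaling factor applied to the `Ih` maximal conductance
#'   (default 1).
#' @param windows_ms STA windows (default `c(30, 100, 200)`).
#' @param condition Condition label (defaults to `"Ih x <scale>"`).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(model, n_trials = 30L, base_seed = 1L,
                              stim = stimulus_spec(), dc = "calibrate",
                              dc_bounds = c(-0.7, 1.2),
                              target_spikes = c(12L, 15L), ih_scale = 1,
                              windows_ms = c(30, 100, 200),
                              condition = NULL) {
  stopifnot(n_trials >= 1L, ih_scale >= 0)
  if (is.null(condition)) condition <- sprintf("Ih x %g", ih_scale)
  structure(
    list(model = model, n_trials = as.integer(n_trials),
         base_seed = as.integer(base_seed), stim = stim, dc = dc,
         dc_bounds = dc_bounds,
         target_spikes = target_spikes, ih_scale = ih_scale,
         windows_ms = windows_ms, condition = condition),
    class = "experiment_config")
}

#' Run one condition of the frozen-noise protocol
#'
#' For each trial: generate the trial's noise, simulate, detect spikes
#' (-55 mV), compute the FDG, the inward/outward percentage decomposition and
#' the per-channel contribution STAs. Aggregates: trial-mean and normalized
#' FDG averages, peak list, pooled-ISI CV, per-channel STA and monotonicity
#' per window, and across-trial variability. Zero-spike trials are flagged and
#' excluded; if more than half are excluded the protocol errors.
#'
#' @param config An [experiment_config()].
#' @param mono_window_ms Window used for the monotonicity quantification
#'   (default 200).
#' @param verbose Print one line per stage (default `FALSE`).
#' @return A `condition_report` (see Details).
#' @details The report carries: `ensemble` (raw `fdg_curve`s), `avg_fdg`,
#'   `avg_fdg_norm` (per-trial normalization then average), `peaks`,
#'   `isi_cv`, `isis` (pooled), `sta` (per window, per channel),
#'   `monotonicity` (per channel at `mono_window_ms`), `variability`,
#'   `spike_counts`, `excluded_trials`, `dc_nA`, `seeds`, `config`.
#' @export
run_protocol <- function(config, mono_window_ms = 200, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  model <- scale_channel(config$model, "Ih", config$ih_scale)
  say <- function(...) if (verbose) message(sprintf(...))
  trial_spec <- function(i, dc) {
    sp <- config$stim
    sp$seed <- config$base_seed + i
    sp$dc_nA <- dc
    sp
  }
  dc <- config$dc
  if (identical(dc, "calibrate")) {
    say("calibrating dc [%s]", config$condition)
    dc <- as.numeric(calibrate_dc(model, trial_spec(1L, 0),
                                  target_spikes = config$target_spikes,
                                  dc_bounds = config$dc_bounds))
  }
  stopifnot(is.numeric(dc))
  say("dc = %.4g nA; running %d trials", dc, config$n_trials)

  trains <- vector("list", config$n_trials)
  curves <- vector("list", config$n_trials)
  pcs <- vector("list", config$n_trials)
  counts <- integer(config$n_trials)
  for (i in seq_len(config$n_trials)) {
    stim <- make_frozen_noise(trial_spec(i, dc))
    sim <- simulate_neuron(model, stim)
    train <- detect_spikes(sim)
    counts[i] <- length(train$spike_times_ms)
    if (counts[i] == 0L) next
    trains[[i]] <- train
    curves[[i]] <- compute_fdg(stim, train)
    pcs[[i]] <- percent_contributions(sim)
  }
  excluded <- which(counts == 0L)
  if (length(excluded) > config$n_trials / 2)
    stop(sprintf("protocol failure: %d of %d trials produced no spikes",
                 length(excluded), config$n_trials))
  ok <- counts > 0L
  trains <- trains[ok]; curves <- curves[ok]; pcs <- pcs[ok]

  ens <- fdg_ensemble(curves, condition = config$condition)
  avg <- average_fdg_insilico(ens)
  avg_norm <- average_fdg_insilico(lapply(curves, normalize_fdg))
  say("averaging done; computing STAs")
  stas <- lapply(config$windows_ms, function(w)
    sta_contributions(pcs, trains, w))
  names(stas) <- paste0("w", config$windows_ms)
  mono_sta <- stas[[paste0("w", mono_window_ms)]]
  if (is.null(mono_sta))
    mono_sta <- sta_contributions(pcs, trains, mono_window_ms)
  mono <- lapply(mono_sta, function(s) {
    if (!inherits(s, "sta_result")) return(s)
    tryCatch(monotonicity(s, polarity = attr(s, "class_label")),
             error = function(e) conditionMessage(e))
  })
  structure(
    list(condition = config$condition,
         ensemble = ens, avg_fdg = avg, avg_fdg_norm = avg_norm,
         peaks = find_fdg_peaks(avg_norm, min_prominence = 0.05),
         isi_cv = isi_cv(trains),
         isis = unlist(lapply(trains, function(tr) diff(tr$spike_times_ms))),
         sta = stas, monotonicity = mono,
         variability = fdg_variability(ens),
         spike_counts = counts, excluded_trials = excluded,
         dc_nA = dc, seeds = config$base_seed + seq_len(config$n_trials),
         config = config),
    class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf(
    "<condition_report> '%s': %d/%d trials, dc %.4g nA, mean %.1f spikes, ISI CV %.3f, peaks @ %s Hz\n",
    x$condition, length(x$ensemble$curves), x$config$n_trials, x$dc_nA,
    mean(x$spike_counts[x$spike_counts > 0]), x$isi_cv,
    if (length(x$peaks)) paste(x$peaks, collapse = ", ") else "none"))
  invisible(x)
}

#' Run the h-conductance battery (paired noise across conditions)
#'
#' Runs [run_protocol()] for each `Ih` scaling factor with identical trial
#' seeds, so that condition differences are attributable to the conductance
#' alone. DC is recalibrated per condition (or fixed values supplied).
#'
#' @param config An [experiment_config()]; its `ih_scale` is overridden.
#' @param factors Ih scaling factors (default `c(0, 0.5, 1, 2)`).
#' @param ... Passed to [run_protocol()].
#' @return Named list of `condition_report`s (names `"ih_x<factor>"`).
#' @export
run_ih_battery <- function(config, factors = c(0, 0.5, 1, 2), ...) {
  reports <- lapply(factors, function(f) {
    cfg <- config
    cfg$ih_scale <- f
    cfg$condition <- sprintf("Ih x %g", f)
    run_protocol(cfg, ...)
  })
  names(reports) <- sprintf("ih_x%g", factors)
  reports
}

#' Compare two condition reports
#'
#' Pointwise ensemble comparison (Bonferroni-corrected t-tests), peak-presence
#' deltas and the two-sample CV test on pooled ISIs.
#'
#' @param report_a,report_b `condition_report`s on the same grid and windows.
#' @return List with `significant_freqs_Hz`, `peaks_a`, `peaks_b`,
#'   `peaks_only_a`, `peaks_only_b`, `cv_a`, `cv_b`, `cv_test`.
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "condition_report"),
            inherits(report_b, "condition_report"))
  shared_grid(c(report_a$ensemble$curves, report_b$ensemble$curves))
  ct <- cv_test(report_a$isis, report_b$isis)
  list(significant_freqs_Hz = compare_pointwise(report_a$ensemble,
                                                report_b$ensemble),
       peaks_a = report_a$peaks, peaks_b = report_b$peaks,
       peaks_only_a = setdiff(report_a$peaks, report_b$peaks),
       peaks_only_b = setdiff(report_b$peaks, report_a$peaks),
       cv_a = report_a$isi_cv, cv_b = report_b$isi_cv,
       cv_test = ct)
}
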