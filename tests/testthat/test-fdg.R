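test_that("compute_fdg matches a direct-DFT oracle on small records", {
  # 1e4-sample record at dt 0.25 ms; noisy stimulus, locked-ish spikes
  set.seed(11)
  n <- 10000L
  dt <- 0.25
  s <- test_noise(n, dt, 0.04)
  stim <- raw_stimulus(s, dt)
  tms <- sort(sample(seq(50, n * dt - 50, by = 10), 18))
  train <- spike_train(tms, span_ms = c(0, n * dt))
  got <- compute_fdg(stim, train)
  want <- fdg_oracle(stim, train)
  expect_lt(max(abs(got$gains - want$gains) / pmax(want$gains, 1e-300)), 1e-6)
})

test_that("gain scales inversely with stimulus amplitude", {
  set.seed(3)
  n <- 5000L
  stim <- raw_stimulus(test_noise(n, 0.5, 0.04) + 0.1, 0.5)
  stim3 <- raw_stimulus(stim$samples * 3, 0.5)
  train <- spike_train(sort(sample(seq(100, 2400, by = 25), 14)),
                       span_ms = c(0, 2500))
  g1 <- compute_fdg(stim, train)
  g3 <- compute_fdg(stim3, train)
  expect_equal(g3$gains, g1$gains / 3, tolerance = 1e-9)
})

test_that("gain is invariant to a common time shift of stimulus and spikes", {
  set.seed(4)
  n <- 5000L
  s <- test_noise(n, 0.5, 0.04)
  s <- s - mean(s) # exact zero mean so demeaning is a no-op in both records
  tms <- sort(sample(seq(400, 2000, by = 20), 12))
  shift_bins <- 600L # 300 ms; the shifted record keeps all content
  g1 <- compute_fdg(raw_stimulus(s, 0.5),
                    spike_train(tms, span_ms = c(0, 2500)))
  g2 <- compute_fdg(raw_stimulus(c(numeric(shift_bins), s), 0.5),
                    spike_train(tms + 300, span_ms = c(0, 2800)))
  expect_lt(max(abs(g1$gains - g2$gains)) / max(g1$gains), 1e-9)
})

test_that("phase-locked spikes put the gain maximum at the drive frequency", {
  for (f0 in c(3, 5.4, 12)) {
    cs <- locked_case(f0, seed = round(f0 * 10))
    g <- compute_fdg(cs$stim, cs$train)
    expect_equal(g$freqs_Hz[which.max(g$gains)], f0, tolerance = 1e-9)
  }
})

test_that("compute_fdg input contract errors are specific", {
  stim <- raw_stimulus(numeric(4000), 0.5)
  expect_error(compute_fdg(stim, spike_train(numeric(0), c(0, 2000))),
               "no spikes")
  short <- raw_stimulus(rnorm(100), 0.5)
  expect_error(compute_fdg(short, spike_train(10, c(0, 50))), "1 s")
})

test_that("ensemble averaging follows the multi-realisation rule", {
  g <- toy_curve(seq(2, 10, length.out = 146))
  expect_equal(average_fdg_insilico(list(g))$gains, g$gains)
  g3 <- toy_curve(3 * g$gains)
  expect_equal(average_fdg_insilico(list(g, g3))$gains, 2 * g$gains)
  # mean lies within the pointwise envelope
  set.seed(5)
  ens <- lapply(1:8, function(i) toy_curve(runif(146, 1, 3)))
  avg <- average_fdg_insilico(ens)
  G <- sapply(ens, `[[`, "gains")
  expect_true(all(avg$gains >= apply(G, 1, min) - 1e-12))
  expect_true(all(avg$gains <= apply(G, 1, max) + 1e-12))
  bad <- toy_curve(g$gains)
  bad$freqs_Hz <- bad$freqs_Hz + 0.1
  expect_error(average_fdg_insilico(list(g, bad)), "grid")
})

test_that("min-max normalization is exact and affine-invariant", {
  g <- toy_curve(seq(2, 10, length.out = 146))
  ng <- normalize_fdg(g)
  expect_identical(range(ng$gains), c(0, 1))
  expect_true(ng$normalized)
  aff <- toy_curve(5 * g$gains + 7)
  expect_equal(normalize_fdg(aff)$gains, ng$gains)
  expect_error(normalize_fdg(toy_curve(rep(2, 146))), "degenerate")
})

test_that("per-neuron averaging weights neurons, not trials", {
  a <- toy_curve(rep(1, 146))
  b <- toy_curve(rep(3, 146))
  one <- average_fdg_invitro(list(n1 = list(a)))
  expect_equal(one$gains, a$gains)
  # neuron 1: one trial at 1; neuron 2: nine trials at 3 -> mean 2, not 2.8
  two <- average_fdg_invitro(list(n1 = list(a), n2 = rep(list(b), 9)))
  expect_equal(two$gains, rep(2, 146))
  expect_error(
    average_fdg_invitro(list(flat = list(toy_curve(rep(2, 146)))),
                        normalize_first = TRUE),
    "flat")
})

test_that("ensemble variability summaries follow the population convention", {
  g <- toy_curve(seq(1, 5, length.out = 146))
  expect_error(fdg_variability(list(g)), ">= 2")
  dup <- fdg_variability(list(g, g))
  expect_equal(dup$mean_sd, 0)
  expect_equal(dup$max_cv, 0)
  # curves g and 3g: pointwise population SD = g, mean = 2g
  v <- fdg_variability(list(g, toy_curve(3 * g$gains)))
  expect_equal(v$mean_sd, mean(g$gains))
  expect_equal(v$max_cv, 0.5)
  expect_error(fdg_variability(list(g, g), band_Hz = c(0.5, 10)), "band")
})

test_that("peak finding handles unimodal, bimodal and prominence filters", {
  f <- fdg_grid()
  uni <- toy_curve(exp(-(f - 3)^2))
  expect_equal(find_fdg_peaks(uni), 3)
  two <- toy_curve(exp(-(f - 3)^2 / 0.5) + 0.8 * exp(-(f - 6)^2 / 0.5))
  expect_equal(find_fdg_peaks(two), c(3, 6))
  expect_equal(find_fdg_peaks(two, min_prominence = 0.9), 3)
  # monotone curve: maxima only at the edge, which is not a local peak
  expect_length(find_fdg_peaks(toy_curve(seq(1, 2, length.out = 146))), 0L)
})

test_that("pointwise ensemble comparison controls and detects", {
  set.seed(9)
  mk_ens <- function(shift_at = NULL) {
    lapply(1:30, function(i) {
      g <- 10 + rnorm(146, sd = 0.5)
      if (!is.null(shift_at)) g[shift_at] <- g[shift_at] + 5 # 10 x sd
      toy_curve(g)
    })
  }
  a <- mk_ens()
  expect_length(compare_pointwise(a, a), 0L)
  idx5 <- which(fdg_grid() == 5)
  b <- mk_ens(shift_at = idx5)
  expect_equal(compare_pointwise(mk_ens(), b), 5)
  expect_error(compare_pointwise(a[1], b), ">= 2")
})

test_that("null ensembles rarely produce significant frequencies", {
  set.seed(10)
  hits <- replicate(120, {
    a <- lapply(1:6, function(i) toy_curve(10 + rnorm(146)))
    b <- lapply(1:6, function(i) toy_curve(10 + rnorm(146)))
    length(compare_pointwise(a, b)) > 0
  })
  expect_lte(mean(hits), 0.07)
})

test_that("spectral estimates satisfy the correlation-domain invariants", {
  set.seed(12)
  stim <- raw_stimulus(test_noise(5000, 0.5, 0.04) + 0.05, 0.5)
  train <- spike_train(sort(sample(seq(100, 2400, 20), 13)),
                       span_ms = c(0, 2500))
  se <- spectral_estimate(stim, train)
  zero_lag <- which(se$lags_ms == 0)
  expect_true(all(se$c_ss[zero_lag] >= abs(se$c_ss) - 1e-12))
  expect_length(se$C_sr, 146)
  # curves round-trip through text
  path <- withr::local_tempfile(fileext = ".tsv")
  curve <- compute_fdg(stim, train)
  write_fdg(curve, path)
  back <- read_fdg(path)
  expect_identical(back$gains, curve$gains)
})
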