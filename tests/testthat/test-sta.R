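test_that("spike isolation keeps only spikes with clean full windows", {
  tr <- spike_train(c(250, 300, 600), span_ms = c(0, 2500))
  expect_equal(isolated_spikes(tr, 200)$spike_times_ms, c(250, 600))
  # incomplete leading window is excluded
  tr2 <- spike_train(100, span_ms = c(0, 2500))
  expect_length(isolated_spikes(tr2, 200)$spike_times_ms, 0L)
  # periodic train at 150 ms ISI: only the first survivor remains
  tr3 <- spike_train(seq(300, 2400, by = 150), span_ms = c(0, 2500))
  expect_equal(isolated_spikes(tr3, 200)$spike_times_ms, 300)
})

test_that("spike isolation is a subset operation, idempotent and nested", {
  set.seed(21)
  tms <- sort(sample(seq(5, 2495, by = 5), 40))
  tr <- spike_train(tms, span_ms = c(0, 2500))
  for (w in c(30, 100, 200)) {
    iso <- isolated_spikes(tr, w)
    expect_true(all(iso$spike_times_ms %in% tms))
    expect_identical(isolated_spikes(iso, w)$spike_times_ms,
                     iso$spike_times_ms)
  }
  # larger window survivors that still have clean data are survivors of the
  # smaller window too
  s200 <- isolated_spikes(tr, 200)$spike_times_ms
  s30 <- isolated_spikes(tr, 30)$spike_times_ms
  expect_true(all(s200 %in% s30))
})

test_that("the STA of a constant signal is that constant with zero spread", {
  tr <- spike_train(c(300, 700, 1100), span_ms = c(0, 2000))
  sta <- sta_signal(rep(4.2, 4000), tr, window_ms = 200, dt_ms = 0.5)
  expect_true(all(sta$mean == 4.2))
  expect_true(all(sta$sd == 0))
  expect_identical(sta$n_spikes, 3L)
  expect_length(sta$mean, 401L)
})

test_that("sinusoid-locked spikes recover the final drive period", {
  f0 <- 5
  dt <- 0.5
  t_ms <- seq(0, by = dt, length.out = 4000)
  sig <- sin(2 * pi * f0 * t_ms / 1000)
  tms <- seq(200, 1800, by = 1000 / f0) # upward zero crossings
  sta <- sta_signal(sig, spike_train(tms, c(0, 2000)), 200, dt)
  want <- sin(2 * pi * f0 * (sta$lag_ms) / 1000) # zero phase at lag 0
  expect_lt(max(abs(sta$mean - want)), 1e-3)
})

test_that("sta_signal is linear in the signal", {
  set.seed(22)
  x <- rnorm(4000)
  y <- rnorm(4000)
  tr <- spike_train(c(300, 800, 1500), span_ms = c(0, 2000))
  sa <- sta_signal(x, tr, 100, 0.5)
  sb <- sta_signal(y, tr, 100, 0.5)
  sc <- sta_signal(2 * x - 3 * y, tr, 100, 0.5)
  expect_equal(sc$mean, 2 * sa$mean - 3 * sb$mean, tolerance = 1e-12)
})

test_that("an unlocked STA stays near the signal mean", {
  set.seed(23)
  trials <- lapply(1:20, function(i) {
    sig <- rnorm(5000)
    tms <- sort(sample(seq(250, 2400, by = 2), 6))
    list(sig = sig, tr = spike_train(tms, c(0, 2500)))
  })
  sta <- sta_signal(lapply(trials, `[[`, "sig"),
                    lapply(trials, `[[`, "tr"), 200, 0.5)
  se <- sta$sd / sqrt(sta$n_trials)
  expect_true(all(abs(sta$mean) <= 3.5 * pmax(se, 1e-3) + 0.75))
  expect_identical(sta$n_trials, 20L)
})

test_that("masked samples are renormalized rather than averaged as values", {
  sig <- c(rep(1, 1000), rep(NA, 10), rep(1, 2990))
  tr <- spike_train(c(502, 900), span_ms = c(0, 2000))
  sta <- sta_signal(sig, tr, 100, 0.5)
  expect_true(all(sta$mean == 1)) # NA window samples dropped, not zeroed
})

test_that("contribution STAs pick the dominant class and flag errors", {
  fix <- shared_sim()
  pc <- percent_contributions(fix$sim)
  tr <- detect_spikes(fix$sim)
  stas <- sta_contributions(pc, tr, 100)
  expect_named(stas, pc$channels)
  s_ih <- stas[["Ih"]]
  expect_s3_class(s_ih, "sta_result")
  expect_identical(attr(s_ih, "class_label"), "inward")
  expect_identical(attr(stas[["Kfast"]], "class_label"), "outward")
  # a channel that never carries current yields an error entry
  sim0 <- fix$sim
  sim0$I_nA <- cbind(sim0$I_nA, dead = 0)
  stas0 <- sta_contributions(percent_contributions(sim0), tr, 100)
  expect_match(stas0[["dead"]], "never defined")
  expect_s3_class(stas0[["Ih"]], "sta_result")
})

test_that("monotonicity of simple shapes is exact", {
  ramp <- seq(0.1, 1, length.out = 50)
  m <- monotonicity(ramp, polarity = "outward", dt_ms = 1)
  expect_identical(m$fraction_increasing, 1)
  expect_identical(m$fraction_decreasing, 0)
  # symmetric triangle: half up, half down, within one smoothing-edge step
  tri <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1])
  mt <- monotonicity(tri, polarity = "outward", dt_ms = 1)
  expect_equal(mt$fraction_increasing, 0.5, tolerance = 0.03)
  expect_equal(mt$fraction_decreasing, 0.5, tolerance = 0.03)
  expect_error(monotonicity(rep(0, 50), polarity = "inward", dt_ms = 1),
               "all-zero")
})

test_that("monotonicity fractions obey the symmetry and scaling laws", {
  set.seed(24)
  for (i in 1:10) {
    x <- abs(cumsum(rnorm(60))) + 1
    m <- monotonicity(x, "outward", dt_ms = 0.5)
    expect_equal(m$fraction_increasing + m$fraction_decreasing +
                   m$fraction_flat, 1, tolerance = 1e-9)
    # positive rescaling leaves fractions unchanged
    m2 <- monotonicity(5 * x, "outward", dt_ms = 0.5)
    expect_identical(m$fraction_increasing, m2$fraction_increasing)
    # reversal swaps increasing and decreasing
    mr <- monotonicity(rev(x), "outward", dt_ms = 0.5)
    expect_equal(mr$fraction_increasing, m$fraction_decreasing)
    expect_equal(mr$fraction_decreasing, m$fraction_increasing)
  }
})

test_that("monotonicity agrees with a direct loop oracle on short traces", {
  oracle <- function(x, span = 5L) {
    n <- length(x)
    half <- (span - 1L) %/% 2L
    sm <- numeric(n)
    for (i in seq_len(n)) {
      h <- min(half, i - 1L, n - i)
      sm[i] <- mean(x[(i - h):(i + h)])
    }
    d <- diff(sm)
    c(inc = sum(d > 0) / (n - 1), dec = sum(d < 0) / (n - 1),
      flat = sum(d == 0) / (n - 1))
  }
  set.seed(25)
  for (i in 1:12) {
    x <- cumsum(rnorm(sample(20:100, 1))) + 10
    x <- x - min(x) + 1
    m <- monotonicity(x, "outward", dt_ms = 1)
    o <- oracle(x)
    expect_identical(m$fraction_increasing, unname(o["inc"]))
    expect_identical(m$fraction_decreasing, unname(o["dec"]))
    expect_identical(m$fraction_flat, unname(o["flat"]))
  }
})

test_that("STA and monotonicity results serialize to text and JSON", {
  tr <- spike_train(c(300, 700), span_ms = c(0, 2000))
  sta <- sta_signal(sin(seq_len(4000) / 50), tr, 100, 0.5)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_sta(sta, p1)
  expect_true(any(grepl("window_ms=100", readLines(p1))))
  m <- monotonicity(sta, "outward")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_monotonicity(m, p2, channel = "x")
  j <- jsonlite::read_json(p2)
  expect_equal(j$fraction_decreasing, m$fraction_decreasing)
})
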