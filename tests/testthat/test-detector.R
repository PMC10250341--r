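# Streaming detector: KDE baseline, near-neighbour refinement, thresholding,
# feature extraction, drift tracking and clog immunity.

make_frame <- function(amp1, ph1 = rep(-0.5, length(amp1)),
                       amp2 = amp1 * 0.8, ph2 = rep(-0.8, length(amp1)),
                       t0 = 0, rate = 5e4) {
  data.frame(time_s = t0 + (seq_along(amp1) - 1) / rate,
             amp_f1 = amp1, phase_f1 = ph1, amp_f2 = amp2, phase_f2 = ph2)
}

test_that("frame baseline is the KDE mode, not the mean", {
  # constant frame
  fr <- make_frame(rep(1e6, 100))
  expect_equal(estimate_frame_baseline(fr)$amp[1], 1e6)
  # 90 samples at A, 10 at 3A: mode must win (a mean would be pulled up 20 %)
  fr <- make_frame(c(rep(1e6, 90), rep(3e6, 10)))
  expect_equal(estimate_frame_baseline(fr)$amp[1], 1e6)
  # Gaussian frame: mode near mu, within 3*sigma/sqrt(n), and matching a
  # dense-grid KDE oracle at the Silverman bandwidth
  set.seed(21)
  x <- rnorm(100, 1e6, 1e3)
  fr <- make_frame(x)
  got <- estimate_frame_baseline(fr)$amp[1]
  expect_lt(abs(got - 1e6), 3 * 1e3 / sqrt(100) * 3)
  h <- bw.nrd0(x)
  expect_lt(abs(got - oracle_kde_peak(x, h)), h / 2)
})

test_that("baseline refinement matches a brute-force k-NN + median oracle", {
  ctl <- detector_control()
  state <- ifcfit:::new_baseline_state(ctl)
  # drifting history A*(1 + 0.001 i)
  amps <- 1e6 * (1 + 0.001 * (1:50))
  for (a in amps)
    state <- refine_baseline(state, list(amp = c(a, 0.8 * a),
                                         phase = c(-0.5, -0.8)))
  new_amp <- 1e6 * 1.052
  state <- refine_baseline(state, list(amp = c(new_amp, 0.8 * new_amp),
                                       phase = c(-0.5, -0.8)))
  hist <- c(amps, new_amp)
  nn <- order(abs(hist - new_amp))[1:5]            # exhaustive nearest search
  expect_equal(state$accuracy$amp[1], median(hist[nn]))
})

test_that("a clog-like step is excluded from the baseline history", {
  ctl <- detector_control()
  state <- ifcfit:::new_baseline_state(ctl)
  for (i in 1:20)
    state <- refine_baseline(state, list(amp = c(1e6, 8e5), phase = c(0, 0)))
  before <- state$accuracy
  state <- refine_baseline(state, list(amp = c(2e6, 1.6e6), phase = c(0, 0)))
  expect_true(state$clogged)
  expect_identical(state$accuracy, before)          # accuracy retained
})

test_that("event runs match the exhaustive run-length oracle", {
  ctl <- detector_control()
  base <- 1e6
  cases <- list(
    flat = rep(0, 100),
    one_pulse = c(rep(0, 40), 0.3 * sin(seq(0, pi, length.out = 20)), rep(0, 40)),
    merged_pair = c(rep(0, 30), rep(0.3, 10), rep(0, 2), rep(0.3, 10), rep(0, 48)),
    split_pair = c(rep(0, 25), rep(0.3, 10), rep(0, 10), rep(0.3, 10), rep(0, 45)),
    too_short = c(rep(0, 50), rep(0.3, 3), rep(0, 47)))
  for (nm in names(cases)) {
    dev <- cases[[nm]]
    stream <- rbind(make_frame(rep(base, 100)),            # priming frame
                    make_frame(base * (1 + dev), t0 = 0.002))
    got <- detect_cells(stream, control = ctl)
    want <- oracle_event_runs(dev > ctl$threshold, ctl$gap_samples,
                              ctl$min_samples)
    expect_equal(nrow(got), nrow(want), info = nm)
  }
  # two transits separated by 2 sub-threshold samples merge; by 10, they split
  merged <- detect_cells(rbind(make_frame(rep(base, 100)),
                               make_frame(base * (1 + cases$merged_pair),
                                          t0 = 0.002)))
  split <- detect_cells(rbind(make_frame(rep(base, 100)),
                              make_frame(base * (1 + cases$split_pair),
                                         t0 = 0.002)))
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
})

test_that("events spanning a frame boundary are stitched", {
  base <- 1e6
  # pulse occupying the last 8 samples of frame 2 and first 8 of frame 3
  f1 <- make_frame(rep(base, 100))
  f2 <- make_frame(base * c(rep(1, 92), rep(1.4, 8)), t0 = 0.002)
  f3 <- make_frame(base * c(rep(1.4, 8), rep(1, 92)), t0 = 0.004)
  got <- detect_cells(rbind(f1, f2, f3))
  expect_equal(nrow(got), 1)
  # 16 samples at equal deviation: tie broken to the earliest -> in frame 2
  expect_lt(got$peak_time, 0.004)
})

test_that("feature vectors carry exactly eight impedance parameters", {
  sim <- simulate_stream(stream_spec(n_cells = 1, duration = 0.1, seed = 6))
  fv <- detect_cells(sim)
  expect_equal(nrow(fv), 1)
  par_cols <- grep("^(peak|base)_(amp|phase)_f[12]$", names(fv), value = TRUE)
  expect_length(par_cols, 8)
  expect_setequal(par_cols,
                  c("peak_amp_f1", "peak_phase_f1", "base_amp_f1", "base_phase_f1",
                    "peak_amp_f2", "peak_phase_f2", "base_amp_f2", "base_phase_f2"))
})

test_that("noiseless features reproduce the sealed circuit and the baseline", {
  spec <- stream_spec(n_cells = 3, duration = 0.2, seed = 8)
  cfg <- acquisition_config(); geom <- geometry_config()
  sim <- simulate_stream(spec, cfg, geom)
  fv <- detect_cells(sim, cfg)
  expect_equal(nrow(fv), 3)
  elems <- intrinsic_to_elements(sim$truth, geom)
  for (i in 1:3) {
    zt1 <- total_impedance(spec$channel, elems[i, ], cfg$f1, geom)
    zt2 <- total_impedance(spec$channel, elems[i, ], cfg$f2, geom)
    expect_equal(fv$peak_amp_f1[i] * exp(1i * fv$peak_phase_f1[i]), zt1,
                 tolerance = 1e-9)
    expect_equal(fv$peak_amp_f2[i] * exp(1i * fv$peak_phase_f2[i]), zt2,
                 tolerance = 1e-9)
  }
  zb1 <- baseline_impedance(spec$channel, cfg$f1)
  expect_equal(fv$base_amp_f1, rep(Mod(zb1), 3), tolerance = 1e-12)
  expect_equal(fv$base_phase_f1, rep(Arg(zb1), 3), tolerance = 1e-12)
})

test_that("noiseless streams are detected with full recall and no false positives", {
  spec <- stream_spec(n_cells = 100, duration = 1, seed = 13)
  sim <- simulate_stream(spec)
  fv <- detect_cells(sim)
  hit <- match_to_truth(fv, sim$truth)
  expect_equal(length(unique(na.omit(hit))), 100)   # recall = 100 %
  expect_equal(sum(is.na(hit)), 0)                  # false positives = 0
})

test_that("recall stays above 99 % with 1 % amplitude noise", {
  spec <- stream_spec(n_cells = 1000, duration = 7.2, noise_sd_amp = 0.01,
                      seed = 14)
  sim <- simulate_stream(spec)
  fv <- detect_cells(sim)
  hit <- match_to_truth(fv, sim$truth)
  expect_gte(length(unique(na.omit(hit))) / 1000, 0.99)
})

test_that("the accuracy baseline tracks slow drift within 0.5 %", {
  spec <- stream_spec(n_cells = 0, duration = 2, baseline_drift = 1e-3)
  cfg <- acquisition_config()
  stream <- render_stream(sample_population(spec), spec, cfg)
  spf <- cfg$samples_per_frame
  ctl <- detector_control()
  state <- ifcfit:::new_baseline_state(ctl)
  worst <- 0
  for (fi in seq_len(nrow(stream) %/% spf)) {
    fr <- stream[((fi - 1) * spf + 1):(fi * spf), ]
    state <- refine_baseline(state, estimate_frame_baseline(fr))
    true_amp <- Mod(baseline_impedance(spec$channel, cfg$f1)) *
      (1 + 1e-3 * fr$time_s[spf])
    worst <- max(worst, abs(state$accuracy$amp[1] - true_amp) / true_amp)
  }
  expect_lt(worst, 0.005)
})

test_that("a 3-frame 2x clog step moves the accuracy baseline by < 1 %", {
  spec <- stream_spec(n_cells = 0, duration = 0.1,
                      clogging = c(0.04, 0.006), clog_factor = 2)
  cfg <- acquisition_config()
  stream <- render_stream(sample_population(spec), spec, cfg)
  fv <- detect_cells(stream, cfg)
  expect_equal(length(attr(fv, "clogged_frames")), 3)
  # replay manually to inspect the accuracy baseline after the clog
  ctl <- detector_control()
  state <- ifcfit:::new_baseline_state(ctl)
  spf <- cfg$samples_per_frame
  base_amp <- Mod(baseline_impedance(spec$channel, cfg$f1))
  for (fi in seq_len(nrow(stream) %/% spf)) {
    fr <- stream[((fi - 1) * spf + 1):(fi * spf), ]
    state <- refine_baseline(state, estimate_frame_baseline(fr))
    expect_lt(abs(state$accuracy$amp[1] - base_amp) / base_amp, 0.01)
  }
})
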