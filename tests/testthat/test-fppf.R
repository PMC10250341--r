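# Grid construction, cached lookup table, and the least-error solver.

small_grid <- function() grid_spec(16L, 8L, 8L, c(1, 4), c(0.2, 0.8), c(1e6, 1e7))

test_that("grid axes are inclusive linear divisions of the ranges", {
  g <- build_grid(grid_spec(2, 2, 2, c(0.5, 1), c(0.1, 1), c(1e6, 2e6)))
  expect_equal(g$csm, c(0.5, 1))
  axes <- build_grid(grid_spec())
  expect_length(axes$csm, 256)
  expect_length(axes$sigma, 128)
  expect_length(axes$rleak, 128)
  expect_equal(axes$csm[c(1, 256)], c(0.5, 5))
  expect_equal(diff(axes$csm), rep(4.5 / 255, 255))
  expect_error(grid_spec(csm_range = c(2, 2)), "min < max")
})

test_that("every cached entry equals a direct forward-model call", {
  geom <- geometry_config(); cfg <- acquisition_config()
  tab <- build_lookup(grid_spec(2, 2, 2, c(1, 2), c(0.3, 0.6), c(1e6, 2e6)),
                      geom, cfg)
  expect_equal(tab$n_entries, 16)                 # 2 freq x 8 circuits
  i <- 0
  for (rl in tab$axes$rleak) for (sg in tab$axes$sigma) for (cs in tab$axes$csm) {
    i <- i + 1
    e <- intrinsic_to_elements(intrinsic_props(cs, sg, rl), geom)
    expect_equal(complex(real = tab$re1[i], imaginary = tab$im1[i]),
                 cell_impedance(e, cfg$f1, geom))
    expect_equal(complex(real = tab$re2[i], imaginary = tab$im2[i]),
                 cell_impedance(e, cfg$f2, geom))
  }
  # idempotent rebuild
  expect_identical(tab, build_lookup(grid_spec(2, 2, 2, c(1, 2), c(0.3, 0.6),
                                               c(1e6, 2e6)), geom, cfg))
  # memory cap refuses before allocating
  expect_error(build_lookup(grid_spec(), max_bytes = 1e6), "GiB")
})

test_that("random lookup entries spot-check against the forward model", {
  geom <- geometry_config(); cfg <- acquisition_config()
  gs <- small_grid()
  tab <- build_lookup(gs, geom, cfg)
  set.seed(31)
  axes <- tab$axes
  for (s in sample(16 * 8 * 8, 200)) {
    i <- (s - 1) %% 16 + 1
    j <- ((s - 1) %/% 16) %% 8 + 1
    k <- (s - 1) %/% (16 * 8) + 1
    e <- intrinsic_to_elements(
      intrinsic_props(axes$csm[i], axes$sigma[j], axes$rleak[k]), geom)
    expect_equal(complex(real = tab$re1[s], imaginary = tab$im1[s]),
                 cell_impedance(e, cfg$f1, geom), tolerance = 1e-15)
  }
})

test_that("feature translation recovers the decoupled cell impedance", {
  geom <- geometry_config(); cfg <- acquisition_config()
  p <- random_props(20, seed = 41)
  fv <- exact_features(p, cfg = cfg, geom = geom)
  elems <- intrinsic_to_elements(p, geom)
  for (i in 1:20) {
    tg <- features_to_target(fv[i, ], cfg)
    expect_false(tg$degenerate)
    expect_equal(tg$z_cell_f1, cell_impedance(elems[i, ], cfg$f1, geom),
                 tolerance = 1e-9)
    expect_equal(tg$z_cell_f2, cell_impedance(elems[i, ], cfg$f2, geom),
                 tolerance = 1e-9)
  }
  # peak = baseline is flagged degenerate
  ch <- default_test_channel()
  zb1 <- baseline_impedance(ch, cfg$f1); zb2 <- baseline_impedance(ch, cfg$f2)
  flat <- data.frame(event_id = 1, peak_time = 0,
                     peak_amp_f1 = Mod(zb1), peak_phase_f1 = Arg(zb1),
                     peak_amp_f2 = Mod(zb2), peak_phase_f2 = Arg(zb2),
                     base_amp_f1 = Mod(zb1), base_phase_f1 = Arg(zb1),
                     base_amp_f2 = Mod(zb2), base_phase_f2 = Arg(zb2))
  expect_true(features_to_target(flat, cfg)$degenerate)
  expect_error(solve_cell(flat, build_lookup(small_grid(), geom, cfg)),
               "degenerate")
})

test_that("noisy feature translation stays within finite-difference bounds", {
  geom <- geometry_config(); cfg <- acquisition_config()
  p <- intrinsic_props(2.5, 0.45, 3e6)
  fv <- exact_features(p, cfg = cfg, geom = geom)
  eps <- 0.01
  # independent first-order sensitivity of z_cell to the f1 peak amplitude
  fd <- function(h) {
    fv2 <- fv; fv2$peak_amp_f1 <- fv$peak_amp_f1 * (1 + h)
    features_to_target(fv2, cfg)$z_cell_f1
  }
  z0 <- features_to_target(fv, cfg)$z_cell_f1
  deriv <- (fd(1e-6) - fd(-1e-6)) / 2e-6
  moved <- fd(eps)
  expect_lt(Mod(moved - (z0 + deriv * eps)), 0.05 * Mod(moved - z0))
})

test_that("the vectorised argmin equals the independent triple-loop oracle", {
  geom <- geometry_config(); cfg <- acquisition_config()
  gs <- small_grid()
  tab <- build_lookup(gs, geom, cfg)
  p <- random_props(100, seed = 17)
  fv <- exact_features(p, cfg = cfg, geom = geom)
  for (i in seq_len(nrow(p))) {
    got <- solve_cell(fv[i, ], tab)
    tg <- features_to_target(fv[i, ], cfg)
    want <- oracle_solve(tg$z_cell_f1, tg$z_cell_f2, gs, geom, cfg)
    expect_equal(unname(got$grid_index), want$idx)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
  }
})

test_that("on-grid circuits are recovered exactly with zero error", {
  geom <- geometry_config(); cfg <- acquisition_config()
  gs <- small_grid()
  tab <- build_lookup(gs, geom, cfg)
  axes <- tab$axes
  set.seed(51)
  for (r in 1:20) {
    idx <- c(sample(16, 1), sample(8, 1), sample(8, 1))
    p <- intrinsic_props(axes$csm[idx[1]], axes$sigma[idx[2]], axes$rleak[idx[3]])
    got <- solve_cell(exact_features(p, cfg = cfg, geom = geom), tab)
    expect_equal(unname(got$grid_index), idx)
    # delta vanishes up to the amp/phase round-trip rounding (~1e-7 of |Z|)
    expect_lt(got$delta, 1e-2)
    expect_equal(got$props, p)
  }
  # boundary flags fire exactly on the axis endpoints
  pb <- intrinsic_props(axes$csm[1], axes$sigma[4], axes$rleak[8])
  fb <- solve_cell(exact_features(pb, cfg = cfg, geom = geom), tab)
  expect_equal(unname(fb$on_boundary), c(TRUE, FALSE, TRUE))
})

test_that("delta is positive for any off-grid circuit", {
  geom <- geometry_config(); cfg <- acquisition_config()
  tab <- build_lookup(small_grid(), geom, cfg)
  p <- random_props(20, seed = 61)
  p$C_sm <- p$C_sm + 0.013          # guaranteed off the 0.2-spaced axis
  fv <- exact_features(p, cfg = cfg, geom = geom)
  for (i in 1:20) expect_gt(solve_cell(fv[i, ], tab)$delta, 0)
})

test_that("the traditional per-cell solver is bit-identical to the cached path", {
  geom <- geometry_config(); cfg <- acquisition_config()
  gs <- small_grid()
  tab <- build_lookup(gs, geom, cfg)
  p <- random_props(50, seed = 71)
  fv <- exact_features(p, cfg = cfg, geom = geom)
  for (i in seq_len(nrow(p))) {
    fast <- solve_cell(fv[i, ], tab)
    slow <- solve_cell_traditional(fv[i, ], gs, geom, cfg)
    expect_identical(fast$grid_index, slow$grid_index)
    expect_identical(fast$delta, slow$delta)       # 0 ulp: same doubles
    expect_identical(fast$props, slow$props)
  }
})

test_that("batch solving is order-preserving and isolates bad events", {
  geom <- geometry_config(); cfg <- acquisition_config()
  tab <- build_lookup(small_grid(), geom, cfg)
  p <- random_props(10, seed = 81)
  fv <- exact_features(p, cfg = cfg, geom = geom)
  one <- solve_cell(fv[1, ], tab)
  batch <- solve_batch(fv, tab)
  expect_identical(batch[[1]], one)
  # permuting inputs permutes outputs identically
  perm <- c(3, 1, 2, 10, 4:9)
  expect_identical(solve_batch(fv[perm, ], tab), batch[perm])
  # a degenerate event yields an error record, not an abort
  ch <- default_test_channel()
  zb1 <- baseline_impedance(ch, cfg$f1); zb2 <- baseline_impedance(ch, cfg$f2)
  fv_bad <- fv
  fv_bad[5, c("peak_amp_f1", "peak_phase_f1", "peak_amp_f2", "peak_phase_f2")] <-
    c(Mod(zb1), Arg(zb1), Mod(zb2), Arg(zb2))
  got <- solve_batch(fv_bad, tab)
  expect_false(is.null(got[[5]]$error))
  expect_identical(got[[6]], batch[[6]])
})

test_that("noiseless off-grid recovery: median within one step, all bounded", {
  # Characterised behaviour of the discrete least-error fit (see the methods
  # vignette): most cells land on the truth-adjacent grid point, but the
  # shallow sigma/R_leak trade-off direction leaves a minority further away.
  geom <- geometry_config(); cfg <- acquisition_config()
  set.seed(91)
  n <- 200
  props <- intrinsic_props(rlnorm(n, log(2.6), 0.15), rlnorm(n, log(0.4), 0.15),
                           rlnorm(n, log(3e6), 0.3))
  gs <- grid_spec_from_sample(props, 64L, 32L, 32L)
  tab <- build_lookup(gs, geom, cfg)
  fv <- exact_features(props, cfg = cfg, geom = geom)
  step <- grid_steps(gs)
  err <- t(vapply(seq_len(n), function(i) {
    r <- solve_cell(fv[i, ], tab)
    abs(unlist(r$props) - unlist(props[i, ])) / step
  }, numeric(3)))
  worst <- apply(err, 1, max)
  expect_gte(mean(worst <= 1), 0.6)
  expect_true(all(worst <= 25))
  expect_lte(median(worst), 1.5)
  expect_lte(median(err[, 1]), 1)        # C_sm alone: median within one step
})

test_that("with 1 % noise the median C_sm error stays within 3 grid steps", {
  spec <- stream_spec(n_cells = 300, duration = 2.3, noise_sd_amp = 0.01,
                      noise_sd_phase = 0.002, seed = 15)
  cfg <- acquisition_config(); geom <- geometry_config()
  sim <- simulate_stream(spec, cfg, geom)
  fv <- detect_cells(sim, cfg)
  gs <- grid_spec_from_sample(sim$truth, 32L, 16L, 16L)
  fit <- ifc_fit(fv, grid = gs, geometry = geom, acquisition = cfg)
  hit <- match_to_truth(fit$properties, sim$truth)
  ok <- !is.na(hit)
  err <- abs(fit$properties$C_sm[ok] - sim$truth$C_sm[hit[ok]]) /
    grid_steps(gs)["csm"]
  expect_lte(median(err), 3)
})
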