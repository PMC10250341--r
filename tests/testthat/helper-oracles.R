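# Independent oracles and fixture builders used across the suite.
# Each oracle is written as plainly as possible and never calls the package
# code path it is used to check.

# --- nodal-analysis oracle -------------------------------------------------
# Full circuit solved as a linear system on node voltages with an explicit
# admittance matrix (1 A injected at the measurement node):
#   node 1 --C_p-- gnd, node 1 --R_ch-- node 2,
#   node 2 --R_leak-- gnd, node 2 --[n/(jwC_m)]-- node 3, node 3 --R_cyto-- gnd
oracle_total_impedance <- function(R_ch, C_p, C_m, R_cyto, R_leak, n_mem, f) {
  w <- 2 * pi * f
  y_cp <- 1i * w * C_p
  y_rch <- 1 / R_ch
  y_leak <- 1 / R_leak
  y_mem <- (1i * w * C_m) / n_mem        # the n_mem series caps as one element
  y_cyto <- 1 / R_cyto
  Y <- matrix(0i, 3, 3)
  Y[1, 1] <- y_cp + y_rch
  Y[1, 2] <- Y[2, 1] <- -y_rch
  Y[2, 2] <- y_rch + y_leak + y_mem
  Y[2, 3] <- Y[3, 2] <- -y_mem
  Y[3, 3] <- y_mem + y_cyto
  v <- solve(Y, c(1 + 0i, 0i, 0i))
  v[1]
}

# cell branch alone (same nodal style, 2 internal nodes collapse to 2x2)
oracle_cell_impedance <- function(C_m, R_cyto, R_leak, n_mem, f) {
  w <- 2 * pi * f
  y_leak <- 1 / R_leak
  y_mem <- (1i * w * C_m) / n_mem
  y_cyto <- 1 / R_cyto
  Y <- matrix(0i, 2, 2)
  Y[1, 1] <- y_leak + y_mem
  Y[1, 2] <- Y[2, 1] <- -y_mem
  Y[2, 2] <- y_mem + y_cyto
  v <- solve(Y, c(1 + 0i, 0i))
  v[1]
}

# --- brute-force KDE oracle ------------------------------------------------
# Gaussian KDE maximised on a dense 10 000-point grid.
oracle_kde_peak <- function(x, h) {
  g <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 10000)
  dens <- vapply(g, function(gi) sum(stats::dnorm((gi - x) / h)), numeric(1))
  g[which.max(dens)]
}

# --- exhaustive run-length oracle ------------------------------------------
# events = maximal supra-threshold runs, merged if separated by < gap
# sub-threshold samples, then dropped if shorter than min_len
oracle_event_runs <- function(mask, gap, min_len) {
  runs <- list()
  i <- 1
  while (i <= length(mask)) {
    if (mask[i]) {
      j <- i
      while (j < length(mask) && mask[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(matrix(integer(), 0, 2))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 < gap) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  m <- do.call(rbind, merged)
  m[m[, 2] - m[, 1] + 1 >= min_len, , drop = FALSE]
}

# --- triple-loop argmin oracle ----------------------------------------------
# Independent least-error search: explicit loops, fresh forward-model calls,
# no vectorisation, no cache.
oracle_solve <- function(z1_target, z2_target, spec, geom, cfg) {
  axes <- build_grid(spec)
  best <- Inf
  best_idx <- c(NA, NA, NA)
  for (k in seq_along(axes$rleak))
    for (j in seq_along(axes$sigma))
      for (i in seq_along(axes$csm)) {
        e <- intrinsic_to_elements(
          data.frame(C_sm = axes$csm[i], sigma_cyto = axes$sigma[j],
                     R_leak = axes$rleak[k]), geom)
        zm1 <- cell_impedance(e, cfg$f1, geom)
        zm2 <- cell_impedance(e, cfg$f2, geom)
        d <- abs(Re(zm1) - Re(z1_target)) + abs(Im(zm1) - Im(z1_target)) +
          abs(Re(zm2) - Re(z2_target)) + abs(Im(zm2) - Im(z2_target))
        if (d < best) {           # strict <: first (smallest flat) index wins
          best <- d
          best_idx <- c(i, j, k)
        }
      }
  list(delta = best, idx = best_idx)
}

# --- fixture builders -------------------------------------------------------

default_test_channel <- function() channel_params(R_ch = 1e6, C_p = 1e-12)

# noiseless feature vector synthesised directly from the forward model at
# full sealing (peak) and the empty channel (baseline)
exact_features <- function(props, ch = default_test_channel(),
                           cfg = acquisition_config(),
                           geom = geometry_config()) {
  elems <- intrinsic_to_elements(props, geom)
  zb1 <- baseline_impedance(ch, cfg$f1)
  zb2 <- baseline_impedance(ch, cfg$f2)
  zt1 <- total_impedance(ch, elems, cfg$f1, geom)
  zt2 <- total_impedance(ch, elems, cfg$f2, geom)
  data.frame(event_id = seq_len(nrow(props)), peak_time = seq_len(nrow(props)),
             peak_amp_f1 = Mod(zt1), peak_phase_f1 = Arg(zt1),
             peak_amp_f2 = Mod(zt2), peak_phase_f2 = Arg(zt2),
             base_amp_f1 = Mod(zb1), base_phase_f1 = Arg(zb1),
             base_amp_f2 = Mod(zb2), base_phase_f2 = Arg(zb2))
}

# random positive intrinsic properties inside the default population regime
random_props <- function(n, seed) {
  set.seed(seed)
  intrinsic_props(C_sm = runif(n, 1, 4), sigma_cyto = runif(n, 0.2, 0.8),
                  R_leak = runif(n, 1e6, 1e7))
}

# match detected events back to ground-truth transits by peak time
match_to_truth <- function(fit_props, truth) {
  vapply(fit_props$peak_time, function(tp) {
    w <- which(tp >= truth$arrival_time &
                 tp <= truth$arrival_time + truth$transit_duration)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
}

grid_steps <- function(gs) {
  axes <- build_grid(gs)
  c(csm = diff(axes$csm[1:2]), sigma = diff(axes$sigma[1:2]),
    rleak = diff(axes$rleak[1:2]))
}
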