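# Seeded two-frequency stream generator with known ground truth.
# Plays the role of the instrument in every end-to-end test: a drifting
# empty-channel baseline, raised-cosine transit pulses rendered from the full
# equivalent circuit, additive noise, and optional clogging episodes.

with_seed <- function(seed, expr) {
  # run expr under a fixed RNG state, restoring the caller's state afterwards
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic impedance stream
#'
#' Describes a simulated acquisition: how many cells transit in how long a
#' stream, the empty-channel circuit, baseline drift and noise levels, the
#' log-normal population the intrinsic properties are drawn from, and an
#' optional clogging episode. Property defaults emulate an epithelial-like
#' population with specific membrane capacitance peaking near 2.6 uF/cm^2 and
#' cytoplasm conductivity near 0.4 S/m, with mega-ohm seal leaks.
#'
#' @param n_cells Number of cell transits to place (>= 0).
#' @param duration Stream duration in seconds.
#' @param channel A [channel_params()] for the empty channel.
#' @param baseline_drift Relative multiplicative baseline drift per second
#'   (dimensionless, e.g. 0.001 = 0.1 %/s).
#' @param noise_sd_amp Relative (multiplicative) Gaussian amplitude noise SD.
#' @param noise_sd_phase Additive Gaussian phase noise SD, rad.
#' @param props_meanlog,props_sdlog Named numeric vectors
#'   (`C_sm`, `sigma_cyto`, `R_leak`) giving the log-normal location and scale
#'   of each intrinsic property (units uF/cm^2, S/m, Ohm).
#' @param transit_range Range of transit durations, seconds; each cell's
#'   transit is drawn uniformly from it.
#' @param clogging `NULL`, or `c(start, duration)` in seconds: a step shift of
#'   the baseline emulating temporary channel clogging.
#' @param clog_factor Multiplicative baseline step applied during clogging.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `"stream_spec"`.
#' @export
stream_spec <- function(n_cells = 100L, duration = 1,
                        channel = channel_params(R_ch = 1e6, C_p = 1e-12),
                        baseline_drift = 0,
                        noise_sd_amp = 0, noise_sd_phase = 0,
                        props_meanlog = c(C_sm = log(2.6), sigma_cyto = log(0.4),
                                          R_leak = log(3e6)),
                        props_sdlog = c(C_sm = 0.15, sigma_cyto = 0.15,
                                        R_leak = 0.3),
                        transit_range = c(4e-4, 8e-4),
                        clogging = NULL, clog_factor = 2,
                        seed = 1L) {
  stopifnot(n_cells >= 0, duration > 0, noise_sd_amp >= 0, noise_sd_phase >= 0,
            all(transit_range > 0), length(transit_range) == 2,
            transit_range[1] <= transit_range[2])
  nm <- c("C_sm", "sigma_cyto", "R_leak")
  stopifnot(all(nm %in% names(props_meanlog)), all(nm %in% names(props_sdlog)),
            all(props_sdlog[nm] >= 0))
  if (!is.null(clogging)) stopifnot(length(clogging) == 2, all(clogging >= 0))
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 channel = channel, baseline_drift = baseline_drift,
                 noise_sd_amp = noise_sd_amp, noise_sd_phase = noise_sd_phase,
                 props_meanlog = props_meanlog[nm], props_sdlog = props_sdlog[nm],
                 transit_range = transit_range, clogging = clogging,
                 clog_factor = clog_factor, seed = as.integer(seed)),
            class = "stream_spec")
}

#' Draw a ground-truth cell population
#'
#' Samples `n_cells` cells with independent log-normal intrinsic properties
#' and places their transits in the stream without overlap, leaving a guard
#' gap of two frame durations around each event and after the stream start
#' (the detector's first frame only primes its baseline).
#'
#' @param spec A [stream_spec()].
#' @param cfg An [acquisition_config()] (frame timing for guard gaps).
#' @return A data.frame (`event_id`, `arrival_time`, `transit_duration`,
#'   `C_sm`, `sigma_cyto`, `R_leak`) sorted by arrival time.
#' @export
sample_population <- function(spec, cfg = acquisition_config()) {
  if (spec$n_cells == 0L)
    return(data.frame(event_id = integer(), arrival_time = numeric(),
                      transit_duration = numeric(), C_sm = numeric(),
                      sigma_cyto = numeric(), R_leak = numeric()))
  with_seed(spec$seed, {
    n <- spec$n_cells
    props <- lapply(c("C_sm", "sigma_cyto", "R_leak"), function(p)
      stats::rlnorm(n, spec$props_meanlog[[p]], spec$props_sdlog[[p]]))
    names(props) <- c("C_sm", "sigma_cyto", "R_leak")
    transit <- stats::runif(n, spec$transit_range[1], spec$transit_range[2])
    guard <- 2 * cfg$frame_duration
    t0 <- 2 * cfg$frame_duration             # keep events out of the priming frame
    usable <- spec$duration - t0 - guard
    occupied <- transit + guard
    free <- usable - sum(occupied)
    if (free < 0)
      stop(sprintf("duration %g s too short to place %d non-overlapping events",
                   spec$duration, n))
    # uniform non-overlapping placement: spread the free time between events
    u <- sort(stats::runif(n)) * free
    arrival <- t0 + u + c(0, cumsum(occupied))[seq_len(n)]
    data.frame(event_id = seq_len(n), arrival_time = arrival,
               transit_duration = transit,
               C_sm = props$C_sm, sigma_cyto = props$sigma_cyto,
               R_leak = props$R_leak)
  })
}

# raised-cosine transit envelope over L samples, exactly 1 at the centre
transit_envelope <- function(L) {
  if (L == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
}

#' Render a ground-truth population into a demodulated impedance stream
#'
#' Outside events every sample is the empty-channel impedance (with
#' multiplicative drift and, during a clogging episode, a step shift). During
#' a transit the sample is a raised-cosine interpolation *in admittance
#' space* between the drifted empty channel and the fully sealed circuit of
#' that cell, so the envelope peak equals [total_impedance()] exactly. The
#' transit window is snapped to the sample grid with an odd sample count so
#' one sample lies exactly at full sealing. Gaussian noise is then applied
#' (relative on amplitudes, additive on phases).
#'
#' @param truth Population data.frame from [sample_population()].
#' @param spec A [stream_spec()].
#' @param cfg An [acquisition_config()].
#' @param geom A [geometry_config()].
#' @return A data.frame with columns `time_s`, `amp_f1`, `phase_f1`,
#'   `amp_f2`, `phase_f2`, one row per sample; the number of rows is a whole
#'   number of frames.
#' @export
render_stream <- function(truth, spec, cfg = acquisition_config(),
                          geom = geometry_config()) {
  n_frames <- ceiling(spec$duration / cfg$frame_duration)
  n <- n_frames * cfg$samples_per_frame
  t <- (seq_len(n) - 1) / cfg$sample_rate
  drift <- 1 + spec$baseline_drift * t
  if (!is.null(spec$clogging)) {
    in_clog <- t >= spec$clogging[1] & t < spec$clogging[1] + spec$clogging[2]
    drift[in_clog] <- drift[in_clog] * spec$clog_factor
  }
  z <- list()
  for (f in c(f1 = cfg$f1, f2 = cfg$f2)) {
    zb <- baseline_impedance(spec$channel, f) * drift
    if (nrow(truth) > 0) {
      elems <- intrinsic_to_elements(truth, geom)
      zt <- total_impedance(spec$channel, elems, f, geom)
      for (i in seq_len(nrow(truth))) {
        s0 <- round(truth$arrival_time[i] * cfg$sample_rate) + 1
        L <- round(truth$transit_duration[i] * cfg$sample_rate)
        if (L %% 2 == 0) L <- L + 1
        idx <- s0:min(s0 + L - 1, n)
        w <- transit_envelope(L)[seq_along(idx)]
        zb[idx] <- 1 / ((1 - w) / zb[idx] + w / zt[i])
      }
    }
    z[[length(z) + 1]] <- zb
  }
  amp1 <- Mod(z[[1]]); ph1 <- Arg(z[[1]])
  amp2 <- Mod(z[[2]]); ph2 <- Arg(z[[2]])
  if (spec$noise_sd_amp > 0 || spec$noise_sd_phase > 0) {
    with_seed(spec$seed + 1L, {
      if (spec$noise_sd_amp > 0) {
        amp1 <- amp1 * (1 + stats::rnorm(n, 0, spec$noise_sd_amp))
        amp2 <- amp2 * (1 + stats::rnorm(n, 0, spec$noise_sd_amp))
      }
      if (spec$noise_sd_phase > 0) {
        ph1 <- ph1 + stats::rnorm(n, 0, spec$noise_sd_phase)
        ph2 <- ph2 + stats::rnorm(n, 0, spec$noise_sd_phase)
      }
    })
  }
  data.frame(time_s = t, amp_f1 = amp1, phase_f1 = ph1,
             amp_f2 = amp2, phase_f2 = ph2)
}

#' Simulate a complete stream with its ground truth
#'
#' Convenience wrapper: [sample_population()] then [render_stream()].
#'
#' @inheritParams render_stream
#' @return A list of class `"ifc_stream"` with elements `stream` (sample
#'   data.frame), `truth` (population data.frame), `spec`, `cfg`, `geom`.
#' @export
#' @examples
#' sim <- simulate_stream(stream_spec(n_cells = 3, duration = 0.1, seed = 7))
#' nrow(sim$truth)
simulate_stream <- function(spec, cfg = acquisition_config(),
                            geom = geometry_config()) {
  truth <- sample_population(spec, cfg)
  stream <- render_stream(truth, spec, cfg, geom)
  structure(list(stream = stream, truth = truth, spec = spec, cfg = cfg,
                 geom = geom), class = "ifc_stream")
}

#' @export
print.ifc_stream <- function(x, ...) {
  cat(sprintf("Synthetic impedance stream: %d samples (%.3f s), %d cell transits\n",
              nrow(x$stream), x$spec$duration, nrow(x$truth)))
  invisible(x)
}
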