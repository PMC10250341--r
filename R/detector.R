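# Streaming per-frame cell detector.
#
# Each 2 ms frame is reduced to a "potential" baseline by Gaussian kernel
# density estimation (the KDE mode is robust to the minority of samples that
# belong to a transit pulse). A near-neighbour comparison against the history
# of recent potential baselines yields the "accuracy" baseline actually used
# for thresholding, which makes the threshold immune to temporary clogging
# steps while still tracking slow drift. Events are maximal supra-threshold
# runs on the f1 amplitude; eight impedance parameters (peak and baseline
# amplitude and phase at both frequencies) are read out per event.

#' Detector control parameters
#'
#' @param threshold Relative amplitude deviation at `f1` that a sample must
#'   exceed to be part of an event (default 0.10 = 10 %).
#' @param min_samples Minimum run length in samples; shorter runs are noise.
#' @param gap_samples Runs separated by fewer than this many sub-threshold
#'   samples are merged into one event.
#' @param k_neighbors Number of nearest historical baselines used for the
#'   accuracy baseline.
#' @param history Length of the potential-baseline ring buffer (frames).
#' @param tol_clog Relative deviation of a frame's potential baseline from
#'   the history median beyond which the frame is treated as clogged and
#'   excluded from the history.
#' @return An object of class `"detector_control"`.
#' @export
detector_control <- function(threshold = 0.10, min_samples = 5L,
                             gap_samples = 3L, k_neighbors = 5L,
                             history = 50L, tol_clog = 0.20) {
  stopifnot(threshold > 0, min_samples >= 1, gap_samples >= 0,
            k_neighbors >= 1, history >= 1, tol_clog > 0)
  structure(list(threshold = threshold, min_samples = as.integer(min_samples),
                 gap_samples = as.integer(gap_samples),
                 k_neighbors = as.integer(k_neighbors),
                 history = as.integer(history), tol_clog = tol_clog),
            class = "detector_control")
}

# Gaussian KDE mode evaluated at the sample points (Silverman bandwidth).
kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  h <- stats::bw.nrd0(x)
  if (!is.finite(h) || h <= 0) return(stats::median(x))
  d <- outer(x, x, "-") / h
  dens <- colSums(exp(-0.5 * d * d))   # unnormalised Gaussian KDE at x
  x[which.max(dens)]
}

circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# circular median: unwrap around the circular mean, then ordinary median.
# Robust to the minority of transit-pulse samples that fall inside the
# baseline amplitude window.
circular_median <- function(theta) {
  mu <- circular_mean(theta)
  d <- atan2(sin(theta - mu), cos(theta - mu))
  mu + stats::median(d)
}

#' Potential baseline of one data frame
#'
#' Per frequency, the baseline amplitude is the sample value maximising a
#' Gaussian kernel density estimate (Silverman bandwidth) evaluated at the
#' sample points — the distribution mode, robust against transit pulses in
#' the frame. The baseline phase is the circular median of the phases of
#' samples within one bandwidth of that amplitude.
#'
#' @param frame Data.frame with columns `amp_f1`, `phase_f1`, `amp_f2`,
#'   `phase_f2` (one data frame's samples).
#' @return Named list with `amp` and `phase`, each a length-2 vector (f1, f2).
#' @export
estimate_frame_baseline <- function(frame) {
  stopifnot(nrow(frame) > 0)
  amp <- phase <- numeric(2)
  for (j in 1:2) {
    a <- frame[[c("amp_f1", "amp_f2")[j]]]
    p <- frame[[c("phase_f1", "phase_f2")[j]]]
    m <- kde_mode(a)
    h <- if (length(unique(a)) > 1L) stats::bw.nrd0(a) else 0
    near <- if (h > 0) abs(a - m) <= h else rep(TRUE, length(a))
    if (!any(near)) near <- abs(a - m) == min(abs(a - m))
    amp[j] <- m
    phase[j] <- circular_median(p[near])
  }
  list(amp = amp, phase = phase)
}

new_baseline_state <- function(control) {
  list(hist_amp = matrix(numeric(0), ncol = 2),
       hist_phase = matrix(numeric(0), ncol = 2),
       accuracy = NULL, control = control)
}

#' Refine the accuracy baseline with a new frame's potential baseline
#'
#' The accuracy baseline at each frequency is the median amplitude (and
#' circular median phase) of the `k` historical potential baselines nearest in
#' amplitude to the new one. If the new potential baseline deviates from the
#' history median by more than `tol_clog` (relative, judged on the f1
#' amplitude), a temporary clog is suspected: the frame is excluded from the
#' history and the previous accuracy baseline is retained.
#'
#' @param state Baseline state as carried by [detect_cells()]; the first call
#'   seeds the history with the frame's own potential baseline.
#' @param potential Output of [estimate_frame_baseline()].
#' @return The updated state, with elements `accuracy` (list `amp`, `phase`)
#'   and `clogged` (logical flag for this frame).
#' @export
refine_baseline <- function(state, potential) {
  ctl <- state$control
  state$clogged <- FALSE
  if (nrow(state$hist_amp) == 0L) {
    state$hist_amp <- matrix(potential$amp, ncol = 2)
    state$hist_phase <- matrix(potential$phase, ncol = 2)
    state$accuracy <- potential
    return(state)
  }
  med <- stats::median(state$hist_amp[, 1])
  if (abs(potential$amp[1] - med) / med > ctl$tol_clog) {
    state$clogged <- TRUE            # clog suspected: keep previous accuracy
    return(state)
  }
  state$hist_amp <- rbind(state$hist_amp, potential$amp)
  state$hist_phase <- rbind(state$hist_phase, potential$phase)
  if (nrow(state$hist_amp) > ctl$history) {
    keep <- seq(nrow(state$hist_amp) - ctl$history + 1L, nrow(state$hist_amp))
    state$hist_amp <- state$hist_amp[keep, , drop = FALSE]
    state$hist_phase <- state$hist_phase[keep, , drop = FALSE]
  }
  amp <- phase <- numeric(2)
  for (j in 1:2) {
    d <- abs(state$hist_amp[, j] - potential$amp[j])
    nn <- order(d)[seq_len(min(ctl$k_neighbors, length(d)))]
    amp[j] <- stats::median(state$hist_amp[nn, j])
    phase[j] <- circular_median(state$hist_phase[nn, j])
  }
  state$accuracy <- list(amp = amp, phase = phase)
  state
}

# maximal runs of TRUE in a logical vector -> matrix [start, end]
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# merge runs separated by < gap samples, drop runs shorter than min_len
merge_and_filter_runs <- function(runs, gap, min_len) {
  if (nrow(runs) == 0L) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, "start"] - merged[nrow(merged), "end"] - 1L < gap)
      merged[nrow(merged), "end"] <- runs[i, "end"]
    else merged <- rbind(merged, runs[i, , drop = FALSE])
  }
  merged[merged[, "end"] - merged[, "start"] + 1L >= min_len, , drop = FALSE]
}

#' Detect cell transits and extract their feature vectors from a stream
#'
#' Processes the stream frame by frame in arrival order, exactly as a
#' real-time front end would: estimate the frame's potential baseline by KDE,
#' refine the accuracy baseline against the history (clog rejection), then
#' threshold the relative f1 amplitude deviation. Supra-threshold runs
#' shorter than `min_samples` are discarded, runs separated by fewer than
#' `gap_samples` sub-threshold samples are merged, and runs touching a frame
#' boundary are stitched with the following frame. The first frame only
#' primes the baseline history, and frames rejected as clogged emit no
#' events (a blocked channel has no transits). For each event, eight impedance parameters
#' are extracted: amplitude and phase of the peak and of the baseline at both
#' frequencies, all peak values read at the single sample with maximal
#' relative f1 amplitude deviation (earliest sample on a tie).
#'
#' @param stream Sample data.frame (`time_s`, `amp_f1`, `phase_f1`, `amp_f2`,
#'   `phase_f2`) or an `"ifc_stream"` object from [simulate_stream()].
#' @param cfg An [acquisition_config()] (frame geometry).
#' @param control A [detector_control()].
#' @return A data.frame of class `"ifc_features"`, one row per detected
#'   event: `event_id`, `peak_time`, the four peak features and the four
#'   baseline features. Attribute `n_frames` carries the number of frames
#'   processed and `clogged_frames` the indices of frames rejected as clogs.
#' @export
#' @examples
#' sim <- simulate_stream(stream_spec(n_cells = 2, duration = 0.1, seed = 3))
#' detect_cells(sim)
detect_cells <- function(stream, cfg = acquisition_config(),
                         control = detector_control()) {
  if (inherits(stream, "ifc_stream")) stream <- stream$stream
  need <- c("time_s", "amp_f1", "phase_f1", "amp_f2", "phase_f2")
  stopifnot(all(need %in% names(stream)))
  spf <- cfg$samples_per_frame
  n_frames <- nrow(stream) %/% spf
  state <- new_baseline_state(control)
  events <- list()
  clogged <- integer(0)
  pending <- NULL    # open run from previous frame: global sample indices
  for (fi in seq_len(n_frames)) {
    idx <- ((fi - 1L) * spf + 1L):(fi * spf)
    frame <- stream[idx, ]
    pot <- estimate_frame_baseline(frame)
    first <- is.null(state$accuracy)
    state <- refine_baseline(state, pot)
    if (state$clogged) {
      # no thresholding in a clogged frame: a blocked channel has no transits
      clogged <- c(clogged, fi)
      pending <- NULL
      next
    }
    if (first) next                       # priming frame: no detection yet
    base <- state$accuracy
    dev <- abs(frame$amp_f1 - base$amp[1]) / base$amp[1]
    mask <- dev > control$threshold
    runs <- true_runs(mask)
    open_tail <- nrow(runs) > 0 && runs[nrow(runs), "end"] == spf
    if (!is.null(pending)) {
      if (nrow(runs) > 0 && runs[1, "start"] == 1L) {
        # event continues across the frame boundary: stitch
        pending <- c(pending, idx[seq_len(runs[1, "end"])])
        runs <- runs[-1, , drop = FALSE]
        if (open_tail && nrow(runs) == 0L) next   # still open
      }
      if (length(pending) >= control$min_samples)
        events[[length(events) + 1L]] <- list(samples = pending, state = base)
      pending <- NULL
    }
    runs <- merge_and_filter_runs(runs, control$gap_samples,
                                  if (open_tail) 1L else control$min_samples)
    if (open_tail && nrow(runs) > 0 && runs[nrow(runs), "end"] == spf) {
      pending <- idx[runs[nrow(runs), "start"]:spf]
      runs <- runs[-nrow(runs), , drop = FALSE]
    }
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= control$min_samples,
                 , drop = FALSE]
    for (ri in seq_len(nrow(runs)))
      events[[length(events) + 1L]] <-
        list(samples = idx[runs[ri, "start"]:runs[ri, "end"]], state = base)
  }
  if (!is.null(pending) && length(pending) >= control$min_samples)
    events[[length(events) + 1L]] <- list(samples = pending,
                                          state = state$accuracy)
  fv <- lapply(seq_along(events), function(i)
    extract_features(stream[events[[i]]$samples, ], events[[i]]$state,
                     event_id = i))
  out <- if (length(fv)) do.call(rbind, fv) else empty_features()
  structure(out, class = c("ifc_features", "data.frame"),
            n_frames = n_frames, clogged_frames = clogged)
}

empty_features <- function() {
  data.frame(event_id = integer(), peak_time = numeric(),
             peak_amp_f1 = numeric(), peak_phase_f1 = numeric(),
             peak_amp_f2 = numeric(), peak_phase_f2 = numeric(),
             base_amp_f1 = numeric(), base_phase_f1 = numeric(),
             base_amp_f2 = numeric(), base_phase_f2 = numeric())
}

#' Extract the eight impedance parameters of one event
#'
#' The peak sample is the event sample with maximal relative amplitude
#' deviation from the accuracy baseline at f1 (ties: earliest sample); all
#' four peak values are read at that one sample so they form self-consistent
#' complex impedances. The four baseline values are the accuracy baseline in
#' force when the event completed.
#'
#' @param event_samples Data.frame of the event's samples (same columns as
#'   the stream).
#' @param baseline Accuracy baseline, a list with `amp` and `phase` length-2
#'   vectors as produced by [refine_baseline()].
#' @param event_id Integer id stamped on the output row.
#' @return One-row data.frame with `event_id`, `peak_time` and the eight
#'   impedance parameters.
#' @export
extract_features <- function(event_samples, baseline, event_id = 1L) {
  stopifnot(nrow(event_samples) > 0)
  dev <- abs(event_samples$amp_f1 - baseline$amp[1]) / baseline$amp[1]
  k <- which.max(dev)                    # which.max takes the earliest tie
  data.frame(event_id = as.integer(event_id),
             peak_time = event_samples$time_s[k],
             peak_amp_f1 = event_samples$amp_f1[k],
             peak_phase_f1 = event_samples$phase_f1[k],
             peak_amp_f2 = event_samples$amp_f2[k],
             peak_phase_f2 = event_samples$phase_f2[k],
             base_amp_f1 = baseline$amp[1], base_phase_f1 = baseline$phase[1],
             base_amp_f2 = baseline$amp[2], base_phase_f2 = baseline$phase[2])
}

#' @export
print.ifc_features <- function(x, ...) {
  cat(sprintf("Cell feature vectors: %d events from %d frames (%d clog-rejected)\n",
              nrow(x), attr(x, "n_frames") %||% NA_integer_,
              length(attr(x, "clogged_frames"))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
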