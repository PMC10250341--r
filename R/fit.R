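#' Fit intrinsic electrical properties for a set of detected cells
#'
#' The package's central fitting function. Takes the feature vectors emitted
#' by [detect_cells()] and fits each cell's specific membrane capacitance,
#' cytoplasm conductivity and leak resistance by least-error search over a
#' linear parameter grid, using either the cached lookup table (`method =
#' "fppf"`, built once and reused for every cell) or the per-cell
#' recomputation reference (`method = "traditional"`). Both methods evaluate
#' the identical objective on the identical grid and return identical fits;
#' they differ only in schedule.
#'
#' @param features Feature data.frame from [detect_cells()] (or any
#'   data.frame with the same eight impedance columns plus `event_id`,
#'   `peak_time`).
#' @param grid A [grid_spec()].
#' @param geometry A [geometry_config()].
#' @param acquisition An [acquisition_config()].
#' @param method `"fppf"` (cached lookup, the fast path) or `"traditional"`
#'   (per-cell recomputation, the reference).
#' @param lookup Optionally a prebuilt [build_lookup()] table (method
#'   `"fppf"` only); must match `grid`, `geometry` and `acquisition`.
#' @return An object of class `"ifc_fit"` with components
#'   \describe{
#'     \item{properties}{data.frame: `event_id`, `peak_time`, `C_sm`
#'       (uF/cm^2), `sigma_cyto` (S/m), `R_leak` (Ohm), `delta` (Ohm),
#'       `i`, `j`, `k`, boundary flags, fitted per-event `R_ch`, `C_p`.}
#'     \item{errors}{data.frame of events that failed to fit.}
#'     \item{grid, geometry, acquisition, method}{the fit configuration.}
#'   }
#' @seealso [coef.ifc_fit()], [summary.ifc_fit()], [plot.ifc_fit()]
#' @export
#' @examples
#' sim <- simulate_stream(stream_spec(n_cells = 3, duration = 0.2, seed = 2))
#' fv <- detect_cells(sim)
#' fit <- ifc_fit(fv, grid = grid_spec(32, 16, 16))
#' coef(fit)
ifc_fit <- function(features, grid = grid_spec(),
                    geometry = geometry_config(),
                    acquisition = acquisition_config(),
                    method = c("fppf", "traditional"), lookup = NULL) {
  method <- match.arg(method)
  t0 <- proc.time()[["elapsed"]]
  if (method == "fppf") {
    if (is.null(lookup)) lookup <- build_lookup(grid, geometry, acquisition)
    else if (!identical(lookup$spec, grid) ||
             !identical(lookup$geom, geometry) ||
             !identical(lookup$cfg, acquisition))
      stop("supplied lookup table was built for a different configuration")
    res <- solve_batch(features, lookup)
  } else {
    res <- lapply(seq_len(nrow(features)), function(i)
      tryCatch(solve_cell_traditional(features[i, ], grid, geometry, acquisition),
               error = function(e) list(error = conditionMessage(e),
                                        event_id = features$event_id[i] %||% i)))
  }
  ok <- !vapply(res, function(r) !is.null(r$error), logical(1))
  rows <- lapply(which(ok), function(i) {
    r <- res[[i]]
    data.frame(event_id = features$event_id[i], peak_time = features$peak_time[i],
               C_sm = r$props$C_sm, sigma_cyto = r$props$sigma_cyto,
               R_leak = r$props$R_leak, delta = r$delta,
               i = r$grid_index[["i"]], j = r$grid_index[["j"]],
               k = r$grid_index[["k"]],
               on_boundary_csm = r$on_boundary[["csm"]],
               on_boundary_sigma = r$on_boundary[["sigma"]],
               on_boundary_rleak = r$on_boundary[["rleak"]],
               R_ch = r$channel$R_ch, C_p = r$channel$C_p)
  })
  props <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), peak_time = numeric(), C_sm = numeric(),
               sigma_cyto = numeric(), R_leak = numeric(), delta = numeric(),
               i = integer(), j = integer(), k = integer(),
               on_boundary_csm = logical(), on_boundary_sigma = logical(),
               on_boundary_rleak = logical(), R_ch = numeric(), C_p = numeric())
  errs <- if (any(!ok))
    data.frame(event_id = vapply(res[!ok], function(r) as.integer(r$event_id),
                                 integer(1)),
               message = vapply(res[!ok], function(r) r$error, character(1)))
  else data.frame(event_id = integer(), message = character())
  structure(list(properties = props, errors = errs, grid = grid,
                 geometry = geometry, acquisition = acquisition,
                 method = method,
                 elapsed_s = proc.time()[["elapsed"]] - t0,
                 n_events = nrow(features)),
            class = "ifc_fit")
}

#' @export
print.ifc_fit <- function(x, ...) {
  cat(sprintf("Least-error circuit fit (%s solver)\n",
              if (x$method == "fppf") "cached-grid" else "traditional per-cell"))
  cat(sprintf("  %d events: %d fitted, %d errored; grid %d x %d x %d\n",
              x$n_events, nrow(x$properties), nrow(x$errors),
              x$grid$n_csm, x$grid$n_sigma, x$grid$n_rleak))
  if (nrow(x$properties)) {
    cat(sprintf("  C_sm  median %.2f uF/cm^2, sigma_cyto median %.2f S/m, R_leak median %.2f MOhm\n",
                stats::median(x$properties$C_sm),
                stats::median(x$properties$sigma_cyto),
                stats::median(x$properties$R_leak) / 1e6))
  }
  invisible(x)
}

#' Per-cell fitted properties as a matrix
#'
#' @param object An `"ifc_fit"`.
#' @param ... Unused.
#' @return Numeric matrix, one row per fitted cell, columns `C_sm`
#'   (uF/cm^2), `sigma_cyto` (S/m), `R_leak` (Ohm).
#' @export
coef.ifc_fit <- function(object, ...) {
  m <- as.matrix(object$properties[, c("C_sm", "sigma_cyto", "R_leak")])
  rownames(m) <- object$properties$event_id
  m
}

#' Fit residuals (least-error objective values)
#'
#' @param object An `"ifc_fit"`.
#' @param ... Unused.
#' @return Numeric vector of per-cell `delta` values (Ohm).
#' @export
residuals.ifc_fit <- function(object, ...) {
  stats::setNames(object$properties$delta, object$properties$event_id)
}

#' @export
summary.ifc_fit <- function(object, ...) {
  p <- object$properties
  s <- list(method = object$method, n_fitted = nrow(p),
            n_errored = nrow(object$errors),
            grid = object$grid,
            quartiles = if (nrow(p)) apply(
              p[, c("C_sm", "sigma_cyto", "R_leak", "delta")], 2,
              stats::quantile, probs = c(0.25, 0.5, 0.75)) else NULL,
            n_on_boundary = if (nrow(p)) sum(p$on_boundary_csm |
                                             p$on_boundary_sigma |
                                             p$on_boundary_rleak) else 0L,
            elapsed_s = object$elapsed_s,
            ms_per_cell = if (nrow(p)) 1000 * object$elapsed_s / nrow(p) else NA)
  class(s) <- "summary.ifc_fit"
  s
}

#' @export
print.summary.ifc_fit <- function(x, ...) {
  cat(sprintf("Least-error circuit fit summary (%s)\n", x$method))
  cat(sprintf("  events fitted: %d (errored: %d, on a grid boundary: %d)\n",
              x$n_fitted, x$n_errored, x$n_on_boundary))
  if (!is.null(x$quartiles)) {
    cat("  quartiles:\n")
    print(signif(x$quartiles, 4))
  }
  cat(sprintf("  throughput: %.2f ms/cell (%.2f s total, informational)\n",
              x$ms_per_cell, x$elapsed_s))
  invisible(x)
}

#' Scatter plot of fitted intrinsic properties
#'
#' Plots cytoplasm conductivity against specific membrane capacitance, one
#' point per cell, optionally with quadrant gating lines.
#'
#' @param x An `"ifc_fit"`.
#' @param gate Optional [quadrant_gate()]; drawn as dotted lines with the
#'   quadrant proportions annotated.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ifc_fit <- function(x, gate = NULL, ...) {
  p <- x$properties
  graphics::plot(p$sigma_cyto, p$C_sm,
                 xlab = expression(sigma[cyto] ~ "(S/m)"),
                 ylab = expression(C[sm] ~ (mu * F / cm^2)),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  if (!is.null(gate)) {
    graphics::abline(v = gate$sigma_threshold, h = gate$csm_threshold,
                     lty = 3, col = "purple")
    q <- quadrant_proportions(p$C_sm, p$sigma_cyto, gate)
    usr <- graphics::par("usr")
    pos <- rbind(c(usr[2], usr[4]), c(usr[1], usr[4]),
                 c(usr[1], usr[3]), c(usr[2], usr[3]))
    for (qi in 1:4)
      graphics::text(pos[qi, 1], pos[qi, 2],
                     sprintf("Q%d: %.1f%%", qi, 100 * q[qi]),
                     adj = c(ifelse(pos[qi, 1] == usr[2], 1.1, -0.1),
                             ifelse(pos[qi, 2] == usr[4], 1.5, -0.5)))
  }
  invisible(x)
}
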