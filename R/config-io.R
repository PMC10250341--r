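# Flat YAML serialisation of the configuration objects, keyed exactly by
# their field names, so a run is reproducible from its config file.

# strip classes and turn named vectors into maps so YAML keeps the names
flatten_cfg <- function(x) {
  if (is.list(x)) lapply(unclass(x), flatten_cfg)
  else if (!is.null(names(x)) && length(x) > 1) as.list(x)
  else x
}

config_classes <- c(acquisition = "acquisition_config",
                    channel = "channel_params",
                    geometry = "geometry_config",
                    grid = "grid_spec",
                    detector = "detector_control",
                    fcnn = "fcnn_config",
                    stream = "stream_spec")

#' Write configuration objects to a YAML file
#'
#' @param ... Named configuration objects (any of [acquisition_config()],
#'   [channel_params()], [geometry_config()], [grid_spec()],
#'   [detector_control()], [fcnn_config()], [stream_spec()]); names must be
#'   among `acquisition`, `channel`, `geometry`, `grid`, `detector`, `fcnn`,
#'   `stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(acquisition = acquisition_config(), path = f)
#' read_config(f)$acquisition
write_config <- function(..., path) {
  objs <- list(...)
  stopifnot(length(objs) > 0, !is.null(names(objs)),
            all(names(objs) %in% names(config_classes)))
  writeLines(yaml::as.yaml(lapply(objs, flatten_cfg)), path)
  invisible(path)
}

#' Read configuration objects from a YAML file
#'
#' Reconstructs typed configuration objects (with full validation) from a
#' file written by [write_config()].
#'
#' @param path YAML file path.
#' @return Named list of configuration objects.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(all(names(raw) %in% names(config_classes)))
  out <- list()
  for (nm in names(raw)) {
    x <- raw[[nm]]
    out[[nm]] <- switch(nm,
      acquisition = acquisition_config(x$f1, x$f2, x$frame_duration, x$sample_rate),
      channel = channel_params(x$R_ch, x$C_p),
      geometry = geometry_config(x$contact_area, x$cyto_cell_constant,
                                 x$n_membranes),
      grid = grid_spec(x$n_csm, x$n_sigma, x$n_rleak,
                       unlist(x$csm_range), unlist(x$sigma_range),
                       unlist(x$rleak_range)),
      detector = detector_control(x$threshold, x$min_samples, x$gap_samples,
                                  x$k_neighbors, x$history, x$tol_clog),
      fcnn = fcnn_config(unlist(x$hidden), x$lr, x$batch_size, x$epochs,
                         x$momentum, x$val_fraction, x$seed),
      stream = stream_spec(x$n_cells, x$duration,
                           channel_params(x$channel$R_ch, x$channel$C_p),
                           x$baseline_drift, x$noise_sd_amp, x$noise_sd_phase,
                           unlist(x$props_meanlog), unlist(x$props_sdlog),
                           unlist(x$transit_range),
                           if (is.null(x$clogging)) NULL else unlist(x$clogging),
                           x$clog_factor, x$seed))
  }
  out
}
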