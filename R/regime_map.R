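#' Classify the model discharge at one conductance-balance point
#'
#' Sets `gNaP` and `gCAN` on a base parameter set, simulates, and runs the
#' discharge classifier.  Deterministic: repeated calls give the same
#' label.
#'
#' @param gnap,gcan maximal conductances, nS (both >= 0).
#' @param base base `model_parameters`.
#' @param cfg a [classifier_config()].
#' @param duration_s,discard_s,I_app,rtol,atol simulation settings passed
#'   to [simulate()].
#' @return a `discharge_classification` (see [classify_discharge()]).
#' @export
classify_point <- function(gnap, gcan, base = model_parameters(),
                           cfg = classifier_config(), duration_s = 46,
                           discard_s = 6, I_app = 0, rtol = 1e-8,
                           atol = 1e-10) {
  if (gnap < 0 || gcan < 0) stop("conductances must be >= 0")
  p <- base
  p$gNaP <- gnap
  p$gCAN <- gcan
  tr <- simulate(p, duration_s = duration_s, discard_s = discard_s,
                 I_app = I_app, rtol = rtol, atol = atol,
                 keep_states = FALSE)
  classify_discharge(tr, cfg)
}

#' One-dimensional conductance sweeps
#'
#' `sweep_gcan()` holds `gNaP` at 2.5 nS and varies `gCAN` (default 0 to
#' 4.5 nS); `sweep_gnap()` holds `gCAN` at 1.5 nS and varies `gNaP`
#' (default 0 to 5 nS).
#'
#' @param gnap,gcan the held conductance, nS.
#' @param values swept conductance grid, nS.
#' @param ... passed to [classify_point()].
#' @return data frame with the swept value, `label`, `burst_frequency`,
#'   `mean_dp_duration`, `mean_dp_amplitude` and `n_events`.
#' @export
sweep_gcan <- function(gnap = 2.5, values = seq(0, 4.5, by = 0.25), ...) {
  .sweep(gnap = rep(gnap, length(values)), gcan = values,
         swept = "gcan", ...)
}

#' @rdname sweep_gcan
#' @export
sweep_gnap <- function(gcan = 1.5, values = seq(0, 5, by = 0.25), ...) {
  .sweep(gnap = values, gcan = rep(gcan, length(values)),
         swept = "gnap", ...)
}

.sweep <- function(gnap, gcan, swept, ...) {
  rows <- lapply(seq_along(gnap), function(i) {
    cl <- classify_point(gnap[i], gcan[i], ...)
    data.frame(gnap = gnap[i], gcan = gcan[i], label = cl$label,
               n_events = nrow(cl$events),
               burst_frequency = cl$burst_frequency,
               mean_dp_duration = cl$mean_dp_duration,
               mean_dp_amplitude = cl$mean_dp_amplitude)
  })
  out <- do.call(rbind, rows)
  attr(out, "swept") <- swept
  out
}

#' Discharge-regime map over the gNaP x gCAN plane
#'
#' Evaluates [classify_point()] on the full grid (default: gNaP 0 to 3 nS
#' and gCAN 0 to 4.5 nS in 0.25 nS steps).  Points are independent, so the
#' map does not depend on evaluation order; a solver failure at one point
#' is recorded as `indeterminate` rather than aborting the map.
#'
#' @param gnap_values,gcan_values grid axes, nS.
#' @param base base `model_parameters`.
#' @param cfg a [classifier_config()].
#' @param ... further arguments for [classify_point()].
#' @return object of class `regime_map`: long-format data frame (one row
#'   per grid point) with `gnap`, `gcan`, `label` and burst statistics.
#' @export
compute_regime_map <- function(gnap_values = seq(0, 3, by = 0.25),
                               gcan_values = seq(0, 4.5, by = 0.25),
                               base = model_parameters(),
                               cfg = classifier_config(), ...) {
  if (!length(gnap_values) || !length(gcan_values))
    stop("empty conductance grid")
  grid <- expand.grid(gnap = gnap_values, gcan = gcan_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- tryCatch(
      classify_point(grid$gnap[i], grid$gcan[i], base = base, cfg = cfg, ...),
      error = function(e) NULL)
    if (is.null(cl))
      return(data.frame(gnap = grid$gnap[i], gcan = grid$gcan[i],
                        label = "indeterminate", n_events = NA_integer_,
                        burst_frequency = NA_real_,
                        mean_dp_duration = NA_real_,
                        mean_dp_amplitude = NA_real_))
    data.frame(gnap = grid$gnap[i], gcan = grid$gcan[i], label = cl$label,
               n_events = nrow(cl$events),
               burst_frequency = cl$burst_frequency,
               mean_dp_duration = cl$mean_dp_duration,
               mean_dp_amplitude = cl$mean_dp_amplitude)
  })
  out <- do.call(rbind, rows)
  attr(out, "gnap_values") <- gnap_values
  attr(out, "gcan_values") <- gcan_values
  class(out) <- c("regime_map", "data.frame")
  out
}

#' Export a regime map as long-format TSV
#' @param map a `regime_map` (or sweep data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a sweep's labels to the ordered sequence of distinct regimes
#'
#' Drops `indeterminate` points and collapses consecutive duplicates,
#' giving the band order along the sweep (e.g. oscillatory, mixed,
#' plateau).
#'
#' @param labels character vector of labels along the sweep.
#' @return character vector of the distinct bands in order.
#' @export
regime_band_order <- function(labels) {
  keep <- labels[labels != "indeterminate"]
  keep[c(TRUE, keep[-1] != keep[-length(keep)])]
}
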