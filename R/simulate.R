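# Fixed layout of the parameter vector handed to the compiled right-hand
# side; must match the #define block in src/model.c.
.rhs_param_order <- c(
  "Cm", "gNaP", "gNa", "gK", "gL", "gCAN", "gCa", "gh",
  "VNaP", "VNa", "VK", "VL", "VCa", "Vh",
  "vm", "sm", "vh", "sh", "tau_h_bar", "vm_na", "sm_na",
  "vn", "sn", "tau_n_bar", "KCAN",
  "lam", "fi", "Vi", "sigma", "IP3", "A", "Kd", "KI", "Ka",
  "LIP3R", "PIP3R", "VSERCA", "KSERCA", "alpha", "VPMCA", "KPMCA",
  "flux_scale")

.rhs_parms <- function(p, I_app = 0, clamp = FALSE) {
  v <- vapply(p[.rhs_param_order], as.numeric, numeric(1))
  c(v, I_app = I_app, clamp = as.numeric(clamp),
    as_printed = as.numeric(identical(p$spiking_mode, "as_printed")))
}

#' Default initial state
#'
#' A hyperpolarized resting start: `V = -60` mV with the gates at their
#' steady state for that voltage, cytosolic calcium at 0.05 uM, the IP3
#' gate at its fixed point `Kd / (ca_i + Kd)`, and total calcium consistent
#' with a loaded ER near 10 uM.
#'
#' @param p a `model_parameters` object.
#' @param ca_er initial ER calcium, uM.
#' @return a [model_state()] vector.
#' @export
default_initial_state <- function(p, ca_er = 10) {
  ca_i <- 0.05
  model_state(V = -60,
              h = gate_steady_state(-60, p$vh, p$sh),
              n = gate_steady_state(-60, p$vn, p$sn),
              ca_i = ca_i,
              ca_tot = ca_i + p$sigma * ca_er,
              l = p$Kd / (ca_i + p$Kd),
              sigma = p$sigma)
}

#' Integrate the model and return a sampled voltage trace
#'
#' Runs the stiff-capable adaptive `lsoda` integrator over `duration_s`
#' seconds of model time, drops the initial transient (default 6 s), and
#' returns the remainder sampled every `dt_out_ms` (default 0.5 ms, fine
#' enough to resolve action potentials).  The default 46 s run therefore
#' yields 40 s of analyzable trace.  The run is deterministic: identical
#' inputs give identical traces.
#'
#' @param p a `model_parameters` object.
#' @param init initial state; defaults to [default_initial_state()].
#' @param duration_s total simulated model time, s; must exceed `discard_s`.
#' @param dt_out_ms output sampling interval, ms.
#' @param I_app constant applied current, pA.
#' @param discard_s initial transient to discard, s.
#' @param rtol,atol solver tolerances.
#' @param keep_states keep all state columns (default) or only `t_s`/`V_mV`.
#' @param engine `"compiled"` (default) or `"R"` (reference implementation,
#'   much slower; used for cross-checking).
#' @return a `trace` object: data frame with columns `t_s`, `V_mV` and
#'   (optionally) `h`, `n`, `ca_i`, `ca_tot`, `l`, with the run metadata in
#'   `attr(, "meta")`.  Time restarts at 0 after the discarded transient.
#' @examples
#' \donttest{
#' tr <- simulate(model_parameters(gNaP = 2.5, gCAN = 0), duration_s = 20)
#' range(tr$V_mV)
#' }
#' @export
simulate <- function(p, init = NULL, duration_s = 46, dt_out_ms = 0.5,
                     I_app = 0, discard_s = 6, rtol = 1e-8, atol = 1e-10,
                     keep_states = TRUE, engine = c("compiled", "R")) {
  stopifnot(inherits(p, "model_parameters"))
  engine <- match.arg(engine)
  if (duration_s <= discard_s)
    stop("duration_s must exceed the discarded transient discard_s")
  if (dt_out_ms <= 0) stop("dt_out_ms must be > 0")
  validate_parameters(p)
  if (is.null(init)) init <- default_initial_state(p)
  t_end <- duration_s * 1000
  times <- seq(0, t_end, by = dt_out_ms)
  y0 <- as.numeric(init)[1:6]
  names(y0) <- c("V", "h", "n", "ca_i", "ca_tot", "l")
  out <- .integrate(y0, times, p, I_app, clamp = FALSE, rtol, atol, engine)
  keep <- out[, "time"] >= discard_s * 1000
  tr <- data.frame(t_s = (out[keep, "time"] - discard_s * 1000) / 1000,
                   V_mV = out[keep, "V"])
  if (keep_states)
    for (nm in c("h", "n", "ca_i", "ca_tot", "l")) tr[[nm]] <- out[keep, nm]
  new_trace(tr, meta = list(
    parameters = unclass(p), I_app = I_app, duration_s = duration_s,
    discard_s = discard_s, dt_out_ms = dt_out_ms, rtol = rtol, atol = atol,
    engine = engine))
}

.integrate <- function(y0, times, p, I_app, clamp, rtol, atol, engine) {
  if (engine == "compiled") {
    out <- deSolve::lsoda(
      y = y0, times = times, func = "prebotsim_derivs",
      parms = .rhs_parms(p, I_app, clamp),
      initfunc = "prebotsim_initmod", dllname = "prebotsim",
      rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    out <- deSolve::lsoda(
      y = y0, times = times,
      func = function(t, y, parms) list(model_rhs(t, y, p, I_app, clamp)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0) {
    last <- out[nrow(out), ]
    stop("solver failure at t = ", format(last[["time"]]), " ms; last state: ",
         paste(sprintf("%s=%.4g", names(last)[-1], last[-1]), collapse = ", "))
  }
  if (any(!is.finite(out[, -1])))
    stop("solver produced non-finite state values")
  out
}

#' Steady-state membrane current under voltage clamp
#'
#' Emulates the current-voltage protocol: the membrane is stepped from the
#' initial (resting) condition to `V_hold` for `t_step_ms`, the non-voltage
#' states relax under clamp, and the total membrane current is read out
#' `t_measure_ms` after step onset (default 400 ms into a 500 ms step, the
#' steady-state convention).
#'
#' @param p a `model_parameters` object.
#' @param V_hold holding potential, mV.
#' @param t_step_ms step duration, ms.
#' @param t_measure_ms measurement time from step onset, ms.
#' @param init initial state at step onset; default [default_initial_state()].
#' @return total membrane current at the measurement time, pA (outward
#'   positive); the clamp current needed to hold the step.
#' @export
voltage_clamp_current <- function(p, V_hold, t_step_ms = 500,
                                  t_measure_ms = 400, init = NULL) {
  stopifnot(inherits(p, "model_parameters"))
  if (t_measure_ms <= 0 || t_measure_ms > t_step_ms)
    stop("t_measure_ms must satisfy 0 < t_measure_ms <= t_step_ms")
  if (is.null(init)) init <- default_initial_state(p)
  y0 <- as.numeric(init)[1:6]
  names(y0) <- c("V", "h", "n", "ca_i", "ca_tot", "l")
  y0["V"] <- V_hold
  times <- c(0, t_measure_ms)
  out <- .integrate(y0, times, p, I_app = 0, clamp = TRUE,
                    rtol = 1e-8, atol = 1e-10, engine = "compiled")
  s_end <- out[nrow(out), -1]
  st <- model_state(V = V_hold, h = s_end[["h"]], n = s_end[["n"]],
                    ca_i = s_end[["ca_i"]], ca_tot = s_end[["ca_tot"]],
                    l = s_end[["l"]], sigma = p$sigma)
  compute_currents(st, p)$total
}

# ---- trace container -------------------------------------------------------

new_trace <- function(df, meta = list()) {
  stopifnot(is.data.frame(df), all(c("t_s", "V_mV") %in% names(df)))
  attr(df, "meta") <- meta
  class(df) <- c("trace", "data.frame")
  df
}

#' Uniformly sampled time-series trace
#'
#' A `trace` is a data frame with columns `t_s` (time, s, strictly
#' increasing, uniform spacing) and `V_mV` (the sampled signal: membrane
#' potential for voltage traces, pA for current traces), optionally the
#' remaining state columns, plus a metadata attribute.
#'
#' @param t_s time samples, s.
#' @param V_mV signal samples.
#' @param ... further columns (full state, ground-truth ids, ...).
#' @param meta named list of metadata stored as an attribute.
#' @return a `trace` object.
#' @export
trace <- function(t_s, V_mV, ..., meta = list()) {
  if (length(t_s) != length(V_mV)) stop("t_s and V_mV lengths differ")
  if (length(t_s) > 1) {
    dt <- diff(t_s)
    if (any(dt <= 0)) stop("t_s must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt)) stop("t_s must be uniformly spaced")
  }
  if (any(!is.finite(V_mV))) stop("all samples must be finite")
  new_trace(data.frame(t_s = t_s, V_mV = V_mV, ...), meta = meta)
}

#' @export
print.trace <- function(x, ...) {
  dt <- if (nrow(x) > 1) x$t_s[2] - x$t_s[1] else NA
  cat(sprintf("<trace> %d samples, %.3f s at dt = %.4g ms; V in [%.1f, %.1f]\n",
              nrow(x), x$t_s[nrow(x)] - x$t_s[1], dt * 1000,
              min(x$V_mV), max(x$V_mV)))
  invisible(x)
}

#' Sampling interval of a trace, in seconds
#' @param tr a `trace`.
#' @return scalar dt, s.
#' @export
trace_dt <- function(tr) {
  if (nrow(tr) < 2) stop("trace too short")
  tr$t_s[2] - tr$t_s[1]
}

#' Write / read a trace as CSV with a key-value metadata sidecar
#'
#' The CSV holds the data columns (`t_s`, `V_mV`, ...); scalar metadata is
#' written to `<path>.meta` as flat `key = value` lines.
#'
#' @param tr a `trace`.
#' @param path CSV file path.
#' @return `read_trace()` returns a `trace`; `write_trace()` returns `path`
#'   invisibly.
#' @export
write_trace <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  meta <- attr(tr, "meta")
  flat <- unlist(meta)
  if (length(flat))
    writeLines(sprintf("%s = %s", names(flat), as.character(flat)),
               paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- list()
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    lines <- readLines(mp)
    kv <- strsplit(lines, " = ", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(x) {
      v <- suppressWarnings(as.numeric(x[2]))
      if (is.na(v)) x[2] else v
    }), vapply(kv, `[`, character(1), 1))
  }
  new_trace(df, meta = meta)
}
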