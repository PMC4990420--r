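#' Calcium-imaging dF/F trace
#'
#' Uniformly sampled fractional fluorescence change of a calcium indicator,
#' a proxy for burst firing of the imaged cell.
#'
#' @param t_s time samples, s (uniform).
#' @param dff dF/F samples (dimensionless).
#' @param meta metadata list.
#' @return data frame of class `dff_trace` with columns `t_s`, `dff`.
#' @export
dff_trace <- function(t_s, dff, meta = list()) {
  if (length(t_s) != length(dff)) stop("t_s and dff lengths differ")
  if (any(!is.finite(dff))) stop("all dF/F samples must be finite")
  if (length(t_s) > 1) {
    d <- diff(t_s)
    if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d))
      stop("t_s must be strictly increasing and uniform")
  }
  out <- data.frame(t_s = t_s, dff = dff)
  attr(out, "meta") <- meta
  class(out) <- c("dff_trace", "data.frame")
  out
}

# linear detrend + mean removal before correlation analyses
.detrend <- function(x) stats::residuals(stats::lm(x ~ seq_along(x)))

#' Autocorrelation rhythmicity score of a dF/F trace
#'
#' Score is the height of the largest non-zero-lag autocorrelation peak of
#' the detrended trace at lags corresponding to periods within
#' `[min_period, max_period]`.  A trace is called rhythmic when the score
#' reaches `threshold` (default 0.3).
#'
#' @param d a `dff_trace`.
#' @param min_period,max_period period search range, s.
#' @param threshold rhythmicity threshold on the score.
#' @return list with `score` in \[0, 1\] (negative correlations truncate to
#'   0), `period` (s, lag of the best peak, `NA` when below threshold) and
#'   logical `rhythmic`.
#' @export
rhythmicity_score <- function(d, min_period = 1, max_period = 20,
                              threshold = 0.3) {
  dt <- d$t_s[2] - d$t_s[1]
  n <- nrow(d)
  if (n * dt < 3 * max_period)
    stop("trace too short: need at least 3 x max_period = ",
         3 * max_period, " s")
  x <- .detrend(d$dff)
  lag_max <- ceiling(max_period / dt)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  win <- lags >= max(2, round(min_period / dt)) & lags <= lag_max
  idx <- which(win)
  # local maxima of the acf inside the window
  peaks <- idx[ac[idx] >= c(ac[idx - 1]) & ac[idx] >= c(ac[pmin(idx + 1, length(ac))])]
  if (!length(peaks)) {
    return(list(score = 0, period = NA_real_, rhythmic = FALSE))
  }
  best <- peaks[which.max(ac[peaks])]
  score <- max(0, ac[best])
  rhythmic <- score >= threshold
  list(score = score,
       period = if (rhythmic) (best - 1L) * dt else NA_real_,
       rhythmic = rhythmic)
}

#' Phase locking of a cell trace to the population rhythm
#'
#' `TRUE` when the peak normalized cross-correlation between the detrended
#' cell trace and the detrended population trace, within lags of
#' `+/- max_lag`, reaches `threshold`.  By default only positive
#' correlation counts as locking (`absolute = FALSE`); set
#' `absolute = TRUE` to accept sign-inverted signals.
#'
#' @param d a `dff_trace` (the cell).
#' @param pop the population-activity trace: a `dff_trace` or `trace`
#'   sampled at the same rate with overlapping time support.
#' @param max_lag lag window, s.
#' @param threshold correlation threshold.
#' @param absolute use `|correlation|` instead of signed correlation.
#' @return logical flag with the peak correlation and its lag (s) attached
#'   as attributes `correlation` and `lag`.
#' @export
phase_locked <- function(d, pop, max_lag = 0.5, threshold = 0.3,
                         absolute = FALSE) {
  pop_sig <- if ("dff" %in% names(pop)) pop$dff else pop$V_mV
  t0 <- max(d$t_s[1], pop$t_s[1])
  t1 <- min(d$t_s[nrow(d)], pop$t_s[nrow(pop)])
  if (t1 <= t0) stop("cell and population traces do not overlap in time")
  dt <- d$t_s[2] - d$t_s[1]
  xi <- d$t_s >= t0 & d$t_s <= t1
  yi <- pop$t_s >= t0 & pop$t_s <= t1
  x <- .detrend(d$dff[xi])
  y <- .detrend(pop_sig[yi])
  m <- min(length(x), length(y))
  cc <- stats::ccf(x[seq_len(m)], y[seq_len(m)],
                   lag.max = max(1, round(max_lag / dt)), plot = FALSE)
  vals <- cc$acf[, 1, 1]
  score <- if (absolute) max(abs(vals)) else max(vals)
  best <- if (absolute) which.max(abs(vals)) else which.max(vals)
  structure(score >= threshold,
            correlation = score, lag = cc$lag[best, 1, 1] * dt)
}

#' Per-cell recordings across pharmacological conditions
#'
#' Bundles one cell's dF/F traces in the conditions of the pacemaker
#' identification protocol: `control`, `cocktail` (chemical synaptic
#' blockade) and optionally `cocktail_ril` (blockade plus riluzole),
#' together with the control-condition population-activity trace.
#'
#' @param cell_id identifier.
#' @param control,cocktail,cocktail_ril `dff_trace` objects (the latter two
#'   may be `NULL` when the protocol stopped earlier).
#' @param population the integrated population-activity trace in control.
#' @return list of class `cell_condition_record`.
#' @export
cell_condition_record <- function(cell_id, control, population,
                                  cocktail = NULL, cocktail_ril = NULL) {
  if (is.null(control)) stop("the control trace is required")
  structure(list(cell_id = cell_id, control = control, cocktail = cocktail,
                 cocktail_ril = cocktail_ril, population = population),
            class = "cell_condition_record")
}

#' Classify a cell through the control / blockade / riluzole decision tree
#'
#' A cell is inspiratory when it is rhythmic AND phase-locked to the
#' population rhythm in control; a pacemaker when it additionally stays
#' rhythmic under synaptic blockade (phase locking is not required there:
#' isolated pacemakers run at their own frequency); riluzole-sensitive
#' (I_NaP-dependent) when pacemaking is lost under blockade + riluzole, and
#' riluzole-resistant (presumed I_CAN-dependent) when it persists.
#'
#' @param rec a [cell_condition_record()].
#' @param min_period,max_period,rhythm_threshold rhythmicity settings
#'   passed to [rhythmicity_score()].
#' @param lock_threshold,max_lag phase-locking settings passed to
#'   [phase_locked()].
#' @return one of `"non_inspiratory"`, `"non_pacemaker"`,
#'   `"pacemaker_ril_sensitive"`, `"pacemaker_ril_resistant"`, with the
#'   per-condition scores in attribute `detail`.
#' @export
classify_cell <- function(rec, min_period = 1, max_period = 20,
                          rhythm_threshold = 0.3, lock_threshold = 0.3,
                          max_lag = 0.5) {
  stopifnot(inherits(rec, "cell_condition_record"))
  rs_ctrl <- rhythmicity_score(rec$control, min_period, max_period,
                               rhythm_threshold)
  locked <- if (rs_ctrl$rhythmic)
    phase_locked(rec$control, rec$population, max_lag, lock_threshold)
  else FALSE
  detail <- list(control = rs_ctrl, locked = locked)
  finish <- function(label) structure(label, detail = detail)
  if (!rs_ctrl$rhythmic || !isTRUE(as.logical(locked)))
    return(finish("non_inspiratory"))
  if (is.null(rec[["cocktail"]]))
    stop("condition trace missing for decision: cocktail")
  rs_ckt <- rhythmicity_score(rec[["cocktail"]], min_period, max_period,
                              rhythm_threshold)
  detail$cocktail <- rs_ckt
  if (!rs_ckt$rhythmic) return(finish("non_pacemaker"))
  if (is.null(rec[["cocktail_ril"]]))
    stop("condition trace missing for decision: cocktail_ril")
  rs_ril <- rhythmicity_score(rec[["cocktail_ril"]], min_period, max_period,
                              rhythm_threshold)
  detail$cocktail_ril <- rs_ril
  if (rs_ril$rhythmic) finish("pacemaker_ril_resistant")
  else finish("pacemaker_ril_sensitive")
}
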