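#' Classifier and burst-measurement configuration
#'
#' Tunable settings of the drive-potential (DP) extraction pipeline and the
#' five-way discharge classifier.  Defaults:
#' \itemize{
#'   \item `v_threshold` -20 mV spike threshold, `refractory_ms` 2 ms;
#'   \item `window_ms` 50 ms running-median window for spike stripping;
#'   \item `onset_frac` 0.2: bursts are measured where the envelope exceeds
#'     baseline + 20\% of the peak-above-baseline (both the onset threshold
#'     and the duration measurement level);
#'   \item `min_gap_s` 0.2 s: events separated by shorter gaps are merged;
#'   \item `min_amplitude` 5 mV: envelope excursions smaller than this are
#'     not bursts (noise floor);
#'   \item `split_s` 1.5 s per-event plateau/oscillatory duration split,
#'     between the canonical oscillatory (0.79 s) and plateau (2.9 s) means
#'     and more than 5 SD from the oscillatory per-cycle spread;
#'   \item depolarization block: an event is plateau-like irrespective of
#'     duration if all its spikes fall within the first `block_early_frac`
#'     (40\%) of the event and the suprathreshold envelope persists at least
#'     `block_quiet_s` (1 s) beyond the last spike;
#'   \item `minority` 0.2: a trace is `mixed` only if the rarer per-event
#'     class makes up at least 20\% of events;
#'   \item `min_events` 3: non-silent traces with fewer events are flagged
#'     `indeterminate`;
#'   \item `tonic_duty` 0.9 / `max_quiescent_s` 2 s: tonic means spiking
#'     with no quiescent inter-burst periods.
#' }
#'
#' @param ... overrides of any default.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(...) {
  cfg <- list(
    v_threshold = -20, refractory_ms = 2,
    window_ms = 50,
    onset_frac = 0.2, min_gap_s = 0.2, min_amplitude = 5,
    split_s = 1.5, minority = 0.2, min_events = 3,
    block_early_frac = 0.4, block_quiet_s = 1,
    tonic_duty = 0.9, max_quiescent_s = 2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown classifier setting(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "classifier_config"
  cfg
}

#' Detect spikes by upward threshold crossing
#'
#' Spike times are upward crossings of `v_threshold` separated by at least
#' the refractory interval.
#'
#' @param tr a voltage `trace`.
#' @param v_threshold crossing threshold, mV.
#' @param refractory_ms minimal inter-spike interval, ms.
#' @return numeric vector of spike times, s.
#' @export
detect_spikes <- function(tr, v_threshold = -20, refractory_ms = 2) {
  V <- tr$V_mV
  idx <- which(V[-1] >= v_threshold & V[-length(V)] < v_threshold) + 1L
  if (!length(idx)) return(numeric(0))
  st <- tr$t_s[idx]
  keep <- c(TRUE, diff(st) >= refractory_ms / 1000)
  while (!all(keep)) {      # re-apply after removals so spacing is >= refractory
    st <- st[keep]
    keep <- c(TRUE, diff(st) >= refractory_ms / 1000)
  }
  st
}

#' Spike-stripped drive-potential envelope
#'
#' Running median of the voltage trace.  The window (default 50 ms) is
#' longer than a spike but much shorter than a burst, so riding action
#' potentials are removed while the slow drive-potential envelope is kept;
#' on spike-free traces the filter is close to the identity (median filters
#' preserve steps and monotone segments).
#'
#' @param tr a voltage `trace`.
#' @param window_ms running-median window, ms.
#' @return a `trace` holding the envelope.
#' @export
dp_envelope <- function(tr, window_ms = 50) {
  dt_ms <- trace_dt(tr) * 1000
  k <- round(window_ms / dt_ms)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3) stop("configuration error: envelope window too small (< 3 samples)")
  if (k >= nrow(tr)) stop("configuration error: envelope window exceeds trace")
  env <- stats::runmed(tr$V_mV, k, endrule = "median")
  out <- tr
  out$V_mV <- as.numeric(env)
  attr(out, "meta") <- c(attr(tr, "meta"), list(envelope_window_ms = window_ms))
  out
}

# Histogram mode of the envelope: robust baseline estimate independent of
# burst duty cycle.  The mode is searched in the lower half of the envelope
# range (so a plateau phase occupying more than half the record cannot be
# mistaken for baseline), and the mode bin is refined to the mean of the
# samples within +/- 2 bins of it, which removes the bin-quantization
# offset.
.envelope_baseline <- function(env_v, binwidth = 0.5) {
  rng <- range(env_v)
  if (diff(rng) < binwidth) return(mean(env_v))
  lower <- env_v[env_v <= rng[1] + 0.5 * diff(rng)]
  breaks <- seq(rng[1] - binwidth / 2, rng[2] + binwidth, by = binwidth)
  h <- graphics::hist(lower, breaks = breaks, plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  near <- abs(env_v - mode_mid) <= 2 * binwidth
  mean(env_v[near])
}

#' Segment a spike-stripped envelope into burst events
#'
#' Baseline is the histogram mode of the envelope; events are maximal
#' intervals where the envelope is at or above
#' `baseline + onset_frac * (peak - baseline)`, merged across gaps shorter
#' than `min_gap_s`.  Per event the DP amplitude (envelope peak minus
#' baseline, mV) and DP duration (time spent above the threshold, s) are
#' measured (the peak is estimated noise-robustly as the mean of the
#' envelope over the event's top 20\% band); when spike times are
#' supplied, spikes are assigned to events
#' and the depolarization-block flag is filled.
#'
#' A trace whose envelope never rises `min_amplitude` above baseline yields
#' zero events (not an error).
#'
#' @param env a spike-stripped envelope `trace` (see [dp_envelope()]).
#' @param spike_times optional spike times from [detect_spikes()], s.
#' @param onset_frac onset threshold as a fraction of peak-above-baseline.
#' @param min_gap_s merge gap, s.
#' @param min_amplitude noise floor, mV.
#' @param amplitude_mode `"band"` (default; noise-robust top-band mean, the
#'   right convention for flat-topped drive potentials) or `"peak"` (the
#'   raw per-event envelope maximum, used for smooth synaptic-current
#'   envelopes).
#' @param cfg optional `classifier_config`; overrides the individual
#'   threshold arguments and supplies the depolarization-block settings.
#' @return data frame of class `burst_events` with columns `onset`,
#'   `offset`, `dp_amplitude`, `dp_duration`, `n_spikes`, `depol_block`
#'   and a `spike_times` list column; baseline and threshold in attributes.
#' @export
segment_bursts <- function(env, spike_times = NULL, onset_frac = 0.2,
                           min_gap_s = 0.2, min_amplitude = 5,
                           amplitude_mode = c("band", "peak"), cfg = NULL) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.null(cfg)) {
    onset_frac <- cfg$onset_frac; min_gap_s <- cfg$min_gap_s
    min_amplitude <- cfg$min_amplitude
  }
  block_early <- if (is.null(cfg)) 0.4 else cfg$block_early_frac
  block_quiet <- if (is.null(cfg)) 1 else cfg$block_quiet_s
  v <- env$V_mV; tt <- env$t_s
  base <- .envelope_baseline(v)
  peak <- max(v)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      dp_amplitude = numeric(0), dp_duration = numeric(0),
                      n_spikes = integer(0), depol_block = logical(0))
  empty$spike_times <- list()
  attr(empty, "baseline_vm") <- base
  class(empty) <- c("burst_events", "data.frame")
  if (peak - base < min_amplitude) return(empty)
  thr <- base + onset_frac * (peak - base)
  above <- v >= thr
  d <- diff(above)
  on_i <- which(d == 1L) + 1L
  off_i <- which(d == -1L)
  if (above[1]) on_i <- c(1L, on_i)
  if (above[length(above)]) off_i <- c(off_i, length(above))
  ev <- cbind(tt[on_i], tt[off_i])
  # merge across short gaps
  if (nrow(ev) > 1) {
    keep_on <- ev[1, 1]; merged <- NULL
    for (i in seq_len(nrow(ev) - 1)) {
      if (ev[i + 1, 1] - ev[i, 2] >= min_gap_s) {
        merged <- rbind(merged, c(keep_on, ev[i, 2]))
        keep_on <- ev[i + 1, 1]
      }
    }
    ev <- rbind(merged, c(keep_on, ev[nrow(ev), 2]))
  }
  n <- nrow(ev)
  amp <- dur <- numeric(n); nsp <- integer(n); blk <- logical(n)
  sp_list <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- tt >= ev[i, 1] & tt <= ev[i, 2]
    vs <- v[sel]
    if (amplitude_mode == "band") {
      # noise-robust DP peak: mean of the envelope over the top 20% band of
      # the event, so residual filtered noise averages out instead of
      # adding a max-statistic offset
      top <- vs >= base + 0.8 * (max(vs) - base)
      amp[i] <- mean(vs[top]) - base
    } else {
      amp[i] <- max(vs) - base
    }
    dur[i] <- sum(v[sel] >= thr) * (tt[2] - tt[1])
    sp <- if (is.null(spike_times)) numeric(0) else
      spike_times[spike_times >= ev[i, 1] & spike_times <= ev[i, 2]]
    sp_list[[i]] <- sp
    nsp[i] <- length(sp)
    if (length(sp)) {
      span <- ev[i, 2] - ev[i, 1]
      blk[i] <- max(sp) <= ev[i, 1] + block_early * span &&
        ev[i, 2] - max(sp) >= block_quiet
    }
  }
  out <- data.frame(onset = ev[, 1], offset = ev[, 2], dp_amplitude = amp,
                    dp_duration = dur, n_spikes = nsp, depol_block = blk)
  out$spike_times <- sp_list
  attr(out, "baseline_vm") <- base
  attr(out, "threshold") <- thr
  class(out) <- c("burst_events", "data.frame")
  out
}

#' Per-event plateau/oscillatory labels
#'
#' An event is plateau-like if its DP duration reaches the split (default
#' 1.5 s) or it shows depolarization block; otherwise oscillatory-like.
#'
#' @param events a `burst_events` data frame.
#' @param cfg a `classifier_config`.
#' @return character vector, `"plateau"` / `"oscillatory"` per event.
#' @export
event_labels <- function(events, cfg = classifier_config()) {
  ifelse(events$dp_duration >= cfg$split_s | events$depol_block,
         "plateau", "oscillatory")
}

#' Five-way discharge-phenotype classification of a voltage trace
#'
#' Runs spike detection, spike stripping, burst segmentation and per-event
#' labelling, then assigns the trace one of `silent`, `tonic`,
#' `oscillatory`, `plateau`, `mixed` (or `indeterminate` when a non-silent
#' trace has fewer than `min_events` events):
#' \itemize{
#'   \item `silent`: no burst events and no sustained spiking;
#'   \item `tonic`: spiking with no quiescent inter-burst periods (continuous
#'     spiking, or burst events covering nearly the whole window);
#'   \item `plateau` / `oscillatory`: at least `1 - minority` of events share
#'     that per-event class;
#'   \item `mixed`: both classes present above the minority fraction.
#' }
#'
#' @param tr a voltage `trace`.
#' @param cfg a `classifier_config`.
#' @param events optional precomputed `burst_events` (with spikes assigned);
#'   when omitted they are measured from `tr`.
#' @return object of class `discharge_classification`: list with `label`,
#'   `indeterminate`, `events`, `per_event_labels`, `mean_dp_amplitude`,
#'   `mean_dp_duration`, `burst_frequency`, `baseline_vm`.
#' @export
classify_discharge <- function(tr, cfg = classifier_config(), events = NULL) {
  spikes <- detect_spikes(tr, cfg$v_threshold, cfg$refractory_ms)
  if (is.null(events)) {
    env <- dp_envelope(tr, cfg$window_ms)
    events <- segment_bursts(env, spike_times = spikes, cfg = cfg)
  }
  n <- nrow(events)
  window <- diff(range(tr$t_s))
  labels <- event_labels(events, cfg)
  res <- list(label = NA_character_, indeterminate = FALSE, events = events,
              per_event_labels = labels,
              mean_dp_amplitude = if (n) mean(events$dp_amplitude) else NA_real_,
              mean_dp_duration = if (n) mean(events$dp_duration) else NA_real_,
              burst_frequency = if (n > 1)
                (n - 1) / (events$onset[n] - events$onset[1]) else NA_real_,
              baseline_vm = attr(events, "baseline_vm"))
  tonic_spiking <- length(spikes) > 1 &&
    max(diff(c(tr$t_s[1], spikes, tr$t_s[length(tr$t_s)]))) < cfg$max_quiescent_s
  if (n == 0) {
    res$label <- if (tonic_spiking) "tonic" else "silent"
  } else if (sum(events$dp_duration) / window > cfg$tonic_duty && tonic_spiking) {
    res$label <- "tonic"
  } else if (n < cfg$min_events) {
    res$label <- "indeterminate"
    res$indeterminate <- TRUE
  } else {
    frac_plateau <- mean(labels == "plateau")
    res$label <- if (frac_plateau >= 1 - cfg$minority) "plateau"
      else if (frac_plateau <= cfg$minority) "oscillatory"
      else "mixed"
  }
  class(res) <- "discharge_classification"
  res
}

#' @export
print.discharge_classification <- function(x, ...) {
  cat(sprintf("<discharge_classification> %s (%d events", x$label,
              nrow(x$events)))
  if (nrow(x$events))
    cat(sprintf("; mean DP %.1f mV / %.2f s; f = %.3g Hz",
                x$mean_dp_amplitude, x$mean_dp_duration, x$burst_frequency))
  cat(")\n")
  invisible(x)
}

#' Summary statistics over burst events
#'
#' Arithmetic mean, SD and SEM of DP amplitude and duration, plus the burst
#' frequency `(n - 1) / (last onset - first onset)`.
#'
#' @param events a `burst_events` data frame with at least one event.
#' @return list with `n`, `amplitude` (mean/sd/sem), `duration`
#'   (mean/sd/sem) and `frequency_hz`; with a single event the SD and SEM
#'   are `NA` and `single_event` is `TRUE`.
#' @export
burst_statistics <- function(events) {
  n <- nrow(events)
  if (n == 0) stop("undefined statistics: no burst events")
  stat <- function(x) list(mean = mean(x),
                           sd = if (n > 1) stats::sd(x) else NA_real_,
                           sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
  list(n = n,
       amplitude = stat(events$dp_amplitude),
       duration = stat(events$dp_duration),
       frequency_hz = if (n > 1)
         (n - 1) / (events$onset[n] - events$onset[1]) else NA_real_,
       single_event = n == 1)
}

#' Mean synaptic-drive envelope amplitude over consecutive burst cycles
#'
#' For a synaptic-current trace, measures each cycle's maximal deflection
#' from baseline and averages the first `n_cycles` cycles (default 15).
#'
#' @param tr a current `trace` (signal in the `V_mV` column, pA).
#' @param n_cycles number of consecutive cycles to average.
#' @param min_deflection smallest deflection treated as a cycle, in the
#'   trace's units.
#' @return mean of the per-cycle maximal deflections.
#' @export
measure_drive_current <- function(tr, n_cycles = 15, min_deflection = 1) {
  ev <- segment_bursts(tr, onset_frac = 0.2, min_gap_s = 0.2,
                       min_amplitude = min_deflection,
                       amplitude_mode = "peak")
  if (nrow(ev) < n_cycles)
    stop("found ", nrow(ev), " burst cycles but ", n_cycles, " were requested")
  mean(ev$dp_amplitude[seq_len(n_cycles)])
}
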