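#' Subtype templates for synthetic pacemaker traces
#'
#' Statistical templates of the three discharge phenotypes, built from the
#' published drive-potential statistics:
#' \itemize{
#'   \item plateau: amplitude N(30.5, 6.6) mV, duration N(2.9, 0.35) s,
#'     inter-burst baseline -52.7 mV, spikes confined to the early burst
#'     phase followed by depolarization block;
#'   \item oscillatory: amplitude N(12.8, 3.8) mV, duration N(0.79, 0.12) s,
#'     baseline -49.2 mV, spikes throughout the burst;
#'   \item mixed: a two-component mixture of the plateau and oscillatory
#'     event templates with plateau weight 0.45 (which reproduces the
#'     overall mixed means of 14.5 mV and 1.74 s), baseline -49.1 mV.
#' }
#' Cycle periods (plateau 8 s, oscillatory 4 s, mixed 5 s) are not reported
#' quantities; they are fixed realistic choices.  The amplitude spreads are
#' per-cycle SDs; the duration spreads are per-cycle SDs consistent with
#' the published SEMs at the published cycle counts.
#'
#' @return named list of `subtype_template` objects for `plateau`,
#'   `oscillatory` and `mixed`.
#' @export
default_templates <- function() {
  tpl <- function(subtype, amp_mean, amp_sd, dur_mean, dur_sd, period_mean,
                  period_sd, baseline, plateau_fraction = NA_real_) {
    structure(list(subtype = subtype,
                   dp_amplitude = c(mean = amp_mean, sd = amp_sd),
                   dp_duration = c(mean = dur_mean, sd = dur_sd),
                   cycle_period = c(mean = period_mean, sd = period_sd),
                   baseline_vm = baseline,
                   plateau_fraction = plateau_fraction,
                   spike_height = 40, spike_width_ms = 4,
                   spike_rate_hz = 15, block_frac = 0.35,
                   noise_sd = 1),
              class = "subtype_template")
  }
  list(
    plateau = tpl("plateau", 30.5, 6.6, 2.9, 0.35, 8, 0.8, -52.7),
    oscillatory = tpl("oscillatory", 12.8, 3.8, 0.79, 0.12, 4, 0.4, -49.2),
    mixed = tpl("mixed", NA, NA, NA, NA, 5, 0.5, -49.1,
                plateau_fraction = 0.45))
}

# truncated-normal draw: redraw outside [lo, hi] (bounds far from the mean
# for every template, so truncation bias is negligible)
.rtrunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic pacemaker voltage trace with ground truth
#'
#' Builds `baseline + square drive potentials + stereotyped spikes + white
#' noise`.  Each cycle draws its period, and its event class for mixed
#' templates; each event draws amplitude and duration from the template.
#' Mixed traces realize the plateau mixing weight exactly (the closest
#' integer count of plateau events, in seeded shuffled order), so the
#' ground-truth composition of every trace is known.  Plateau-class events
#' carry spikes only in the early burst phase (depolarization block);
#' oscillatory-class events spike throughout.
#'
#' @param tpl a `subtype_template` (see [default_templates()]).
#' @param n_cycles number of burst cycles.
#' @param dt_ms sampling interval, ms (default 1 ms).
#' @param seed RNG seed; every draw flows from it.
#' @param noise_sd override the template's additive noise SD, mV.
#' @return a voltage `trace` with attribute `ground_truth`: a data frame
#'   with one row per generated event (`onset`, `offset`, `amplitude`,
#'   `duration`, `class`).
#' @export
generate_trace <- function(tpl, n_cycles, dt_ms = 1, seed = 1,
                           noise_sd = NULL) {
  stopifnot(inherits(tpl, "subtype_template"), n_cycles >= 1)
  if (is.null(noise_sd)) noise_sd <- tpl$noise_sd
  set.seed(seed)
  mixed <- identical(tpl$subtype, "mixed")
  base_tpls <- default_templates()
  chk <- if (mixed) base_tpls[c("plateau", "oscillatory")] else list(tpl)
  for (ct in chk)
    if (ct$dp_duration[["mean"]] >= ct$cycle_period[["mean"]])
      stop("inconsistent template: mean duration must be below the mean period")
  if (mixed) {
    n_plateau <- round(tpl$plateau_fraction * n_cycles)
    classes <- sample(c(rep("plateau", n_plateau),
                        rep("oscillatory", n_cycles - n_plateau)))
  } else {
    classes <- rep(tpl$subtype, n_cycles)
  }
  comp <- function(cls) if (mixed) base_tpls[[cls]] else tpl
  # event amplitude/duration follow the event-class component template;
  # cycle timing follows the trace's own template, stretched where needed
  # so consecutive drive potentials stay separated by at least 0.6 s
  durs <- vapply(classes, function(cls) {
    ct <- comp(cls)
    .rtrunc(1, ct$dp_duration[["mean"]], ct$dp_duration[["sd"]],
            0.05, ct$dp_duration[["mean"]] + 4 * ct$dp_duration[["sd"]])
  }, numeric(1))
  periods <- pmax(
    .rtrunc(n_cycles, tpl$cycle_period[["mean"]], tpl$cycle_period[["sd"]],
            0.5 * tpl$cycle_period[["mean"]], 2 * tpl$cycle_period[["mean"]]),
    durs + 0.6)
  # the amplitude floor stays above the segmentation noise floor, so every
  # generated event is detectable
  amps <- vapply(classes, function(cls) {
    ct <- comp(cls)
    .rtrunc(1, ct$dp_amplitude[["mean"]], ct$dp_amplitude[["sd"]],
            max(6, ct$dp_amplitude[["mean"]] - 2.8 * ct$dp_amplitude[["sd"]]),
            ct$dp_amplitude[["mean"]] + 4 * ct$dp_amplitude[["sd"]])
  }, numeric(1))
  lead <- 1                                  # quiet lead-in/out, s
  onsets <- lead + c(0, cumsum(periods))[seq_len(n_cycles)]
  total_s <- lead + sum(periods) + lead
  dt <- dt_ms / 1000
  tt <- seq(0, total_s, by = dt)
  v <- rep(tpl$baseline_vm, length(tt))
  for (i in seq_len(n_cycles)) {
    sel <- tt >= onsets[i] & tt < onsets[i] + durs[i]
    v[sel] <- v[sel] + amps[i]
    ct <- comp(classes[i])
    spike_end <- if (classes[i] == "plateau")
      onsets[i] + ct$block_frac * durs[i] else onsets[i] + durs[i]
    n_sp <- max(1L, round(ct$spike_rate_hz * (spike_end - onsets[i])))
    sp_t <- onsets[i] + (seq_len(n_sp) - 0.5) / n_sp * (spike_end - onsets[i])
    w <- ct$spike_width_ms / 1000
    for (s0 in sp_t) {
      ssel <- tt >= s0 - w / 2 & tt <= s0 + w / 2
      v[ssel] <- v[ssel] +
        ct$spike_height * (1 - abs(tt[ssel] - s0) / (w / 2))  # triangular spike
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  gt <- data.frame(onset = onsets, offset = onsets + durs,
                   amplitude = amps, duration = durs, class = classes)
  out <- trace(tt, v, meta = list(subtype = tpl$subtype, seed = seed,
                                  noise_sd = noise_sd, dt_ms = dt_ms))
  attr(out, "ground_truth") <- gt
  out
}

#' Virtual pacemaker population with an exact subtype composition
#'
#' The packaged reference compositions are the published per-subtype counts
#' at E18.5 (plateau 3, mixed 9, oscillatory 23 of 35) and an interpolated
#' E16.5 composition (plateau 13, mixed 1, oscillatory 13 of 27: plateau
#' and oscillatory bursters nearly equally present, total as published; the
#' per-subtype breakdown at this stage is not published).
#'
#' @param stage stage tag, e.g. `"E18.5"`.
#' @param composition named integer vector of counts, names among
#'   `plateau`, `mixed`, `oscillatory`.
#' @param seed population seed; each cell receives a derived seed.
#' @return object of class `virtual_population`: data frame with `cell_id`,
#'   `subtype`, `seed`, plus attributes `stage` and `templates`.
#' @examples
#' pop <- generate_population("E18.5", stage_composition("E18.5"), seed = 1)
#' table(pop$subtype)
#' @export
generate_population <- function(stage, composition, seed = 1) {
  if (any(composition < 0) || any(composition != round(composition)))
    stop("composition counts must be non-negative integers")
  bad <- setdiff(names(composition), c("plateau", "mixed", "oscillatory"))
  if (length(bad)) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
  subtypes <- rep(names(composition), composition)
  n <- length(subtypes)
  pop <- data.frame(
    cell_id = if (n) sprintf("%s_cell%02d", stage, seq_len(n)) else character(0),
    subtype = subtypes,
    seed = if (n) seed * 10000L + seq_len(n) else integer(0),
    stringsAsFactors = FALSE)
  attr(pop, "stage") <- stage
  attr(pop, "templates") <- default_templates()
  class(pop) <- c("virtual_population", "data.frame")
  pop
}

#' Published / packaged stage compositions
#' @param stage `"E18.5"` (published counts) or `"E16.5"` (interpolated).
#' @return named count vector usable with [generate_population()].
#' @export
stage_composition <- function(stage = c("E18.5", "E16.5")) {
  stage <- match.arg(stage)
  switch(stage,
         "E18.5" = c(plateau = 3, mixed = 9, oscillatory = 23),
         "E16.5" = c(plateau = 13, mixed = 1, oscillatory = 13))
}

#' Synthesize and classify every cell of a virtual population
#'
#' Generates one voltage trace per cell from its subtype template and runs
#' the discharge classifier on it.
#'
#' @param pop a `virtual_population`.
#' @param n_cycles burst cycles per cell trace.
#' @param cfg a [classifier_config()].
#' @param dt_ms trace sampling interval, ms.
#' @return data frame with `cell_id`, `subtype` (truth) and `label`
#'   (classifier output).
#' @export
classify_population <- function(pop, n_cycles = 20, cfg = classifier_config(),
                                dt_ms = 1) {
  tpls <- attr(pop, "templates")
  labels <- vapply(seq_len(nrow(pop)), function(i) {
    tr <- generate_trace(tpls[[pop$subtype[i]]], n_cycles = n_cycles,
                         dt_ms = dt_ms, seed = pop$seed[i])
    classify_discharge(tr, cfg)$label
  }, character(1))
  data.frame(cell_id = pop$cell_id, subtype = pop$subtype, label = labels,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dF/F trace from a burst rhythm
#'
#' Burst onsets become unit impulses convolved with a single-exponential
#' indicator decay kernel (default tau 1 s), sampled at the imaging frame
#' interval (default 0.1 s), plus white noise.
#'
#' @param burst_onsets burst onset times, s; `numeric(0)` gives a
#'   noise-only trace.
#' @param duration_s trace length, s.
#' @param kernel_tau indicator decay time constant, s.
#' @param frame_interval imaging frame interval, s.
#' @param amplitude dF/F amplitude per burst.
#' @param noise_sd additive noise SD (dF/F units).
#' @param seed RNG seed.
#' @return a `dff_trace` with the onset times in `attr(, "ground_truth")`.
#' @export
generate_dff <- function(burst_onsets, duration_s, kernel_tau = 1,
                         frame_interval = 0.1, amplitude = 0.2,
                         noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  tt <- seq(0, duration_s, by = frame_interval)
  sig <- rep(0, length(tt))
  for (on in burst_onsets) {
    sel <- tt >= on
    sig[sel] <- sig[sel] + amplitude * exp(-(tt[sel] - on) / kernel_tau)
  }
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(tt), 0, noise_sd)
  out <- dff_trace(tt, sig, meta = list(kernel_tau = kernel_tau,
                                        frame_interval = frame_interval,
                                        noise_sd = noise_sd, seed = seed))
  attr(out, "ground_truth") <- burst_onsets
  out
}

#' Generate a synthetic synaptic-drive current trace
#'
#' Baseline-zero current trace with `n_bursts` smooth envelope deflections
#' whose per-cycle amplitudes are drawn around the requested mean.
#'
#' @param n_bursts number of burst deflections.
#' @param amp_mean,amp_sd per-cycle amplitude mean and SD (pA).
#' @param period_s cycle period, s.
#' @param width_s deflection width, s.
#' @param noise_sd additive noise SD, pA.
#' @param dt_ms sampling interval, ms.
#' @param seed RNG seed.
#' @return a current `trace` (pA in the `V_mV` column) with the drawn
#'   amplitudes in `attr(, "ground_truth")`.
#' @export
generate_drive_current <- function(n_bursts, amp_mean, amp_sd = 0,
                                   period_s = 4, width_s = 1, noise_sd = 0,
                                   dt_ms = 5, seed = 1) {
  set.seed(seed)
  amps <- if (n_bursts > 0)
    .rtrunc(n_bursts, amp_mean, amp_sd, 0.2 * amp_mean, 5 * amp_mean)
  else numeric(0)
  total <- n_bursts * period_s + 2
  dt <- dt_ms / 1000
  tt <- seq(0, total, by = dt)
  sig <- rep(0, length(tt))
  onsets <- 1 + (seq_len(n_bursts) - 1) * period_s
  for (i in seq_len(n_bursts)) {
    sel <- tt >= onsets[i] & tt <= onsets[i] + width_s
    ph <- (tt[sel] - onsets[i]) / width_s
    sig[sel] <- sig[sel] + amps[i] * sin(pi * ph)^2   # smooth envelope bump
  }
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(tt), 0, noise_sd)
  out <- trace(tt, sig, meta = list(n_bursts = n_bursts, seed = seed))
  attr(out, "ground_truth") <- amps
  out
}
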