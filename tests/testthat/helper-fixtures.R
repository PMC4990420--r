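# Deterministic hand-built traces for burst-metric tests (no RNG).

# Square drive potentials on a flat baseline, optional triangular spikes.
# durations/amplitudes are per-event; events start at `lead` and repeat
# every `period` seconds.
make_square_trace <- function(durations, amplitudes, period = 8,
                              baseline = -52.7, dt = 0.001, lead = 1,
                              spike_height = 40, spike_rate = 0,
                              spike_end_frac = 1) {
  n <- length(durations)
  stopifnot(length(amplitudes) == n)
  total <- lead + n * period + lead
  tt <- seq(0, total, by = dt)
  v <- rep(baseline, length(tt))
  onsets <- lead + (seq_len(n) - 1) * period
  for (i in seq_len(n)) {
    sel <- tt >= onsets[i] & tt < onsets[i] + durations[i]
    v[sel] <- v[sel] + amplitudes[i]
    if (spike_rate > 0) {
      span <- durations[i] * spike_end_frac
      n_sp <- max(1L, round(spike_rate * span))
      sp_t <- onsets[i] + (seq_len(n_sp) - 0.5) / n_sp * span
      w <- 0.004
      for (s0 in sp_t) {
        ssel <- tt >= s0 - w / 2 & tt <= s0 + w / 2
        v[ssel] <- v[ssel] + spike_height * (1 - abs(tt[ssel] - s0) / (w / 2))
      }
    }
  }
  trace(tt, v, meta = list(onsets = onsets))
}

# Base parameter set used across the ODE tests (the reference conductance
# balance).
test_params <- function(...) model_parameters(...)

# Synthetic imaging cell: dF/F traces for the three-condition protocol.
# `kind` decides what the cell does in each condition.
make_imaging_cell <- function(kind, pop_onsets, duration = 120, seed = 1,
                              noise = 0.02) {
  own <- seq(1.3, duration - 2, by = 6.3)      # unrelated rhythm after blockade
  ctrl <- switch(kind,
    non_inspiratory = numeric(0),
    pop_onsets)
  ckt <- switch(kind,
    non_inspiratory = numeric(0),
    non_pacemaker = numeric(0),
    own)
  ril <- switch(kind,
    pacemaker_ril_resistant = own,
    numeric(0))
  cell_condition_record(
    cell_id = paste0(kind, "_", seed),
    control = generate_dff(ctrl, duration, noise_sd = noise, seed = seed),
    population = generate_dff(pop_onsets, duration, noise_sd = noise / 2,
                              seed = seed + 5000),
    cocktail = generate_dff(ckt, duration, noise_sd = noise, seed = seed + 10000),
    cocktail_ril = generate_dff(ril, duration, noise_sd = noise,
                                seed = seed + 20000))
}
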