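#!/usr/bin/env Rscript
# Single-cell conductance-balance simulations: with gNaP fixed at 2.5 nS,
# the discharge phenotype of the model neuron follows gCAN -- plateau
# bursting at 2.5 nS, a mixed plateau/oscillatory pattern at 1 nS and pure
# oscillatory bursting at 0 nS.  Writes one voltage trace and one
# classification row per configuration.

library(prebotsim)

out_dir <- "results/single_cell"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- classifier_config()
rows <- list()
for (gcan in c(2.5, 1, 0)) {
  p <- model_parameters(gNaP = 2.5, gCAN = gcan)
  tr <- simulate(p)
  cl <- classify_discharge(tr, cfg)
  message(sprintf("gCAN = %.1f nS -> %s (%d events, mean DP %.1f mV / %.2f s)",
                  gcan, cl$label, nrow(cl$events),
                  cl$mean_dp_amplitude, cl$mean_dp_duration))
  # store a 5 ms-resolution copy (envelope scale; the classifier above ran
  # on the full 0.5 ms trace)
  thin <- tr[seq(1, nrow(tr), by = 10), ]
  write_trace(trace(thin$t_s, thin$V_mV, meta = attr(tr, "meta")),
              file.path(out_dir, sprintf("trace_gcan_%.1f.csv", gcan)))
  ev <- cl$events
  ev$spike_times <- NULL
  ev$gcan <- gcan
  utils::write.csv(ev, file.path(out_dir, sprintf("events_gcan_%.1f.csv", gcan)),
                   row.names = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    gnap = 2.5, gcan = gcan, label = cl$label, n_events = nrow(cl$events),
    mean_dp_amplitude = cl$mean_dp_amplitude,
    mean_dp_duration = cl$mean_dp_duration,
    burst_frequency = cl$burst_frequency, baseline_vm = cl$baseline_vm)
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out_dir, "classification.csv"),
                 row.names = FALSE)
message("wrote ", out_dir, "/classification.csv")
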