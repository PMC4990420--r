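#!/usr/bin/env Rscript
# In-silico pharmacology and voltage-dependence protocols on the three
# reference configurations: riluzole (gNaP block) and FFA / 9-phenanthrol
# (gCAN block) selectivity, burst-frequency vs applied current, and
# steady-state I-V curves.

library(prebotsim)

out_dir <- "results/pharmacology"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- classifier_config()

configs <- list(plateau = c(gNaP = 2.5, gCAN = 2.5),
                mixed = c(gNaP = 2.5, gCAN = 1),
                oscillatory = c(gNaP = 2.5, gCAN = 0),
                pure_ICAN = c(gNaP = 0, gCAN = 2.5))

classify_cfg <- function(p) classify_discharge(simulate(p, keep_states = FALSE), cfg)

rows <- list()
for (nm in names(configs)) {
  g <- configs[[nm]]
  p <- model_parameters(gNaP = g[["gNaP"]], gCAN = g[["gCAN"]])
  for (drug in c("none", "riluzole", "FFA", "phenanthrol9")) {
    pd <- if (drug == "none") p else apply_blocker(p, drug)
    cl <- classify_cfg(pd)
    census <- table(factor(cl$per_event_labels,
                           levels = c("plateau", "oscillatory")))
    rows[[length(rows) + 1]] <- data.frame(
      configuration = nm, drug = drug, label = cl$label,
      n_events = nrow(cl$events),
      n_plateau_events = census[["plateau"]],
      n_oscillatory_events = census[["oscillatory"]])
    message(sprintf("%-11s + %-12s -> %-13s (%dP / %dO events)",
                    nm, drug, cl$label, census[["plateau"]],
                    census[["oscillatory"]]))
  }
}
utils::write.csv(do.call(rbind, rows), file.path(out_dir, "blocker_census.csv"),
                 row.names = FALSE)

message("burst frequency vs applied current ...")
fi <- NULL
for (nm in c("plateau", "oscillatory")) {
  g <- configs[[nm]]
  p <- model_parameters(gNaP = g[["gNaP"]], gCAN = g[["gCAN"]])
  fc <- current_frequency_curve(p, c(-2, 0, 2, 4, 6, 8))
  fc$configuration <- nm
  fi <- rbind(fi, fc)
  message(sprintf("  %-11s: %s Hz", nm,
                  paste(sprintf("%.3f", fc$frequency_hz), collapse = " ")))
}
utils::write.csv(fi, file.path(out_dir, "frequency_vs_current.csv"),
                 row.names = FALSE)

message("steady-state I-V curves (0.5 s steps, measured at 400 ms) ...")
iv <- NULL
for (nm in c("plateau", "oscillatory")) {
  g <- configs[[nm]]
  p <- model_parameters(gNaP = g[["gNaP"]], gCAN = g[["gCAN"]])
  cur <- iv_curve(p)
  cur$configuration <- nm
  iv <- rbind(iv, cur)
}
utils::write.csv(iv, file.path(out_dir, "iv_curves.csv"), row.names = FALSE)
message("wrote ", out_dir)
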