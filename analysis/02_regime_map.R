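#!/usr/bin/env Rscript
# Discharge-regime structure of the gNaP x gCAN conductance plane: the two
# one-dimensional sweeps (gCAN at fixed gNaP = 2.5 nS; gNaP at fixed
# gCAN = 1.5 nS) and the full two-dimensional map at 0.25 nS resolution.
# About 290 stiff-ODE simulations of 46 s model time each.

library(prebotsim)

out_dir <- "results/regime_map"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

message("gCAN sweep at gNaP = 2.5 nS ...")
sw_can <- sweep_gcan()
write_regime_map(sw_can, file.path(out_dir, "sweep_gcan.tsv"))
message("  band order: ", paste(regime_band_order(sw_can$label),
                                collapse = " -> "))

message("gNaP sweep at gCAN = 1.5 nS ...")
sw_nap <- sweep_gnap()
write_regime_map(sw_nap, file.path(out_dir, "sweep_gnap.tsv"))
message("  band order: ", paste(regime_band_order(sw_nap$label),
                                collapse = " -> "))
message("  (weakly active low-gNaP points with < 3 events in the 40 s ",
        "window are reported as indeterminate)")

message("full map, gNaP 0-3 nS x gCAN 0-4.5 nS ...")
map <- compute_regime_map()
write_regime_map(map, file.path(out_dir, "regime_map.tsv"))
message("  label counts:")
print(table(map$label))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gg <- ggplot(as.data.frame(map), aes(gnap, gcan, fill = label)) +
    geom_tile(colour = "grey30", linewidth = 0.1) +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "gNaP (nS)", y = "gCAN (nS)", fill = "discharge",
         title = "Model discharge phenotype over the conductance plane") +
    theme_minimal()
  ggsave(file.path(out_dir, "regime_map.pdf"), gg, width = 6, height = 4.5)
  message("wrote ", out_dir, "/regime_map.pdf")
}
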