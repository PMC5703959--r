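#!/usr/bin/env Rscript
# Stage 1: generate the two-trait GWAS summary statistics, the LD-blocked
# reference panel, and the ground-truth labels for the default pleiotropic
# architecture (20,000 SNPs; 90% null / 4% per-trait / 2% pleiotropic;
# |z| non-centrality 3; panel of 500 samples, 10-SNP blocks at rho = 0.9),
# plus a matched independent-label negative control.

suppressMessages(library(pleiocfdr))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

seed <- 20260923L
cfg <- sim_config(seed = seed)
sim <- simulate_two_trait_stats(cfg)
panel <- simulate_reference_panel(cfg)

write_results_table(sim$stats_a, "results/data/trait_a.tsv")
write_results_table(sim$stats_b, "results/data/trait_b.tsv")
write_results_table(sim$truth, "results/data/truth.tsv")
write_reference_panel(panel, "results/data/panel.tsv")

ctrl <- simulate_two_trait_stats(negative_control_config(seed = seed + 1L))
write_results_table(ctrl$stats_a, "results/data/control_trait_a.tsv")
write_results_table(ctrl$stats_b, "results/data/control_trait_b.tsv")

tab <- table(sim$truth$component)
cat("Simulated", nrow(sim$stats_a), "SNPs per trait. Component counts:\n")
print(tab)
cat("Panel:", nrow(panel$info), "SNPs x", ncol(panel$dosages),
    "samples; MAF range",
    paste(round(range(panel$info$maf), 3), collapse = "-"), "\n")
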