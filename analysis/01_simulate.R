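#!/usr/bin/env Rscript
# Generates the synthetic study inputs: a candidate genetic/epigenetic
# network with planted ground truth, control expression from that truth, and
# disease expression from a perturbed truth (a share of abilities rescaled, a
# share of edges dropped). Writes the TSV bundle the later stages read.

suppressMessages(library(gwgendrug))
gw_log_level("info")

dir.create("results", showWarnings = FALSE)
bundle <- write_synthetic_bundle(
  "results/synthetic_input",
  n_control = 86, n_disease = 123,   # cohort sizes of the motivating study
  seed = 1L,
  n_protein = 10, n_gene = 20, n_lncRNA = 6, n_miRNA = 6, n_tf = 8,
  density = 0.25, spurious_fraction = 0.5, cascade = FALSE)

net <- bundle$network
cat(sprintf("candidate network: %d nodes, %d edges (%d planted true, %.0f%% spurious)\n",
            nrow(net$nodes), nrow(net$edges),
            nrow(bundle$truth_control$true_edges),
            100 * (1 - nrow(bundle$truth_control$true_edges) / nrow(net$edges))))
cat(sprintf("disease truth: %d edges after perturbation\n",
            nrow(bundle$truth_disease$true_edges)))
cat("inputs written under results/synthetic_input/\n")
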