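# shared fixture builders; everything is generated in code, no stored data

quiet_logs <- function() gw_log_level("error")
quiet_logs()

# hand-built five-kind network: two proteins in a ppi, one TF-regulated gene
# with a miRNA repressor, one lncRNA
tiny_network <- function() {
  nodes <- data.frame(
    id = c("PA", "PB", "TF1", "G1", "L1", "M1"),
    kind = c("protein", "protein", "TF", "gene", "lncRNA", "miRNA"))
  edges <- data.frame(
    source = c("PA", "TF1", "L1", "M1"),
    target = c("PB", "G1", "G1", "G1"),
    mode = c("ppi", "tf->gene", "lncRNA->gene", "miRNA->gene"))
  gwgen(nodes, edges)
}

# expression matrix with given entity rows, half control half disease
make_expr <- function(values, n_control = ncol(values) / 2) {
  colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  grp <- rep(c("control", "disease"), c(n_control, ncol(values) - n_control))
  expression_matrix(values, stats::setNames(grp, colnames(values)))
}

# single-layer generator instance used across identification tests
flat_instance <- function(seed, n_samples = 100, noise_sd = 0, spurious = 0,
                          prob_negative = 0, ...) {
  gen <- generate_candidate_gwgen(6, 8, 4, 4, density = 0.3,
                                  spurious_fraction = spurious, seed = seed,
                                  noise_sd = noise_sd, cascade = FALSE,
                                  prob_negative = prob_negative, ...)
  expr <- simulate_expression(gen$truth, gen$network, n_samples,
                              seed = seed + 5000L)
  list(gen = gen, expr = expr)
}

# expected regression coefficient for a true edge (miRNA abilities enter
# negatively)
model_coef <- function(edge_row) {
  ifelse(grepl("^miRNA->", edge_row$mode), -edge_row$ability, edge_row$ability)
}

# canonical edge keys of a truth table
truth_keys <- function(truth) {
  e <- truth$true_edges
  ppi <- e$mode == "ppi"
  s <- ifelse(ppi, pmin(e$source, e$target), e$source)
  t <- ifelse(ppi, pmax(e$source, e$target), e$target)
  paste(s, t, e$mode, sep = "\r")
}

network_keys <- function(net) {
  paste(net$edges$source, net$edges$target, net$edges$mode, sep = "\r")
}
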