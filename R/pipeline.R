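# End-to-end driver: identification + pruning per group, principal network
# projection, core extraction, comparison, optional enrichment and the
# optional drug-discovery stages. Each stage failure aborts with a
# stage-labelled message; seeds and timings are logged and written.

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stopf("[stage %s] %s", name, conditionMessage(e))
  })
  gw_log("info", "stage %s done in %.2fs", name,
         as.numeric(Sys.time() - t0, units = "secs"))
  res
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads the candidate network and expression data, identifies and prunes the
#' real network separately for control and disease samples, extracts both
#' core networks by principal network projection, compares them and labels
#' expression direction, optionally runs gene-set over-representation on the
#' disease core, and writes TSV/JSON results under `config$paths$out_dir`.
#' When `config$dti$enabled`, a DTI model is cross-validated on the feature
#' table at `config$paths$dti_features` (rows = pairs) with 0/1 labels in
#' `config$paths$dti_labels`; when `config$drug$enabled`, the drug tables at
#' `config$paths$drug_tables` are screened and the selected combination
#' written as JSON. Any stage failure aborts with a stage-labelled message.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, a list with both pruned networks, both cores, the
#'   comparison, directions and (if configured) enrichment.
#' @export
run_pipeline <- function(config = default_config()) {
  gw_log_level(config$log_level %||% "info")
  out_dir <- config$paths$out_dir %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seeds$pipeline %||% 1L)

  inputs <- .stage("identify", {
    if (is.null(config$paths$network) || !file.exists(config$paths$network)) {
      stopf("candidate network file not found: %s", config$paths$network %||% "<unset>")
    }
    if (is.null(config$paths$expression) || !file.exists(config$paths$expression)) {
      stopf("expression file not found: %s", config$paths$expression %||% "<unset>")
    }
    list(network = read_edge_table(config$paths$network),
         expr = read_expression_table(config$paths$expression, config$paths$groups))
  })

  real <- .stage("prune", {
    lapply(c(control = "control", disease = "disease"), function(g) {
      prune_network(inputs$network, subset_samples(inputs$expr, g),
                    log1p = isTRUE(config$identify$log1p))
    })
  })

  cores <- .stage("pnp", {
    lapply(real, function(r) {
      pnp_core(r, threshold = config$pnp$energy_threshold, top_k = config$pnp$top_k)
    })
  })

  cmp <- .stage("compare", {
    comparison <- diff_networks(cores$disease$core, cores$control$core)
    direction <- expression_direction(inputs$expr, config$compare$min_abs_log2fc)
    enrichment <- NULL
    if (!is.null(config$paths$gene_sets)) {
      sets <- read_gene_sets(config$paths$gene_sets)
      enrichment <- enrich_gene_sets(cores$disease$core$nodes$id, sets,
                                     inputs$network$nodes$id)
    }
    list(comparison = comparison, direction = direction, enrichment = enrichment)
  })

  dti <- NULL
  if (isTRUE(config$dti$enabled)) {
    dti <- .stage("dti-train", {
      p <- config$paths
      for (f in c("dti_features", "dti_labels")) {
        if (is.null(p[[f]]) || !file.exists(p[[f]])) stopf("%s file not found", f)
      }
      feats <- as.matrix(utils::read.delim(p$dti_features, row.names = 1,
                                           check.names = FALSE))
      labs <- utils::read.delim(p$dti_labels)$label
      cfg <- do.call(dti_config, c(config$dti[setdiff(names(config$dti), "enabled")],
                                   list(seed = config$seeds$dti %||% 1L)))
      cv <- cross_validate(feats, labs, cfg)
      utils::write.table(cv$report, file.path(out_dir, "dti_cv_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cv
    })
  }

  drug <- NULL
  if (isTRUE(config$drug$enabled)) {
    drug <- .stage("drug-select", {
      if (is.null(config$paths$drug_tables)) stopf("drug_tables directory unset")
      tab <- read_drug_spec_tables(config$paths$drug_tables)
      desired <- unlist(config$drug$desired)
      comb <- select_combination(tab, desired, max_size = config$drug$max_size)
      jsonlite::write_json(
        list(drugs = comb$drugs, aggregate_regulation = as.list(comb$aggregate),
             total_side_effect = comb$total_side_effect,
             subset_diagnostics = comb$subsets),
        file.path(out_dir, "drug_combination.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      comb
    })
  }

  write_edge_table(real$control, file.path(out_dir, "real_network_control.tsv"))
  write_edge_table(real$disease, file.path(out_dir, "real_network_disease.tsv"))
  write_edge_table(cores$control$core, file.path(out_dir, "core_control.tsv"))
  write_edge_table(cores$disease$core, file.path(out_dir, "core_disease.tsv"))
  utils::write.table(cmp$direction, file.path(out_dir, "expression_direction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seeds = config$seeds,
    n_candidate_edges = nrow(inputs$network$edges),
    n_real_edges = vapply(real, function(r) nrow(r$edges), numeric(1)),
    pnp_rank = vapply(cores, function(c) c$I, numeric(1)),
    n_core_nodes = vapply(cores, function(c) nrow(c$core$nodes), numeric(1)),
    edges_common = nrow(cmp$comparison$common_edges),
    edges_disease_only = nrow(cmp$comparison$disease_only_edges),
    edges_control_only = nrow(cmp$comparison$control_only_edges)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cmp$enrichment)) {
    utils::write.table(cmp$enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(real = real, cores = cores, comparison = cmp$comparison,
                 direction = cmp$direction, enrichment = cmp$enrichment,
                 dti = dti, drug = drug, summary = summary))
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates a candidate network with planted truth, simulates control
#' samples from it and disease samples from a perturbed truth, and writes the
#' edge table, expression matrix and group labels that [run_pipeline()]
#' expects.
#'
#' @param dir Output directory.
#' @param n_control,n_disease Samples per group.
#' @param seed Integer seed.
#' @param ... Passed to [generate_candidate_gwgen()].
#' @return Invisibly, a list with the paths, the generated network and both
#'   truths.
#' @export
write_synthetic_bundle <- function(dir, n_control = 60, n_disease = 60,
                                   seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_candidate_gwgen(..., seed = seed)
  truth_dis <- perturb_truth(gen$truth, seed = seed + 1L)
  ctrl <- simulate_expression(gen$truth, gen$network, n_control,
                              seed = seed + 2L, group = "control")
  dis <- simulate_expression(truth_dis, gen$network, n_disease,
                             seed = seed + 3L, group = "disease")
  expr <- combine_expression(ctrl, dis)
  paths <- list(network = file.path(dir, "candidate_network.tsv"),
                expression = file.path(dir, "expression.tsv"),
                groups = file.path(dir, "groups.tsv"))
  write_edge_table(gen$network, paths$network)
  write_expression_table(expr, paths$expression, paths$groups)
  invisible(list(paths = paths, network = gen$network,
                 truth_control = gen$truth, truth_disease = truth_dis))
}
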