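# Disease/control core-network comparison: edge and node partitions, per-node
# expression direction, and gene-set over-representation in place of an
# online annotation service.

#' Partition two core networks into common and group-specific parts
#'
#' Edge identity is (source, target, mode) with undirected interactions in
#' canonical order, so the three edge sets partition the union of both cores.
#'
#' @param core_disease,core_control [gwgen()] networks.
#' @return Object of class `"gwgen_comparison"` with edge data frames
#'   `common_edges`, `disease_only_edges`, `control_only_edges` and node id
#'   vectors `common_nodes`, `disease_only_nodes`, `control_only_nodes`.
#' @export
diff_networks <- function(core_disease, core_control) {
  kd <- edge_key(core_disease$edges)
  kc <- edge_key(core_control$edges)
  structure(list(
    common_edges = core_disease$edges[kd %in% kc, , drop = FALSE],
    disease_only_edges = core_disease$edges[!kd %in% kc, , drop = FALSE],
    control_only_edges = core_control$edges[!kc %in% kd, , drop = FALSE],
    common_nodes = sort(intersect(core_disease$nodes$id, core_control$nodes$id)),
    disease_only_nodes = sort(setdiff(core_disease$nodes$id, core_control$nodes$id)),
    control_only_nodes = sort(setdiff(core_control$nodes$id, core_disease$nodes$id))
  ), class = "gwgen_comparison")
}

#' @export
print.gwgen_comparison <- function(x, ...) {
  cat("core network comparison:\n")
  cat(sprintf("  edges: %d common, %d disease-only, %d control-only\n",
              nrow(x$common_edges), nrow(x$disease_only_edges), nrow(x$control_only_edges)))
  cat(sprintf("  nodes: %d common, %d disease-only, %d control-only\n",
              length(x$common_nodes), length(x$disease_only_nodes), length(x$control_only_nodes)))
  invisible(x)
}

#' Label each entity's expression direction in disease versus control
#'
#' Uses the pseudo-counted log2 fold change of group means,
#' `log2((mean_disease + 1) / (mean_control + 1))`, labelling
#' `higher-in-disease` / `lower-in-disease` when its magnitude reaches
#' `min_abs_log2fc` and `unchanged` otherwise.
#'
#' @param expr An [expression_matrix()] containing both groups.
#' @param min_abs_log2fc Direction threshold (default 0.5).
#' @return Data frame `id`, `log2fc`, `direction`.
#' @export
expression_direction <- function(expr, min_abs_log2fc = 0.5) {
  dis <- expr$group == "disease"
  ctl <- expr$group == "control"
  if (!any(dis) || !any(ctl)) stopf("both groups must be nonempty")
  m_d <- rowMeans(expr$values[, dis, drop = FALSE])
  m_c <- rowMeans(expr$values[, ctl, drop = FALSE])
  lfc <- log2((m_d + 1) / (m_c + 1))
  direction <- ifelse(abs(lfc) < min_abs_log2fc, "unchanged",
                      ifelse(lfc > 0, "higher-in-disease", "lower-in-disease"))
  data.frame(id = rownames(expr$values), log2fc = unname(lfc),
             direction = unname(direction), stringsAsFactors = FALSE)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric p-value per set (the probability of an
#' overlap at least as large under random selection from the universe), with
#' Benjamini-Hochberg q-values across sets. Raw p-values are kept alongside.
#'
#' @param nodes Selected node ids (must lie within `universe`).
#' @param sets A [read_gene_sets()] collection (or named list).
#' @param universe Background node ids.
#' @return Data frame `set`, `set_size`, `overlap`, `p`, `q`, sorted by `p`.
#' @export
enrich_gene_sets <- function(nodes, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  nodes <- unique(nodes)
  if (length(setdiff(nodes, universe))) stopf("nodes must be a subset of the universe")
  n_univ <- length(universe)
  n_sel <- length(nodes)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(members, nodes))
    K <- length(members)
    p <- stats::phyper(k - 1, K, n_univ - K, n_sel, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}
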