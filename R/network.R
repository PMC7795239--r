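# Mixed directed/undirected networks over proteins, genes, TFs, lncRNAs and
# miRNAs. Protein-protein interaction ("ppi") edges are undirected and stored
# with source < target; every other mode is a directed regulation.

#' Supported edge modes
#'
#' `"ppi"` is an undirected protein-protein interaction; all other modes are
#' directed regulations named `<source kind>-><target kind>`.
#'
#' @return Character vector of mode names.
#' @export
edge_modes <- function() {
  c("ppi",
    "tf->gene", "tf->lncRNA", "tf->miRNA",
    "lncRNA->gene", "lncRNA->lncRNA", "lncRNA->miRNA",
    "miRNA->gene", "miRNA->lncRNA", "miRNA->miRNA")
}

.mode_kinds <- function() {
  data.frame(
    mode = edge_modes(),
    source_kind = c("protein", "TF", "TF", "TF", "lncRNA", "lncRNA", "lncRNA",
                    "miRNA", "miRNA", "miRNA"),
    target_kind = c("protein", "gene", "lncRNA", "miRNA", "gene", "lncRNA",
                    "miRNA", "gene", "lncRNA", "miRNA"),
    stringsAsFactors = FALSE
  )
}

node_kinds <- function() c("protein", "gene", "TF", "lncRNA", "miRNA")

.canonicalize_ppi <- function(edges) {
  ppi <- edges$mode == "ppi"
  if (any(ppi)) {
    s <- edges$source[ppi]
    t <- edges$target[ppi]
    flip <- s > t
    edges$source[ppi] <- ifelse(flip, t, s)
    edges$target[ppi] <- ifelse(flip, s, t)
  }
  edges
}

#' Construct a candidate (or identified) genetic/epigenetic network
#'
#' @param nodes Data frame with columns `id`, `kind` (`kind` in
#'   [node_kinds()]); ids must be unique and nonempty.
#' @param edges Data frame with columns `source`, `target`, `mode` and
#'   optionally `ability` (numeric, `NA` before identification).
#' @return An object of class `"gwgen"` with canonicalized, deduplicated edges.
#' @export
gwgen <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "kind") %in% names(nodes))) stopf("nodes needs columns id, kind")
  if (nrow(edges) > 0 && !all(c("source", "target", "mode") %in% names(edges))) {
    stopf("edges needs columns source, target, mode")
  }
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  if (any(!nzchar(nodes$id))) stopf("empty node id")
  bad_kind <- setdiff(unique(nodes$kind), node_kinds())
  if (length(bad_kind)) stopf("unknown node kind: %s", paste(bad_kind, collapse = ", "))
  if (is.null(edges$ability)) edges$ability <- rep(NA_real_, nrow(edges))
  edges <- edges[, c("source", "target", "mode"), drop = FALSE] |>
    cbind(ability = as.numeric(edges$ability))
  bad_mode <- setdiff(unique(edges$mode), edge_modes())
  if (length(bad_mode)) stopf("unknown edge mode: %s", paste(bad_mode, collapse = ", "))
  edges <- .canonicalize_ppi(edges)
  edges <- edges[!duplicated(edges[, c("source", "target", "mode")]), , drop = FALSE]
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing)) stopf("edge endpoint(s) not in nodes: %s", paste(missing, collapse = ", "))
  kind_of <- stats::setNames(nodes$kind, nodes$id)
  mk <- .mode_kinds()
  for (m in unique(edges$mode)) {
    row <- mk[mk$mode == m, ]
    e <- edges[edges$mode == m, ]
    bad <- kind_of[e$source] != row$source_kind | kind_of[e$target] != row$target_kind
    if (any(bad)) {
      stopf("edge kind inconsistent with mode %s: %s -> %s", m,
            e$source[bad][1], e$target[bad][1])
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "gwgen")
}

#' @export
print.gwgen <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = node_kinds()))
  cat("gwgen network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  modes <- table(x$edges$mode)
  if (length(modes)) {
    cat("  edges:", paste(sprintf("%s=%d", names(modes), modes), collapse = ", "), "\n")
  }
  n_ab <- sum(!is.na(x$edges$ability))
  cat("  identified abilities:", n_ab, "of", nrow(x$edges), "\n")
  invisible(x)
}

# Infer node kinds from the modes an id participates in; conflicting roles are
# an error (a node has exactly one kind).
.infer_nodes <- function(edges) {
  mk <- .mode_kinds()
  bad <- setdiff(unique(edges$mode), mk$mode)
  if (length(bad)) stopf("unknown edge mode: %s", paste(bad, collapse = ", "))
  src_kind <- unname(stats::setNames(mk$source_kind, mk$mode)[edges$mode])
  tgt_kind <- unname(stats::setNames(mk$target_kind, mk$mode)[edges$mode])
  df <- rbind(data.frame(id = edges$source, kind = src_kind, stringsAsFactors = FALSE),
              data.frame(id = edges$target, kind = tgt_kind, stringsAsFactors = FALSE))
  df <- unique(df)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stopf("node(s) with conflicting kinds across edge modes: %s",
          paste(unique(dup), collapse = ", "))
  }
  df[order(df$id), , drop = FALSE]
}

#' Read a network from a tab-separated edge table
#'
#' Expects a header with columns `source`, `target`, `mode` and optionally
#' `ability`. Node kinds are inferred from the edge modes; an id used in
#' incompatible roles is an error.
#'
#' @param path Path to a TSV file.
#' @return A [gwgen()] network.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) stopf("empty edge table: %s", path)
  if (!all(c("source", "target", "mode") %in% names(df))) {
    stopf("edge table needs columns source, target, mode")
  }
  if (!is.null(df$ability)) {
    df$ability <- suppressWarnings(as.numeric(df$ability))
  }
  gwgen(.infer_nodes(df), df)
}

#' Write a network as a tab-separated edge table
#'
#' Output is sorted (mode, source, target) so writing is byte-stable across
#' read/write round trips.
#'
#' @param network A [gwgen()] network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(network, path) {
  e <- network$edges
  e <- e[order(e$mode, e$source, e$target), , drop = FALSE]
  if (all(is.na(e$ability))) e$ability <- NULL
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# incoming candidate regulators of one target, grouped the way the regression
# design orders them (TF, lncRNA, miRNA blocks; ppi partners for proteins)
.regulators_of <- function(network, target_id) {
  kind <- network$nodes$kind[match(target_id, network$nodes$id)]
  if (is.na(kind)) stopf("node not in network: %s", target_id)
  e <- network$edges
  if (kind == "protein") {
    ppi <- e[e$mode == "ppi" & (e$source == target_id | e$target == target_id), , drop = FALSE]
    partners <- ifelse(ppi$source == target_id, ppi$target, ppi$source)
    return(list(kind = kind,
                regulators = data.frame(id = partners,
                                        class = rep("protein", length(partners)),
                                        stringsAsFactors = FALSE)))
  }
  if (!kind %in% c("gene", "lncRNA", "miRNA")) {
    return(list(kind = kind, regulators = data.frame(id = character(), class = character())))
  }
  inc <- e[e$target == target_id & e$mode != "ppi", , drop = FALSE]
  cls <- sub("->.*$", "", inc$mode)           # tf / lncRNA / miRNA
  ord <- order(match(cls, c("tf", "lncRNA", "miRNA")), inc$source)
  list(kind = kind,
       regulators = data.frame(id = inc$source[ord],
                               class = c(tf = "TF", lncRNA = "lncRNA", miRNA = "miRNA")[cls[ord]],
                               stringsAsFactors = FALSE))
}

# targets that have at least one candidate regulator / interaction partner
.identifiable_targets <- function(network) {
  e <- network$edges
  ids <- unique(c(e$target[e$mode != "ppi"], e$source[e$mode == "ppi"], e$target[e$mode == "ppi"]))
  sort(ids)
}

edge_key <- function(edges) paste(edges$source, edges$target, edges$mode, sep = "\r")
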