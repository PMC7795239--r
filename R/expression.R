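# Entity x sample expression with control/disease group labels. Values are
# nonnegative and complete; TFs are measured through their own row (the
# gene/protein expression proxy).

#' Construct an expression matrix with group labels
#'
#' @param values Numeric matrix, entities in rows (rownames = ids), samples in
#'   columns (colnames = sample ids). Nonnegative, no missing values.
#' @param group Character/factor of `"control"`/`"disease"`, one per sample.
#' @return Object of class `"expr_matrix"`: list with `values` and `group`.
#' @export
expression_matrix <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("values needs unique rownames (entity ids)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("values needs unique colnames (sample ids)")
  }
  if (ncol(values) < 2) stopf("need at least 2 samples")
  if (anyNA(values)) stopf("missing expression values")
  if (any(values < 0)) stopf("negative expression values")
  group <- as.character(group)
  if (length(group) != ncol(values)) stopf("one group label per sample required")
  if (is.null(names(group))) names(group) <- colnames(values)
  if (!setequal(names(group), colnames(values))) stopf("group labels do not match sample ids")
  group <- group[colnames(values)]
  bad <- setdiff(unique(group), c("control", "disease"))
  if (length(bad)) stopf("group labels must be control/disease, got: %s", paste(bad, collapse = ", "))
  structure(list(values = values, group = group), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "entities x", ncol(x$values), "samples (",
      sum(x$group == "control"), "control /", sum(x$group == "disease"), "disease )\n")
  invisible(x)
}

#' Number of samples
#' @param expr An [expression_matrix()].
#' @return Integer sample count.
#' @export
n_samples <- function(expr) ncol(expr$values)

#' Read an expression matrix and its group labels
#'
#' @param path TSV, first column entity ids, remaining columns samples.
#' @param groups_path TSV with columns `sample`, `group`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, groups_path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!file.exists(groups_path)) stopf("no such file: %s", groups_path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stopf("duplicate entity row: %s", ids[duplicated(ids)][1])
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- ids
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g))) stopf("groups file needs columns sample, group")
  missing <- setdiff(colnames(values), g$sample)
  if (length(missing)) stopf("sample(s) missing from groups file: %s", paste(missing, collapse = ", "))
  extra <- setdiff(g$sample, colnames(values))
  if (length(extra)) stopf("group label(s) for unknown sample(s): %s", paste(extra, collapse = ", "))
  expression_matrix(values, stats::setNames(g$group, g$sample))
}

#' Write an expression matrix and its group labels
#'
#' @param expr An [expression_matrix()].
#' @param path Output TSV for values.
#' @param groups_path Output TSV for group labels.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, groups_path) {
  df <- data.frame(entity = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- data.frame(sample = colnames(expr$values), group = unname(expr$group))
  utils::write.table(g, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to one group
#'
#' @param expr An [expression_matrix()].
#' @param group `"control"` or `"disease"`.
#' @return An [expression_matrix()] holding only that group's samples.
#' @export
subset_samples <- function(expr, group = c("control", "disease")) {
  group <- match.arg(group)
  keep <- expr$group == group
  if (sum(keep) < 2) stopf("fewer than 2 samples in group %s", group)
  expression_matrix(expr$values[, keep, drop = FALSE], expr$group[keep])
}

#' Combine expression matrices over disjoint sample sets
#'
#' @param ... [expression_matrix()] objects sharing the same entities.
#' @return A single [expression_matrix()].
#' @export
combine_expression <- function(...) {
  xs <- list(...)
  ids <- rownames(xs[[1]]$values)
  for (x in xs[-1]) {
    if (!identical(rownames(x$values), ids)) stopf("entity rows differ between matrices")
  }
  expression_matrix(do.call(cbind, lapply(xs, function(x) x$values)),
                    unlist(lapply(xs, function(x) x$group)))
}

# Drop network nodes absent from the expression matrix (with a logged warning)
# rather than erroring; returns the restricted network.
align_network_expression <- function(network, expr) {
  missing <- setdiff(network$nodes$id, rownames(expr$values))
  if (length(missing) == 0) return(network)
  gw_log("warn", "dropping %d network node(s) absent from expression data: %s",
         length(missing), paste(utils::head(missing, 5), collapse = ", "))
  keep_nodes <- network$nodes[!network$nodes$id %in% missing, , drop = FALSE]
  e <- network$edges
  keep <- e$source %in% keep_nodes$id & e$target %in% keep_nodes$id
  gwgen(keep_nodes, e[keep, , drop = FALSE])
}
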