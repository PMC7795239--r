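# Principal network projection: the identified abilities are arranged in a
# node x regulator matrix H, decomposed by SVD, and each node is scored by the
# squared projection of its row onto the top singular vectors carrying at
# least 85% of the energy. The top-scoring nodes induce the core network.

#' Assemble the network matrix H of an identified network
#'
#' Rows are the target entities (proteins, then genes, lncRNAs, miRNAs; sorted
#' by id within kind); columns are the regulators (proteins participating in
#' interactions together with TFs, then lncRNAs, then miRNAs). An undirected
#' protein interaction contributes its ability symmetrically to both
#' (A-row, B-column) and (B-row, A-column).
#'
#' @param real A [gwgen()] with identified abilities (from [prune_network()]).
#' @return Object of class `"network_matrix"`: `H`, `row_index`, `col_index`.
#' @export
build_network_matrix <- function(real) {
  e <- real$edges
  if (nrow(e) == 0) stopf("network has no edges")
  if (anyNA(e$ability)) stopf("network has unidentified abilities")
  kind_of <- stats::setNames(real$nodes$kind, real$nodes$id)
  rows <- unlist(lapply(c("protein", "gene", "lncRNA", "miRNA"), function(k)
    sort(real$nodes$id[real$nodes$kind == k])))
  ppi <- e[e$mode == "ppi", , drop = FALSE]
  dir <- e[e$mode != "ppi", , drop = FALSE]
  block1 <- sort(unique(c(ppi$source, ppi$target, dir$source[kind_of[dir$source] == "TF"])))
  block2 <- sort(unique(dir$source[kind_of[dir$source] == "lncRNA"]))
  block3 <- sort(unique(dir$source[kind_of[dir$source] == "miRNA"]))
  cols <- c(block1, block2, block3)
  H <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(dir)) H[cbind(dir$target, dir$source)] <- dir$ability
  if (nrow(ppi)) {
    H[cbind(ppi$source, ppi$target)] <- ppi$ability
    H[cbind(ppi$target, ppi$source)] <- ppi$ability
  }
  structure(list(H = H, row_index = rows, col_index = cols),
            class = "network_matrix")
}

#' Singular value decomposition of a network matrix
#'
#' @param nm A [build_network_matrix()] result (or a plain matrix).
#' @return Object of class `"pnp_result"`: `H`, `row_index`, `singular_values`
#'   (descending), `left_vectors` (S), `right_vectors` (D), `energies`
#'   (normalized squared singular values).
#' @export
decompose_network <- function(nm) {
  H <- if (inherits(nm, "network_matrix")) nm$H else as.matrix(nm)
  row_index <- if (inherits(nm, "network_matrix")) nm$row_index else rownames(H)
  sv <- svd(H)
  tot <- sum(sv$d^2)
  structure(list(H = H, row_index = row_index,
                 singular_values = sv$d,
                 left_vectors = sv$u, right_vectors = sv$v,
                 energies = if (tot > 0) sv$d^2 / tot else rep(NaN, length(sv$d))),
            class = "pnp_result")
}

#' Number of singular structures needed to reach an energy threshold
#'
#' @param pnp A [decompose_network()] result.
#' @param threshold Energy fraction in (0, 1], default 0.85.
#' @return Minimal `I` with cumulative energy >= `threshold`.
#' @export
energy_rank <- function(pnp, threshold = 0.85) {
  if (!(threshold > 0 && threshold <= 1)) stopf("threshold must be in (0,1]")
  if (sum(pnp$singular_values^2) == 0) stopf("all-zero network matrix: energy undefined")
  cum <- cumsum(pnp$energies)
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Project nodes onto the top singular vectors and score them
#'
#' `Z[a, b]` is the projection of row `a` of `H` on the `b`-th right singular
#' vector; the node score is the sum of squared projections over the top `I`
#' vectors (at full rank this equals the squared row norm).
#'
#' @param pnp A [decompose_network()] result.
#' @param I Number of singular vectors to project on.
#' @return Named numeric vector of node scores; the projection matrix `Z` is
#'   attached as `attr(, "Z")`.
#' @export
project_scores <- function(pnp, I) {
  if (!is_count(I) || I > ncol(pnp$right_vectors)) {
    stopf("I must be in 1..%d", ncol(pnp$right_vectors))
  }
  Z <- pnp$H %*% pnp$right_vectors[, seq_len(I), drop = FALSE]
  s <- rowSums(Z^2)
  names(s) <- pnp$row_index
  attr(s, "Z") <- Z
  s
}

#' Extract the core network of the top-scoring nodes
#'
#' Retains the `top_k` highest-scoring nodes (ties broken by lexicographic
#' id; all nodes if fewer exist) and induces the subnetwork on them.
#'
#' @param real The identified [gwgen()] network.
#' @param scores Named node scores from [project_scores()]; must cover every
#'   scored (target-kind) node of `real`.
#' @param top_k Number of nodes to retain (default 3000).
#' @return A [gwgen()] core network; retained ids in `attr(, "retained")`.
#' @export
extract_core <- function(real, scores, top_k = 3000) {
  if (!is_count(top_k)) stopf("top_k must be >= 1")
  need <- real$nodes$id
  missing <- setdiff(need, names(scores))
  if (length(missing)) stopf("scores missing for node(s): %s", paste(missing, collapse = ", "))
  ord <- order(-scores[need], need)
  retained <- need[ord][seq_len(min(top_k, length(need)))]
  keep_edges <- real$edges$source %in% retained & real$edges$target %in% retained
  nodes <- real$nodes[real$nodes$id %in% retained, , drop = FALSE]
  out <- gwgen(nodes, real$edges[keep_edges, , drop = FALSE])
  attr(out, "retained") <- retained
  out
}

#' Run the full principal-network-projection stage
#'
#' Target-kind nodes (proteins, genes, lncRNAs, miRNAs) are scored by their
#' H-row projections ([project_scores()]). Regulator-only nodes (TFs) have no
#' row; they are ranked by the symmetric column score, the squared projection
#' of their H-column onto the top `I` left singular vectors, so that every
#' node can compete for a core slot. Nodes without surviving edges score 0.
#'
#' @param real Identified [gwgen()] network.
#' @param threshold Energy threshold (default 0.85).
#' @param top_k Core size (default 3000).
#' @return List with `pnp` (decomposition), `I`, `scores`, `core`.
#' @export
pnp_core <- function(real, threshold = 0.85, top_k = 3000) {
  nm <- build_network_matrix(real)
  pnp <- decompose_network(nm)
  I <- energy_rank(pnp, threshold)
  scores <- project_scores(pnp, I)
  full <- stats::setNames(rep(0, nrow(real$nodes)), real$nodes$id)
  full[names(scores)] <- scores
  # column score for regulator-only nodes (TFs)
  tfs <- intersect(real$nodes$id[real$nodes$kind == "TF"], nm$col_index)
  if (length(tfs)) {
    Zc <- t(pnp$H[, tfs, drop = FALSE]) %*% pnp$left_vectors[, seq_len(I), drop = FALSE]
    full[tfs] <- rowSums(Zc^2)
  }
  core <- extract_core(real, full, top_k)
  list(pnp = pnp, I = I, scores = full, core = core)
}
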