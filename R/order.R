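# System-order detection: for each entity the number of genuine regulators is
# the order minimizing AIC = log(SSE/N) + 2*(order+1)/N over a nested family
# of refitted models, ordered by decreasing |coefficient| from the full
# constrained fit. Edges outside the detected order are false positives and
# removed, yielding the real network.

#' Akaike information criterion for a fitted order
#'
#' `omega = sse / n_samples` is the residual variance estimate;
#' `aic = log(omega) + 2 * (order + 1) / n_samples` (natural log; +1 counts
#' the basal level). A perfect fit (`sse = 0`) has `omega` floored at 1e-12
#' with a logged warning, keeping the criterion finite.
#'
#' @param sse Residual sum of squares (>= 0).
#' @param order Retained regulator count (>= 0).
#' @param n_samples Sample count (>= 1).
#' @return List with `order`, `omega`, `aic`.
#' @export
compute_aic <- function(sse, order, n_samples) {
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  if (sse < 0) stopf("sse must be >= 0")
  omega <- sse / n_samples
  if (omega < 1e-12) {
    gw_log("warn", "residual variance ~0; flooring omega at 1e-12")
    omega <- 1e-12
  }
  list(order = order, omega = omega,
       aic = log(omega) + 2 * (order + 1) / n_samples)
}

# refit the problem restricted to a subset of regulator columns
.refit_subset <- function(problem, keep_idx) {
  O <- nrow(problem$column_meta)
  cols <- c(keep_idx, O + 1L)
  sub <- structure(list(
    target_id = problem$target_id,
    response = problem$response,
    design = problem$design[, cols, drop = FALSE],
    column_meta = problem$column_meta[keep_idx, , drop = FALSE],
    mirna_mask = problem$mirna_mask[cols],
    kind = problem$kind
  ), class = "gw_regression")
  fit_constrained(sub)
}

#' Detect the true system order of one target by AIC minimization
#'
#' Fits the full constrained model, ranks candidate regulators by decreasing
#' absolute coefficient, refits the nested models of order `k = 0..K`, and
#' returns the order minimizing AIC (ties resolved toward fewer regulators).
#'
#' @inheritParams build_regression
#' @return List of class `"gw_order"`: `retained` (column_meta rows of the
#'   surviving regulators), `estimate` (the refitted [fit_constrained()] at
#'   the selected order), `order`, and `aic_path` (data frame over k).
#' @export
detect_order <- function(target_id, network, expr, log1p = FALSE) {
  problem <- build_regression(target_id, network, expr, log1p = log1p)
  N <- length(problem$response)
  K <- nrow(problem$column_meta)
  full <- fit_constrained(problem)
  rank_idx <- order(abs(full$theta[seq_len(K)]), decreasing = TRUE)
  fits <- vector("list", K + 1L)
  aics <- numeric(K + 1L)
  for (k in 0:K) {
    keep <- if (k == 0) integer(0) else sort(rank_idx[seq_len(k)])
    fits[[k + 1L]] <- .refit_subset(problem, keep)
    aics[k + 1L] <- compute_aic(fits[[k + 1L]]$sse, k, N)$aic
  }
  k_star <- which.min(aics) - 1L      # which.min takes the first (smallest k) tie
  best <- fits[[k_star + 1L]]
  structure(list(target_id = target_id,
                 retained = best$column_meta,
                 estimate = best,
                 order = k_star,
                 aic_path = data.frame(order = 0:K, aic = aics)),
            class = "gw_order")
}

#' Prune a candidate network to its data-supported real network
#'
#' Runs [detect_order()] on every identifiable target. A directed regulation
#' survives iff the target's detected order retains its source; an undirected
#' protein interaction survives iff *both* endpoint regressions retain it
#' (every design column of the interactive model contains the target's own
#' expression, so one equation alone cannot reject an interaction), with
#' ability averaged over the two estimates. Deterministic given its inputs.
#'
#' @param network A [gwgen()] candidate network.
#' @param expr An [expression_matrix()]; network nodes missing from it are
#'   dropped with a logged warning.
#' @param log1p Passed to [build_regression()].
#' @return A [gwgen()] whose edges carry fitted abilities, with per-target
#'   basal levels in `attr(, "basal")`.
#' @export
prune_network <- function(network, expr, log1p = FALSE) {
  network <- align_network_expression(network, expr)
  targets <- .identifiable_targets(network)
  kept <- list()
  basal <- numeric(0)
  ppi_votes <- list()
  for (tg in targets) {
    det <- detect_order(tg, network, expr, log1p = log1p)
    basal[tg] <- unname(det$estimate$theta["(basal)"])
    if (det$order == 0) next
    th <- det$estimate$theta[seq_len(det$order)]
    meta <- det$retained
    is_ppi <- meta$class == "protein"
    if (any(!is_ppi)) {
      m <- meta[!is_ppi, , drop = FALSE]
      mode <- ifelse(m$class == "TF", "tf",
                     ifelse(m$class == "lncRNA", "lncRNA", "miRNA"))
      kind <- network$nodes$kind[match(tg, network$nodes$id)]
      kept[[length(kept) + 1L]] <- data.frame(
        source = m$id, target = tg,
        mode = paste0(mode, "->", kind),
        ability = unname(th[!is_ppi]),
        stringsAsFactors = FALSE)
    }
    if (any(is_ppi)) {
      partners <- meta$id[is_ppi]
      ab <- unname(th[is_ppi])
      for (i in seq_along(partners)) {
        a <- min(tg, partners[i]); b <- max(tg, partners[i])
        key <- paste(a, b, sep = "\r")
        ppi_votes[[key]] <- c(ppi_votes[[key]], ab[i])
      }
    }
  }
  both <- names(ppi_votes)[vapply(ppi_votes, length, integer(1)) == 2L]
  if (length(both)) {
    pr <- do.call(rbind, strsplit(both, "\r", fixed = TRUE))
    kept[[length(kept) + 1L]] <- data.frame(
      source = pr[, 1], target = pr[, 2], mode = "ppi",
      ability = vapply(ppi_votes[both], mean, numeric(1)),
      stringsAsFactors = FALSE)
  }
  edges <- if (length(kept)) do.call(rbind, kept) else
    data.frame(source = character(), target = character(),
               mode = character(), ability = numeric())
  out <- gwgen(network$nodes, edges)
  attr(out, "basal") <- basal
  out
}
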