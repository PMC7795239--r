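# Per-entity regression problems and constrained least-squares estimation of
# interaction/regulation abilities. A protein is regressed on the elementwise
# products of its own expression with each candidate partner's; a gene,
# lncRNA or miRNA is regressed on its candidate TF and lncRNA expressions and
# on miRNA * (own expression) products, whose coefficients are constrained to
# be nonpositive (miRNA regulation is repressive). The final design column is
# the all-ones basal-level column.

#' Build the regression problem for one target entity
#'
#' @param target_id Node id of the target (protein, gene, lncRNA or miRNA).
#' @param network A [gwgen()] candidate network.
#' @param expr An [expression_matrix()] covering the target and all its
#'   candidate regulators.
#' @param log1p If `TRUE`, apply `log1p` to expression before building the
#'   design (default off: abilities are estimated on the raw scale).
#' @return Object of class `"gw_regression"`: `target_id`, `response` (length
#'   N), `design` (N x (O+1), intercept last), `column_meta` (regulator id and
#'   class per non-intercept column) and `mirna_mask` (TRUE on columns whose
#'   coefficient is constrained nonpositive).
#' @export
build_regression <- function(target_id, network, expr, log1p = FALSE) {
  reg <- .regulators_of(network, target_id)
  V <- expr$values
  if (isTRUE(log1p)) V <- base::log1p(V)
  if (!target_id %in% rownames(V)) stopf("target %s absent from expression", target_id)
  missing <- setdiff(reg$regulators$id, rownames(V))
  if (length(missing)) {
    stopf("candidate regulator(s) of %s absent from expression: %s",
          target_id, paste(missing, collapse = ", "))
  }
  y <- V[target_id, ]
  N <- length(y)
  meta <- reg$regulators
  # identifiability: regulator count + intercept must stay below N; keep the
  # N-2 candidates most correlated with the response otherwise
  if (nrow(meta) + 1L >= N) {
    keep_n <- N - 2L
    if (keep_n < 1L) stopf("too few samples (%d) to fit target %s", N, target_id)
    cors <- vapply(seq_len(nrow(meta)), function(i) {
      r <- V[meta$id[i], ]
      col <- if (meta$class[i] %in% c("protein", "miRNA")) r * y else r
      s <- stats::sd(col)
      if (s == 0 || stats::sd(y) == 0) 0 else abs(stats::cor(col, y))
    }, numeric(1))
    keep <- order(cors, decreasing = TRUE)[seq_len(keep_n)]
    gw_log("warn", "target %s: truncating %d candidates to the %d most correlated",
           target_id, nrow(meta), keep_n)
    meta <- meta[sort(keep), , drop = FALSE]
  }
  O <- nrow(meta)
  X <- matrix(0, N, O + 1L)
  mask <- logical(O + 1L)
  if (O > 0) {
    for (i in seq_len(O)) {
      r <- V[meta$id[i], ]
      X[, i] <- switch(meta$class[i],
                       protein = y * r,      # p_q[n] * p_r[n]
                       miRNA = r * y,        # m_w[n] * own expression
                       r)                    # TF / lncRNA expression
      if (meta$class[i] == "miRNA") mask[i] <- TRUE
    }
  }
  X[, O + 1L] <- 1
  colnames(X) <- c(if (O > 0) meta$id, "(basal)")
  rownames(meta) <- NULL
  structure(list(target_id = target_id, response = unname(y), design = X,
                 column_meta = meta, mirna_mask = mask, kind = reg$kind),
            class = "gw_regression")
}

# box-constrained least squares: minimize 0.5||X theta - y||^2 subject to
# theta[mask] <= 0; full-rank path via quadprog, rank-deficient path via the
# SVD pseudoinverse (minimum-norm, flagged)
.solve_constrained <- function(X, y, mask) {
  p <- ncol(X)
  qrX <- qr(X)
  rank_deficient <- qrX$rank < p
  warn <- character(0)
  if (!rank_deficient) {
    theta <- qr.coef(qrX, y)
    if (!any(mask) || all(theta[mask] <= 1e-12)) {
      theta[mask & theta > 0] <- 0
      return(list(theta = unname(theta), rank_deficient = FALSE, warn = warn))
    }
    Dmat <- crossprod(X)
    dvec <- drop(crossprod(X, y))
    Amat <- -diag(p)[, mask, drop = FALSE]
    sc <- mean(diag(Dmat))
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, Amat, rep(0, sum(mask))),
      error = function(e) {
        quadprog::solve.QP(Dmat + diag(1e-10 * sc, p), dvec, Amat, rep(0, sum(mask)))
      })
    theta <- sol$solution
    theta[mask & theta > 0] <- 0     # tidy numerical dust on active constraints
    return(list(theta = theta, rank_deficient = FALSE, warn = warn))
  }
  # minimum-norm least squares, then project masked coefficients into the box
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  theta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  theta <- drop(theta)
  theta[mask & theta > 0] <- 0
  warn <- "rank-deficient design; minimum-norm solution"
  list(theta = theta, rank_deficient = TRUE, warn = warn)
}

#' Estimate abilities by constrained least squares
#'
#' Minimizes `0.5 * ||design %*% theta - response||^2` subject to
#' `theta <= 0` on the miRNA-product columns. With no active constraint this
#' reduces to ordinary least squares.
#'
#' @param problem A [build_regression()] problem.
#' @return Object of class `"gw_fit"`: `theta` (named; last entry the basal
#'   level), `sse`, `active` (constraints at the boundary), `rank_deficient`
#'   flag and the mirrored `column_meta`/`mirna_mask`.
#' @export
fit_constrained <- function(problem) {
  X <- problem$design
  y <- problem$response
  sol <- .solve_constrained(X, y, problem$mirna_mask)
  if (length(sol$warn)) gw_log("warn", "target %s: %s", problem$target_id, sol$warn[1])
  theta <- stats::setNames(sol$theta, colnames(X))
  resid <- y - drop(X %*% theta)
  structure(list(target_id = problem$target_id,
                 theta = theta,
                 sse = sum(resid^2),
                 active = problem$mirna_mask & abs(theta) < 1e-9,
                 rank_deficient = sol$rank_deficient,
                 column_meta = problem$column_meta,
                 mirna_mask = problem$mirna_mask,
                 kind = problem$kind),
            class = "gw_fit")
}

#' @export
print.gw_fit <- function(x, ...) {
  cat("gw_fit for", x$target_id, "(", x$kind, "):",
      length(x$theta) - 1L, "regulators, sse =", format(x$sse, digits = 4), "\n")
  invisible(x)
}
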