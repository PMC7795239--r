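# regression construction and constrained least-squares estimation

test_that("gene design holds TF/lncRNA columns, miRNA products and basal", {
  set.seed(10)
  nodes <- data.frame(id = c("T1", "T2", "L1", "M1", "G1"),
                      kind = c("TF", "TF", "lncRNA", "miRNA", "gene"))
  edges <- data.frame(source = c("T1", "T2", "L1", "M1"), target = "G1",
                      mode = c("tf->gene", "tf->gene", "lncRNA->gene", "miRNA->gene"))
  net <- gwgen(nodes, edges)
  vals <- matrix(runif(50, 0.1, 3), 5, 10, dimnames = list(nodes$id, NULL))
  expr <- make_expr(vals)
  pr <- build_regression("G1", net, expr)
  expect_equal(dim(pr$design), c(10L, 5L))
  expect_equal(pr$mirna_mask, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(pr$design[, 1], unname(vals["T1", ]))
  expect_equal(pr$design[, 4], unname(vals["M1", ] * vals["G1", ]))
  expect_equal(pr$design[, 5], rep(1, 10))
})

test_that("protein design columns are own-times-partner products", {
  set.seed(11)
  nodes <- data.frame(id = c("PA", "PB", "PC"), kind = "protein")
  edges <- data.frame(source = c("PA", "PA"), target = c("PB", "PC"), mode = "ppi")
  net <- gwgen(nodes, edges)
  vals <- matrix(runif(24, 0.1, 2), 3, 8, dimnames = list(nodes$id, NULL))
  expr <- make_expr(vals)
  pr <- build_regression("PA", net, expr)
  expect_setequal(pr$column_meta$id, c("PB", "PC"))
  i <- match("PB", pr$column_meta$id)
  expect_equal(pr$design[, i], unname(vals["PA", ] * vals["PB", ]))
})

test_that("a zero-expression target yields all-zero miRNA product columns", {
  nodes <- data.frame(id = c("M1", "G1"), kind = c("miRNA", "gene"))
  net <- gwgen(nodes, data.frame(source = "M1", target = "G1", mode = "miRNA->gene"))
  vals <- rbind(M1 = runif(6, 0.5, 2), G1 = rep(0, 6))
  pr <- build_regression("G1", net, make_expr(vals))
  expect_true(all(pr$design[, 1] == 0))
})

test_that("an exact line is fitted exactly", {
  pr <- structure(list(target_id = "t", response = c(3, 5, 7),
                       design = cbind(c(1, 2, 3), 1),
                       column_meta = data.frame(id = "x", class = "TF"),
                       mirna_mask = c(FALSE, FALSE), kind = "gene"),
                  class = "gw_regression")
  fit <- fit_constrained(pr)
  expect_equal(unname(fit$theta), c(2, 1), tolerance = 1e-10)
  expect_lt(fit$sse, 1e-20)
})

test_that("the nonpositivity constraint clips a positive coefficient at zero", {
  set.seed(12)
  x <- runif(50, 0.5, 2)
  y <- 0.5 * x + 1 + rnorm(50, 0, 0.05)   # truth positive, column masked
  pr <- structure(list(target_id = "t", response = y, design = cbind(x, 1),
                       column_meta = data.frame(id = "m", class = "miRNA"),
                       mirna_mask = c(TRUE, FALSE), kind = "gene"),
                  class = "gw_regression")
  fit <- fit_constrained(pr)
  expect_equal(unname(fit$theta[1]), 0)
  expect_true(fit$active[1])
  ols <- qr.coef(qr(cbind(x, 1)), y)
  expect_gt(ols[1], 0)
  expect_gte(fit$sse, sum((y - cbind(x, 1) %*% ols)^2))
})

test_that("with no masked columns the fit equals ordinary least squares", {
  set.seed(13)
  for (r in 1:5) {
    X <- cbind(matrix(runif(40 * 3, 0.1, 2), 40, 3), 1)
    y <- X %*% runif(4, -1, 1) + rnorm(40, 0, 0.1)
    pr <- structure(list(target_id = "t", response = drop(y), design = X,
                         column_meta = data.frame(id = paste0("r", 1:3), class = "TF"),
                         mirna_mask = rep(FALSE, 4), kind = "gene"),
                    class = "gw_regression")
    fit <- fit_constrained(pr)
    expect_equal(unname(fit$theta), unname(qr.coef(qr(X), drop(y))),
                 tolerance = 1e-8)
  }
})

test_that("constrained sse never beats unconstrained sse", {
  set.seed(14)
  for (r in 1:10) {
    X <- cbind(matrix(runif(30 * 4, 0.1, 2), 30, 4), 1)
    y <- drop(X %*% c(runif(2, -1, 1), runif(2, 0.2, 1), 1) + rnorm(30, 0, 0.3))
    mask <- c(FALSE, FALSE, TRUE, TRUE, FALSE)
    pr <- structure(list(target_id = "t", response = y, design = X,
                         column_meta = data.frame(id = paste0("r", 1:4),
                                                  class = c("TF", "TF", "miRNA", "miRNA")),
                         mirna_mask = mask, kind = "gene"),
                    class = "gw_regression")
    fit <- fit_constrained(pr)
    sse_ols <- sum(qr.resid(qr(X), y)^2)
    expect_gte(fit$sse, sse_ols - 1e-10)
    if (!any(fit$active)) expect_equal(fit$sse, sse_ols, tolerance = 1e-8)
    expect_true(all(fit$theta[mask] <= 1e-12))
  }
})

test_that("noiseless synthetic data returns the planted abilities", {
  inst <- flat_instance(seed = 21, noise_sd = 0)
  te <- inst$gen$truth$true_edges
  for (tg in unique(te$target)) {
    fit <- fit_constrained(build_regression(tg, inst$gen$network, inst$expr))
    rows <- te[te$target == tg, ]
    expect_equal(unname(fit$theta[rows$source]), unname(model_coef(rows)),
                 tolerance = 1e-8)
  }
})

test_that("over-parameterised targets are truncated to the sample budget", {
  set.seed(15)
  n_tf <- 12
  nodes <- data.frame(id = c(sprintf("T%02d", 1:n_tf), "G1"),
                      kind = c(rep("TF", n_tf), "gene"))
  edges <- data.frame(source = sprintf("T%02d", 1:n_tf), target = "G1",
                      mode = "tf->gene")
  net <- gwgen(nodes, edges)
  vals <- matrix(runif(13 * 10, 0.1, 2), 13, 10, dimnames = list(nodes$id, NULL))
  pr <- build_regression("G1", net, make_expr(vals))
  expect_equal(ncol(pr$design), 10 - 2 + 1)   # N-2 regulators + basal
})
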