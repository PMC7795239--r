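# generators: planted-truth bookkeeping, model-exact expression, DTI data

test_that("generator is deterministic and spurious-free when asked", {
  g1 <- generate_candidate_gwgen(10, 20, 5, 5, density = 0.1,
                                 spurious_fraction = 0.5, seed = 1)
  g2 <- generate_candidate_gwgen(10, 20, 5, 5, density = 0.1,
                                 spurious_fraction = 0.5, seed = 1)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_identical(g1$truth$true_edges, g2$truth$true_edges)

  g0 <- generate_candidate_gwgen(10, 20, 5, 5, density = 0.1,
                                 spurious_fraction = 0, seed = 2)
  expect_setequal(network_keys(g0$network), truth_keys(g0$truth))
})

test_that("spurious fraction is honoured on average", {
  fracs <- vapply(1:20, function(s) {
    g <- generate_candidate_gwgen(8, 15, 5, 5, density = 0.15,
                                  spurious_fraction = 0.5, seed = s)
    1 - nrow(g$truth$true_edges) / nrow(g$network$edges)
  }, numeric(1))
  # binomial-ish tolerance around the target around n~60 candidate edges
  expect_gt(mean(fracs), 0.42)
  expect_lt(mean(fracs), 0.58)
})

test_that("miRNA abilities are nonnegative in the planted truth", {
  g <- generate_candidate_gwgen(6, 10, 5, 8, density = 0.3, seed = 3)
  mir <- grepl("^miRNA->", g$truth$true_edges$mode)
  expect_true(any(mir))
  expect_true(all(g$truth$true_edges$ability[mir] >= 0))
})

test_that("noiseless expression follows the model equation exactly", {
  # single gene, one TF with ability 2, basal 1: g = 2 t + 1
  net <- gwgen(data.frame(id = c("TF1", "G1"), kind = c("TF", "gene")),
               data.frame(source = "TF1", target = "G1", mode = "tf->gene"))
  truth <- gwgen_truth(
    data.frame(source = "TF1", target = "G1", mode = "tf->gene", ability = 2),
    basal = c(G1 = 1), noise_sd = 0)
  expr <- simulate_expression(truth, net, 10, seed = 4)
  expect_equal(expr$values["G1", ], 2 * expr$values["TF1", ] + 1,
               tolerance = 1e-12)
})

test_that("fitted regression recovers -gamma exactly at zero noise", {
  net <- gwgen(data.frame(id = c("M1", "G1"), kind = c("miRNA", "gene")),
               data.frame(source = "M1", target = "G1", mode = "miRNA->gene"))
  truth <- gwgen_truth(
    data.frame(source = "M1", target = "G1", mode = "miRNA->gene", ability = 1.3),
    basal = c(G1 = 2), noise_sd = 0)
  expr <- simulate_expression(truth, net, 20, seed = 5)
  g <- expr$values["G1", ]; m <- expr$values["M1", ]
  # closed-form least squares oracle on the regression form
  X <- cbind(m * g, 1)
  oracle <- solve(crossprod(X), crossprod(X, g))
  expect_equal(unname(oracle[, 1]), c(-1.3, 2), tolerance = 1e-9)
  fit <- fit_constrained(build_regression("G1", net, expr))
  expect_equal(unname(fit$theta), c(-1.3, 2), tolerance = 1e-9)
})

test_that("refitting the true model leaves residuals at the noise level", {
  inst <- flat_instance(seed = 11, n_samples = 1000, noise_sd = 0.2,
                        spurious = 0)
  te <- inst$gen$truth$true_edges
  tg <- names(which.max(table(te$target[te$mode != "ppi"])))
  fit <- fit_constrained(build_regression(tg, inst$gen$network, inst$expr))
  resid_sd <- sqrt(fit$sse / 1000)
  expect_lt(abs(mean(inst$expr$values[tg, ] -
                       drop(build_regression(tg, inst$gen$network, inst$expr)$design %*%
                              fit$theta))), 0.05)
  expect_lt(abs(resid_sd - 0.2), 0.03)
})

test_that("dti dataset is separable, seeded and noise-calibrated", {
  d1 <- generate_dti_dataset(n_drugs = 20, n_targets = 20, n_pairs = 300,
                             drug_dim = 8, target_dim = 10, seed = 6)
  d2 <- generate_dti_dataset(n_drugs = 20, n_targets = 20, n_pairs = 300,
                             drug_dim = 8, target_dim = 10, seed = 6)
  expect_identical(d1$pairs, d2$pairs)
  expect_identical(d1$features, d2$features)

  # latent linear rule separates the classes in the raw features
  score <- as.numeric(d1$features %*% c(d1$rule$w_drug, d1$rule$w_target))
  expect_true(all((score > d1$rule$threshold) == (d1$pairs$label == 1)))
  # and a linear classifier fitted on the features achieves 100% training
  # accuracy (perfect separation)
  fit <- suppressWarnings(glm(d1$pairs$label ~ score, family = binomial()))
  expect_equal(mean((fitted(fit) >= 0.5) == (d1$pairs$label == 1)), 1)

  dn <- generate_dti_dataset(n_drugs = 110, n_targets = 100, n_pairs = 10000,
                             drug_dim = 5, target_dim = 5, label_noise = 0.1,
                             seed = 7)
  clean <- generate_dti_dataset(n_drugs = 110, n_targets = 100, n_pairs = 10000,
                                drug_dim = 5, target_dim = 5, label_noise = 0,
                                seed = 7)
  flip_rate <- mean(dn$pairs$label != clean$pairs$label)
  expect_lt(abs(flip_rate - 0.1), 0.01)
})

test_that("requesting more pairs than the universe allows errors", {
  expect_error(generate_dti_dataset(n_drugs = 5, n_targets = 5, n_pairs = 100,
                                    drug_dim = 3, target_dim = 3, seed = 1),
               "exceed")
})

test_that("printed drug tables are reproduced by the fixture", {
  tab <- paper_drug_fixture()
  expect_setequal(
    intersect(tab$bindings$Sulforaphane, names(default_desired_regulation())),
    c("IKK", "STAT3", "PPARgamma", "ETS1", "FAS"))
  expect_equal(side_effect_count("Sulforaphane", tab,
                                 names(default_desired_regulation())), 23)
  expect_equal(unname(tab$regulation["Biotin", c("IKK", "STAT3", "PPARgamma", "ETS1")]),
               c(-1.214, 1.075, 0.969, -0.986))
  expect_true(is.na(tab$regulation["Biotin", "FAS"]))
  expect_equal(tab$toxicity[["Biotin"]], 2.058)

  d <- withr::local_tempdir()
  write_drug_spec_tables(tab, d)
  back <- read_drug_spec_tables(d)
  expect_equal(back$regulation[rownames(tab$regulation), colnames(tab$regulation)],
               tab$regulation)
  expect_equal(back$toxicity[names(tab$toxicity)], tab$toxicity)
  expect_equal(back$sensitivity[names(tab$sensitivity)], tab$sensitivity)
  for (dr in names(tab$bindings)) {
    expect_setequal(back$bindings[[dr]], tab$bindings[[dr]])
  }
})
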