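# drug design specifications and combination selection

test_that("side-effect counts come from bindings minus biomarkers", {
  tab <- paper_drug_fixture()
  bm <- names(default_desired_regulation())
  printed <- c(Anisomycin = 37, Sulforaphane = 23, Memantine = 11,
               Trimetozine = 14, Biotin = 19, Gabexate = 31,
               Famotidine = 25, Cilostazol = 26, Acetylcysteine = 41)
  for (d in names(printed)) {
    expect_equal(side_effect_count(d, tab, bm), unname(printed[d]))
  }
  expect_error(side_effect_count("Aspirin", tab, bm), "unknown drug")

  # bindings entirely inside the biomarker panel mean zero side effect
  tab0 <- drug_spec_tables(matrix(1, 1, 1, dimnames = list("D", "IKK")),
                           c(D = 1), c(D = 1), list(D = "IKK"))
  expect_equal(side_effect_count("D", tab0, c("IKK", "STAT3")), 0)

  # brute-force set difference oracle on random tables
  set.seed(91)
  for (r in 1:10) {
    targets <- sprintf("t%02d", 1:15)
    bnd <- sample(targets, sample(3:10, 1))
    bms <- sample(targets, sample(2:6, 1))
    tabr <- drug_spec_tables(matrix(1, 1, 1, dimnames = list("D", "x")),
                             c(D = 1), c(D = 1), list(D = bnd))
    expect_equal(side_effect_count("D", tabr, bms), sum(!bnd %in% bms))
  }
})

test_that("side-effect count never grows as the biomarker panel grows", {
  tab <- paper_drug_fixture()
  bm <- names(default_desired_regulation())
  for (d in names(tab$bindings)) {
    counts <- vapply(0:5, function(k) side_effect_count(d, tab, bm[seq_len(k)]),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("regulation flags match the printed table annotations", {
  tab <- paper_drug_fixture()
  desired <- default_desired_regulation()
  fl <- regulation_flags("Sulforaphane", tab, desired)
  expect_equal(unname(fl["ETS1"]), "unwanted")   # printed +0.089 against ETS1-down
  expect_true(all(fl[c("IKK", "STAT3", "PPARgamma", "FAS")] == "desired"))

  fb <- regulation_flags("Biotin", tab, desired)
  expect_true(all(fb[c("IKK", "STAT3", "PPARgamma", "ETS1")] == "desired"))
  expect_equal(unname(fb["FAS"]), "absent")

  # flipping every desired direction flips desired <-> unwanted
  flipped <- ifelse(desired == "up", "down", "up")
  names(flipped) <- names(desired)
  for (d in names(tab$bindings)) {
    a <- regulation_flags(d, tab, desired)
    b <- regulation_flags(d, tab, flipped)
    swap <- c(desired = "unwanted", unwanted = "desired", absent = "absent")
    expect_equal(unname(b), unname(swap[a]))
  }
})

test_that("strict filtering keeps exactly the all-desired drugs, ranked by LD50", {
  tab <- paper_drug_fixture()
  res <- filter_candidates(tab, default_desired_regulation(),
                           allow_unwanted = FALSE)
  expect_equal(res$drug, c("Memantine", "Trimetozine", "Biotin"))  # LD50 desc
  expect_true(all(diff(res$ld50) <= 0))
  none <- filter_candidates(tab, default_desired_regulation(), min_ld50 = Inf)
  expect_equal(nrow(none), 0L)
  all9 <- filter_candidates(tab, default_desired_regulation(),
                            allow_unwanted = TRUE)
  expect_equal(nrow(all9), 9L)
  expect_equal(anyDuplicated(all9$drug), 0L)
})

test_that("combination selection finds the unique feasible pair on the fixture", {
  tab <- paper_drug_fixture()
  desired <- default_desired_regulation()
  comb <- select_combination(tab, desired, max_size = 2)
  expect_setequal(comb$drugs, c("Biotin", "Sulforaphane"))
  expect_equal(unname(comb$aggregate["ETS1"]), 0.089 - 0.986, tolerance = 1e-12)
  expect_true(all(ifelse(desired == "up", comb$aggregate > 0, comb$aggregate < 0)))
  expect_equal(comb$total_side_effect, 23 + 19)
  expect_setequal(unname(comb$ld50), c(3.110, 2.058))

  # exhaustive diagnostics: no feasible singleton, exactly one feasible pair
  feas <- comb$subsets[comb$subsets$feasible, ]
  expect_equal(nrow(feas[feas$size == 1, ]), 0L)
  expect_equal(feas$drugs[feas$size == 2], "Biotin+Sulforaphane")
})

test_that("a self-sufficient drug is returned as a singleton", {
  reg <- matrix(c(-1, 1, 0.5, -2), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("X", "Y")))
  tab <- drug_spec_tables(reg, c(A = 2, B = 3), c(A = -1, B = -2),
                          list(A = c("X", "Y"), B = c("X", "Y")))
  comb <- select_combination(tab, c(X = "down", Y = "up"), max_size = 2)
  expect_equal(comb$drugs, "A")
  expect_error(select_combination(tab, c(X = "up", Y = "up"), max_size = 1),
               "no feasible")
})

test_that("selection matches an independent brute-force enumerator", {
  # oracle: enumerate subsets, apply the same feasibility and ordering rules,
  # implemented independently of select_combination
  brute <- function(tab, desired, max_size) {
    drugs <- names(tab$bindings)
    best <- NULL
    subsets <- unlist(lapply(seq_len(max_size), function(s)
      utils::combn(sort(drugs), s, simplify = FALSE)), recursive = FALSE)
    score <- function(ds) {
      agg <- sapply(names(desired), function(bm) {
        sum(sapply(ds, function(d) {
          r <- tab$regulation[d, bm]
          if (is.na(r) || !bm %in% tab$bindings[[d]]) 0 else r
        }))
      })
      cov <- all(names(desired) %in% unlist(tab$bindings[ds]))
      ok <- all(ifelse(desired == "up", agg > 0, agg < 0))
      if (!cov || !ok) return(NULL)
      tse <- sum(sapply(ds, function(d)
        length(setdiff(tab$bindings[[d]], names(desired)))))
      list(ds = ds, key = c(length(ds), tse, -min(tab$toxicity[ds])))
    }
    for (s in subsets) {
      sc <- score(s)
      if (is.null(sc)) next
      if (is.null(best)) { best <- sc; next }
      for (i in 1:3) {
        if (sc$key[i] < best$key[i]) { best <- sc; break }
        if (sc$key[i] > best$key[i]) break
        if (i == 3 && paste(sc$ds, collapse = "+") < paste(best$ds, collapse = "+"))
          best <- sc
      }
    }
    if (is.null(best)) NULL else best$ds
  }
  set.seed(92)
  for (r in 1:12) {
    nd <- sample(4:8, 1)
    drugs <- sprintf("D%02d", seq_len(nd))
    bms <- c("b1", "b2", "b3")
    reg <- matrix(round(runif(nd * 3, -2, 2), 2), nd, 3,
                  dimnames = list(drugs, bms))
    reg[matrix(runif(nd * 3) < 0.3, nd, 3)] <- NA
    bindings <- lapply(seq_len(nd), function(i) {
      b <- bms[!is.na(reg[i, ])]
      c(b, sprintf("off%d_%d", i, seq_len(sample(0:5, 1))))
    })
    names(bindings) <- drugs
    tab <- drug_spec_tables(reg, stats::setNames(round(runif(nd, 1, 4), 2), drugs),
                            stats::setNames(round(runif(nd, -1, 0), 2), drugs),
                            bindings)
    desired <- stats::setNames(sample(c("up", "down"), 3, TRUE), bms)
    expected <- brute(tab, desired, 2)
    if (is.null(expected)) {
      expect_error(select_combination(tab, desired, 2), "no feasible")
    } else {
      expect_equal(sort(select_combination(tab, desired, 2)$drugs),
                   sort(expected))
    }
  }
})

test_that("selection is invariant to input row order", {
  tab <- paper_drug_fixture()
  perm <- sample(names(tab$bindings))
  tab2 <- drug_spec_tables(tab$regulation[perm, ], tab$toxicity[perm],
                           tab$sensitivity[perm], tab$bindings[perm])
  c1 <- select_combination(tab, default_desired_regulation(), 2)
  c2 <- select_combination(tab2, default_desired_regulation(), 2)
  expect_setequal(c1$drugs, c2$drugs)
})
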