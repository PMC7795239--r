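# Drug design specifications: regulation ability (LINCS-style signed
# perturbation scores), toxicity (LD50, larger = safer), sensitivity (EC50,
# smaller = more potent) and side effect (number of predicted bindings beyond
# the desired biomarkers). Candidate drugs are screened against a desired
# regulation profile and combined into a multiple-molecule targeting drug
# whose aggregate regulation drives every biomarker in the right direction.

#' Bundle the drug specification tables
#'
#' @param regulation Numeric matrix, drugs x genes; positive = upregulation,
#'   negative = downregulation, `NA` = drug does not bind that gene.
#' @param toxicity Named numeric vector of LD50 values (mol/kg).
#' @param sensitivity Named numeric vector of EC50 values.
#' @param bindings Named list: drug id -> character vector of bound targets
#'   within the core network.
#' @return Object of class `"drug_spec_tables"`.
#' @export
drug_spec_tables <- function(regulation, toxicity, sensitivity, bindings) {
  regulation <- as.matrix(regulation)
  drugs <- names(bindings)
  if (is.null(drugs)) stopf("bindings must be a named list")
  missing_tox <- setdiff(drugs, names(toxicity))
  if (length(missing_tox)) stopf("drug(s) without LD50: %s", paste(missing_tox, collapse = ", "))
  missing_sen <- setdiff(drugs, names(sensitivity))
  if (length(missing_sen)) stopf("drug(s) without EC50: %s", paste(missing_sen, collapse = ", "))
  if (!all(drugs %in% rownames(regulation))) stopf("regulation rows must cover all drugs")
  structure(list(regulation = regulation, toxicity = toxicity,
                 sensitivity = sensitivity, bindings = bindings),
            class = "drug_spec_tables")
}

#' The printed candidate-drug tables for the diabetes biomarker panel
#'
#' Nine candidate drugs with their bound biomarkers among IKK, STAT3,
#' PPARgamma, ETS1 and FAS, side-effect counts (bindings in the core network
#' beyond the biomarkers, represented as synthetic `OFFTARGET_*` ids so the
#' counts are reproducible), signed regulation abilities, LD50 and EC50
#' values, exactly as printed.
#'
#' @return A [drug_spec_tables()] object.
#' @export
paper_drug_fixture <- function() {
  biomarkers <- c("IKK", "STAT3", "PPARgamma", "ETS1", "FAS")
  reg <- rbind(
    Anisomycin     = c( 0.822,  0.809,  3.622,  5.507, -0.184),
    Sulforaphane   = c(-0.029,  0.079,  0.075,  0.089, -0.059),
    Memantine      = c(-0.997,  0.707,     NA,     NA,     NA),
    Trimetozine    = c(-0.724,  0.650,  0.489,     NA,     NA),
    Biotin         = c(-1.214,  1.075,  0.969, -0.986,     NA),
    Gabexate       = c(-1.324, -0.942,  1.237, -2.151,     NA),
    Famotidine     = c(-0.693,  0.356, -1.004, -0.119,     NA),
    Cilostazol     = c(-0.570, -1.622,  0.387, -1.222,     NA),
    Acetylcysteine = c(-0.788,  0.645, -0.620,  1.923, -1.000))
  colnames(reg) <- biomarkers
  toxicity <- c(Anisomycin = 3.535, Sulforaphane = 3.110, Memantine = 2.346,
                Trimetozine = 2.148, Biotin = 2.058, Gabexate = 1.999,
                Famotidine = 1.952, Cilostazol = 1.889, Acetylcysteine = 1.294)
  sensitivity <- c(Anisomycin = -1.099, Sulforaphane = -0.008, Memantine = -0.383,
                   Trimetozine = -0.851, Biotin = -0.249, Gabexate = -0.229,
                   Famotidine = -0.548, Cilostazol = -0.141, Acetylcysteine = -0.554)
  side_effect <- c(Anisomycin = 37, Sulforaphane = 23, Memantine = 11,
                   Trimetozine = 14, Biotin = 19, Gabexate = 31,
                   Famotidine = 25, Cilostazol = 26, Acetylcysteine = 41)
  bindings <- lapply(rownames(reg), function(d) {
    bound <- biomarkers[!is.na(reg[d, ])]
    c(bound, sprintf("OFFTARGET_%s_%02d", toupper(substr(d, 1, 3)),
                     seq_len(side_effect[[d]])))
  })
  names(bindings) <- rownames(reg)
  drug_spec_tables(reg, toxicity, sensitivity, bindings)
}

#' Desired regulation directions for the diabetes biomarker panel
#'
#' Upregulation of STAT3 and PPARgamma, downregulation of IKK, ETS1 and FAS.
#'
#' @return Named character vector of `"up"`/`"down"`.
#' @export
default_desired_regulation <- function() {
  c(IKK = "down", STAT3 = "up", PPARgamma = "up", ETS1 = "down", FAS = "down")
}

#' Side-effect count of a drug
#'
#' The number of the drug's bound targets that are not desired biomarkers.
#'
#' @param drug Drug id.
#' @param tables A [drug_spec_tables()].
#' @param biomarkers Character vector of desired biomarker ids.
#' @return Integer count.
#' @export
side_effect_count <- function(drug, tables, biomarkers) {
  if (!drug %in% names(tables$bindings)) stopf("unknown drug: %s", drug)
  length(setdiff(tables$bindings[[drug]], biomarkers))
}

#' Per-biomarker regulation status of a drug
#'
#' `"desired"` if the drug binds the biomarker and regulates it in the wanted
#' direction, `"unwanted"` if it binds but regulates the wrong way (an exact
#' zero cannot drive a direction and counts as unwanted, logged), `"absent"`
#' if unbound.
#'
#' @param drug Drug id.
#' @param tables A [drug_spec_tables()].
#' @param desired Named `"up"`/`"down"` vector over biomarkers.
#' @return Named character vector over the biomarkers in `desired`.
#' @export
regulation_flags <- function(drug, tables, desired) {
  if (!drug %in% names(tables$bindings)) stopf("unknown drug: %s", drug)
  vapply(names(desired), function(bm) {
    r <- if (bm %in% colnames(tables$regulation)) tables$regulation[drug, bm] else NA_real_
    if (is.na(r) || !bm %in% tables$bindings[[drug]]) return("absent")
    if (r == 0) {
      gw_log("info", "%s has zero regulation on %s: counted unwanted", drug, bm)
      return("unwanted")
    }
    ok <- (desired[[bm]] == "up" && r > 0) || (desired[[bm]] == "down" && r < 0)
    if (ok) "desired" else "unwanted"
  }, character(1))
}

#' Screen candidate drugs against the design specifications
#'
#' Removes drugs with unwanted regulations (unless `allow_unwanted`) or
#' failing the numeric thresholds, then ranks survivors by LD50 descending
#' (least toxic first), side effect ascending, EC50 ascending, then id.
#'
#' @param tables A [drug_spec_tables()].
#' @param desired Named `"up"`/`"down"` vector over biomarkers.
#' @param min_ld50 Minimum LD50 (toxicity ceiling).
#' @param max_ec50 Maximum EC50 (sensitivity floor).
#' @param max_side_effect Maximum side-effect count.
#' @param allow_unwanted Keep drugs with unwanted regulations?
#' @return Data frame `drug`, `ld50`, `ec50`, `side_effect`, `n_desired`,
#'   `n_unwanted`, ranked.
#' @export
filter_candidates <- function(tables, desired, min_ld50 = -Inf, max_ec50 = Inf,
                              max_side_effect = Inf, allow_unwanted = FALSE) {
  biomarkers <- names(desired)
  rows <- lapply(names(tables$bindings), function(d) {
    fl <- regulation_flags(d, tables, desired)
    data.frame(drug = d,
               ld50 = tables$toxicity[[d]],
               ec50 = tables$sensitivity[[d]],
               side_effect = side_effect_count(d, tables, biomarkers),
               n_desired = sum(fl == "desired"),
               n_unwanted = sum(fl == "unwanted"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  keep <- df$ld50 >= min_ld50 & df$ec50 <= max_ec50 & df$side_effect <= max_side_effect
  if (!allow_unwanted) keep <- keep & df$n_unwanted == 0
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$ld50, df$side_effect, df$ec50, df$drug), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# aggregate regulation of a drug subset on each biomarker (unbound = 0)
.aggregate_regulation <- function(tables, drugs, biomarkers) {
  vapply(biomarkers, function(bm) {
    vals <- vapply(drugs, function(d) {
      r <- if (bm %in% colnames(tables$regulation)) tables$regulation[d, bm] else NA_real_
      if (is.na(r) || !bm %in% tables$bindings[[d]]) 0 else r
    }, numeric(1))
    sum(vals)
  }, numeric(1))
}

#' Select a multiple-molecule targeting drug combination
#'
#' Exhaustively searches drug subsets of size up to `max_size`. A subset is
#' feasible when every biomarker is bound by at least one member and the
#' summed regulation ability over members has the desired sign for every
#' biomarker (net-effect reasoning: a member's small unwanted regulation may
#' be overruled by a partner). Among feasible subsets the winner has minimal
#' size, then minimal total side effect, then maximal minimum LD50, then
#' lexicographically smallest ids.
#'
#' @param tables A [drug_spec_tables()].
#' @param desired Named `"up"`/`"down"` vector over biomarkers.
#' @param max_size Maximum combination size (default 2).
#' @return Object of class `"drug_combination"`: `drugs`, `aggregate`
#'   (per-biomarker summed regulation), `total_side_effect`, `ld50`, `ec50`,
#'   and a `subsets` diagnostic data frame over every evaluated subset.
#' @export
select_combination <- function(tables, desired, max_size = 2) {
  if (!is_count(max_size)) stopf("max_size must be >= 1")
  biomarkers <- names(desired)
  drugs <- sort(names(tables$bindings))
  subsets <- unlist(lapply(seq_len(min(max_size, length(drugs))), function(s)
    utils::combn(drugs, s, simplify = FALSE)), recursive = FALSE)
  diag_rows <- vector("list", length(subsets))
  best <- NULL
  best_key <- NULL
  for (i in seq_along(subsets)) {
    ds <- subsets[[i]]
    bound <- unique(unlist(tables$bindings[ds]))
    covered <- all(biomarkers %in% bound)
    agg <- .aggregate_regulation(tables, ds, biomarkers)
    signs_ok <- all(ifelse(desired == "up", agg > 0, agg < 0))
    feasible <- covered && signs_ok
    tse <- sum(vapply(ds, side_effect_count, numeric(1),
                      tables = tables, biomarkers = biomarkers))
    diag_rows[[i]] <- data.frame(
      drugs = paste(ds, collapse = "+"), size = length(ds),
      covered = covered, signs_ok = signs_ok, feasible = feasible,
      total_side_effect = tse, min_ld50 = min(tables$toxicity[ds]),
      stringsAsFactors = FALSE)
    if (feasible) {
      key <- list(length(ds), tse, -min(tables$toxicity[ds]), paste(ds, collapse = "+"))
      better <- is.null(best_key) ||
        (key[[1]] < best_key[[1]] ||
           (key[[1]] == best_key[[1]] && (key[[2]] < best_key[[2]] ||
              (key[[2]] == best_key[[2]] && (key[[3]] < best_key[[3]] ||
                 (key[[3]] == best_key[[3]] && key[[4]] < best_key[[4]]))))))
      if (better) {
        best <- ds
        best_key <- key
      }
    }
  }
  if (is.null(best)) {
    stopf("no feasible combination of size <= %d covers all biomarkers", max_size)
  }
  structure(list(drugs = best,
                 aggregate = .aggregate_regulation(tables, best, biomarkers),
                 total_side_effect = sum(vapply(best, side_effect_count, numeric(1),
                                                tables = tables, biomarkers = biomarkers)),
                 ld50 = tables$toxicity[best],
                 ec50 = tables$sensitivity[best],
                 subsets = do.call(rbind, diag_rows)),
            class = "drug_combination")
}

#' @export
print.drug_combination <- function(x, ...) {
  cat("multiple-molecule targeting drug:", paste(x$drugs, collapse = " + "), "\n")
  cat("  aggregate regulation:",
      paste(sprintf("%s=%.3f", names(x$aggregate), x$aggregate), collapse = ", "), "\n")
  cat("  total side effect:", x$total_side_effect,
      "| LD50:", paste(format(x$ld50), collapse = ", "),
      "| EC50:", paste(format(x$ec50), collapse = ", "), "\n")
  invisible(x)
}

#' Write the drug specification tables as TSV files
#'
#' @param tables A [drug_spec_tables()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_drug_spec_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- data.frame(drug = rownames(tables$regulation), tables$regulation,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(reg, file.path(dir, "regulation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tox <- data.frame(drug = names(tables$toxicity), ld50 = unname(tables$toxicity))
  utils::write.table(tox, file.path(dir, "toxicity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sen <- data.frame(drug = names(tables$sensitivity), ec50 = unname(tables$sensitivity))
  utils::write.table(sen, file.path(dir, "sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bind <- do.call(rbind, lapply(names(tables$bindings), function(d)
    data.frame(drug = d, target = tables$bindings[[d]], stringsAsFactors = FALSE)))
  utils::write.table(bind, file.path(dir, "bindings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read drug specification tables written by [write_drug_spec_tables()]
#'
#' @param dir Directory holding `regulation.tsv`, `toxicity.tsv`,
#'   `sensitivity.tsv`, `bindings.tsv`.
#' @return A [drug_spec_tables()].
#' @export
read_drug_spec_tables <- function(dir) {
  reg <- utils::read.delim(file.path(dir, "regulation.tsv"), check.names = FALSE)
  regm <- as.matrix(reg[, -1, drop = FALSE])
  rownames(regm) <- reg$drug
  tox <- utils::read.delim(file.path(dir, "toxicity.tsv"))
  sen <- utils::read.delim(file.path(dir, "sensitivity.tsv"))
  bind <- utils::read.delim(file.path(dir, "bindings.tsv"))
  bindings <- split(bind$target, bind$drug)
  bindings <- bindings[unique(bind$drug)]
  drug_spec_tables(regm, stats::setNames(tox$ld50, tox$drug),
                   stats::setNames(sen$ec50, sen$drug), bindings)
}
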