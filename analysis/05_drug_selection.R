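#!/usr/bin/env Rscript
# Drug-design-specification screening on the printed candidate-drug tables:
# side effects, regulation flags against the desired biomarker directions,
# strict filtering, and the exhaustive multiple-molecule combination search.

suppressMessages(library(gwgendrug))
gw_log_level("error")

tab <- paper_drug_fixture()
desired <- default_desired_regulation()
cat("desired regulation:",
    paste(sprintf("%s %s", names(desired), ifelse(desired == "up", "up", "down")),
          collapse = ", "), "\n\n")

ranked <- filter_candidates(tab, desired, allow_unwanted = TRUE)
cat("all candidates ranked by LD50 (toxicity, larger = safer):\n")
print(ranked, row.names = FALSE)
utils::write.table(ranked, "results/drug_candidates_ranked.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

strict <- filter_candidates(tab, desired, allow_unwanted = FALSE)
cat("\nper-drug strict screen (no unwanted regulation):",
    paste(strict$drug, collapse = ", "), "\n")

comb <- select_combination(tab, desired, max_size = 2)
cat("\n")
print(comb)
jsonlite::write_json(
  list(drugs = comb$drugs,
       aggregate_regulation = as.list(comb$aggregate),
       total_side_effect = comb$total_side_effect,
       ld50 = as.list(comb$ld50), ec50 = as.list(comb$ec50),
       n_subsets_evaluated = nrow(comb$subsets),
       feasible_subsets = comb$subsets$drugs[comb$subsets$feasible],
       subset_diagnostics = comb$subsets),
  "results/drug_combination.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("\nselection report written to results/drug_combination.json\n")
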