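# gwgendrug

Systems-level identification of genome-wide genetic and epigenetic networks
(GWGENs) from expression data, core-network extraction, and systematic
screening of multiple-molecule drug combinations — with a deep-learning
drug–target interaction (DTI) classifier in between. The package is aimed at
computational systems biologists who want the whole chain — candidate network
→ identified network → core network → biomarker-targeting drug combination —
runnable and testable offline on synthetic data with planted ground truth.

## What it computes

**Network identification.** Each entity's expression over *N* samples follows
a static regression model: proteins interact through product terms
(*p<sub>q</sub>p<sub>r</sub>* with ability κ), genes/lncRNAs/miRNAs are
driven by TFs (α), lncRNAs (β) and repressing miRNAs (−γ·m·own expression,
γ ≥ 0), plus a basal level λ and Gaussian noise. Abilities are estimated by
least squares with the nonpositivity constraint on miRNA coefficients
(quadratic programming). The number of genuine regulators of each entity is
detected by minimizing

    AIC(k) = log(SSE_k / N) + 2(k+1)/N

over a nested model family ranked by |coefficient|; edges outside the
detected order are pruned as false positives.

**Principal network projection (PNP).** The identified abilities form a node
× regulator matrix H; its SVD energies E<sub>i</sub> = v<sub>i</sub>²/Σv²
determine the top-I singular structures holding ≥ 85% energy, each node gets
the score S(a) = Σ<sub>b≤I</sub> (h<sub>a,:</sub>·d<sub>:,b</sub>)², and the
top-scoring nodes induce the core network. Disease and control cores are
partitioned into common and group-specific parts, with log2-fold expression
direction labels and exact hypergeometric gene-set over-representation.

**DTI model.** Drug+target descriptor pairs (363 + 996 features) are
standardized, PCA-reduced to 618 components, and classified by a
618–512–256–128–64–1 network (ReLU, dropout 0.4, sigmoid output) trained
with Adam (lr 1e-4, batch 100) on binary cross-entropy under ten-fold
cross-validation with early stopping; metrics include the fold table,
ROC and AUC. The training loop is compiled and fully seeded.

**Drug design specifications.** Candidate drugs are screened by regulation
ability (signed, vs. desired biomarker directions), toxicity (LD50, larger =
safer), sensitivity (EC50, smaller = more potent) and side effect (bindings
beyond the biomarkers); an exhaustive subset search returns the smallest
feasible combination whose *summed* regulation drives every biomarker the
desired way.

## Worked example

The shipped nine-drug candidate table (bindings to the biomarker panel IKK,
STAT3, PPARγ, ETS1, FAS, with printed regulation abilities, LD50, EC50 and
side-effect counts) drives the combination search:

```r
library(gwgendrug)
tab <- paper_drug_fixture()
desired <- default_desired_regulation()   # IKK down, STAT3 up, PPARg up, ETS1 down, FAS down
select_combination(tab, desired, max_size = 2)
#> multiple-molecule targeting drug: Biotin + Sulforaphane
#>   aggregate regulation: IKK=-1.243, STAT3=1.154, PPARgamma=1.044, ETS1=-0.897, FAS=-0.059
#>   total side effect: 42 | LD50: 2.058, 3.110 | EC50: -0.249, -0.008
```

The pair is the unique feasible subset of size ≤ 2: no single drug covers
all five biomarkers with the right signs, and Biotin's strong ETS1
downregulation (−0.986) outweighs Sulforaphane's small unwanted +0.089, for
a net −0.897. The strict per-drug screen instead keeps

```r
filter_candidates(tab, desired, allow_unwanted = FALSE)$drug
#> [1] "Memantine"   "Trimetozine" "Biotin"
```

The full synthetic workflow lives in `analysis/01_simulate.R` …
`05_drug_selection.R` (run them in order from the repository root; outputs
land under `results/`). A minimal end-to-end run:

```r
bundle <- write_synthetic_bundle("input", seed = 1, n_protein = 6, n_gene = 8,
                                 n_lncRNA = 4, n_miRNA = 4, density = 0.3,
                                 spurious_fraction = 0.3, cascade = FALSE)
cfg <- default_config(paths = c(bundle$paths, out_dir = "out"),
                      pnp = list(top_k = 10))
res <- run_pipeline(cfg)
```

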