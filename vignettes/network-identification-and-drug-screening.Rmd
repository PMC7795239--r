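---
title: "Identifying genetic/epigenetic networks and screening drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying genetic/epigenetic networks and screening drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgendrug)
```

## The models

gwgendrug treats a cell's genome-wide genetic and epigenetic network (GWGEN)
as the union of a protein-protein interaction network and a gene regulatory
network over genes, transcription factors (TFs), lncRNAs and miRNAs. Each
entity's expression across $N$ samples is described by a static regression
model:

* **Protein** $q$: $p_q[n] = \sum_r \kappa_{qr}\, p_q[n] p_r[n] + \lambda_q +
  \varepsilon_q[n]$ over its candidate interaction partners $r$. Note the
  *product* regressor $p_q p_r$: interaction strength scales with both
  partners' abundance.
* **Gene** $x$: $g_x[n] = \sum_u \alpha_{xu} t_u[n] + \sum_v \beta_{xv}
  l_v[n] - \sum_w \gamma_{xw}\, m_w[n] g_x[n] + \lambda_x +
  \varepsilon_x[n]$, with TF abilities $\alpha$, lncRNA abilities $\beta$,
  and miRNA repression strengths $\gamma \ge 0$ entering negatively through
  the product with the gene's own expression.
* **lncRNA** and **miRNA** targets follow the same form with their own
  ability symbols.

$\lambda$ is a basal level absorbing unmodelled regulation; $\varepsilon$ is
Gaussian noise. Each target's model is linear in its unknown abilities, so
identification is least squares with the sign constraint
$-\gamma \le 0$ on every miRNA-product coefficient — a convex box-constrained
problem solved by quadratic programming (`fit_constrained()`), falling back
to a flagged minimum-norm solution on rank-deficient designs.

## Order detection and pruning

Candidate networks mined from interaction databases are heavily
false-positive. For each target, `detect_order()` fits the full constrained
model, ranks candidates by absolute coefficient, refits the nested models of
order $k = 0, \dots, K$, and keeps the order minimizing

$$\mathrm{AIC}(k) = \log\!\big(\mathrm{SSE}_k / N\big) + \frac{2(k+1)}{N},$$

with ties resolved toward fewer regulators and a $10^{-12}$ floor on the
residual variance of perfect fits. Edges outside the selected order are
false positives and removed (`prune_network()`). An undirected interaction
is kept only when *both* endpoint regressions retain it: every design column
of the interactive model contains the target's own expression, so a single
equation cannot reject an interaction for a protein whose variation is
exogenous (any product column explains a large share of the protein's own
variance). Requiring mutual support guards against this self-product
artifact; the surviving ability is the mean of the two estimates.

The nested (greedy) search is validated against an exhaustive subset search
on small instances (`study_aic_oracle()`): with three planted regulators of
ability 0.8–2 among six candidates at $N = 60$, noise 0.05, the nested
search attains the exhaustive minimum AIC in ≥ 95% of instances.

## Principal network projection

The identified abilities are arranged in a node × regulator matrix $H$
(`build_network_matrix()`), with protein interactions entered symmetrically,
and decomposed as $H = S V D^\top$. With energies
$E_i = v_i^2 / \sum_j v_j^2$, the smallest $I$ with
$\sum_{i \le I} E_i \ge 0.85$ retains the singular structures carrying 85%
of the network energy. Each node is scored by
$S(a) = \sum_{b \le I} (h_{a,:} \cdot d_{:,b})^2$ — at full rank this is the
squared row norm (Parseval), and ranking is invariant to taking the square
root. The top 3000 nodes (default) induce the core network. TFs have no row
in $H$; so that they can compete for core membership they are ranked by the
symmetric column score (squared projection of their column onto the top
*left* singular vectors), a package design choice. Score ties at the
boundary break by lexicographic id, so extraction is deterministic and
monotone in the core size.

Core networks for disease and control are compared edge-by-edge
(`diff_networks()`), nodes are labelled by pseudo-counted log2 fold change
($|\mathrm{lfc}| \ge 0.5$ by default; the direction criterion is a package
choice since the source material states none), and gene-set
over-representation uses the exact hypergeometric upper tail with
Benjamini–Hochberg correction — a deliberately generic, offline stand-in
for web-based pathway annotation.

## The drug–target interaction classifier

Drug and target descriptor vectors (363 + 996 dimensions by convention) are
concatenated per pair, standardized with training-set statistics, and
reduced by PCA to 618 components — reconciling the 1359 raw features with
the 618-unit input layer; the reduction dimension is configurable and
clipped to the available rank. The classifier is a fully connected network,
618–512–256–128–64–1, ReLU hidden activations, dropout 0.4 after each
hidden layer, sigmoid output, trained with Adam (learning rate $10^{-4}$,
batch size 100) on binary cross-entropy with probabilities clipped to
$[10^{-7}, 1-10^{-7}]$. A quarter of the data is held out for testing;
ten-fold stratified cross-validation runs on the remainder; early stopping
monitors validation loss with patience 10 and restores the best weights;
the fold with the best testing accuracy becomes the working model. The
output layer is initialised near zero so training starts from the
uninformative predictor (initial loss $\approx \log 2$ on balanced classes)
regardless of depth. The training loop is compiled (RcppArmadillo) and
draws all randomness — initialisation, shuffling, dropout — from R's RNG,
so every run is reproducible from its seed; inference disables dropout and
is deterministic.

ROC curves come from a threshold sweep over the unique scores and AUC from
the trapezoid rule; the tests verify AUC equals the normalised Mann–Whitney
U statistic and cross-check against an independent ROC implementation.

## Drug design specifications

Four specifications screen candidate drugs against a desired regulation
profile over biomarkers (here: IKK down, STAT3 up, PPARγ up, ETS1 down, FAS
down):

* **Regulation ability** — signed perturbation-response score; a drug's
  regulation of a bound biomarker is *desired* when its sign matches the
  wanted direction (an exact zero cannot drive a direction and counts as
  unwanted).
* **Toxicity** — LD50 in mol/kg, larger is safer.
* **Sensitivity** — EC50, smaller is more potent.
* **Side effect** — the number of predicted bindings in the core network
  beyond the desired biomarkers.

`select_combination()` searches all drug subsets up to `max_size` and
requires every biomarker to be bound by some member *and* the summed
regulation over members to carry the desired sign — net-effect reasoning: a
member's small unwanted regulation may be overruled by a partner. Among
feasible subsets the winner has minimal size, then minimal total side
effect, then maximal minimum LD50, then lexicographically smallest ids (the
tie hierarchy is a package choice). On the shipped nine-drug table this
search has a unique feasible pair, Sulforaphane + Biotin, whose aggregate
ETS1 regulation $0.089 - 0.986 = -0.897$ is the textbook net-effect case;
no singleton is feasible. The alternative reading — strict per-drug sign
correctness — is provided by `filter_candidates(allow_unwanted = FALSE)`
and keeps Memantine, Trimetozine and Biotin.

## The synthetic-data generator

`generate_candidate_gwgen()` plants a true network and dilutes it with
spurious candidate edges (50% by default). Design choices worth knowing:

* **Exact model balance.** Expression of a regulated node solves its model
  equation in closed form — the model is linear in the node's own
  expression, e.g. $g = (\sum \alpha t + \sum \beta l + \lambda +
  \varepsilon) / (1 + \sum \gamma m)$ — so simulated data satisfies the
  regression identity *exactly* at the planted parameters and noiseless
  identification recovers them to machine precision. No iterative solving
  is needed.
* **Exogenous drivers.** TFs and half of the proteins are exogenous with
  i.i.d. $|N(1, 0.5^2)|$ expression. The interactive model needs this: if
  every protein obeyed its own balance with constant basal levels,
  expression would be constant across samples.
* **Ability distributions.** Magnitudes are uniform in $[0.5, 2]$ —
  bounded away from zero so edge recovery is well-posed — with protein
  interaction abilities negative (keeping the protein balance solvable at
  positive expression), miRNA strengths positive, and TF/lncRNA abilities
  negative with probability 0.2. Basal levels are drawn in $[1, 2]$ and
  raised to compensate planted negative regulation, so genes with strong
  repressors are not simulated as dead; each target's summed miRNA load is
  capped (default 1.5) so repression does not compress the response below
  the noise. A few percent of values still clip at zero (expression is
  nonnegative; ~2% on single-layer truths, ~6% under cascades); the count
  is logged.
* **Single-layer versus cascade truths.** By default lncRNAs and miRNAs are
  themselves regulated along a random acyclic order (deep cascades). For
  identifiability studies `cascade = FALSE` plants a single regulatory
  layer: at zero noise a cascade makes some designs exactly collinear (a
  regulated lncRNA is an exact linear function of its own regulators when
  they co-occur as candidates), so the noiseless recovery study is only
  well-posed on single-layer truths.

The DTI generator draws descriptor matrices i.i.d. normal and labels pairs
by a latent linear rule at the quantile matching the requested
negative:positive ratio (1:1 default, uniform random non-positive pairs —
the reference criteria for negative sampling are not publicly available).
A `margin` option excludes pairs near the labelling threshold so classes
are separated by a gap; `label_noise` flips labels independently.

What the generators do *not* emulate: count noise and library-size effects
of sequencing, dropout/zero inflation beyond clipping, confounders, batch
structure, feedback loops (the models are static regressions), or realistic
descriptor correlation structure. Passing tests demonstrate correctness of
the machinery under the stated models, not performance on real RNA-seq or
binding data.

## Study sizes and measured behaviour

The standard studies (run by `analysis/` and the acceptance machinery) use:
parameter recovery on 50 replicate networks at $N = 200$, noise 0.1
(median absolute error ≈ 0.01, well under the 0.05 bar; noiseless replicates
recover to $10^{-8}$); edge recovery on 50 replicates of a 50-node,
~10-candidates-per-target, 50% spurious single-layer network (precision
≈ 0.85, recall ≈ 0.99); and the DTI cross-validation on 5000 pairs with a
0.4-sd margin, 30 epochs per fold (mean testing accuracy ≈ 100% on this
separable task, ~6 minutes on one core). The 100-epoch default of
`dti_config()` is kept for real use.

## Known limitations

* **AIC is liberal.** With penalty $2/N$, a spurious regressor survives
  whenever its incremental $\chi^2$ exceeds 2, which happens for ~16% of
  null candidates — and for the *best* of ten null candidates almost
  always. Pure-noise targets therefore usually retain one or two spurious
  regulators; an empty retained set is the exception, not the rule. The
  0.85 precision of the edge-recovery study is what the criterion's penalty
  can deliver, not a tuning artifact.
* **Self-product endogeneity.** The interactive (protein) and miRNA terms
  place the target's own expression inside the design, so the regressors
  carry the response's noise. Consequences: miRNA-ability estimates
  attenuate as total repression grows, and protein equations cannot by
  themselves reject spurious interactions (PPI precision is ≈ 0.5 even
  under mutual-support pruning; this is a property of the model family).
* **Cascade collinearity.** Deeply cascaded truths produce regressor
  correlations near 1 and drop overall precision to ≈ 0.7 — reported by
  `analysis/02_identify_prune.R` as the harder condition.
* The direction threshold, PNP column score for TFs, and combination tie
  hierarchy are package choices where the source material is silent; each
  is stated above.
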