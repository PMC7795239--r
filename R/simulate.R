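# Synthetic candidate networks with planted ground truth, expression generated
# from the interactive/regulatory models, and synthetic drug-target interaction
# datasets. The generators are first-class: every downstream stage is tested
# against the planted truth they record.

#' Construct a ground-truth object by hand
#'
#' @param true_edges Data frame `source`, `target`, `mode`, `ability`. Ability
#'   is in model convention: for `miRNA->*` edges it is the repression strength
#'   (>= 0) that enters the model negatively; for `ppi` it is the interaction
#'   ability kappa; otherwise the signed transcriptional ability.
#' @param basal Named numeric vector of basal levels (lambda), one per target
#'   entity. For `ppi` edges the canonical `target` (lexicographically larger
#'   id) is taken as the responder whose balance generates expression.
#' @param noise_sd Standard deviation of the additive model noise (>= 0).
#' @return Object of class `"gwgen_truth"`.
#' @export
gwgen_truth <- function(true_edges, basal, noise_sd = 0.1) {
  true_edges <- as.data.frame(true_edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "mode", "ability") %in% names(true_edges)))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  mir <- grepl("^miRNA->", true_edges$mode)
  if (any(true_edges$ability[mir] < 0)) {
    stopf("miRNA regulation abilities must be >= 0 (they enter the model negatively)")
  }
  true_edges <- .canonicalize_ppi(true_edges)
  structure(list(true_edges = true_edges, basal = basal, noise_sd = noise_sd),
            class = "gwgen_truth")
}

# sample spurious edges of a given mode that avoid existing pairs / self loops
.sample_spurious <- function(mode, n, pools, existing_keys, rng_ids) {
  mk <- .mode_kinds()
  row <- mk[mk$mode == mode, ]
  src_pool <- pools[[row$source_kind]]
  tgt_pool <- pools[[row$target_kind]]
  out <- list()
  tries <- 0L
  while (length(out) < n && tries < 200L * n + 200L) {
    tries <- tries + 1L
    s <- sample(src_pool, 1L)
    t <- sample(tgt_pool, 1L)
    if (s == t) next
    e <- data.frame(source = s, target = t, mode = mode, stringsAsFactors = FALSE)
    e <- .canonicalize_ppi(e)
    k <- edge_key(e)
    if (k %in% existing_keys) next
    existing_keys <- c(existing_keys, k)
    out[[length(out) + 1L]] <- e
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Generate a candidate network with a planted true subnetwork
#'
#' Plants a true network (recorded in the returned ground truth) and dilutes it
#' with spurious candidate edges so that identification and pruning can be
#' scored against a known answer. Proteins are split into exogenous drivers
#' (never targets of planted interactions; they supply the sample-to-sample
#' variation the interactive model needs) and responders. Directed regulations
#' among lncRNAs/miRNAs follow a random acyclic order so expression can be
#' generated consistently.
#'
#' Ability magnitudes are drawn uniformly from `ability_range`; protein
#' interaction abilities are negative (so the interactive balance stays
#' solvable with positive expression), miRNA repression strengths positive,
#' and TF/lncRNA abilities carry a random sign (`prob_negative`).
#'
#' @param n_protein,n_gene,n_lncRNA,n_miRNA Node counts (>= 1).
#' @param density Probability that each eligible regulator-target pair is a
#'   planted true edge, in (0,1).
#' @param spurious_fraction Fraction of candidate edges that are spurious, in
#'   \\[0,1).
#' @param seed Integer seed.
#' @param n_tf Number of transcription-factor nodes (default
#'   `max(2, ceiling(n_gene/2))`).
#' @param ability_range Magnitude range for planted abilities.
#' @param prob_negative Probability of a negative sign on TF/lncRNA abilities.
#' @param basal_range Range for basal levels lambda.
#' @param noise_sd Noise standard deviation recorded in the ground truth.
#' @param mirna_load_cap Upper bound on each target's summed miRNA repression
#'   strengths (draws are rescaled above it). Caps the self-product
#'   denominator so the planted signal is not compressed below the noise;
#'   `Inf` disables.
#' @param cascade If `TRUE` (default), lncRNAs and miRNAs are themselves
#'   regulated (by TFs and by lower-ranked lncRNAs/miRNAs), producing deep
#'   regulatory cascades. If `FALSE`, only genes and responder proteins are
#'   regulated and every regulator stays exogenous; use this single-layer
#'   design for noiseless identifiability studies, where cascades make some
#'   designs exactly collinear (a regulated lncRNA is then an exact linear
#'   function of its own regulators).
#' @return List with `network` (a [gwgen()], abilities unset) and `truth`
#'   (a [gwgen_truth()]).
#' @export
generate_candidate_gwgen <- function(n_protein, n_gene, n_lncRNA, n_miRNA,
                                     density = 0.15, spurious_fraction = 0.5,
                                     seed = 1L, n_tf = NULL,
                                     ability_range = c(0.5, 2),
                                     prob_negative = 0.2,
                                     basal_range = c(1, 2),
                                     noise_sd = 0.1, cascade = TRUE,
                                     mirna_load_cap = 1.5) {
  for (n in c(n_protein, n_gene, n_lncRNA, n_miRNA)) {
    if (!is_count(n)) stopf("node counts must be positive integers")
  }
  if (!(density > 0 && density < 1)) stopf("density must be in (0,1)")
  if (!(spurious_fraction >= 0 && spurious_fraction < 1)) {
    stopf("spurious_fraction must be in [0,1)")
  }
  set.seed(seed)
  n_tf <- n_tf %||% max(2L, ceiling(n_gene / 2))

  prot <- sprintf("P%03d", seq_len(n_protein))
  tfs <- sprintf("TF%03d", seq_len(n_tf))
  genes <- sprintf("G%03d", seq_len(n_gene))
  lnc <- sprintf("L%03d", seq_len(n_lncRNA))
  mir <- sprintf("M%03d", seq_len(n_miRNA))
  nodes <- data.frame(
    id = c(prot, tfs, genes, lnc, mir),
    kind = c(rep("protein", n_protein), rep("TF", n_tf), rep("gene", n_gene),
             rep("lncRNA", n_lncRNA), rep("miRNA", n_miRNA)),
    stringsAsFactors = FALSE
  )

  drivers <- prot[seq_len(ceiling(n_protein / 2))]
  responders <- setdiff(prot, drivers)
  # acyclic generation order over the lncRNA/miRNA pool
  rank_pool <- sample(c(lnc, mir))

  draw_ability <- function(n, sign = c("mixed", "neg", "pos")) {
    sign <- match.arg(sign)
    mag <- stats::runif(n, ability_range[1], ability_range[2])
    s <- switch(sign,
                mixed = ifelse(stats::runif(n) < prob_negative, -1, 1),
                neg = -1, pos = 1)
    mag * s
  }

  true <- list()
  add <- function(sources, target, mode, sign) {
    if (length(sources) == 0) return(NULL)
    data.frame(source = sources, target = target, mode = mode,
               ability = draw_ability(length(sources), sign),
               stringsAsFactors = FALSE)
  }
  pick <- function(pool) pool[stats::runif(length(pool)) < density]

  for (p in responders) true[[length(true) + 1L]] <- add(pick(drivers), p, "ppi", "neg")
  for (g in genes) {
    true[[length(true) + 1L]] <- add(pick(tfs), g, "tf->gene", "mixed")
    true[[length(true) + 1L]] <- add(pick(lnc), g, "lncRNA->gene", "mixed")
    true[[length(true) + 1L]] <- add(pick(mir), g, "miRNA->gene", "pos")
  }
  for (x in if (cascade) rank_pool else character(0)) {
    r <- match(x, rank_pool)
    lower_l <- intersect(rank_pool[seq_len(r - 1L)], lnc)
    lower_m <- intersect(rank_pool[seq_len(r - 1L)], mir)
    if (x %in% lnc) {
      true[[length(true) + 1L]] <- add(pick(tfs), x, "tf->lncRNA", "mixed")
      true[[length(true) + 1L]] <- add(pick(lower_l), x, "lncRNA->lncRNA", "mixed")
      true[[length(true) + 1L]] <- add(pick(lower_m), x, "miRNA->lncRNA", "pos")
    } else {
      true[[length(true) + 1L]] <- add(pick(tfs), x, "tf->miRNA", "mixed")
      true[[length(true) + 1L]] <- add(pick(lower_l), x, "lncRNA->miRNA", "mixed")
      true[[length(true) + 1L]] <- add(pick(lower_m), x, "miRNA->miRNA", "pos")
    }
  }
  true <- do.call(rbind, true[!vapply(true, is.null, logical(1))])
  if (is.null(true) || nrow(true) == 0) stopf("no true edges planted; increase density")
  true <- .canonicalize_ppi(true)

  # keep each target's total miRNA repression moderate: if the summed
  # repression strengths exceed mirna_load_cap the response is compressed far
  # below the (additive) noise and no method could recover the signal
  mir_rows <- grepl("^miRNA->", true$mode)
  if (any(mir_rows) && is.finite(mirna_load_cap)) {
    for (tg in unique(true$target[mir_rows])) {
      i <- which(mir_rows & true$target == tg)
      tot <- sum(true$ability[i])
      if (tot > mirna_load_cap) true$ability[i] <- true$ability[i] * mirna_load_cap / tot
    }
  }

  pools <- list(protein = prot, TF = tfs, gene = genes, lncRNA = lnc, miRNA = mir)
  n_spur <- round(nrow(true) * spurious_fraction / (1 - spurious_fraction))
  spurious <- NULL
  if (n_spur > 0) {
    per_mode <- table(true$mode)
    alloc <- round(n_spur * as.numeric(per_mode) / sum(per_mode))
    existing <- edge_key(true)
    sp <- list()
    for (i in seq_along(per_mode)) {
      if (alloc[i] == 0) next
      s <- .sample_spurious(names(per_mode)[i], alloc[i], pools, existing, NULL)
      if (!is.null(s)) {
        existing <- c(existing, edge_key(s))
        sp[[length(sp) + 1L]] <- s
      }
    }
    if (length(sp)) spurious <- do.call(rbind, sp)
  }

  cand <- true[, c("source", "target", "mode")]
  if (!is.null(spurious)) cand <- rbind(cand, spurious)
  cand$ability <- NA_real_

  target_ids <- c(prot, genes, lnc, mir)
  basal <- stats::setNames(stats::runif(length(target_ids), basal_range[1], basal_range[2]),
                           target_ids)
  # basal transcription compensates planted repression so expression stays
  # positive: a gene with strong negative regulators is not dead, it has a
  # higher basal level (regulator expression is unit-scale)
  lin_neg <- !mir_rows & true$mode != "ppi" & true$ability < 0
  if (any(lin_neg)) {
    comp <- tapply(-true$ability[lin_neg], true$target[lin_neg], sum)
    basal[names(comp)] <- basal[names(comp)] + 1.2 * comp
  }
  list(network = gwgen(nodes, cand),
       truth = gwgen_truth(true, basal, noise_sd))
}

#' Simulate expression from a planted ground truth
#'
#' Exogenous nodes (TFs, driver proteins, and any node without planted
#' regulators) get i.i.d. positive expression |N(1, 0.5^2)|. Every regulated
#' node's expression solves its model balance exactly: the model is linear in
#' the target's own expression, so e.g. a gene obeys
#' `g = (sum alpha t + sum beta l + lambda + eps) / (1 + sum gamma m)`.
#' The generated data therefore satisfies the fitted regression identity at
#' the planted parameters, with residual exactly `eps ~ N(0, noise_sd^2)`.
#' Negative values are clipped to zero (expression is nonnegative) and the
#' clip count logged.
#'
#' @param truth A [gwgen_truth()].
#' @param network The matching candidate [gwgen()] (used for the
#'   identifiability precondition).
#' @param n_samples Number of samples; must exceed the maximum candidate
#'   in-degree plus one.
#' @param seed Integer seed.
#' @param group Group label assigned to all samples.
#' @param sample_prefix Prefix for generated sample ids.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(truth, network, n_samples, seed = 1L,
                                group = c("control", "disease"),
                                sample_prefix = NULL) {
  group <- match.arg(group)
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  tab <- table(c(network$edges$target[network$edges$mode != "ppi"],
                 network$edges$source[network$edges$mode == "ppi"],
                 network$edges$target[network$edges$mode == "ppi"]))
  max_deg <- if (length(tab)) max(tab) else 0L
  if (n_samples <= max_deg + 1) {
    stopf("n_samples (%d) must exceed max candidate in-degree + 1 (%d)",
          n_samples, max_deg + 1)
  }
  set.seed(seed)
  ids <- network$nodes$id
  N <- n_samples
  vals <- matrix(abs(stats::rnorm(length(ids) * N, 1, 0.5)), length(ids), N,
                 dimnames = list(ids, NULL))
  te <- truth$true_edges
  # ppi: responders are the planted interaction targets; an edge is planted
  # driver -> responder, and the responder endpoint holds the balance.
  ppi <- te[te$mode == "ppi", , drop = FALSE]
  reg_dir <- te[te$mode != "ppi", , drop = FALSE]
  responders <- unique(ppi$target)   # generator plants driver (source) -> responder (target)
  # nodes regulated only through ppi as *source* side keep exogenous values
  regulated <- unique(c(reg_dir$target, responders))

  # generation order: proteins depend only on drivers; lncRNA/miRNA follow the
  # planted acyclic order (sources precede targets); genes come last.
  kind_of <- stats::setNames(network$nodes$kind, network$nodes$id)
  pool <- regulated[kind_of[regulated] %in% c("lncRNA", "miRNA")]
  deps <- reg_dir[reg_dir$target %in% pool & reg_dir$source %in% pool, , drop = FALSE]
  ordered <- character(0)
  remaining <- pool
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(x) {
      srcs <- deps$source[deps$target == x]
      all(srcs %in% ordered)
    }, logical(1))]
    if (length(ready) == 0) stopf("cyclic lncRNA/miRNA regulation in planted truth")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  gen_order <- c(regulated[kind_of[regulated] == "protein"], ordered,
                 regulated[kind_of[regulated] == "gene"])

  n_clip <- 0L
  for (x in gen_order) {
    eps <- stats::rnorm(N, 0, truth$noise_sd)
    lambda <- truth$basal[[x]]
    if (is.null(lambda) || is.na(lambda)) stopf("no basal level for target %s", x)
    if (kind_of[[x]] == "protein") {
      part <- ppi[ppi$target == x, , drop = FALSE]
      denom <- 1 - colSums(matrix(part$ability * vals[part$source, , drop = FALSE],
                                  nrow = nrow(part)))
      v <- (lambda + eps) / denom
    } else {
      inc <- reg_dir[reg_dir$target == x, , drop = FALSE]
      mir <- grepl("^miRNA->", inc$mode)
      lin <- inc[!mir, , drop = FALSE]
      num <- lambda + eps
      if (nrow(lin)) {
        num <- num + colSums(matrix(lin$ability * vals[lin$source, , drop = FALSE],
                                    nrow = nrow(lin)))
      }
      denom <- rep(1, N)
      if (any(mir)) {
        mm <- inc[mir, , drop = FALSE]
        denom <- denom + colSums(matrix(mm$ability * vals[mm$source, , drop = FALSE],
                                        nrow = nrow(mm)))
      }
      v <- num / denom
    }
    neg <- v < 0
    if (any(neg)) {
      n_clip <- n_clip + sum(neg)
      v[neg] <- 0
    }
    vals[x, ] <- v
  }
  if (n_clip > 0) gw_log("info", "clipped %d negative simulated values to 0", n_clip)
  prefix <- sample_prefix %||% substr(group, 1, 1)
  colnames(vals) <- sprintf("%s%03d", prefix, seq_len(N))
  expression_matrix(vals, stats::setNames(rep(group, N), colnames(vals)))
}

#' Perturb a ground truth to create a second (disease) condition
#'
#' Rescales a random fraction of planted abilities and drops another random
#' fraction of planted edges, so control and disease cores differ.
#'
#' @param truth A [gwgen_truth()].
#' @param rescale_fraction Fraction of abilities rescaled by `factor`.
#' @param drop_fraction Fraction of true edges removed in the new condition.
#' @param factor Rescale multiplier.
#' @param seed Integer seed.
#' @return A new [gwgen_truth()].
#' @export
perturb_truth <- function(truth, rescale_fraction = 0.3, drop_fraction = 0.2,
                          factor = 2, seed = 1L) {
  set.seed(seed)
  te <- truth$true_edges
  n <- nrow(te)
  resc <- sample(n, round(rescale_fraction * n))
  te$ability[resc] <- te$ability[resc] * factor
  drop <- sample(setdiff(seq_len(n), resc), round(drop_fraction * n))
  if (length(drop)) te <- te[-drop, , drop = FALSE]
  gwgen_truth(te, truth$basal, truth$noise_sd)
}

#' Generate a synthetic drug-target interaction dataset
#'
#' Drug and target descriptor vectors are i.i.d. standard normal; a latent
#' linear rule over both blocks scores every pair, the score quantile giving
#' the requested negative:positive ratio defines binding, and labels are
#' flipped with probability `label_noise`. With `label_noise = 0` the classes
#' are linearly separable in the raw features by construction.
#'
#' @param n_drugs,n_targets Number of drugs / targets.
#' @param n_pairs Number of drug-target pairs to sample (default: all).
#' @param drug_dim,target_dim Descriptor dimensions (defaults 363 and 996).
#' @param neg_pos_ratio Negative:positive class ratio (> 0).
#' @param label_noise Label flip probability in \\[0, 0.5).
#' @param margin Exclusion band around the labelling threshold, in standard
#'   deviations of the latent score: pairs closer than this are not sampled,
#'   so the two classes are separated by a gap (0 disables).
#' @param seed Integer seed.
#' @return List of class `"dti_dataset"`: `pairs` (drug, target, label),
#'   `features` (pairs x (drug_dim+target_dim) matrix, drug block first),
#'   `drug_features`, `target_features`, and the latent `rule`.
#' @export
generate_dti_dataset <- function(n_drugs = 100, n_targets = 100, n_pairs = NULL,
                                 drug_dim = 363, target_dim = 996,
                                 neg_pos_ratio = 1, label_noise = 0,
                                 margin = 0, seed = 1L) {
  if (drug_dim < 1 || target_dim < 1) stopf("descriptor dims must be >= 1")
  if (neg_pos_ratio <= 0) stopf("neg_pos_ratio must be > 0")
  if (label_noise < 0 || label_noise >= 0.5) stopf("label_noise must be in [0, 0.5)")
  set.seed(seed)
  D <- matrix(stats::rnorm(n_drugs * drug_dim), n_drugs, drug_dim,
              dimnames = list(sprintf("DRUG%04d", seq_len(n_drugs)), NULL))
  T_ <- matrix(stats::rnorm(n_targets * target_dim), n_targets, target_dim,
               dimnames = list(sprintf("TGT%04d", seq_len(n_targets)), NULL))
  w_d <- stats::rnorm(drug_dim) / sqrt(drug_dim)
  w_t <- stats::rnorm(target_dim) / sqrt(target_dim)
  sd_score <- as.numeric(D %*% w_d)
  st_score <- as.numeric(T_ %*% w_t)
  score <- outer(sd_score, st_score, `+`)
  pos_frac <- 1 / (1 + neg_pos_ratio)
  thr <- stats::quantile(score, 1 - pos_frac, names = FALSE)
  lab_all <- score > thr
  total <- n_drugs * n_targets
  n_pairs <- n_pairs %||% total
  n_pos <- round(n_pairs * pos_frac)
  n_neg <- n_pairs - n_pos
  eligible <- abs(score - thr) >= margin * stats::sd(score)
  pos_idx <- which(lab_all & eligible)
  neg_idx <- which(!lab_all & eligible)
  if (n_pos > length(pos_idx)) stopf("requested positives exceed the positive pair universe")
  if (n_neg > length(neg_idx)) stopf("requested negatives exceed the non-positive pair universe")
  idx <- c(sample(pos_idx, n_pos), sample(neg_idx, n_neg))
  idx <- sample(idx)     # shuffle pair order
  di <- ((idx - 1L) %% n_drugs) + 1L
  ti <- ((idx - 1L) %/% n_drugs) + 1L
  label <- as.integer(lab_all[idx])
  if (label_noise > 0) {
    flip <- stats::runif(length(label)) < label_noise
    label[flip] <- 1L - label[flip]
  }
  features <- cbind(D[di, , drop = FALSE], T_[ti, , drop = FALSE])
  rownames(features) <- paste(rownames(D)[di], rownames(T_)[ti], sep = ":")
  structure(list(
    pairs = data.frame(drug = rownames(D)[di], target = rownames(T_)[ti],
                       label = label, stringsAsFactors = FALSE),
    features = features,
    drug_features = D, target_features = T_,
    rule = list(w_drug = w_d, w_target = w_t, threshold = thr)
  ), class = "dti_dataset")
}
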