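# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# Run the full depth -> features -> screening -> SVM chain on synthetic
# cohorts drawn from one genome (region_seed) and report test accuracy
# plus feature-selection quality.
run_sex_pipeline <- function(seed, region_seed = 1, male_depth_ratio = 0.5,
                             alpha = 0.05) {
  tr <- simulate_depth_matrix(sim_depth_params(
    seed = seed, region_seed = region_seed,
    male_depth_ratio = male_depth_ratio))
  te <- simulate_depth_matrix(sim_depth_params(
    seed = seed + 5000L, region_seed = region_seed,
    male_depth_ratio = male_depth_ratio))
  norm <- normalize_depths(tr$depths, tr$features)
  sel <- suppressWarnings(
    select_features(fit_feature_models(norm, tr$truth), alpha))
  ids <- sel$feature_id[sel$selected]
  truth_ids <- tr$features$feature_id[tr$features$sex_linked]
  n_fp <- sum(!ids %in% truth_ids)
  n_tp <- sum(ids %in% truth_ids)
  if (length(ids) < 2) {
    return(list(accuracy = NA_real_, n_selected = length(ids),
                n_fp = n_fp, n_tp = n_tp))
  }
  feats <- norm[, c("sample_id", ids)]
  scr <- screen_training_labels(feats, tr$truth)
  model <- train_sex_model(feats[scr$kept, ], tr$truth[scr$kept, ], seed = 1)
  norm_te <- normalize_depths(te$depths, te$features)
  pred <- predict_sex(model, norm_te[, c("sample_id", ids)], min_prob = 0.7)
  list(accuracy = mean(pred$predicted_sex == te$truth$sex),
       n_selected = length(ids), n_fp = n_fp, n_tp = n_tp,
       n_removed = sum(!scr$kept))
}

# Strain classifier end-to-end under the planted regime.
run_strain_pipeline <- function(seed, super_alpha_fraction = 0.3,
                                error_rate = 0.01) {
  sim <- simulate_allele_counts(sim_strain_params(
    seed = seed, super_alpha_fraction = super_alpha_fraction,
    error_rate = error_rate))
  model <- train_strain_model(sim$counts, sim$truth, seed = seed)
  list(accuracy = accuracy(model$confusion), mcc = mcc(model$confusion),
       beta1 = model$beta1, separation = model$separation)
}

# Independent least-squares branch lengths + minimum-evolution score for
# each of the 3 unrooted 4-taxon topologies; oracle for NJ.
min_evolution_4taxa <- function(dm) {
  taxa <- rownames(dm)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))  # partner of taxon 1
  best <- NULL
  for (s in seq_along(splits)) {
    pair1 <- splits[[s]]
    pair2 <- setdiff(1:4, pair1)
    # edges: 4 pendant + 1 internal; rows = 6 taxon pairs
    pairs <- utils::combn(4, 2)
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    for (k in 1:6) {
      i <- pairs[1, k]; j <- pairs[2, k]
      X[k, i] <- 1; X[k, j] <- 1
      same_side <- (i %in% pair1) == (j %in% pair1)
      if (!same_side) X[k, 5] <- 1
      y[k] <- dm[i, j]
    }
    beta <- qr.coef(qr(X), y)
    len <- sum(abs(beta))
    if (is.null(best) || len < best$len) {
      best <- list(len = len, split = taxa[pair1])
    }
  }
  best
}

# The unrooted split {a, b} vs rest recovered from a 4-taxon phylo tree.
nj_4taxon_split <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sizes <- vapply(parts, length, integer(1))
  inner <- parts[sizes == 2]
  if (length(inner) == 0) return(NULL)
  sort(labs[inner[[1]]])
}
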