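#' Screen morphological sex labels by PCA cluster concordance
#'
#' Morphological sexing of field material is error-prone; before model
#' training, samples are projected onto the first principal component of
#' the standardized selected features and split into two clusters
#' (k-means, k = 2, deterministically initialised at the two PC1
#' extremes). Each cluster takes the majority morphological label;
#' samples whose own label disagrees with their cluster majority are
#' flagged for removal.
#'
#' @param features Wide tibble: `sample_id` plus the selected feature
#'   columns (normalized depths).
#' @param labels Tibble with `sample_id` and `sex`, or a vector of
#'   labels aligned with `features` rows.
#' @return A tibble `sample_id`, `sex`, `pc1`, `cluster`, `cluster_sex`,
#'   `kept`. Kept sample ids are `out$sample_id[out$kept]`.
#' @export
screen_training_labels <- function(features, labels) {
  x <- sample_feature_matrix(features)
  sex <- align_labels(labels, rownames(x))
  if (length(unique(sex)) < 2) {
    stop("both sexes must be present for label screening.", call. = FALSE)
  }
  if (nrow(x) < 4) stop("need at least 4 labelled samples.", call. = FALSE)

  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  pc1 <- stats::prcomp(xs, center = FALSE, scale. = FALSE)$x[, 1]
  centers <- matrix(c(min(pc1), max(pc1)), ncol = 1)
  km <- stats::kmeans(matrix(pc1, ncol = 1), centers = centers)
  cluster <- km$cluster

  cluster_sex <- character(2)
  for (k in 1:2) {
    tab <- table(sex[cluster == k])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      stop("tied majority labels in PC1 cluster ", k,
           "; cannot assign a consensus sex (",
           paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ").",
           call. = FALSE)
    }
    cluster_sex[k] <- top
  }
  consensus <- cluster_sex[cluster]
  tibble::tibble(
    sample_id = rownames(x),
    sex = sex,
    pc1 = unname(pc1),
    cluster = unname(cluster),
    cluster_sex = unname(consensus),
    kept = sex == consensus
  )
}

#' Train the depth-based sex classifier
#'
#' Standardizes the selected features and fits a maximum-margin
#' classifier (support vector machine, radial-basis kernel, cost 1) with
#' logistic probability calibration, the approach used for depth-based
#' sexing of *Aedes* ddRAD samples.
#'
#' @param features Wide tibble: `sample_id` plus feature columns
#'   (screened training samples only).
#' @param labels Tibble with `sample_id`, `sex`, or an aligned vector.
#' @param cost SVM cost parameter.
#' @param seed Seed for the internal cross-validation used by the
#'   probability calibration.
#' @return A `sex_model` object.
#' @export
train_sex_model <- function(features, labels, cost = 1, seed = 1L) {
  x <- sample_feature_matrix(features)
  sex <- align_labels(labels, rownames(x))
  sex <- factor(sex, levels = c("female", "male"))
  if (any(table(sex) < 3)) {
    stop("need at least 3 samples per class to train.", call. = FALSE)
  }
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- scale(x, center = mu, scale = sd_)
  fit <- withr::with_seed(as.integer(seed), {
    e1071::svm(x = xs, y = sex, kernel = "radial", cost = cost,
               probability = TRUE, scale = FALSE)
  })
  structure(
    list(feature_ids = colnames(x), means = mu, sds = sd_, fit = fit,
         levels = levels(sex),
         training_report = list(n_train = nrow(x),
                                n_female = sum(sex == "female"),
                                n_male = sum(sex == "male"))),
    class = "sex_model"
  )
}

#' Predict sex from normalized depth features
#'
#' @param model A `sex_model` from [train_sex_model()].
#' @param features Wide tibble containing `sample_id` and all model
#'   features; unknown model features raise an error naming them.
#' @param min_prob Confidence threshold: a call is `confident` iff
#'   `max(p, 1 - p) > min_prob`. The preliminary-model refinement uses
#'   0.7; joint sex-and-strain reporting uses 0.6.
#' @return A tibble `sample_id`, `p_male`, `predicted_sex`, `confident`.
#'   A probability of exactly 0.5 is called female with
#'   `confident = FALSE` (documented tie rule).
#' @export
predict_sex <- function(model, features, min_prob = 0.7) {
  stopifnot(inherits(model, "sex_model"))
  x <- sample_feature_matrix(features)
  missing <- setdiff(model$feature_ids, colnames(x))
  if (length(missing) > 0) {
    stop("features missing from input: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, model$feature_ids, drop = FALSE]
  xs <- scale(x, center = model$means, scale = model$sds)
  pred <- stats::predict(model$fit, xs, probability = TRUE)
  p_male <- attr(pred, "probabilities")[, "male"]
  tibble::tibble(
    sample_id = rownames(x),
    p_male = unname(p_male),
    predicted_sex = ifelse(p_male > 0.5, "male", "female"),
    confident = pmax(p_male, 1 - p_male) > min_prob
  )
}

#' Save / load a fitted sex model
#'
#' Serialization round-trips to identical predictions.
#' @param model A `sex_model`.
#' @param path File path.
#' @return `write_sex_model` returns `path` invisibly; `read_sex_model`
#'   returns the model.
#' @export
write_sex_model <- function(model, path) {
  stopifnot(inherits(model, "sex_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_sex_model
#' @export
read_sex_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sex_model"))
  model
}

#' @export
print.sex_model <- function(x, ...) {
  cat("Depth-based sex classifier (RBF SVM)\n")
  cat(sprintf("  features: %d, trained on %d samples (%d F / %d M)\n",
              length(x$feature_ids), x$training_report$n_train,
              x$training_report$n_female, x$training_report$n_male))
  invisible(x)
}

#' @export
glance.sex_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_ids),
    n_train = x$training_report$n_train,
    n_female = x$training_report$n_female,
    n_male = x$training_report$n_male
  )
}

# ---- internal helpers ----

sample_feature_matrix <- function(features) {
  if (!"sample_id" %in% names(features)) {
    stop("feature table needs a `sample_id` column.", call. = FALSE)
  }
  feat_cols <- setdiff(names(features), c("sample_id", "batch"))
  x <- as.matrix(features[feat_cols])
  rownames(x) <- features$sample_id
  storage.mode(x) <- "double"
  x
}

align_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    idx <- match(sample_ids, labels$sample_id)
    if (anyNA(idx)) {
      stop("labels missing for samples: ",
           paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    as.character(labels$sex[idx])
  } else {
    if (length(labels) != length(sample_ids)) {
      stop("label vector length does not match sample count.", call. = FALSE)
    }
    as.character(labels)
  }
}
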