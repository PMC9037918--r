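#' Normalize raw depths to log2 relative depth
#'
#' Each sample's counts are divided by a per-sample scale — the median
#' raw depth over its negative-control tags (`mode = "control_tag"`) or
#' its total library depth (`mode = "library_size"`) — then
#' log2-transformed with a +0.5 pseudo-depth so zero counts stay finite:
#' `norm[i, j] = log2((depth[i, j] + 0.5) / scale_i)`.
#' Control tags are retained in the output (they stay flagged in the
#' feature table), and the transform is invariant to rescaling a whole
#' sample in control-tag mode.
#'
#' @param depths Wide tibble as produced by [simulate_depth_matrix()]:
#'   `sample_id`, `batch`, then one numeric column per feature.
#' @param features Feature table with `feature_id` and `kind`; required
#'   for `mode = "control_tag"`.
#' @param mode `"control_tag"` or `"library_size"`.
#' @return A tibble of the same shape with normalized values.
#' @export
normalize_depths <- function(depths, features = NULL,
                             mode = c("control_tag", "library_size")) {
  mode <- match.arg(mode)
  meta_cols <- intersect(c("sample_id", "batch"), names(depths))
  feat_cols <- setdiff(names(depths), meta_cols)
  mat <- as.matrix(depths[feat_cols])
  if (any(mat < 0)) stop("depths must be non-negative.", call. = FALSE)

  if (mode == "control_tag") {
    if (is.null(features)) {
      stop("control-tag normalization needs a `features` table.", call. = FALSE)
    }
    ctrl <- features$feature_id[features$kind == "control_tag"]
    ctrl <- intersect(ctrl, feat_cols)
    if (length(ctrl) < 1) {
      stop("control-tag normalization requires >= 1 control_tag feature.",
           call. = FALSE)
    }
    scale_i <- apply(mat[, ctrl, drop = FALSE], 1, stats::median)
    bad <- scale_i <= 0
    if (any(bad)) {
      stop("samples with all-zero control tags: ",
           paste(depths$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  } else {
    scale_i <- rowSums(mat)
    bad <- scale_i <= 0
    if (any(bad)) {
      stop("samples with zero total depth: ",
           paste(depths$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  norm <- log2((mat + 0.5) / scale_i)
  dplyr::bind_cols(depths[meta_cols], tibble::as_tibble(norm))
}

#' Per-feature linear models for a sex effect on depth
#'
#' Fits, for every feature, an ordinary least-squares model
#' `normalized depth ~ sex + batch` and tests the sex coefficient with a
#' t-test; p-values are corrected across features by Benjamini-Hochberg.
#' Sex is coded female = 0, male = 1, so a positive effect is a male
#' depth excess. Batches containing a single sample are merged into a
#' pooled level before fitting.
#'
#' @param norm Normalized wide tibble from [normalize_depths()].
#' @param info Sample table with `sample_id`, `sex` (`"female"`/`"male"`)
#'   and optionally `batch`; if `batch` is absent it is taken from
#'   `norm`.
#' @return A tibble `feature_id`, `effect`, `p_value`, `q_value`,
#'   ordered as the input features; class `wolb_feature_selection`.
#' @export
fit_feature_models <- function(norm, info) {
  meta_cols <- intersect(c("sample_id", "batch"), names(norm))
  feat_cols <- setdiff(names(norm), meta_cols)
  if (!"batch" %in% names(info) && "batch" %in% names(norm)) {
    info <- dplyr::left_join(info, norm[c("sample_id", "batch")],
                             by = "sample_id")
  }
  info <- info[match(norm$sample_id, info$sample_id), ]
  if (anyNA(info$sex)) stop("every sample needs a sex label.", call. = FALSE)
  sex <- factor(info$sex, levels = c("female", "male"))
  if (any(table(sex) < 2)) {
    stop("need at least 2 samples of each sex.", call. = FALSE)
  }
  batch <- if ("batch" %in% names(info)) as.character(info$batch) else
    rep("b1", nrow(info))
  singletons <- names(which(table(batch) == 1))
  batch[batch %in% singletons] <- ".pooled"
  batch <- factor(batch)

  if (nlevels(batch) > 1) {
    X <- stats::model.matrix(~ sex + batch)
  } else {
    X <- stats::model.matrix(~ sex)
  }
  Y <- as.matrix(norm[feat_cols])
  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, Y)                       # p x features
  resid <- Y - X %*% coefs
  df_res <- nrow(X) - qr_x$rank
  rss <- colSums(resid^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  sex_col <- which(colnames(X) == "sexmale")
  var_unit <- xtx_inv[sex_col, sex_col]
  sigma2 <- rss / df_res
  se <- sqrt(sigma2 * var_unit)
  beta <- coefs[sex_col, ]

  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df_res)
  # degenerate features: constant depth -> no effect, p = 1;
  # exact separation with zero residual -> p = 0 via infinite t
  const <- apply(Y, 2, function(col) stats::var(col) == 0)
  p[const] <- 1
  beta[const] <- 0
  p[is.nan(p)] <- 1
  out <- tibble::tibble(
    feature_id = feat_cols,
    effect = unname(beta),
    p_value = unname(p),
    q_value = stats::p.adjust(p, method = "BH")
  )
  class(out) <- c("wolb_feature_selection", class(out))
  out
}

#' Select sex-associated features at a q-value threshold
#'
#' @param selection Output of [fit_feature_models()].
#' @param alpha q-value threshold in (0, 1\]; features with
#'   `q_value <= alpha` are selected.
#' @param method Multiple-testing correction used to recompute q-values:
#'   `"BH"` (default) or `"bonferroni"`.
#' @return The selection tibble with a logical `selected` column, sorted
#'   by ascending q-value then feature id. Selected feature ids are
#'   `out$feature_id[out$selected]`. Warns when nothing is selected.
#' @export
select_features <- function(selection, alpha = 0.05, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1].", call. = FALSE)
  out <- selection
  if (method != "BH") {
    out$q_value <- stats::p.adjust(out$p_value, method = method)
  }
  out$selected <- out$q_value <= alpha
  out <- out[order(out$q_value, out$feature_id), ]
  if (!any(out$selected)) {
    warning("no features selected at alpha = ", alpha, call. = FALSE)
  }
  class(out) <- c("wolb_feature_selection", setdiff(class(out), "wolb_feature_selection"))
  out
}

#' Volcano-style plot of per-feature sex effects
#'
#' @param object A `wolb_feature_selection` tibble.
#' @param ... Unused.
#' @return A ggplot: sex effect (log2 units) against -log10 q-value,
#'   selected features highlighted when a `selected` column is present.
#' @export
autoplot.wolb_feature_selection <- function(object, ...) {
  df <- object
  df$neglog_q <- -log10(pmax(df$q_value, 1e-300))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$neglog_q))
  if ("selected" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                                 alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "firebrick"))
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, colour = "grey40")
  }
  p + ggplot2::labs(x = "sex effect (log2 depth, male - female)",
                    y = expression(-log[10] ~ "q-value")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
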