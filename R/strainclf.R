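#' Discover diagnostic sites between two endosymbiont references
#'
#' Emulates read-simulation based site discovery: windows of `read_len`
#' bases are tiled along the wAlbA reference every `step` bases and
#' matched against the wAlbB reference allowing up to
#' `floor((1 - min_identity) * read_len)` mismatches. A window "uniquely
#' maps" iff it has exactly one such match. Mismatched columns inside
#' uniquely-mapping windows become diagnostic sites when every covering
#' window agrees on a single alternate base. Substitutions inside
#' repeated context are excluded automatically because their windows map
#' to multiple locations.
#'
#' @param ref_a,ref_b Single DNA sequences (character string,
#'   [Biostrings::DNAString] or length-1 `DNAStringSet`): the wAlbA-like
#'   and wAlbB-like references.
#' @param read_len Window (simulated read) length in bp.
#' @param step Tiling step in bp.
#' @param min_identity Identity required for a window alignment (default
#'   0.95 over `read_len`).
#' @return A tibble `site_id`, `position` (0-based on `ref_b`),
#'   `allele_a`, `allele_b`, sorted by position; zero rows (with a
#'   warning) when no window maps uniquely.
#' @export
discover_diagnostic_sites <- function(ref_a, ref_b, read_len = 100,
                                      step = 25, min_identity = 0.95) {
  a <- as_single_dna(ref_a)
  b <- as_single_dna(ref_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("references must be non-empty.", call. = FALSE)
  }
  if (read_len > min(length(a), length(b))) {
    stop("read_len exceeds the shortest reference.", call. = FALSE)
  }
  max_mm <- floor((1 - min_identity) * read_len)
  starts <- unique(c(seq(1, length(a) - read_len + 1, by = step),
                     length(a) - read_len + 1))

  cand <- list()
  n_unique <- 0
  for (s in starts) {
    win <- Biostrings::subseq(a, s, s + read_len - 1)
    hits <- Biostrings::matchPattern(win, b, max.mismatch = max_mm,
                                     with.indels = FALSE)
    if (length(hits) != 1) next
    n_unique <- n_unique + 1
    hb <- Biostrings::start(hits)[1]
    wa <- strsplit(as.character(win), "")[[1]]
    wb <- strsplit(as.character(Biostrings::subseq(b, hb, hb + read_len - 1)),
                   "")[[1]]
    mm <- which(wa != wb)
    if (length(mm) > 0) {
      cand[[length(cand) + 1]] <- tibble::tibble(
        position = hb + mm - 2L,   # 0-based on ref_b
        allele_a = wa[mm],
        allele_b = wb[mm]
      )
    }
  }
  if (n_unique == 0) {
    warning("no uniquely mapping windows; returning an empty site set.",
            call. = FALSE)
    return(tibble::tibble(site_id = character(), position = integer(),
                          allele_a = character(), allele_b = character()))
  }
  if (length(cand) == 0) {
    return(tibble::tibble(site_id = character(), position = integer(),
                          allele_a = character(), allele_b = character()))
  }
  sites <- dplyr::bind_rows(cand) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_alt = dplyr::n_distinct(.data$allele_a),
      allele_a = dplyr::first(.data$allele_a),
      allele_b = dplyr::first(.data$allele_b),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_alt == 1, .data$allele_a != .data$allele_b) |>
    dplyr::arrange(.data$position)
  tibble::tibble(
    site_id = sprintf("site%05d", sites$position),
    position = as.integer(sites$position),
    allele_a = sites$allele_a,
    allele_b = sites$allele_b
  )
}

#' Count diagnostic allele observations per sample
#'
#' Observations matching the wAlbA allele at a diagnostic site count
#' into `a_count`; observations matching the wAlbB allele count into the
#' remainder of `total_count`. Observations matching neither allele, or
#' falling outside the diagnostic site set, are excluded and reported in
#' the `dropped` attribute.
#'
#' @param observations Long tibble `sample_id`, `position` (0-based),
#'   `base`, and optionally `count` (default 1 per row).
#' @param sites Diagnostic site table from
#'   [discover_diagnostic_sites()].
#' @return A tibble `sample_id`, `a_count`, `total_count` (one row per
#'   sample), with attribute `dropped` giving per-sample excluded
#'   observation counts.
#' @export
count_alleles <- function(observations, sites) {
  obs <- observations
  if (!"count" %in% names(obs)) obs$count <- 1L
  if (!all(obs$base %in% c("A", "C", "G", "T"))) {
    stop("observation bases must be A, C, G or T.", call. = FALSE)
  }
  obs <- dplyr::left_join(
    obs, sites[c("position", "allele_a", "allele_b")], by = "position")
  obs$kind <- dplyr::case_when(
    is.na(obs$allele_a) ~ "off_site",
    obs$base == obs$allele_a ~ "A",
    obs$base == obs$allele_b ~ "B",
    TRUE ~ "other"
  )
  out <- obs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      a_count = sum(.data$count[.data$kind == "A"]),
      total_count = sum(.data$count[.data$kind %in% c("A", "B")]),
      .groups = "drop"
    )
  dropped <- obs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(dropped = sum(.data$count[.data$kind %in%
                                                 c("off_site", "other")]),
                     .groups = "drop")
  attr(out, "dropped") <- dropped
  out
}

#' Drop samples with too few allelic observations
#'
#' Samples with fewer than `min_total` allelic observations are removed
#' ("fewer than" is strict: a sample with exactly `min_total`
#' observations is kept).
#'
#' @param counts Tibble with `total_count` per sample.
#' @param min_total Minimum observation count (default 10).
#' @return The filtered tibble; removed sample ids in attribute
#'   `removed`.
#' @export
filter_min_observations <- function(counts, min_total = 10) {
  if (min_total < 0) stop("min_total must be >= 0.", call. = FALSE)
  keep <- counts$total_count >= min_total
  out <- counts[keep, ]
  attr(out, "removed") <- counts$sample_id[!keep]
  out
}

#' Laplace-smoothed wAlbA allele-fraction score
#'
#' `score = (a_count + k) / (total_count + 2k)` with pseudocount `k`
#' added to both allele classes, so the score is strictly inside (0, 1)
#' and its natural log is always finite. A sample with no observations
#' scores exactly 0.5 (uninformative).
#'
#' @param a_count,total_count Non-negative counts (vectorized);
#'   `a_count <= total_count`.
#' @param pseudocount Smoothing constant `k > 0` (default 1).
#' @return Numeric scores in (0, 1).
#' @export
compute_score <- function(a_count, total_count, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0.", call. = FALSE)
  if (any(a_count < 0) || any(total_count < 0) || any(a_count > total_count)) {
    stop("need 0 <= a_count <= total_count.", call. = FALSE)
  }
  (a_count + pseudocount) / (total_count + 2 * pseudocount)
}

#' Train the wAlbB-vs-superinfection classifier
#'
#' Splits the samples into stratified train/test sets, fits a univariate
#' logistic regression of the class label on the natural log of the
#' Laplace-smoothed score by maximum likelihood (Newton iterations,
#' tolerance 1e-8) and evaluates the held-out confusion matrix. Under
#' perfect separation the fit falls back to a lightly ridge-penalized
#' likelihood and flags it.
#'
#' @param counts Tibble `sample_id`, `a_count`, `total_count`.
#' @param labels Tibble `sample_id`, `label` with labels `"B"` (wAlbB
#'   single infection) and `"AB"` (superinfection), or an aligned
#'   vector.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Seed for the stratified split.
#' @param pseudocount Smoothing constant passed to [compute_score()].
#' @param class_threshold Probability cutoff for calling `"AB"`.
#' @return A `strain_model` object with elements `beta0`, `beta1`,
#'   `pseudocount`, `class_threshold`, `separation`, `confusion`
#'   (held-out [confusion_matrix()], positive class `"AB"`), and the
#'   train/test sample ids.
#' @export
train_strain_model <- function(counts, labels, test_fraction = 0.2,
                               seed = 1L, pseudocount = 1,
                               class_threshold = 0.5) {
  if (is.data.frame(labels)) {
    lab <- labels$label[match(counts$sample_id, labels$sample_id)]
  } else {
    lab <- as.character(labels)
  }
  if (anyNA(lab) || !all(lab %in% c("B", "AB"))) {
    stop("labels must be 'B' or 'AB' for every sample.", call. = FALSE)
  }
  if (!(class_threshold > 0 && class_threshold < 1)) {
    stop("class_threshold must be in (0, 1).", call. = FALSE)
  }
  score <- compute_score(counts$a_count, counts$total_count, pseudocount)
  x <- log(score)
  y <- as.integer(lab == "AB")

  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(y), lab), function(idx) {
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  train_idx <- setdiff(seq_along(y), test_idx)
  if (length(unique(y[train_idx])) < 2) {
    stop("both classes must be present in the training split.", call. = FALSE)
  }

  fit <- logistic_newton(cbind(1, x[train_idx]), y[train_idx])
  separation <- !fit$converged || any(abs(fit$beta) > 30)
  if (separation) {
    fit <- logistic_newton(cbind(1, x[train_idx]), y[train_idx], ridge = 1e-3)
  }

  model <- structure(
    list(beta0 = fit$beta[1], beta1 = fit$beta[2],
         se = sqrt(diag(solve(fit$hessian))),
         pseudocount = pseudocount, class_threshold = class_threshold,
         separation = separation,
         train_ids = counts$sample_id[train_idx],
         test_ids = counts$sample_id[test_idx]),
    class = "strain_model"
  )

  if (length(test_idx) > 0) {
    pred <- predict_strain(model, counts[test_idx, ])
    model$confusion <- confusion_matrix(lab[test_idx], pred$predicted_label,
                                        positive = "AB")
  }
  model
}

#' Classify samples as wAlbB-single or superinfected
#'
#' `P(AB) = logistic(beta0 + beta1 * ln(score))`; a sample is called
#' `"AB"` iff `P(AB) >= class_threshold`. A call is `confident` iff
#' `max(p, 1 - p) > 0.6`, the cutoff used for joint sex-and-strain
#' reporting.
#'
#' @param model A `strain_model`.
#' @param counts Tibble `sample_id`, `a_count`, `total_count`.
#' @return A tibble `sample_id`, `score`, `p_ab`, `predicted_label`,
#'   `confident`.
#' @export
predict_strain <- function(model, counts) {
  stopifnot(inherits(model, "strain_model"))
  score <- compute_score(counts$a_count, counts$total_count,
                         model$pseudocount)
  p <- stats::plogis(model$beta0 + model$beta1 * log(score))
  tibble::tibble(
    sample_id = counts$sample_id,
    score = score,
    p_ab = p,
    predicted_label = ifelse(p >= model$class_threshold, "AB", "B"),
    confident = pmax(p, 1 - p) > 0.6
  )
}

#' @export
print.strain_model <- function(x, ...) {
  cat("Log-score logistic strain classifier (positive class AB)\n")
  cat(sprintf("  P(AB) = logistic(%.4f + %.4f * ln(score))%s\n",
              x$beta0, x$beta1,
              if (x$separation) "  [ridge-penalized: separation]" else ""))
  if (!is.null(x$confusion)) {
    cat(sprintf("  held-out accuracy %.3f, MCC %.3f (n = %d)\n",
                accuracy(x$confusion), mcc(x$confusion),
                length(x$test_ids)))
  }
  invisible(x)
}

#' @export
tidy.strain_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "log(score)"),
    estimate = c(x$beta0, x$beta1),
    std.error = x$se
  )
}

#' @export
glance.strain_model <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$train_ids),
    n_test = length(x$test_ids),
    accuracy = if (is.null(x$confusion)) NA_real_ else accuracy(x$confusion),
    mcc = if (is.null(x$confusion)) NA_real_ else mcc(x$confusion),
    separation = x$separation
  )
}

# Newton / IRLS fit of a Bernoulli GLM with optional ridge penalty on
# all coefficients; shared by the strain classifier and the penalized
# fallback of the incidence GLM.
logistic_newton <- function(X, y, ridge = 0, tol = 1e-8, maxit = 100) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  H <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(X, y - p)) - ridge * beta
    H <- crossprod(X, X * w) + diag(ridge, ncol(X))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged, hessian = H)
}

log_likelihood_logistic <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

as_single_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1) {
      stop("expected a single reference sequence.", call. = FALSE)
    }
    x <- x[[1]]
  }
  if (is.character(x)) {
    if (length(x) != 1) {
      stop("expected a single reference sequence.", call. = FALSE)
    }
    x <- Biostrings::DNAString(x)
  }
  stopifnot(inherits(x, "DNAString"))
  x
}
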