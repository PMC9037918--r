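#' Average replicate crossing points with a consistency rule
#'
#' Three replicate runs per marker are averaged when they are
#' consistent. With two or more present replicates whose spread
#' (max - min) is within `max_spread` cycles, the arithmetic mean is
#' reported (`status = "ok"`). A spread beyond `max_spread` flags the
#' marker `"inconsistent"` and yields no Cp. A single present replicate
#' is used as-is (`"single"`); all-missing replicates are
#' `"undetected"`. Missing amplification must be encoded as `NA`, never
#' as `Cp = 0`.
#'
#' @param cp Long tibble `sample_id`, `marker`, `rep1`, `rep2`, `rep3`
#'   (as written by [simulate_qpcr()]).
#' @param max_spread Maximum allowed replicate spread in cycles
#'   (default 1.0).
#' @return A tibble `sample_id`, `marker`, `cp` (`NA` unless status is
#'   `"ok"` or `"single"`), `status`.
#' @export
average_cp <- function(cp, max_spread = 1) {
  reps <- as.matrix(cp[c("rep1", "rep2", "rep3")])
  if (any(reps <= 0, na.rm = TRUE)) {
    stop("Cp values must be positive when present (missing = NA).",
         call. = FALSE)
  }
  n_present <- rowSums(!is.na(reps))
  spread <- apply(reps, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else max(r) - min(r)
  })
  status <- dplyr::case_when(
    n_present == 0 ~ "undetected",
    n_present == 1 ~ "single",
    spread <= max_spread ~ "ok",
    TRUE ~ "inconsistent"
  )
  mean_cp <- rowMeans(reps, na.rm = TRUE)
  tibble::tibble(
    sample_id = cp$sample_id,
    marker = cp$marker,
    cp = ifelse(status %in% c("ok", "single"), mean_cp, NA_real_),
    status = status
  )
}

#' Relative symbiont density from a Cp difference
#'
#' `density = 2 ^ (cp_host - cp_target)`: more target DNA means an
#' earlier (lower) target crossing point and hence a higher density.
#' The exponent direction is configurable for labs that report the
#' opposite convention.
#'
#' @param cp_host,cp_target Averaged crossing points (vectorized; `NA`
#'   propagates as an absent density).
#' @param direction `"host_minus_target"` (default) or
#'   `"target_minus_host"`.
#' @return Relative densities (numeric, `NA` where either Cp is absent).
#' @export
relative_density <- function(cp_host, cp_target,
                             direction = c("host_minus_target",
                                           "target_minus_host")) {
  direction <- match.arg(direction)
  d <- if (direction == "host_minus_target") cp_host - cp_target
       else cp_target - cp_host
  2^d
}

#' Call infection status from averaged crossing points
#'
#' A strain is present iff its marker amplified (status `"ok"` or
#' `"single"`) with an averaged Cp at or below `max_cp`. Samples whose
#' host ITS2 marker did not amplify fail the species/DNA check and are
#' excluded (listed in the `excluded` attribute with a reason).
#'
#' @param averaged Output of [average_cp()] containing markers `ITS2`,
#'   `wAlbA`, `wAlbB` per sample.
#' @param max_cp Presence cutoff in cycles (default 35).
#' @return A tibble `sample_id`, `status` (`uninfected`, `A_only`,
#'   `B_only`, `AB`), `density_a`, `density_b` (present iff the strain
#'   is detected); attribute `excluded` is a tibble `sample_id`,
#'   `reason`.
#' @export
call_infection <- function(averaged, max_cp = 35) {
  wide <- averaged |>
    dplyr::select("sample_id", "marker", "cp") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "cp")
  for (m in c("ITS2", "wAlbA", "wAlbB")) {
    if (!m %in% names(wide)) wide[[m]] <- NA_real_
  }
  bad_host <- is.na(wide$ITS2)
  excluded <- tibble::tibble(
    sample_id = wide$sample_id[bad_host],
    reason = "host ITS2 marker undetected"
  )
  wide <- wide[!bad_host, ]
  has_a <- !is.na(wide$wAlbA) & wide$wAlbA <= max_cp
  has_b <- !is.na(wide$wAlbB) & wide$wAlbB <= max_cp
  out <- tibble::tibble(
    sample_id = wide$sample_id,
    status = dplyr::case_when(
      has_a & has_b ~ "AB",
      has_a ~ "A_only",
      has_b ~ "B_only",
      TRUE ~ "uninfected"
    ),
    density_a = ifelse(has_a, relative_density(wide$ITS2, wide$wAlbA),
                       NA_real_),
    density_b = ifelse(has_b, relative_density(wide$ITS2, wide$wAlbB),
                       NA_real_)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Population-by-sex infection incidence table
#'
#' @param calls Infection calls from [call_infection()].
#' @param metadata Tibble `sample_id`, `population`, `sex`.
#' @return A tibble with one row per observed (population, sex) stratum:
#'   per-status percentages (`pct_a`, `pct_b`, `pct_ab`,
#'   `pct_uninfected`, rounded to 1 decimal) and the stratum size `n`.
#'   Empty strata are omitted. Class `wolb_incidence`.
#' @export
incidence_table <- function(calls, metadata) {
  df <- dplyr::inner_join(calls, metadata, by = "sample_id")
  if (nrow(df) < nrow(calls)) {
    warning(nrow(calls) - nrow(df), " call(s) without metadata dropped.",
            call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$population, .data$sex) |>
    dplyr::summarise(
      pct_a = round(100 * mean(.data$status == "A_only"), 1),
      pct_b = round(100 * mean(.data$status == "B_only"), 1),
      pct_ab = round(100 * mean(.data$status == "AB"), 1),
      pct_uninfected = round(100 * mean(.data$status == "uninfected"), 1),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("wolb_incidence", class(out))
  out
}

#' Stacked-bar plot of infection incidence
#'
#' @param object A `wolb_incidence` tibble from [incidence_table()].
#' @param ... Unused.
#' @return A ggplot of per-stratum status percentages.
#' @export
autoplot.wolb_incidence <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = "status", values_to = "pct",
                        names_prefix = "pct_")
  long$status <- factor(long$status,
                        levels = c("ab", "b", "a", "uninfected"),
                        labels = c("wAlbA+wAlbB", "wAlbB only", "wAlbA only",
                                   "uninfected"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$sex, y = .data$pct,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = NULL, y = "% of individuals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio test for a sex-by-population interaction in
#' superinfection incidence
#'
#' Restricts to wAlbB-single and superinfected individuals, keeps
#' populations with more than `min_per_sex` such individuals in each
#' sex, and fits binomial (logit) GLMs of superinfection on
#' `sex * population` versus `sex + population`. The interaction is
#' tested by the likelihood-ratio chi-square. Under separation both
#' models are refit with a lightly ridge-penalized likelihood and the
#' result is flagged.
#'
#' @param calls Infection calls from [call_infection()].
#' @param metadata Tibble `sample_id`, `population`, `sex`.
#' @param min_per_sex A population is analysed only if both sexes have
#'   more than this many B/AB individuals (default 5).
#' @return A one-row tibble `statistic`, `df`, `p_value`, `n`,
#'   `n_populations`, `method` (`"glm"` or `"penalized"`).
#' @export
fit_incidence_glm <- function(calls, metadata, min_per_sex = 5) {
  df <- dplyr::inner_join(calls, metadata, by = "sample_id") |>
    dplyr::filter(.data$status %in% c("B_only", "AB"))
  keep_pops <- df |>
    dplyr::count(.data$population, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L)
  sex_cols <- setdiff(names(keep_pops), "population")
  ok <- length(sex_cols) == 2 &
    apply(keep_pops[sex_cols], 1, function(r) all(r > min_per_sex))
  keep_pops <- keep_pops$population[ok]
  if (length(keep_pops) < 2) {
    stop("need >= 2 populations with more than ", min_per_sex,
         " B/AB individuals per sex.", call. = FALSE)
  }
  df <- df[df$population %in% keep_pops, ]
  df$y <- as.integer(df$status == "AB")
  df$sex <- factor(df$sex)
  df$population <- factor(df$population)

  full <- suppressWarnings(
    stats::glm(y ~ sex * population, family = stats::binomial(), data = df))
  add <- suppressWarnings(
    stats::glm(y ~ sex + population, family = stats::binomial(), data = df))
  separated <- !full$converged || any(abs(stats::coef(full)) > 15, na.rm = TRUE)

  if (!separated) {
    lrt <- stats::anova(add, full, test = "LRT")
    statistic <- max(lrt$Deviance[2], 0)  # guard tiny negative round-off
    dfree <- lrt$Df[2]
    p <- stats::pchisq(statistic, dfree, lower.tail = FALSE)
    method <- "glm"
  } else {
    Xf <- stats::model.matrix(~ sex * population, df)
    Xa <- stats::model.matrix(~ sex + population, df)
    ff <- logistic_newton(Xf, df$y, ridge = 1e-3)
    fa <- logistic_newton(Xa, df$y, ridge = 1e-3)
    statistic <- 2 * (log_likelihood_logistic(ff$beta, Xf, df$y) -
                        log_likelihood_logistic(fa$beta, Xa, df$y))
    dfree <- ncol(Xf) - ncol(Xa)
    p <- stats::pchisq(statistic, dfree, lower.tail = FALSE)
    method <- "penalized"
  }
  tibble::tibble(statistic = statistic, df = dfree, p_value = p,
                 n = nrow(df), n_populations = length(keep_pops),
                 method = method)
}

#' Contingency test of sex against single-vs-super infection
#'
#' Pearson chi-square without continuity correction; Fisher's exact
#' test is substituted whenever any expected cell count falls below 5,
#' and the method used is reported. A table with a zero margin is
#' degenerate and returns p = 1.
#'
#' @param counts A 2x2 matrix (rows = sexes, columns = infection
#'   classes, e.g. B_only / AB) of non-negative counts.
#' @return A one-row tibble `statistic` (`NA` for the exact test),
#'   `p_value`, `method`, `degenerate`.
#' @export
sex_by_infection_test <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2, 2)) || any(m < 0)) {
    stop("counts must be a non-negative 2x2 matrix.", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(m)
    tibble::tibble(statistic = NA_real_, p_value = ft$p.value,
                   method = "fisher", degenerate = FALSE)
  } else {
    ct <- stats::chisq.test(m, correct = FALSE)
    tibble::tibble(statistic = unname(ct$statistic),
                   p_value = ct$p.value,
                   method = "chisq", degenerate = FALSE)
  }
}

#' Two-way ANOVA of log density across sex and population
#'
#' Densities are log10-transformed for normality and analysed with a
#' sex-by-population ANOVA using Type II sums of squares (appropriate
#' for unbalanced field data). Empty sex-by-population cells drop the
#' interaction (additive model, with a warning); a single observed sex
#' drops the sex term and flags it.
#'
#' @param data Tibble with columns `density` (> 0), `population`, `sex`
#'   — typically superinfected individuals for one strain.
#' @return A tibble `term`, `sumsq`, `df`, `statistic`, `p_value`, with
#'   attributes `model` (`"interaction"`, `"additive"` or `"no_sex"`)
#'   and `df_residual`.
#' @export
density_anova <- function(data) {
  df <- data[!is.na(data$density), ]
  if (any(df$density <= 0)) stop("densities must be positive.", call. = FALSE)
  df$logd <- log10(df$density)
  df$population <- factor(df$population)
  df$sex <- factor(df$sex)
  if (nlevels(df$population) < 2) {
    stop("need >= 2 populations.", call. = FALSE)
  }
  if (nlevels(df$sex) < 2) {
    fit <- stats::lm(logd ~ population, data = df)
    model <- "no_sex"
  } else if (any(table(df$sex, df$population) == 0)) {
    warning("empty sex-by-population cells; dropping the interaction.",
            call. = FALSE)
    fit <- stats::lm(logd ~ sex + population, data = df)
    model <- "additive"
  } else {
    fit <- stats::lm(logd ~ sex * population, data = df)
    model <- "interaction"
  }
  aov2 <- car::Anova(fit, type = 2)
  terms <- rownames(aov2)
  keep <- terms != "Residuals"
  out <- tibble::tibble(
    term = terms[keep],
    sumsq = aov2$`Sum Sq`[keep],
    df = aov2$Df[keep],
    statistic = aov2$`F value`[keep],
    p_value = aov2$`Pr(>F)`[keep]
  )
  attr(out, "model") <- model
  attr(out, "df_residual") <- aov2$Df[!keep]
  out
}

#' Association between wAlbA and wAlbB densities in superinfected hosts
#'
#' Pearson correlation and least-squares regression of log10 wAlbB
#' density on log10 wAlbA density. Groups with fewer than `min_n`
#' individuals are skipped with a reason, matching the rule that
#' correlations are only computed where at least `min_n` individuals
#' are available.
#'
#' @param data Tibble with `density_a` and `density_b` (both > 0) for
#'   one stratum (e.g. one population and sex).
#' @param min_n Minimum sample size (default 10).
#' @return A one-row tibble `n`, `r`, `r_p_value`, `slope`,
#'   `intercept`, `slope_p_value`, `skipped`, `reason`.
#' @export
density_association <- function(data, min_n = 10) {
  df <- data[!is.na(data$density_a) & !is.na(data$density_b), ]
  skip_row <- function(reason) {
    tibble::tibble(n = nrow(df), r = NA_real_, r_p_value = NA_real_,
                   slope = NA_real_, intercept = NA_real_,
                   slope_p_value = NA_real_, skipped = TRUE, reason = reason)
  }
  if (nrow(df) < min_n) {
    return(skip_row(sprintf("n = %d below minimum %d", nrow(df), min_n)))
  }
  la <- log10(df$density_a)
  lb <- log10(df$density_b)
  if (stats::var(la) == 0 || stats::var(lb) == 0) {
    return(skip_row("zero variance in log density"))
  }
  ct <- stats::cor.test(la, lb, method = "pearson")
  fit <- stats::lm(lb ~ la)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  tibble::tibble(
    n = nrow(df),
    r = unname(ct$estimate),
    r_p_value = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_p_value = sm$coefficients[2, 4],
    skipped = FALSE, reason = NA_character_
  )
}

#' Scatter plot of paired log densities with the fitted regression
#'
#' @param data Tibble with `density_a`, `density_b`.
#' @return A ggplot of log10 densities with a least-squares line.
#' @export
plot_density_association <- function(data) {
  df <- data[!is.na(data$density_a) & !is.na(data$density_b), ]
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$density_a),
                                   y = log10(.data$density_b))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(log[10] ~ "wAlbA density"),
                  y = expression(log[10] ~ "wAlbB density")) +
    ggplot2::theme_minimal()
}
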