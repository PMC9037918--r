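#' Parameters for the sequencing-depth simulator
#'
#' Describes a cohort of female and male mosquitoes sequenced over a set
#' of genomic features (100 kbp regions or ddRAD tags). Depths are
#' negative-binomially distributed around a base mean; at sex-linked
#' regions the male mean is multiplied by `male_depth_ratio` (0.5
#' emulates a hemizygous region). Sequencing batches contribute a shared
#' multiplicative log-normal effect, and every sample additionally gets
#' its own log-normal library-size factor. Control tags are never
#' sex-linked and support control-tag depth normalisation.
#'
#' @param n_females,n_males Sample counts per sex.
#' @param n_regions Number of autosomal/region features.
#' @param n_sex_regions How many of those regions are sex-linked
#'   (`<= n_regions`).
#' @param base_mean_depth Mean read depth at an unaffected feature.
#' @param male_depth_ratio Multiplier applied to the male mean at
#'   sex-linked regions (> 0; 1 means no sex signal).
#' @param dispersion Negative-binomial size parameter (> 0; smaller is
#'   more overdispersed).
#' @param n_batches Number of sequencing batches (assigned round-robin).
#' @param batch_effect_sd Standard deviation, on the natural-log scale,
#'   of the per-batch multiplicative effect.
#' @param sample_effect_sd Standard deviation (natural-log scale) of the
#'   per-sample library-size factor.
#' @param n_control_tags Number of negative-control tags (ratio exactly 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param region_seed Seed controlling *which* regions are sex-linked
#'   (the simulated genome). Defaults to `seed`; fix it while varying
#'   `seed` to draw independent cohorts from the same genome, as needed
#'   for train/test splits.
#' @return A `sim_depth_params` list.
#' @export
sim_depth_params <- function(n_females = 40, n_males = 40,
                             n_regions = 1000, n_sex_regions = 50,
                             base_mean_depth = 100, male_depth_ratio = 0.5,
                             dispersion = 5, n_batches = 2,
                             batch_effect_sd = 0.2, sample_effect_sd = 0.2,
                             n_control_tags = 20, seed = 1L,
                             region_seed = seed) {
  p <- list(n_females = n_females, n_males = n_males, n_regions = n_regions,
            n_sex_regions = n_sex_regions, base_mean_depth = base_mean_depth,
            male_depth_ratio = male_depth_ratio, dispersion = dispersion,
            n_batches = n_batches, batch_effect_sd = batch_effect_sd,
            sample_effect_sd = sample_effect_sd,
            n_control_tags = n_control_tags, seed = as.integer(seed),
            region_seed = as.integer(region_seed))
  if (p$n_females < 0 || p$n_males < 0 || p$n_regions < 1 ||
      p$n_sex_regions < 0 || p$n_sex_regions > p$n_regions) {
    stop("invalid counts: need n_sex_regions <= n_regions and non-negative sizes.",
         call. = FALSE)
  }
  if (p$base_mean_depth <= 0 || p$male_depth_ratio <= 0 || p$dispersion <= 0) {
    stop("base_mean_depth, male_depth_ratio and dispersion must be positive.",
         call. = FALSE)
  }
  if (p$n_batches < 1 || p$batch_effect_sd < 0 || p$sample_effect_sd < 0 ||
      p$n_control_tags < 0) {
    stop("invalid batch/control-tag parameters.", call. = FALSE)
  }
  structure(p, class = "sim_depth_params")
}

#' Simulate a raw depth matrix with planted sex-linked regions
#'
#' Draws `depth[i, j] ~ NegBinom(mean = base * ratio(sex_i, region_j) *
#' batch_i * lib_i, size = dispersion)`. Which regions are sex-linked is
#' chosen uniformly at random under the same seed, so the truth tables
#' are reproducible alongside the counts.
#'
#' @param params A [sim_depth_params()] object.
#' @return A list with three tibbles:
#' \describe{
#'   \item{depths}{wide table: `sample_id`, `batch`, then one column of
#'     raw counts per feature.}
#'   \item{features}{`feature_id`, `kind` (`region_100kbp` or
#'     `control_tag`), `sex_linked` flag.}
#'   \item{truth}{`sample_id`, `sex` (`female`/`male`).}
#' }
#' @export
simulate_depth_matrix <- function(params) {
  stopifnot(inherits(params, "sim_depth_params"))
  p <- params
  sex_linked_regions <- withr::with_seed(p$region_seed, {
    sort(sample.int(p$n_regions, p$n_sex_regions))
  })
  withr::with_seed(p$seed, {
    n <- p$n_females + p$n_males
    sample_id <- sprintf("S%04d", seq_len(n))
    sex <- rep(c("female", "male"), c(p$n_females, p$n_males))
    batch <- sprintf("b%d", rep_len(seq_len(p$n_batches), n))

    region_ids <- sprintf("R%04d", seq_len(p$n_regions))
    control_ids <- if (p$n_control_tags > 0) {
      sprintf("C%03d", seq_len(p$n_control_tags))
    } else character()
    features <- tibble::tibble(
      feature_id = c(region_ids, control_ids),
      kind = rep(c("region_100kbp", "control_tag"),
                 c(p$n_regions, p$n_control_tags)),
      sex_linked = c(seq_len(p$n_regions) %in% sex_linked_regions,
                     rep(FALSE, p$n_control_tags))
    )

    batch_fac <- exp(stats::rnorm(p$n_batches, 0, p$batch_effect_sd))
    lib_fac <- exp(stats::rnorm(n, 0, p$sample_effect_sd))
    scale_i <- batch_fac[rep_len(seq_len(p$n_batches), n)] * lib_fac

    ratio <- matrix(1, n, nrow(features))
    male <- sex == "male"
    ratio[male, features$sex_linked] <- p$male_depth_ratio

    mu <- p$base_mean_depth * scale_i * ratio
    depths <- matrix(
      stats::rnbinom(length(mu), size = p$dispersion, mu = mu),
      nrow = n
    )
    colnames(depths) <- features$feature_id

    list(
      depths = dplyr::bind_cols(
        tibble::tibble(sample_id = sample_id, batch = batch),
        tibble::as_tibble(depths)
      ),
      features = features,
      truth = tibble::tibble(sample_id = sample_id, sex = sex)
    )
  })
}

#' Parameters for the diagnostic-allele count simulator
#'
#' Emulates per-sample counts of wAlbA-diagnostic allele observations at
#' diagnostic SNP sites. Superinfected (AB) samples draw wAlbA
#' observations as `Binomial(n_sites, super_alpha_fraction)`; samples
#' infected with wAlbB only draw spurious wAlbA observations at
#' `error_rate`.
#'
#' @param n_super,n_single_b Sample counts for the two classes.
#' @param sites_per_sample_mean Mean number of allelic observations per
#'   sample (Poisson-distributed).
#' @param super_alpha_fraction Expected wAlbA-allele fraction in
#'   superinfected samples, in (0, 1).
#' @param error_rate Spurious wAlbA observation rate in wAlbB-only
#'   samples; must satisfy `0 <= error_rate < super_alpha_fraction < 1`.
#' @param seed Integer seed.
#' @return A `sim_strain_params` list.
#' @export
sim_strain_params <- function(n_super = 200, n_single_b = 200,
                              sites_per_sample_mean = 100,
                              super_alpha_fraction = 0.3,
                              error_rate = 0.01, seed = 1L) {
  p <- list(n_super = n_super, n_single_b = n_single_b,
            sites_per_sample_mean = sites_per_sample_mean,
            super_alpha_fraction = super_alpha_fraction,
            error_rate = error_rate, seed = as.integer(seed))
  if (p$n_super < 0 || p$n_single_b < 0 || p$sites_per_sample_mean <= 0) {
    stop("invalid sample/site counts.", call. = FALSE)
  }
  if (!(p$error_rate >= 0 && p$error_rate < p$super_alpha_fraction &&
        p$super_alpha_fraction < 1)) {
    stop("need 0 <= error_rate < super_alpha_fraction < 1.", call. = FALSE)
  }
  structure(p, class = "sim_strain_params")
}

#' Simulate wAlbA/wAlbB allele-observation counts
#'
#' @param params A [sim_strain_params()] object.
#' @return A list with `counts` (tibble `sample_id`, `a_count`,
#'   `total_count`) and `truth` (tibble `sample_id`, `label` in
#'   `{"AB", "B"}`).
#' @export
simulate_allele_counts <- function(params) {
  stopifnot(inherits(params, "sim_strain_params"))
  p <- params
  withr::with_seed(p$seed, {
    n <- p$n_super + p$n_single_b
    sample_id <- sprintf("W%04d", seq_len(n))
    label <- rep(c("AB", "B"), c(p$n_super, p$n_single_b))
    total <- stats::rpois(n, p$sites_per_sample_mean)
    prob <- ifelse(label == "AB", p$super_alpha_fraction, p$error_rate)
    a <- stats::rbinom(n, size = total, prob = prob)
    list(
      counts = tibble::tibble(sample_id = sample_id, a_count = a,
                              total_count = total),
      truth = tibble::tibble(sample_id = sample_id, label = label)
    )
  })
}

#' Parameters for the COI haplotype alignment simulator
#'
#' Haplotypes are generated by mutating a random root sequence under a
#' two-parameter substitution scheme: each haplotype receives a
#' `Poisson(seq_length * mutation_rate)` number of substitutions (at
#' least one for non-root haplotypes so haplotypes are distinct), each
#' being a transition with probability `kappa / (kappa + 1)` where
#' `kappa` is the transition:transversion ratio.
#'
#' @param n_haplotypes Number of distinct haplotypes.
#' @param seq_length Alignment length in bp.
#' @param mutation_rate Expected substitutions per site separating a
#'   haplotype from the root.
#' @param transition_transversion_ratio Transition:transversion ratio
#'   (kappa).
#' @param n_individuals Number of individuals to assign to haplotypes
#'   (multinomially, uniform weights, every haplotype gets at least one
#'   individual when `n_individuals >= n_haplotypes`).
#' @param seed Integer seed.
#' @return A `sim_haplo_params` list.
#' @export
sim_haplo_params <- function(n_haplotypes = 10, seq_length = 623,
                             mutation_rate = 0.01,
                             transition_transversion_ratio = 4,
                             n_individuals = 50, seed = 1L) {
  p <- list(n_haplotypes = n_haplotypes, seq_length = as.integer(seq_length),
            mutation_rate = mutation_rate,
            transition_transversion_ratio = transition_transversion_ratio,
            n_individuals = n_individuals, seed = as.integer(seed))
  if (p$seq_length <= 0) stop("seq_length must be > 0.", call. = FALSE)
  if (p$n_haplotypes < 1 || p$n_individuals < 1 || p$mutation_rate < 0 ||
      p$transition_transversion_ratio <= 0) {
    stop("invalid haplotype simulation parameters.", call. = FALSE)
  }
  structure(p, class = "sim_haplo_params")
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate an aligned set of COI sequences with known haplotypes
#'
#' @param params A [sim_haplo_params()] object.
#' @return A list with `alignment` (tibble `id`, `seq`: equal-length
#'   gap-free ACGT strings, one row per individual) and `truth` (tibble
#'   `id`, `haplotype` giving the planted haplotype index of each
#'   individual as `"H<k>"`).
#' @export
simulate_coi_alignment <- function(params) {
  stopifnot(inherits(params, "sim_haplo_params"))
  p <- params
  bases <- c("A", "C", "G", "T")
  withr::with_seed(p$seed, {
    root <- sample(bases, p$seq_length, replace = TRUE)
    p_ts <- p$transition_transversion_ratio /
      (p$transition_transversion_ratio + 1)
    haplos <- vector("list", p$n_haplotypes)
    haplos[[1]] <- root
    k <- 2
    guard <- 0
    while (k <= p$n_haplotypes) {
      guard <- guard + 1
      if (guard > 1000 * p$n_haplotypes) {
        stop("could not generate distinct haplotypes; raise mutation_rate.",
             call. = FALSE)
      }
      h <- root
      n_mut <- max(1L, stats::rpois(1, p$seq_length * p$mutation_rate))
      n_mut <- min(n_mut, p$seq_length)
      pos <- sample.int(p$seq_length, n_mut)
      for (j in pos) {
        if (stats::runif(1) < p_ts) {
          h[j] <- transition_of[[h[j]]]
        } else {
          tv <- setdiff(bases, c(h[j], transition_of[[h[j]]]))
          h[j] <- sample(tv, 1)
        }
      }
      if (!any(vapply(haplos[seq_len(k - 1)],
                      function(x) identical(x, h), logical(1)))) {
        haplos[[k]] <- h
        k <- k + 1
      }
    }
    # every haplotype observed at least once, remainder uniform
    if (p$n_individuals >= p$n_haplotypes) {
      assign <- c(seq_len(p$n_haplotypes),
                  sample.int(p$n_haplotypes,
                             p$n_individuals - p$n_haplotypes,
                             replace = TRUE))
    } else {
      assign <- sample.int(p$n_haplotypes, p$n_individuals)
    }
    id <- sprintf("ind%03d", seq_len(p$n_individuals))
    seqs <- vapply(assign, function(a) paste(haplos[[a]], collapse = ""),
                   character(1))
    list(
      alignment = tibble::tibble(id = id, seq = seqs),
      truth = tibble::tibble(id = id, haplotype = sprintf("H%d", assign))
    )
  })
}

#' Parameters for the qPCR crossing-point simulator
#'
#' Emulates a LightCycler run of three markers per sample: the host ITS2
#' marker and the wAlbA/wAlbB strain markers, three replicates each. An
#' infected strain's true crossing point is
#' `Cp_host - log2(true density)`; replicates add Gaussian noise of sd
#' `cp_sd`. Markers of absent strains never amplify and are emitted as
#' missing (`NA`) sentinels, never as `Cp = 0`.
#'
#' @param n_samples Number of samples.
#' @param host_cp_mean Mean host-marker crossing point (cycles).
#' @param cp_sd Replicate noise sd (cycles, `>= 0`).
#' @param density_a_log2_mean,density_b_log2_mean Mean log2 relative
#'   density of each strain when present.
#' @param density_log2_sd Between-sample sd of log2 density (adds the
#'   biological density variation the density statistics operate on).
#' @param status_probs Probabilities over statuses
#'   `c(uninfected, A_only, B_only, AB)`; must sum to 1.
#' @param seed Integer seed.
#' @return A `sim_qpcr_params` list.
#' @export
sim_qpcr_params <- function(n_samples = 100, host_cp_mean = 20,
                            cp_sd = 0.3,
                            density_a_log2_mean = -2,
                            density_b_log2_mean = 2,
                            density_log2_sd = 1,
                            status_probs = c(0.02, 0.01, 0.17, 0.8),
                            seed = 1L) {
  p <- list(n_samples = n_samples, host_cp_mean = host_cp_mean,
            cp_sd = cp_sd, density_a_log2_mean = density_a_log2_mean,
            density_b_log2_mean = density_b_log2_mean,
            density_log2_sd = density_log2_sd,
            status_probs = status_probs, seed = as.integer(seed))
  if (p$cp_sd < 0) stop("cp_sd must be >= 0.", call. = FALSE)
  if (length(p$status_probs) != 4 ||
      abs(sum(p$status_probs) - 1) > 1e-8 || any(p$status_probs < 0)) {
    stop("status_probs must be a 4-vector of probabilities summing to 1.",
         call. = FALSE)
  }
  if (p$n_samples < 1 || p$host_cp_mean <= 0 || p$density_log2_sd < 0) {
    stop("invalid qPCR simulation parameters.", call. = FALSE)
  }
  structure(p, class = "sim_qpcr_params")
}

#' Simulate replicate qPCR crossing-point records
#'
#' @param params A [sim_qpcr_params()] object.
#' @return A list with `cp` (tibble `sample_id`, `marker` in
#'   `{"ITS2", "wAlbA", "wAlbB"}`, `rep1`..`rep3`; `NA` = no
#'   amplification) and `truth` (tibble `sample_id`, `status`,
#'   `density_a`, `density_b`; densities `NA` when the strain is absent).
#' @export
simulate_qpcr <- function(params) {
  stopifnot(inherits(params, "sim_qpcr_params"))
  p <- params
  statuses <- c("uninfected", "A_only", "B_only", "AB")
  withr::with_seed(p$seed, {
    n <- p$n_samples
    sample_id <- sprintf("Q%04d", seq_len(n))
    status <- sample(statuses, n, replace = TRUE, prob = p$status_probs)
    has_a <- status %in% c("A_only", "AB")
    has_b <- status %in% c("B_only", "AB")
    dens_a <- ifelse(
      has_a, 2^stats::rnorm(n, p$density_a_log2_mean, p$density_log2_sd),
      NA_real_)
    dens_b <- ifelse(
      has_b, 2^stats::rnorm(n, p$density_b_log2_mean, p$density_log2_sd),
      NA_real_)
    cp_host <- rep(p$host_cp_mean, n)

    reps_for <- function(true_cp) {
      t(vapply(true_cp, function(cc) {
        if (is.na(cc)) rep(NA_real_, 3) else cc + stats::rnorm(3, 0, p$cp_sd)
      }, numeric(3)))
    }
    cp_a_true <- ifelse(has_a, cp_host - log2(dens_a), NA_real_)
    cp_b_true <- ifelse(has_b, cp_host - log2(dens_b), NA_real_)
    host_reps <- reps_for(cp_host)
    a_reps <- reps_for(cp_a_true)
    b_reps <- reps_for(cp_b_true)

    cp <- tibble::tibble(
      sample_id = rep(sample_id, each = 3),
      marker = rep(c("ITS2", "wAlbA", "wAlbB"), times = n),
      rep1 = as.vector(rbind(host_reps[, 1], a_reps[, 1], b_reps[, 1])),
      rep2 = as.vector(rbind(host_reps[, 2], a_reps[, 2], b_reps[, 2])),
      rep3 = as.vector(rbind(host_reps[, 3], a_reps[, 3], b_reps[, 3]))
    )
    list(
      cp = cp,
      truth = tibble::tibble(sample_id = sample_id, status = status,
                             density_a = dens_a, density_b = dens_b)
    )
  })
}
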