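random_ref <- function(n, seed) {
  set.seed(seed)
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

test_that("identical references yield no diagnostic sites", {
  r <- paste(random_ref(500, 1), collapse = "")
  sites <- discover_diagnostic_sites(r, r, read_len = 100, step = 25)
  expect_equal(nrow(sites), 0)
})

test_that("planted substitutions are recovered; repeats are excluded", {
  bases <- c("A", "C", "G", "T")
  ref_b <- random_ref(2000, 42)
  ref_b[1501:1800] <- ref_b[201:500]      # 300 bp duplicated block
  ref_a <- ref_b
  plant <- c(50, 700, 1000, 1200, 1950)   # unique context
  for (p in plant) ref_a[p] <- setdiff(bases, ref_a[p])[1]
  ref_a[350] <- setdiff(bases, ref_a[350])[1]  # inside the repeat

  sites <- discover_diagnostic_sites(paste(ref_a, collapse = ""),
                                     paste(ref_b, collapse = ""))
  expect_equal(sites$position, sort(plant) - 1L)  # 0-based
  expect_false(349 %in% sites$position)
  # direct column comparison confirms the alleles
  expect_equal(sites$allele_a, ref_a[sort(plant)])
  expect_equal(sites$allele_b, ref_b[sort(plant)])
})

test_that("allele counting apportions observations by diagnostic allele", {
  sites <- tibble::tibble(site_id = c("s1", "s2"), position = c(10L, 20L),
                          allele_a = c("A", "C"), allele_b = c("G", "T"))
  obs <- tibble::tibble(
    sample_id = rep("x", 4),
    position = c(10L, 10L, 20L, 20L),
    base = c("A", "G", "T", "C"),
    count = c(30L, 70L, 50L, 10L)
  )
  counts <- count_alleles(obs, sites)
  expect_equal(counts$a_count, 40)     # 30 A-at-s1 + 10 C-at-s2
  expect_equal(counts$total_count, 160)

  # off-site and third-allele observations are dropped and logged
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(
    sample_id = "x", position = c(99L, 10L), base = c("A", "C"),
    count = c(5L, 7L)))
  counts2 <- count_alleles(obs2, sites)
  expect_equal(counts2$total_count, 160)
  expect_equal(attr(counts2, "dropped")$dropped, 12)
})

test_that("generator truth round-trips through count_alleles semantics", {
  sim <- simulate_allele_counts(sim_strain_params(
    n_super = 20, n_single_b = 20, seed = 12))
  # rebuild a long observation table from the counts at one fake site
  # per observation class and verify count_alleles recovers the table
  sites <- tibble::tibble(site_id = "s1", position = 0L,
                          allele_a = "A", allele_b = "G")
  obs <- dplyr::bind_rows(
    tibble::tibble(sample_id = sim$counts$sample_id, position = 0L,
                   base = "A", count = sim$counts$a_count),
    tibble::tibble(sample_id = sim$counts$sample_id, position = 0L,
                   base = "G",
                   count = sim$counts$total_count - sim$counts$a_count)
  )
  back <- count_alleles(obs, sites)
  back <- back[match(sim$counts$sample_id, back$sample_id), ]
  expect_equal(back$a_count, sim$counts$a_count)
  expect_equal(back$total_count, sim$counts$total_count)
})

test_that("minimum-observation filter is strict at the boundary", {
  counts <- tibble::tibble(sample_id = c("a", "b", "c"),
                           a_count = c(1, 2, 3),
                           total_count = c(9, 10, 11))
  kept <- filter_min_observations(counts, min_total = 10)
  expect_equal(kept$sample_id, c("b", "c"))   # 10 kept: "fewer than" strict
  expect_equal(attr(kept, "removed"), "a")
  expect_equal(nrow(filter_min_observations(counts, 0)), 3)
})

test_that("Laplace-smoothed score matches its closed form", {
  expect_equal(compute_score(0, 10), 1 / 12)
  expect_equal(compute_score(10, 10), 11 / 12)
  expect_equal(compute_score(0, 0), 0.5)
  # symmetry: score(a, n) + score(n - a, n) = 1
  expect_equal(compute_score(3, 10) + compute_score(7, 10), 1)
  expect_error(compute_score(-1, 10))
  expect_error(compute_score(5, 10, pseudocount = 0))
})

test_that("logistic fit matches a grid-search likelihood maximum", {
  set.seed(7)
  n <- 20
  lab <- rep(c("AB", "B"), each = 10)
  # overlapping classes so the likelihood has an interior maximum
  sim_counts <- tibble::tibble(
    sample_id = sprintf("g%02d", 1:n),
    a_count = c(rbinom(10, 20, 0.3), rbinom(10, 20, 0.12)),
    total_count = 20
  )
  model <- train_strain_model(sim_counts, lab, test_fraction = 0, seed = 1)

  ll <- function(b0, b1) {
    s <- log(compute_score(sim_counts$a_count, sim_counts$total_count))
    eta <- b0 + b1 * s
    y <- as.integer(lab == "AB")
    sum(y * eta - log1p(exp(eta)))
  }
  # coarse-to-fine grid search around the fit
  grid <- expand.grid(b0 = seq(model$beta0 - 2, model$beta0 + 2, length = 81),
                      b1 = seq(model$beta1 - 2, model$beta1 + 2, length = 81))
  grid$ll <- mapply(ll, grid$b0, grid$b1)
  best <- grid[which.max(grid$ll), ]
  expect_gte(ll(model$beta0, model$beta1), best$ll - 1e-4)

  # and against the stats::glm maximum-likelihood fit
  s <- log(compute_score(sim_counts$a_count, sim_counts$total_count))
  ref <- glm(I(lab == "AB") ~ s, family = binomial())
  expect_equal(unname(c(model$beta0, model$beta1)), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("planted strain regime is classified accurately across seeds", {
  res <- lapply(1:10, function(s) run_strain_pipeline(seed = s))
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  b1 <- vapply(res, `[[`, numeric(1), "beta1")
  expect_gte(sum(acc >= 0.95), 9)
  expect_true(all(b1 > 0))
})

test_that("permuted labels perform at chance", {
  sim <- simulate_allele_counts(sim_strain_params(seed = 31))
  mccs <- vapply(1:20, function(r) {
    perm <- withr::with_seed(r, sample(nrow(sim$truth)))
    labels <- sim$truth
    labels$label <- labels$label[perm]
    m <- train_strain_model(sim$counts, labels, seed = r)
    mcc(m$confusion)
  }, numeric(1))
  # null MCC on an 80-sample test set: 95% band roughly +/- 2/sqrt(n)
  expect_lt(abs(mean(mccs)), 0.1)
  expect_gte(mean(abs(mccs) < 2 / sqrt(80)), 0.8)
})

test_that("prediction is monotone in score and handles empty counts", {
  sim <- simulate_allele_counts(sim_strain_params(seed = 41))
  model <- train_strain_model(sim$counts, sim$truth, seed = 1)
  counts <- tibble::tibble(sample_id = c("p1", "p2", "p3", "p0"),
                           a_count = c(0, 10, 40, 0),
                           total_count = c(50, 50, 50, 0))
  pred <- predict_strain(model, counts)
  expect_true(model$beta1 > 0)
  expect_true(all(diff(pred$p_ab[1:3]) > 0))
  # n = 0 sample: score 0.5, finite probability
  expect_equal(pred$score[4], 0.5)
  expect_equal(pred$p_ab[4],
               plogis(model$beta0 + model$beta1 * log(0.5)))
  # equal counts give identical outputs
  same <- predict_strain(model, tibble::tibble(
    sample_id = c("u", "v"), a_count = c(5, 5), total_count = c(30, 30)))
  expect_equal(same$p_ab[1], same$p_ab[2])
})

test_that("class imbalance pulls the uninformative-sample call to the prior", {
  # with AB prior -> 1 the predicted P(AB) at score 0.5 approaches 1
  sim <- simulate_allele_counts(sim_strain_params(
    n_super = 380, n_single_b = 20, seed = 51))
  model <- train_strain_model(sim$counts, sim$truth, seed = 1)
  p_uninformative <- plogis(model$beta0 + model$beta1 * log(0.5))
  expect_gt(p_uninformative, 0.5)
})

test_that("perfect separation falls back to a flagged penalized fit", {
  counts <- tibble::tibble(sample_id = sprintf("z%02d", 1:20),
                           a_count = rep(c(40, 0), each = 10),
                           total_count = 50)
  labels <- rep(c("AB", "B"), each = 10)
  model <- suppressWarnings(
    train_strain_model(counts, labels, test_fraction = 0.2, seed = 1))
  expect_true(model$separation)
  expect_true(is.finite(model$beta0) && is.finite(model$beta1))
  expect_gt(model$beta1, 0)
})
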