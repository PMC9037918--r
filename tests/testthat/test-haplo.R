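aln <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = sprintf("s%02d", seq_along(seqs)), seq = seqs)
}

test_that("trimming removes any column with gaps or ambiguity", {
  a <- aln("ACGTA", "AC-TA", "ACGTN")
  out <- trim_and_filter(a)
  expect_equal(attr(out, "retained_length"), 3)
  expect_equal(out$seq, c("ACT", "ACT", "ACT"))  # cols 3 (gap) and 5 (N) removed

  clean <- aln("ACGT", "ACGT")
  expect_equal(trim_and_filter(clean)$seq, clean$seq)
  expect_error(trim_and_filter(aln("--", "--")), "no alignment columns")
  expect_error(trim_and_filter(aln("ACG", "AC")), "equal length")
})

test_that("haplotype collapsing groups identical sequences in input order", {
  a <- aln("AAAA", "CCCC", "AAAA", "GGGG", "CCCC", "AAAA")
  hs <- collapse_haplotypes(a)
  expect_equal(hs$haplotype_id, c("H1", "H2", "H3"))
  expect_equal(hs$count, c(3L, 2L, 1L))
  expect_equal(sum(hs$count), nrow(a))

  # identical input sequences -> one haplotype
  same <- collapse_haplotypes(aln(rep("ACGT", 10)))
  expect_equal(nrow(same), 1)
  expect_equal(same$count, 10L)

  # permutation invariance of the partition
  perm <- a[c(4, 2, 6, 1, 3, 5), ]
  hs_perm <- collapse_haplotypes(perm)
  expect_setequal(
    vapply(hs$members, function(m) paste(sort(m), collapse = ","),
           character(1)),
    vapply(hs_perm$members, function(m) paste(sort(m), collapse = ","),
           character(1)))

  # population multiset carried through
  meta <- tibble::tibble(id = a$id,
                         population = c("X", "Y", "X", "Z", "Y", "X"))
  hs_pop <- collapse_haplotypes(a, meta)
  expect_equal(sort(hs_pop$populations[[1]]), c("X", "X", "X"))
})

test_that("K2P distance matches its closed form", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)

  # P = 0.1, Q = 0.05 on 20 sites: 2 transitions + 1 transversion
  s1 <- paste(rep("A", 20), collapse = "")
  s2 <- paste(c("G", "G", "C", rep("A", 17)), collapse = "")
  d <- k2p_distance(s1, s2)
  expect_equal(d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-10)

  # one transition in 623 sites: slightly above the p-distance
  t1 <- paste(rep("C", 623), collapse = "")
  t2 <- paste(c("T", rep("C", 622)), collapse = "")
  d1 <- k2p_distance(t1, t2)
  expect_gt(d1, 1 / 623)
  expect_equal(d1, 1 / 623, tolerance = 0.01)

  # saturation flagged as NA
  expect_warning(
    dna <- k2p_distance(paste(rep("A", 4), collapse = ""),
                        paste(rep("G", 4), collapse = "")),
    "undefined")
  expect_true(is.na(dna))
  expect_error(k2p_distance("ACG", "AC"), "equal length")
})

test_that("K2P >= p-distance and agrees to first order at small divergence", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (r in 1:20) {
    n <- 400
    a <- sample(bases, n, replace = TRUE)
    b <- a
    k <- rbinom(1, 3, 0.5) + 1
    pos <- sample(n, k)
    for (j in pos) b[j] <- sample(setdiff(bases, a[j]), 1)
    d <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    p_dist <- mean(a != b)
    expect_gte(d, p_dist - 1e-12)
    if (d < 0.01) expect_equal(d, p_dist, tolerance = 0.01)
  }
})

test_that("K2P matrix agrees with the reference K80 implementation", {
  sim <- simulate_coi_alignment(sim_haplo_params(
    n_haplotypes = 6, n_individuals = 6, mutation_rate = 0.02, seed = 14))
  dm <- k2p_matrix(sim$alignment)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(sim$alignment$seq),
                                                "")))
  rownames(bin) <- sim$alignment$id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(dm, ref[rownames(dm), colnames(dm)], tolerance = 1e-10)
})

test_that("NJ recovers additive trees exactly", {
  # hand-drawn 5-taxon tree: ((A:2,B:3):1,(C:2,D:4):2,E:5);
  # pairwise path lengths computed by hand from the drawing
  dm <- matrix(c(0,  5,  7,  9,  8,
                 5,  0,  8, 10,  9,
                 7,  8,  0,  6,  9,
                 9, 10,  6,  0, 11,
                 8,  9,  9, 11,  0), 5, 5,
               dimnames = list(c("A", "B", "C", "D", "E"),
                               c("A", "B", "C", "D", "E")))
  tree <- nj_tree(dm)
  expect_false(attr(tree, "clamped"))
  # exact recovery: the tree's path-length matrix equals the input
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)

  # random additive matrices, 6-8 taxa
  set.seed(37)
  for (r in 1:5) {
    ntip <- sample(6:8, 1)
    gen <- ape::rtree(ntip, br = function(n) runif(n, 0.5, 2))
    gen$tip.label <- paste0("t", seq_len(ntip))
    dmat <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(dmat)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dmat), colnames(dmat)],
                 dmat, tolerance = 1e-8)
  }
})

test_that("NJ matches exhaustive minimum-evolution on a 4-taxon toy", {
  # ultrametric toy: ((A,B),(C,D)) with clean separation
  dm <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"),
                               c("A", "B", "C", "D")))
  oracle <- min_evolution_4taxa(dm)
  tree <- nj_tree(dm)
  split <- nj_4taxon_split(tree)
  same <- setequal(split, oracle$split) ||
    setequal(split, setdiff(c("A", "B", "C", "D"), oracle$split))
  expect_true(same)

  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3 taxa")
  asym <- dm; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})

test_that("bootstrap support is high for well-separated clades", {
  # two clades of 3 haplotypes with 20 diagnostic sites between them
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  core <- sample(bases, 200, replace = TRUE)
  other <- core
  other[1:20] <- vapply(core[1:20],
                        function(b) sample(setdiff(bases, b), 1),
                        character(1))
  wiggle <- function(x, pos) {
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    paste(x, collapse = "")
  }
  a <- aln(wiggle(core, 30), wiggle(core, 40), wiggle(core, 50),
           wiggle(other, 60), wiggle(other, 70), wiggle(other, 80))
  bs <- bootstrap_support(a, n_reps = 200, seed = 2)
  expect_gte(max(bs$support$support_pct), 95)

  # one replicate: supports are 0 or 100
  bs1 <- bootstrap_support(a, n_reps = 1, seed = 3)
  expect_true(all(bs1$support$support_pct %in% c(0, 100)))

  # reproducibility
  bs2 <- bootstrap_support(a, n_reps = 20, seed = 5)
  bs3 <- bootstrap_support(a, n_reps = 20, seed = 5)
  expect_identical(bs2$support, bs3$support)
})

test_that("minimum spanning network connects chains and stars correctly", {
  # 3 haplotypes in a line: A -1- B -1- C; no A-C edge
  hs <- collapse_haplotypes(aln("AAAA", "AAAT", "AATT"))
  net <- build_network(hs)
  expect_equal(nrow(net), 2)
  expect_setequal(paste(net$from, net$to), c("H1 H2", "H2 H3"))
  expect_equal(net$steps, c(1L, 1L))

  # max_steps below the minimal difference disconnects the network
  far <- collapse_haplotypes(aln("AAAA", "TTTT"))
  net_far <- build_network(far, max_steps = 2)
  expect_equal(nrow(net_far), 0)
  expect_equal(max(attr(net_far, "nodes")$component), 2)

  # star phylogeny: hub has maximal degree
  hub <- "AAAAAAAAAA"
  spokes <- vapply(1:5, function(i) {
    x <- strsplit(hub, "")[[1]]
    x[i] <- "G"
    paste(x, collapse = "")
  }, character(1))
  star <- collapse_haplotypes(aln(hub, spokes))
  net_star <- build_network(star)
  deg <- table(c(net_star$from, net_star$to))
  expect_equal(names(deg)[which.max(deg)], "H1")
  expect_equal(unname(deg["H1"]), 5)

  # tie-equal alternative edges are retained: perfect square A-B-C-D
  sq <- collapse_haplotypes(aln("AAAA", "AAAT", "AATT", "AATA"))
  # H1-H2 1, H2-H3 1, H3-H4 1, H4-H1 1 (cycle of ties)
  net_sq <- build_network(sq)
  expect_equal(nrow(net_sq), 4)
})

test_that("alignment FASTA round-trips through files", {
  a <- aln("ACGTACGT", "ACGTACGA")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a, path)
  back <- read_alignment(path)
  expect_equal(back$seq, a$seq)
})
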