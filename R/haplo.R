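#' Read / write an aligned FASTA as a tibble
#'
#' @param path FASTA file path.
#' @return `read_alignment()` returns a tibble `id`, `seq` (uppercase);
#'   `write_alignment()` returns `path` invisibly.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(ss), seq = unname(toupper(as.character(ss))))
}

#' @rdname read_alignment
#' @param alignment Tibble `id`, `seq`.
#' @export
write_alignment <- function(alignment, path) {
  ss <- Biostrings::DNAStringSet(alignment$seq)
  names(ss) <- alignment$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

alignment_matrix <- function(alignment) {
  seqs <- toupper(alignment$seq)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences must be aligned (equal length).", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- alignment$id
  m
}

#' Remove alignment columns with gaps, Ns or ambiguity codes
#'
#' Positions containing any gap or missing/ambiguous base in any
#' sequence are eliminated for all sequences, so downstream distances
#' are computed over fully resolved columns only.
#'
#' @param alignment Tibble `id`, `seq` of equal-length sequences.
#' @return The filtered alignment tibble; attribute `retained_length`
#'   gives the number of surviving columns. Errors if no column
#'   survives.
#' @export
trim_and_filter <- function(alignment) {
  m <- alignment_matrix(alignment)
  ok_col <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(ok_col)) {
    stop("no alignment columns retained after filtering.", call. = FALSE)
  }
  m <- m[, ok_col, drop = FALSE]
  out <- tibble::tibble(id = alignment$id,
                        seq = unname(apply(m, 1, paste, collapse = "")))
  attr(out, "retained_length") <- sum(ok_col)
  out
}

#' Collapse aligned sequences into haplotypes
#'
#' Individuals with byte-identical sequences share a haplotype.
#' Haplotypes are numbered `H1`, `H2`, ... by first occurrence in input
#' order, the convention used for COI barcoding tables.
#'
#' @param alignment Filtered alignment tibble `id`, `seq`.
#' @param metadata Optional tibble `id`, `population`.
#' @return A `haplotype_set` tibble: `haplotype_id`, `count`,
#'   `populations` (list column of the member populations, multiset),
#'   `members` (list column of individual ids), `sequence`.
#' @export
collapse_haplotypes <- function(alignment, metadata = NULL) {
  seqs <- alignment$seq
  first_idx <- !duplicated(seqs)
  uniq <- seqs[first_idx]
  hap_of <- match(seqs, uniq)
  pops <- if (!is.null(metadata)) {
    as.character(metadata$population[match(alignment$id, metadata$id)])
  } else {
    rep(NA_character_, nrow(alignment))
  }
  out <- tibble::tibble(
    haplotype_id = sprintf("H%d", seq_along(uniq)),
    count = as.integer(tabulate(hap_of, nbins = length(uniq))),
    populations = lapply(seq_along(uniq), function(k) pops[hap_of == k]),
    members = lapply(seq_along(uniq), function(k) alignment$id[hap_of == k]),
    sequence = uniq
  )
  class(out) <- c("haplotype_set", class(out))
  out
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With `P` the proportion of transition differences and `Q` the
#' proportion of transversion differences,
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`.
#' When a logarithm argument is non-positive (saturated divergence) the
#' distance is undefined and returned as `NA` with a warning.
#'
#' @param seq1,seq2 Equal-length gap-free sequences (character
#'   strings).
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences must have equal length.", call. = FALSE)
  }
  k2p_from_chars(a, b)
}

k2p_from_chars <- function(a, b) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- a != b
  n <- length(a)
  if (n == 0) stop("zero-length sequences.", call. = FALSE)
  ts <- sum(diff & (purine[a] == purine[b]))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance undefined (log-domain violation); returning NA.",
            call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Pairwise K2P distance matrix
#'
#' @param alignment Tibble `id`, `seq` (or a `haplotype_set`, in which
#'   case haplotype ids label the matrix).
#' @return A symmetric labelled matrix of K2P distances with zero
#'   diagonal.
#' @export
k2p_matrix <- function(alignment) {
  if (inherits(alignment, "haplotype_set")) {
    ids <- alignment$haplotype_id
    seqs <- alignment$sequence
  } else {
    ids <- alignment$id
    seqs <- alignment$seq
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2p_from_chars(m[i, ], m[j, ])
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining on a symmetric distance matrix.
#' Negative branch lengths (possible on non-additive matrices) are
#' clamped to zero by default and flagged via the `clamped` attribute.
#'
#' @param dm Symmetric labelled distance matrix with >= 3 taxa.
#' @param allow_negative Keep negative branch lengths as estimated?
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm, allow_negative = FALSE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 taxa.", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric.", call. = FALSE)
  }
  if (anyNA(dm)) stop("distance matrix contains undefined entries.",
                      call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  clamped <- FALSE
  if (!allow_negative && any(tree$edge.length < 0)) {
    tree$edge.length[tree$edge.length < 0] <- 0
    clamped <- TRUE
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; a
#' K2P + NJ tree is rebuilt per replicate and each internal branch of
#' the original tree receives the percentage of replicates containing
#' its bipartition. Replicate distances that saturate (undefined K2P)
#' are capped at 0.75 substitutions/site so every replicate yields a
#' tree.
#'
#' @param alignment Tibble `id`, `seq` with >= 3 distinct sequences
#'   (typically one representative per haplotype).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A list: `tree` (the original NJ tree with `node.label` set
#'   to support percentages) and `support` (tibble `node`,
#'   `support_pct`).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1L) {
  m <- alignment_matrix(alignment)
  ids <- rownames(m)
  dist_of <- function(mat) {
    n <- nrow(mat)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- suppressWarnings(k2p_from_chars(mat[i, ], mat[j, ]))
        if (is.na(v)) v <- 0.75
        d[i, j] <- d[j, i] <- v
      }
    }
    d
  }
  orig <- nj_tree(dist_of(m))
  boot_trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(dist_of(m[, cols, drop = FALSE]))
    })
  })
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(orig, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  orig$node.label <- as.character(support)
  list(
    tree = orig,
    support = tibble::tibble(
      node = ape::Ntip(orig) + seq_along(support),
      support_pct = support
    )
  )
}

#' Minimum spanning haplotype network
#'
#' Connects haplotypes by Hamming distance (number of differing
#' nucleotide columns) using a minimum spanning network: all edges of a
#' minimum spanning tree plus every alternative edge of equal weight
#' that would join the same components, so equally parsimonious
#' connections are retained. Edges longer than `max_steps` mutation
#' steps are excluded, which can leave the network in several connected
#' components (reported).
#'
#' @param hs A `haplotype_set` from [collapse_haplotypes()].
#' @param max_steps Maximum mutational steps for a connection (default
#'   `Inf`, i.e. no cutoff).
#' @return A `haplo_network` tibble `from`, `to`, `steps` with
#'   attributes `nodes` (tibble `haplotype_id`, `count`, `component`).
#' @export
build_network <- function(hs, max_steps = Inf) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (nrow(hs) < 2) stop("need >= 2 haplotypes.", call. = FALSE)
  ids <- hs$haplotype_id
  m <- do.call(rbind, strsplit(hs$sequence, ""))
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  steps <- apply(pairs, 2, function(p) sum(m[p[1], ] != m[p[2], ]))
  edges <- tibble::tibble(i = pairs[1, ], j = pairs[2, ], steps = steps)
  edges <- edges[edges$steps <= max_steps, ]
  edges <- edges[order(edges$steps, edges$i, edges$j), ]

  # Kruskal with tie-inclusion: for each distance class, keep every edge
  # whose endpoints lay in different components before the class was
  # processed, then merge.
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  kept <- logical(nrow(edges))
  for (w in unique(edges$steps)) {
    idx <- which(edges$steps == w)
    roots <- vapply(idx, function(e) {
      c(find(edges$i[e]), find(edges$j[e]))
    }, integer(2))
    keep_w <- roots[1, ] != roots[2, ]
    kept[idx[keep_w]] <- TRUE
    for (e in idx[keep_w]) {
      ri <- find(edges$i[e]); rj <- find(edges$j[e])
      if (ri != rj) parent[ri] <- rj
    }
  }
  net <- tibble::tibble(
    from = ids[edges$i[kept]],
    to = ids[edges$j[kept]],
    steps = edges$steps[kept]
  )
  comp <- vapply(seq_len(n), find, integer(1))
  nodes <- tibble::tibble(
    haplotype_id = ids,
    count = hs$count,
    component = match(comp, unique(comp))
  )
  class(net) <- c("haplo_network", class(net))
  attr(net, "nodes") <- nodes
  net
}

#' Plot a haplotype network
#'
#' Nodes are placed by classical multidimensional scaling of the
#' network's step distances and sized by haplotype frequency.
#'
#' @param object A `haplo_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplo_network <- function(object, ...) {
  nodes <- attr(object, "nodes")
  n <- nrow(nodes)
  d <- matrix(max(object$steps) * 2, n, n,
              dimnames = list(nodes$haplotype_id, nodes$haplotype_id))
  diag(d) <- 0
  for (k in seq_len(nrow(object))) {
    d[object$from[k], object$to[k]] <- object$steps[k]
    d[object$to[k], object$from[k]] <- object$steps[k]
  }
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  seg <- dplyr::mutate(
    object,
    x = nodes$x[match(.data$from, nodes$haplotype_id)],
    y = nodes$y[match(.data$from, nodes$haplotype_id)],
    xend = nodes$x[match(.data$to, nodes$haplotype_id)],
    yend = nodes$y[match(.data$to, nodes$haplotype_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$count),
      colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$haplotype_id),
      vjust = -1.2, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "individuals")
}
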