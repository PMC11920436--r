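# Nonparametric cluster-based permutation tests over channel x time (ERP) and
# channel x frequency x time (TFR) arrays. Candidate samples exceed the
# two-sided cluster-forming threshold on the paired t statistic; clusters are
# connected sets under temporal/spectral adjacency plus a montage neighbor
# graph; observed cluster masses (sum of t) are compared against the
# permutation distribution of the maximum cluster mass obtained by flipping
# the sign of each subject's condition difference.

#' Channel adjacency graph for a montage
#'
#' Default neighbor structure for the six-channel frontocentral montage:
#' Fz-Cz, Cz-Pz, Pz-Oz, C3-Cz, Cz-C4, Fz-C3, Fz-C4, C3-Pz, C4-Pz. A custom
#' edge list overrides the default.
#'
#' @param channels channel labels.
#' @param edges optional two-column matrix/data frame of channel label pairs.
#' @return an `adjacency_graph`: list with `channels` and a symmetric logical
#'   `matrix` (no self-loops).
#' @export
build_adjacency <- function(channels, edges = NULL) {
  default_edges <- rbind(
    c("Fz", "Cz"), c("Cz", "Pz"), c("Pz", "Oz"), c("C3", "Cz"),
    c("Cz", "C4"), c("Fz", "C3"), c("Fz", "C4"), c("C3", "Pz"),
    c("C4", "Pz"))
  if (is.null(edges)) {
    edges <- default_edges[default_edges[, 1] %in% channels &
                           default_edges[, 2] %in% channels, , drop = FALSE]
  } else {
    edges <- as.matrix(edges)
    bad <- setdiff(unique(c(edges)), channels)
    if (length(bad)) stop("unknown channel label(s): ",
                          paste(bad, collapse = ", "))
  }
  A <- matrix(FALSE, length(channels), length(channels),
              dimnames = list(channels, channels))
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- TRUE
    A[edges[k, 2], edges[k, 1]] <- TRUE
  }
  diag(A) <- FALSE
  structure(list(channels = channels, matrix = A),
            class = "adjacency_graph")
}

# Label connected components of a logical candidate array.
# dims = c(nch, nf, nt); adjacency: logical channel matrix.
label_clusters <- function(cand, dims, adj) {
  labels <- integer(length(cand))
  nxt <- 0L
  nch <- dims[1]; nf <- dims[2]; nt <- dims[3]
  idx_of <- function(ch, f, t) ch + nch * (f - 1L) + nch * nf * (t - 1L)
  neighbors_of <- function(i) {
    t <- (i - 1L) %/% (nch * nf) + 1L
    r <- (i - 1L) %% (nch * nf)
    f <- r %/% nch + 1L
    ch <- r %% nch + 1L
    out <- integer(0)
    if (t > 1L) out <- c(out, i - nch * nf)
    if (t < nt) out <- c(out, i + nch * nf)
    if (f > 1L) out <- c(out, i - nch)
    if (f < nf) out <- c(out, i + nch)
    nb <- which(adj[ch, ])
    if (length(nb)) out <- c(out, idx_of(nb, f, t))
    out
  }
  for (start in which(cand)) {
    if (labels[start]) next
    nxt <- nxt + 1L
    stack <- start
    labels[start] <- nxt
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- neighbors_of(i)
      nb <- nb[cand[nb] & labels[nb] == 0L]
      labels[nb] <- nxt
      stack <- c(stack, nb)
    }
  }
  labels
}

# Cluster masses for one t map: returns list(pos, neg) of cluster masses and
# the label vectors.
cluster_masses <- function(tmap, tcrit, dims, adj) {
  pos_lab <- label_clusters(tmap > tcrit, dims, adj)
  neg_lab <- label_clusters(tmap < -tcrit, dims, adj)
  pos <- if (max(pos_lab)) vapply(seq_len(max(pos_lab)), function(k)
    sum(tmap[pos_lab == k]), 0) else numeric(0)
  neg <- if (max(neg_lab)) vapply(seq_len(max(neg_lab)), function(k)
    sum(tmap[neg_lab == k]), 0) else numeric(0)
  list(pos = pos, neg = neg, pos_lab = pos_lab, neg_lab = neg_lab)
}

#' Paired cluster-based permutation test
#'
#' @param condA,condB numeric arrays, subject x channel x time or
#'   subject x channel x frequency x time, matched subjects.
#' @param adjacency an [build_adjacency()] graph (or `NULL` for
#'   temporal(-spectral) adjacency only).
#' @param alpha_cluster two-sided cluster-forming alpha on the paired t
#'   statistic (default 0.01).
#' @param n_permutations number of random within-subject sign flips (default
#'   500), or `"all"` for exhaustive enumeration of the 2^n assignments.
#' @param seed permutation seed.
#' @param alpha cluster significance level (default 0.05); the
#'   Bonferroni-corrected level for the study's three condition contrasts is
#'   0.05/3 = 0.0167 per side, printed alongside.
#' @return a `cluster_test`: `clusters` data frame (id, sign, mass, p,
#'   n_members, cohens_d), `t_map`, `labels` (signed cluster id per sample),
#'   `dims`, `perm_max` (permutation distribution), `params`.
#' @export
paired_cluster_test <- function(condA, condB, adjacency = NULL,
                                alpha_cluster = 0.01, n_permutations = 500,
                                seed = NULL, alpha = 0.05) {
  stopifnot(identical(dim(condA), dim(condB)))
  dn <- dim(condA)
  n <- dn[1]
  stopifnot(n >= 2)
  dims <- if (length(dn) == 3) c(dn[2], 1L, dn[3]) else
          if (length(dn) == 4) dn[2:4] else
          stop("arrays must be subject x channel x [frequency x] time")
  p <- prod(dims)
  D <- matrix(condA - condB, nrow = n)   # subjects x samples
  adj <- if (is.null(adjacency)) {
    matrix(FALSE, dims[1], dims[1])
  } else {
    stopifnot(dims[1] == length(adjacency$channels))
    adjacency$matrix
  }
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  ss <- colSums(D^2)

  t_of_signs <- function(S) {   # S: nperm x n
    M <- S %*% D / n
    V <- (matrix(ss, nrow(S), p, byrow = TRUE) - n * M^2) / (n - 1)
    M / sqrt(V / n)
  }

  obs_t <- as.vector(t_of_signs(matrix(1, 1, n)))
  obs <- cluster_masses(obs_t, tcrit, dims, adj)

  exhaustive <- identical(n_permutations, "all") ||
    (is.numeric(n_permutations) && 2^n <= n_permutations)
  S <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_permutations * n,
                                  replace = TRUE), ncol = n))
  }
  n_perm <- nrow(S)
  max_pos <- numeric(n_perm)
  min_neg <- numeric(n_perm)
  block <- max(1L, floor(2e6 / p))
  for (b0 in seq(1, n_perm, by = block)) {
    rows <- b0:min(n_perm, b0 + block - 1)
    Tm <- t_of_signs(S[rows, , drop = FALSE])
    for (r in seq_along(rows)) {
      cm <- cluster_masses(Tm[r, ], tcrit, dims, adj)
      max_pos[rows[r]] <- if (length(cm$pos)) max(cm$pos) else 0
      min_neg[rows[r]] <- if (length(cm$neg)) min(cm$neg) else 0
    }
  }
  # two-sided max-statistic correction: one null distribution of the largest
  # absolute cluster mass controls the family-wise rate over both signs
  max_abs <- pmax(max_pos, -min_neg)

  p_of <- function(mass) {
    count <- sum(max_abs >= abs(mass))
    if (exhaustive) count / n_perm else (count + 1) / (n_perm + 1)
  }
  rows <- list()
  labels <- integer(p)
  cid <- 0L
  for (k in seq_along(obs$pos)) {
    cid <- cid + 1L
    members <- which(obs$pos_lab == k)
    labels[members] <- cid
    rows[[cid]] <- data.frame(
      id = cid, sign = "pos", mass = obs$pos[k],
      p = p_of(obs$pos[k]),
      n_members = length(members),
      cohens_d = cluster_cohens_d(D, members))
  }
  for (k in seq_along(obs$neg)) {
    cid <- cid + 1L
    members <- which(obs$neg_lab == k)
    labels[members] <- -cid
    rows[[cid]] <- data.frame(
      id = cid, sign = "neg", mass = obs$neg[k],
      p = p_of(obs$neg[k]),
      n_members = length(members),
      cohens_d = cluster_cohens_d(D, members))
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = character(0), mass = numeric(0),
               p = numeric(0), n_members = integer(0), cohens_d = numeric(0))
  structure(list(clusters = clusters, t_map = array(obs_t, dims),
                 labels = array(labels, dims), dims = dims,
                 perm_max = list(pos = max_pos, neg = min_neg,
                                 abs = max_abs),
                 params = list(alpha_cluster = alpha_cluster,
                               n_permutations = n_perm, alpha = alpha,
                               exhaustive = exhaustive, n_subjects = n)),
            class = "cluster_test")
}

cluster_cohens_d <- function(D, members) {
  diffs <- rowMeans(D[, members, drop = FALSE])
  s <- stats::sd(diffs)
  if (s == 0) return(NA_real_)
  mean(diffs) / s
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> n=%d subjects, %d permutations%s, cluster-forming alpha=%.3g\n",
              x$params$n_subjects, x$params$n_permutations,
              if (x$params$exhaustive) " (exhaustive)" else "",
              x$params$alpha_cluster))
  if (nrow(x$clusters)) {
    print(x$clusters, row.names = FALSE)
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Paired Cohen's d over a cluster
#'
#' `d = mean(diff) / sd(diff)` where `diff` is each subject's mean A-B
#' difference across the cluster members. Zero-SD input yields `NA` with a
#' warning.
#'
#' @param condA,condB subject x ... arrays as in [paired_cluster_test()].
#' @param members linear indices (or logical mask) of cluster member samples.
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(condA, condB, members) {
  stopifnot(identical(dim(condA), dim(condB)))
  n <- dim(condA)[1]
  D <- matrix(condA - condB, nrow = n)
  if (is.logical(members)) members <- which(members)
  if (!length(members)) stop("empty cluster")
  d <- cluster_cohens_d(D, members)
  if (is.na(d)) warning("zero standard deviation of paired differences")
  d
}
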