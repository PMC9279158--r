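# Internal numerics shared across modules.

# Brute-force k-nearest neighbours (Euclidean) in blocks; returns an
# n x k index matrix excluding self.  Fine for the tens of thousands of
# points this pipeline sees.
knn_index <- function(X, k, block = 1024L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(k, n - 1L)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(X[s:e, , drop = FALSE], X)
    for (i in seq_len(e - s + 1L)) {
      d2[i, s + i - 1L] <- Inf  # exclude self
      out[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

# Shared-nearest-neighbour graph (Jaccard weights over kNN lists, pruned)
# followed by Louvain community detection.  Seeded via the R RNG.
snn_louvain <- function(X, k = 20L, resolution = 0.2, seed = 1L,
                        prune = 1 / 15) {
  n <- nrow(X)
  if (n < 2L) stop("cannot cluster fewer than 2 entities")
  k <- min(k, n - 1L)
  nn <- knn_index(X, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)                       # shared-neighbour counts
  S <- as(as(S, "CsparseMatrix"), "generalMatrix")
  jac <- S
  jac@x <- S@x / (2 * k - S@x)                     # Jaccard of kNN sets
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

# Vectorised two-group Wilcoxon rank-sum test over matrix rows.
# Normal approximation with tie correction and continuity correction,
# matching wilcox.test(exact = FALSE, correct = TRUE).
row_wilcoxon <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- as.matrix(mat[, c(idx1, idx2), drop = FALSE])
  nr <- nrow(sub)
  p <- numeric(nr)
  for (i in seq_len(nr)) {
    r <- rank(sub[i, ])
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for group 1
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n1 + n2 + 1) -
      sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) { p[i] <- 1; next }
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[i] <- 2 * pnorm(-abs(z))
  }
  pmin(p, 1)
}

# Centered running mean along a vector with shrinking windows at the edges
# (window w must be odd).
running_mean <- function(v, w) {
  n <- length(v)
  if (w <= 1L || n == 1L) return(v)
  h <- (min(w, if (n %% 2L == 1L) n else n - 1L) - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Per-column z-scaling of a genes x entities matrix (genes are rows):
# subtract row mean, divide by row sd; zero-variance rows -> 0.
scale_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / max(1, ncol(m) - 1))
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  attr(z, "zero_variance") <- rownames(m)[sdv == 0]
  z
}

# Best agreement between two labellings over all label matchings
# (labels are arbitrary; used for truth comparisons).
match_accuracy <- function(pred, truth) {
  tab <- table(pred, truth)
  if (nrow(tab) == 0) return(NA_real_)
  # greedy over permutations for small label sets; exact for <= 6 labels
  preds <- rownames(tab); truths <- colnames(tab)
  if (length(preds) <= length(truths)) {
    perms <- all_injections(seq_along(preds), seq_along(truths))
    best <- 0
    for (p in perms) best <- max(best, sum(tab[cbind(seq_along(preds), p)]))
  } else {
    perms <- all_injections(seq_along(truths), seq_along(preds))
    best <- 0
    for (p in perms) best <- max(best, sum(t(tab)[cbind(seq_along(truths), p)]))
  }
  best / length(pred)
}

all_injections <- function(from, to) {
  if (length(from) == 0) return(list(integer()))
  out <- list()
  for (t in to) {
    rest <- all_injections(from[-1], setdiff(to, t))
    out <- c(out, lapply(rest, function(r) c(t, r)))
  }
  out
}

# Adjusted Rand index between two partitions.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}
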