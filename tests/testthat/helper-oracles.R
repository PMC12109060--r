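# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths (closed forms,
# exhaustive enumeration, dense-matrix algorithms).

# Closed-form ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# Exact upper-tail hypergeometric probability by summing binomial
# coefficients: P(X >= k), X ~ Hypergeom(N, K, n).
hyper_oracle <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the textbook cumulative-minimum recipe.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Ordinary pooled two-sample t-test per row of two matrices.
pooled_t_oracle <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  s2 <- ((n1 - 1) * apply(x1, 1, var) + (n2 - 1) * apply(x2, 1, var)) /
    (n1 + n2 - 2)
  d <- rowMeans(x1) - rowMeans(x2)
  tt <- d / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# --- dense-matrix graph oracles (small graphs only) -------------------------

# Symmetric 0/1 adjacency matrix of a ppi_network.
adj_matrix_of <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$protein1[i]; b <- net$edges$protein2[i]
    A[a, b] <- 1L; A[b, a] <- 1L
  }
  A
}

# All-pairs shortest paths by Floyd-Warshall.
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

closeness_oracle <- function(A, harmonic = TRUE) {
  D <- floyd_warshall(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    if (harmonic) sum(1 / d) else 1 / sum(d)
  }, numeric(1))
}

is_clique <- function(A, S) {
  length(S) < 2L || all(A[S, S][upper.tri(A[S, S])] == 1L)
}

# MCC by exhaustive subset enumeration: every clique that no outside vertex
# extends is maximal.
mcc_oracle <- function(A) {
  n <- nrow(A)
  score <- numeric(n)
  for (bits in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0)
    if (!is_clique(A, S)) next
    outside <- setdiff(seq_len(n), S)
    maximal <- !any(vapply(outside, function(u) all(A[u, S] == 1L), logical(1)))
    if (maximal) score[S] <- score[S] + factorial(length(S) - 1L)
  }
  score
}

mnc_oracle <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    if (!length(nb)) return(0L)
    sub <- A[nb, nb, drop = FALSE]
    # component sizes by repeated neighbourhood expansion
    unassigned <- seq_along(nb)
    best <- 0L
    while (length(unassigned)) {
      comp <- unassigned[1]
      repeat {
        grown <- unique(c(comp, which(colSums(sub[comp, , drop = FALSE]) > 0)))
        if (length(grown) == length(comp)) break
        comp <- grown
      }
      best <- max(best, length(comp))
      unassigned <- setdiff(unassigned, comp)
    }
    best
  }, integer(1))
}

# Random small graph as an edge list (all scores above any cutoff).
random_edge_list <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- which(runif(nrow(pairs)) < p)
  data.frame(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
             combined_score = rep(900, length(keep)),
             stringsAsFactors = FALSE)
}

# Fine-grid trapezoidal reference for the closed-loop area of one cycle of
# a voltammogram built from known sweep functions.
quadrature_oracle <- function(f_fwd, f_rev, v_low, v_high, n = 1e6) {
  grid <- seq(v_low, v_high, length.out = n)
  h <- diff(grid)
  y <- f_fwd(grid) - f_rev(grid)
  sum((y[-1] + y[-length(y)]) / 2 * h)
}
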