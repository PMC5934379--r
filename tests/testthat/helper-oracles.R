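# Independent oracles used to cross-check the package implementation.
# These deliberately avoid igraph and the package's own linear-algebra
# paths: graphs are plain edge matrices, cores are found by literal
# pruning, and LOOCV is an explicit refit loop.

# --- graph oracles --------------------------------------------------------

oracle_degrees <- function(edges, nodes) {
  d <- setNames(rep(0L, length(nodes)), nodes)
  if (length(edges)) {
    tab <- table(c(edges[, 1], edges[, 2]))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

# highest k-core by brute-force iterative pruning
oracle_highest_core <- function(edges, nodes) {
  bestK <- 0L
  bestSet <- nodes
  k <- 1L
  repeat {
    nd <- nodes
    ed <- edges
    repeat {
      deg <- oracle_degrees(ed, nd)
      drop <- names(deg)[deg < k]
      if (!length(drop) || !length(nd)) break
      nd <- setdiff(nd, drop)
      if (length(ed))
        ed <- ed[ed[, 1] %in% nd & ed[, 2] %in% nd, , drop = FALSE]
    }
    if (!length(nd)) break
    bestK <- k
    bestSet <- nd
    k <- k + 1L
  }
  list(k = bestK, core = sort(bestSet))
}

oracle_vertex_weight <- function(edges, nodes, v) {
  nb <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  if (!length(nb)) return(0)
  sub <- unique(c(v, nb))
  ed <- edges[edges[, 1] %in% sub & edges[, 2] %in% sub, , drop = FALSE]
  hc <- oracle_highest_core(ed, sub)
  core <- hc$core
  ce <- ed[ed[, 1] %in% core & ed[, 2] %in% core, , drop = FALSE]
  nv <- length(core)
  dens <- if (nv < 2) 0 else 2 * nrow(ce) / (nv * (nv - 1))
  hc$k * dens
}

edges_to_graph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(edges[, 1], edges[, 2]))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
    vertices = nodes)
}

# --- enrichment oracles ---------------------------------------------------

# upper-tail hypergeometric by explicit combinatorial summation
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- regression oracles ---------------------------------------------------

# explicit leave-one-out refit loop
oracle_loocv <- function(X, y) {
  n <- nrow(X)
  press <- sum(vapply(seq_len(n), function(i) {
    cf <- lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    (y[i] - sum(X[i, ] * cf))^2
  }, numeric(1)))
  list(rmse = sqrt(press / n),
       r2 = 1 - press / sum((y - mean(y))^2))
}

# best-match Jaccard of recovered clusters against planted truth
mean_best_jaccard <- function(recovered, truth) {
  mean(vapply(truth, function(tr) {
    if (!length(recovered)) return(0)
    max(vapply(recovered, function(m)
      length(intersect(m, tr)) / length(union(m, tr)), numeric(1)))
  }, numeric(1)))
}
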