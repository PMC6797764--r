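# Independent brute-force oracles used to validate the package's
# implementations, written deliberately without reusing package internals
# or the libraries that back them.

# Benjamini-Hochberg step-up, literal formula on sorted p-values.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  run <- p[o] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(run))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Run-length compression by explicit scan.
runs_oracle <- function(labels) {
  out <- labels[1]
  for (l in labels[-1]) if (l != out[length(out)]) out <- c(out, l)
  out
}

# Entries per zone by scanning transitions (initial run excluded).
entries_oracle <- function(labels) {
  z <- runs_oracle(labels)
  tab <- table(z[-1])
  counts <- stats::setNames(as.integer(tab), names(tab))
  for (extra in setdiff(unique(z), names(counts))) counts[extra] <- 0L
  counts
}

# HEH frequency by explicit triple scan over the run sequence.
heh_oracle <- function(runs, hidden = "hidden", entry = "entry") {
  pairs <- 0L; triples <- 0L
  n <- length(runs)
  if (n >= 2) for (i in seq_len(n - 1)) {
    if (runs[i] == hidden && runs[i + 1] == entry) {
      pairs <- pairs + 1L
      if (i + 2 <= n && runs[i + 2] == hidden) triples <- triples + 1L
    }
  }
  if (pairs == 0) NA_real_ else triples / pairs
}

# Unnormalized betweenness by BFS shortest-path counting over all pairs.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ] > 0))
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in nbrs[[v]]) {
          if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
          if (d[u] == d[v] + 1) sg[u] <- sg[u] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t2 in (s + 1):n) {
    if (is.infinite(dist[s, t2])) next
    for (v in seq_len(n)) {
      if (v == s || v == t2) next
      if (dist[s, v] + dist[v, t2] == dist[s, t2]) {
        bw[v] <- bw[v] + sigma[s, v] * sigma[t2, v] / sigma[s, t2]
      }
    }
  }
  bw
}

# Topological overlap by literal triple loop.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    u <- setdiff(seq_len(n), c(i, j))
    l <- sum(a[i, u] * a[u, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# First principal component of row-standardized data via the sample-side
# eigendecomposition (independent of svd-based implementation).
eigengene_oracle <- function(x) {
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(xs), symmetric = TRUE)
  list(me = ev$vectors[, 1], var_explained = ev$values[1] / sum(ev$values))
}

# Random undirected simple graph as an adjacency matrix.
random_graph_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  on <- up[stats::runif(length(up)) < p]
  a[on] <- 1L
  a + t(a)
}

# Adjacency -> edge data frame with uniform high confidence.
adj_to_edges <- function(a, conf = 0.9) {
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  data.frame(protein_a = paste0("n", idx[, 1]),
             protein_b = paste0("n", idx[, 2]),
             confidence = conf)
}
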