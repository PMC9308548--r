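# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (and igraph): exhaustive enumeration and direct formula
# transcription only.

# Hypergeometric upper tail P(X >= x) by direct summation of choose terms.
oracle_hyper_tail <- function(x, K, N, n) {
  ks <- seq(max(x, 0), min(K, n))
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the definition:
# q_i = min over j with p_(j) >= p_i of p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-300)
    min(1, min(ps[js] * n / js))
  }, numeric(1L))
}

# Welch t and p transcribed from the textbook formulas.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# ---- exhaustive graph-metric oracles (adjacency matrix, n <= 8) ----

# All-pairs shortest-path distances by breadth-first search.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0L)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (D[s, w] > d) { D[s, w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

oracle_closeness <- function(adj) {
  D <- oracle_distances(adj)
  apply(D, 1L, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else length(reach) / sum(reach)
  })
}

# Geodesic counts by enumerating every simple path between each pair.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1L]] <<- path; return() }
      for (w in which(adj[v, ] == 1)) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    found
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1L))
      geo <- ps[lens == min(lens)]
      through <- vapply(seq_len(n), function(v) {
        if (v == s || v == t) 0
        else sum(vapply(geo, function(p) v %in% p, logical(1L)))
      }, numeric(1L))
      btw <- btw + through / length(geo)
    }
  }
  btw
}

oracle_transitivity_local <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2L) return(0)
    sum(adj[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1L))
}

# Trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, is_pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[is_pos] >= t),
                     numeric(1L)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!is_pos] >= t),
                     numeric(1L)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Random undirected graph as a 0/1 adjacency matrix.
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1L, p)
  adj + t(adj)
}
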