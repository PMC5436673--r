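# Small graph builders used across the suite.

cycle_graph <- function(n = 3L, labels = LETTERS[seq_len(n)]) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) W[i, i %% n + 1L] <- 1
  directed_graph(W)
}

path_graph_sym <- function(n = 3L, labels = letters[seq_len(n)]) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    W[i, i + 1L] <- 1
    W[i + 1L, i] <- 1
  }
  directed_graph(W)
}

is_strongly_connected_fixture <- function(W) {
  igraph::is_connected(igraph::graph_from_adjacency_matrix(W != 0),
    mode = "strong"
  )
}

random_unit_rows <- function(n, k, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  Z / sqrt(rowSums(Z^2))
}

# Independent double-loop evaluation of the hierarchical-distance objective;
# deliberately naive so it cannot share bugs with the vectorized version.
objective_loop <- function(h, mu) {
  tot <- 0
  n <- length(h)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + (abs(h[i] - h[j]) - mu[i, j])^2
    }
  }
  tot
}

# Exhaustive minimum of the objective over the integer grid {0..K}^n with the
# anchored coordinates fixed.
grid_minimum <- function(mu, K, anchor_idx, anchor_lev) {
  n <- nrow(mu)
  free <- setdiff(seq_len(n), anchor_idx)
  grid <- as.matrix(expand.grid(rep(list(0:K), length(free))))
  best <- Inf
  h <- numeric(n)
  h[anchor_idx] <- anchor_lev
  for (r in seq_len(nrow(grid))) {
    h[free] <- grid[r, ]
    v <- objective_loop(h, mu)
    if (v < best) best <- v
  }
  best
}
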