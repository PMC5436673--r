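test_that("transition matrix is row-stochastic with stated degenerate handling", {
  g <- cycle_graph(3L)
  tm <- transition_matrix(g, eta = 1)
  expect_equal(tm$P, g$W[tm$labels, tm$labels], ignore_attr = TRUE)
  expect_equal(rowSums(tm$P), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-10)

  # teleportation mixes in the uniform jump
  tm85 <- transition_matrix(g, eta = 0.85)
  expect_equal(max(tm85$P), 0.85 + 0.15 / 3)
  expect_equal(min(tm85$P), 0.15 / 3)
  expect_equal(rowSums(tm85$P), rep(1, 3), ignore_attr = TRUE)

  # sink row becomes uniform before teleportation
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1
  W[2, 3] <- 1 # node 3 has no out-edges
  tms <- transition_matrix(directed_graph(W), eta = 1)
  expect_equal(tms$P[3, ], rep(1 / 3, 3), ignore_attr = TRUE)
  expect_true(all(tms$P >= 0))
})

test_that("default teleportation depends on strong connectivity", {
  expect_equal(transition_matrix(cycle_graph(4L))$eta, 1)
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1
  W[2, 3] <- 1
  expect_equal(transition_matrix(directed_graph(W))$eta, 0.99)
})

test_that("Perron vector is the stationary distribution", {
  # symmetric cycle: uniform by symmetry
  pr <- perron_vector(transition_matrix(cycle_graph(5L), eta = 1))
  expect_equal(unname(pr$psi), rep(0.2, 5), tolerance = 1e-10)
  expect_equal(pr$rho, 1, tolerance = 1e-8)

  # undirected path: stationary mass proportional to degree
  prp <- perron_vector(transition_matrix(path_graph_sym(3L), eta = 1))
  expect_equal(unname(prp$psi), c(0.25, 0.5, 0.25), tolerance = 1e-10)

  # random strongly connected graph vs an independent power-iteration oracle
  set.seed(42)
  repeat {
    W <- matrix(rbinom(25, 1, 0.5), 5, 5)
    diag(W) <- 0
    if (all(rowSums(W) > 0) &&
          igraph::is_connected(igraph::graph_from_adjacency_matrix(W),
            mode = "strong")) break
  }
  tm <- transition_matrix(directed_graph(W), eta = 1)
  pr5 <- perron_vector(tm)
  v <- rep(1 / 5, 5)
  for (i in 1:5000) v <- as.vector(v %*% tm$P)
  expect_equal(unname(pr5$psi), v / sum(v), tolerance = 1e-8)
  expect_equal(as.vector(pr5$psi %*% tm$P), unname(pr5$psi), tolerance = 1e-8)
})

test_that("Perron vector is equivariant under node relabeling", {
  ph <- simulate_hierarchy(12, 3, 0.6, 0.8, seed = 21)
  g <- ph$graph
  perm <- c(5, 1, 12, 3, 9, 2, 7, 11, 4, 10, 6, 8)
  gp <- directed_graph(g$W[perm, perm], labels = g$labels[perm])
  psi <- perron_vector(transition_matrix(g, eta = 0.99))$psi
  psip <- perron_vector(transition_matrix(gp, eta = 0.99))$psi
  expect_equal(psip, psi[perm], tolerance = 1e-10)
})

test_that("directed Laplacian satisfies its algebraic identities", {
  ph <- simulate_hierarchy(15, 4, 0.5, 0.7, seed = 8)
  tm <- transition_matrix(ph$graph, eta = 0.99)
  pr <- perron_vector(tm)
  se <- directed_laplacian(tm, pr)
  expect_lt(max(abs(se$L_d - t(se$L_d))), 1e-10)
  expect_lt(abs(se$lambdas[1]), 1e-8)
  expect_lt(max(abs(se$L_d %*% sqrt(pr$psi))), 1e-8)
  expect_true(all(diff(se$lambdas) >= -1e-12))
  expect_lte(max(se$lambdas), 2 + 1e-8)
})

test_that("symmetric graphs reduce to the symmetric normalized Laplacian", {
  g <- path_graph_sym(6L)
  se <- directed_laplacian(transition_matrix(g, eta = 1))
  d <- rowSums(g$W)
  Lsym <- diag(6) - diag(1 / sqrt(d)) %*% g$W %*% diag(1 / sqrt(d))
  expect_lt(max(abs(se$L_d - Lsym)), 1e-10)

  # 3-node path has closed-form spectrum 0, 1, 2
  se3 <- directed_laplacian(transition_matrix(path_graph_sym(3L), eta = 1))
  expect_equal(se3$lambdas, c(0, 1, 2), tolerance = 1e-8)

  # and the full-pipeline embedding matches the symmetric-Laplacian oracle
  Z <- spectral_embedding(g, k = 3, eta = 1)$Z
  eo <- eigen(Lsym, symmetric = TRUE)
  Yo <- eo$vectors[, 6:4]
  Yo <- apply(Yo, 2, function(v) {
    i <- which(abs(v) > 1e-12)[1]
    if (v[i] < 0) -v else v
  })
  Zo <- Yo / sqrt(rowSums(Yo^2))
  expect_equal(unname(Z), Zo, tolerance = 1e-8)
})

test_that("embedding rows are unit-norm and sign-fixing makes runs identical", {
  ph <- simulate_hierarchy(20, 4, 0.6, 1, seed = 13)
  se1 <- spectral_embedding(ph$graph, k = 4)
  se2 <- spectral_embedding(ph$graph, k = 4)
  expect_identical(se1$Z, se2$Z)
  expect_equal(sqrt(rowSums(se1$Z^2)), rep(1, 20),
    ignore_attr = TRUE, tolerance = 1e-10
  )
  # k = 1: scalar normalization gives +/-1
  z1 <- spectral_embed(directed_laplacian(transition_matrix(ph$graph)), 1)$Z
  expect_true(all(abs(abs(z1) - 1) < 1e-10))
  expect_error(
    spectral_embed(directed_laplacian(transition_matrix(ph$graph)), 99),
    class = "hierord_error_params"
  )
})

test_that("embedding places nodes near their level peers", {
  # nearest neighbour in embedding space has planted level within 1,
  # for at least 70% of nodes on average over 20 seeds
  agree <- vapply(1:20, function(s) {
    ph <- simulate_hierarchy(40, 9, 0.6, 1.5, seed = 400 + s)
    Z <- spectral_embedding(ph$graph, k = 4)$Z
    lev <- ph$levels$level
    D <- as.matrix(dist(Z))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    mean(abs(lev[nn] - lev) <= 1)
  }, numeric(1))
  expect_gte(mean(agree), 0.7)
})

test_that("spectral gaps are consecutive eigenvalue differences", {
  expect_equal(spectral_gaps(c(0, 0.2, 0.9, 1.0)), c(0.2, 0.7, 0.1))
  expect_equal(spectral_gaps(rep(0.5, 4)), rep(0, 3))
  lam <- sort(runif(7))
  expect_length(spectral_gaps(lam), 6)
  expect_true(all(spectral_gaps(lam) >= 0))
})

test_that("parameter suggestion applies the large-gap rule", {
  sug <- suggest_parameters(c(0.5, 0.4, 0.45, 0.02, 0.02, 0.02), c = 2)
  expect_equal(sug$k, 3L)
  expect_warning(
    sug_flat <- suggest_parameters(rep(0.1, 6), c = 2),
    "falling back"
  )
  expect_equal(sug_flat$k, 4L)
  expect_error(suggest_parameters(c(0.1, 0.2)), class = "hierord_error_params")
  # K from the run of similar gaps following the large ones
  sug2 <- suggest_parameters(c(0.5, 0.4, 0.45, 0.02, 0.021, 0.019, 0.02, 0.022, 0.001))
  expect_equal(sug2$k, 3L)
  expect_equal(sug2$n_levels, 8L)
  expect_equal(sug2$K, 7L)
})
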