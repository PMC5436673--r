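#' Random-walk transition matrix with teleportation
#'
#' Builds the row-stochastic transition matrix `P = D^-1 W`, where `D` is the
#' diagonal matrix of out-degrees. Rows with zero out-degree are replaced by
#' the uniform distribution. Teleportation then mixes in a uniform jump,
#' `P' = eta * P + (1 - eta) / n`, which guarantees irreducibility — and
#' hence a unique positive Perron vector — for `eta < 1` even when the graph
#' is not strongly connected.
#'
#' @param g a [directed_graph()].
#' @param eta teleportation retention in (0, 1]. Default: 1 when the graph is
#'   strongly connected, otherwise 0.99.
#' @return An object of class `transition_matrix` with fields `P` (after
#'   teleportation), `eta`, `labels`, `n`.
#' @export
transition_matrix <- function(g, eta = NULL) {
  stopifnot(inherits(g, "hierord_graph"))
  W <- g$W
  n <- nrow(W)
  if (is.null(eta)) {
    eta <- if (is_strongly_connected(W)) 1 else 0.99
  }
  if (!(eta > 0 && eta <= 1)) {
    abort("eta must lie in (0, 1]", class = "hierord_error_params")
  }
  d <- rowSums(W)
  P <- W / ifelse(d > 0, d, 1)
  P[d == 0, ] <- 1 / n
  P <- eta * P + (1 - eta) / n
  structure(
    list(P = P, eta = eta, labels = g$labels, n = n),
    class = "transition_matrix"
  )
}

#' Perron vector of a transition matrix
#'
#' The Perron vector `psi` is the unique positive left eigenvector of the
#' transition matrix at its largest eigenvalue `rho` (`rho = 1` for a
#' row-stochastic matrix): the stationary distribution of the random walk.
#' Computed by a dense eigendecomposition of the transpose, with the sign and
#' scale fixed so that `psi` is positive and sums to one.
#'
#' @param tm a [transition_matrix()].
#' @param tol positivity tolerance; entries below `-tol` (relative to `1/n`)
#'   signal a reducible chain.
#' @return A list with `psi` (length-n positive vector summing to 1) and
#'   `rho`.
#' @export
perron_vector <- function(tm, tol = 1e-8) {
  stopifnot(inherits(tm, "transition_matrix"))
  e <- eigen(t(tm$P))
  i <- which.max(Re(e$values))
  rho <- Re(e$values[i])
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (min(v) < -tol / tm$n || min(v) <= 0) {
    abort(
      paste0(
        "Perron vector has non-positive entries: the transition matrix is ",
        "reducible (graph not strongly connected). Lower eta below 1 to ",
        "add teleportation."
      ),
      class = "hierord_error_reducible"
    )
  }
  list(psi = setNames(v, tm$labels), rho = rho)
}

#' Normalized directed Laplacian and its spectrum
#'
#' Builds the symmetric operator
#' \deqn{L_d = I - \frac{\Psi^{1/2} P \Psi^{-1/2} +
#'   \Psi^{-1/2} P^\top \Psi^{1/2}}{2},}
#' where `Psi = diag(psi)` holds the Perron vector of the transition matrix
#' `P`. For a symmetric graph walked without teleportation this reduces to
#' the familiar symmetric normalized Laplacian `I - D^{-1/2} W D^{-1/2}`.
#' Eigenvalues are returned in ascending order (`lambda_1 = 0`, with
#' eigenvector `sqrt(psi)`); each eigenvector's sign is fixed by making its
#' first nonzero component positive, so repeated runs are bitwise identical.
#'
#' @param tm a [transition_matrix()].
#' @param pr the matching [perron_vector()] result; computed when `NULL`.
#' @return An object of class `spectral_embedding` with `L_d`, `lambdas`
#'   (ascending), `vectors` (all n sign-fixed eigenvectors), `psi`, `eta`,
#'   `labels`; the embedding fields `k`, `Y`, `Z` are filled by
#'   [spectral_embed()].
#' @export
directed_laplacian <- function(tm, pr = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  pr <- pr %||% perron_vector(tm)
  psi <- pr$psi
  if (min(psi) < 1e-14) {
    abort("Perron vector entry below positivity tolerance",
      class = "hierord_error_reducible"
    )
  }
  s <- sqrt(psi)
  M <- (s * tm$P) * rep(1 / s, each = length(s)) # Psi^1/2 P Psi^-1/2
  L <- diag(tm$n) - (M + t(M)) / 2
  L <- (L + t(L)) / 2 # kill last-bit asymmetry
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_len(tm$n)) # ascending eigenvalues
  lambdas <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  V <- apply(V, 2L, fix_sign)
  dimnames(L) <- list(tm$labels, tm$labels)
  rownames(V) <- tm$labels
  structure(
    list(
      L_d = L, lambdas = lambdas, vectors = V, psi = psi, rho = pr$rho,
      eta = tm$eta, labels = tm$labels, k = NULL, Y = NULL, Z = NULL
    ),
    class = "spectral_embedding"
  )
}

fix_sign <- function(v) {
  i <- which(abs(v) > 1e-12)[1L]
  if (!is.na(i) && v[i] < 0) -v else v
}

#' Row-normalized k-dimensional spectral embedding
#'
#' Takes the first `k` eigenvectors of the directed Laplacian as `Y` (the
#' constant-direction first eigenvector included, matching the definition of
#' the eigenmap; set `drop_first = TRUE` for the common alternative) and
#' scales each row of `Y` to unit Euclidean norm, so that every node's
#' representative vector `f(u_i)` lies on the surface of the k-dimensional
#' sphere.
#'
#' @param se a [directed_laplacian()] result.
#' @param k embedding dimension, `1 <= k <= n`.
#' @param drop_first if `TRUE`, use eigenvectors `2..k+1` instead of `1..k`.
#' @return `se` with `k`, `Y` and `Z` populated.
#' @export
spectral_embed <- function(se, k, drop_first = FALSE) {
  stopifnot(inherits(se, "spectral_embedding"))
  n <- length(se$labels)
  if (!(k >= 1L && k <= n - drop_first)) {
    abort(sprintf("k must lie in [1, %d]", n - drop_first),
      class = "hierord_error_params"
    )
  }
  cols <- if (drop_first) seq(2L, k + 1L) else seq_len(k)
  Y <- se$vectors[, cols, drop = FALSE]
  rn <- sqrt(rowSums(Y^2))
  if (any(rn < 1e-12)) {
    abort(
      paste0(
        "embedding row with near-zero norm (node ",
        paste(se$labels[rn < 1e-12], collapse = ", "),
        "): k too small or degenerate graph"
      ),
      class = "hierord_error_degenerate_embedding"
    )
  }
  se$k <- as.integer(k)
  se$Y <- Y
  se$Z <- Y / rn
  se
}

#' One-shot spectral embedding of a graph
#'
#' Convenience wrapper: transition matrix, Perron vector, directed Laplacian
#' and row-normalized embedding in one call.
#'
#' @inheritParams transition_matrix
#' @inheritParams spectral_embed
#' @param k embedding dimension.
#' @return A `spectral_embedding` with `Y` and `Z` populated.
#' @export
spectral_embedding <- function(g, k, eta = NULL, drop_first = FALSE) {
  tm <- transition_matrix(g, eta = eta)
  spectral_embed(directed_laplacian(tm), k = k, drop_first = drop_first)
}

#' Spectral gaps of the Laplacian
#'
#' The gap vector `gamma_i = lambda_{i+1} - lambda_i` (magnitudes of
#' consecutive eigenvalue differences, nonnegative for the ascending
#' spectrum) drives the choice of the embedding dimension `k` and the number
#' of hierarchy levels; see [suggest_parameters()].
#'
#' @param se a `spectral_embedding` (lambdas populated) or a numeric vector
#'   of ascending eigenvalues.
#' @return Numeric vector of `n - 1` gaps.
#' @export
spectral_gaps <- function(se) {
  lambdas <- if (inherits(se, "spectral_embedding")) se$lambdas else se
  diff(lambdas)
}

#' Suggest embedding dimension and level count from spectral gaps
#'
#' A heuristic reading of the gap profile, always to be confirmed by eye:
#' the embedding dimension `k` is the index of the last gap that stands out
#' against the bulk (exceeds `c` times the median gap); the total number of
#' hierarchy levels is `k` plus the length of the run of mutually similar
#' consecutive gaps that follows, and `K` is that count minus one. When no
#' gap stands out, `k` falls back to `default_k` with a warning. Both values
#' are suggestions that the caller can override, and the full gap vector is
#' part of the return value so the evidence stays visible.
#'
#' @param gaps numeric gap vector (length >= 3) or a `spectral_embedding`.
#' @param c multiple of the median gap a gap must exceed to count as large.
#' @param similar_ratio consecutive gaps whose ratio stays within
#'   `[1/similar_ratio, similar_ratio]` are treated as "relatively similar".
#' @param default_k fallback dimension when no gap is large.
#' @return A list with `k`, `K`, `n_levels`, `gaps`, and a human-readable
#'   `reason`.
#' @export
suggest_parameters <- function(gaps, c = 2, similar_ratio = 3, default_k = 4L) {
  if (inherits(gaps, "spectral_embedding")) gaps <- spectral_gaps(gaps)
  if (length(gaps) < 3L) {
    abort("need at least 3 spectral gaps", class = "hierord_error_params")
  }
  thr <- c * median(gaps)
  large <- which(gaps > thr)
  if (length(large) == 0L) {
    warn(sprintf(
      "no spectral gap exceeds %g x median; falling back to k = %d",
      c, default_k
    ))
    k <- as.integer(min(default_k, length(gaps)))
    reason_k <- sprintf("fallback: no gap exceeds %.3g (= %g * median gap)", thr, c)
  } else {
    k <- max(large)
    reason_k <- sprintf(
      "gap %d (%.3g) is the last gap exceeding %.3g (= %g * median gap)",
      k, gaps[k], thr, c
    )
  }
  # run of mutually similar gaps after gap k
  run <- 0L
  i <- k + 1L
  while (i <= length(gaps)) {
    ref <- if (run == 0L) gaps[i] else gaps[i - 1L]
    lo <- min(ref, gaps[i])
    hi <- max(ref, gaps[i])
    similar <- (hi <= 1e-12) || (lo > 0 && hi / lo <= similar_ratio)
    if (run > 0L && !similar) break
    run <- run + 1L
    i <- i + 1L
  }
  n_levels <- k + run
  K <- max(1L, n_levels - 1L)
  list(
    k = as.integer(k),
    K = as.integer(K),
    n_levels = as.integer(n_levels),
    gaps = gaps,
    reason = paste0(
      "k: ", reason_k, "; K: ", run,
      " similar consecutive gaps follow, total levels ", n_levels,
      ", so K = ", K
    )
  )
}

#' @export
print.spectral_embedding <- function(x, ...) {
  cat(sprintf(
    "<spectral_embedding> n=%d, eta=%g, lambda in [%.4g, %.4g]%s\n",
    length(x$labels), x$eta, min(x$lambdas), max(x$lambdas),
    if (is.null(x$k)) "" else sprintf(", k=%d", x$k)
  ))
  invisible(x)
}
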