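#' Regularized Tanimoto similarity between embedding rows
#'
#' Tanimoto similarity generalizes the Jaccard index to real vectors. For
#' unit-norm representative vectors `f_i`, the regularized form
#' \deqn{s(u_i, u_j) = \frac{f_i^\top f_j}
#'   {\|f_i - f_j\|_2^2 + f_i^\top f_j + \epsilon}}
#' is bounded: with `epsilon = 1/delta` and `delta = K/2`, it lies within
#' `[-1/(3 + epsilon), 1/(1 + epsilon)]`. The diagonal is computed by the
#' same formula. `K` is the maximum hierarchy level the similarity will be
#' mapped onto.
#'
#' @param Z numeric matrix of unit-norm row vectors (the embedding), or a
#'   `spectral_embedding` with `Z` populated.
#' @param K maximum hierarchy level (>= 1).
#' @return Symmetric n x n similarity matrix.
#' @export
tanimoto_similarity <- function(Z, K) {
  if (inherits(Z, "spectral_embedding")) {
    if (is.null(Z$Z)) abort("embedding not populated; call spectral_embed()",
      class = "hierord_error_params")
    Z <- Z$Z
  }
  if (K < 1) abort("K must be >= 1", class = "hierord_error_params")
  delta <- K / 2
  eps <- 1 / delta
  G <- Z %*% t(Z)
  sq <- rowSums(Z^2)
  dist2 <- outer(sq, sq, `+`) - 2 * G
  dist2[dist2 < 0] <- 0
  denom <- dist2 + G + eps
  if (any(denom < 1e-12)) {
    abort("similarity denominator below 1e-12",
      class = "hierord_error_degenerate_embedding"
    )
  }
  S <- G / denom
  (S + t(S)) / 2
}

#' Pseudo hierarchical distance from similarities
#'
#' The pseudo hierarchical distance
#' \deqn{\mu(u_i, u_j) = \delta - s(u_i, u_j), \qquad \delta = K/2,}
#' estimates the absolute difference in hierarchy level between two nodes:
#' similar nodes are assumed close in the hierarchy, dissimilar nodes far
#' apart. Its entries always lie strictly inside `(0, K)`.
#'
#' @param S symmetric similarity matrix from [tanimoto_similarity()].
#' @param K maximum hierarchy level.
#' @return Symmetric n x n matrix of pseudo distances.
#' @export
pseudo_distance <- function(S, K) {
  if (K < 1) abort("K must be >= 1", class = "hierord_error_params")
  K / 2 - S
}

#' Bundle similarities and pseudo distances for a graph embedding
#'
#' @inheritParams tanimoto_similarity
#' @return An object of class `distance_model` with fields `K`, `delta`,
#'   `epsilon`, `S`, `mu`, `labels`.
#' @export
distance_model <- function(Z, K) {
  labels <- if (inherits(Z, "spectral_embedding")) Z$labels else rownames(Z)
  S <- tanimoto_similarity(Z, K)
  mu <- pseudo_distance(S, K)
  labels <- labels %||% sprintf("n%d", seq_len(nrow(S)))
  dimnames(S) <- dimnames(mu) <- list(labels, labels)
  structure(
    list(K = K, delta = K / 2, epsilon = 2 / K, S = S, mu = mu,
      labels = labels),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  off <- x$mu[upper.tri(x$mu)]
  cat(sprintf(
    "<distance_model> n=%d, K=%d, mu in [%.4g, %.4g]\n",
    length(x$labels), x$K, min(off), max(off)
  ))
  invisible(x)
}

#' Sum of squared hierarchical-distance errors
#'
#' The objective being minimized when levels are assigned: over unordered
#' node pairs `i < j`,
#' \deqn{\sum_{i<j} \left( |h(u_i) - h(u_j)| - \mu(u_i, u_j) \right)^2.}
#' The diagonal is excluded (its terms are constants) and each pair is
#' counted once, which halves the symmetric double sum without moving the
#' minimizer.
#'
#' @param h numeric vector of hierarchy levels, length n.
#' @param dm a [distance_model()] or a symmetric `mu` matrix.
#' @return Nonnegative scalar.
#' @export
hierarchy_objective <- function(h, dm) {
  mu <- if (inherits(dm, "distance_model")) dm$mu else dm
  stopifnot(length(h) == nrow(mu))
  R <- abs(outer(h, h, `-`)) - mu
  sum(R[upper.tri(R)]^2)
}
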