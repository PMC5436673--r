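#' Simulate a planted-hierarchy directed graph
#'
#' Generates a directed graph whose nodes carry known hierarchy levels and
#' whose connectivity obeys the locality assumption behind pseudo
#' hierarchical distances: when information is processed in stepwise fashion,
#' direct connections between nodes far apart in the hierarchy are rare.
#' Levels are assigned deterministically by round-robin over node indices
#' (spread as evenly as possible over `{0, ..., K}`), so that only the edges
#' are random; each ordered pair `(u, v)`, `u != v`, receives a directed edge
#' independently with probability
#' \deqn{p_0 \exp(-\beta \, |h(u) - h(v)|).}
#' `beta = 0` gives a plain directed Erdos-Renyi graph; larger `beta` makes
#' the hierarchy easier to recover. Weak connectivity is enforced by
#' resampling; an error is raised if it is not reached within `max_attempts`.
#'
#' @param n number of nodes (>= 2).
#' @param K maximum hierarchy level (>= 1); levels occupy `{0, ..., K}`.
#' @param p0 base edge probability in (0, 1].
#' @param beta nonnegative decay rate of edge probability with level distance.
#' @param seed integer seed; equal seeds give identical output.
#' @param max_attempts resampling budget for weak connectivity.
#' @param require_connected enforce weak connectivity by resampling; set to
#'   `FALSE` for regimes (e.g. very large `beta`) where cross-level edges are
#'   essentially impossible and the graph is legitimately disconnected.
#' @return An object of class `planted_hierarchy`: a list with `graph`
#'   (a [directed_graph()]), `levels` (tibble `label`, `level` of the planted
#'   truth) and `params`.
#' @examples
#' ph <- simulate_hierarchy(n = 20, K = 4, p0 = 0.5, beta = 1, seed = 42)
#' ph$graph
#' table(ph$levels$level)
#' @export
simulate_hierarchy <- function(n, K, p0, beta, seed, max_attempts = 100L,
                               require_connected = TRUE) {
  if (n < 2L) abort("n must be >= 2", class = "hierord_error_params")
  if (K < 1L) abort("K must be >= 1", class = "hierord_error_params")
  if (!(p0 > 0 && p0 <= 1)) {
    abort("p0 must lie in (0, 1]", class = "hierord_error_params")
  }
  if (beta < 0) abort("beta must be >= 0", class = "hierord_error_params")
  n <- as.integer(n)
  K <- as.integer(K)

  labels <- sprintf("v%0*d", nchar(n), seq_len(n))
  lev <- (seq_len(n) - 1L) %% (K + 1L)
  prob <- p0 * exp(-beta * abs(outer(lev, lev, `-`)))
  diag(prob) <- 0

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  W <- NULL
  for (attempt in seq_len(max_attempts)) {
    cand <- matrix(as.numeric(runif(n * n) < prob), n, n)
    diag(cand) <- 0
    if (!require_connected || is_weakly_connected(cand)) {
      W <- cand
      break
    }
  }
  if (is.null(W)) {
    abort(
      sprintf(
        "no weakly connected graph in %d attempts (n=%d, K=%d, p0=%g, beta=%g); increase p0 or max_attempts",
        max_attempts, n, K, p0, beta
      ),
      class = "hierord_error_disconnected"
    )
  }
  dimnames(W) <- list(labels, labels)
  structure(
    list(
      graph = directed_graph(W),
      levels = tibble::tibble(label = labels, level = as.numeric(lev)),
      params = list(n = n, K = K, p0 = p0, beta = beta, seed = as.integer(seed))
    ),
    class = "planted_hierarchy"
  )
}

#' @export
print.planted_hierarchy <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<planted_hierarchy> n=%d K=%d p0=%g beta=%g seed=%d, %d directed edges\n",
    p$n, p$K, p$p0, p$beta, p$seed, sum(x$graph$W > 0)
  ))
  invisible(x)
}

#' Anchor the true extremes of a planted hierarchy
#'
#' Convenience for recovery experiments: fixes the first node of planted
#' level 0 at level 0 and the first node of planted level `K` at level `K`,
#' mimicking the practice of anchoring the areas whose extreme position in
#' the hierarchy is known a priori.
#'
#' @param ph a [simulate_hierarchy()] result.
#' @return A two-row anchor tibble (`label`, `level`).
#' @export
planted_anchors <- function(ph) {
  stopifnot(inherits(ph, "planted_hierarchy"))
  K <- ph$params$K
  bottom <- ph$levels$label[ph$levels$level == 0][1L]
  top <- ph$levels$label[ph$levels$level == K][1L]
  tibble::tibble(label = c(bottom, top), level = c(0, K))
}

is_weakly_connected <- function(W) {
  ig <- igraph::graph_from_adjacency_matrix(W != 0, mode = "directed")
  igraph::is_connected(ig, mode = "weak")
}

is_strongly_connected <- function(W) {
  ig <- igraph::graph_from_adjacency_matrix(W != 0, mode = "directed")
  igraph::is_connected(ig, mode = "strong")
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
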