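#' Map continuous levels onto the discrete hierarchy
#'
#' Rounds half-up to the nearest integer, then clips to `{0, ..., K}`.
#'
#' @param h numeric vector of continuous levels.
#' @param K maximum level.
#' @return Integer vector in `{0, ..., K}`.
#' @export
discretize_levels <- function(h, K) {
  stopifnot(all(is.finite(h)))
  as.integer(pmin(pmax(floor(h + 0.5), 0), K))
}

# Smoothed objective and gradient over the free coordinates. |x| is replaced
# by sqrt(x^2 + tau^2) so a quasi-Newton method sees a C^2 surface; at
# tau = 1e-6 the smoothing bias is far below the optimizer's tolerance.
make_smoothed_fns <- function(mu, h_fixed, free, tau) {
  upper <- upper.tri(mu)
  fn <- function(x) {
    h <- h_fixed
    h[free] <- x
    D <- outer(h, h, `-`)
    A <- sqrt(D^2 + tau^2)
    R <- A - mu
    sum(R[upper]^2)
  }
  gr <- function(x) {
    h <- h_fixed
    h[free] <- x
    D <- outer(h, h, `-`)
    A <- sqrt(D^2 + tau^2)
    G <- 2 * (A - mu) * D / A
    diag(G) <- 0
    rowSums(G)[free]
  }
  list(fn = fn, gr = gr)
}

# Geometric continuation schedule: anneal the smoothing width from K/3 down
# to the target tau. Heavy smoothing first washes out the spurious local
# minima created by the absolute-value kinks; each stage warm-starts the
# next. The final stage always uses tau itself.
tau_schedule <- function(K, tau) {
  s <- K / 3 * (1 / 3)^(0:8)
  unique(c(s[s > tau * 3], tau))
}

#' Assign hierarchy levels by anchored least squares
#'
#' Minimizes the sum of squared differences between the level gaps
#' `|h(u_i) - h(u_j)|` and the pseudo hierarchical distances `mu(u_i, u_j)`
#' over the box `[0, K]^n`, with the anchored nodes held fixed (removed from
#' the optimization, not penalized). The objective is nonconvex, so the
#' minimization is restarted from `restarts` seeded uniform random points;
#' restart `r` uses seed `seed + r`. The absolute value is smoothed as
#' `sqrt(x^2 + tau^2)` and each restart is solved with box-constrained
#' L-BFGS-B using the analytic gradient, under a continuation scheme: the
#' smoothing width is annealed geometrically from `K/3` down to `tau`, each
#' stage warm-starting the next, which steers the iterate past the spurious
#' local minima that the absolute-value kinks create at small `tau`. The
#' reported solution is the
#' coordinate-wise mean over the restarts whose (unsmoothed) objective is
#' within `keep_frac` of the best restart — an average of local minima, which
#' is appropriate because many distinct level assignments fit the pairwise
#' distances about equally well — re-clipped to `[0, K]` with anchors
#' re-imposed.
#'
#' @param dm a [distance_model()].
#' @param anchors anchor set (see [validate_anchors()]); at least one node.
#' @param restarts number of random restarts (>= 1).
#' @param seed integer seed; restart `r` uses `seed + r`.
#' @param tau smoothing width for the absolute value (> 0).
#' @param keep_frac restarts with objective `<= (1 + keep_frac) * best` enter
#'   the average.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return An object of class `hierarchy_fit`; see [fit_hierarchy()].
#' @export
minimize_levels <- function(dm, anchors, restarts = 50L, seed = 1L,
                            tau = 1e-6, keep_frac = 0.05, maxit = 500L) {
  stopifnot(inherits(dm, "distance_model"))
  n <- length(dm$labels)
  K <- dm$K
  g_stub <- structure(list(labels = dm$labels), class = "hierord_graph")
  anchors <- validate_anchors(anchors, g_stub, K)
  if (nrow(anchors) == 0L) {
    abort("at least one anchor is required", class = "hierord_error_anchors")
  }
  if (restarts < 1L) {
    abort("restarts must be >= 1", class = "hierord_error_params")
  }
  if (tau <= 0) abort("tau must be > 0", class = "hierord_error_params")

  anchor_idx <- match(anchors$label, dm$labels)
  free <- setdiff(seq_len(n), anchor_idx)
  h_fixed <- numeric(n)
  h_fixed[anchor_idx] <- anchors$level

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  taus <- tau_schedule(K, tau)
  fns <- lapply(taus, function(tt) make_smoothed_fns(dm$mu, h_fixed, free, tt))
  sols <- matrix(NA_real_, nrow = restarts, ncol = n)
  objs <- rep(NA_real_, restarts)
  conv <- rep(NA_integer_, restarts)
  seeds <- as.integer(seed) + seq_len(restarts)

  for (r in seq_len(restarts)) {
    h <- h_fixed
    if (length(free) > 0L) {
      set.seed(seeds[r])
      x <- runif(length(free), 0, K)
      failed <- FALSE
      for (f in fns) {
        res <- tryCatch(
          optim(x, f$fn, f$gr,
            method = "L-BFGS-B", lower = 0, upper = K,
            control = list(maxit = maxit)
          ),
          error = function(e) NULL
        )
        if (is.null(res)) {
          failed <- TRUE
          break
        }
        x <- res$par
      }
      if (failed) next
      h[free] <- x
      conv[r] <- res$convergence
    } else {
      conv[r] <- 0L
    }
    sols[r, ] <- h
    objs[r] <- hierarchy_objective(h, dm)
  }
  ok <- which(!is.na(objs))
  if (length(ok) == 0L) {
    abort("optimizer failed in every restart", class = "hierord_error_optim")
  }
  best_obj <- min(objs[ok])
  kept <- ok[objs[ok] <= (1 + keep_frac) * best_obj]
  h_avg <- colMeans(sols[kept, , drop = FALSE])
  h_avg <- pmin(pmax(h_avg, 0), K)
  h_avg[anchor_idx] <- anchors$level
  best_r <- ok[which.min(objs[ok])]

  structure(
    list(
      labels = dm$labels,
      h = setNames(h_avg, dm$labels),
      levels = setNames(discretize_levels(h_avg, K), dm$labels),
      objective = hierarchy_objective(h_avg, dm),
      best_h = setNames(sols[best_r, ], dm$labels),
      best_objective = best_obj,
      restarts = tibble::tibble(
        restart = seq_len(restarts),
        seed = seeds,
        objective = objs,
        convergence = conv,
        kept = seq_len(restarts) %in% kept
      ),
      anchors = anchors,
      params = list(
        K = K, restarts = as.integer(restarts), seed = as.integer(seed),
        tau = tau, keep_frac = keep_frac
      ),
      distance_model = dm,
      embedding = NULL
    ),
    class = "hierarchy_fit"
  )
}

#' Fit hierarchy levels for a directed graph
#'
#' End-to-end pipeline: random-walk transition matrix with teleportation,
#' Perron vector, normalized directed Laplacian, row-normalized k-dimensional
#' eigenmap, regularized Tanimoto similarities and pseudo hierarchical
#' distances, then anchored multi-restart least squares and discretization.
#' Anchors encode the partial hierarchical information available (e.g. the
#' bottom sensory area fixed at level 0, a top association area at level K).
#'
#' @inheritParams transition_matrix
#' @inheritParams minimize_levels
#' @param anchors anchor set: data frame (`label`, `level`), named numeric
#'   vector, or string `"V1=0,46=9"`.
#' @param k embedding dimension (see [suggest_parameters()]).
#' @param K maximum hierarchy level; levels live in `[0, K]`.
#' @param drop_first drop the first eigenvector from the embedding
#'   (default keeps it).
#' @return An object of class `hierarchy_fit` with continuous levels `h`,
#'   discrete `levels`, the final `objective`, per-restart records, the
#'   distance model and the spectral embedding. Use [tidy()] for a per-node
#'   tibble and [glance()] for a one-row fit summary.
#' @examples
#' ph <- simulate_hierarchy(n = 24, K = 5, p0 = 0.6, beta = 1.5, seed = 7)
#' fit <- fit_hierarchy(ph$graph, planted_anchors(ph),
#'   k = 3, K = 5, restarts = 10, seed = 7
#' )
#' tidy(fit)
#' glance(fit)
#' @export
fit_hierarchy <- function(g, anchors, k, K, eta = NULL, restarts = 50L,
                          seed = 1L, tau = 1e-6, keep_frac = 0.05,
                          drop_first = FALSE) {
  stopifnot(inherits(g, "hierord_graph"))
  se <- spectral_embedding(g, k = k, eta = eta, drop_first = drop_first)
  dm <- distance_model(se, K)
  fit <- minimize_levels(dm, validate_anchors(anchors, g, K),
    restarts = restarts, seed = seed, tau = tau, keep_frac = keep_frac
  )
  fit$embedding <- se
  fit$params$k <- as.integer(k)
  fit$params$eta <- se$eta
  fit$params$drop_first <- drop_first
  fit
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat(sprintf(
    "<hierarchy_fit> n=%d, K=%d, %d/%d restarts averaged, objective %.4f\n",
    length(x$labels), x$params$K, sum(x$restarts$kept),
    nrow(x$restarts), x$objective
  ))
  cat("anchors:", paste(sprintf("%s=%g", x$anchors$label, x$anchors$level),
    collapse = ", "), "\n")
  invisible(x)
}
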