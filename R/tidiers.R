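#' Tidy a hierarchy fit
#'
#' @param x a [fit_hierarchy()] / [minimize_levels()] result.
#' @param ... unused.
#' @return A tibble with one row per node: `label`, `h` (continuous level),
#'   `level` (discrete), `anchored`.
#' @method tidy hierarchy_fit
#' @export
tidy.hierarchy_fit <- function(x, ...) {
  tibble::tibble(
    label = x$labels,
    h = as.numeric(x$h),
    level = as.integer(x$levels),
    anchored = x$labels %in% x$anchors$label
  )
}

#' One-row summary of a hierarchy fit
#'
#' @param x a `hierarchy_fit`.
#' @param ... unused.
#' @method glance hierarchy_fit
#' @export
glance.hierarchy_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$labels),
    k = x$params$k %||% NA_integer_,
    K = x$params$K,
    eta = x$params$eta %||% NA_real_,
    n_anchors = nrow(x$anchors),
    restarts = x$params$restarts,
    kept = sum(x$restarts$kept),
    objective = x$objective,
    best_objective = x$best_objective
  )
}

#' Tidy a spectral embedding
#'
#' @param x a `spectral_embedding`.
#' @param ... unused.
#' @return A tibble with `index`, `lambda` (ascending eigenvalues) and `gap`
#'   (`lambda[i + 1] - lambda[i]`, `NA` on the last row).
#' @method tidy spectral_embedding
#' @export
tidy.spectral_embedding <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$lambdas),
    lambda = x$lambdas,
    gap = c(spectral_gaps(x), NA_real_)
  )
}

#' Spectral-gap profile plot
#'
#' Bar plot of the spectral gaps `gamma_i` against their index — the visual
#' evidence used to pick the embedding dimension and the number of hierarchy
#' levels.
#'
#' @param object a `spectral_embedding`.
#' @param ... unused.
#' @method autoplot spectral_embedding
#' @export
autoplot.spectral_embedding <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$gap), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$gap)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "gap index i",
      y = expression(gamma[i] == lambda[i + 1] - lambda[i]),
      title = "Spectral gaps of the directed Laplacian"
    ) +
    ggplot2::theme_minimal()
}

#' Hierarchy fit plot
#'
#' Without a reference: nodes arranged by continuous level. With a
#' reference level table: scatter of computed against reference levels with
#' the identity line, the standard visual check of a recovered hierarchy.
#'
#' @param object a `hierarchy_fit`.
#' @param reference optional reference level table (`label`, `level`).
#' @param ... unused.
#' @method autoplot hierarchy_fit
#' @export
autoplot.hierarchy_fit <- function(object, reference = NULL, ...) {
  df <- tidy(object)
  if (is.null(reference)) {
    df <- df[order(df$h), ]
    df$label <- factor(df$label, levels = df$label)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$label)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$anchored)) +
        ggplot2::labs(x = "continuous hierarchy level h", y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  reference <- as_level_table(reference)
  df <- dplyr::inner_join(df, reference, by = "label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level.y, y = .data$h)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$anchored)) +
    ggplot2::labs(
      x = "reference level", y = "computed level h",
      title = "Computed vs reference hierarchy"
    ) +
    ggplot2::theme_minimal()
}
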