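#' Score a computed hierarchy against a reference
#'
#' Aligns the two level tables by node label (restricting to the
#' intersection, with a message when the label sets differ) and computes the
#' Pearson correlation coefficient (PCC), mean absolute error (MAE) and root
#' mean square error (RMSE) with population (`1/n`) denominators:
#' \deqn{\mathrm{MAE} = \frac{1}{n}\sum_i |x_i - \tilde x_i|, \qquad
#'       \mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (x_i - \tilde x_i)^2}.}
#' PCC is 1 and both errors 0 when the computed levels reproduce the
#' reference exactly. When either vector is constant over the intersection
#' the PCC is undefined; the report then carries `pcc = NA` with
#' `pcc_defined = FALSE` rather than a number.
#'
#' @param reference reference level table (data frame `label`, `level` or
#'   named numeric vector), e.g. a published hierarchy model.
#' @param computed computed level table in the same form, or a
#'   `hierarchy_fit` (its continuous levels are used).
#' @param use for a `hierarchy_fit`, score the `"continuous"` (default) or
#'   `"discrete"` levels.
#' @return A one-row tibble of class `evaluation_report` with columns `n`,
#'   `pcc`, `pcc_defined`, `mae`, `rmse`.
#' @examples
#' ref <- tibble::tibble(label = c("a", "b", "c"), level = c(0, 1, 2))
#' est <- tibble::tibble(label = c("a", "b", "c"), level = c(0, 2, 2))
#' evaluate_levels(ref, est)
#' @export
evaluate_levels <- function(reference, computed,
                            use = c("continuous", "discrete")) {
  use <- match.arg(use)
  if (inherits(computed, "hierarchy_fit")) {
    computed <- tibble::tibble(
      label = computed$labels,
      level = if (use == "discrete") as.numeric(computed$levels)
              else as.numeric(computed$h)
    )
  }
  reference <- as_level_table(reference)
  computed <- as_level_table(computed)
  common <- intersect(reference$label, computed$label)
  if (length(common) < 2L) {
    abort("need at least 2 common labels to evaluate",
      class = "hierord_error_evaluate"
    )
  }
  if (length(common) < nrow(reference) || length(common) < nrow(computed)) {
    inform(sprintf(
      "evaluating on the %d labels common to both tables", length(common)
    ))
  }
  x <- reference$level[match(common, reference$label)]
  xt <- computed$level[match(common, computed$label)]
  n <- length(common)
  dx <- x - mean(x)
  dxt <- xt - mean(xt)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dxt^2))
  pcc_defined <- den > 0
  pcc <- if (pcc_defined) sum(dx * dxt) / den else NA_real_
  out <- tibble::tibble(
    n = n,
    pcc = pcc,
    pcc_defined = pcc_defined,
    mae = mean(abs(x - xt)),
    rmse = sqrt(mean((x - xt)^2))
  )
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Reference hierarchy levels of the macaque cortical systems
#'
#' The published 10-level assignment of macaque cortical areas (levels 0-9),
#' for the 32 visual areas and the 16 somatosensory-motor areas, shipped as
#' plain-text tables. These are consumed as reference data for evaluating a
#' computed hierarchy; the package does not re-derive them.
#'
#' @param system `"vision"` (32 areas) or `"somatomotor"` (16 areas).
#' @return A tibble with columns `label` and `level`.
#' @export
fv91_levels <- function(system = c("vision", "somatomotor")) {
  system <- match.arg(system)
  path <- system.file("extdata",
    paste0("fv91_", system, "_levels.tsv"),
    package = "hierord", mustWork = TRUE
  )
  read_levels(path)
}
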