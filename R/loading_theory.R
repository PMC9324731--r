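#' Residual shift induced by a task-difficulty change
#'
#' First-order effect of a perceived difficulty shift `Delta delta` on a
#' logistic fit residual: `y' = y - K(theta, delta) * Delta delta`, with `K`
#' the task-difficulty [sensitivity()]. This is the mechanism by which a
#' subgroup that experiences serial-position effects differently imprints
#' structure on the residuals.
#'
#' @param y residual value(s).
#' @param theta,delta the cell's ability and difficulty (logits).
#' @param delta_shift the difficulty change `Delta delta` (logits).
#' @return Shifted residual(s).
#' @export
shifted_residual <- function(y, theta, delta, delta_shift) {
  y - sensitivity(theta, delta) * delta_shift
}

#' Cohort ability distribution
#'
#' Normal model for the spread of person ability across the cohort,
#' `p(theta) = N(mean, sd^2)`. Defaults match a memory-clinic style cohort
#' centred slightly below the item difficulties: mean -0.6, sd 1.0 logits.
#'
#' @param mean mean ability (logits).
#' @param sd ability standard deviation (logits), > 0.
#' @return List of class `ability_distribution`.
#' @export
ability_distribution <- function(mean = -0.6, sd = 1.0) {
  if (!is.finite(sd) || sd <= 0)
    stop_cserecall("cserecall_parameter_error", "sd must be > 0")
  structure(list(mean = mean, sd = sd), class = "ability_distribution")
}

#' Cohort-averaged task-difficulty sensitivity
#'
#' Numerically integrates the Rasch sensitivity over the cohort ability
#' distribution: `E[K] = integral p(theta) * dP/d delta dtheta`. Always in
#' (-0.25, 0); largest in magnitude when the item difficulty sits at the
#' cohort mean ability, symmetric in `delta - mean`, and approaching the
#' point value -0.25 as `sd -> 0` at `delta = mean`. Adaptive quadrature
#' over `mean +/- 8 sd` at absolute tolerance `abs_tol`.
#'
#' @param delta item difficulty (logits); vectorized.
#' @param dist an [ability_distribution()].
#' @param abs_tol absolute quadrature tolerance.
#' @return Expected sensitivity value(s).
#' @examples
#' integrated_sensitivity(-0.6, ability_distribution(-0.6, 1))
#' @export
integrated_sensitivity <- function(delta, dist = ability_distribution(),
                                   abs_tol = 1e-8) {
  stopifnot(inherits(dist, "ability_distribution"))
  vapply(delta, function(d) {
    r <- tryCatch(
      stats::integrate(function(th) dnorm(th, dist$mean, dist$sd) *
                         sensitivity(th, d),
                       lower = dist$mean - 8 * dist$sd,
                       upper = dist$mean + 8 * dist$sd,
                       abs.tol = abs_tol),
      error = function(e) stop_cserecall(
        "cserecall_numeric_error",
        paste("quadrature failed:", conditionMessage(e))))
    r$value
  }, numeric(1))
}

#' Theoretical prediction of residual-contrast loadings
#'
#' Predicts, up to a common proportionality constant, the loading of each
#' item on a residual-PCA contrast induced by a serial-position difficulty
#' shift: `L_j proportional to a_x * Delta delta_x * E[K](delta_j)`, where
#' `a_x` is the PCA1 loading of the explanatory variable governing item
#' `j`'s region (primacy coefficient for Pr items, recency for Rr; mid-list
#' items take shift 0 unless one is supplied), `Delta delta_x` is the
#' region's perceived difficulty shift, and `E[K]` the cohort-averaged
#' sensitivity at the item's difficulty. Predictions are exactly linear in
#' both `a_x` and `Delta delta_x`, vanish where either is zero, and peak for
#' items targeted nearest the cohort mean ability. An optional least-squares
#' rescaling against an empirical loading vector is provided for overlay
#' plots; the raw proportional values are always retained.
#'
#' @param pca1 a [pca_explanatory()] result (its PC`component` loadings
#'   supply `a_x`).
#' @param design the [word_list_design()] giving each item's region.
#' @param delta per-item difficulties (logits).
#' @param delta_shift named shifts in logits, e.g.
#'   `c(primacy = 2, recency = 2)`; unnamed regions get 0. Sign is the
#'   user's: +2 models a subgroup for whom those items are effectively
#'   harder, -2 easier.
#' @param dist an [ability_distribution()].
#' @param component which PCA1 component's coefficients to use (default 1).
#' @param rescale_to optional empirical loading vector (length = items); the
#'   returned `loading_scaled` column minimizes the squared difference over
#'   items with nonzero prediction.
#' @return Data frame of class `loading_prediction`: `item`, `region`,
#'   `variable`, `a`, `delta_shift`, `int_sensitivity`, `loading_raw`, and
#'   `loading_scaled` when `rescale_to` is given.
#' @export
predict_loadings <- function(pca1, design, delta,
                             delta_shift = c(primacy = 2, recency = 2),
                             dist = ability_distribution(), component = 1,
                             rescale_to = NULL) {
  if (!inherits(pca1, "pca1_result"))
    stop_cserecall("cserecall_dependency_error",
                   "pca1 must be a pca_explanatory() result")
  stopifnot(inherits(design, "word_list_design"),
            length(delta) == design$L)
  region_var <- c(Pr = "primacy", Mr = "middle", Rr = "recency")
  vars <- region_var[design$items$region]
  a <- ifelse(vars %in% rownames(pca1$loadings),
              pca1$loadings[match(vars, rownames(pca1$loadings)), component],
              0)
  dd <- ifelse(vars %in% names(delta_shift), delta_shift[vars], 0)
  ek <- integrated_sensitivity(delta, dist)
  raw <- a * dd * ek
  out <- data.frame(item = seq_len(design$L), region = design$items$region,
                    variable = unname(vars), a = unname(a),
                    delta_shift = unname(dd), int_sensitivity = ek,
                    loading_raw = unname(raw), stringsAsFactors = FALSE)
  if (!is.null(rescale_to)) {
    stopifnot(length(rescale_to) == design$L)
    nz <- raw != 0 & is.finite(rescale_to)
    s <- if (any(nz)) sum(raw[nz] * rescale_to[nz]) / sum(raw[nz]^2) else 1
    out$loading_scaled <- raw * s
    attr(out, "scale_factor") <- s
  }
  class(out) <- c("loading_prediction", "data.frame")
  out
}
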