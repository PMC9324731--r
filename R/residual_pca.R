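#' Principal contrasts of standardized Rasch residuals (PCA2)
#'
#' Multidimensionality diagnostic: after a Rasch fit has absorbed the single
#' intended dimension, any surviving shared structure among item residuals
#' suggests a secondary dimension (here, serial-position effects experienced
#' differently across the cohort). Performs an eigendecomposition of the
#' item-by-item Pearson correlation matrix of standardized residuals
#' (pairwise-complete over persons); each component is a "contrast" whose
#' eigenvalue is expressed in item units (eigenvalues sum to the number of
#' retained items). A first-contrast eigenvalue clearly above ~2 items is
#' conventionally taken as more structure than chance. Items are grouped
#' into clusters by their contrast-1 loadings.
#'
#' @param residuals persons-by-items matrix from [standardized_residuals()].
#' @param delta optional item difficulties; used only to fix the loading
#'   sign so the highest-difficulty item loads non-negatively on contrast 1
#'   (default: first item non-negative).
#' @param n_clusters number of loading clusters (default 3: the two
#'   serial-position ends and the mid list).
#' @return An object of class `residual_contrasts`: `loadings` (items x
#'   contrasts), `eigenvalues` (item units), `variance_fraction`, `clusters`
#'   (integer per item, ordered by decreasing contrast-1 loading),
#'   `items_kept`, `n_persons`.
#' @export
residual_contrasts <- function(residuals, delta = NULL, n_clusters = 3) {
  y <- as.matrix(residuals)
  if (ncol(y) < 2)
    stop_cserecall("cserecall_degenerate_pca", "need at least 2 items")
  if (ncol(y) < 3)
    warning("fewer than 3 items: contrasts are of limited meaning")
  v <- apply(y, 2, stats::var, na.rm = TRUE)
  keep <- is.finite(v) & v > 1e-12
  if (any(!keep))
    warning("excluding ", sum(!keep), " item(s) with zero residual variance")
  y <- y[, keep, drop = FALSE]
  R <- stats::cor(y, use = "pairwise.complete.obs")
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  rownames(V) <- colnames(y)
  colnames(V) <- paste0("contrast", seq_len(ncol(V)))
  anchor <- if (!is.null(delta)) which.max(delta[keep]) else 1L
  for (kk in seq_len(ncol(V)))
    if (V[anchor, kk] < 0) V[, kk] <- -V[, kk]
  cl <- cut(rank(-V[, 1], ties.method = "first"),
            breaks = n_clusters, labels = FALSE)
  structure(list(loadings = V, eigenvalues = e$values,
                 variance_fraction = e$values / sum(e$values),
                 clusters = stats::setNames(cl, colnames(y)),
                 items_kept = which(keep), n_persons = nrow(y)),
            class = "residual_contrasts")
}

#' @export
print.residual_contrasts <- function(x, ...) {
  cat("Residual PCA (PCA2):", length(x$eigenvalues), "items,",
      x$n_persons, "persons\n")
  cat(sprintf("  first-contrast eigenvalue: %.2f items (%.0f%% of unexplained variance)\n",
              x$eigenvalues[1], 100 * x$variance_fraction[1]))
  cat("  contrast-1 loadings:\n")
  print(round(x$loadings[, 1], 2))
  invisible(x)
}

#' Observed-variance decomposition for the Rasch fit
#'
#' Splits the total variance of the observations into the part explained by
#' the Rasch measures — further separated into person, item, and
#' person-item (interaction) components of the fitted probabilities — and
#' the model-unexplained (binomial residual) part, which is attributed to
#' the residual contrasts in proportion to their eigenvalues. All fractions
#' sum to 1. The headline diagnostic numbers are the raw variance explained
#' by the item measures and the share of unexplained variance carried by the
#' first contrast.
#'
#' @param data the fitted [response_matrix()] (or matrix).
#' @param fit the [fit_rasch()] result.
#' @param contrasts a [residual_contrasts()] result on the same fit.
#' @return An object of class `rasch_variance_table`: list with `fractions`
#'   (named: persons, items, person_item, one entry per contrast), plus
#'   `explained_fraction`, `items_fraction`, `first_contrast_fraction`.
#' @export
variance_decomposition <- function(data, fit, contrasts) {
  x <- as_response_mat(data)
  stopifnot(inherits(fit, "rasch_fit"), inherits(contrasts, "residual_contrasts"))
  ok_p <- is.finite(fit$theta); ok_i <- is.finite(fit$delta)
  P <- plogis(outer(fit$theta[ok_p], fit$delta[ok_i], "-"))
  obs <- !is.na(x[ok_p, ok_i, drop = FALSE])
  P[!obs] <- NA
  # explained: spread of the modelled probabilities (two-way ANOVA of P)
  grand <- mean(P, na.rm = TRUE)
  rowm <- rowMeans(P, na.rm = TRUE); colm <- colMeans(P, na.rm = TRUE)
  ss_row <- sum((rowm - grand)^2 * rowSums(obs))
  ss_col <- sum((colm - grand)^2 * colSums(obs))
  ss_tot <- sum((P - grand)^2, na.rm = TRUE)
  ss_int <- max(ss_tot - ss_row - ss_col, 0)
  # unexplained: expected binomial residual sum of squares
  ss_unexp <- sum(P * (1 - P), na.rm = TRUE)
  total <- ss_tot + ss_unexp
  ev <- contrasts$eigenvalues / sum(contrasts$eigenvalues)
  fr <- c(persons = ss_row, items = ss_col, person_item = ss_int) / total
  fr_contrasts <- stats::setNames(ev * ss_unexp / total,
                                  paste0("contrast", seq_along(ev)))
  structure(list(
    fractions = c(fr, fr_contrasts),
    explained_fraction = ss_tot / total,
    items_fraction = unname(fr["items"]),
    first_contrast_fraction = unname(fr_contrasts[1])
  ), class = "rasch_variance_table")
}

#' @export
print.rasch_variance_table <- function(x, ...) {
  cat("Variance decomposition (fractions of total observed variance):\n")
  f <- x$fractions
  show <- c(f[c("persons", "items", "person_item")],
            f[grep("^contrast[12]$", names(f))])
  for (nm in names(show)) cat(sprintf("  %-14s %5.1f%%\n", nm, 100 * show[nm]))
  cat(sprintf("  (explained by measures %.1f%%, unexplained %.1f%%)\n",
              100 * x$explained_fraction, 100 * (1 - x$explained_fraction)))
  invisible(x)
}

#' Disattenuated correlation between two sets of person measures
#'
#' Correlation corrected for measurement unreliability:
#' `corr(A, B) / sqrt(R_A * R_B)`, clipped to \[-1, 1\] (with a flag) when
#' the correction overshoots. A disattenuated correlation near +/-1 says the
#' two item clusters measure one dimension; a low magnitude says two.
#'
#' @param a,b paired person measures (e.g. from per-cluster Rasch fits).
#' @param rel_a,rel_b their separation reliabilities, in (0, 1].
#' @return List: `value`, `raw` (uncorrected and unclipped disattenuated
#'   value), `observed` correlation, `clipped` flag.
#' @examples
#' disattenuated_correlation(c(1, 2, 3), c(3, 2.5, 1), 0.5, 0.5)
#' @export
disattenuated_correlation <- function(a, b, rel_a, rel_b) {
  if (rel_a <= 0 || rel_b <= 0 || rel_a > 1 || rel_b > 1)
    stop_cserecall("cserecall_parameter_error",
                   "reliabilities must be in (0, 1]")
  ok <- is.finite(a) & is.finite(b)
  obs <- stats::cor(a[ok], b[ok])
  raw <- obs / sqrt(rel_a * rel_b)
  val <- min(max(raw, -1), 1)
  list(value = val, raw = raw, observed = obs, clipped = !isTRUE(all.equal(raw, val)))
}

#' Person measures from an item cluster
#'
#' Refits the Rasch model on a subset of items (e.g. one residual-PCA
#' cluster) and returns the person measures with their separation
#' reliability — the ingredients of [disattenuated_correlation()]. Small
#' clusters give few degrees of freedom and hence poor reliability; this is
#' reported, not treated as an error.
#'
#' @param data a [response_matrix()] or matrix.
#' @param items item indices of the cluster.
#' @param control a [rasch_control()].
#' @return List: `theta`, `se`, `reliability`, `items`.
#' @export
cluster_person_measures <- function(data, items, control = rasch_control()) {
  x <- as_response_mat(data)
  check_item_index(items, ncol(x))
  fit <- fit_rasch(x[, items, drop = FALSE], control = control)
  list(theta = fit$theta, se = fit$theta_se,
       reliability = separation_reliability(fit$theta, fit$theta_se),
       items = items)
}

#' Multidimensionality decision checklist
#'
#' Assembles the conventional residual-PCA decision aids into one report:
#' (1) the ratio of raw variance explained by the item measures to the
#' unexplained variance in the first contrast — is it big enough to be a
#' concern? (2) the first-contrast eigenvalue against the ~2-item chance
#' threshold — is the secondary dimension bigger than chance? (3) the
#' vertical separation of the loading clusters — does the secondary
#' dimension have substance?
#'
#' @param contrasts a [residual_contrasts()] result.
#' @param variance the matching [variance_decomposition()] result.
#' @param eigen_threshold chance threshold in item units (default 2.0).
#' @return An object of class `linacre_checklist`: per-check list with the
#'   underlying numbers and a `flag` (TRUE = evidence of multidimensionality
#'   on that check).
#' @export
linacre_checklist <- function(contrasts, variance, eigen_threshold = 2.0) {
  stopifnot(inherits(contrasts, "residual_contrasts"),
            inherits(variance, "rasch_variance_table"))
  l1 <- contrasts$loadings[, 1]
  cl <- contrasts$clusters
  spread <- if (length(unique(cl)) >= 2) {
    mn <- tapply(l1, cl, mean)
    max(mn) - min(mn)
  } else NA_real_
  n_items <- length(contrasts$eigenvalues)
  checks <- list(
    variance_ratio = list(
      items_explained = variance$items_fraction,
      first_contrast_unexplained = variance$first_contrast_fraction,
      ratio = variance$items_fraction / variance$first_contrast_fraction,
      flag = variance$items_fraction < 2 * variance$first_contrast_fraction
    ),
    eigenvalue = list(
      value = contrasts$eigenvalues[1], threshold = eigen_threshold,
      flag = contrasts$eigenvalues[1] >= eigen_threshold
    ),
    clusters = list(
      n_clusters = length(unique(cl)), loading_spread = spread,
      sufficient_items = n_items > 2,
      flag = is.finite(spread) && spread > 0.5 && n_items > 2
    )
  )
  structure(list(checks = checks,
                 note = if (n_items <= 2)
                   "too few items for a meaningful secondary contrast" else NULL),
            class = "linacre_checklist")
}

#' @export
print.linacre_checklist <- function(x, ...) {
  ck <- x$checks
  cat("Multidimensionality checklist:\n")
  cat(sprintf("  1. items-explained %.1f%% vs first-contrast unexplained %.1f%% (ratio %.1f) -> %s\n",
              100 * ck$variance_ratio$items_explained,
              100 * ck$variance_ratio$first_contrast_unexplained,
              ck$variance_ratio$ratio,
              if (ck$variance_ratio$flag) "FLAG" else "ok"))
  cat(sprintf("  2. first-contrast eigenvalue %.2f vs threshold %.1f -> %s\n",
              ck$eigenvalue$value, ck$eigenvalue$threshold,
              if (ck$eigenvalue$flag) "FLAG" else "ok"))
  cat(sprintf("  3. %d clusters, contrast-1 loading spread %.2f -> %s\n",
              ck$clusters$n_clusters, ck$clusters$loading_spread,
              if (ck$clusters$flag) "FLAG" else "ok"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
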