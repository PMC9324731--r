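comparable_columns <- c("primacy", "recency", "frequency")

# extract the variable (non-constant) explanatory columns as a plain matrix
explanatory_vars <- function(X, drop_constant = TRUE) {
  Xd <- as.data.frame(X)
  cols <- intersect(c(comparable_columns, "middle"), names(Xd))
  m <- as.matrix(Xd[, cols, drop = FALSE])
  if (drop_constant) {
    v <- apply(m, 2, stats::var)
    m <- m[, v > 1e-12, drop = FALSE]
  }
  m
}

#' Pairwise Pearson correlations of the explanatory variables
#'
#' The primacy and recency log-factorial variables are strongly negatively
#' correlated by construction (for the 15-item list, r = -0.94); frequency
#' is only weakly related to either.
#'
#' @param X an [explanatory_matrix()] (or data frame with `primacy`,
#'   `recency`, `frequency` columns).
#' @return Correlation matrix of the non-constant explanatory variables.
#' @export
explanatory_correlations <- function(X) {
  m <- explanatory_vars(X)
  if (nrow(m) < 3)
    stop_cserecall("cserecall_degenerate_pca", "need at least 3 items")
  stats::cor(m)
}

#' PCA of the explanatory variables (PCA1)
#'
#' Eigendecomposition of the covariance matrix of the centered,
#' unstandardized explanatory variables — the first step of the principal
#' component regression behind a construct specification equation. The
#' constant mid-range column carries zero variance and is excluded (it is
#' absorbed into the regression intercept). Unstandardized covariance PCA is
#' the default because the variables already share the logit unit; a
#' correlation-matrix mode is available. Component signs are fixed so the
#' first variable's (primacy) loading on PC1 is positive and each later
#' component's largest-magnitude loading is positive.
#'
#' @param X an [explanatory_matrix()].
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return An object of class `pca1_result`: list with `loadings` (variables
#'   x components), `eigenvalues`, `variance_fraction`, `center`, `mode`.
#' @examples
#' p <- pca_explanatory(explanatory_matrix(word_list_design(15)))
#' round(p$loadings[, 1], 2)
#' @export
pca_explanatory <- function(X, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  m <- explanatory_vars(X)
  if (nrow(m) < 2 || ncol(m) < 1)
    stop_cserecall("cserecall_degenerate_pca",
                   "need >= 2 items and >= 1 variable with nonzero variance")
  S <- if (mode == "covariance") stats::cov(m) else stats::cor(m)
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  rownames(V) <- colnames(m)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  for (kk in seq_len(ncol(V))) {
    pivot <- if (kk == 1L) 1L else which.max(abs(V[, kk]))
    if (V[pivot, kk] < 0) V[, kk] <- -V[, kk]
  }
  structure(list(loadings = V,
                 eigenvalues = e$values,
                 variance_fraction = e$values / sum(e$values),
                 center = colMeans(m), mode = mode),
            class = "pca1_result")
}

#' @export
print.pca1_result <- function(x, ...) {
  cat("PCA of explanatory variables (", x$mode, " mode)\n", sep = "")
  cat("Eigenvalues:", paste(signif(x$eigenvalues, 3), collapse = ", "), "\n")
  print(round(x$loadings, 2))
  invisible(x)
}

# value/uncertainty formatter in metrology style: U to 1 significant figure,
# value rounded to the same place, e.g. +5(3), +0.7(5)
format_uncertain <- function(value, U) {
  mapply(function(v, u) {
    if (!is.finite(u) || u <= 0) return(sprintf("%+.3g", v))
    dec <- max(0, -floor(log10(u)))
    u1 <- signif(u, 1)
    sprintf("%+.*f(%s)", dec, round(v, dec),
            sub("^0\\.0*", "", format(u1, scientific = FALSE)))
  }, value, U)
}

#' Construct specification equation by principal component regression
#'
#' Fits a construct specification equation (CSE) for item difficulty: the
#' empirical Rasch difficulties `delta` are regressed on the leading
#' principal components of the explanatory variables, and the component
#' coefficients are mapped back to the original variables, giving
#' `z_R = beta0 + beta_Pr*Primacy + beta_Rr*Recency + beta_f*Frequency`.
#' With all components retained this is identically ordinary least squares.
#' Coefficient uncertainty combines, in quadrature, the regression
#' (modelling) standard errors with the measurement uncertainty `U_delta` of
#' the input difficulties propagated through the same linear estimator; both
#' the fitted values and their propagated uncertainties are reported with
#' coverage factor `k = 2`.
#'
#' @param delta empirical item difficulties (logits), one per item.
#' @param X the matching [explanatory_matrix()].
#' @param n_components number of principal components retained (default:
#'   all, reproducing OLS).
#' @param U_delta optional expanded (`k = 2`) uncertainties of `delta`.
#' @param pca_mode passed to [pca_explanatory()].
#' @return An object of class `cse_model`: coefficients (`intercept`,
#'   `beta`), their `k = 2` uncertainties (`intercept_U`, `beta_U`), fitted
#'   `z_R` with `U_zR`, Pearson `R` against `delta`, the retained component
#'   count, residual sd, and the full combined coefficient covariance.
#' @examples
#' t1 <- load_table1_fixture()
#' m <- fit_cse(t1$delta, t1$X, U_delta = t1$U_delta)
#' print(m)
#' @export
fit_cse <- function(delta, X, n_components = NULL, U_delta = NULL,
                    pca_mode = "covariance") {
  m <- explanatory_vars(X)
  n <- nrow(m); K <- ncol(m)
  stopifnot(length(delta) == n)
  if (is.null(n_components)) n_components <- K
  if (n_components < 1 || n_components > K)
    stop_cserecall("cserecall_parameter_error",
                   sprintf("n_components must be in 1..%d", K))
  if (n <= n_components + 1)
    stop_cserecall("cserecall_parameter_error",
                   "item count must exceed retained components + 1")
  pca <- pca_explanatory(X, mode = pca_mode)
  V <- pca$loadings[, seq_len(n_components), drop = FALSE]
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  if (pca$mode == "correlation") {
    sds <- apply(m, 2, stats::sd)
    mc <- sweep(mc, 2, sds, "/")
  }
  S <- mc %*% V                        # component scores, centered
  StS <- crossprod(S)
  if (min(diag(StS)) < 1e-12)
    stop_cserecall("cserecall_degenerate_regression",
                   "rank-deficient scores after centering")
  G <- solve(StS, t(S))                # gamma = G %*% delta
  gamma <- drop(G %*% delta)
  B_slope <- V %*% G                   # beta = B_slope %*% delta (on scaled X)
  if (pca$mode == "correlation") B_slope <- B_slope / sds
  beta <- drop(B_slope %*% delta)
  B0 <- rep(1 / n, n) - drop(crossprod(ctr, B_slope))
  intercept <- sum(B0 * delta)
  B <- rbind(intercept = B0, B_slope)  # (K+1) x n linear estimator

  fitted <- intercept + drop(m %*% beta)
  resid <- delta - fitted
  dof <- n - n_components - 1
  sigma2 <- sum(resid^2) / dof
  cov_model <- sigma2 * tcrossprod(B)
  if (!is.null(U_delta)) {
    stopifnot(length(U_delta) == n)
    u <- U_delta / 2                   # expanded k=2 -> standard
    cov_meas <- B %*% (u^2 * t(B))
  } else cov_meas <- 0 * cov_model
  cov_comb <- cov_model + cov_meas
  U_coef <- 2 * sqrt(pmax(diag(cov_comb), 0))
  Z <- cbind(1, m)
  U_zR <- 2 * sqrt(pmax(rowSums((Z %*% cov_comb) * Z), 0))

  structure(list(
    intercept = intercept, beta = stats::setNames(beta, colnames(m)),
    intercept_U = U_coef[1],
    beta_U = stats::setNames(U_coef[-1], colnames(m)),
    z_R = fitted, U_zR = U_zR, residuals = resid,
    R = stats::cor(delta, fitted),
    n_components = n_components, sigma = sqrt(sigma2),
    coef_cov = cov_comb, pca = pca, delta = delta,
    U_delta = U_delta
  ), class = "cse_model")
}

#' @export
print.cse_model <- function(x, ...) {
  terms <- c(format_uncertain(x$intercept, x$intercept_U),
             paste0(format_uncertain(x$beta, x$beta_U), "·",
                    names(x$beta)))
  cat("CSE (PCR,", x$n_components, "components):\n")
  cat("  z_R =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  Pearson R(delta, z_R) = %.2f, residual sd = %.2f logits\n",
              x$R, x$sigma))
  invisible(x)
}

#' Per-item contributions of each CSE term
#'
#' Splits each fitted difficulty into intercept plus one `beta_k * X_k` term
#' per explanatory variable; rows sum to `z_R` exactly.
#'
#' @param model a [fit_cse()] result.
#' @param X the [explanatory_matrix()] used in the fit.
#' @return Data frame: `item`, `intercept`, one column per variable term,
#'   `z_R`.
#' @export
cse_contributions <- function(model, X) {
  stopifnot(inherits(model, "cse_model"))
  m <- explanatory_vars(X)
  terms <- sweep(m, 2, model$beta, "*")
  colnames(terms) <- paste0(colnames(m), "_term")
  out <- data.frame(item = seq_len(nrow(m)), intercept = model$intercept,
                    terms, z_R = model$intercept + rowSums(terms))
  rownames(out) <- NULL
  out
}

#' Subgroup construct specification equations
#'
#' Independently fits one CSE per group of empirical difficulties over the
#' same items and explanatory variables, for side-by-side comparison of
#' intercepts (interpreted as twice the mid-range difficulty) and
#' serial-position coefficients across, e.g., clinical subgroups.
#'
#' @param delta_by_group named list of difficulty vectors (same length).
#' @param X the common [explanatory_matrix()].
#' @param n_components,U_delta_by_group,pca_mode per-fit settings;
#'   `U_delta_by_group` may be a named list parallel to `delta_by_group`.
#' @return An object of class `cse_group_models`: named list of
#'   [fit_cse()] results with a comparison `print()` method.
#' @export
subgroup_cse <- function(delta_by_group, X, n_components = NULL,
                         U_delta_by_group = NULL, pca_mode = "covariance") {
  stopifnot(is.list(delta_by_group), length(delta_by_group) >= 1)
  out <- lapply(names(delta_by_group), function(g) {
    fit_cse(delta_by_group[[g]], X, n_components = n_components,
            U_delta = U_delta_by_group[[g]], pca_mode = pca_mode)
  })
  names(out) <- names(delta_by_group)
  class(out) <- "cse_group_models"
  out
}

#' @export
print.cse_group_models <- function(x, ...) {
  cat("Construct specification equations by group:\n")
  for (g in names(x)) {
    m <- x[[g]]
    terms <- c(format_uncertain(m$intercept, m$intercept_U),
               paste0(format_uncertain(m$beta, m$beta_U), "·",
                      names(m$beta)))
    cat(sprintf("  %-8s z_R = %s   [R = %.2f]\n", g,
                paste(terms, collapse = " "), m$R))
  }
  invisible(x)
}
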