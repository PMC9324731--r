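#' Binary response matrix container
#'
#' Wraps a persons-by-items 0/1 matrix (NA = missing) with person
#' identifiers and optional clinical-group labels.
#'
#' @param x numeric/integer matrix of 0/1 responses (NA allowed).
#' @param persons person identifiers (default `P1..Pn`); must be unique.
#' @param groups optional group label per person (e.g. HC/SCD/MCI/AD).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(x, persons = NULL, groups = NULL) {
  x <- as.matrix(x)
  bad <- which(!(is.na(x) | x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_cserecall("cserecall_format_error",
                   sprintf("non-binary cell at row %d, column %d: %s",
                           bad[1, 1], bad[1, 2], x[bad[1, 1], bad[1, 2]]))
  storage.mode(x) <- "integer"
  if (is.null(persons)) persons <- paste0("P", seq_len(nrow(x)))
  if (anyDuplicated(persons))
    stop_cserecall("cserecall_format_error", "duplicate person identifiers")
  if (!is.null(groups) && length(groups) != nrow(x))
    stop_cserecall("cserecall_format_error", "groups must have one label per person")
  rownames(x) <- as.character(persons)
  if (is.null(colnames(x))) colnames(x) <- paste0("I", seq_len(ncol(x)))
  structure(list(x = x, persons = as.character(persons), groups = groups),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$x), "persons x", ncol(x$x), "items;",
      sum(is.na(x$x)), "missing cells\n")
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("Groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

as_response_mat <- function(data) {
  if (inherits(data, "response_matrix")) data$x else as.matrix(data)
}

#' Rasch model response probability and sensitivity
#'
#' For the dichotomous Rasch model the log-odds of success equal person
#' ability minus item difficulty: `P = exp(theta - delta)/(1 + exp(theta - delta))`.
#' The task-difficulty sensitivity is its derivative
#' `K = dP/d delta = -exp(theta - delta)/(1 + exp(theta - delta))^2 = -P(1-P)`,
#' a "resonance" curve peaking at -0.25 where `theta = delta` and falling off
#' symmetrically to zero at either end of the scale.
#'
#' @param theta person ability (logits).
#' @param delta item difficulty (logits).
#' @return `success_probability`: probability in (0,1).
#'   `sensitivity`: probability change per logit of difficulty, in (-0.25, 0].
#' @examples
#' success_probability(0, 0) # 0.5
#' sensitivity(0, 0)         # -0.25
#' @export
success_probability <- function(theta, delta) plogis(theta - delta)

#' @rdname success_probability
#' @export
sensitivity <- function(theta, delta) {
  p <- plogis(theta - delta)
  -p * (1 - p)
}

#' Estimation settings for the Rasch fit
#'
#' @param tol convergence tolerance: maximum absolute parameter change, in
#'   logits, below which iteration stops.
#' @param max_iter maximum number of alternating Newton sweeps.
#' @param bias_correction apply the `(L-1)/L` shrinkage to item difficulties
#'   (classical JMLE bias correction). Off by default: at the list lengths
#'   and cohort sizes targeted here the correction is far below the reported
#'   measurement uncertainties.
#' @param extreme_adjust score-unit adjustment applied to zero/perfect raw
#'   scores so a finite (flagged) estimate can be reported; `NULL` (default)
#'   leaves extreme persons/items unestimated.
#' @param max_step Newton step clamp in logits, guards early oscillation.
#' @return A list of class `rasch_control`.
#' @export
rasch_control <- function(tol = 1e-4, max_iter = 200, bias_correction = FALSE,
                          extreme_adjust = NULL, max_step = 1) {
  stopifnot(tol > 0, max_iter >= 1, max_step > 0)
  structure(list(tol = tol, max_iter = max_iter,
                 bias_correction = bias_correction,
                 extreme_adjust = extreme_adjust, max_step = max_step),
            class = "rasch_control")
}

#' Joint maximum-likelihood Rasch estimation
#'
#' Estimates person abilities `theta_i` and item difficulties `delta_j` of
#' the dichotomous Rasch model by joint maximum likelihood (JMLE):
#' alternating damped Newton updates of the person and item parameters until
#' the largest parameter change falls below `control$tol`. Identification is
#' by centering: estimated item difficulties have mean exactly zero over
#' non-extreme items; person abilities are free. Standard uncertainties come
#' from the observed information, `u = 1/sqrt(sum P(1-P))` over the cells
#' entering each parameter's likelihood. Persons or items with all-0 or
#' all-1 observed responses carry no finite MLE; they are flagged and
#' excluded from estimation (or, with `extreme_adjust`, estimated from an
#' adjusted raw score and still flagged). Missing cells are skipped in all
#' sums.
#'
#' @param data a [response_matrix()] or plain 0/1 matrix (rows = persons).
#' @param control a [rasch_control()].
#' @return An object of class `rasch_fit`: list with `theta`, `theta_se`,
#'   `delta`, `delta_se`, logical flags `person_extreme`, `item_extreme`,
#'   `convergence` (iterations, final max change, converged), and cohort
#'   summary `theta_mean`, `theta_sd` over non-extreme persons.
#' @examples
#' set.seed(1)
#' x <- simulate_cohort(cohort_spec(n = 80), seed = 1)$responses
#' fit <- fit_rasch(x)
#' round(fit$delta, 2)
#' @export
fit_rasch <- function(data, control = rasch_control()) {
  x <- as_response_mat(data)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop_cserecall("cserecall_degenerate_data",
                   "need at least 2 persons and 2 items")
  obs <- !is.na(x)
  vals <- x[obs]
  if (all(vals == vals[1]))
    stop_cserecall("cserecall_degenerate_data", "all responses are identical")

  n_row <- rowSums(obs); n_col <- colSums(obs)
  rs <- rowSums(x, na.rm = TRUE); cs <- colSums(x, na.rm = TRUE)
  p_ext <- rs == 0 | rs == n_row | n_row == 0
  i_ext <- cs == 0 | cs == n_col | n_col == 0
  adj <- control$extreme_adjust
  if (!is.null(adj)) {
    est_p <- n_row > 0; est_i <- n_col > 0
  } else {
    # a parameter can become effectively extreme once its extreme
    # counterparts are dropped, so iterate the exclusion to a fixed point
    est_p <- !p_ext; est_i <- !i_ext
    repeat {
      xs <- x; xs[!obs] <- 0L
      cs_u <- colSums(xs[est_p, , drop = FALSE])
      nc_u <- colSums(obs[est_p, , drop = FALSE])
      est_i2 <- est_i & cs_u > 0 & cs_u < nc_u & nc_u > 0
      rs_u <- rowSums(xs[, est_i2, drop = FALSE])
      nr_u <- rowSums(obs[, est_i2, drop = FALSE])
      est_p2 <- est_p & rs_u > 0 & rs_u < nr_u & nr_u > 0
      if (identical(est_p2, est_p) && identical(est_i2, est_i)) break
      est_p <- est_p2; est_i <- est_i2
      if (!any(est_p) || !any(est_i)) break
    }
    p_ext <- !est_p; i_ext <- !est_i
  }
  if (!any(est_p) || !any(est_i))
    stop_cserecall("cserecall_degenerate_data",
                   "no non-extreme persons or items to estimate")
  # cells entering the likelihood: observed, both parameters estimated
  use <- obs & outer(est_p, est_i, "&")
  xs <- x; xs[!use] <- 0L
  rs_a <- rowSums(xs); cs_a <- colSums(xs)
  nr_a <- rowSums(use); nc_a <- colSums(use)
  if (!is.null(adj)) {
    rs_a <- pmin(pmax(rs_a, adj), nr_a - adj)
    cs_a <- pmin(pmax(cs_a, adj), nc_a - adj)
  }

  # PROX-style start values from logit-transformed raw scores
  theta <- qlogis(pmin(pmax(rs_a / pmax(nr_a, 1), 0.02), 0.98))
  delta <- -qlogis(pmin(pmax(cs_a / pmax(nc_a, 1), 0.02), 0.98))
  delta[est_i] <- delta[est_i] - mean(delta[est_i])
  theta[!est_p] <- NA_real_; delta[!est_i] <- NA_real_

  th <- ifelse(is.na(theta), 0, theta); de <- ifelse(is.na(delta), 0, delta)
  converged <- FALSE; change <- Inf; it <- 0L
  # block coordinate ascent: given the other block, each parameter solves an
  # independent 1-D concave problem, so iterate Newton within the block
  for (it in seq_len(control$max_iter)) {
    th0 <- th; de0 <- de
    for (inner in 1:30) {
      P <- plogis(outer(th, de, "-")); W <- P * (1 - P)
      P[!use] <- 0; W[!use] <- 0
      d_th <- (rs_a - rowSums(P)) / pmax(rowSums(W), 1e-10)
      d_th <- pmin(pmax(d_th, -control$max_step), control$max_step)
      th[est_p] <- th[est_p] + d_th[est_p]
      if (max(abs(d_th[est_p])) < control$tol / 10) break
    }
    for (inner in 1:30) {
      P <- plogis(outer(th, de, "-")); W <- P * (1 - P)
      P[!use] <- 0; W[!use] <- 0
      d_de <- (colSums(P) - cs_a) / pmax(colSums(W), 1e-10)
      d_de <- pmin(pmax(d_de, -control$max_step), control$max_step)
      de[est_i] <- de[est_i] + d_de[est_i]
      if (max(abs(d_de[est_i])) < control$tol / 10) break
    }
    ctr <- mean(de[est_i])
    de[est_i] <- de[est_i] - ctr
    th[est_p] <- th[est_p] - ctr

    change <- max(abs(c((th - th0)[est_p], (de - de0)[est_i])))
    if (change < control$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_cserecall("cserecall_convergence_error",
                   sprintf("JMLE did not converge in %d iterations (last max change %.3g logits)",
                           control$max_iter, change),
                   iterations = it, last_change = change)

  if (isTRUE(control$bias_correction)) {
    L_eff <- sum(est_i)
    de[est_i] <- de[est_i] * (L_eff - 1) / L_eff
  }

  P <- plogis(outer(th, de, "-")); W <- P * (1 - P); W[!use] <- 0
  theta_se <- 1 / sqrt(pmax(rowSums(W), 1e-300))
  delta_se <- 1 / sqrt(pmax(colSums(W), 1e-300))
  th[!est_p] <- NA_real_; theta_se[!est_p] <- NA_real_
  de[!est_i] <- NA_real_; delta_se[!est_i] <- NA_real_

  keep <- est_p & !p_ext
  out <- list(
    theta = stats::setNames(th, rownames(x)),
    theta_se = stats::setNames(theta_se, rownames(x)),
    delta = stats::setNames(de, colnames(x)),
    delta_se = stats::setNames(delta_se, colnames(x)),
    person_extreme = stats::setNames(p_ext, rownames(x)),
    item_extreme = stats::setNames(i_ext, colnames(x)),
    convergence = list(iterations = it, last_change = change,
                       converged = converged),
    theta_mean = mean(th[keep]),
    theta_sd = stats::sd(th[keep]),
    groups = if (inherits(data, "response_matrix")) data$groups else NULL,
    control = control
  )
  class(out) <- "rasch_fit"
  out
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Rasch JMLE fit:", length(x$theta), "persons,", length(x$delta), "items\n")
  cat(sprintf("  converged in %d iterations (max change %.2g logits)\n",
              x$convergence$iterations, x$convergence$last_change))
  cat(sprintf("  person ability: mean %.2f, sd %.2f logits (%d extreme persons, %d extreme items)\n",
              x$theta_mean, x$theta_sd,
              sum(x$person_extreme), sum(x$item_extreme)))
  cat("  item difficulties (centered):\n")
  print(round(x$delta, 2))
  invisible(x)
}

#' Standardized Rasch residuals
#'
#' `y_ij = (x_ij - P_ij) / sqrt(P_ij (1 - P_ij))` with `P_ij` the fitted
#' success probability. Missing cells, and cells whose person or item
#' parameter is extreme (so `P` is degenerate), propagate as `NA`.
#'
#' @param data the [response_matrix()] (or matrix) the model was fitted to.
#' @param fit a [fit_rasch()] result.
#' @return Matrix of standardized residuals, persons by items.
#' @export
standardized_residuals <- function(data, fit) {
  x <- as_response_mat(data)
  stopifnot(inherits(fit, "rasch_fit"),
            nrow(x) == length(fit$theta), ncol(x) == length(fit$delta))
  P <- plogis(outer(fit$theta, fit$delta, "-"))
  y <- (x - P) / sqrt(P * (1 - P))
  y[is.na(x)] <- NA_real_
  dimnames(y) <- dimnames(x)
  y
}

#' Back-conversion of logit measures to the success-probability scale
#'
#' Measurand restitution in reverse: converts a logit measure (person
#' ability against a reference difficulty, or vice versa) to the
#' `P_success` scale, with an uncertainty interval obtained by transforming
#' the endpoints `measure +/- k*U` through the same logistic. Because the
#' logistic is nonlinear, the interval is asymmetric about the central value
#' except exactly at `P = 0.5` — the familiar counted-fractions compression
#' near the ends of the probability scale.
#'
#' @param measure measure in logits (e.g. group mean ability).
#' @param reference reference in logits (e.g. mean region difficulty).
#' @param U standard uncertainty of `measure - reference`, logits, >= 0.
#' @param k coverage factor for the reported interval (default 2).
#' @return Data frame with columns `central`, `lower`, `upper`.
#' @examples
#' to_psuccess(1, 0, U = 0.5) # central 0.731, interval [0.5, 0.881]
#' @export
to_psuccess <- function(measure, reference = 0, U = 0, k = 2) {
  if (any(U < 0)) stop_cserecall("cserecall_parameter_error", "U must be >= 0")
  d <- measure - reference
  data.frame(central = plogis(d),
             lower = plogis(d - k * U),
             upper = plogis(d + k * U))
}

#' Rasch person-separation reliability
#'
#' Fraction of observed person-measure variance not attributable to
#' measurement error: `(var(theta) - mean(se^2)) / var(theta)`, floored at
#' 0. Small item subsets (e.g. a 4-item serial-position cluster) give low
#' reliability — a diagnostic, not an error.
#'
#' @param theta person measures (NA allowed).
#' @param se their standard uncertainties.
#' @return Reliability in \[0, 1\].
#' @export
separation_reliability <- function(theta, se) {
  ok <- is.finite(theta) & is.finite(se)
  v <- stats::var(theta[ok])
  if (!is.finite(v) || v <= 0) return(0)
  max(0, (v - mean(se[ok]^2)) / v)
}
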