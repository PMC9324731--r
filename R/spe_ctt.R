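#' Classic-test-theory proportion correct
#'
#' Raw CTT score for item `j`: the mean of the 0/1 column over non-missing
#' responses, `1/N_TP * sum_i x_ij`. Ordinal, not interval — provided for
#' side-by-side comparison with the Rasch restitution.
#'
#' @param data a [response_matrix()] or 0/1 matrix.
#' @param j item index (or vector); default all items.
#' @return Proportion(s) in \[0, 1\].
#' @export
ctt_proportion <- function(data, j = NULL) {
  x <- as_response_mat(data)
  if (is.null(j)) j <- seq_len(ncol(x))
  check_item_index(j, ncol(x))
  out <- vapply(j, function(jj) {
    col <- x[, jj]
    if (all(is.na(col)))
      stop_cserecall("cserecall_undefined_score",
                     sprintf("item %d has no observed responses", jj))
    mean(col, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, colnames(x)[j])
}

#' Serial-position curves by region and group
#'
#' Summarises recall success per clinical group and serial-position region
#' by two routes: (a) the raw CTT proportion correct and (b) the Rasch
#' restitution, converting group mean ability against mean region difficulty
#' back to the `P_success` scale via [to_psuccess()], with an asymmetric
#' `k = 2` interval. No uncertainty interval is attached to the CTT route:
#' without compensating for ordinality a credible CTT uncertainty cannot be
#' stated. The group ability uncertainty combines the standard error of the
#' group mean with the mean individual measurement uncertainty in
#' quadrature.
#'
#' @param data a [response_matrix()] (its `groups`, if present, are the
#'   default grouping).
#' @param fit the corresponding [fit_rasch()] result.
#' @param design a [word_list_design()] supplying the region partition.
#' @param groups optional group label per person; default `data$groups`,
#'   else a single group `"all"`.
#' @param method `"mean_ability"` (default): convert group mean ability vs
#'   mean region difficulty; `"per_item"`: average per-item conversions.
#' @param k coverage factor for the Rasch-route interval.
#' @return An object of class `spe_summary`: data frame with one row per
#'   group x region (`group`, `region`, `n`, `ctt`, `rasch_central`,
#'   `rasch_lower`, `rasch_upper`).
#' @export
spe_curves <- function(data, fit, design, groups = NULL,
                       method = c("mean_ability", "per_item"), k = 2) {
  method <- match.arg(method)
  x <- as_response_mat(data)
  stopifnot(inherits(fit, "rasch_fit"), inherits(design, "word_list_design"),
            ncol(x) == design$L)
  if (is.null(groups))
    groups <- if (inherits(data, "response_matrix") && !is.null(data$groups))
      data$groups else rep("all", nrow(x))
  stopifnot(length(groups) == nrow(x))

  rows <- list()
  for (g in unique(groups)) {
    in_g <- groups == g
    if (!any(in_g)) { warning("empty group skipped: ", g); next }
    th <- fit$theta[in_g]; se <- fit$theta_se[in_g]
    ok <- is.finite(th)
    for (r in c("Pr", "Mr", "Rr")) {
      items <- which(design$items$region == r)
      if (length(items) == 0) next
      ctt <- mean(ctt_proportion(x[in_g, , drop = FALSE], items))
      if (!any(ok)) { warning("group has only extreme persons: ", g); next }
      u_th <- sqrt(stats::var(th[ok]) / sum(ok) + mean(se[ok]^2))
      if (!is.finite(u_th)) u_th <- mean(se[ok])  # one-person group
      if (method == "mean_ability") {
        ps <- to_psuccess(mean(th[ok]), mean(fit$delta[items], na.rm = TRUE),
                          U = u_th, k = k)
      } else {
        per <- to_psuccess(rep(mean(th[ok]), length(items)),
                           fit$delta[items], U = u_th, k = k)
        ps <- as.data.frame(t(colMeans(per)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = r, n = sum(in_g), ctt = ctt,
        rasch_central = ps$central, rasch_lower = ps$lower,
        rasch_upper = ps$upper, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spe_summary", "data.frame")
  out
}
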