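#' Specification of a synthetic recall cohort
#'
#' Describes a cohort of one or more clinical-style groups for simulation
#' under the Rasch generative model: each group has its own normal ability
#' distribution and, optionally, its own perceived-difficulty modifiers — an
#' overall logit shift plus additive shifts per serial-position region
#' (`Pr`, `Mr`, `Rr`). Region shifts are the mechanism behind planted
#' multidimensionality: e.g. `c(Pr = 2)` removes the primacy benefit (makes
#' early items 2 logits harder) for that group.
#'
#' @param n persons per group (vector, one per group).
#' @param labels group labels (recycled/defaulted to `G1..`).
#' @param ability_mean,ability_sd per-group normal ability parameters
#'   (logits; recycled). Defaults mean -0.6, sd 1.0.
#' @param shift per-group overall difficulty shift (logits; recycled).
#' @param region_shift `NULL`, or a list (one element per group) of named
#'   numeric vectors with names among `Pr`, `Mr`, `Rr`.
#' @param base_delta base item difficulties (length `design$L`). Default:
#'   the canonical empirical 15-item difficulties when `design$L == 15`,
#'   else the centered [theoretical_difficulty()] of the design.
#' @param design a [word_list_design()] (default 15 items).
#' @param seed default seed used by [simulate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100, labels = NULL, ability_mean = -0.6,
                        ability_sd = 1, shift = 0, region_shift = NULL,
                        base_delta = NULL, design = word_list_design(15),
                        seed = 1L) {
  stopifnot(inherits(design, "word_list_design"))
  G <- length(n)
  if (any(n < 1) || any(n != floor(n)))
    stop_cserecall("cserecall_parameter_error", "group sizes must be positive integers")
  if (is.null(labels)) labels <- if (G == 1) "all" else paste0("G", seq_len(G))
  ability_mean <- rep_len(ability_mean, G)
  ability_sd <- rep_len(ability_sd, G)
  if (any(ability_sd <= 0))
    stop_cserecall("cserecall_parameter_error", "ability_sd must be > 0")
  shift <- rep_len(shift, G)
  if (is.null(region_shift)) region_shift <- rep(list(numeric(0)), G)
  if (length(region_shift) != G)
    stop_cserecall("cserecall_parameter_error",
                   "region_shift must have one element per group")
  if (!all(unlist(lapply(region_shift, function(z)
    length(z) == 0 || all(names(z) %in% c("Pr", "Mr", "Rr"))))))
    stop_cserecall("cserecall_parameter_error",
                   "region_shift names must be among Pr, Mr, Rr")
  if (is.null(base_delta)) {
    base_delta <- if (design$L == 15) table1_delta() else {
      d <- theoretical_difficulty(design); d - mean(d)
    }
  }
  if (length(base_delta) != design$L)
    stop_cserecall("cserecall_parameter_error", "base_delta must have length L")
  structure(list(n = as.integer(n), labels = labels,
                 ability_mean = ability_mean, ability_sd = ability_sd,
                 shift = shift, region_shift = region_shift,
                 base_delta = base_delta, design = design,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# effective difficulty vector for group g
group_delta <- function(spec, g) {
  d <- spec$base_delta + spec$shift[g]
  rs <- spec$region_shift[[g]]
  for (r in names(rs))
    d[spec$design$items$region == r] <- d[spec$design$items$region == r] + rs[[r]]
  d
}

#' Simulate binary recall responses for a cohort
#'
#' Draws each person's ability from their group's normal distribution and
#' each response from a Bernoulli with the Rasch
#' [success_probability()] at the group's effective item difficulties
#' (base + overall shift + region shifts). Identical spec and seed give a
#' bitwise-identical matrix. The true parameters are returned alongside the
#' responses for parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (default `spec$seed`).
#' @return List: `responses` (a [response_matrix()] carrying group labels),
#'   `theta` (true abilities), `delta_effective` (groups x items matrix of
#'   true difficulties), `spec`, `seed`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n = c(30, 30), seed = 7))
#' colMeans(sim$responses$x)
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  L <- spec$design$L
  G <- length(spec$n)
  D <- t(vapply(seq_len(G), function(g) group_delta(spec, g), numeric(L)))
  rownames(D) <- spec$labels
  theta <- numeric(0); grp <- character(0)
  X <- matrix(NA_integer_, nrow = sum(spec$n), ncol = L)
  row0 <- 0L
  for (g in seq_len(G)) {
    th_g <- rnorm(spec$n[g], spec$ability_mean[g], spec$ability_sd[g])
    P <- plogis(outer(th_g, D[g, ], "-"))
    X[row0 + seq_len(spec$n[g]), ] <- rbinom(length(P), 1L, P)
    theta <- c(theta, th_g)
    grp <- c(grp, rep(spec$labels[g], spec$n[g]))
    row0 <- row0 + spec$n[g]
  }
  colnames(X) <- paste0("I", seq_len(L))
  list(responses = response_matrix(X, groups = grp),
       theta = theta, delta_effective = D, spec = spec, seed = seed)
}

#' Memory-clinic style 4-group cohort preset
#'
#' A 225-person specification shaped like a typical memory-clinic research
#' cohort: 66 healthy controls (HC), 99 with subjective cognitive decline
#' (SCD), 27 with mild cognitive impairment (MCI) and 33 with dementia
#' (AD), overall mean ability about -0.6 logits with sd 1.0, and the
#' canonical 15-item empirical difficulties as base. The per-group ability
#' means (-0.1, -0.5, -1.0, -1.6) are *invented* plausible values: only the
#' ordering HC > SCD > MCI > AD and the overall mean/sd are anchored; their
#' cohort-weighted mean is -0.60. The impaired groups (MCI, AD) optionally
#' lose the primacy benefit: `primacy_penalty` logits are added to their
#' `Pr`-region difficulties (default +2).
#'
#' @param primacy_penalty logit penalty on primacy items for MCI and AD
#'   (0 disables, making all groups share one difficulty vector).
#' @param seed default simulation seed carried by the spec.
#' @return A [cohort_spec()].
#' @export
neuromet_like_preset <- function(primacy_penalty = 2, seed = 1L) {
  pen <- if (primacy_penalty == 0) numeric(0) else c(Pr = primacy_penalty)
  cohort_spec(
    n = c(66L, 99L, 27L, 33L),
    labels = c("HC", "SCD", "MCI", "AD"),
    ability_mean = c(-0.1, -0.5, -1.0, -1.6),
    ability_sd = 1,
    region_shift = list(numeric(0), numeric(0), pen, pen),
    seed = seed
  )
}
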