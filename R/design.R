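#' Word-list design for a serial recall test
#'
#' Describes the fixed design of a word-list recall task: the list length
#' `L`, the presentation order of the words, their relative corpus
#' frequencies, and the partition of positions into the three serial-position
#' regions: primacy (`Pr`), mid-range (`Mr`) and recency (`Rr`). For the
#' canonical 15-word list (RAVLT immediate recall) the default partition is
#' Pr = positions 1-4, Mr = 5-11, Rr = 12-15, reflecting the long-standing
#' observation that the primacy benefit is confined to roughly the first
#' four words and the recency benefit to the last four.
#'
#' @param L list length (number of words), at least 3.
#' @param words optional character vector of word labels, length `L`.
#' @param rel_freq optional relative corpus frequencies, probabilities in
#'   (0, 1], length `L`.
#' @param freq_logit optional pre-tabulated frequency explanatory variable in
#'   logits, length `L`. When supplied it is used verbatim (pass-through) by
#'   [explanatory_matrix()] instead of the `-M log(rel_freq)` form.
#' @param regions optional character vector of region tags (`"Pr"`, `"Mr"`,
#'   `"Rr"`), length `L`, partitioning the positions. Defaults to first
#'   `min(4, floor((L-1)/2))` positions Pr, the mirror-image tail Rr, and the
#'   remainder Mr (giving 4/7/4 for L = 15).
#' @return An object of class `word_list_design`: a list with elements `L`
#'   and `items` (a data frame with columns `item`, `word`, `rel_freq`,
#'   `freq_logit`, `region`).
#' @examples
#' d <- word_list_design(15)
#' table(d$items$region)
#' @export
word_list_design <- function(L, words = NULL, rel_freq = NULL,
                             freq_logit = NULL, regions = NULL) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 3)
    stop_cserecall("cserecall_invalid_design", "list length L must be a single number >= 3")
  L <- as.integer(L)
  j <- seq_len(L)
  if (is.null(words)) words <- paste0("word", j)
  if (length(words) != L)
    stop_cserecall("cserecall_invalid_design", "words must have length L")
  if (!is.null(rel_freq)) {
    if (length(rel_freq) != L || any(!is.finite(rel_freq)) ||
        any(rel_freq <= 0) || any(rel_freq > 1))
      stop_cserecall("cserecall_invalid_frequency",
                     "rel_freq must be length L with all values in (0, 1]")
  }
  if (!is.null(freq_logit) && length(freq_logit) != L)
    stop_cserecall("cserecall_invalid_design", "freq_logit must have length L")
  if (is.null(regions)) {
    n_edge <- min(4L, (L - 1L) %/% 2L)
    regions <- rep("Mr", L)
    regions[seq_len(n_edge)] <- "Pr"
    regions[seq.int(L - n_edge + 1L, L)] <- "Rr"
  }
  if (length(regions) != L || !all(regions %in% c("Pr", "Mr", "Rr")))
    stop_cserecall("cserecall_invalid_design",
                   "regions must be length L with tags in {Pr, Mr, Rr}")
  out <- list(
    L = L,
    items = data.frame(
      item = j, word = words,
      rel_freq = if (is.null(rel_freq)) NA_real_ else rel_freq,
      freq_logit = if (is.null(freq_logit)) NA_real_ else freq_logit,
      region = regions,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "word_list_design"
  out
}

#' @export
print.word_list_design <- function(x, ...) {
  cat("Word-list design: L =", x$L, "items\n")
  cat("Regions:", paste(sprintf("%s=%d", names(table(x$items$region)),
                                table(x$items$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Entropy scale constant
#'
#' The Brillouin-entropy scale constant `M = 1/ln(L)` converting factorial
#' (combinatorial) entropy terms to the logit task-difficulty scale. For the
#' 15-word list, `M = 1/ln(15) = 0.369`.
#'
#' @param L list length (may be a positive real for analysis purposes), > 1.
#' @return The dimensionless constant `1/ln(L)`.
#' @examples
#' scale_constant(15) # 0.369
#' @export
scale_constant <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 2)
    stop_cserecall("cserecall_invalid_design", "L must be a single number >= 2")
  1 / log(L)
}

check_item_index <- function(j, L) {
  if (any(!is.finite(j)) || any(j < 1) || any(j > L) || any(j != floor(j)))
    stop_cserecall("cserecall_index_error",
                   sprintf("item index must be an integer in 1..%d", L))
}

#' Serial-position and frequency explanatory variables (logits)
#'
#' Brillouin-entropy explanatory variables for the difficulty of recalling
#' the word at position `j` of an `L`-word list. More ordered (lower entropy)
#' tasks are easier; each variable is a log-factorial count of orderings
#' scaled by `M = 1/ln(L)`:
#'
#' * primacy: `-M * ln(j!)` — zero at position 1, strictly decreasing in `j`;
#' * recency: `-M * ln((L-1-j)!)` with the factorial argument clipped at 0 —
#'   zero for the last positions, non-increasing towards the front;
#' * mid-range: the constant `M * ln(floor(L/2)!)`, entering the total task
#'   difficulty twice (its doubled value is the constant "Middle" column);
#' * frequency: `-M * ln(p_rel)` for relative corpus frequency `p_rel`, a
#'   semantic (non-positional) contribution; tabulated values can be passed
#'   through unchanged instead (the functional form is offered as-is and not
#'   empirically validated against any corpus).
#'
#' Factorials are evaluated through [lgamma()] so large lists do not
#' overflow. Note the orientation: these are *reductions* in task difficulty
#' entering the additive decomposition
#' `delta_j = delta_Pr(j) + 2*delta_Mr + delta_Rr(j) + delta_freq(j)`,
#' so the primacy column is most negative at the *end* of the list (and
#' mirror-image for recency), exactly as tabulated.
#'
#' @param j item position(s), integers in `1..L`.
#' @param L list length, >= 3 (>= 2 for `primacy_difficulty`).
#' @param doubled for `midrange_difficulty`: return twice the single-term
#'   value (the form in which the constant enters the decomposition).
#' @param p_rel relative word frequency, in (0, 1].
#' @param values optional tabulated frequency variable returned unchanged
#'   (pass-through mode).
#' @return Logit value(s).
#' @examples
#' primacy_difficulty(1:4, 15)
#' recency_difficulty(14, 15) # 0
#' midrange_difficulty(15, doubled = TRUE) # 6.30
#' @export
primacy_difficulty <- function(j, L) {
  M <- scale_constant(L)
  check_item_index(j, L)
  -M * lgamma(j + 1)
}

#' @rdname primacy_difficulty
#' @export
recency_difficulty <- function(j, L) {
  M <- scale_constant(L)
  check_item_index(j, L)
  -M * lgamma(pmax(L - 1 - j, 0) + 1)
}

#' @rdname primacy_difficulty
#' @export
midrange_difficulty <- function(L, doubled = FALSE) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 3)
    stop_cserecall("cserecall_invalid_design", "L must be a single number >= 3")
  v <- scale_constant(L) * lgamma(floor(L / 2) + 1)
  if (doubled) 2 * v else v
}

#' @rdname primacy_difficulty
#' @export
frequency_difficulty <- function(p_rel = NULL, L = NULL, values = NULL) {
  if (!is.null(values)) return(values)
  if (is.null(p_rel) || is.null(L))
    stop_cserecall("cserecall_invalid_frequency",
                   "either `values` or both `p_rel` and `L` must be supplied")
  if (any(!is.finite(p_rel)) || any(p_rel <= 0) || any(p_rel > 1))
    stop_cserecall("cserecall_invalid_frequency", "p_rel must be in (0, 1]")
  -scale_constant(L) * log(p_rel)
}

item_frequency_logits <- function(design) {
  it <- design$items
  if (!all(is.na(it$freq_logit))) return(it$freq_logit)
  if (!all(is.na(it$rel_freq)))
    return(frequency_difficulty(it$rel_freq, design$L))
  rep(0, design$L)
}

#' Theoretical task difficulty of each list item
#'
#' Additive entropy decomposition of the recall difficulty of item `j`:
#' `delta_j = delta_Pr(j) + 2*delta_Mr + delta_Rr(j) + delta_freq(j)`.
#' The frequency term is taken from the design's tabulated `freq_logit`
#' column when present, else from `-M log(rel_freq)`, else 0.
#'
#' @param design a [word_list_design()].
#' @param j item position(s); default all items.
#' @return Numeric vector of theoretical difficulties in logits.
#' @export
theoretical_difficulty <- function(design, j = NULL) {
  stopifnot(inherits(design, "word_list_design"))
  if (is.null(j)) j <- seq_len(design$L)
  check_item_index(j, design$L)
  freq <- item_frequency_logits(design)[j]
  primacy_difficulty(j, design$L) +
    midrange_difficulty(design$L, doubled = TRUE) +
    recency_difficulty(j, design$L) +
    freq
}

#' Per-item table of the four entropy explanatory variables
#'
#' Builds the item-by-variable table used throughout the construct
#' specification machinery: `primacy`, the constant doubled `middle`,
#' `recency` and `frequency`, one row per list position. For `L = 15` the
#' primacy and recency columns reproduce the canonical tabulated values to
#' 2 decimal places (the computed doubled middle term is 6.30; the published
#' table prints 6.31 from an unstated rounding — both are documented in the
#' package vignette).
#'
#' @param design a [word_list_design()].
#' @return An object of class `explanatory_matrix`: a data frame with
#'   columns `item`, `region`, `primacy`, `middle`, `recency`, `frequency`
#'   and attribute `M` (the scale constant).
#' @examples
#' X <- explanatory_matrix(word_list_design(15))
#' round(X$primacy, 2)
#' @export
explanatory_matrix <- function(design) {
  stopifnot(inherits(design, "word_list_design"))
  j <- seq_len(design$L)
  out <- data.frame(
    item = j,
    region = design$items$region,
    primacy = primacy_difficulty(j, design$L),
    middle = rep(midrange_difficulty(design$L, doubled = TRUE), design$L),
    recency = recency_difficulty(j, design$L),
    frequency = item_frequency_logits(design),
    stringsAsFactors = FALSE
  )
  attr(out, "M") <- scale_constant(design$L)
  class(out) <- c("explanatory_matrix", "data.frame")
  out
}
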