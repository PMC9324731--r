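#' Read a binary response matrix from CSV
#'
#' Expects a header row of item identifiers, a first column of person
#' identifiers, an optional `group` column, and 0/1/empty cells (empty =
#' missing). Any other cell value is rejected with its location; duplicate
#' person identifiers are rejected.
#'
#' @param path CSV file path.
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path) {
  if (!file.exists(path))
    stop_cserecall("cserecall_format_error", paste("file not found:", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2)
    stop_cserecall("cserecall_format_error", "need a person column plus items")
  persons <- df[[1]]
  df <- df[, -1, drop = FALSE]
  groups <- NULL
  gcol <- which(tolower(names(df)) == "group")
  if (length(gcol) == 1) { groups <- df[[gcol]]; df <- df[, -gcol, drop = FALSE] }
  x <- matrix(NA_integer_, nrow(df), ncol(df),
              dimnames = list(persons, names(df)))
  for (jj in seq_len(ncol(df))) {
    cell <- trimws(df[[jj]])
    blank <- cell == "" | is.na(cell)
    bad <- !blank & !(cell %in% c("0", "1"))
    if (any(bad))
      stop_cserecall("cserecall_format_error",
                     sprintf("non-binary cell at row %d, column '%s': '%s'",
                             which(bad)[1], names(df)[jj], cell[which(bad)[1]]))
    x[!blank, jj] <- as.integer(cell[!blank])
  }
  response_matrix(x, persons = persons, groups = groups)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_response_matrix()]: person ids first, then an optional
#' `group` column, then the 0/1 items with missing cells left empty.
#'
#' @param data a [response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(data, path) {
  stopifnot(inherits(data, "response_matrix"))
  df <- data.frame(person = data$persons, stringsAsFactors = FALSE)
  if (!is.null(data$groups)) df$group <- data$groups
  df <- cbind(df, as.data.frame(data$x))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an item metadata table
#'
#' CSV with columns `item` (1-based presentation order), `word`, and
#' optionally `rel_freq` (probability in (0,1]), `freq_logit` (tabulated
#' frequency variable) and `region` (Pr/Mr/Rr). Returns the corresponding
#' [word_list_design()].
#'
#' @param path CSV file path.
#' @return A [word_list_design()].
#' @export
read_item_table <- function(path) {
  if (!file.exists(path))
    stop_cserecall("cserecall_format_error", paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"item" %in% names(df))
    stop_cserecall("cserecall_format_error", "item table needs an 'item' column")
  df <- df[order(df$item), , drop = FALSE]
  L <- nrow(df)
  if (!identical(as.integer(df$item), seq_len(L)))
    stop_cserecall("cserecall_format_error",
                   "item order indices must be exactly 1..L with no gaps")
  word_list_design(
    L,
    words = if ("word" %in% names(df)) df$word else NULL,
    rel_freq = if ("rel_freq" %in% names(df)) df$rel_freq else NULL,
    freq_logit = if ("freq_logit" %in% names(df)) df$freq_logit else NULL,
    regions = if ("region" %in% names(df)) df$region else NULL
  )
}

#' Canonical 15-item RAVLT immediate-recall reference table
#'
#' Loads the bundled reference table for the 15-item immediate-recall list:
#' the four explanatory variables (primacy, constant middle, recency,
#' tabulated frequency), the empirical Rasch difficulties `delta` with
#' expanded (`k = 2`) uncertainties `U_delta`, and the published CSE fitted
#' values `zR` with `U_zR` — 15 rows by 9 columns, exactly as tabulated.
#' The frequency column is tabulated (its generating corpus is unstated);
#' the `middle` column carries the printed constant 6.31.
#'
#' @return List: `table` (the 15 x 9 data frame), `design` (a
#'   [word_list_design()] with the tabulated frequency logits), `X` (an
#'   [explanatory_matrix()]-classed data frame holding the *tabulated*
#'   columns verbatim), `delta`, `U_delta`, `z_R`, `U_zR`.
#' @examples
#' t1 <- load_table1_fixture()
#' sum(t1$delta) # 0
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_ravlt_ir.csv", package = "cserecall")
  tb <- utils::read.csv(path)
  design <- word_list_design(15, freq_logit = tb$frequency)
  X <- data.frame(item = tb$item, region = design$items$region,
                  primacy = tb$primacy, middle = tb$middle,
                  recency = tb$recency, frequency = tb$frequency,
                  stringsAsFactors = FALSE)
  attr(X, "M") <- scale_constant(15)
  class(X) <- c("explanatory_matrix", "data.frame")
  list(table = tb, design = design, X = X,
       delta = tb$delta, U_delta = tb$U_delta,
       z_R = tb$zR, U_zR = tb$U_zR)
}

# internal: canonical empirical difficulties (default simulation base)
table1_delta <- function() load_table1_fixture()$delta
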