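#' Construct a response data object
#'
#' Bundles an n x k matrix of ordinal item responses (coded 0..m_i, `NA` for
#' missing) with per-person categorical covariates. This is the common input
#' container for all model fitting and diagnostic functions.
#'
#' @param responses integer matrix (persons x items) with column names; each
#'   non-missing entry of item i must lie in `0..(ncat[i] - 1)`.
#' @param covariates data frame of factors (one row per person) or `NULL`.
#'   The first factor level of each covariate is treated as its reference
#'   level.
#' @param person_id character vector of unique person identifiers; defaults
#'   to row numbers.
#' @param ncat integer vector of category counts per item (`m_i + 1`);
#'   defaults to 5 (a five-point Likert item recoded 0..4) for every item.
#' @return an object of class `response_data`.
#' @export
response_data <- function(responses, covariates = NULL, person_id = NULL,
                          ncat = NULL) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  storage.mode(responses) <- "integer"
  n <- nrow(responses); k <- ncol(responses)
  if (n < 1L) stop("need at least one person")
  if (k < 2L) stop("need at least two items")
  if (is.null(ncat)) ncat <- rep(5L, k)
  ncat <- as.integer(rep_len(ncat, k))
  names(ncat) <- colnames(responses)
  for (i in seq_len(k)) {
    yi <- responses[, i]
    bad <- !is.na(yi) & (yi < 0L | yi >= ncat[i])
    if (any(bad))
      stop(sprintf("item %s has responses outside 0..%d", colnames(responses)[i],
                   ncat[i] - 1L))
  }
  if (is.null(person_id)) person_id <- as.character(seq_len(n))
  person_id <- as.character(person_id)
  if (anyDuplicated(person_id)) stop("person_id values must be unique")
  if (length(person_id) != n) stop("person_id length does not match data")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per person")
    for (j in seq_along(covariates))
      if (!is.factor(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
  }
  structure(list(responses = responses, covariates = covariates,
                 person_id = person_id, ncat = ncat),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("response_data: %d persons x %d items (%s categories)\n",
              nrow(x$responses), ncol(x$responses),
              paste(unique(x$ncat), collapse = "/")))
  if (!is.null(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  miss <- mean(is.na(x$responses))
  cat(sprintf("missing cells: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.response_data <- function(x) dim(x$responses)

#' Scale specification
#'
#' Describes a (sub)scale: its ordered item set, which items are
#' reverse-scored, and the number of response categories per item.
#'
#' @param name scale name.
#' @param items character vector of item column names, in order.
#' @param reverse_scored subset of `items` to be reverse scored
#'   (`y -> m - y`), e.g. for dimensionality analyses.
#' @param ncat category count (`m + 1`) per item; recycled.
#' @return an object of class `scale_spec`.
#' @export
scale_spec <- function(name, items, reverse_scored = character(), ncat = 5L) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicated items in scale spec")
  if (!all(reverse_scored %in% items))
    stop("reverse_scored items must be a subset of the item list")
  structure(list(name = name, items = items,
                 reverse_scored = as.character(reverse_scored),
                 ncat = as.integer(rep_len(ncat, length(items)))),
            class = "scale_spec")
}

#' Scale specifications for the PSS-14
#'
#' The 14-item Perceived Stress Scale splits into a negatively worded
#' "Perceived Stress" subscale (items 1, 2, 3, 8, 11, 12, 14) and a
#' positively worded "Perceived Control" subscale (items 4, 5, 6, 7, 9, 10,
#' 13), each on a five-point response format. The negatively worded items
#' are the ones reverse scored when both subscales are analysed together.
#'
#' @param which one of `"stress"`, `"control"`, `"full"`.
#' @return a `scale_spec`.
#' @export
pss14_spec <- function(which = c("full", "stress", "control")) {
  which <- match.arg(which)
  stress <- paste0("item", c(1, 2, 3, 8, 11, 12, 14))
  control <- paste0("item", c(4, 5, 6, 7, 9, 10, 13))
  switch(which,
    stress = scale_spec("Perceived Stress", stress, reverse_scored = stress),
    control = scale_spec("Perceived Control", control),
    full = scale_spec("PSS-14", paste0("item", 1:14), reverse_scored = stress))
}

#' Read item responses from a delimited text file
#'
#' Expects a header row and one row per person. Raw Likert codes `1..m+1`
#' are shifted to the internal `0..m` coding; cells outside that range are
#' set to missing with a warning reporting how many were dropped.
#'
#' @param path file path (CSV by default).
#' @param spec a [scale_spec()] naming the item columns.
#' @param covariate_names character vector of covariate columns to carry
#'   along (optional).
#' @param id_column name of the person identifier column, or `NULL` to use
#'   row numbers.
#' @param sep field separator.
#' @return a [response_data()] object.
#' @export
read_responses <- function(path, spec, covariate_names = character(),
                           id_column = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_items <- setdiff(spec$items, names(df))
  if (length(missing_items))
    stop("unknown item column(s): ", paste(missing_items, collapse = ", "))
  missing_cov <- setdiff(covariate_names, names(df))
  if (length(missing_cov))
    stop("unknown covariate column(s): ", paste(missing_cov, collapse = ", "))
  raw <- as.matrix(df[spec$items])
  storage.mode(raw) <- "integer"
  y <- raw - 1L
  n_bad <- 0L
  for (i in seq_along(spec$items)) {
    bad <- !is.na(y[, i]) & (y[, i] < 0L | y[, i] >= spec$ncat[i])
    n_bad <- n_bad + sum(bad)
    y[bad, i] <- NA_integer_
  }
  if (n_bad > 0L)
    warning(sprintf("%d out-of-range response(s) set to missing", n_bad))
  pid <- if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("unknown id column: ", id_column)
    as.character(df[[id_column]])
  } else NULL
  cov <- if (length(covariate_names)) df[covariate_names] else NULL
  response_data(y, covariates = cov, person_id = pid, ncat = spec$ncat)
}

#' Write item responses to a delimited text file
#'
#' Inverse of [read_responses()]: internal `0..m` codes are written as raw
#' `1..m+1` Likert codes, missing cells as empty fields.
#'
#' @param data a [response_data()] object.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_responses <- function(data, path, sep = ",") {
  out <- as.data.frame(data$responses + 1L)
  out <- cbind(person_id = data$person_id, out)
  if (!is.null(data$covariates)) out <- cbind(out, data$covariates)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Reverse-score the flagged items of a scale
#'
#' Maps `y -> m_i - y` for every item in `spec$reverse_scored`; other items
#' and missing cells are unchanged. Applying the function twice returns the
#' original data.
#'
#' @param data a [response_data()].
#' @param spec a [scale_spec()] whose `reverse_scored` items exist in `data`.
#' @return a [response_data()] with the flagged items reversed.
#' @export
apply_reverse_scoring <- function(data, spec) {
  missing_items <- setdiff(spec$reverse_scored, colnames(data$responses))
  if (length(missing_items))
    stop("items not in data: ", paste(missing_items, collapse = ", "))
  y <- data$responses
  for (it in spec$reverse_scored)
    y[, it] <- (data$ncat[it] - 1L) - y[, it]
  data$responses <- y
  data
}

#' Total scores over an item set
#'
#' Computes the raw total score (the sufficient statistic for the person
#' parameter under a Rasch model) over the given items. Persons with any
#' missing response in the set are flagged invalid and get `NA`; no
#' imputation is performed.
#'
#' @param data a [response_data()].
#' @param items item names; defaults to all items.
#' @return a data frame with columns `person_id`, `score`, `valid`.
#' @export
total_scores <- function(data, items = colnames(data$responses)) {
  if (length(items) == 0L) stop("empty item list")
  missing_items <- setdiff(items, colnames(data$responses))
  if (length(missing_items))
    stop("items not in data: ", paste(missing_items, collapse = ", "))
  y <- data$responses[, items, drop = FALSE]
  valid <- rowSums(is.na(y)) == 0L
  score <- ifelse(valid, rowSums(y), NA_integer_)
  data.frame(person_id = data$person_id, score = as.integer(score),
             valid = valid, stringsAsFactors = FALSE)
}

#' Restrict a response data object to a subset of persons and/or items
#'
#' @param data a [response_data()].
#' @param persons logical or integer index of persons to keep.
#' @param items item names to keep.
#' @return a [response_data()].
#' @export
subset_response_data <- function(data, persons = NULL,
                                 items = colnames(data$responses)) {
  if (is.null(persons)) persons <- seq_len(nrow(data$responses))
  y <- data$responses[persons, items, drop = FALSE]
  cov <- if (!is.null(data$covariates))
    droplevels_keep_ref(data$covariates[persons, , drop = FALSE]) else NULL
  response_data(y, covariates = cov, person_id = data$person_id[persons],
                ncat = data$ncat[items])
}

# Drop unused rows without dropping factor levels (reference levels must
# survive subsetting so that DIF parameterizations stay aligned).
droplevels_keep_ref <- function(df) df
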