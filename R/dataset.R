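#' Encode a raw response table into transactions
#'
#' Turns a respondent-by-question categorical table into a transaction
#' dataset: each row becomes one transaction, each non-missing cell one
#' (question, answer) item. Internally transactions are stored as a logical
#' incidence matrix over the codebook's canonical item universe, which makes
#' support counting a column/row reduction.
#'
#' @param raw_table Data frame, one row per respondent, one column per
#'   question (column names are question ids). Factors are coerced to
#'   character; `NA` or `""` cells are missing.
#' @param cb A [codebook()]. Every column of `raw_table` must match a
#'   codebook question or be listed in `ignore_columns`.
#' @param timepoint Label for the survey round, e.g. `"T1"` or `"T2"`.
#' @param respondent_ids Optional character vector of respondent ids;
#'   defaults to `r1, r2, ...`.
#' @param ignore_columns Columns to drop without complaint (e.g. free text).
#' @return A `survey_dataset`: list with the codebook, the item universe,
#'   the `n x n_items` logical incidence matrix, respondent ids and the
#'   timepoint.
#' @export
encode_transactions <- function(raw_table, cb, timepoint = "T1",
                                respondent_ids = NULL,
                                ignore_columns = character(0)) {
  stopifnot(inherits(cb, "codebook"))
  raw_table <- as.data.frame(raw_table)
  if (nrow(raw_table) == 0L)
    stop("response table has no rows; a dataset must contain at least one transaction",
         call. = FALSE)
  keep <- setdiff(names(raw_table), ignore_columns)
  unknown <- setdiff(keep, question_ids(cb))
  if (length(unknown))
    stop("columns not in codebook (and not ignored): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(raw_table)
  if (is.null(respondent_ids)) respondent_ids <- paste0("r", seq_len(n))
  stopifnot(length(respondent_ids) == n)

  universe <- item_universe(cb)
  mat <- matrix(FALSE, nrow = n, ncol = nrow(universe),
                dimnames = list(NULL, universe$token))
  for (qid in keep) {
    col <- as.character(raw_table[[qid]])
    miss <- is.na(col) | col == ""
    allowed <- cb$questions[[qid]]$answers
    bad <- !miss & !(col %in% allowed)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("illegal answer '", col[i], "' for question '", qid,
           "' in row ", i, call. = FALSE)
    }
    if (cb$missing_policy == "explicit_missing_item") {
      col[miss] <- "missing"
      miss <- rep(FALSE, n)
    }
    ok <- which(!miss)
    if (length(ok)) {
      j <- match(paste0(qid, "=", col[ok]), universe$token)
      mat[cbind(ok, j)] <- TRUE
    }
  }
  structure(list(codebook = cb, universe = universe, incidence = mat,
                 respondent_id = as.character(respondent_ids),
                 timepoint = timepoint, n = n),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("A survey dataset: ", x$n, " transactions (", x$timepoint, "), ",
      ncol(x$incidence), " items in the universe, ",
      sum(colSums(x$incidence) > 0L), " observed\n", sep = "")
  invisible(x)
}

#' Per-question answer tallies of a dataset
#'
#' Reproduces the familiar "n (%)" descriptive table: for each question, the
#' count of each allowed answer plus a `missing` row, with percentages of
#' the total number of respondents. Counts and the missing row always sum
#' to `n`.
#'
#' @param dataset A `survey_dataset`.
#' @param decimals Decimal places for the percentage (half-up rounding, the
#'   convention of published survey tables); default 1.
#' @return Data frame with columns `question_id`, `answer`, `count`,
#'   `percent`.
#' @export
dataset_summary <- function(dataset, decimals = 1) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cb <- dataset$codebook
  u <- dataset$universe
  counts <- colSums(dataset$incidence)
  out <- lapply(question_ids(cb), function(qid) {
    rows <- which(u$question_id == qid)
    # order answers as declared in the codebook, then the missing row
    ans <- cb$questions[[qid]]$answers
    cnt <- counts[rows][match(ans, u$answer[rows])]
    cnt[is.na(cnt)] <- 0
    if (cb$missing_policy == "explicit_missing_item") {
      miss <- counts[rows][match("missing", u$answer[rows])]
    } else {
      miss <- dataset$n - sum(cnt)
    }
    data.frame(question_id = qid,
               answer = c(ans, "missing"),
               count = as.integer(c(cnt, miss)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$percent <- round_half_up(100 * out$count / dataset$n, decimals)
  rownames(out) <- NULL
  out
}

# Half-up decimal rounding (so 0.25 -> 0.3 at one decimal), matching how
# survey percentages are conventionally printed. The 1e-9 nudge guards
# against count ratios that land a hair below .5 through binary round-off.
round_half_up <- function(x, decimals = 1) {
  p <- 10^decimals
  floor(x * p + 0.5 + 1e-9) / p
}

#' Read a response table from CSV
#'
#' UTF-8 CSV with a header row of question ids; empty cells are missing.
#'
#' @param path CSV path.
#' @return Data frame of character columns.
#' @export
read_responses_csv <- function(path) {
  if (!file.exists(path)) stop("responses file not found: ", path, call. = FALSE)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
}
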