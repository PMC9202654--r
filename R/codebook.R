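#' Define a survey question
#'
#' A question definition ties a stable question id to its finite set of
#' allowed categorical answers and to its mining role: whether its items may
#' appear on the antecedent ("if") side of a rule, the consequent ("then")
#' side, both, or neither.
#'
#' @param id Short stable token identifying the question. Must not contain
#'   `"="` or `";"` (these delimit item tokens).
#' @param answers Character vector of allowed answer tokens (non-empty, no
#'   duplicates, same character restrictions as `id`).
#' @param label Human-readable question text; defaults to `id`.
#' @param role One of `"antecedent"`, `"consequent"`, `"both"`, `"excluded"`.
#' @return A `question_def` object.
#' @export
question_def <- function(id, answers, label = id,
                         role = c("antecedent", "consequent", "both", "excluded")) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[=;]", id))
    stop("question id must not contain '=' or ';': ", id, call. = FALSE)
  answers <- as.character(answers)
  if (length(answers) == 0L)
    stop("question '", id, "' has no allowed answers", call. = FALSE)
  if (anyDuplicated(answers))
    stop("question '", id, "' has duplicated answers", call. = FALSE)
  if (any(grepl("[=;]", answers)) || any(!nzchar(answers)))
    stop("answers for '", id, "' must be non-empty and free of '=' and ';'",
         call. = FALSE)
  structure(list(id = id, label = as.character(label), answers = answers,
                 role = role),
            class = "question_def")
}

#' Assemble a survey codebook
#'
#' The codebook is the contract between a raw response table and the
#' transaction encoding: which columns are questions, which answers are
#' legal, which questions are eligible as rule antecedents or consequents,
#' and how missing answers are treated.
#'
#' @param questions List of [question_def()] objects.
#' @param missing_policy `"omit_item"` (a missing answer emits no item, the
#'   default: pattern support is then defined over present answers only) or
#'   `"explicit_missing_item"` (a missing answer emits an item with the
#'   reserved answer token `"missing"`, so summary tables can reproduce
#'   published "Missing" rows).
#' @return A `codebook` object.
#' @export
codebook <- function(questions,
                     missing_policy = c("omit_item", "explicit_missing_item")) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(questions, "question_def")) questions <- list(questions)
  if (!length(questions) || !all(vapply(questions, inherits, TRUE, "question_def")))
    stop("'questions' must be a non-empty list of question_def objects",
         call. = FALSE)
  ids <- vapply(questions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated question ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  roles <- vapply(questions, `[[`, "", "role")
  if (!any(roles %in% c("antecedent", "both")))
    stop("codebook needs at least one antecedent-eligible question", call. = FALSE)
  if (!any(roles %in% c("consequent", "both")))
    stop("codebook needs at least one consequent-eligible question", call. = FALSE)
  names(questions) <- ids
  structure(list(questions = questions, missing_policy = missing_policy),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  roles <- vapply(x$questions, `[[`, "", "role")
  cat("A survey codebook: ", length(x$questions), " questions (",
      sum(roles %in% c("antecedent", "both")), " antecedent-eligible, ",
      sum(roles %in% c("consequent", "both")), " consequent-eligible), ",
      "missing policy '", x$missing_policy, "'\n", sep = "")
  invisible(x)
}

question_ids <- function(cb) names(cb$questions)

question_roles <- function(cb) vapply(cb$questions, `[[`, "", "role")

#' Read a codebook from YAML or JSON
#'
#' Expects a mapping with a `questions` list of `{id, label, answers, role}`
#' entries and an optional `missing_policy`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [codebook()] object.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$questions))
    stop("codebook file has no 'questions' entry: ", path, call. = FALSE)
  qs <- lapply(raw$questions, function(q) {
    question_def(id = q$id,
                 answers = unlist(q$answers),
                 label = if (is.null(q$label)) q$id else q$label,
                 role = if (is.null(q$role)) "antecedent" else q$role)
  })
  codebook(qs, missing_policy = if (is.null(raw$missing_policy)) "omit_item"
                                else raw$missing_policy)
}

#' Write a codebook to YAML
#'
#' @param cb A [codebook()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  out <- list(
    missing_policy = cb$missing_policy,
    questions = lapply(unname(cb$questions), function(q) {
      list(id = q$id, label = q$label, answers = as.list(q$answers),
           role = q$role)
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

# Canonical item universe of a codebook: one row per (question, answer) pair,
# radix-sorted by (question_id, answer) so item index order IS canonical item
# order everywhere downstream. Under the explicit_missing policy the reserved
# "missing" answer is part of the universe.
item_universe <- function(cb) {
  qs <- cb$questions
  ans <- lapply(qs, function(q) {
    a <- q$answers
    if (cb$missing_policy == "explicit_missing_item") a <- c(a, "missing")
    a
  })
  u <- data.frame(
    question_id = rep(names(qs), lengths(ans)),
    answer = unlist(ans, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  u <- u[order(u$question_id, u$answer, method = "radix"), , drop = FALSE]
  u$token <- paste0(u$question_id, "=", u$answer)
  rownames(u) <- NULL
  u
}

# Parse "question=answer" tokens against a codebook's universe, returning
# canonical (sorted, duplicate-free) item indices. Errors on unknown tokens
# and on two items sharing a question.
parse_item_tokens <- function(tokens, universe, what = "itemset") {
  tokens <- as.character(tokens)
  if (!length(tokens)) return(integer(0))
  idx <- match(tokens, universe$token)
  if (anyNA(idx))
    stop("unknown item token(s) in ", what, ": ",
         paste(tokens[is.na(idx)], collapse = ", "), call. = FALSE)
  idx <- sort(unique(idx))
  if (anyDuplicated(universe$question_id[idx]))
    stop(what, " contains two items for the same question", call. = FALSE)
  idx
}
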