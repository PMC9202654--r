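#' Configure the CCEB economic classification
#'
#' The Brazilian Economic Classification Criteria (CCEB) scores households
#' on possession of durable goods and education of the household head; the
#' score ranges over the integers 0-46 and maps to one of six raw classes
#' (A, B1, B2, C1, C2, DE), each with a distinct average monthly income.
#' Published analyses often merge B1/B2 into B and C1/C2 into C, which is
#' the default `merge_map` here. The score-to-class interval table itself is
#' revised by ABEP over time and is not hard-coded: supply the edition you
#' use.
#'
#' @param cutoffs Data frame with integer columns `lower`, `upper` and a
#'   character column `class` (values among A, B1, B2, C1, C2, DE). The
#'   closed intervals `[lower, upper]` must be disjoint and cover 0-46.
#' @param merge_map Named character vector mapping each raw class to the
#'   reported class; default merges B1,B2 -> B and C1,C2 -> C.
#' @return A `cceb_config` object.
#' @export
cceb_config <- function(cutoffs,
                        merge_map = c(A = "A", B1 = "B", B2 = "B",
                                      C1 = "C", C2 = "C", DE = "DE")) {
  cutoffs <- as.data.frame(cutoffs)
  stopifnot(all(c("lower", "upper", "class") %in% names(cutoffs)))
  raw_classes <- c("A", "B1", "B2", "C1", "C2", "DE")
  if (!all(cutoffs$class %in% raw_classes))
    stop("cutoff classes must be among ", paste(raw_classes, collapse = ", "),
         call. = FALSE)
  covered <- integer(0)
  for (i in seq_len(nrow(cutoffs))) {
    iv <- cutoffs$lower[i]:cutoffs$upper[i]
    if (any(iv %in% covered))
      stop("CCEB cutoff intervals overlap", call. = FALSE)
    covered <- c(covered, iv)
  }
  if (!setequal(covered, 0:46))
    stop("CCEB cutoff intervals must partition the score range 0-46 exactly",
         call. = FALSE)
  if (!all(cutoffs$class %in% names(merge_map)))
    stop("merge_map lacks entries for some raw classes", call. = FALSE)
  structure(list(cutoffs = cutoffs, merge_map = merge_map),
            class = "cceb_config")
}

#' Map CCEB scores to reported economic classes
#'
#' Looks each score up in the configured interval table and applies the
#' class merge (so a score falling in a B1 or B2 interval reports "B" under
#' the default merge).
#'
#' @param score Integer vector of CCEB scores in 0-46.
#' @param config A [cceb_config()].
#' @return Character vector of reported class tokens.
#' @export
cceb_class <- function(score, config) {
  stopifnot(inherits(config, "cceb_config"))
  score <- as.integer(score)
  if (any(is.na(score) | score < 0L | score > 46L))
    stop("CCEB scores must be integers in [0, 46]", call. = FALSE)
  raw <- character(length(score))
  for (i in seq_len(nrow(config$cutoffs))) {
    hit <- score >= config$cutoffs$lower[i] & score <= config$cutoffs$upper[i]
    raw[hit] <- config$cutoffs$class[i]
  }
  unname(config$merge_map[raw])
}
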