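#' Designate the four behavior items
#'
#' Binds the four COVID-19 behavior questions to their affirmative items:
#' the three protective measures — keeping at least 1 m distance when out,
#' sanitizing/washing hands, only leaving home when extremely necessary and
#' wearing a face covering — and the "kept going out (leaving home) for
#' work as usual" behavior.
#'
#' @param distance_item,sanitize_item,mask_item,go_out_normally_item Item
#'   tokens (`"question=answer"`), each the "yes" item of one behavior
#'   question; the four must reference four distinct questions.
#' @return A `behavior_spec` object.
#' @export
behavior_spec <- function(distance_item, sanitize_item, mask_item,
                          go_out_normally_item) {
  items <- c(distance = distance_item, sanitize = sanitize_item,
             mask = mask_item, go_out_normally = go_out_normally_item)
  stopifnot(all(nzchar(items)), length(items) == 4L)
  qs <- sub("=.*$", "", items)
  if (anyDuplicated(qs))
    stop("the four behavior items must reference four distinct questions",
         call. = FALSE)
  structure(list(items = items), class = "behavior_spec")
}

#' Behavior spec for the default codebook
#'
#' @return A [behavior_spec()] bound to the four behavior questions of
#'   [default_codebook()].
#' @export
default_behavior_spec <- function() {
  behavior_spec("distance_1m=yes", "sanitize_hands=yes",
                "mask_necessary=yes", "go_out_normally=yes")
}

# indices of the four behavior items in a dataset's universe (validates)
behavior_indices <- function(spec, dataset) {
  stopifnot(inherits(spec, "behavior_spec"), inherits(dataset, "survey_dataset"))
  idx <- match(spec$items, dataset$universe$token)
  if (anyNA(idx))
    stop("behavior item(s) not in the dataset codebook: ",
         paste(spec$items[is.na(idx)], collapse = ", "), call. = FALSE)
  stats::setNames(idx, names(spec$items))
}

rule_consequent_tokens <- function(rules) strsplit(rules$consequent, ";", fixed = TRUE)

#' Split rules into behavior groups by their consequents
#'
#' Keeps only rules whose consequent mentions at least one of the four
#' behavior items and splits them into the two reported groups:
#' `group_continued` — rules whose consequent contains the
#' going-out-normally item (habits continued regardless of the pandemic) —
#' and `group_protective` — rules whose consequent contains at least one of
#' the three protective items. `group_all_protective` is the subset of the
#' protective group whose consequent contains all three protective items.
#' Membership looks at the consequent only; antecedent content is ignored.
#'
#' @param rules An `association_rules` data frame.
#' @param spec A [behavior_spec()].
#' @param dataset Optional `survey_dataset` used to validate the spec items
#'   against the codebook.
#' @return A `rule_groups` list with elements `group_continued`,
#'   `group_protective`, `group_all_protective` (each an
#'   `association_rules` subset, input order preserved) and `n_discarded`.
#' @export
filter_rules_by_consequent <- function(rules, spec, dataset = NULL) {
  stopifnot(inherits(rules, "association_rules"), inherits(spec, "behavior_spec"))
  if (!is.null(dataset)) behavior_indices(spec, dataset)
  cons <- rule_consequent_tokens(rules)
  protective <- spec$items[c("distance", "sanitize", "mask")]
  has_go_out <- vapply(cons, function(tk) spec$items[["go_out_normally"]] %in% tk, TRUE)
  n_prot <- vapply(cons, function(tk) sum(protective %in% tk), 0L)
  keep_rows <- function(i) {
    out <- rules[i, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, n = attr(rules, "n"),
              class = c("association_rules", "data.frame"))
  }
  structure(list(
    group_continued = keep_rows(which(has_go_out)),
    group_protective = keep_rows(which(n_prot >= 1L)),
    group_all_protective = keep_rows(which(n_prot == 3L)),
    n_discarded = sum(!has_go_out & n_prot == 0L)
  ), class = "rule_groups")
}

#' @export
print.rule_groups <- function(x, ...) {
  cat("Rule groups by behavior consequent:\n",
      "  continued going out normally: ", nrow(x$group_continued), " rules\n",
      "  >=1 protective measure:       ", nrow(x$group_protective), " rules\n",
      "  all three protective:         ", nrow(x$group_all_protective), " rules\n",
      "  discarded (no behavior item): ", x$n_discarded, "\n", sep = "")
  invisible(x)
}

#' Flatten rule groups to a single table
#'
#' One row per (rule, group) membership with a `group` column
#' (`"continued"` or `"protective"`) and an `all_protective` flag on the
#' protective rows; a rule whose consequent mentions both the going-out
#' item and a protective item appears once per group.
#'
#' @param groups A `rule_groups` object.
#' @return Data frame in the rule CSV schema plus `group` and
#'   `all_protective` columns.
#' @export
rule_group_table <- function(groups) {
  stopifnot(inherits(groups, "rule_groups"))
  cont <- as.data.frame(groups$group_continued)
  prot <- as.data.frame(groups$group_protective)
  all3 <- as.data.frame(groups$group_all_protective)
  if (nrow(cont)) { cont$group <- "continued"; cont$all_protective <- FALSE }
  if (nrow(prot)) {
    prot$group <- "protective"
    key <- paste(prot$antecedent, prot$consequent, sep = "->")
    key3 <- paste(all3$antecedent, all3$consequent, sep = "->")
    prot$all_protective <- key %in% key3
  }
  out <- rbind(
    if (nrow(cont)) cont else NULL,
    if (nrow(prot)) prot else NULL
  )
  if (is.null(out))
    out <- cbind(data.frame(antecedent = character(0), consequent = character(0),
                            count = integer(0), support = numeric(0),
                            confidence = numeric(0), lift = numeric(0)),
                 data.frame(group = character(0), all_protective = logical(0)))
  rownames(out) <- NULL
  out
}

#' Respondents covered by rules
#'
#' A respondent is covered by a rule when their transaction contains every
#' item of the rule's antecedent and consequent (the union whose frequency
#' is the rule's support).
#'
#' @param rules An `association_rules` data frame (one or more rows).
#' @param dataset A `survey_dataset`.
#' @return `rule_coverage`: integer vector, per rule, of covered-respondent
#'   counts; `covered_respondents`: logical vector over transactions, TRUE
#'   where at least one rule covers the respondent.
#' @export
rule_coverage <- function(rules, dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  vapply(seq_len(nrow(rules)), function(i) {
    idx <- parse_item_tokens(
      c(strsplit(rules$antecedent[i], ";", fixed = TRUE)[[1L]],
        strsplit(rules$consequent[i], ";", fixed = TRUE)[[1L]]),
      dataset$universe, what = "rule")
    as.integer(count_itemset(dataset$incidence, idx))
  }, 0L)
}

#' @rdname rule_coverage
#' @export
covered_respondents <- function(rules, dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  covered <- rep(FALSE, dataset$n)
  for (i in seq_len(nrow(rules))) {
    idx <- parse_item_tokens(
      c(strsplit(rules$antecedent[i], ";", fixed = TRUE)[[1L]],
        strsplit(rules$consequent[i], ";", fixed = TRUE)[[1L]]),
      dataset$universe, what = "rule")
    covered <- covered |
      (rowSums(dataset$incidence[, idx, drop = FALSE]) == length(idx))
  }
  covered
}

#' Venn partition of respondents over the four behaviors
#'
#' Assigns every respondent to exactly one of the 16 cells defined by
#' presence/absence of the four behavior items, the cross-classification a
#' four-set Venn diagram displays. By default the partition covers all
#' respondents, independent of any mined rules; pass `within` (e.g.
#' [covered_respondents()]) to restrict to a subset, as when reporting only
#' rule-covered respondents.
#'
#' @param dataset A `survey_dataset`.
#' @param spec A [behavior_spec()].
#' @param within Optional logical vector over transactions restricting the
#'   partition (counts and percentages then refer to that subset).
#' @param decimals Decimal places for the half-up-rounded percentage.
#' @return A `venn_table` data frame: 16 rows with 0/1 columns `distance`,
#'   `sanitize`, `mask`, `go_out_normally`, then `count` and `percent`;
#'   counts sum to the number of respondents considered.
#' @export
venn_partition <- function(dataset, spec, within = NULL, decimals = 1) {
  idx <- behavior_indices(spec, dataset)
  m <- dataset$incidence[, idx, drop = FALSE]
  if (!is.null(within)) {
    stopifnot(is.logical(within), length(within) == dataset$n)
    m <- m[within, , drop = FALSE]
  }
  n <- nrow(m)
  if (n == 0L) stop("no respondents to partition", call. = FALSE)
  cell <- as.integer(m %*% c(8L, 4L, 2L, 1L))  # distance is the high bit
  counts <- tabulate(cell + 1L, nbins = 16L)
  profiles <- expand.grid(go_out_normally = 0:1, mask = 0:1,
                          sanitize = 0:1, distance = 0:1)[, 4:1]
  out <- cbind(profiles,
               data.frame(count = counts,
                          percent = round_half_up(100 * counts / n, decimals)))
  rownames(out) <- NULL
  structure(out, n = n, class = c("venn_table", "data.frame"))
}

#' Print a percentage the way survey tables do
#'
#' `100 * count / n`, rounded half-up to the requested number of decimal
#' places and formatted with exactly that many decimals.
#'
#' @param count Non-negative integer count, at most `n`.
#' @param n Positive total.
#' @param decimals Decimal places (default 1).
#' @return Character vector, e.g. `"47.6"`.
#' @export
format_percentage <- function(count, n, decimals = 1) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(count < 0 | count > n))
    stop("count must lie in [0, n]", call. = FALSE)
  formatC(round_half_up(100 * count / n, decimals),
          format = "f", digits = decimals)
}
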