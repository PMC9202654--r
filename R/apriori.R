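#' Mining thresholds and constraints
#'
#' Holds the interestingness thresholds of the rule search. Defaults follow
#' the analysis this package reproduces: minimum support 5% and minimum
#' confidence 68%, both inclusive. Threshold tests are performed on count
#' ratios (integer numerators and denominators) with a 1e-9 absolute guard,
#' so a support of exactly 5/100 passes a 0.05 threshold regardless of
#' binary representation.
#'
#' @param min_support Minimum fraction of transactions containing an
#'   itemset (rule support applies to antecedent-union-consequent), in (0, 1].
#' @param min_confidence Minimum conditional frequency of the consequent
#'   given the antecedent, in (0, 1].
#' @param max_itemset_size Optional cap on itemset size (`NULL` = no cap).
#' @param use_roles If `TRUE` (default), rule generation only emits rules
#'   whose antecedent items come from antecedent-eligible questions and
#'   whose consequent items come from consequent-eligible questions. Set
#'   `FALSE` to count rules over all possible consequents.
#' @return A `mining_config` object.
#' @export
mining_config <- function(min_support = 0.05, min_confidence = 0.68,
                          max_itemset_size = NULL, use_roles = TRUE) {
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      is.na(min_support) || min_support <= 0 || min_support > 1)
    stop("min_support must be a single number in (0, 1]", call. = FALSE)
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      is.na(min_confidence) || min_confidence <= 0 || min_confidence > 1)
    stop("min_confidence must be a single number in (0, 1]", call. = FALSE)
  if (!is.null(max_itemset_size)) {
    max_itemset_size <- as.integer(max_itemset_size)
    if (is.na(max_itemset_size) || max_itemset_size < 1L)
      stop("max_itemset_size must be a positive integer or NULL", call. = FALSE)
  }
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_itemset_size = max_itemset_size,
                 use_roles = isTRUE(use_roles)),
            class = "mining_config")
}

# count >= threshold * base, robust to the threshold arriving as a double
# (counts are exact integers; the guard is far below their spacing).
meets_threshold <- function(count, threshold, base) {
  count >= threshold * base - 1e-9
}

# Deterministic sort key for an index vector: zero-padded indices joined by
# a space. Because item indices are assigned in canonical (question_id,
# answer) radix order, radix-sorting these keys is canonical itemset order,
# with a prefix sorting before its extensions.
itemset_key <- function(idx) paste(sprintf("%05d", idx), collapse = " ")

count_itemset <- function(mat, idx) {
  k <- length(idx)
  if (k == 0L) return(nrow(mat))
  if (k == 1L) return(sum(mat[, idx]))
  sum(rowSums(mat[, idx, drop = FALSE]) == k)
}

#' Support of an itemset in a dataset
#'
#' The fraction of transactions containing every item of the set. The empty
#' itemset has support 1 (every transaction contains it).
#'
#' @param itemset Character vector of `"question=answer"` item tokens (may
#'   be empty).
#' @param dataset A `survey_dataset`.
#' @return A fraction in `[0, 1]`.
#' @export
support_of <- function(itemset, dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  idx <- parse_item_tokens(itemset, dataset$universe)
  count_itemset(dataset$incidence, idx) / dataset$n
}

record_table <- function(index_list, counts, n, universe) {
  index_list <- lapply(unname(index_list), function(i) as.integer(unname(i)))
  counts <- unname(counts)
  size <- lengths(index_list)
  keys <- vapply(index_list, itemset_key, "")
  ord <- order(size, -counts, keys, method = "radix")
  index_list <- index_list[ord]
  df <- data.frame(
    itemset = vapply(index_list, function(i)
      paste(universe$token[i], collapse = ";"), ""),
    size = size[ord],
    count = as.integer(counts[ord]),
    support = counts[ord] / n,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  structure(df, index_list = index_list, n = n,
            class = c("frequent_itemsets", "data.frame"))
}

#' Mine frequent itemsets level-wise (Apriori)
#'
#' Classic Apriori: frequent 1-itemsets are found by a column scan; frequent
#' k-itemsets are built by joining (k-1)-itemsets that share a (k-2)-prefix
#' in canonical order, pruning every candidate with an infrequent (k-1)-subset
#' (downward closure), then counting the survivors against the transactions.
#' Transactions holding fewer than k frequent items are skipped at level k.
#'
#' @param dataset A `survey_dataset`.
#' @param config A [mining_config()].
#' @return A `frequent_itemsets` data frame (`itemset`, `size`, `count`,
#'   `support`), sorted by size ascending, support descending, canonical
#'   itemset order.
#' @export
mine_frequent_itemsets <- function(dataset, config = mining_config()) {
  stopifnot(inherits(dataset, "survey_dataset"), inherits(config, "mining_config"))
  m <- dataset$incidence
  n <- dataset$n
  ms <- config$min_support
  cap <- if (is.null(config$max_itemset_size)) Inf else config$max_itemset_size
  qid <- dataset$universe$question_id

  counts1 <- colSums(m)
  freq1 <- which(meets_threshold(counts1, ms, n))
  all_sets <- lapply(freq1, identity)
  all_counts <- counts1[freq1]
  frequent_keys <- new.env(hash = TRUE, parent = emptyenv())
  for (j in freq1) assign(itemset_key(j), TRUE, envir = frequent_keys)

  prev <- all_sets  # frequent (k-1)-itemsets in canonical order
  k <- 2L
  while (length(prev) >= 2L && k <= cap) {
    prev <- prev[order(vapply(prev, itemset_key, ""), method = "radix")]
    cands <- apriori_join(prev, k, qid, frequent_keys)
    if (!length(cands)) break
    active <- rowSums(m[, freq1, drop = FALSE]) >= k
    sub <- m[active, , drop = FALSE]
    cnt <- vapply(cands, function(idx) count_itemset(sub, idx), 0)
    keep <- meets_threshold(cnt, ms, n)
    prev <- cands[keep]
    if (length(prev)) {
      for (s in prev) assign(itemset_key(s), TRUE, envir = frequent_keys)
      all_sets <- c(all_sets, prev)
      all_counts <- c(all_counts, cnt[keep])
    }
    k <- k + 1L
  }
  record_table(all_sets, all_counts, n, dataset$universe)
}

# Candidate generation: join lexicographically sorted frequent (k-1)-sets
# sharing their first k-2 items; drop candidates with two items from one
# question (impossible in a transaction) or any infrequent (k-1)-subset.
apriori_join <- function(prev, k, qid, frequent_keys) {
  prefixes <- vapply(prev, function(i) itemset_key(i[-(k - 1L)]), "")
  out <- list()
  for (grp in split(seq_along(prev), prefixes)) {
    if (length(grp) < 2L) next
    lasts <- vapply(prev[grp], function(i) i[k - 1L], 0L)
    o <- order(lasts)
    grp <- grp[o]; lasts <- lasts[o]
    for (a in seq_len(length(grp) - 1L)) {
      base <- prev[[grp[a]]]
      for (b in (a + 1L):length(grp)) {
        cand <- c(base, lasts[b])
        if (anyDuplicated(qid[cand])) next
        pruned <- FALSE
        for (drop in seq_len(k - 2L)) {  # the two (k-1)-parents are frequent
          if (!exists(itemset_key(cand[-drop]), envir = frequent_keys,
                      inherits = FALSE)) { pruned <- TRUE; break }
        }
        if (!pruned) out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Exhaustive frequent-itemset enumeration (test oracle)
#'
#' Enumerates every non-empty subset of the observed items by bitmask
#' containment arithmetic — a deliberately different code path from the
#' level-wise miner — and filters by support. Refuses item universes above
#' 20 observed items (2^20 subsets) to guard against exponential blowup.
#'
#' @inheritParams mine_frequent_itemsets
#' @return Same structure and ordering contract as
#'   [mine_frequent_itemsets()].
#' @export
brute_force_frequent_itemsets <- function(dataset, config = mining_config()) {
  stopifnot(inherits(dataset, "survey_dataset"), inherits(config, "mining_config"))
  m <- dataset$incidence
  n <- dataset$n
  obs <- which(colSums(m) > 0L)
  k <- length(obs)
  if (k > 20L)
    stop("brute-force enumeration refused: ", k,
         " observed items exceed the 20-item guard", call. = FALSE)
  cap <- if (is.null(config$max_itemset_size)) Inf else config$max_itemset_size
  if (k == 0L) return(record_table(list(), integer(0), n, dataset$universe))
  bits <- as.integer(2^(seq_len(k) - 1L))
  tmask <- as.integer(m[, obs, drop = FALSE] %*% bits)
  sets <- list(); counts <- numeric(0)
  for (s in seq_len(2L^k - 1L)) {
    member <- bitwAnd(s, bits) > 0L
    if (sum(member) > cap) next
    cnt <- sum(bitwAnd(tmask, s) == s)
    if (meets_threshold(cnt, config$min_support, n)) {
      sets[[length(sets) + 1L]] <- obs[member]
      counts <- c(counts, cnt)
    }
  }
  record_table(sets, counts, n, dataset$universe)
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset Z of size >= 2 and every non-empty proper
#' subset A of Z, the rule A => Z\\A is emitted when its confidence
#' support(Z)/support(A) meets the threshold and, if role constraints are
#' active, every antecedent item belongs to an antecedent-eligible question
#' and every consequent item to a consequent-eligible one. All metrics are
#' derived from the itemset counts; lift is
#' support(Z) / (support(A) * support(Z\\A)).
#'
#' @param frequent Output of [mine_frequent_itemsets()] (or the brute-force
#'   oracle) on the same dataset.
#' @param dataset The `survey_dataset` the itemsets were mined from.
#' @param config The same [mining_config()].
#' @return An `association_rules` data frame with columns `antecedent`,
#'   `consequent` (semicolon-joined item tokens), `count`, `support`,
#'   `confidence`, `lift`, sorted by support, confidence and lift
#'   descending, then canonical antecedent/consequent order.
#' @export
generate_rules <- function(frequent, dataset, config = mining_config()) {
  stopifnot(inherits(frequent, "frequent_itemsets"),
            inherits(dataset, "survey_dataset"),
            inherits(config, "mining_config"))
  if (attr(frequent, "n") != dataset$n)
    stop("frequent itemsets were mined from a dataset of different size",
         call. = FALSE)
  index_list <- attr(frequent, "index_list")
  n <- dataset$n
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(index_list))
    assign(itemset_key(index_list[[i]]), frequent$count[i], envir = counts)
  roles <- question_roles(dataset$codebook)
  item_role <- roles[match(dataset$universe$question_id, names(roles))]
  ante_ok <- item_role %in% c("antecedent", "both")
  cons_ok <- item_role %in% c("consequent", "both")

  ante <- list(); cons <- list(); cnt <- numeric(0); conf <- numeric(0)
  for (r in which(frequent$size >= 2L)) {
    z <- index_list[[r]]
    cz <- frequent$count[r]
    s <- length(z)
    for (mask in seq_len(2L^s - 2L)) {
      inA <- bitwAnd(mask, as.integer(2^(seq_len(s) - 1L))) > 0L
      a <- z[inA]; c_ <- z[!inA]
      if (config$use_roles && (!all(ante_ok[a]) || !all(cons_ok[c_]))) next
      ca <- get(itemset_key(a), envir = counts)  # frequent by downward closure
      if (!meets_threshold(cz, config$min_confidence, ca)) next
      ante[[length(ante) + 1L]] <- a
      cons[[length(cons) + 1L]] <- c_
      cnt <- c(cnt, cz)
      conf <- c(conf, cz / ca)
    }
  }
  cc <- vapply(cons, function(i) get(itemset_key(i), envir = counts), 0)
  lift <- if (length(cnt)) cnt * n / (vapply(ante, function(i)
    get(itemset_key(i), envir = counts), 0) * cc) else numeric(0)
  akey <- vapply(ante, itemset_key, "")
  ckey <- vapply(cons, itemset_key, "")
  ord <- order(-cnt, -conf, -lift, akey, ckey, method = "radix")
  df <- data.frame(
    antecedent = vapply(ante[ord], function(i)
      paste(dataset$universe$token[i], collapse = ";"), ""),
    consequent = vapply(cons[ord], function(i)
      paste(dataset$universe$token[i], collapse = ";"), ""),
    count = as.integer(cnt[ord]),
    support = cnt[ord] / n,
    confidence = conf[ord],
    lift = lift[ord],
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  structure(df, n = n, class = c("association_rules", "data.frame"))
}
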