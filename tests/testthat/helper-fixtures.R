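# Fixtures are built in code: small random survey datasets and independent
# oracles the mining implementation is checked against.

# The five-transaction worked example over three yes-items a, b, c:
# {abc, ab, ac, bc, abc}. Supports: each singleton 0.8, each pair 0.6,
# the triple 0.4.
toy_abc_dataset <- function() {
  cb <- codebook(list(
    question_def("a", "y", role = "both"),
    question_def("b", "y", role = "both"),
    question_def("c", "y", role = "both")
  ))
  raw <- data.frame(a = c("y", "y", "y", NA, "y"),
                    b = c("y", "y", NA, "y", "y"),
                    c = c("y", NA, "y", "y", "y"))
  encode_transactions(raw, cb)
}

# A dataset of `n` transactions in which exactly `k` contain the
# mask-wearing item (the published toy database has n = 100, k = 70).
mask_toy_dataset <- function(n = 100, k = 70) {
  cb <- codebook(list(
    question_def("gender", c("female", "male"), role = "antecedent"),
    question_def("mask", c("yes", "no"), role = "consequent")
  ))
  raw <- data.frame(gender = rep("female", n),
                    mask = c(rep("yes", k), rep("no", n - k)))
  encode_transactions(raw, cb)
}

# Random survey: nq two-answer questions with mixed roles, random answers
# with some missingness. Item universe size 2*nq (<= 14 by default), so the
# brute-force oracles stay cheap.
random_survey <- function(seed, n = 30, nq = 5, missing_rate = 0.1) {
  set.seed(seed)
  qs <- lapply(seq_len(nq), function(i) {
    question_def(paste0("q", i), c("u", "v"),
                 role = sample(c("antecedent", "consequent", "both"), 1L))
  })
  # guarantee at least one of each eligibility
  qs[[1]] <- question_def("q1", c("u", "v"), role = "antecedent")
  qs[[nq]] <- question_def(paste0("q", nq), c("u", "v"), role = "consequent")
  cb <- codebook(qs)
  raw <- as.data.frame(lapply(seq_len(nq), function(i) {
    x <- sample(c("u", "v"), n, replace = TRUE)
    x[stats::runif(n) < missing_rate] <- NA
    x
  }))
  names(raw) <- paste0("q", seq_len(nq))
  encode_transactions(raw, cb)
}

# Independent frequent-itemset oracle: enumerate every non-empty subset of
# observed items with plain matrix scans (no bitmasks, no level-wise join),
# returning a plain sorted table of itemset token / count pairs.
scan_frequent_oracle <- function(dataset, config) {
  m <- dataset$incidence
  n <- dataset$n
  obs <- which(colSums(m) > 0L)
  cap <- if (is.null(config$max_itemset_size)) length(obs)
         else min(config$max_itemset_size, length(obs))
  out <- list()
  for (k in seq_len(cap)) {
    combos <- utils::combn(obs, k, simplify = FALSE)
    for (idx in combos) {
      cnt <- sum(rowSums(m[, idx, drop = FALSE]) == k)
      if (cnt / n >= config$min_support - 1e-9)
        out[[length(out) + 1L]] <- data.frame(
          itemset = paste(dataset$universe$token[idx], collapse = ";"),
          count = cnt)
    }
  }
  if (!length(out)) return(data.frame(itemset = character(0), count = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$itemset), , drop = FALSE]
}

# Independent rule oracle: for every support-qualifying union found by the
# scan oracle, enumerate every antecedent/consequent split, recompute all
# counts by direct scans, and apply confidence and role filters.
scan_rule_oracle <- function(dataset, config) {
  m <- dataset$incidence
  n <- dataset$n
  freq <- scan_frequent_oracle(dataset, config)
  roles <- vapply(dataset$codebook$questions, `[[`, "", "role")
  item_role <- roles[match(dataset$universe$question_id, names(roles))]
  out <- list()
  for (set_tokens in freq$itemset) {
    tokens <- strsplit(set_tokens, ";", fixed = TRUE)[[1L]]
    s <- length(tokens)
    if (s < 2L) next
    idx <- match(tokens, dataset$universe$token)
    cz <- sum(rowSums(m[, idx, drop = FALSE]) == s)
    for (mask in seq_len(2L^s - 2L)) {
      inA <- bitwAnd(mask, 2L^(seq_len(s) - 1L)) > 0L
      a <- idx[inA]; c_ <- idx[!inA]
      if (config$use_roles &&
          (!all(item_role[a] %in% c("antecedent", "both")) ||
           !all(item_role[c_] %in% c("consequent", "both")))) next
      ca <- sum(rowSums(m[, a, drop = FALSE]) == length(a))
      if (cz / ca < config$min_confidence - 1e-9) next
      cc <- sum(rowSums(m[, c_, drop = FALSE]) == length(c_))
      out[[length(out) + 1L]] <- data.frame(
        antecedent = paste(dataset$universe$token[a], collapse = ";"),
        consequent = paste(dataset$universe$token[c_], collapse = ";"),
        count = cz, confidence = cz / ca, lift = cz * n / (ca * cc))
    }
  }
  if (!length(out))
    return(data.frame(antecedent = character(0), consequent = character(0),
                      count = integer(0), confidence = numeric(0),
                      lift = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$antecedent, df$consequent), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# normalize a frequent_itemsets table for set comparison with the oracle
freq_as_plain <- function(freq) {
  df <- data.frame(itemset = freq$itemset, count = freq$count)
  df <- df[order(df$itemset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rules_as_plain <- function(rules) {
  df <- data.frame(antecedent = rules$antecedent, consequent = rules$consequent,
                   count = rules$count, confidence = rules$confidence,
                   lift = rules$lift)
  df <- df[order(df$antecedent, df$consequent), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# small codebook for planted-rule cohorts: a work-situation antecedent, two
# noise antecedents and the four behavior questions
planted_cohort_codebook <- function() {
  yn <- c("yes", "no")
  codebook(list(
    question_def("home_office", yn, role = "antecedent"),
    question_def("gender", c("female", "male"), role = "antecedent"),
    question_def("afraid_financial", yn, role = "antecedent"),
    question_def("distance_1m", yn, role = "consequent"),
    question_def("sanitize_hands", yn, role = "consequent"),
    question_def("mask_necessary", yn, role = "consequent"),
    question_def("go_out_normally", yn, role = "consequent")
  ))
}

# behavior marginals near the study's first round, with going-out-normally
# at 3% (below the 5% support floor); antecedent noise near 50/50
planted_cohort_profile <- function() {
  latent_class_spec(1, list(list(
    home_office = c(yes = 0.345, no = 0.655),
    gender = c(female = 0.55, male = 0.45),
    afraid_financial = c(yes = 0.27, no = 0.73),
    distance_1m = c(yes = 0.58, no = 0.42),
    sanitize_hands = c(yes = 0.62, no = 0.38),
    mask_necessary = c(yes = 0.64, no = 0.36),
    go_out_normally = c(yes = 0.03, no = 0.97)
  )))
}

planted_cohort <- function(seed, n = 5000,
                           prevalence = 0.2, confidence = 0.8) {
  simulate_survey(synthetic_config(
    n = n, seed = seed, cb = planted_cohort_codebook(),
    spec = planted_cohort_profile(),
    planted = planted_rule("home_office=yes", "mask_necessary=yes",
                           target_confidence = confidence,
                           antecedent_prevalence = prevalence)))
}
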