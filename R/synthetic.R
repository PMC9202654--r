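#' Latent-class answer model
#'
#' A finite mixture over respondent classes; each class carries, for every
#' question, a probability distribution over its allowed answers plus the
#' reserved `"missing"` category. Sampling a cohort means drawing a class
#' per respondent and then answers independently per question given the
#' class — dependence among items is induced only through class membership
#' (and through planted rules).
#'
#' @param class_weights Numeric mixture proportions, non-negative, summing
#'   to 1 (tolerance 1e-9).
#' @param profiles List (one element per class) of named lists: per
#'   question id, a named probability vector over
#'   `allowed_answers + "missing"` (absent categories count as 0) summing
#'   to 1 (tolerance 1e-9).
#' @return A `latent_class_spec` object.
#' @export
latent_class_spec <- function(class_weights, profiles) {
  class_weights <- as.numeric(class_weights)
  if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-9)
    stop("class weights must be non-negative and sum to 1", call. = FALSE)
  if (length(profiles) != length(class_weights))
    stop("one profile per class weight required", call. = FALSE)
  for (pr in profiles) {
    for (qid in names(pr)) {
      p <- pr[[qid]]
      if (is.null(names(p)) || any(!nzchar(names(p))))
        stop("answer probabilities for '", qid, "' must be named", call. = FALSE)
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("answer probabilities for '", qid,
             "' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  structure(list(class_weights = class_weights, profiles = profiles),
            class = "latent_class_spec")
}

#' Plant a ground-truth rule in a synthetic cohort
#'
#' Describes a dependency the generator injects so recovery by the mining
#' pipeline can be tested: the antecedent itemset is forced to occur at
#' `antecedent_prevalence`, and among antecedent carriers the consequent is
#' forced present with probability `target_confidence` and forced absent
#' otherwise, so the rule's population confidence equals the target.
#'
#' @param antecedent,consequent Character vectors of `"question=answer"`
#'   item tokens; the two sides must involve disjoint question sets.
#' @param target_confidence Fraction in (0, 1].
#' @param antecedent_prevalence Fraction in (0, 1).
#' @return A `planted_rule` object.
#' @export
planted_rule <- function(antecedent, consequent, target_confidence,
                         antecedent_prevalence) {
  stopifnot(length(antecedent) >= 1L, length(consequent) >= 1L)
  if (target_confidence <= 0 || target_confidence > 1)
    stop("target_confidence must be in (0, 1]", call. = FALSE)
  if (antecedent_prevalence <= 0 || antecedent_prevalence >= 1)
    stop("antecedent_prevalence must be in (0, 1)", call. = FALSE)
  aq <- sub("=.*$", "", antecedent); cq <- sub("=.*$", "", consequent)
  if (length(intersect(aq, cq)) || anyDuplicated(aq) || anyDuplicated(cq))
    stop("planted antecedent and consequent must involve distinct questions",
         call. = FALSE)
  structure(list(antecedent = antecedent, consequent = consequent,
                 target_confidence = target_confidence,
                 antecedent_prevalence = antecedent_prevalence),
            class = "planted_rule")
}

#' Synthetic cohort configuration
#'
#' @param n Cohort size (> 0).
#' @param seed Integer seed; a fixed seed makes the cohort bit-for-bit
#'   reproducible.
#' @param cb The [codebook()] the cohort is generated against.
#' @param spec A [latent_class_spec()]; defaults to [default_t1_profile()]
#'   when `cb` is the default codebook.
#' @param planted List of [planted_rule()] objects (may be empty).
#' @param timepoint Timepoint label for the resulting dataset.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n, seed, cb = default_codebook(),
                             spec = default_t1_profile(), planted = list(),
                             timepoint = "T1") {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer", call. = FALSE)
  stopifnot(inherits(cb, "codebook"), inherits(spec, "latent_class_spec"))
  if (inherits(planted, "planted_rule")) planted <- list(planted)
  stopifnot(all(vapply(planted, inherits, TRUE, "planted_rule")))
  # validate the spec against the codebook
  for (pr in spec$profiles) {
    extra <- setdiff(names(pr), question_ids(cb))
    if (length(extra))
      stop("profile covers unknown question(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    for (qid in names(pr)) {
      legal <- c(cb$questions[[qid]]$answers, "missing")
      bad <- setdiff(names(pr[[qid]]), legal)
      if (length(bad))
        stop("profile for '", qid, "' has illegal answer(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  u <- item_universe(codebook(cb$questions, "explicit_missing_item"))
  for (p in planted) {
    parse_item_tokens(p$antecedent, u, "planted antecedent")
    parse_item_tokens(p$consequent, u, "planted consequent")
  }
  structure(list(n = n, seed = as.integer(seed), codebook = cb, spec = spec,
                 planted = planted, timepoint = timepoint),
            class = "synthetic_config")
}

#' Simulate a survey cohort
#'
#' Draws `n` respondents from the latent-class model, then applies each
#' planted rule by post-hoc overwrite: antecedent answers are set for a
#' Bernoulli(`antecedent_prevalence`) subset and blanked elsewhere, and
#' among carriers the consequent answers are set with probability
#' `target_confidence` and blanked otherwise ("blanked" = made missing).
#' One pseudo-random stream is consumed in fixed question order, so a fixed
#' seed reproduces the cohort exactly; the caller's RNG state is restored
#' on exit. The overwrite distorts the marginals of the questions involved;
#' the realized planted counts are recorded in the result's `planted`
#' attribute.
#'
#' @param config A [synthetic_config()].
#' @return A `survey_dataset` (see [encode_transactions()]); the raw
#'   response table is attached as attribute `raw_table` and planted-rule
#'   bookkeeping as attribute `planted`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister")

  cb <- config$codebook
  n <- config$n
  spec <- config$spec
  k <- length(spec$class_weights)
  cls <- if (k == 1L) rep(1L, n) else
    sample.int(k, n, replace = TRUE, prob = spec$class_weights)

  raw <- as.data.frame(
    matrix(NA_character_, nrow = n, ncol = length(cb$questions),
           dimnames = list(NULL, question_ids(cb))),
    stringsAsFactors = FALSE)
  for (qid in question_ids(cb)) {  # fixed question order, one stream
    u <- stats::runif(n)
    for (g in seq_len(k)) {
      p <- spec$profiles[[g]][[qid]]
      rows <- which(cls == g)
      if (!length(rows)) next
      if (is.null(p)) next  # question absent from profile stays missing
      ans <- names(p)
      j <- findInterval(u[rows], cumsum(p), left.open = TRUE) + 1L
      pick <- ans[pmin(j, length(ans))]  # guard the top boundary round-off
      pick[pick == "missing"] <- NA_character_
      raw[rows, qid] <- pick
    }
  }

  planted_log <- list()
  for (p in config$planted) {
    aq <- sub("=.*$", "", p$antecedent); aa <- sub("^[^=]*=", "", p$antecedent)
    cq <- sub("=.*$", "", p$consequent); ca <- sub("^[^=]*=", "", p$consequent)
    carrier <- stats::runif(n) < p$antecedent_prevalence
    for (j in seq_along(aq)) {
      raw[carrier, aq[j]] <- aa[j]
      raw[!carrier, aq[j]] <- NA_character_
    }
    hit <- carrier & (stats::runif(n) < p$target_confidence)
    for (j in seq_along(cq)) {
      raw[hit, cq[j]] <- ca[j]
      raw[carrier & !hit, cq[j]] <- NA_character_
    }
    planted_log[[length(planted_log) + 1L]] <-
      list(antecedent = p$antecedent, consequent = p$consequent,
           n_carriers = sum(carrier), n_hits = sum(hit))
  }

  ds <- encode_transactions(raw, cb, timepoint = config$timepoint)
  attr(ds, "raw_table") <- raw
  attr(ds, "planted") <- planted_log
  attr(ds, "seed") <- config$seed
  ds
}

#' Uniform single-class profile over a codebook's answers
#'
#' Assigns every allowed answer of every question equal probability (no
#' missingness) — a neutral fallback profile for simulating against a
#' custom codebook when no calibrated profile is supplied.
#'
#' @param cb A [codebook()].
#' @return A [latent_class_spec()] with a single class.
#' @export
uniform_profile <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  profile <- lapply(cb$questions, function(q) {
    stats::setNames(rep(1 / length(q$answers), length(q$answers)), q$answers)
  })
  latent_class_spec(1, list(profile))
}

#' The default survey codebook
#'
#' The 26 variables whose marginal distributions the source tables print
#' at both timepoints: 11 sociodemographic questions, 11 yes/no work and
#' economic-perception questions (all antecedent-eligible) and the 4 yes/no
#' behavior questions (consequent-eligible): keeping 1 m distance,
#' hand sanitizing, only leaving home when necessary with a face covering,
#' and going out normally for work as usual.
#'
#' @param missing_policy Passed to [codebook()].
#' @return A [codebook()] object.
#' @export
default_codebook <- function(missing_policy = "omit_item") {
  yn <- c("yes", "no")
  q <- function(id, answers, role, label = id) question_def(id, answers, label, role)
  codebook(list(
    q("gender", c("female", "male"), "antecedent", "Gender"),
    q("age", c("18-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-90"),
      "antecedent", "Age band (years)"),
    q("education",
      c("no_schooling", "incomplete_elementary", "elementary_diploma",
        "high_school_diploma", "higher_education", "masters", "doctorate"),
      "antecedent", "Educational attainment"),
    q("ethnicity", c("asian", "white", "indigenous", "brown", "black"),
      "antecedent", "Self-reported ethnicity"),
    q("marital_status", c("married", "divorced", "single", "widowed"),
      "antecedent", "Marital status"),
    q("work_type",
      c("full_time_employee", "self_employed", "unemployed",
        "liberal_professional", "public_servant"),
      "antecedent", "Work type"),
    q("economic_class", c("A", "B", "C", "DE"), "antecedent",
      "CCEB economic class (merged)"),
    q("household_income",
      c("le_500", "501-1000", "1001-1500", "1501-2000", "2001-2500",
        "2501-3000", "3001-4000", "4001-5000", "5001-10000", "10001-25000",
        "ge_25001"),
      "antecedent", "Monthly household income (BRL)"),
    q("household_size", c("1", "2", "3-5", "6plus"), "antecedent",
      "People in the household"),
    q("maternal_education",
      c("no_schooling", "elementary_diploma", "junior_high_diploma",
        "high_school_diploma", "higher_education"),
      "antecedent", "Maternal education"),
    q("region", c("north", "northeast", "central_west", "southeast", "south"),
      "antecedent", "Brazilian geographic region"),
    q("more_productive", yn, "antecedent", "Feels more productive at work"),
    q("less_productive", yn, "antecedent", "Feels less productive at work"),
    q("worked_home_before", yn, "antecedent", "Already worked from home before"),
    q("home_office", yn, "antecedent", "Working or studying from home"),
    q("video_calls", yn, "antecedent", "Started using video calling apps often"),
    q("reduced_hours", yn, "antecedent", "Reduced hours or taking turns"),
    q("waiting_rules_end", yn, "antecedent",
      "Waiting for distancing rules' suspension to go back"),
    q("leave_home_afraid", yn, "antecedent",
      "Needs to leave home for work but is afraid"),
    q("afraid_financial", yn, "antecedent",
      "Afraid of present or future financial difficulties"),
    q("recover_soon", yn, "antecedent",
      "Believes economy recovers within 1-2 years"),
    q("recover_long", yn, "antecedent",
      "Believes economic struggles will last 2+ years"),
    q("distance_1m", yn, "consequent", "Stays at least 1 m apart when out"),
    q("sanitize_hands", yn, "consequent",
      "Sanitizes hands with alcohol gel or washes hands when out"),
    q("mask_necessary", yn, "consequent",
      "Only leaves home when extremely necessary, wearing a face covering"),
    q("go_out_normally", yn, "consequent",
      "Keeps moving outdoors (leaving home) for work as usual")
  ), missing_policy = missing_policy)
}

# published T1 counts (N = 7802) behind the default profile; missing takes
# the remainder so each distribution sums to 1 exactly
t1_counts <- function() {
  list(
    gender = c(female = 5366, male = 1148),
    age = c("18-19" = 98, "20-29" = 1188, "30-39" = 1601, "40-49" = 1464,
            "50-59" = 1133, "60-69" = 599, "70-90" = 118),
    education = c(no_schooling = 21, incomplete_elementary = 91,
                  elementary_diploma = 232, high_school_diploma = 1871,
                  higher_education = 3079, masters = 638, doctorate = 429),
    ethnicity = c(asian = 108, white = 3128, indigenous = 20, brown = 1173,
                  black = 244),
    marital_status = c(married = 3206, divorced = 801, single = 2204,
                       widowed = 33),
    work_type = c(full_time_employee = 1279, self_employed = 947,
                  unemployed = 1431, liberal_professional = 735,
                  public_servant = 1871),
    economic_class = c(A = 889, B = 2435, C = 1242, DE = 125),
    household_income = c(le_500 = 105, "501-1000" = 235, "1001-1500" = 349,
                         "1501-2000" = 368, "2001-2500" = 267,
                         "2501-3000" = 382, "3001-4000" = 417,
                         "4001-5000" = 429, "5001-10000" = 970,
                         "10001-25000" = 765, ge_25001 = 269),
    household_size = c("1" = 470, "2" = 1286, "3-5" = 2557, "6plus" = 172),
    maternal_education = c(no_schooling = 769, elementary_diploma = 1085,
                           junior_high_diploma = 541,
                           high_school_diploma = 1149,
                           higher_education = 1099),
    region = c(north = 273, northeast = 961, central_west = 362,
               southeast = 3624, south = 1076),
    more_productive = c(yes = 676, no = 7126),
    less_productive = c(yes = 2186, no = 5616),
    worked_home_before = c(yes = 379, no = 7423),
    home_office = c(yes = 2692, no = 5110),
    video_calls = c(yes = 2658, no = 5144),
    reduced_hours = c(yes = 803, no = 6999),
    waiting_rules_end = c(yes = 589, no = 7213),
    leave_home_afraid = c(yes = 821, no = 6981),
    afraid_financial = c(yes = 2139, no = 5663),
    recover_soon = c(yes = 2011, no = 5791),
    recover_long = c(yes = 3455, no = 4347),
    distance_1m = c(yes = 4525, no = 3277),
    sanitize_hands = c(yes = 4863, no = 2939),
    mask_necessary = c(yes = 4984, no = 2818),
    go_out_normally = c(yes = 123, no = 7679)
  )
}

#' Single-class answer profile calibrated to the published T1 marginals
#'
#' One latent class whose per-question answer probabilities equal the
#' published T1 counts divided by the cohort size N = 7802; each question's
#' remainder (respondents in the published "Missing" row) goes to the
#' reserved `"missing"` category, so every distribution sums to 1 exactly.
#' The four behavior questions have no missing mass.
#'
#' @return A [latent_class_spec()] with a single class.
#' @export
default_t1_profile <- function() {
  counts <- t1_counts()
  N <- 7802
  profile <- lapply(counts, function(cnt) {
    p <- cnt / N
    miss <- 1 - sum(p)
    if (miss > 1e-12) p <- c(p, missing = miss)
    p / sum(p)
  })
  latent_class_spec(1, list(profile))
}

#' @rdname default_t1_profile
#' @details `t1_marginals()` exposes the configured (analytic, pre-sampling)
#'   probabilities per question and answer, the calibration target the
#'   generator is tested against.
#' @return For `t1_marginals()`: data frame `question_id`, `answer`, `prob`.
#' @export
t1_marginals <- function() {
  prof <- default_t1_profile()$profiles[[1L]]
  do.call(rbind, lapply(names(prof), function(qid) {
    data.frame(question_id = qid, answer = names(prof[[qid]]),
               prob = unname(prof[[qid]]), stringsAsFactors = FALSE)
  }))
}
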