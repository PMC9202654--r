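make_rules <- function(antecedent, consequent) {
  structure(data.frame(antecedent = antecedent, consequent = consequent,
                       count = 10L, support = 0.1, confidence = 0.7,
                       lift = 1.2, stringsAsFactors = FALSE),
            n = 100L, class = c("association_rules", "data.frame"))
}

test_that("rules are grouped by which behavior items their consequents hold", {
  spec <- default_behavior_spec()
  rl <- make_rules(
    antecedent = rep("gender=female", 5),
    consequent = c(
      "distance_1m=yes;mask_necessary=yes;sanitize_hands=yes",  # all three
      "mask_necessary=yes",                                      # one protective
      "go_out_normally=yes",                                     # continued
      "go_out_normally=yes;mask_necessary=yes",                  # both groups
      "home_office=yes"                                          # no behavior
    ))
  g <- filter_rules_by_consequent(rl, spec)
  expect_equal(g$group_continued$consequent,
               c("go_out_normally=yes", "go_out_normally=yes;mask_necessary=yes"))
  expect_equal(nrow(g$group_protective), 3)
  expect_equal(g$group_all_protective$consequent,
               "distance_1m=yes;mask_necessary=yes;sanitize_hands=yes")
  expect_equal(g$n_discarded, 1)

  # all_protective is contained in protective
  expect_true(all(g$group_all_protective$consequent %in% g$group_protective$consequent))

  tab <- rule_group_table(g)
  expect_setequal(unique(tab$group), c("continued", "protective"))
  expect_equal(sum(tab$all_protective), 1)

  empty <- filter_rules_by_consequent(rl[0, ], spec)
  expect_equal(nrow(empty$group_continued), 0)
  expect_equal(nrow(empty$group_protective), 0)
})

test_that("randomized consequents match an independent membership check", {
  spec <- default_behavior_spec()
  pool <- c("distance_1m=yes", "sanitize_hands=yes", "mask_necessary=yes",
            "go_out_normally=yes", "home_office=yes", "gender=female")
  set.seed(31)
  cons <- vapply(1:30, function(i)
    paste(sample(pool, sample(1:3, 1)), collapse = ";"), "")
  rl <- make_rules(rep("age=30-39", 30), cons)
  g <- filter_rules_by_consequent(rl, spec)
  toks <- strsplit(cons, ";", fixed = TRUE)
  prot <- c("distance_1m=yes", "sanitize_hands=yes", "mask_necessary=yes")
  expect_equal(nrow(g$group_continued),
               sum(vapply(toks, function(t) "go_out_normally=yes" %in% t, TRUE)))
  expect_equal(nrow(g$group_protective),
               sum(vapply(toks, function(t) any(prot %in% t), TRUE)))
  expect_equal(nrow(g$group_all_protective),
               sum(vapply(toks, function(t) all(prot %in% t), TRUE)))
})

test_that("rule coverage counts union containment and equals support * n", {
  ds <- random_survey(42, n = 40, nq = 5, missing_rate = 0.15)
  cfg <- mining_config(0.15, 0.5)
  rl <- generate_rules(mine_frequent_itemsets(ds, cfg), ds, cfg)
  cov <- rule_coverage(rl, ds)
  for (i in seq_len(nrow(rl))) {
    idx <- match(c(strsplit(rl$antecedent[i], ";")[[1]],
                   strsplit(rl$consequent[i], ";")[[1]]),
                 colnames(ds$incidence))
    expect_equal(cov[i], sum(rowSums(ds$incidence[, idx, drop = FALSE]) == length(idx)))
  }
  # coverage / n is the rule support, exactly as a ratio of counts
  expect_identical(cov, rl$count)
  expect_equal(cov / ds$n, rl$support)

  # a rule absent from every transaction covers nobody
  absent <- make_rules("q1=u", "q5=v")
  raw <- data.frame(q1 = rep("v", 10), q5 = rep("u", 10))
  cb <- codebook(list(question_def("q1", c("u", "v"), role = "antecedent"),
                      question_def("q5", c("u", "v"), role = "consequent")))
  expect_equal(rule_coverage(absent, encode_transactions(raw, cb)), 0L)
})

test_that("the Venn partition conserves n and matches a 16-bin tally", {
  cb <- planted_cohort_codebook()
  spec <- default_behavior_spec()
  set.seed(7)
  n <- 200
  raw <- data.frame(
    home_office = sample(c("yes", "no"), n, TRUE),
    gender = sample(c("female", "male"), n, TRUE),
    afraid_financial = sample(c("yes", "no"), n, TRUE),
    distance_1m = sample(c("yes", "no"), n, TRUE),
    sanitize_hands = sample(c("yes", "no"), n, TRUE),
    mask_necessary = sample(c("yes", "no"), n, TRUE),
    go_out_normally = sample(c("yes", "no"), n, TRUE)
  )
  ds <- encode_transactions(raw, cb)
  v <- venn_partition(ds, spec)
  expect_equal(nrow(v), 16)
  expect_equal(sum(v$count), n)
  # independent tally loop
  for (r in seq_len(16)) {
    hit <- (raw$distance_1m == "yes") == (v$distance[r] == 1) &
      (raw$sanitize_hands == "yes") == (v$sanitize[r] == 1) &
      (raw$mask_necessary == "yes") == (v$mask[r] == 1) &
      (raw$go_out_normally == "yes") == (v$go_out_normally[r] == 1)
    expect_equal(v$count[r], sum(hit))
  }

  # a cohort built to hold 45 go-out-only respondents reports 45 in that cell
  n2 <- 7802
  raw2 <- data.frame(
    home_office = rep("no", n2), gender = rep("female", n2),
    afraid_financial = rep("no", n2),
    distance_1m = c(rep("no", 45), rep("yes", n2 - 45)),
    sanitize_hands = c(rep("no", 45), rep("yes", n2 - 45)),
    mask_necessary = c(rep("no", 45), rep("yes", n2 - 45)),
    go_out_normally = c(rep("yes", 45), rep("no", n2 - 45))
  )
  v2 <- venn_partition(encode_transactions(raw2, cb), spec)
  cell <- v2[v2$distance == 0 & v2$sanitize == 0 & v2$mask == 0 &
               v2$go_out_normally == 1, ]
  expect_equal(cell$count, 45)
  expect_equal(cell$percent, 0.6)
  all_cell <- v2[v2$distance == 1 & v2$sanitize == 1 & v2$mask == 1 &
                   v2$go_out_normally == 0, ]
  expect_equal(all_cell$count, n2 - 45)

  # restricted mode partitions only the designated respondents
  within <- raw2$go_out_normally == "yes"
  v3 <- venn_partition(encode_transactions(raw2, cb), spec, within = within)
  expect_equal(sum(v3$count), 45)
  expect_equal(v3$percent[v3$go_out_normally == 1 & v3$distance == 0 &
                            v3$sanitize == 0 & v3$mask == 0], 100)
})

test_that("percentages print half-up at the requested precision", {
  expect_identical(format_percentage(3711, 7802, 1), "47.6")
  expect_identical(format_percentage(1401, 3062, 1), "45.8")
  expect_identical(format_percentage(56, 3062, 1), "1.8")   # 1.8288 rounds down
  expect_identical(format_percentage(0, 7802, 1), "0.0")
  expect_identical(format_percentage(1, 8, 0), "13")        # 12.5 rounds half UP, not to even
  expect_identical(format_percentage(11, 32877, 2), "0.03")
  expect_error(format_percentage(1, 0), "positive")
  expect_error(format_percentage(5, 3), "\\[0, n\\]")
})
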