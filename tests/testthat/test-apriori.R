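test_that("support is the containment fraction, 1 for the empty itemset", {
  ds <- mask_toy_dataset(100, 70)
  expect_identical(support_of("mask=yes", ds), 0.7)
  expect_identical(support_of(character(0), ds), 1.0)
  expect_error(support_of("mask=maybe", ds), "unknown item")
  expect_error(support_of(c("mask=yes", "mask=no"), ds), "same question")

  # random itemsets match a direct containment scan
  ds2 <- random_survey(21, n = 20, nq = 4)
  obs <- colnames(ds2$incidence)[colSums(ds2$incidence) > 0]
  set.seed(99)
  for (i in 1:10) {
    tok <- sample(obs, 2)
    if (sub("=.*", "", tok[1]) == sub("=.*", "", tok[2])) next
    direct <- mean(ds2$incidence[, tok[1]] & ds2$incidence[, tok[2]])
    expect_equal(support_of(tok, ds2), direct)
  }
})

test_that("the five-transaction example mines exactly the six frequent sets", {
  ds <- toy_abc_dataset()
  cfg <- mining_config(min_support = 0.6, min_confidence = 0.5)
  fi <- mine_frequent_itemsets(ds, cfg)
  expect_equal(fi$itemset,
               c("a=y", "b=y", "c=y", "a=y;b=y", "a=y;c=y", "b=y;c=y"))
  expect_equal(fi$count, c(4L, 4L, 4L, 3L, 3L, 3L))
  expect_equal(fi$support, c(0.8, 0.8, 0.8, 0.6, 0.6, 0.6))
  # the triple sits at 0.4 and is excluded
  expect_false("a=y;b=y;c=y" %in% fi$itemset)

  # rule {a} -> {b}: support 0.6, confidence 0.6/0.8, lift 0.75/0.8
  rl <- generate_rules(fi, ds, cfg)
  r <- rl[rl$antecedent == "a=y" & rl$consequent == "b=y", ]
  expect_equal(r$support, 0.6)
  expect_equal(r$confidence, 0.75)
  expect_equal(r$lift, 0.9375)
})

test_that("degenerate thresholds behave: unanimity and config errors", {
  cb <- codebook(list(question_def("q1", c("u", "v"), role = "antecedent"),
                      question_def("q2", c("u", "v"), role = "consequent")))
  raw <- data.frame(q1 = rep("u", 8), q2 = c(rep("u", 5), rep("v", 3)))
  ds <- encode_transactions(raw, cb)
  fi <- mine_frequent_itemsets(ds, mining_config(min_support = 1.0))
  expect_equal(fi$itemset, "q1=u")  # the single universal item

  expect_error(mining_config(min_support = 0), "min_support")
  expect_error(mining_config(min_support = 1.01), "min_support")
  expect_error(mining_config(min_confidence = 0), "min_confidence")
  expect_error(mining_config(min_confidence = 1.2), "min_confidence")
  expect_error(mining_config(max_itemset_size = 0), "max_itemset_size")
})

test_that("identical supports give confidence 1 and lift 1/s", {
  # X and Y always co-occur in 6 of 10 transactions
  cb <- codebook(list(question_def("x", "y", role = "both"),
                      question_def("w", "y", role = "both")))
  raw <- data.frame(x = c(rep("y", 6), rep(NA, 4)),
                    w = c(rep("y", 6), rep(NA, 4)))
  ds <- encode_transactions(raw, cb)
  cfg <- mining_config(0.5, 0.5)
  rl <- generate_rules(mine_frequent_itemsets(ds, cfg), ds, cfg)
  expect_equal(nrow(rl), 2)  # both directions
  expect_equal(rl$confidence, c(1, 1))
  expect_equal(rl$lift, c(1 / 0.6, 1 / 0.6))
})

test_that("miner and rule generator match the exhaustive oracles", {
  for (seed in 101:110) {
    ds <- random_survey(seed, n = sample(15:40, 1), nq = sample(4:6, 1))
    cfg <- mining_config(min_support = sample(c(0.2, 0.25, 0.3), 1),
                         min_confidence = sample(c(0.5, 0.6, 0.68), 1),
                         use_roles = seed %% 2 == 0)
    fi <- mine_frequent_itemsets(ds, cfg)
    expect_identical(freq_as_plain(fi), freq_as_plain(
      brute_force_frequent_itemsets(ds, cfg)))
    expect_equal(freq_as_plain(fi)$count, scan_frequent_oracle(ds, cfg)$count)
    expect_equal(rules_as_plain(generate_rules(fi, ds, cfg)),
                 scan_rule_oracle(ds, cfg))
  }
})

test_that("mining output is deterministic across repeated runs", {
  ds <- random_survey(77, n = 35, nq = 6)
  cfg <- mining_config(0.2, 0.5)
  fi1 <- mine_frequent_itemsets(ds, cfg)
  fi2 <- mine_frequent_itemsets(ds, cfg)
  expect_identical(fi1$itemset, fi2$itemset)
  expect_identical(fi1$count, fi2$count)
  rl1 <- generate_rules(fi1, ds, cfg)
  rl2 <- generate_rules(fi2, ds, cfg)
  expect_identical(rl1, rl2)
  # ordering contract: size ascending, support descending within size
  expect_true(!is.unsorted(fi1$size))
  for (k in unique(fi1$size)) {
    expect_true(!is.unsorted(-fi1$support[fi1$size == k]))
  }
  expect_true(!is.unsorted(-rl1$support))
})

test_that("the size cap and role constraints restrict output as configured", {
  ds <- random_survey(55, n = 40, nq = 6, missing_rate = 0)
  capped <- mine_frequent_itemsets(ds, mining_config(0.1, 0.5, max_itemset_size = 2))
  expect_true(all(capped$size <= 2))
  full <- mine_frequent_itemsets(ds, mining_config(0.1, 0.5))
  expect_identical(freq_as_plain(capped), freq_as_plain(full[full$size <= 2, ]))

  cfg_roles <- mining_config(0.15, 0.5, use_roles = TRUE)
  cfg_free <- mining_config(0.15, 0.5, use_roles = FALSE)
  fi <- mine_frequent_itemsets(ds, cfg_roles)
  rl_roles <- generate_rules(fi, ds, cfg_roles)
  rl_free <- generate_rules(fi, ds, cfg_free)
  key <- function(r) paste(r$antecedent, r$consequent, sep = "->")
  expect_true(all(key(rl_roles) %in% key(rl_free)))
  roles <- vapply(ds$codebook$questions, `[[`, "", "role")
  for (i in seq_len(nrow(rl_roles))) {
    aq <- sub("=.*", "", strsplit(rl_roles$antecedent[i], ";")[[1]])
    cq <- sub("=.*", "", strsplit(rl_roles$consequent[i], ";")[[1]])
    expect_true(all(roles[aq] %in% c("antecedent", "both")))
    expect_true(all(roles[cq] %in% c("consequent", "both")))
  }
})

test_that("the brute-force oracle refuses oversized item universes", {
  cb <- codebook(c(
    lapply(1:11, function(i) question_def(paste0("q", i), c("u", "v"),
                                          role = "antecedent")),
    list(question_def("q12", c("u", "v"), role = "consequent"))
  ))
  set.seed(1)
  raw <- as.data.frame(matrix(sample(c("u", "v"), 12 * 5, TRUE), nrow = 5,
                              dimnames = list(NULL, paste0("q", 1:12))))
  ds <- encode_transactions(raw, cb)  # up to 24 observed items
  expect_error(brute_force_frequent_itemsets(ds, mining_config(0.2)),
               "20-item guard")
})
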