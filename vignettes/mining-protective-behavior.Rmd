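---
title: "Mining social determinants of protective behavior from survey transactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining social determinants of protective behavior from survey transactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behaviorminer)
```

## The problem and the model

During the COVID-19 pandemic, compliance with self-protective measures —
keeping at least 1 m distance from others when out of the house, sanitizing
or washing hands, and only leaving home when extremely necessary while
wearing a face covering — varied widely across social and economic strata.
`behaviorminer` treats a cross-sectional questionnaire cohort as a
*transaction database* and asks which combinations of sociodemographic and
work-situation answers co-occur with reports of protective (or
non-protective) behavior.

The atomic unit is an **item**, a `(question, answer)` pair such as
`home_office=yes`. A respondent's answers at one timepoint form a
**transaction** (a set of items, at most one per question). For an itemset
$Z$ and a database of $n$ transactions,

- **support**: $\mathrm{supp}(Z) = |\{t : Z \subseteq t\}| / n$, the
  fraction of respondents answering according to $Z$;
- a rule $X \Rightarrow Y$ (disjoint itemsets) has
  **confidence** $\mathrm{conf} = \mathrm{supp}(X \cup Y)/\mathrm{supp}(X)$,
  the conditional frequency of $Y$ given $X$; and
- **lift** $= \mathrm{supp}(X \cup Y)/(\mathrm{supp}(X)\,\mathrm{supp}(Y))$,
  the ratio of the observed joint frequency to the one expected under
  independence — 1 means no association, above 1 positive association.

Frequent itemsets are found with the level-wise **Apriori** algorithm:
frequent $k$-itemsets are built by joining frequent $(k-1)$-itemsets that
share a $(k-2)$-prefix in canonical order, and any candidate with an
infrequent $(k-1)$-subset is pruned before counting (downward closure).
Every frequent itemset of size $\ge 2$ is then split into every
antecedent/consequent pair, and splits that meet the confidence threshold
(and the role constraints below) become rules.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_support` | 0.05 | minimum fraction of respondents containing the rule's full item union (dimensionless fraction) |
| `min_confidence` | 0.68 | minimum conditional frequency of the consequent given the antecedent |
| `max_itemset_size` | unlimited | optional cap on pattern size |
| `use_roles` | `TRUE` | restrict antecedents to antecedent-eligible questions and consequents to consequent-eligible ones |

The defaults are the thresholds of the analysis this package
operationalizes: a 5% support floor ("the minimum frequency of any
question-answer pair to be considered relevant") and a 68% confidence
floor, both inclusive because they are stated as minima. Support of a rule
is the support of the union $X \cup Y$, the standard Apriori convention.
Role constraints are applied at **rule generation**, not at itemset mining,
and can be switched off to count the rules obtainable over all possible
consequents; this keeps the frequent-itemset stage identical in both
analyses.

## From survey files to rules

```{r toy}
cb <- codebook(list(
  question_def("home_office", c("yes", "no"), "Working from home",
               role = "antecedent"),
  question_def("mask_necessary", c("yes", "no"),
               "Only leaves home when necessary, masked", role = "consequent")
))
raw <- data.frame(home_office = c("yes", "yes", "no", NA, "yes"),
                  mask_necessary = c("yes", "yes", "no", "yes", "yes"))
ds <- encode_transactions(raw, cb)
support_of("mask_necessary=yes", ds)
```

Missing answers follow the codebook's `missing_policy`. The default,
`omit_item`, emits no item for a missing cell, so pattern support is
defined over *present* answers only — the cleanest semantics for mining.
The alternative `explicit_missing_item` materializes a reserved
`missing` answer so that descriptive tables (`dataset_summary()`) can
reproduce published "Missing" rows exactly. Which convention the original
analysis used for antecedent variables is not stated in its report; `omit_item`
is the default here because an absent answer cannot support a pattern.

Respondents are never pooled across survey rounds: each timepoint is its
own dataset, mined separately.

### Behavior groups and the Venn partition

After mining, rules are filtered by their **consequents**: rules whose
consequent contains the going-out-normally item describe people continuing
their pre-pandemic habits; rules whose consequent contains at least one of
the three protective items describe people adopting protection (with the
all-three subset reported separately). Antecedent content plays no part in
group membership. A rule "covers" a respondent when the transaction
contains the rule's full item union — the same count that defines the
rule's support.

Independently of any rules, `venn_partition()` classifies every respondent
into one of the $2^4$ cells of presence/absence of the four behavior
items, the cross-classification a four-set Venn diagram displays; a
restricted mode (`within =`) reproduces figure-style reporting limited to
rule-covered respondents, since published diagrams are ambiguous about
which denominator they use.

### Economic classification

The CCEB instrument scores households 0–46 and classifies them into
A, B1, B2, C1, C2, DE; analyses commonly merge B1/B2 into B and C1/C2
into C, the default `merge_map` of `cceb_config()`. The score-to-class
cutoff table is an ABEP publication that is revised over time and is not
printed in the survey report this package follows, so the cutoffs are
mandatory user configuration — there is deliberately no hard-coded
default, and the tests use a clearly labelled synthetic cutoff table.

## The synthetic cohort generator

The original raw survey data are not deposited, so the package ships a
seeded generator that emulates the cohort's statistical structure:

- a **latent-class model**: each respondent draws a class, then answers
  each question independently from that class's answer distribution
  (including a `missing` category). `default_t1_profile()` is a
  single-class profile whose per-question marginals equal the published
  first-round tables exactly (counts divided by N = 7802) for the 26
  variables with printed distributions — 11 sociodemographic, 11 binary
  work/economic-perception, and the 4 behavior questions. The survey
  counted 13 work-area antecedents, but two lack printed categorical
  distributions (average daily hours worked is continuous), so they cannot
  be calibrated and are omitted.
- **planted rules**: ground-truth dependencies for recovery testing. The
  antecedent is forced to a configured prevalence and, among carriers, the
  consequent is set with the target confidence and blanked otherwise — a
  post-hoc overwrite that controls the conditional frequency exactly in
  expectation at the cost of distorting the overwritten questions'
  marginals (the realized counts are recorded in the dataset's `planted`
  attribute).

One pseudo-random stream is consumed in fixed question order, so a fixed
seed reproduces a cohort bit for bit across platforms, and the caller's
RNG state is restored afterwards.

What the generator does **not** emulate: dependence among antecedent
variables beyond what a single class induces (the published tables give
marginals only, so any richer copula would be invented), longitudinal
linkage of respondents appearing in both rounds, and realistic
item-nonresponse mechanisms (missingness is independent given class).
Pipeline tests passing on synthetic cohorts therefore demonstrate
correctness of the machinery and recoverability of planted structure, not
fidelity to the original cohort's joint distribution.

```{r planted}
cbp <- codebook(list(
  question_def("home_office", c("yes", "no"), role = "antecedent"),
  question_def("gender", c("female", "male"), role = "antecedent"),
  question_def("mask_necessary", c("yes", "no"), role = "consequent"),
  question_def("distance_1m", c("yes", "no"), role = "consequent")
))
spec <- latent_class_spec(1, list(list(
  home_office = c(yes = 0.345, no = 0.655),
  gender = c(female = 0.6, male = 0.4),
  mask_necessary = c(yes = 0.64, no = 0.36),
  distance_1m = c(yes = 0.58, no = 0.42)
)))
ds <- simulate_survey(synthetic_config(
  5000, seed = 42, cb = cbp, spec = spec,
  planted = planted_rule("home_office=yes", "mask_necessary=yes",
                         target_confidence = 0.8,
                         antecedent_prevalence = 0.2)))
cfg <- mining_config()  # 5% support, 68% confidence
rules <- generate_rules(mine_frequent_itemsets(ds, cfg), ds, cfg)
subset(as.data.frame(rules), antecedent == "home_office=yes" &
         consequent == "mask_necessary=yes")
```

## Numerical and design choices

- **Canonical order.** Items are totally ordered by `(question_id,
  answer)` in C-locale (radix) string order; itemsets are kept sorted and
  compared lexicographically on item indices. All output orderings —
  itemsets by (size, support descending, canonical order), rules by
  (support, confidence, lift descending, antecedent then consequent) — are
  derived from it, so identical inputs give byte-identical outputs.
- **Threshold comparisons.** Support and confidence tests compare integer
  counts against `threshold * base` with a 1e-9 absolute guard. Counts are
  exact integers, so a support of exactly 5/100 passes a 0.05 floor
  regardless of the binary representation of 0.05; the guard is orders of
  magnitude below the spacing of achievable count ratios at survey scale.
- **Rounding.** Reported percentages round half-up (`format_percentage`),
  not half-to-even, matching how survey tables are conventionally printed;
  a 1e-9 nudge protects ratios that sit on a half boundary analytically
  but a hair below it in floating point.
- **Degenerate inputs.** An empty response table is an error (a dataset
  must have at least one transaction); the empty itemset has support 1;
  `min_support = 1` returns only unanimously held items; a candidate
  containing two items of one question is pruned outright since no
  transaction can contain it.
- **Counting strategy.** Transactions are a logical incidence matrix;
  level-k counting scans only transactions holding at least k frequent
  items. This is ample at survey scale (tens of thousands of rows, tens of
  items); no FP-Growth/Eclat variant is provided.
- **Verification scale.** The exhaustive oracles
  (`brute_force_frequent_itemsets()` and the scan-based rule oracle in the
  test helpers) are run on 50 seeded random datasets of up to 40
  transactions over up to 14 items, where full subset enumeration is
  exact and cheap; planted-rule recovery uses 20 cohorts of n = 5000 and
  marginal calibration one cohort of n = 7802, the published first-round
  size. These sizes make the whole suite run in well under a minute while
  keeping every check exact or governed by 4-standard-error bounds.

## Known limitations

- The published headline rule counts (1694 and 2490 behavior-consequent
  rules, 32,877 rules in total) are properties of the undeposited raw
  data; synthetic cohorts reproduce the *shape* of the analysis (which
  metrics, which filters, which exclusions) but not those exact counts.
- Group membership by consequent containment allows a rule mentioning both
  the going-out item and a protective item to belong to both groups; the
  flattened group table keeps such duplicates explicit.
- Under a single latent class, antecedent items are independent, so
  high-order antecedent combinations are rarer than in real cohorts where
  sociodemographic variables correlate; planted rules are the mechanism
  for making specific dependencies testable.
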