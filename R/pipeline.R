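#' Configure an end-to-end mining run
#'
#' Bundles everything one run needs: where the responses and codebook come
#' from (or a synthetic-cohort request in place of a file), the mining
#' thresholds, the binding of the four behavior items, and reporting
#' options. Validation happens here, before any data is touched, so a bad
#' threshold fails fast.
#'
#' @param outdir Output directory (created if needed).
#' @param responses Path to a responses CSV, or `NULL` when `simulate` is
#'   given.
#' @param codebook_path Path to a YAML/JSON codebook; `NULL` uses
#'   [default_codebook()].
#' @param simulate `NULL`, or a list `list(n =, seed =)` requesting a
#'   synthetic cohort from [default_t1_profile()] instead of reading a CSV.
#' @param mining A [mining_config()] or a list of its arguments.
#' @param behaviors A [behavior_spec()] or a list/vector with entries
#'   `distance`, `sanitize`, `mask`, `go_out_normally`; `NULL` uses
#'   [default_behavior_spec()].
#' @param timepoint Timepoint label.
#' @param decimals Decimal places for reported percentages.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(outdir, responses = NULL, codebook_path = NULL,
                            simulate = NULL, mining = mining_config(),
                            behaviors = NULL, timepoint = "T1", decimals = 1) {
  if (is.list(mining) && !inherits(mining, "mining_config"))
    mining <- do.call(mining_config, mining)
  stopifnot(inherits(mining, "mining_config"))
  if (is.null(behaviors)) behaviors <- default_behavior_spec()
  if (!inherits(behaviors, "behavior_spec"))
    behaviors <- behavior_spec(behaviors[["distance"]], behaviors[["sanitize"]],
                               behaviors[["mask"]], behaviors[["go_out_normally"]])
  if (is.null(responses) && is.null(simulate))
    stop("either 'responses' or 'simulate' must be given", call. = FALSE)
  if (!is.null(responses) && !file.exists(responses))
    stop("responses file not found: ", responses, call. = FALSE)
  if (!is.null(codebook_path) && !file.exists(codebook_path))
    stop("codebook file not found: ", codebook_path, call. = FALSE)
  if (!is.null(simulate) && (is.null(simulate$n) || is.null(simulate$seed)))
    stop("'simulate' needs both n and seed", call. = FALSE)
  structure(list(outdir = outdir, responses = responses,
                 codebook_path = codebook_path, simulate = simulate,
                 mining = mining, behaviors = behaviors,
                 timepoint = timepoint, decimals = decimals),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments
#'   (`outdir`, `responses`, `codebook`, `simulate`, `mining`, `behaviors`,
#'   `timepoint`, `decimals`).
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    outdir = raw$outdir %||% dirname(path),
    responses = raw$responses,
    codebook_path = raw$codebook,
    simulate = raw$simulate,
    mining = raw$mining %||% mining_config(),
    behaviors = raw$behaviors,
    timepoint = raw$timepoint %||% "T1",
    decimals = raw$decimals %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  plain <- list(
    responses = config$responses, codebook = config$codebook_path,
    simulate = config$simulate,
    mining = unclass(config$mining), behaviors = unclass(config$behaviors),
    timepoint = config$timepoint, decimals = config$decimals
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

write_stage_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full mining pipeline
#'
#' Executes encode -> summarize -> mine -> generate rules -> filter by
#' behavior consequents -> Venn partition, writing one CSV per stage plus a
#' run manifest (JSON) that records a hash of the configuration, the tool
#' version and the counts at every stage — the numbers an auditable run
#' reports: cohort size, frequent itemsets, total rules, rules per behavior
#' group. Any stage failure aborts with a stage-labelled error and removes
#' the partial outputs of this run.
#'
#' @param config A [pipeline_config()] or a path to a YAML config.
#' @param quiet Suppress the per-stage count messages.
#' @return Invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  out <- function(name) file.path(config$outdir, name)

  cb <- stage("encode", {
    if (is.null(config$codebook_path)) default_codebook()
    else read_codebook(config$codebook_path)
  })
  dataset <- stage("encode", {
    if (!is.null(config$simulate)) {
      spec <- if (is.null(config$codebook_path)) default_t1_profile()
              else uniform_profile(cb)
      simulate_survey(synthetic_config(
        n = config$simulate$n, seed = config$simulate$seed, cb = cb,
        spec = spec, timepoint = config$timepoint))
    } else {
      encode_transactions(read_responses_csv(config$responses), cb,
                          timepoint = config$timepoint)
    }
  })
  say("encode: ", dataset$n, " transactions")

  summary_df <- stage("summarize", dataset_summary(dataset, config$decimals))
  written <- c(written, write_stage_csv(summary_df, out("summary.csv")))

  frequent <- stage("mine", mine_frequent_itemsets(dataset, config$mining))
  say("mine: ", nrow(frequent), " frequent itemsets")
  written <- c(written, write_stage_csv(frequent, out("frequent_itemsets.csv")))

  rules <- stage("rules", generate_rules(frequent, dataset, config$mining))
  say("rules: ", nrow(rules), " rules generated")
  written <- c(written, write_stage_csv(rules, out("rules.csv")))

  groups <- stage("filter",
                  filter_rules_by_consequent(rules, config$behaviors, dataset))
  say("filter: ", nrow(groups$group_continued), " continued / ",
      nrow(groups$group_protective), " protective (",
      nrow(groups$group_all_protective), " with all three)")
  written <- c(written,
               write_stage_csv(rule_group_table(groups), out("rule_groups.csv")))

  venn <- stage("venn", venn_partition(dataset, config$behaviors,
                                       decimals = config$decimals))
  written <- c(written, write_stage_csv(venn, out("venn.csv")))

  manifest <- list(
    tool = "behaviorminer",
    version = as.character(utils::packageVersion("behaviorminer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    timepoint = config$timepoint,
    seed = if (!is.null(config$simulate)) config$simulate$seed,
    counts = list(
      n = dataset$n,
      n_items_observed = sum(colSums(dataset$incidence) > 0L),
      n_frequent_itemsets = nrow(frequent),
      n_rules = nrow(rules),
      n_rules_continued = nrow(groups$group_continued),
      n_rules_protective = nrow(groups$group_protective),
      n_rules_all_protective = nrow(groups$group_all_protective),
      n_rules_discarded = groups$n_discarded
    ),
    outputs = basename(written)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  written <- c(written, out("manifest.json"))
  ok <- TRUE
  invisible(manifest)
}
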