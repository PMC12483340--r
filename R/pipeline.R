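# Orchestration: generate -> mine -> evaluate -> report, with seeded
# reproducibility and plain-text artifacts (CSV cohort, TSV tables, NDJSON
# rule sets, JSON run metadata).

#' Pipeline configuration
#'
#' Exactly one of `generator` (a [generator_config()]) or `cohort_path` (a
#' CSV readable by [read_cohort()]) must be given.
#'
#' @param scale Scale name, used when reading a cohort from CSV.
#' @param generator A [generator_config()], or NULL.
#' @param cohort_path Path to an input cohort CSV, or NULL.
#' @param mining A [mining_config()].
#' @param k_per_class Rules kept per class by [top_rules()].
#' @param auc_mode AUC scoring mode for [evaluate_rules()].
#' @param out_dir Output directory (created if absent).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = "GAD7",
                            generator = NULL,
                            cohort_path = NULL,
                            mining = mining_config(),
                            k_per_class = c(minimal_mild = 1L, moderate = 2L,
                                            severe = 1L),
                            auc_mode = c("tree_probability", "rule_binary"),
                            out_dir = tempfile("sevrules_run_")) {
  if (is.null(generator) == is.null(cohort_path)) {
    stop("provide exactly one of generator or cohort_path", call. = FALSE)
  }
  structure(list(scale = scale, generator = generator,
                 cohort_path = cohort_path, mining = mining,
                 k_per_class = k_per_class,
                 auc_mode = match.arg(auc_mode), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full mining pipeline
#'
#' Generates (or reads) the cohort, mines the rule catalog, selects the top
#' rules per class, evaluates them across repetitions and writes all
#' artifacts to `config$out_dir`: `cohort.csv` (if generated),
#' `catalog.tsv`, `top_rules.ndjson`, `report.tsv` and `run_metadata.json`.
#' Re-running with the same configuration reproduces byte-identical catalog
#' and report files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `cohort`, `mining`, `rules`, `report` and
#'   the written `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory ", config$out_dir, call. = FALSE)
  }
  paths <- list()
  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator)
    paths$cohort <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort)
  } else {
    cohort <- read_cohort(config$cohort_path, scale_spec(config$scale))
  }
  mining <- mine(cohort, config$mining)
  paths$catalog <- file.path(config$out_dir, "catalog.tsv")
  utils::write.table(mining$catalog, paths$catalog, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rules <- top_rules(mining, config$k_per_class)
  paths$rules <- file.path(config$out_dir, "top_rules.ndjson")
  write_rules(rules, paths$rules)
  report <- evaluate_rules(mining, rules, auc_mode = config$auc_mode)
  paths$report <- file.path(config$out_dir, "report.tsv")
  render_report(report, paths$report)
  meta <- list(
    scale = mining$spec$name,
    n = nrow(cohort),
    base_seed = config$mining$seed,
    generator_seed = if (!is.null(config$generator)) config$generator$seed,
    profile = config$mining$profile,
    hp_grid = config$mining$hp_grid,
    reps_per_config = config$mining$reps_per_config,
    feature_sets = config$mining$feature_sets,
    maxdepth_grid = config$mining$maxdepth_grid,
    cv_folds = config$mining$cv_folds,
    train_fraction = config$mining$train_fraction,
    n_trees = mining$n_trees,
    distinct_rules = mining$totals$distinct_rules,
    total_repetitions = mining$totals$total_repetitions,
    skipped = mining$skipped,
    auc_mode = config$auc_mode,
    package_version = as.character(utils::packageVersion("sevrules"))
  )
  paths$metadata <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(cohort = cohort, mining = mining, rules = rules,
                 report = report, paths = paths))
}

# ---- rule serialization -----------------------------------------------------

rule_to_list <- function(rule) {
  count <- attr(rule, "count")
  out <- list(
    scale = rule$scale,
    class = rule$class,
    conditions = lapply(unname(rule$conditions), function(cond) {
      if (cond$type == "ordinal") {
        list(var = cond$var, type = "ordinal", lo = cond$lo, hi = cond$hi)
      } else {
        list(var = cond$var, type = "nominal", levels = as.list(cond$levels),
             all_levels = as.list(cond$all_levels))
      }
    }),
    string = format_rule(rule)
  )
  if (!is.null(count) && !is.na(count)) out$count <- as.integer(count)
  out
}

rule_from_list <- function(x) {
  conds <- lapply(x$conditions, function(cond) {
    if (identical(cond$type, "ordinal")) {
      if (cond$lo > cond$hi) stop("contradictory interval", call. = FALSE)
      new_condition_ord(cond$var, cond$lo, cond$hi)
    } else {
      lev <- unlist(cond$levels)
      if (!length(lev)) stop("empty level set", call. = FALSE)
      new_condition_nom(cond$var, lev, unlist(cond$all_levels))
    }
  })
  rule <- canonicalize(new_rule(x$scale, x$class, conds))
  if (is.numeric(x$count)) attr(rule, "count") <- as.integer(x$count)
  rule
}

#' Write / read a rule set (NDJSON)
#'
#' One JSON object per line, carrying the structured conditions alongside
#' the human-readable rule string; the round-trip is lossless up to
#' canonicalisation.
#'
#' @param rules A `sev_rule_set` or list of `sev_rule`.
#' @param path File path.
#' @return `write_rules()`: `path` invisibly. `read_rules()`: a
#'   `sev_rule_set`.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(rules, function(r) {
    jsonlite::toJSON(rule_to_list(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rules <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rules[[i]] <- tryCatch(
      rule_from_list(jsonlite::fromJSON(lines[i], simplifyVector = FALSE)),
      error = function(e) {
        stop("malformed rule file at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  structure(rules, class = "sev_rule_set")
}

# ---- report rendering -------------------------------------------------------

#' Render an evaluation report as a TSV table
#'
#' One row per (class, rule); metric cells formatted `"mean (SD)"` to three
#' decimals, repetition counts as integers; column order Class, Rule,
#' Repetition, Accuracy, Sensitivity, Specificity, Precision, F-score, AUC.
#' Rendering is pure: the same report always yields the same bytes.
#'
#' @param report A [evaluate_rules()] result.
#' @param path Optional output TSV path.
#' @return The formatted data frame, invisibly if `path` is given.
#' @export
render_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "rule_eval_report"), nrow(report) > 0)
  fmt <- function(m) sprintf("%.3f (%.3f)", report[[paste0(m, "_mean")]],
                             report[[paste0(m, "_sd")]])
  label_for <- function(scale, class) {
    spec <- scale_spec(scale)
    spec$level_labels[match(class, spec$levels)]
  }
  out <- data.frame(
    Class = mapply(label_for, report$scale, report$class, USE.NAMES = FALSE),
    Rule = report$rule,
    Repetition = as.integer(report$count),
    Accuracy = fmt("accuracy"),
    Sensitivity = fmt("sensitivity"),
    Specificity = fmt("specificity"),
    Precision = fmt("precision"),
    `F-score` = fmt("f1"),
    AUC = fmt("auc"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
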