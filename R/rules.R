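# Rule mining: repeated 70/30 resampling across feature sets and the
# minsplit/minbucket grid, CV-tuned tree fits, root-to-leaf rule extraction,
# canonicalisation and repetition counting.

# ---- conditions and rules ---------------------------------------------------

new_condition_ord <- function(var, lo, hi) {
  list(var = var, type = "ordinal", lo = as.integer(lo), hi = as.integer(hi))
}

new_condition_nom <- function(var, levels, all_levels) {
  list(var = var, type = "nominal", levels = levels, all_levels = all_levels)
}

#' Construct a classification rule
#'
#' A rule is the conjunction of item conditions (integer intervals inside the
#' 0--3 response range, e.g. `GAD2 < 2`) and, optionally, nominal demographic
#' conditions (category subsets), predicting one severity class.
#'
#' @param scale Scale name (`"GAD7"`/`"PHQ9"`).
#' @param class Predicted severity class (one of [severity_levels()]).
#' @param conditions List of conditions as produced by [extract_rules()].
#' @return Object of class `sev_rule`.
#' @export
new_rule <- function(scale, class, conditions = list()) {
  structure(list(scale = scale, class = class, conditions = conditions),
            class = "sev_rule")
}

condition_order_key <- function(cond) {
  idx <- suppressWarnings(as.integer(sub("^(GAD|PHQ)", "", cond$var)))
  if (grepl("^(GAD|PHQ)[0-9]+$", cond$var) && !is.na(idx)) {
    sprintf("0%02d", idx)
  } else {
    paste0("1", cond$var)
  }
}

format_condition <- function(cond) {
  if (cond$type == "ordinal") {
    lo <- cond$lo
    hi <- cond$hi
    if (lo == 0L) {
      sprintf("%s<%d", cond$var, hi + 1L)
    } else if (hi == 3L) {
      if (lo == 3L) sprintf("%s=3", cond$var) else sprintf("%s>=%d", cond$var, lo)
    } else {
      sprintf("%d<=%s<%d", lo, cond$var, hi + 1L)
    }
  } else {
    sprintf("%s in {%s}", cond$var, paste(cond$levels, collapse = ","))
  }
}

#' Render a rule as its canonical text
#'
#' Deterministic: conditions sorted by item index (items first, demographics
#' after), one condition per variable, integer thresholds only (e.g.
#' `"GAD2<2 and GAD4>=2"`, `"GAD4=3"`). A rule with no conditions renders as
#' `"(all)"`.
#'
#' @param rule A `sev_rule`.
#' @return Single character string.
#' @export
format_rule <- function(rule) {
  if (!length(rule$conditions)) return("(all)")
  paste(vapply(rule$conditions, format_condition, character(1)),
        collapse = " and ")
}

#' @export
print.sev_rule <- function(x, ...) {
  cat(sprintf("<rule %s> %s -> %s\n", x$scale, format_rule(x), x$class))
  invisible(x)
}

#' Canonicalise a rule
#'
#' Intersects all conditions on the same variable (e.g. `GAD4>=2` and
#' `GAD4>=3` collapse to `GAD4=3`), drops full-range conditions, and sorts
#' conditions by item index so that logically identical root-to-leaf paths
#' render identically. Idempotent. A contradictory (empty-intersection) path
#' is an error; such paths cannot arise from a fitted tree.
#'
#' @param rule A `sev_rule`.
#' @return The canonical `sev_rule`.
#' @export
canonicalize <- function(rule) {
  stopifnot(inherits(rule, "sev_rule"))
  by_var <- split(rule$conditions,
                  vapply(rule$conditions, function(c) c$var, character(1)))
  merged <- lapply(by_var, function(conds) {
    c1 <- conds[[1]]
    if (c1$type == "ordinal") {
      lo <- max(vapply(conds, function(c) c$lo, integer(1)))
      hi <- min(vapply(conds, function(c) c$hi, integer(1)))
      if (lo > hi) stop("contradictory conditions on ", c1$var, call. = FALSE)
      if (lo == 0L && hi == 3L) return(NULL)
      new_condition_ord(c1$var, lo, hi)
    } else {
      lev <- Reduce(intersect, lapply(conds, function(c) c$levels))
      if (!length(lev)) stop("contradictory conditions on ", c1$var, call. = FALSE)
      if (setequal(lev, c1$all_levels)) return(NULL)
      new_condition_nom(c1$var, c1$all_levels[c1$all_levels %in% lev],
                        c1$all_levels)
    }
  })
  merged <- Filter(Negate(is.null), merged)
  keys <- vapply(merged, condition_order_key, character(1))
  rule$conditions <- unname(merged[order(keys)])
  rule
}

#' Extract the root-to-leaf rules of a fitted tree
#'
#' One rule per leaf: the conjunction of the split conditions along the path
#' from the root, predicting the leaf's majority class; returned canonical
#' (per-variable conditions intersected). A single-leaf tree yields one rule
#' with no conditions.
#'
#' @param tree A fitted [sevcart()] object.
#' @param scale Scale name recorded on the rules (default taken from the
#'   tree's response if available).
#' @return List of elements `rule` (a canonical `sev_rule`), `counts` (leaf
#'   class counts, named) and `n` (leaf size).
#' @export
extract_rules <- function(tree, scale = NULL) {
  stopifnot(inherits(tree, "sevcart"))
  enc <- tree$encoding
  scale <- scale %||% if (any(grepl("^GAD", enc$predictors))) "GAD7" else "PHQ9"
  out <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      rule <- canonicalize(new_rule(scale, tree$levels[node$majority], conds))
      out[[length(out) + 1L]] <<- list(
        rule = rule,
        counts = stats::setNames(node$counts, tree$levels),
        n = node$n
      )
      return(invisible())
    }
    s <- node$split
    name <- enc$predictors[s$var]
    if (s$type == "ordinal") {
      left_cond <- new_condition_ord(name, 0L, as.integer(ceiling(s$threshold)) - 1L)
      right_cond <- new_condition_ord(name, as.integer(ceiling(s$threshold)), 3L)
    } else {
      lev <- enc$plevels[[s$var]]
      left_cond <- new_condition_nom(name, lev[s$left_levels], lev)
      right_cond <- new_condition_nom(name, lev[-s$left_levels], lev)
    }
    walk(node$left, c(conds, list(left_cond)))
    walk(node$right, c(conds, list(right_cond)))
  }
  walk(tree$root, list())
  out
}

# ---- resampling -------------------------------------------------------------

#' Random 70/30 train/test partition
#'
#' Without-replacement partition; the training size is `n * train_fraction`
#' rounded half up (so 20,585 rows at 0.70 give 14,410 / 6,175). Disjoint and
#' exhaustive; reproducible given `seed`.
#'
#' @param table Data frame to partition.
#' @param train_fraction Fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with `train`, `test` (row subsets) and `train_idx`,
#'   `test_idx` (sorted row indices).
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L) {
  n <- nrow(table)
  if (n == 0L) stop("table is empty", call. = FALSE)
  # floor(n*f + 0.5) alone is unsafe: 20585 * 0.7 is 14409.4999... in doubles.
  n_train <- as.integer(floor(n * train_fraction + 0.5 + 1e-9))
  if (n_train < 1L || n_train >= n) {
    stop("train_fraction ", train_fraction, " leaves an empty partition",
         call. = FALSE)
  }
  train_idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

# ---- mining configuration ---------------------------------------------------

#' Configuration for the rule-mining ensemble
#'
#' The full ("replication") design mirrors the reference design: five feature
#' sets (items only, plus one demographic variable at a time), the 3x3
#' hyperparameter grid `{500, 1000, 2000}^2` for (minsplit, minbucket) stated
#' at the reference cohort size 20,585, and 1000 repetitions per
#' configuration (45,000 trees per scale). The "demo" profile is a scaled
#' down design for routine runs: one feature set (items only), the single
#' most constrained hyperparameter pair (2000, 2000), the configuration that
#' yields the largest nodes and simplest trees and so suits a small cohort,
#' and 50 repetitions.
#'
#' @param profile `"demo"` or `"replication"`; presets overridable by the
#'   other arguments.
#' @param feature_sets List of character vectors of demographic variables
#'   added to the items (the items themselves are always included;
#'   `character(0)` = items only).
#' @param hp_grid Data frame with columns `minsplit`, `minbucket`, stated at
#'   the reference size.
#' @param reps_per_config Repetitions per (feature set, hyperparameter)
#'   configuration.
#' @param train_fraction Training fraction of each random partition.
#' @param seed Base seed; every repetition seed derives from it.
#' @param maxdepth_grid Candidate depths for CV tuning (default 1..8).
#' @param cv_folds CV folds for depth tuning (default 10).
#' @param scale_to_n When TRUE (default), `minsplit`/`minbucket` stated for
#'   the reference size `reference_n` are rescaled proportionally to the
#'   actual cohort size, preserving the constraint geometry at reduced n.
#' @param reference_n Reference cohort size at which `hp_grid` values are
#'   stated (default 20,585).
#' @param keep_trees Keep the fitted tree of every repetition in the result
#'   (needed for probability-scored AUC evaluation). Default TRUE.
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(profile = c("demo", "replication"),
                          feature_sets = NULL,
                          hp_grid = NULL,
                          reps_per_config = NULL,
                          train_fraction = 0.7,
                          seed = 1L,
                          maxdepth_grid = 1:8,
                          cv_folds = 10L,
                          scale_to_n = TRUE,
                          reference_n = 20585L,
                          keep_trees = TRUE) {
  profile <- match.arg(profile)
  if (profile == "replication") {
    feature_sets <- feature_sets %||% list(
      items_only = character(0), plus_sex = "sex", plus_skin_color = "skin_color",
      plus_education = "education", plus_age_group = "age_group")
    hp_grid <- hp_grid %||% expand.grid(minsplit = c(500L, 1000L, 2000L),
                                        minbucket = c(500L, 1000L, 2000L))
    reps_per_config <- reps_per_config %||% 1000L
  } else {
    feature_sets <- feature_sets %||% list(items_only = character(0))
    hp_grid <- hp_grid %||% data.frame(minsplit = 2000L, minbucket = 2000L)
    reps_per_config <- reps_per_config %||% 50L
  }
  if (reps_per_config < 1L) stop("reps_per_config must be >= 1", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(profile = profile,
                 feature_sets = feature_sets,
                 hp_grid = as.data.frame(hp_grid),
                 reps_per_config = as.integer(reps_per_config),
                 train_fraction = train_fraction,
                 seed = as.integer(seed),
                 maxdepth_grid = as.integer(maxdepth_grid),
                 cv_folds = as.integer(cv_folds),
                 scale_to_n = isTRUE(scale_to_n),
                 reference_n = as.integer(reference_n),
                 keep_trees = isTRUE(keep_trees)),
            class = "mining_config")
}

scale_hp <- function(value, n, reference_n, floor_at = 2L) {
  max(floor_at, as.integer(round(value * n / reference_n)))
}

# ---- mining -----------------------------------------------------------------

#' Mine stable decision-tree rules by repeated resampling
#'
#' For each (feature set x hyperparameter configuration x repetition): draw a
#' random `train_fraction` partition, tune the maximum depth on the training
#' part by stratified CV, grow the tree, extract and canonicalise its
#' root-to-leaf rules, and increment their repetition counts in the catalog.
#' Per-repetition seeds derive deterministically from the base seed, so the
#' whole ensemble is reproducible. Configurations whose (rescaled) `minsplit`
#' exceeds the training size are skipped with a warning.
#'
#' @param table A validated `item_response_table`.
#' @param config A [mining_config()].
#' @return Object of class `rule_mining`: `catalog` (data frame with class,
#'   rule string, condition count, repetition count), `rules` (canonical rule
#'   objects keyed by class/string), `reps` (per-repetition artifacts: seeds,
#'   partitions, selected depth, fitted tree), `table`, `config`, `n_trees`,
#'   and `totals` (distinct rules, total repetitions).
#' @export
mine <- function(table, config = mining_config()) {
  stopifnot(inherits(table, "item_response_table"),
            inherits(config, "mining_config"))
  spec <- attr(table, "scale_spec")
  n <- nrow(table)
  y <- as.integer(factor(as.character(table$severity),
                         levels = severity_levels()))
  class_levels <- severity_levels()
  n_fs <- length(config$feature_sets)
  n_hp <- nrow(config$hp_grid)
  reps <- config$reps_per_config
  seeds <- matrix(derive_seeds(config$seed, n_fs * n_hp * reps),
                  nrow = reps)
  counts <- new.env(parent = emptyenv())
  rules <- new.env(parent = emptyenv())
  artifacts <- vector("list", n_fs * n_hp * reps)
  n_art <- 0L
  skipped <- character(0)
  fs_names <- names(config$feature_sets) %||% paste0("fs", seq_len(n_fs))
  for (fi in seq_len(n_fs)) {
    predictors <- c(spec$items, config$feature_sets[[fi]])
    enc <- encode_predictors(table, predictors)
    for (hi in seq_len(n_hp)) {
      ms <- config$hp_grid$minsplit[hi]
      mb <- config$hp_grid$minbucket[hi]
      if (config$scale_to_n) {
        ms <- scale_hp(ms, n, config$reference_n, floor_at = 2L)
        mb <- scale_hp(mb, n, config$reference_n, floor_at = 1L)
      }
      n_train <- as.integer(floor(n * config$train_fraction + 0.5 + 1e-9))
      if (ms > n_train) {
        msg <- sprintf("feature set '%s', minsplit %d > training size %d: skipped",
                       fs_names[fi], ms, n_train)
        warning(msg, call. = FALSE)
        skipped <- c(skipped, msg)
        next
      }
      control <- sevcart_control(ms, mb, max(config$maxdepth_grid))
      for (r in seq_len(reps)) {
        seed_r <- seeds[r, (fi - 1L) * n_hp + hi]
        sub_seeds <- derive_seeds(seed_r, 2L)
        train_idx <- sort(withr::with_seed(sub_seeds[1],
                                           sample.int(n, n_train)))
        test_idx <- setdiff(seq_len(n), train_idx)
        tuned <- tune_maxdepth_encoded(y, class_levels, enc, control,
                                       train_idx, config$maxdepth_grid,
                                       config$cv_folds, sub_seeds[2])
        fit <- fit_encoded(y, class_levels, enc,
                           sevcart_control(ms, mb, tuned$depth),
                           idx = train_idx)
        leaf_rules <- extract_rules(fit, scale = spec$name)
        for (lr in leaf_rules) {
          key <- paste(lr$rule$class, format_rule(lr$rule), sep = "\r")
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          if (is.null(rules[[key]])) rules[[key]] <- lr$rule
        }
        n_art <- n_art + 1L
        artifacts[[n_art]] <- list(
          feature_set = fs_names[fi], fs_index = fi,
          minsplit = ms, minbucket = mb, hp_index = hi,
          rep_index = r, seed = seed_r, depth = tuned$depth,
          train_idx = train_idx, test_idx = test_idx,
          tree = if (config$keep_trees) fit else NULL
        )
      }
    }
  }
  artifacts <- artifacts[seq_len(n_art)]
  keys <- ls(counts)
  catalog <- data.frame(
    scale = rep(spec$name, length(keys)),
    class = vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, character(1), 1L),
    rule = vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, character(1), 2L),
    n_conditions = vapply(keys, function(k) length(rules[[k]]$conditions),
                          integer(1)),
    count = vapply(keys, function(k) as.integer(counts[[k]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  catalog <- catalog[order(catalog$class, -catalog$count,
                           catalog$n_conditions, catalog$rule), ]
  rownames(catalog) <- NULL
  rule_list <- stats::setNames(lapply(keys, function(k) rules[[k]]), keys)
  structure(list(
    catalog = catalog,
    rules = rule_list,
    reps = artifacts,
    table = table,
    spec = spec,
    config = config,
    n_trees = n_art,
    skipped = skipped,
    totals = list(distinct_rules = nrow(catalog),
                  total_repetitions = sum(catalog$count))
  ), class = "rule_mining")
}

#' @export
print.rule_mining <- function(x, ...) {
  cat(sprintf("<rule_mining> %s: %d trees, %d distinct rules, %d repetitions\n",
              x$spec$name, x$n_trees, x$totals$distinct_rules,
              x$totals$total_repetitions))
  top <- utils::head(x$catalog[order(-x$catalog$count), ], 6)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Most repeated rules per severity class
#'
#' Rules are ranked within class by repetition count (descending), ties
#' broken toward the rule with fewer conditions, then lexicographically. The
#' default keeps one rule for each extreme class and two for the middle
#' class, the conventional reporting layout for tripartite severity rules.
#'
#' @param mining A [mine()] result (or its `catalog` plus `rules`).
#' @param k_per_class Named integer vector: rules kept per class.
#' @return List of `sev_rule` objects (with `count` attached as an
#'   attribute), ordered by class then rank; classes absent from the catalog
#'   contribute nothing, with a warning.
#' @export
top_rules <- function(mining,
                      k_per_class = c(minimal_mild = 1L, moderate = 2L,
                                      severe = 1L)) {
  stopifnot(inherits(mining, "rule_mining"))
  catalog <- mining$catalog
  if (!nrow(catalog)) stop("empty rule catalog", call. = FALSE)
  out <- list()
  for (cl in severity_levels()) {
    k <- k_per_class[[cl]] %||% 1L
    sub <- catalog[catalog$class == cl, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no rules for class '", cl, "'", call. = FALSE)
      next
    }
    sub <- sub[order(-sub$count, sub$n_conditions, sub$rule), , drop = FALSE]
    for (i in seq_len(min(k, nrow(sub)))) {
      key <- paste(cl, sub$rule[i], sep = "\r")
      rule <- mining$rules[[key]]
      attr(rule, "count") <- sub$count[i]
      out[[length(out) + 1L]] <- rule
    }
  }
  structure(out, class = "sev_rule_set")
}

#' @export
print.sev_rule_set <- function(x, ...) {
  for (r in x) {
    cat(sprintf("%-13s %-40s x%s\n", r$class, format_rule(r),
                attr(r, "count") %||% "?"))
  }
  invisible(x)
}
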