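# One-vs-rest screening evaluation of mined rules: confusion counts, point
# metrics, ROC-AUC, mean (SD) summaries across repetitions, and external
# validation of frozen rule sets.

#' Apply a rule to a respondent table
#'
#' TRUE where every condition holds (interval containment for items,
#' set membership for nominal conditions); a rule with no conditions matches
#' every row.
#'
#' @param rule A `sev_rule`.
#' @param table Data frame holding the rule's variables.
#' @return Logical vector of length `nrow(table)`.
#' @export
apply_rule <- function(rule, table) {
  stopifnot(inherits(rule, "sev_rule"))
  hit <- rep(TRUE, nrow(table))
  for (cond in rule$conditions) {
    if (!cond$var %in% names(table)) {
      stop("table lacks rule variable '", cond$var, "'", call. = FALSE)
    }
    v <- table[[cond$var]]
    hit <- hit & if (cond$type == "ordinal") {
      v >= cond$lo & v <= cond$hi
    } else {
      as.character(v) %in% cond$levels
    }
  }
  hit
}

#' One-vs-rest confusion counts
#'
#' Rows whose true label equals `target_class` are positives; `predicted`
#' flags the rows the screener calls positive.
#'
#' @param predicted Logical vector of predicted positives.
#' @param truth Vector of true class labels.
#' @param target_class The class treated as positive.
#' @return List of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
confusion <- function(predicted, truth, target_class) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths", call. = FALSE)
  }
  pos <- truth == target_class
  structure(list(
    tp = sum(predicted & pos), fp = sum(predicted & !pos),
    tn = sum(!predicted & !pos), fn = sum(!predicted & pos),
    n = length(truth)
  ), class = "confusion_counts")
}

#' Point screening metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity `TP/(TN+FP)`
#' complement, precision `TP/(TP+FP)` and F1. Precision and F1 are undefined
#' when nothing is flagged positive (`TP+FP = 0`); they are then reported as
#' 0 with `precision_defined = FALSE` so that means over repetitions remain
#' computable.
#'
#' @param cm A [confusion()] result.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, and the flag `precision_defined`.
#' @export
point_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  if (cm$n == 0) stop("empty evaluation", call. = FALSE)
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  prec_def <- (cm$tp + cm$fp) > 0
  prec <- if (prec_def) cm$tp / (cm$tp + cm$fp) else 0
  f1 <- if (prec_def && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else 0
  list(accuracy = (cm$tp + cm$tn) / cm$n,
       sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1, precision_defined = prec_def)
}

#' Trapezoidal ROC-AUC
#'
#' Area under the ROC curve traced over all score thresholds, by the
#' trapezoidal rule; equal to the Mann-Whitney concordance probability with
#' ties counted 1/2. A constant score gives 0.5; for a binary 0/1 score the
#' area equals (sensitivity + specificity) / 2.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param positives Logical vector marking true positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives) {
  if (length(scores) != length(positives)) {
    stop("scores and positives have different lengths", call. = FALSE)
  }
  positives <- as.logical(positives)
  n_pos <- sum(positives)
  n_neg <- sum(!positives)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  }
  # Sweep thresholds from high to low; at each distinct score accumulate the
  # (FPR, TPR) vertex and add the trapezoid against the previous vertex.
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positives[ord]
  boundary <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(p)[boundary]
  fp <- cumsum(!p)[boundary]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

metric_names <- function() {
  c("accuracy", "sensitivity", "specificity", "precision", "f1", "auc")
}

#' Evaluate selected rules across all mining repetitions
#'
#' For every repetition retained by [mine()], each selected rule is applied
#' to that repetition's held-out test partition and scored one-vs-rest
#' against its predicted class; results are summarised as mean (SD) per
#' metric across repetitions. Metrics are computed on every repetition's
#' test set whether or not that repetition's tree contained the rule.
#'
#' AUC modes: `"tree_probability"` (default) scores each test row with the
#' repetition tree's predicted probability of the rule's class, giving a
#' graded, class-level curve (all rules of one class share it);
#' `"rule_binary"` uses the 0/1 rule indicator, whose AUC is exactly
#' (sensitivity + specificity) / 2. Repetitions whose test partition lacks
#' the target class are skipped for that rule and counted.
#'
#' @param mining A [mine()] result (with `keep_trees = TRUE` for the
#'   tree-probability mode).
#' @param rules A `sev_rule_set` (default [top_rules()] of `mining`).
#' @param auc_mode `"tree_probability"` or `"rule_binary"`.
#' @return Object of class `rule_eval_report`: a data frame with one row per
#'   rule (class, rule, repetition count, `<metric>_mean` and `<metric>_sd`
#'   columns, repetitions used/skipped, undefined-precision count).
#' @export
evaluate_rules <- function(mining, rules = top_rules(mining),
                           auc_mode = c("tree_probability", "rule_binary")) {
  stopifnot(inherits(mining, "rule_mining"))
  auc_mode <- match.arg(auc_mode)
  if (auc_mode == "tree_probability" && !mining$config$keep_trees) {
    stop("tree-probability AUC requires keep_trees = TRUE in mining_config",
         call. = FALSE)
  }
  table <- mining$table
  truth_all <- as.character(table$severity)
  n_rules <- length(rules)
  n_reps <- length(mining$reps)
  vals <- array(NA_real_, c(n_reps, n_rules, length(metric_names())),
                dimnames = list(NULL, NULL, metric_names()))
  undef_prec <- integer(n_rules)
  class_idx <- vapply(rules, function(r) match(r$class, severity_levels()),
                      integer(1))
  for (ri in seq_len(n_reps)) {
    art <- mining$reps[[ri]]
    test <- table[art$test_idx, , drop = FALSE]
    truth <- truth_all[art$test_idx]
    prob_cache <- list()
    test_x <- if (auc_mode == "tree_probability") encode_newdata(art$tree, test)
    for (qi in seq_len(n_rules)) {
      rule <- rules[[qi]]
      pred <- apply_rule(rule, test)
      cm <- confusion(pred, truth, rule$class)
      pm <- point_metrics(cm)
      if (!pm$precision_defined) undef_prec[qi] <- undef_prec[qi] + 1L
      vals[ri, qi, 1:5] <- c(pm$accuracy, pm$sensitivity, pm$specificity,
                             pm$precision, pm$f1)
      pos <- truth == rule$class
      if (any(pos) && !all(pos)) {
        if (auc_mode == "tree_probability") {
          key <- as.character(class_idx[qi])
          if (is.null(prob_cache[[key]])) {
            prob_cache[[key]] <- predict_encoded_prob(art$tree, test_x,
                                                      class_idx[qi])
          }
          vals[ri, qi, "auc"] <- roc_auc(prob_cache[[key]], pos)
        } else {
          vals[ri, qi, "auc"] <- roc_auc(as.numeric(pred), pos)
        }
      }
    }
  }
  summarise <- function(m) {
    mean_ <- apply(vals[, , m, drop = FALSE], 2, mean, na.rm = TRUE)
    sd_ <- apply(vals[, , m, drop = FALSE], 2, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2) 0 else stats::sd(z)
    })
    list(mean = mean_, sd = sd_)
  }
  rows <- data.frame(
    scale = vapply(rules, function(r) r$scale, character(1)),
    class = vapply(rules, function(r) r$class, character(1)),
    rule = vapply(rules, format_rule, character(1)),
    count = vapply(rules, function(r) as.integer(attr(r, "count") %||% NA_integer_),
                   integer(1)),
    stringsAsFactors = FALSE
  )
  for (m in metric_names()) {
    s <- summarise(m)
    rows[[paste0(m, "_mean")]] <- s$mean
    rows[[paste0(m, "_sd")]] <- s$sd
  }
  rows$n_reps <- n_reps
  rows$n_skipped_auc <- apply(vals[, , "auc", drop = FALSE], 2,
                              function(z) sum(is.na(z)))
  rows$n_undefined_precision <- undef_prec
  structure(rows, class = c("rule_eval_report", "data.frame"),
            auc_mode = auc_mode)
}

#' @export
print.rule_eval_report <- function(x, ...) {
  cat(sprintf("<rule_eval_report> %d rules, %d repetitions, AUC mode: %s\n",
              nrow(x), x$n_reps[1] %||% 0L, attr(x, "auc_mode")))
  show <- data.frame(
    class = x$class, rule = x$rule, reps = x$count,
    accuracy = sprintf("%.3f (%.3f)", x$accuracy_mean, x$accuracy_sd),
    sensitivity = sprintf("%.3f (%.3f)", x$sensitivity_mean, x$sensitivity_sd),
    auc = sprintf("%.3f (%.3f)", x$auc_mean, x$auc_sd)
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' Validate a frozen rule set on a new cohort
#'
#' Applies rules unchanged, in a single pass, to the full new table (no
#' resampling) and reports per-rule one-vs-rest metrics. The two middle-class
#' rules are additionally evaluated as their union (a row is flagged if
#' either rule fires). AUC uses the binary rule indicator.
#'
#' @param rules A `sev_rule_set` (or list of `sev_rule`).
#' @param table A validated `item_response_table` on the same scale.
#' @return Data frame with one row per rule plus one per-class union row for
#'   classes holding more than one rule; columns as in [point_metrics()]
#'   plus `auc`.
#' @export
external_validate <- function(rules, table) {
  stopifnot(inherits(table, "item_response_table"))
  spec <- attr(table, "scale_spec")
  for (r in rules) {
    if (!identical(r$scale, spec$name)) {
      stop("rule scale ", r$scale, " does not match table scale ", spec$name,
           call. = FALSE)
    }
  }
  truth <- as.character(table$severity)
  eval_one <- function(pred, class, label) {
    cm <- confusion(pred, truth, class)
    pm <- point_metrics(cm)
    auc <- if (any(truth == class) && !all(truth == class)) {
      roc_auc(as.numeric(pred), truth == class)
    } else NA_real_
    data.frame(class = class, rule = label, n = cm$n,
               accuracy = pm$accuracy, sensitivity = pm$sensitivity,
               specificity = pm$specificity, precision = pm$precision,
               f1 = pm$f1, auc = auc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rules, function(r) {
    eval_one(apply_rule(r, table), r$class, format_rule(r))
  }))
  classes <- vapply(rules, function(r) r$class, character(1))
  for (cl in unique(classes[duplicated(classes)])) {
    members <- rules[classes == cl]
    pred <- Reduce(`|`, lapply(members, apply_rule, table = table))
    label <- paste(vapply(members, format_rule, character(1)),
                   collapse = " OR ")
    out <- rbind(out, eval_one(pred, cl, label))
  }
  rownames(out) <- NULL
  out
}
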