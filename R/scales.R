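# Instrument definitions, scoring and severity stratification.

#' Scale specification for GAD-7 or PHQ-9
#'
#' Defines an instrument: its item columns, the admissible item response range
#' (0 = "not at all" to 3 = "nearly every day"), and the tripartite severity
#' cutoffs on the total score. Both instruments share the lower cutoff of 10;
#' the severe cutoff is 15 for GAD-7 (total range 0--21) and 20 for PHQ-9
#' (total range 0--27). Scores below 10 are "minimal or mild"; scores from 10
#' up to (but excluding) the severe cutoff are "moderate" (for PHQ-9 this
#' class is reported as "moderate or moderately severe"); scores at or above
#' the severe cutoff are "severe".
#'
#' @param name `"GAD7"` or `"PHQ9"`.
#' @param cutoff_moderate Total-score threshold at which the moderate class
#'   starts. Default 10 for both instruments.
#' @param cutoff_severe Total-score threshold at which the severe class
#'   starts. Default 15 (GAD-7) or 20 (PHQ-9).
#' @return An object of class `scale_spec`: a list with fields `name`,
#'   `n_items`, `item_min`, `item_max`, `items` (column names `GAD1..GAD7` or
#'   `PHQ1..PHQ9`), `max_total`, `cutoff_moderate`, `cutoff_severe`, severity
#'   `levels` and display `level_labels`.
#' @examples
#' spec <- scale_spec("GAD7")
#' total_score(c(3, 3, 3, 3, 3, 3, 3), spec)
#' stratify(c(0, 9, 10, 14, 15, 21), spec)
#' @export
scale_spec <- function(name = c("GAD7", "PHQ9"),
                       cutoff_moderate = 10L,
                       cutoff_severe = NULL) {
  name <- match.arg(name)
  n_items <- if (name == "GAD7") 7L else 9L
  prefix <- if (name == "GAD7") "GAD" else "PHQ"
  cutoff_severe <- as.integer(cutoff_severe %||% if (name == "GAD7") 15L else 20L)
  cutoff_moderate <- as.integer(cutoff_moderate)
  spec <- structure(list(
    name = name,
    n_items = n_items,
    item_min = 0L,
    item_max = 3L,
    items = paste0(prefix, seq_len(n_items)),
    max_total = n_items * 3L,
    cutoff_moderate = cutoff_moderate,
    cutoff_severe = cutoff_severe,
    levels = severity_levels(),
    level_labels = c(
      "Minimal or mild",
      if (name == "GAD7") "Moderate" else "Moderate or moderately severe",
      "Severe"
    )
  ), class = "scale_spec")
  if (!(spec$item_min < spec$item_max)) {
    stop("item range is degenerate", call. = FALSE)
  }
  if (!(cutoff_moderate < cutoff_severe && cutoff_severe <= spec$max_total)) {
    stop("severity cutoffs must satisfy cutoff_moderate < cutoff_severe <= ",
         spec$max_total, call. = FALSE)
  }
  spec
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> %s: %d items (0-%d), total 0-%d\n",
              x$name, x$n_items, x$item_max, x$max_total))
  cat(sprintf("  severity: %s < %d <= %s < %d <= %s\n",
              x$levels[1], x$cutoff_moderate, x$levels[2],
              x$cutoff_severe, x$levels[3]))
  invisible(x)
}

#' The three severity levels, ordered
#'
#' @return Character vector `c("minimal_mild", "moderate", "severe")`, in
#'   increasing order of severity. The same internal token `moderate` serves
#'   both scales; display strings differ per scale (see [scale_spec()]).
#' @export
severity_levels <- function() c("minimal_mild", "moderate", "severe")

severity_factor <- function(x) {
  factor(x, levels = severity_levels(), ordered = TRUE)
}

check_item_matrix <- function(m, spec, context = "responses") {
  bad <- !is.finite(m) | m != floor(m) | m < spec$item_min | m > spec$item_max
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop(sprintf(
      "invalid %s: row %d, item %s has value %s (must be an integer in [%d, %d])",
      context, idx[1, 1], colnames(m)[idx[1, 2]] %||% idx[1, 2],
      format(m[idx[1, 1], idx[1, 2]]), spec$item_min, spec$item_max
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Total score of an item response vector or matrix
#'
#' @param responses Integer vector of length `spec$n_items`, or a matrix /
#'   data frame with one column per item (rows are respondents).
#' @param spec A [scale_spec()].
#' @return Integer total (or vector of totals), the plain arithmetic sum,
#'   in `[0, n_items * 3]`.
#' @export
total_score <- function(responses, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) {
    responses <- matrix(responses, nrow = 1,
                        dimnames = list(NULL, names(responses)))
    single <- TRUE
  } else {
    single <- FALSE
  }
  if (ncol(responses) != spec$n_items) {
    stop(sprintf("expected %d item responses, got %d",
                 spec$n_items, ncol(responses)), call. = FALSE)
  }
  storage.mode(responses) <- "double"
  check_item_matrix(responses, spec)
  out <- as.integer(rowSums(responses))
  if (single) out[1] else out
}

#' Map total scores to severity classes
#'
#' `minimal_mild` iff `total < cutoff_moderate`; `moderate` iff
#' `cutoff_moderate <= total < cutoff_severe`; `severe` iff
#' `total >= cutoff_severe`.
#'
#' @param total Integer vector of total scores.
#' @param spec A [scale_spec()].
#' @return Ordered factor with levels [severity_levels()].
#' @export
stratify <- function(total, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (any(!is.finite(total) | total < 0 | total > spec$max_total)) {
    stop(sprintf("total score outside attainable range [0, %d]",
                 spec$max_total), call. = FALSE)
  }
  lv <- severity_levels()
  out <- ifelse(total < spec$cutoff_moderate, lv[1],
                ifelse(total < spec$cutoff_severe, lv[2], lv[3]))
  severity_factor(out)
}

# Canonical demographic level sets, in report order.
demographic_levels <- function() {
  list(
    sex = c("male", "female", "nonbinary"),
    skin_color = c("white", "black", "parda", "other"),
    education = c("up_to_high_school", "undergraduate", "graduate"),
    age_group = c("18-29", "30-39", "40-49", "50-60", "more_than_60")
  )
}

#' Validate a raw respondent table
#'
#' Checks that all item columns of `spec` are present, drops rows with any
#' missing, non-integer or out-of-range item value (mirroring the exclusion
#' of incomplete responses at data collection), coerces known demographic
#' columns (`sex`, `skin_color`, `education`, `age_group`) to factors, and
#' attaches derived `total` and `severity` columns. Validation is idempotent:
#' re-validating a validated table changes nothing.
#'
#' @param raw A data frame with the item columns of `spec` and optionally
#'   demographic columns.
#' @param spec A [scale_spec()].
#' @return The validated table, of class `item_response_table` (a data
#'   frame), with attributes `scale_spec` and `validation` (a list with
#'   `n_input`, `n_retained`, `n_dropped`).
#' @export
validate_table <- function(raw, spec) {
  stopifnot(is.data.frame(raw), inherits(spec, "scale_spec"))
  missing_cols <- setdiff(spec$items, names(raw))
  if (length(missing_cols)) {
    stop("missing item columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  n_input <- nrow(raw)
  items <- raw[spec$items]
  for (j in seq_along(items)) {
    items[[j]] <- suppressWarnings(as.numeric(as.character(items[[j]])))
  }
  m <- as.matrix(items)
  ok <- rowSums(!is.finite(m) | m != floor(m) |
                  m < spec$item_min | m > spec$item_max) == 0
  ok[is.na(ok)] <- FALSE
  out <- raw[ok, , drop = FALSE]
  m <- m[ok, , drop = FALSE]
  for (j in seq_along(spec$items)) out[[spec$items[j]]] <- as.integer(m[, j])
  dl <- demographic_levels()
  for (v in names(dl)) {
    if (v %in% names(out) && !is.factor(out[[v]])) {
      vals <- as.character(out[[v]])
      lev <- if (all(stats::na.omit(vals) %in% dl[[v]])) dl[[v]] else sort(unique(vals))
      out[[v]] <- factor(vals, levels = lev)
    }
  }
  out$total <- as.integer(rowSums(m))
  out$severity <- stratify(out$total, spec)
  rownames(out) <- NULL
  structure(out,
            class = c("item_response_table", "data.frame"),
            scale_spec = spec,
            validation = list(n_input = n_input,
                              n_retained = sum(ok),
                              n_dropped = n_input - sum(ok)))
}

#' Read a respondent cohort from CSV
#'
#' Expects a UTF-8 header row with the item columns of `spec` (e.g.
#' `GAD1..GAD7`) and optionally `sex`, `skin_color`, `education`,
#' `age_group`, `age`. Empty cells are treated as missing; rows with missing
#' or invalid item values are dropped by [validate_table()].
#'
#' @param path CSV file path.
#' @param spec A [scale_spec()].
#' @return A validated `item_response_table`.
#' @export
read_cohort <- function(path, spec) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  validate_table(raw, spec)
}

#' Write a cohort table to CSV
#'
#' Deterministic, byte-stable output: same table, same bytes.
#'
#' @param table A data frame (typically an `item_response_table`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
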