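# From-scratch CART classifier: exhaustive Gini split search over ordinal and
# nominal predictors, growth under minsplit/minbucket/maxdepth constraints,
# maxdepth selection by stratified k-fold cross-validation.

#' Gini impurity of a class-count vector
#'
#' `1 - sum(p_c^2)` with `p_c = count_c / total`; 0 for a pure node, at most
#' `1 - 1/K` for `K` classes.
#'
#' @param class_counts Nonnegative integer vector with at least one positive
#'   entry.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @examples
#' gini_impurity(c(10, 0, 0)) # 0
#' gini_impurity(c(5, 5))     # 0.5
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    stop("class counts must be nonnegative with a positive total",
         call. = FALSE)
  }
  n <- sum(class_counts)
  1 - sum((class_counts / n)^2)
}

#' Weighted Gini decrease of a binary split
#'
#' `G(parent) - (nL/n) G(left) - (nR/n) G(right)`; nonnegative for any split
#' of the parent.
#'
#' @param parent_counts,left_counts,right_counts Class-count vectors;
#'   `left + right` must equal `parent` elementwise and both children must be
#'   nonempty.
#' @return The impurity decrease (>= 0).
#' @export
split_gain <- function(parent_counts, left_counts, right_counts) {
  if (length(left_counts) != length(parent_counts) ||
      length(right_counts) != length(parent_counts) ||
      any(left_counts + right_counts != parent_counts)) {
    stop("left and right counts must sum to the parent counts", call. = FALSE)
  }
  n <- sum(parent_counts)
  nl <- sum(left_counts)
  nr <- sum(right_counts)
  if (nl == 0 || nr == 0) stop("split children must be nonempty", call. = FALSE)
  gini_impurity(parent_counts) -
    (nl / n) * gini_impurity(left_counts) -
    (nr / n) * gini_impurity(right_counts)
}

#' Control parameters for [sevcart()]
#'
#' @param minsplit Minimum number of observations a node must hold to be
#'   eligible for splitting.
#' @param minbucket Minimum number of observations in any terminal node; the
#'   two constraints are checked independently (no implied relation).
#' @param maxdepth Maximum node depth (root = depth 0); `maxdepth = 1` allows
#'   at most a stump.
#' @return A list of class `sevcart_control`.
#' @export
sevcart_control <- function(minsplit = 20L, minbucket = 7L, maxdepth = 8L) {
  minsplit <- as.integer(minsplit)
  minbucket <- as.integer(minbucket)
  maxdepth <- as.integer(maxdepth)
  if (minbucket < 1L) stop("minbucket must be >= 1", call. = FALSE)
  if (minsplit < 2L) stop("minsplit must be >= 2", call. = FALSE)
  if (maxdepth < 1L) stop("maxdepth must be >= 1", call. = FALSE)
  structure(list(minsplit = minsplit, minbucket = minbucket,
                 maxdepth = maxdepth), class = "sevcart_control")
}

# ---- predictor encoding -----------------------------------------------------

# Encode predictor columns once into an integer matrix plus type metadata so
# repeated fits on row subsets avoid per-fit model.frame overhead.
# Ordinal (numeric/integer) columns keep their integer values; nominal
# (factor/character) columns are coded 1..L with the level set recorded.
encode_predictors <- function(data, predictors) {
  miss <- setdiff(predictors, names(data))
  if (length(miss)) {
    stop("predictors not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p <- length(predictors)
  n <- nrow(data)
  x <- matrix(0L, n, p, dimnames = list(NULL, predictors))
  ptype <- character(p)
  plevels <- vector("list", p)
  for (j in seq_len(p)) {
    col <- data[[predictors[j]]]
    if (is.factor(col) || is.character(col)) {
      col <- as.factor(col)
      ptype[j] <- "nominal"
      plevels[[j]] <- levels(col)
      if (length(plevels[[j]]) > 8L) {
        stop("nominal predictor '", predictors[j],
             "' has more than 8 levels", call. = FALSE)
      }
      x[, j] <- as.integer(col)
    } else if (is.numeric(col)) {
      if (any(!is.finite(col) | col != floor(col))) {
        stop("ordinal predictor '", predictors[j],
             "' must be integer-valued and non-missing", call. = FALSE)
      }
      ptype[j] <- "ordinal"
      x[, j] <- as.integer(col)
    } else {
      stop("unsupported predictor type for '", predictors[j], "'",
           call. = FALSE)
    }
  }
  list(x = x, ptype = ptype, plevels = plevels, predictors = predictors)
}

encode_newdata <- function(object, newdata) {
  enc <- object$encoding
  p <- length(enc$predictors)
  miss <- setdiff(enc$predictors, names(newdata))
  if (length(miss)) {
    stop("newdata lacks predictors: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(newdata)
  x <- matrix(0L, n, p, dimnames = list(NULL, enc$predictors))
  for (j in seq_len(p)) {
    col <- newdata[[enc$predictors[j]]]
    if (enc$ptype[j] == "nominal") {
      code <- match(as.character(col), enc$plevels[[j]])
      if (any(is.na(code) & !is.na(col))) {
        stop("unknown level in predictor '", enc$predictors[j], "'",
             call. = FALSE)
      }
      x[, j] <- code
    } else {
      x[, j] <- as.integer(col)
    }
    if (anyNA(x[, j])) {
      stop("missing value in predictor '", enc$predictors[j],
           "' (no surrogate splits)", call. = FALSE)
    }
  }
  x
}

# ---- split search -----------------------------------------------------------

# Exhaustive best split for the rows `idx`. Ordinal predictors: thresholds
# midway between consecutive observed values (condition: value < threshold
# goes left). Nominal predictors: all 2^(L-1)-1 binary level partitions,
# enumerated by ascending bitmask with the first level pinned left.
# Ties: largest gain wins; on exact ties the earliest candidate in scan order
# (lowest predictor index, then lowest threshold / lowest mask) is kept, which
# makes fitted trees deterministic.
best_split_enc <- function(y, enc, idx, minbucket, K) {
  n <- length(idx)
  yi <- y[idx]
  parent_counts <- tabulate(yi, K)
  g_parent <- 1 - sum((parent_counts / n)^2)
  best <- NULL
  best_gain <- 0
  for (j in seq_along(enc$predictors)) {
    v <- enc$x[idx, j]
    if (enc$ptype[j] == "ordinal") {
      vmin <- min(v)
      off <- v - vmin
      nv <- max(off) + 1L
      if (nv == 1L) next
      tab <- matrix(tabulate(off * K + yi, nv * K), nrow = K)
      csum <- t(apply(tab, 1, cumsum))          # K x nv cumulative left counts
      if (K == 1L) csum <- matrix(csum, nrow = 1)
      observed <- which(colSums(tab) > 0L)
      vals <- vmin + observed - 1L
      if (length(observed) < 2L) next
      for (s in seq_len(length(observed) - 1L)) {
        lc <- csum[, observed[s]]
        nl <- sum(lc)
        nr <- n - nl
        if (nl < minbucket || nr < minbucket) next
        rc <- parent_counts - lc
        gain <- g_parent - (nl / n) * (1 - sum((lc / nl)^2)) -
          (nr / n) * (1 - sum((rc / nr)^2))
        if (gain > best_gain) {
          best_gain <- gain
          best <- list(var = j, type = "ordinal",
                       threshold = (vals[s] + vals[s + 1L]) / 2,
                       gain = gain)
        }
      }
    } else {
      L <- length(enc$plevels[[j]])
      tab <- matrix(tabulate((v - 1L) * K + yi, L * K), nrow = K)
      for (mask in seq_len(bitwShiftL(1L, L) - 2L)) {
        if (bitwAnd(mask, 1L) == 0L) next     # pin level 1 left: unique partitions
        left_levels <- which(bitwAnd(bitwShiftL(1L, seq_len(L) - 1L), mask) > 0L)
        lc <- rowSums(tab[, left_levels, drop = FALSE])
        nl <- sum(lc)
        nr <- n - nl
        if (nl < minbucket || nr < minbucket) next
        rc <- parent_counts - lc
        gain <- g_parent - (nl / n) * (1 - sum((lc / nl)^2)) -
          (nr / n) * (1 - sum((rc / nr)^2))
        if (gain > best_gain) {
          best_gain <- gain
          best <- list(var = j, type = "nominal", left_levels = left_levels,
                       gain = gain)
        }
      }
    }
  }
  best
}

split_goes_left <- function(split, v) {
  if (split$type == "ordinal") v < split$threshold else v %in% split$left_levels
}

# ---- growth -----------------------------------------------------------------

grow_node <- function(y, enc, idx, depth, control, K) {
  n <- length(idx)
  counts <- tabulate(y[idx], K)
  # Majority label; ties broken toward the more severe (highest-index) class.
  majority <- max(which(counts == max(counts)))
  node <- list(n = n, counts = counts, depth = depth, majority = majority,
               prob = counts / n)
  if (depth >= control$maxdepth || n < control$minsplit ||
      sum(counts > 0L) == 1L) {
    node$leaf <- TRUE
    return(node)
  }
  split <- best_split_enc(y, enc, idx, control$minbucket, K)
  if (is.null(split)) {
    node$leaf <- TRUE
    return(node)
  }
  left_sel <- split_goes_left(split, enc$x[idx, split$var])
  node$leaf <- FALSE
  node$split <- split
  node$left <- grow_node(y, enc, idx[left_sel], depth + 1L, control, K)
  node$right <- grow_node(y, enc, idx[!left_sel], depth + 1L, control, K)
  node
}

#' Fit a severity classification tree
#'
#' A from-scratch CART classifier: greedy recursive binary partitioning that
#' at each node picks the split with the largest decrease in Gini impurity
#' over all candidates (ordinal thresholds midway between consecutive
#' observed values; all binary level partitions for nominal predictors with
#' up to 8 levels), subject to `minsplit`, `minbucket` and `maxdepth`. A node
#' becomes a leaf when it is pure, too small to split, at maximum depth, or
#' when no legal split has positive gain. No surrogate splits, no
#' cost-complexity pruning: depth is the pruning parameter (see
#' [tune_maxdepth()]).
#'
#' @param formula Model formula, e.g. `severity ~ GAD1 + ... + GAD7`. The
#'   response must be a factor (class labels); `.` expands to all other
#'   columns.
#' @param data A data frame (typically an `item_response_table`).
#' @param control A [sevcart_control()].
#' @return An object of class `sevcart` with the fitted `root` node, the
#'   predictor `encoding`, class `levels`, `control` and training size `n`.
#' @seealso [predict.sevcart()], [variable_importance()], [extract_rules()]
#' @export
sevcart <- function(formula, data, control = sevcart_control()) {
  stopifnot(inherits(control, "sevcart_control"))
  if (nrow(data) == 0L) stop("empty training table", call. = FALSE)
  response <- all.vars(formula[[2]])
  predictors <- attr(stats::terms(formula, data = data), "term.labels")
  y <- data[[response]]
  if (is.null(y)) stop("response '", response, "' not found", call. = FALSE)
  y <- droplevels(as.factor(y))
  enc <- encode_predictors(data, predictors)
  fit_encoded(as.integer(y), levels(y), enc, control,
              call = match.call(), response = response)
}

# Internal fitting path shared by sevcart() and mine(); `y` integer 1..K.
fit_encoded <- function(y, class_levels, enc, control, idx = NULL,
                        call = NULL, response = "severity") {
  K <- length(class_levels)
  idx <- idx %||% seq_along(y)
  root <- grow_node(y, enc, idx, 0L, control, K)
  structure(list(root = root, encoding = enc, levels = class_levels,
                 control = control, n = length(idx), response = response,
                 call = call),
            class = "sevcart")
}

# ---- prediction -------------------------------------------------------------

route_rows <- function(node, x, idx, assign_leaf, depth_cap) {
  if (node$leaf || node$depth >= depth_cap) {
    assign_leaf(node, idx)
    return(invisible())
  }
  v <- x[idx, node$split$var]
  left_sel <- split_goes_left(node$split, v)
  if (length(li <- idx[left_sel])) route_rows(node$left, x, li, assign_leaf, depth_cap)
  if (length(ri <- idx[!left_sel])) route_rows(node$right, x, ri, assign_leaf, depth_cap)
  invisible()
}

#' Predict severity classes or class probabilities
#'
#' Rows are routed by the split conditions to a leaf; the predicted label is
#' the leaf majority (ties broken toward the more severe class) and the
#' probability vector is the leaf class counts normalised. A row whose
#' ordinal value equals a split's integer boundary `k` goes left, since the
#' condition is `value < k + 0.5`. Missing predictor values are an error
#' (there are no surrogate splits).
#'
#' @param object A fitted [sevcart()] tree.
#' @param newdata Data frame with the tree's predictors.
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix.
#' @param maxdepth Optional depth cap: nodes at this depth are treated as
#'   leaves. Growing a tree with a smaller `maxdepth` and truncating a deeper
#'   tree are equivalent, which [tune_maxdepth()] exploits.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric `n x K` matrix of
#'   probabilities (rows sum to 1).
#' @export
predict.sevcart <- function(object, newdata, type = c("class", "prob"),
                            maxdepth = NULL, ...) {
  type <- match.arg(type)
  x <- encode_newdata(object, newdata)
  depth_cap <- maxdepth %||% Inf
  n <- nrow(x)
  K <- length(object$levels)
  cls <- integer(n)
  prob <- matrix(NA_real_, n, K, dimnames = list(NULL, object$levels))
  assign_leaf <- function(node, idx) {
    cls[idx] <<- node$majority
    prob[idx, ] <<- matrix(node$prob, length(idx), K, byrow = TRUE)
  }
  if (n > 0) route_rows(object$root, x, seq_len(n), assign_leaf, depth_cap)
  if (type == "class") {
    factor(object$levels[cls], levels = object$levels)
  } else {
    prob
  }
}

# ---- depth tuning by cross-validation --------------------------------------

# Stratified fold assignment: within each class, rows are shuffled and folds
# dealt in rotation, so class shares are balanced across folds.
stratified_folds <- function(y, k, seed) {
  if (length(y) < k) stop("fewer rows than folds", call. = FALSE)
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

#' Select the maximum tree depth by stratified k-fold cross-validation
#'
#' For each candidate depth the mean held-out accuracy over stratified
#' k-fold CV is computed; the depth with maximal mean accuracy is returned,
#' ties broken toward the smallest depth. Because a depth-`d` CART fit equals
#' the depth-`d` truncation of a deeper fit (splitting decisions are local
#' and top-down), one tree per fold is grown at the largest candidate depth
#' and evaluated at every depth via truncated prediction; this is an exact
#' optimisation, not an approximation.
#'
#' @param formula,data,control As in [sevcart()].
#' @param depth_grid Candidate depths (default 1..8).
#' @param cv_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `depth` (the selection), `cv_accuracy` (named mean
#'   accuracy per candidate depth) and `folds` used.
#' @export
tune_maxdepth <- function(formula, data, control = sevcart_control(),
                          depth_grid = 1:8, cv_folds = 10L, seed = 1L) {
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  response <- all.vars(formula[[2]])
  predictors <- attr(stats::terms(formula, data = data), "term.labels")
  y <- droplevels(as.factor(data[[response]]))
  enc <- encode_predictors(data, predictors)
  tune_maxdepth_encoded(as.integer(y), levels(y), enc, control,
                        seq_len(nrow(data)), depth_grid, cv_folds, seed)
}

tune_maxdepth_encoded <- function(y, class_levels, enc, control, idx,
                                  depth_grid, cv_folds, seed) {
  depth_grid <- sort(unique(as.integer(depth_grid)))
  folds <- stratified_folds(y[idx], cv_folds, seed)
  deep <- sevcart_control(control$minsplit, control$minbucket, max(depth_grid))
  acc <- matrix(NA_real_, cv_folds, length(depth_grid),
                dimnames = list(NULL, depth_grid))
  for (f in seq_len(cv_folds)) {
    train_idx <- idx[folds != f]
    test_idx <- idx[folds == f]
    if (!length(test_idx) || !length(train_idx)) next
    fit <- fit_encoded(y, class_levels, enc, deep, idx = train_idx)
    for (d in seq_along(depth_grid)) {
      pred <- predict_encoded_class(fit, enc$x[test_idx, , drop = FALSE],
                                    depth_grid[d])
      acc[f, d] <- mean(pred == y[test_idx])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best <- depth_grid[which.max(mean_acc)]   # which.max takes first: smallest depth
  list(depth = best, cv_accuracy = mean_acc, folds = folds)
}

# Class prediction on an already-encoded matrix (hot path for CV and mining).
predict_encoded_class <- function(object, x, depth_cap = Inf) {
  n <- nrow(x)
  cls <- integer(n)
  assign_leaf <- function(node, idx) cls[idx] <<- node$majority
  if (n > 0) route_rows(object$root, x, seq_len(n), assign_leaf, depth_cap)
  cls
}

predict_encoded_prob <- function(object, x, class_index, depth_cap = Inf) {
  n <- nrow(x)
  pr <- numeric(n)
  assign_leaf <- function(node, idx) pr[idx] <<- node$prob[class_index]
  if (n > 0) route_rows(object$root, x, seq_len(n), assign_leaf, depth_cap)
  pr
}

# ---- inspection -------------------------------------------------------------

#' Variable importance of a fitted tree
#'
#' Sum over internal nodes of `n * split_gain`, attributed to the split
#' predictor; zero for predictors never used.
#'
#' @param tree A fitted [sevcart()] object.
#' @return Named nonnegative numeric vector over all predictors.
#' @export
variable_importance <- function(tree) {
  stopifnot(inherits(tree, "sevcart"))
  imp <- stats::setNames(numeric(length(tree$encoding$predictors)),
                         tree$encoding$predictors)
  walk <- function(node) {
    if (!node$leaf) {
      imp[node$split$var] <<- imp[node$split$var] + node$n * node$split$gain
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  imp
}

tree_depth <- function(tree) {
  walk <- function(node) {
    if (node$leaf) node$depth else max(walk(node$left), walk(node$right))
  }
  walk(tree$root)
}

n_leaves <- function(tree) {
  walk <- function(node) if (node$leaf) 1L else walk(node$left) + walk(node$right)
  walk(tree$root)
}

format_split_condition <- function(split, enc, side) {
  name <- enc$predictors[split$var]
  if (split$type == "ordinal") {
    if (side == "left") {
      sprintf("%s < %g", name, split$threshold)
    } else {
      sprintf("%s >= %g", name, split$threshold)
    }
  } else {
    lev <- enc$plevels[[split$var]]
    keep <- if (side == "left") split$left_levels else
      setdiff(seq_along(lev), split$left_levels)
    sprintf("%s in {%s}", name, paste(lev[keep], collapse = ","))
  }
}

#' @export
print.sevcart <- function(x, ...) {
  cat(sprintf("Severity classification tree: n = %d, depth = %d, %d leaves\n",
              x$n, tree_depth(x), n_leaves(x)))
  cat(sprintf("minsplit = %d, minbucket = %d, maxdepth = %d\n",
              x$control$minsplit, x$control$minbucket, x$control$maxdepth))
  walk <- function(node, label, indent) {
    star <- if (node$leaf) " *" else ""
    cat(sprintf("%s%s: n=%d (%s) -> %s%s\n",
                strrep("  ", indent), label, node$n,
                paste(node$counts, collapse = "/"),
                x$levels[node$majority], star))
    if (!node$leaf) {
      walk(node$left, format_split_condition(node$split, x$encoding, "left"),
           indent + 1L)
      walk(node$right, format_split_condition(node$split, x$encoding, "right"),
           indent + 1L)
    }
  }
  walk(x$root, "root", 0L)
  invisible(x)
}

#' @export
summary.sevcart <- function(object, ...) {
  print(object)
  imp <- variable_importance(object)
  imp <- imp[imp > 0]
  if (length(imp)) {
    cat("\nVariable importance (n x Gini gain):\n")
    print(round(sort(imp, decreasing = TRUE), 3))
  }
  invisible(object)
}
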