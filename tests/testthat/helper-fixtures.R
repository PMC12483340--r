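# Shared fixture builders and independent oracles. Everything is generated in
# code at test time; no stored data.

gad7 <- scale_spec("GAD7")
phq9 <- scale_spec("PHQ9")

# A small raw item table with valid rows (no demographics).
make_item_table <- function(n, spec = gad7, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:3, n * spec$n_items, replace = TRUE), n)
    colnames(m) <- spec$items
    as.data.frame(m)
  })
}

# Random tiny classification dataset for oracle-equivalence checks: ordinal
# 0-3 predictors, outcome classes cut from a noisy linear signal so splits
# carry real but imperfect information.
make_tiny_dataset <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(12:30, 1)
    p <- sample(2:3, 1)
    X <- as.data.frame(matrix(sample(0:3, n * p, replace = TRUE), n, p))
    names(X) <- paste0("x", seq_len(p))
    latent <- rowSums(X) + stats::rnorm(n, 0, 1.5)
    K <- sample(2:3, 1)
    y <- cut(latent,
             breaks = stats::quantile(latent, probs = seq(0, 1, length = K + 1)),
             include.lowest = TRUE, labels = paste0("c", 1:K))
    cbind(X, y = y)
  })
}

# Brute-force best split: enumerate every ordinal threshold of every
# predictor by direct subsetting and return the maximal legal gain.
brute_force_best_gain <- function(data, response, predictors, minbucket) {
  y <- as.factor(data[[response]])
  K <- nlevels(y)
  parent <- tabulate(as.integer(y), K)
  best <- 0
  for (v in predictors) {
    x <- data[[v]]
    vals <- sort(unique(x))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      sel <- x < thr
      if (sum(sel) < minbucket || sum(!sel) < minbucket) next
      l <- tabulate(as.integer(y)[sel], K)
      g <- split_gain(parent, l, parent - l)
      if (g > best) best <- g
    }
  }
  best
}

# Rank-based (Mann-Whitney) AUC with ties counted 1/2: an independent
# computation route from the trapezoidal sweep in roc_auc().
rank_auc <- function(scores, positives) {
  r <- rank(scores)
  n_pos <- sum(positives)
  n_neg <- sum(!positives)
  (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Structural audit used on every fitted tree: count conservation, the
# minbucket/minsplit constraints and the depth bound.
audit_tree <- function(tree) {
  ctrl <- tree$control
  ok <- TRUE
  walk <- function(node) {
    if (!node$leaf) {
      if (node$n < ctrl$minsplit) ok <<- FALSE
      if (!all(node$left$counts + node$right$counts == node$counts)) ok <<- FALSE
      walk(node$left)
      walk(node$right)
    } else {
      if (node$n < ctrl$minbucket) ok <<- FALSE
      if (node$depth > ctrl$maxdepth) ok <<- FALSE
    }
    if (sum(node$counts) != node$n) ok <<- FALSE
  }
  walk(tree$root)
  leaf_total <- 0
  walk2 <- function(node) {
    if (node$leaf) leaf_total <<- leaf_total + node$n
    else { walk2(node$left); walk2(node$right) }
  }
  walk2(tree$root)
  ok && leaf_total == tree$n
}

rule_vars <- function(rule) {
  vapply(rule$conditions, function(c) c$var, character(1))
}

rule_of_class <- function(rules, cl) {
  cls <- vapply(rules, function(r) r$class, character(1))
  rules[[which(cls == cl)[1]]]
}

# Fitted rpart reference tree under identical settings (Gini, same
# constraints, no surrogates/competitors, depth-only pruning).
fit_rpart_reference <- function(data, minsplit, minbucket, maxdepth) {
  rpart::rpart(y ~ ., data = data, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(
                 minsplit = minsplit, minbucket = minbucket,
                 maxdepth = maxdepth, cp = 0, xval = 0,
                 maxsurrogate = 0, usesurrogate = 0, maxcompete = 0))
}
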