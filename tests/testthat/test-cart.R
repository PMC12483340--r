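test_that("gini_impurity and split_gain follow their definitions", {
  expect_equal(gini_impurity(c(10, 0, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(1, 2, 3)), 11 / 18)
  expect_error(gini_impurity(c(0, 0)), "positive total")
  expect_error(gini_impurity(c(-1, 2)), "nonnegative")

  expect_equal(split_gain(c(5, 5), c(5, 0), c(0, 5)), 0.5)
  expect_equal(split_gain(c(4, 4), c(3, 1), c(1, 3)), 0.125)
  expect_error(split_gain(c(5, 5), c(5, 5), c(0, 0)), "nonempty")
  expect_error(split_gain(c(5, 5), c(4, 0), c(0, 5)), "sum to the parent")
})

test_that("best split matches brute-force enumeration on tiny instances", {
  for (case in 1:100) {
    d <- make_tiny_dataset(400 + case)
    preds <- setdiff(names(d), "y")
    y <- as.integer(d$y)
    enc <- sevrules:::encode_predictors(d, preds)
    got <- sevrules:::best_split_enc(y, enc, seq_len(nrow(d)),
                                     minbucket = 2L, K = nlevels(d$y))
    want <- brute_force_best_gain(d, "y", preds, minbucket = 2L)
    if (is.null(got)) {
      expect_equal(want, 0)
    } else {
      expect_equal(got$gain, want, tolerance = 1e-12)
    }
  }
})

test_that("best split handles separation, constants and the ordinal convention", {
  # perfectly ordered predictor: threshold at the class boundary, gain = parent impurity
  d <- data.frame(x = c(0, 0, 1, 1, 2, 2, 3, 3),
                  y = factor(rep(c("a", "b"), each = 4)))
  enc <- sevrules:::encode_predictors(d, "x")
  s <- sevrules:::best_split_enc(as.integer(d$y), enc, 1:8, 1L, 2L)
  expect_equal(s$threshold, 1.5)
  expect_equal(s$gain, 0.5)

  # constant predictor: no split
  d2 <- data.frame(x = rep(2, 10), y = factor(rep(c("a", "b"), 5)))
  enc2 <- sevrules:::encode_predictors(d2, "x")
  expect_null(sevrules:::best_split_enc(as.integer(d2$y), enc2, 1:10, 1L, 2L))

  # unobserved middle value: threshold midway between observed values
  d3 <- data.frame(x = c(0, 0, 0, 2, 2, 2), y = factor(c("a", "a", "a", "b", "b", "b")))
  enc3 <- sevrules:::encode_predictors(d3, "x")
  s3 <- sevrules:::best_split_enc(as.integer(d3$y), enc3, 1:6, 1L, 2L)
  expect_equal(s3$threshold, 1)
})

test_that("grown trees honour size, purity and depth constraints", {
  # pure training set -> single leaf
  d <- data.frame(x1 = sample(0:3, 50, TRUE), y = factor(rep("a", 50)))
  fit <- sevcart(y ~ x1, d, sevcart_control(2, 1, 5))
  expect_true(fit$root$leaf)
  expect_equal(as.character(unique(predict(fit, d))), "a")

  # maxdepth = 1 -> at most a stump
  co <- generate_cohort(generator_config("GAD7", n = 800, seed = 15))
  f1 <- sevcart(severity ~ GAD1 + GAD2 + GAD3 + GAD4 + GAD5 + GAD6 + GAD7,
                co, sevcart_control(50, 25, 1))
  expect_lte(sevrules:::tree_depth(f1), 1L)
  expect_true(audit_tree(f1))

  # structural audit on a larger seeded fit
  f2 <- sevcart(severity ~ GAD1 + GAD2 + GAD3 + GAD4 + GAD5 + GAD6 + GAD7,
                co, sevcart_control(40, 15, 6))
  expect_true(audit_tree(f2))
  expect_error(sevcart(severity ~ GAD1, co[0, ], sevcart_control(2, 1, 2)),
               "empty")
})

test_that("training accuracy matches an independent reference tree on 100 random instances", {
  for (case in 1:100) {
    d <- make_tiny_dataset(1000 + case)
    ctrl <- sevcart_control(minsplit = 6, minbucket = 2, maxdepth = 3)
    fit <- sevcart(y ~ ., d, ctrl)
    expect_true(audit_tree(fit))
    acc_mine <- mean(predict(fit, d) == d$y)
    rfit <- fit_rpart_reference(d, 6, 2, 3)
    acc_ref <- mean(predict(rfit, d, type = "class") == d$y)
    expect_equal(acc_mine, acc_ref, tolerance = 1e-12)
  }
})

test_that("prediction routes by threshold convention and returns proper probabilities", {
  co <- generate_cohort(generator_config("GAD7", n = 600, seed = 19))
  fit <- sevcart(severity ~ GAD2 + GAD4, co, sevcart_control(50, 25, 2))
  pr <- predict(fit, co, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(co)))

  # a stump on one item: value exactly at the integer boundary goes left
  d <- data.frame(x = c(rep(0, 30), rep(1, 30), rep(2, 30), rep(3, 30)),
                  y = factor(c(rep("lo", 60), rep("hi", 60)), levels = c("lo", "hi")))
  stump <- sevcart(y ~ x, d, sevcart_control(2, 1, 1))
  expect_equal(stump$root$split$threshold, 1.5)
  expect_equal(as.character(predict(stump, data.frame(x = 1))), "lo")
  expect_equal(as.character(predict(stump, data.frame(x = 2))), "hi")
  expect_error(predict(stump, data.frame(x = NA_integer_)), "missing value")
})

test_that("leaf label ties break toward the more severe class", {
  d <- data.frame(x = rep(1L, 30),
                  y = factor(rep(severity_levels(), each = 10),
                             levels = severity_levels()))
  fit <- sevcart(y ~ x, d, sevcart_control(50, 25, 2))
  expect_true(fit$root$leaf)
  expect_equal(fit$root$counts, c(10L, 10L, 10L))
  expect_equal(as.character(predict(fit, d[1, , drop = FALSE])), "severe")
})

test_that("depth-capped prediction equals refitting at the smaller depth", {
  co <- generate_cohort(generator_config("GAD7", n = 1500, seed = 29))
  form <- severity ~ GAD1 + GAD2 + GAD3 + GAD4 + GAD5 + GAD6 + GAD7
  deep <- sevcart(form, co, sevcart_control(60, 30, 6))
  for (d in c(1, 2, 3)) {
    shallow <- sevcart(form, co, sevcart_control(60, 30, d))
    expect_identical(predict(deep, co, maxdepth = d), predict(shallow, co))
  }
})

test_that("cross-validated depth selection picks minimal sufficient depth", {
  # one item fully determines the class -> depth 1, ties to the smallest
  d <- data.frame(x1 = rep(0:3, each = 50),
                  x2 = sample(0:3, 200, TRUE),
                  y = factor(rep(c("a", "a", "b", "b"), each = 50)))
  td <- tune_maxdepth(y ~ x1 + x2, d, sevcart_control(20, 10, 8),
                      depth_grid = 1:4, cv_folds = 10, seed = 3)
  expect_equal(td$depth, 1L)
  td2 <- tune_maxdepth(y ~ x1 + x2, d, sevcart_control(20, 10, 8),
                       depth_grid = 1:4, cv_folds = 10, seed = 3)
  expect_identical(td$depth, td2$depth)
  expect_identical(td$cv_accuracy, td2$cv_accuracy)

  # pure-noise outcome: held-out accuracy cannot reward depth, so the
  # smallest depth is favoured (modal) and the deepest is rarely chosen
  picks <- integer(50)
  for (i in 1:50) {
    dn <- withr::with_seed(700 + i, data.frame(
      x1 = sample(0:3, 2000, TRUE), x2 = sample(0:3, 2000, TRUE),
      y = factor(sample(c("a", "b"), 2000, TRUE))))
    picks[i] <- tune_maxdepth(y ~ x1 + x2, dn, sevcart_control(194, 194, 8),
                              depth_grid = 1:4, cv_folds = 10,
                              seed = 800 + i)$depth
  }
  tab <- table(factor(picks, levels = 1:4))
  expect_equal(unname(which.max(tab)), 1L)
  expect_gt(mean(picks == 1L), mean(picks == 4L))

  expect_error(tune_maxdepth(y ~ x1, d[1:5, ], sevcart_control(2, 1, 2),
                             cv_folds = 10), "fewer rows than folds")
})

test_that("variable importance attributes n x gain to split predictors", {
  d <- data.frame(GAD2 = c(rep(0, 40), rep(3, 40)),
                  GAD5 = sample(0:3, 80, TRUE),
                  y = factor(rep(c("a", "b"), each = 40)))
  stump <- sevcart(y ~ GAD2 + GAD5, d, sevcart_control(10, 5, 1))
  imp <- variable_importance(stump)
  expect_gt(imp[["GAD2"]], 0)
  expect_equal(imp[["GAD5"]], 0)
  expect_equal(unname(imp["GAD2"]), 80 * stump$root$split$gain)

  leaf <- sevcart(y ~ GAD2, data.frame(GAD2 = rep(1, 30),
                                       y = factor(rep("a", 30))),
                  sevcart_control(2, 1, 3))
  expect_true(all(variable_importance(leaf) == 0))
})

test_that("demographics get negligible importance when they carry no signal", {
  ok <- logical(50)
  for (i in 1:50) {
    co <- generate_cohort(generator_config("GAD7", n = 1500, seed = 1300 + i))
    fit <- sevcart(severity ~ GAD1 + GAD2 + GAD3 + GAD4 + GAD5 + GAD6 + GAD7 +
                     sex + skin_color + education + age_group,
                   co, sevcart_control(73, 73, 4))
    imp <- variable_importance(fit)
    demo_share <- sum(imp[c("sex", "skin_color", "education", "age_group")]) /
      max(sum(imp), .Machine$double.eps)
    ok[i] <- demo_share < 0.05
  }
  expect_gte(mean(ok), 0.9)
})

test_that("adding a strictly separating predictor never lowers the root gain", {
  for (i in 1:20) {
    d <- make_tiny_dataset(2200 + i)
    preds <- setdiff(names(d), "y")
    g0 <- brute_force_best_gain(d, "y", preds, 1L)
    d$sep <- as.integer(as.integer(d$y) >= 2)  # separates class 1 from the rest
    enc <- sevrules:::encode_predictors(d, c(preds, "sep"))
    s <- sevrules:::best_split_enc(as.integer(d$y), enc, seq_len(nrow(d)), 1L,
                                   nlevels(d$y))
    expect_gte(s$gain, g0 - 1e-12)
  }
})
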