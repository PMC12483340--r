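gad_rule <- function(class, conds) {
  canonicalize(new_rule("GAD7", class, lapply(conds, function(c) {
    sevrules:::new_condition_ord(c[[1]], c[[2]], c[[3]])
  })))
}

test_that("apply_rule implements interval conjunction semantics", {
  tab <- data.frame(GAD2 = c(1, 2, 3, 0), GAD4 = c(0, 0, 3, 2))
  r_min <- gad_rule("minimal_mild", list(list("GAD2", 0, 1), list("GAD4", 0, 1)))
  expect_equal(apply_rule(r_min, tab), c(TRUE, FALSE, FALSE, FALSE))
  r_sev <- gad_rule("severe", list(list("GAD2", 2, 3), list("GAD4", 3, 3)))
  expect_equal(apply_rule(r_sev, tab), c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(apply_rule(new_rule("GAD7", "moderate"), tab)))
  expect_error(apply_rule(gad_rule("severe", list(list("GAD9", 2, 3))), tab),
               "GAD9")
})

test_that("confusion counts and point metrics follow their definitions", {
  truth <- c(rep("severe", 3), rep("moderate", 7))
  cm0 <- confusion(rep(FALSE, 10), truth, "severe")
  expect_equal(unlist(cm0[c("tp", "fn", "tn", "fp")]), c(tp = 0, fn = 3, tn = 7, fp = 0))
  pm0 <- point_metrics(cm0)
  expect_equal(pm0$sensitivity, 0)
  expect_false(pm0$precision_defined)
  expect_equal(pm0$precision, 0)

  cm1 <- confusion(truth == "severe", truth, "severe")
  expect_equal(cm1$fp + cm1$fn, 0)
  expect_equal(point_metrics(cm1)$accuracy, 1)

  # arithmetic from definitions: TP=50, FN=50, TN=90, FP=10
  cm <- structure(list(tp = 50, fp = 10, tn = 90, fn = 50, n = 200),
                  class = "confusion_counts")
  pm <- point_metrics(cm)
  expect_equal(pm$accuracy, 0.70)
  expect_equal(pm$sensitivity, 0.50)
  expect_equal(pm$specificity, 0.90)
  expect_equal(pm$precision, 50 / 60)
  expect_equal(pm$f1, 2 * (50 / 60) * 0.5 / (50 / 60 + 0.5))
  expect_equal(pm$f1, 0.625)

  expect_error(confusion(c(TRUE, FALSE), c("a"), "a"), "length")
})

test_that("confusion counts always conserve n and complementing swaps sens/spec", {
  for (i in 1:25) {
    set.seed(3000 + i)
    truth <- sample(severity_levels(), 40, TRUE)
    pred <- sample(c(TRUE, FALSE), 40, TRUE)
    cm <- confusion(pred, truth, "severe")
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 40)
    pm <- point_metrics(cm)
    expect_equal(pm$accuracy, (cm$tp + cm$tn) / 40)
    pmc <- point_metrics(confusion(!pred, truth, "severe"))
    expect_equal(pm$sensitivity, 1 - pmc$sensitivity)
    expect_equal(pm$specificity, 1 - pmc$specificity)
  }
})

test_that("trapezoidal AUC equals the rank-based computation and its closed forms", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), pos), 1)
  expect_equal(roc_auc(rep(2, 10), pos), 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
  expect_error(roc_auc(1:3, c(TRUE, FALSE)), "length")

  for (i in 1:100) {
    set.seed(100 + i)
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # heavy ties
    positives <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(positives) || all(positives)) next
    expect_equal(roc_auc(scores, positives), rank_auc(scores, positives),
                 tolerance = 1e-10)
  }

  # binary 0/1 score: AUC = (sensitivity + specificity) / 2 exactly
  for (i in 1:25) {
    set.seed(500 + i)
    truth <- sample(severity_levels(), 50, TRUE)
    pred <- sample(c(TRUE, FALSE), 50, TRUE)
    pos <- truth == "severe"
    if (!any(pos) || all(pos)) next
    pm <- point_metrics(confusion(pred, truth, "severe"))
    expect_equal(roc_auc(as.numeric(pred), pos),
                 (pm$sensitivity + pm$specificity) / 2, tolerance = 1e-12)
  }
})

test_that("evaluation across repetitions reports mean (SD) per rule", {
  co <- generate_cohort(generator_config("GAD7", n = 2000, seed = 61))
  mg1 <- mine(co, mining_config("demo", reps_per_config = 1, seed = 13))
  rep1 <- evaluate_rules(mg1)
  sd_cols <- grep("_sd$", names(rep1), value = TRUE)
  expect_true(all(unlist(rep1[sd_cols]) == 0))

  mg <- mine(co, mining_config("demo", reps_per_config = 8, seed = 14))
  tr <- top_rules(mg)
  repb <- evaluate_rules(mg, tr, auc_mode = "rule_binary")
  expect_true(all(repb$accuracy_mean >= 0 & repb$accuracy_mean <= 1))
  # rule-binary AUC mean equals mean (sens+spec)/2 across the same repetitions
  expect_equal(repb$auc_mean,
               (repb$sensitivity_mean + repb$specificity_mean) / 2,
               tolerance = 1e-12)
  # class-level probability AUC: both rules of one class share the curve
  rept <- evaluate_rules(mg, tr, auc_mode = "tree_probability")
  mods <- which(rept$class == "moderate")
  if (length(mods) == 2) {
    expect_equal(rept$auc_mean[mods[1]], rept$auc_mean[mods[2]])
  }
})

test_that("a rule that coincides with the class definition scores perfectly", {
  # two row profiles: GAD2=3 & rest 2 (total 15, severe); GAD2=0 & rest 2 (12)
  base <- as.data.frame(matrix(2L, 60, 7, dimnames = list(NULL, gad7$items)))
  base$GAD2 <- rep(c(0L, 3L), each = 30)
  tab <- validate_table(base, gad7)
  expect_setequal(as.character(unique(tab$severity)), c("moderate", "severe"))
  res <- external_validate(list(gad_rule("severe", list(list("GAD2", 2, 3)))),
                           tab)
  expect_equal(res$accuracy, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$auc, 1)
})

test_that("external validation applies frozen rules unchanged", {
  cfg <- generator_config("GAD7", n = 4000, seed = 71)
  co <- generate_cohort(cfg)
  mg <- mine(co, mining_config("demo", reps_per_config = 20, seed = 15))
  tr <- top_rules(mg)
  report <- evaluate_rules(mg, tr, auc_mode = "rule_binary")

  # self-consistency: single-pass metrics on the training cohort sit near the
  # repetition means
  selfv <- external_validate(tr, co)
  for (i in seq_along(tr)) {
    row <- selfv[selfv$rule == format_rule(tr[[i]]) &
                   selfv$class == tr[[i]]$class, ][1, ]
    expect_lt(abs(row$accuracy - report$accuracy_mean[i]), 0.05)
  }

  # reproducibility on a fresh cohort from the same generating process
  cfg2 <- cfg
  cfg2$seed <- 72L
  co2 <- generate_cohort(cfg2)
  ext <- external_validate(tr, co2)
  for (i in seq_along(tr)) {
    row <- ext[ext$rule == format_rule(tr[[i]]) &
                 ext$class == tr[[i]]$class, ][1, ]
    cl <- tr[[i]]$class
    denom <- c(accuracy = nrow(co2),
               sensitivity = sum(co2$severity == cl),
               specificity = sum(co2$severity != cl))
    for (m in c("accuracy", "sensitivity", "specificity")) {
      mu <- report[[paste0(m, "_mean")]][i]
      # the repetition SD reflects test-partition noise only; an independent
      # cohort adds its own binomial sampling error, so both enter the bound
      tol <- 3 * sqrt(report[[paste0(m, "_sd")]][i]^2 +
                        mu * (1 - mu) / denom[[m]])
      expect_lt(abs(row[[m]] - mu), tol)
    }
  }

  # the two middle-class rules are also pooled as a union screener
  expect_true(any(grepl(" OR ", ext$rule)))

  # a severe rule that never fires has zero sensitivity
  never <- gad_rule("severe", list(list("GAD1", 3, 3), list("GAD2", 0, 0)))
  keep <- !(co2$GAD1 == 3L & co2$GAD2 == 0L)
  tab2 <- validate_table(as.data.frame(co2)[keep, ], gad7)
  expect_gt(sum(tab2$severity == "severe"), 0)
  res <- external_validate(list(never), tab2)
  expect_equal(res$sensitivity, 0)

  # scale mismatch is an error
  co9 <- generate_cohort(generator_config("PHQ9", n = 50, seed = 5))
  expect_error(external_validate(tr, co9), "does not match")
})
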