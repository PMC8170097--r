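# LOOCV protocol, AUC, confusion decomposition, scenario grid

test_that("every subject is held out exactly once", {
  d <- toy_features(n = 16, effect = 3)
  cv <- loocv_scores(d$x, d$y, model_spec("LR"), seed = 1)
  expect_equal(nrow(cv), 16)
  expect_equal(cv$label, d$y)
  expect_true(all(cv$pred %in% c(0, 1)))
})

test_that("a separable toy problem is classified nearly perfectly", {
  d <- toy_features(n = 30, effect = 6, seed = 2)
  for (kind in c("LR", "SVM")) {
    cv <- loocv_scores(d$x, d$y, model_spec(kind), seed = 1)
    expect_gte(auc(cv$score, cv$label), 0.95)
  }
})

test_that("LOOCV is reproducible under a fixed seed", {
  d <- toy_features(n = 12, effect = 2, seed = 3)
  a <- loocv_scores(d$x, d$y, model_spec("MLP"), seed = 42)
  b <- loocv_scores(d$x, d$y, model_spec("MLP"), seed = 42)
  expect_identical(a, b)
})

test_that("fold preprocessing never sees the held-out subject", {
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4)
  x_test <- x[1, , drop = FALSE]
  x_train <- x[-1, , drop = FALSE]
  pp <- speechmarkers:::preprocess_fold(x_train, x_test)
  # poison the held-out row: training-side statistics must be unchanged
  poisoned <- x_test; poisoned[1, ] <- 1e9
  pp2 <- speechmarkers:::preprocess_fold(x_train, poisoned)
  expect_identical(pp$train, pp2$train)
  expect_identical(pp$center, pp2$center)
  expect_identical(pp$scale, pp2$scale)
  # and an NA in the held-out row is imputed with the training median
  x_na <- x_test; x_na[1, 2] <- NA
  pp3 <- speechmarkers:::preprocess_fold(x_train, x_na)
  med <- stats::median(x_train[, 2])
  expect_equal(pp3$test[1, 2],
               (med - mean(x_train[, 2])) / stats::sd(x_train[, 2]),
               ignore_attr = TRUE)
})

test_that("constant features are dropped per fold with a warning", {
  d <- toy_features(n = 12, effect = 2, seed = 5)
  d$x$const <- 1
  expect_warning(cv <- loocv_scores(d$x, d$y, model_spec("LR"), seed = 1),
                 "constant")
  expect_equal(nrow(cv), 12)
})

test_that("a single-class training fold is an error", {
  x <- data.frame(f = rnorm(4))
  expect_error(loocv_scores(x, c(0, 1, 1, 1), model_spec("LR")),
               "single class")
})

test_that("AUC matches trivial cases and the tie convention", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals brute-force concordant-pair counting", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(6)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- if (i %% 4 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    expect_equal(auc(s, y), brute(s, y))
  }
})

test_that("confusion summaries reproduce the published error rates", {
  # multilingual LR block and its per-language decomposition
  en <- preds_from_counts(43, 13, 39, 11)
  fr <- preds_from_counts(15, 3, 22, 7)
  cm <- confusion_summary(c(en$pred, fr$pred), c(en$label, fr$label),
                          c(rep("en", 106), rep("fr", 47)))
  expect_equal(cm$overall$error_rate, 22.22)
  expect_equal(cm$overall[c("TP", "FP", "TN", "FN")],
               list(TP = 58, FP = 16, TN = 61, FN = 18))
  expect_equal(cm$per_language$en$error_rate, 22.64)
  expect_equal(cm$per_language$fr$error_rate, 21.28)
  expect_equal(cm$per_language$fr$fp_share, 30)
  # per-language cells sum to the overall matrix
  for (cell in c("TP", "FP", "TN", "FN"))
    expect_equal(cm$per_language$en[[cell]] + cm$per_language$fr[[cell]],
                 cm$overall[[cell]])

  perfect <- confusion_summary(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$overall$error_rate, 0)
  expect_equal(perfect$overall$FP + perfect$overall$FN, 0)

  expect_error(confusion_summary(c(1, 0), c(1, 0), c("en", "de")),
               "unknown language")
})

test_that("the scenario grid covers all eight scenarios with consistent matrices", {
  set.seed(7)
  n_l <- 10                      # per group per language
  y <- rep(rep(c(0, 1), each = n_l), 2)
  langs <- rep(c("en", "fr"), each = 2 * n_l)
  p <- 12
  reg <- data.frame(feature = paste0("f", 1:p),
                    subgroup = rep(c("task", "semantic", "syntactic",
                                     "paralinguistic"), each = 3))
  x <- matrix(rnorm(length(y) * p), ncol = p,
              dimnames = list(NULL, reg$feature))
  x[, c("f4", "f7")] <- x[, c("f4", "f7")] + 2 * y   # informative non-task
  ages <- rnorm(length(y), 70, 6)
  sel <- list(selected = c("f4", "f7"), alpha = 0.05,
              excluded_task_count = 0)

  res <- run_scenarios(as.data.frame(x), y, langs, reg, sel, ages = ages,
                       models = "LR", seed = 1)
  expect_length(res, 8)
  expect_setequal(vapply(res, `[[`, character(1), "scenario_id"),
                  c("en_all_language", "fr_all_language",
                    "multi_all_language", "en_generalizable",
                    "fr_generalizable", "multi_generalizable",
                    "en_baseline_all_subgroups", "multi_age_only"))
  expect_false(any(vapply(res, function(r) isTRUE(r$skipped), logical(1))))
  for (r in res) {
    cm <- r$confusion
    for (cell in c("TP", "FP", "TN", "FN"))
      expect_equal(Reduce(`+`, lapply(cm$per_language, `[[`, cell)),
                   cm$overall[[cell]])
    expect_equal(cm$overall$TP + cm$overall$FP + cm$overall$TN +
                   cm$overall$FN, r$n)
  }
  # generalizable runs use strictly fewer features than all-language runs
  nf <- function(id, mk) res[[paste(id, mk, sep = ".")]]$n_features
  expect_lt(nf("multi_generalizable", "LR"), nf("multi_all_language", "LR"))
  expect_equal(nf("multi_age_only", "LR"), 1)

  # reproducibility of the whole grid
  res2 <- run_scenarios(as.data.frame(x), y, langs, reg, sel, ages = ages,
                        models = "LR", seed = 1)
  expect_identical(res, res2)
})

test_that("an empty selection produces explicit skip entries", {
  d <- toy_features(n = 16, p = 4, effect = 2, seed = 8)
  reg <- data.frame(feature = names(d$x), subgroup = "semantic")
  sel <- list(selected = character(0), alpha = 0.05)
  res <- run_scenarios(d$x, d$y, rep(c("en", "fr"), each = 8), reg, sel,
                       ages = rnorm(16, 70, 5), models = "LR", seed = 1)
  skipped <- Filter(function(r) isTRUE(r$skipped), res)
  expect_equal(sort(unique(vapply(skipped, `[[`, character(1),
                                  "scenario_id"))),
               c("en_generalizable", "fr_generalizable",
                 "multi_generalizable"))
})
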