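#' Leave-one-out classification experiments
#'
#' Three classifier families are evaluated under leave-one-out
#' cross-validation: L2-regularized logistic regression (LR), a
#' radial-basis support vector machine (SVM, cost 1) and a one-hidden-layer
#' multilayer perceptron (MLP, 100 logistic units, L2 weight decay 0.01).
#' Within each fold, missing values are imputed with training-fold medians
#' and features are standardized to training-fold mean 0 / sd 1; the
#' held-out subject never contributes to either statistic.  The AUC is
#' computed once from the pooled held-out scores (a per-fold AUC is
#' undefined with a single test sample).
#'
#' @name ml_eval
NULL

#' Model specification
#'
#' @param kind `"LR"`, `"SVM"` or `"MLP"`.
#' @return a `model_spec` list with the family's fixed hyperparameters:
#'   LR: L2 penalty with inverse strength `C = 1`; SVM: radial kernel,
#'   `cost = 1`; MLP: one hidden layer of 100 logistic units, weight decay
#'   0.01, the fitter's default iteration cap (100).
#' @export
model_spec <- function(kind = c("LR", "SVM", "MLP")) {
  kind <- match.arg(kind)
  hp <- switch(kind,
    LR  = list(C = 1),
    SVM = list(cost = 1, kernel = "radial"),
    MLP = list(size = 100, decay = 0.01, maxit = 100))
  structure(list(kind = kind, hyperparameters = hp), class = "model_spec")
}

# Fit on standardized training data and score standardized test rows.
# Returns continuous decision scores oriented so larger = more AD-like,
# plus hard 0/1 predictions at the model's native threshold.
fit_and_score <- function(x_train, y_train, x_test, spec, seed) {
  kind <- spec$kind
  if (kind == "LR") {
    # glmnet ridge at the fixed lambda equivalent to an L2 penalty with
    # inverse strength C = 1 on the summed log-likelihood
    lam <- 1 / (nrow(x_train) * spec$hyperparameters$C)
    xtr <- x_train
    if (ncol(xtr) == 1) {            # glmnet requires >= 2 columns
      xtr <- cbind(xtr, 0)
      x_test <- cbind(x_test, 0)
    }
    fit <- glmnet::glmnet(xtr, factor(y_train, levels = c(0, 1)),
                          family = "binomial", alpha = 0, lambda = lam,
                          standardize = FALSE)
    sc <- as.numeric(stats::predict(fit, x_test, type = "link"))
    list(score = sc, pred = as.numeric(sc > 0))
  } else if (kind == "SVM") {
    fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                      kernel = spec$hyperparameters$kernel,
                      cost = spec$hyperparameters$cost, scale = FALSE)
    pr <- stats::predict(fit, x_test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # decision values are oriented toward the first class in the colname
    positive_first <- startsWith(colnames(dv)[1], "1")
    sc <- if (positive_first) as.numeric(dv) else -as.numeric(dv)
    list(score = sc, pred = as.numeric(sc > 0))
  } else {
    set.seed(seed)
    fit <- nnet::nnet(x_train, y_train, size = spec$hyperparameters$size,
                      decay = spec$hyperparameters$decay,
                      maxit = spec$hyperparameters$maxit,
                      entropy = TRUE, trace = FALSE,
                      MaxNWts = (ncol(x_train) + 2) *
                        spec$hyperparameters$size + spec$hyperparameters$size + 1)
    sc <- as.numeric(stats::predict(fit, x_test))
    list(score = sc, pred = as.numeric(sc > 0.5))
  }
}

# training-fold preprocessing: median imputation then standardization;
# constant columns are dropped (with a warning) because they carry no
# information and break scaling
preprocess_fold <- function(x_train, x_test) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x_train))) {
    x_train[is.na(x_train[, j]), j] <- med[j]
    x_test[is.na(x_test[, j]), j] <- med[j]
  }
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  keep <- which(sd > 0)
  if (length(keep) < ncol(x_train))
    warning(sprintf("%d constant feature(s) dropped in a fold",
                    ncol(x_train) - length(keep)))
  if (length(keep) == 0) stop("no usable features in fold", call. = FALSE)
  list(train = scale(x_train[, keep, drop = FALSE], mu[keep], sd[keep]),
       test = scale(x_test[, keep, drop = FALSE], mu[keep], sd[keep]),
       center = mu, scale = sd, kept = keep)
}

#' Leave-one-out cross-validated scores
#'
#' Holds out every subject once, fits the model on the rest (with
#' training-fold imputation and standardization) and records the held-out
#' continuous score and hard prediction.
#'
#' @param features subjects x features data frame or matrix.
#' @param labels binary labels (AD positive).
#' @param spec a [model_spec()].
#' @param seed integer seed; MLP fits derive per-fold seeds from it.
#' @return data frame with one row per subject: `score`, `pred`, `label`.
#' @export
loocv_scores <- function(features, labels, spec, seed = 1) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  y <- as01(labels)
  n <- nrow(x)
  stopifnot(n >= 4)
  score <- pred <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold has a single class", call. = FALSE)
    pp <- preprocess_fold(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    fs <- fit_and_score(pp$train, ytr, pp$test, spec, seed = seed + i)
    score[i] <- fs$score
    pred[i] <- fs$pred
  }
  data.frame(score = score, pred = pred, label = y)
}

#' Area under the ROC curve
#'
#' Rank-based AUC equal to the normalized Mann-Whitney U statistic; tied
#' scores contribute 1/2.
#'
#' @param scores continuous classifier scores.
#' @param labels binary labels (positive = AD = 1).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix summary with per-language decomposition
#'
#' Builds the overall 2x2 confusion matrix (AD positive) and one per
#' language, the overall and per-language error rates (percent), and each
#' language's false-positive share of its errors, `FP / (FP + FN)`.
#'
#' @param predictions hard 0/1 predictions.
#' @param labels binary ground-truth labels.
#' @param language_tags language of each subject (`"en"`/`"fr"`), or
#'   `NULL` for a single-language run.
#' @return list with `overall` (list `TP`, `FP`, `TN`, `FN`, `n`,
#'   `error_rate`) and `per_language` (named list of the same shape plus
#'   `fp_share`).
#' @export
confusion_summary <- function(predictions, labels, language_tags = NULL) {
  y <- as01(labels); p <- as01(predictions)
  stopifnot(length(y) == length(p))
  if (is.null(language_tags)) language_tags <- rep("all", length(y))
  if (length(language_tags) != length(y))
    stop("language_tags length mismatch", call. = FALSE)
  known <- c("en", "fr", "all")
  if (!all(language_tags %in% known))
    stop("unknown language tag(s): ",
         paste(setdiff(unique(language_tags), known), collapse = ", "),
         call. = FALSE)

  cell <- function(sel) {
    tp <- sum(p[sel] == 1 & y[sel] == 1)
    fp <- sum(p[sel] == 1 & y[sel] == 0)
    tn <- sum(p[sel] == 0 & y[sel] == 0)
    fn <- sum(p[sel] == 0 & y[sel] == 1)
    n <- sum(sel)
    err <- if (n > 0) round(100 * (fp + fn) / n, 2) else NA_real_
    list(TP = tp, FP = fp, TN = tn, FN = fn, n = n, error_rate = err,
         fp_share = if (fp + fn > 0) round(100 * fp / (fp + fn), 2)
                    else NA_real_)
  }
  per_lang <- lapply(sort(unique(language_tags)),
                     function(l) cell(language_tags == l))
  names(per_lang) <- sort(unique(language_tags))
  list(overall = cell(rep(TRUE, length(y))), per_language = per_lang)
}

#' Run the full scenario grid
#'
#' Eight scenarios, each under every requested model: `{en, fr, multi}` x
#' `{all language features, generalizable features}`, an English baseline
#' over all subgroups (task-specific included), and a multilingual
#' age-only baseline.  "Language features" means the semantic, syntactic
#' and paralinguistic subgroups.  Multilingual runs concatenate the two
#' cohorts; the language tag is used only for the error decomposition,
#' never as a model input.
#'
#' @param features subjects x features data frame.
#' @param labels binary labels (AD positive).
#' @param languages `"en"`/`"fr"` per subject.
#' @param registry feature registry (`feature`, `subgroup`).
#' @param selection result of [select_generalizable()].
#' @param ages numeric vector of ages (for the age-only baseline); `NA`s
#'   allowed.
#' @param models model kinds to run.
#' @param seed integer seed.
#' @return list of `experiment_result` entries: `scenario_id`, `model`,
#'   `auc`, `confusion` (from [confusion_summary()]), `n_features`, or a
#'   `skipped` marker when a feature set is empty.
#' @export
run_scenarios <- function(features, labels, languages, registry, selection,
                          ages = NULL, models = c("LR", "SVM", "MLP"),
                          seed = 1) {
  features <- as.data.frame(features)
  y <- as01(labels)
  lang_feats <- registry$feature[registry$subgroup %in%
                                 c("semantic", "syntactic", "paralinguistic")]
  lang_feats <- intersect(lang_feats, names(features))
  gen_feats <- intersect(selection$selected, names(features))
  all_feats <- intersect(registry$feature, names(features))

  scen <- list(
    en_all_language    = list(rows = languages == "en", cols = lang_feats),
    fr_all_language    = list(rows = languages == "fr", cols = lang_feats),
    multi_all_language = list(rows = rep(TRUE, length(y)), cols = lang_feats),
    en_generalizable    = list(rows = languages == "en", cols = gen_feats),
    fr_generalizable    = list(rows = languages == "fr", cols = gen_feats),
    multi_generalizable = list(rows = rep(TRUE, length(y)), cols = gen_feats),
    en_baseline_all_subgroups = list(rows = languages == "en",
                                     cols = all_feats),
    multi_age_only = list(rows = rep(TRUE, length(y)), cols = "age"))

  results <- list()
  for (sid in names(scen)) {
    sc <- scen[[sid]]
    xx <- if (identical(sc$cols, "age")) {
      if (is.null(ages) || all(is.na(ages))) NULL
      else data.frame(age = ages[sc$rows])
    } else if (length(sc$cols) == 0) NULL
      else features[sc$rows, sc$cols, drop = FALSE]
    for (mk in models) {
      if (is.null(xx)) {
        results[[paste(sid, mk, sep = ".")]] <-
          list(scenario_id = sid, model = mk, skipped = TRUE,
               reason = "empty feature set")
        next
      }
      sp <- model_spec(mk)
      cv <- suppressWarnings(
        loocv_scores(xx, y[sc$rows], sp, seed = seed))
      cm <- confusion_summary(cv$pred, cv$label,
                              language_tags = languages[sc$rows])
      results[[paste(sid, mk, sep = ".")]] <- structure(
        list(scenario_id = sid, model = mk,
             auc = auc(cv$score, cv$label),
             confusion = cm,
             error_rate = cm$overall$error_rate,
             n = nrow(xx), n_features = ncol(xx), skipped = FALSE),
        class = "experiment_result")
    }
  }
  results
}
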