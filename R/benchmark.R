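# Random Forest / linear-SVM benchmark harness.  The classifiers exist only
# as comparators for the distance-based diagnostics: default hyperparameters,
# no tuning, no probability calibration.

#' Classification statistics for a set of predictions
#'
#' Confusion counts plus the four summary statistics used throughout:
#' sensitivity SE (recall of the designated sensitivity class, by default the
#' first factor level), specificity SP (recall of the other class), overall
#' accuracy ACC, and the correct classification rate CCR = (SE + SP) / 2
#' (balanced accuracy; for exactly balanced classes ACC = CCR).
#'
#' A prediction of `NA` counts as incorrect.  When the truth contains only
#' one class, the recall of the absent class is undefined: it is reported as
#' `NA` and `incomplete` is set.
#'
#' @param truth factor of true labels (binary).
#' @param predicted factor/vector of predicted labels, same length.
#' @param sensitivity_class the class whose recall is SE; default
#'   `levels(truth)[1]`.
#' @return an object of class `classification_stats`: list with `confusion`
#'   (per-class correct/incorrect counts), `se`, `sp`, `acc`, `ccr`,
#'   `sensitivity_class`, `incomplete`.
#' @export
classification_stats <- function(truth, predicted,
                                 sensitivity_class = NULL) {
  # keep declared levels: a single-class test set must still report the
  # absent class (with NA recall), not silently drop it
  if (!is.factor(truth)) truth <- factor(truth)
  if (length(predicted) != length(truth))
    stop("'truth' and 'predicted' must have the same length", call. = FALSE)
  lv <- levels(truth)
  if (nlevels(truth) > 2)
    stop("classification_stats() supports binary labels", call. = FALSE)
  if (is.null(sensitivity_class)) sensitivity_class <- lv[1]
  sensitivity_class <- as.character(sensitivity_class)
  correct <- !is.na(predicted) & as.character(predicted) == as.character(truth)
  confusion <- data.frame(
    class = lv,
    n = as.integer(table(truth)[lv]),
    correct = vapply(lv, function(cl)
      sum(correct[truth == cl]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  confusion$incorrect <- confusion$n - confusion$correct
  recall <- ifelse(confusion$n > 0, confusion$correct / confusion$n, NA_real_)
  names(recall) <- lv
  se <- unname(recall[sensitivity_class])
  sp <- if (length(lv) == 2)
    unname(recall[setdiff(lv, sensitivity_class)]) else NA_real_
  structure(list(confusion = confusion, se = se, sp = sp,
                 acc = mean(correct),
                 ccr = mean(c(se, sp)),
                 sensitivity_class = sensitivity_class,
                 incomplete = anyNA(c(se, sp))),
            class = "classification_stats")
}

#' @export
print.classification_stats <- function(x, ...) {
  cat(sprintf("SE %.4f  SP %.4f  ACC %.4f  CCR %.4f%s\n",
              x$se, x$sp, x$acc, x$ccr,
              if (x$incomplete) "  [incomplete: single-class truth]" else ""))
  invisible(x)
}

# Fit one classifier on (X, y) and predict rows of Xnew.  Data are already
# range-scaled, so the SVM's internal rescaling is disabled (it would warn on
# fold-constant columns and add nothing).
fit_predict <- function(algorithm, X, y, Xnew) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2)
    stop("degenerate single-class training fold", call. = FALSE)
  if (algorithm == "rf") {
    fit <- randomForest::randomForest(x = X, y = y)
    stats::predict(fit, Xnew)
  } else if (algorithm == "svm") {
    fit <- e1071::svm(x = X, y = y, kernel = "linear", scale = FALSE)
    stats::predict(fit, Xnew)
  } else stop("unknown algorithm '", algorithm, "'", call. = FALSE)
}

make_model_run <- function(algorithm, protocol, ds, predicted, seed,
                           repeat_index = NA_integer_) {
  stats <- classification_stats(ds$labels, predicted)
  structure(list(algorithm = algorithm, protocol = protocol, seed = seed,
                 repeat_index = repeat_index,
                 ids = ds$ids, truth = as.character(ds$labels),
                 predicted = as.character(predicted),
                 outliers = ds$ids[is.na(predicted) |
                                     as.character(predicted) !=
                                     as.character(ds$labels)],
                 stats = stats),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("%s / %s (seed %s): %d molecules, %d outlier(s)\n",
              toupper(x$algorithm), x$protocol, x$seed, length(x$ids),
              length(x$outliers)))
  print(x$stats)
  invisible(x)
}

#' Leave-one-out evaluation of a benchmark classifier
#'
#' Predicts every molecule with a model trained on all the others, using the
#' implementation defaults of [randomForest::randomForest()] or a
#' linear-kernel [e1071::svm()].  Molecules whose prediction differs from
#' their label form the outlier set compared against the rivality cliffs.
#'
#' @param algorithm `"rf"` or `"svm"`.
#' @param ds a scaled `descriptor_dataset`.
#' @param seed RNG seed (the forest is stochastic); fixed seeds reproduce
#'   predictions bit-identically.
#' @return an object of class `model_run`: per-molecule predictions, outlier
#'   ids and [classification_stats()].
#' @export
evaluate_loo <- function(algorithm = c("rf", "svm"), ds, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (!ds$scaled) stop("'ds' must be scaled", call. = FALSE)
  X <- ds$features
  n <- nrow(X)
  predicted <- factor(rep(NA_character_, n), levels = levels(ds$labels))
  with_seed(seed, {
    for (i in seq_len(n))
      predicted[i] <- fit_predict(algorithm, X[-i, , drop = FALSE],
                                  ds$labels[-i], X[i, , drop = FALSE])
  })
  make_model_run(algorithm, "LOO", ds, predicted, seed)
}

#' Repeated stratified k-fold cross-validation of a benchmark classifier
#'
#' Each repeat assigns molecules to `folds` stratified folds at random, then
#' predicts every fold from a model trained on the remaining ones.  Repeats
#' differ only in the fold assignment; comparing their outlier sets shows
#' which misclassifications are stable and which depend on the partition.
#'
#' @inheritParams evaluate_loo
#' @param folds number of folds, default 5.
#' @param repeats number of repeated partitions, default 5.
#' @return list of `model_run`, one per repeat.
#' @export
evaluate_cv <- function(algorithm = c("rf", "svm"), ds, folds = 5,
                        repeats = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (!ds$scaled) stop("'ds' must be scaled", call. = FALSE)
  X <- ds$features
  n <- nrow(X)
  runs <- vector("list", repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- integer(n)
      for (cl in levels(ds$labels)) {
        idx <- which(ds$labels == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      predicted <- factor(rep(NA_character_, n), levels = levels(ds$labels))
      for (f in seq_len(folds)) {
        test <- fold == f
        if (!any(test)) next
        predicted[test] <- fit_predict(algorithm, X[!test, , drop = FALSE],
                                       ds$labels[!test],
                                       X[test, , drop = FALSE])
      }
      runs[[r]] <- make_model_run(algorithm, sprintf("CV%d", folds), ds,
                                  predicted, seed, repeat_index = r)
    }
  })
  runs
}

#' External validation of a benchmark classifier
#'
#' Fits once on the training set and predicts the test set.  A single-class
#' test set leaves SE or SP undefined; the statistics are then flagged
#' `incomplete` rather than silently dropped.
#'
#' @param algorithm `"rf"` or `"svm"`.
#' @param train,test scaled `descriptor_dataset`s with matching columns and
#'   disjoint ids.
#' @param seed RNG seed for the forest.
#' @return a `model_run` over the test molecules.
#' @export
evaluate_external <- function(algorithm = c("rf", "svm"), train, test,
                              seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(train, "descriptor_dataset"),
            inherits(test, "descriptor_dataset"))
  if (length(intersect(train$ids, test$ids)))
    stop("train and test ids overlap", call. = FALSE)
  missing <- setdiff(colnames(train$features), colnames(test$features))
  if (length(missing))
    stop("test set missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  Xnew <- test$features[, colnames(train$features), drop = FALSE]
  predicted <- NULL
  with_seed(seed, {
    predicted <- fit_predict(algorithm, train$features, train$labels, Xnew)
  })
  # score against the training label universe so a single-class test works
  test_univ <- test
  test_univ$labels <- factor(as.character(test$labels),
                             levels = levels(train$labels))
  make_model_run(algorithm, "external", test_univ, predicted, seed)
}

#' Agreement between classifier outliers and rivality cliffs
#'
#' Cross-tabulates the misclassified molecules of a benchmark run against
#' the activity cliffs of a rivality profile at one TN, reporting the Jaccard
#' agreement and the discordant molecules annotated with their border status
#' (discordance is expected precisely on activity borders, where the
#' classification outcome is unstable).
#'
#' @param run a `model_run`.
#' @param rivality a `rivality_result` over the same molecules.
#' @param tn which TN column of `rivality` to use; default its first.
#' @return list with `jaccard`, `both`, `only_model`, `only_rivality`
#'   (id vectors) and `discordant` (data frame with `id`, `source`,
#'   `is_border`).
#' @export
compare_outliers <- function(run, rivality, tn = NULL) {
  stopifnot(inherits(run, "model_run"), inherits(rivality, "rivality_result"))
  if (!setequal(run$ids, rivality$ids))
    stop("model run and rivality profile cover different molecules",
         call. = FALSE)
  if (is.null(tn)) tn <- rivality$tn[1]
  col <- paste0("TN", tn)
  if (!col %in% colnames(rivality$ri))
    stop("TN ", tn, " not present in the rivality profile", call. = FALSE)
  cliffs <- rivality$cliffs[[col]]
  borders <- rivality$borders[[col]]
  both <- intersect(run$outliers, cliffs)
  only_model <- setdiff(run$outliers, cliffs)
  only_rivality <- setdiff(cliffs, run$outliers)
  uni <- union(run$outliers, cliffs)
  jaccard <- if (length(uni)) length(both) / length(uni) else 1
  discordant <- data.frame(
    id = c(only_model, only_rivality),
    source = c(rep("model_only", length(only_model)),
               rep("rivality_only", length(only_rivality))),
    stringsAsFactors = FALSE)
  discordant$is_border <- discordant$id %in% borders
  list(jaccard = jaccard, both = both, only_model = only_model,
       only_rivality = only_rivality, discordant = discordant)
}

#' Write a model run to disk
#'
#' @param run a `model_run`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_model_run <- function(run, dir) {
  stopifnot(inherits(run, "model_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(id = run$ids, truth = run$truth, predicted = run$predicted,
               outlier = run$ids %in% run$outliers, stringsAsFactors = FALSE),
    file.path(dir, sprintf("%s_%s_predictions.csv", run$algorithm,
                           tolower(run$protocol))),
    row.names = FALSE)
  jsonlite::write_json(
    list(algorithm = run$algorithm, protocol = run$protocol, seed = run$seed,
         se = run$stats$se, sp = run$stats$sp, acc = run$stats$acc,
         ccr = run$stats$ccr, n_outliers = length(run$outliers)),
    file.path(dir, sprintf("%s_%s_stats.json", run$algorithm,
                           tolower(run$protocol))),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
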