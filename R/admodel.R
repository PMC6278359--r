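# Applicability-domain assessment of external molecules and cliff-erasure
# curation of training sets.

#' Rivality index of an external molecule against a training context
#'
#' Computes the rivality index of a single test molecule using only its
#' distances to the molecules of a training set: the test molecule is added
#' to the training context on its own (test molecules never see each other),
#' its nearest same-class and different-class training neighbors give `d_x`
#' and `d_y`, and the neighborhood prefix rule is applied over the training
#' rank list exactly as in the in-set computation.  Because the external
#' distances are evaluated with the same arithmetic as the in-set distance
#' matrix, the external rivality of a held-out training molecule reproduces
#' its in-set value exactly.
#'
#' The molecule's true class label is required: `d_x`/`d_y` are defined
#' relative to it.  The assessment is therefore label-aware, matching the
#' external-validation setting where test labels are known.
#'
#' @param train a scaled `descriptor_dataset` (the training context).
#' @param x named numeric vector of scaled descriptor values over the
#'   training columns.
#' @param label class label of the test molecule; must be one of the training
#'   classes.
#' @param tn threshold of neighbors; `0` for the plain index, `>= 1` for the
#'   neighborhood-weighted index.
#' @return list with `ri`, `sentinel`, `d_x`, `d_y`, `same_id`, `diff_id`
#'   (nearest training neighbors of each kind) and, for `tn >= 1`, `profile`
#'   (cn / cn_x / cn_y / weights over the training rank list).
#' @export
external_rivality <- function(train, x, label, tn = 1) {
  stopifnot(inherits(train, "descriptor_dataset"))
  if (!train$scaled)
    stop("'train' must be a scaled dataset", call. = FALSE)
  X <- train$features
  if (is.null(names(x))) {
    if (length(x) != ncol(X))
      stop("test vector length does not match training columns", call. = FALSE)
    names(x) <- colnames(X)
  }
  missing <- setdiff(colnames(X), names(x))
  if (length(missing))
    stop("test vector missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- x[colnames(X)]
  if (any(!is.finite(x)))
    stop("test vector contains non-finite values", call. = FALSE)
  label <- as.character(label)
  if (!label %in% levels(train$labels))
    stop("unknown class label '", label, "'", call. = FALSE)
  tn <- as.integer(tn)
  if (tn < 0L) stop("'tn' must be >= 0", call. = FALSE)

  d <- unname(euclidean_to_point(X, x))
  ord <- order(d)                      # ties broken by training row index
  same <- as.character(train$labels)[ord] == label
  n_same <- sum(same); n_diff <- length(ord) - n_same
  if (n_same < max(1L, tn) || n_diff < max(1L, tn))
    stop("TN = ", tn, " infeasible: training set has ", n_same,
         " molecules of class '", label, "' and ", n_diff, " of other classes",
         call. = FALSE)
  p_same <- which(same)[1]
  p_diff <- which(!same)[1]
  d_x <- d[ord[p_same]]
  d_y <- d[ord[p_diff]]
  detail <- list(d_x = d_x, d_y = d_y,
                 same_id = train$ids[ord[p_same]],
                 diff_id = train$ids[ord[p_diff]])

  if (tn == 0L) {
    v <- rivality_plain(d_x, d_y)
    return(c(list(ri = as.numeric(v), sentinel = attr(v, "sentinel")[1]),
             detail))
  }
  cum_same <- cumsum(same)
  cum_diff <- seq_along(ord) - cum_same
  cn <- which(cum_same >= tn & cum_diff >= tn)[1]
  cn_x <- cum_same[cn]; cn_y <- cn - cn_x
  w_x <- (cn - cn_x) / cn; w_y <- (cn - cn_y) / cn
  a <- d_x * w_x; b <- d_y * w_y
  if (a == 0 && b == 0) {
    ri <- RI_SENTINEL; sentinel <- TRUE
  } else if (a == b) {
    ri <- 0; sentinel <- FALSE
  } else {
    ri <- (a - b) / (a + b); sentinel <- FALSE
  }
  c(list(ri = ri, sentinel = sentinel), detail,
    list(profile = list(tn = tn, cn = cn, cn_x = cn_x, cn_y = cn_y,
                        w_x = w_x, w_y = w_y)))
}

#' Applicability-domain assessment of an external set
#'
#' Runs [external_rivality()] for every molecule of a test set against a
#' training context, one molecule at a time, and assembles the
#' applicability-domain report.  The verdict per molecule is a pure function
#' of its rivality index at the first requested TN: `outside` when `RI > 0`,
#' `border` when `|RI| <=` border threshold (sentinels excluded), `inside`
#' otherwise.  A molecule can satisfy both rules (small positive RI); it is
#' then reported as `border`, consistent with the border set overlapping the
#' cliff set.
#'
#' The RI-based prediction — `RI <= 0` means "will be classified correctly" —
#' is scored against that promise to give aggregate [classification_stats()]
#' and the CMODI of the test set.
#'
#' @param train a scaled `descriptor_dataset`; its `scale_params` are used to
#'   project the test molecules unless `scaling = "none"`.
#' @param test a `descriptor_dataset` of external molecules.  With
#'   `scaling = "train"` (default) it must be unscaled and is projected with
#'   the training parameters; with `"none"` it must already be scaled into
#'   the same coordinates as `train`.
#' @param tn integer vector of thresholds; the first element drives the
#'   verdicts.
#' @param border_threshold positive scalar; default is the pairwise-distance
#'   standard deviation of the training set.
#' @param scaling `"train"` or `"none"` (see above).
#' @return an object of class `ad_report`: list with `table` (one row per
#'   test molecule: ri per TN, verdict, nearest neighbors, out-of-range
#'   flag), `stats` (a `classification_stats`), `cmodi`, `per_class`,
#'   `border_threshold`, `tn`.
#' @export
ad_assess <- function(train, test, tn = 1, border_threshold = NULL,
                      scaling = c("train", "none")) {
  stopifnot(inherits(train, "descriptor_dataset"),
            inherits(test, "descriptor_dataset"))
  scaling <- match.arg(scaling)
  if (!train$scaled) stop("'train' must be scaled", call. = FALSE)
  if (n_molecules(test) < 1) stop("empty test set", call. = FALSE)
  if (scaling == "train") {
    if (test$scaled)
      stop("scaling = 'train' expects an unscaled test set", call. = FALSE)
    test <- apply_scale(test, train$scale_params)
  } else if (!test$scaled) {
    stop("scaling = 'none' expects an already-scaled test set", call. = FALSE)
  }
  missing <- setdiff(colnames(train$features), colnames(test$features))
  if (length(missing))
    stop("test set missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tn <- as.integer(tn)
  if (is.null(border_threshold)) {
    tm <- build_distance_model(train)
    border_threshold <- pairwise_distance_sd(tm)
  }
  if (border_threshold <= 0)
    stop("'border_threshold' must be positive", call. = FALSE)

  n <- n_molecules(test)
  ri <- matrix(NA_real_, n, length(tn),
               dimnames = list(test$ids, paste0("TN", tn)))
  sentinel <- matrix(FALSE, n, length(tn))
  d_x <- d_y <- numeric(n)
  same_id <- diff_id <- character(n)
  for (i in seq_len(n)) {
    for (k in seq_along(tn)) {
      r <- external_rivality(train, test$features[i, ],
                             as.character(test$labels[i]), tn[k])
      ri[i, k] <- r$ri
      sentinel[i, k] <- r$sentinel
      if (k == 1L) {
        d_x[i] <- r$d_x; d_y[i] <- r$d_y
        same_id[i] <- r$same_id; diff_id[i] <- r$diff_id
      }
    }
  }
  ri1 <- ri[, 1]
  verdict <- ifelse(abs(ri1) <= border_threshold & !sentinel[, 1], "border",
                    ifelse(ri1 > 0, "outside", "inside"))
  tab <- data.frame(id = test$ids, class = as.character(test$labels),
                    ri, verdict = verdict,
                    d_x = d_x, d_y = d_y,
                    nearest_same = same_id, nearest_diff = diff_id,
                    out_of_range = test$out_of_range,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  m <- cmodi(ri1, test$labels)
  # RI <= 0 predicts "classified correctly": predicted label = true label
  # when RI <= 0, the other class's label otherwise (binary path).
  truth <- test$labels
  predicted <- as.character(truth)
  if (nlevels(train$labels) == 2) {
    lv <- levels(train$labels)
    flip <- ri1 > 0
    predicted[flip] <- ifelse(as.character(truth)[flip] == lv[1],
                              lv[2], lv[1])
  } else {
    predicted[ri1 > 0] <- NA
  }
  stats <- classification_stats(truth, factor(predicted,
                                              levels = levels(train$labels)))
  structure(list(table = tab, stats = stats, cmodi = m$cmodi,
                 per_class = m$per_class,
                 border_threshold = border_threshold, tn = tn),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat("Applicability-domain report:", nrow(x$table), "test molecules\n")
  cat("Verdicts:", paste(sprintf("%s %d", names(table(x$table$verdict)),
                                 as.integer(table(x$table$verdict))),
                         collapse = ", "), "\n")
  cat(sprintf("Test CMODI %.4f (border threshold %.4g, verdict TN %d)\n",
              x$cmodi, x$border_threshold, x$tn[1]))
  invisible(x)
}

#' Write an applicability-domain report to disk
#'
#' @param report an `ad_report`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_ad_report <- function(report, dir) {
  stopifnot(inherits(report, "ad_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(dir, "ad_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cmodi = report$cmodi, per_class = as.list(report$per_class),
         border_threshold = report$border_threshold, tn = report$tn,
         stats = unclass(report$stats)),
    file.path(dir, "ad_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Remove activity cliffs from a dataset
#'
#' Cliff-erasure curation: computes the rivality index of every molecule at
#' the stated TN (plain index for `tn = 0`) and removes exactly the molecules
#' with `RI > 0`.  The curated dataset keeps its scaled coordinates and
#' scaling parameters; the distance model must be rebuilt by the caller,
#' since the rivality of the survivors changes once their rivals are gone.
#'
#' @param ds a scaled `descriptor_dataset`.
#' @param model the `distance_model` built from `ds`.
#' @param tn threshold of neighbors used for the erasure decision.
#' @return list with `dataset` (curated), `removed` (ids) and `ri` (the
#'   per-molecule values the decision was based on).
#' @export
erase_cliffs <- function(ds, model, tn = 1) {
  stopifnot(inherits(ds, "descriptor_dataset"),
            inherits(model, "distance_model"))
  if (model$n != n_molecules(ds))
    stop("'model' does not match 'ds'", call. = FALSE)
  res <- rivality_profile(model, ds$labels, tn = tn,
                          border_threshold = pairwise_distance_sd(model))
  ri <- res$ri[, 1]
  removed <- ds$ids[ri > 0]
  if (!length(removed))
    return(list(dataset = ds, removed = character(0), ri = ri))
  keep <- setdiff(ds$ids, removed)
  sizes <- table(droplevels(ds$labels[ds$ids %in% keep]))
  if (length(sizes) < nlevels(ds$labels) || any(sizes < 2))
    stop("erasing cliffs would leave a class with < 2 members", call. = FALSE)
  list(dataset = subset_molecules(ds, keep), removed = removed, ri = ri)
}

#' Stratified random train/test split
#'
#' Partitions a dataset into training and test ids, stratified by class so
#' both classes are represented on both sides.  Within each class,
#' `round(fraction * n_class)` molecules go to training (so 62 + 62 at 0.8
#' gives a 100-molecule training set).  Reproducible: the same seed always
#' yields the same partition, and the caller's RNG state is left untouched.
#'
#' @param ds a `descriptor_dataset`.
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` character id vectors.
#' @export
split_dataset <- function(ds, fraction = 0.8, seed = 1) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  train <- character(0)
  with_seed(seed, {
    for (cl in levels(ds$labels)) {
      ids_cl <- ds$ids[ds$labels == cl]
      n_tr <- round(fraction * length(ids_cl))
      if (n_tr < 1 || n_tr > length(ids_cl) - 1)
        stop("fraction ", fraction, " leaves class '", cl,
             "' unrepresented on one side of the partition", call. = FALSE)
      train <- c(train, sample(ids_cl, n_tr))
    }
  })
  train <- ds$ids[ds$ids %in% train]   # restore original order
  list(train = train, test = setdiff(ds$ids, train))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}
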