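# Rivality index, weighted rivality index, modelability (CMODI),
# activity-cliff and activity-border detection.

RI_SENTINEL <- -1e-6

#' Plain rivality index from a pair of nearest-neighbor distances
#'
#' The rivality index of a molecule contrasts the distance `d_x` to its
#' nearest neighbor of the same class against the distance `d_y` to its
#' nearest neighbor of any different class:
#' `RI = (d_x - d_y) / (d_x + d_y)`, a value in \[-1, +1\].  Negative values
#' mean the nearest neighbor overall is same-class (the molecule should be
#' correctly classified by a similarity-based model); positive values mark
#' likely activity cliffs.
#'
#' Two special cases: `d_x == d_y != 0` yields exactly 0 (the molecule sits
#' at the same distance from both classes); `d_x == d_y == 0` is a 0/0
#' indetermination (at least three coincident molecules) and is assigned the
#' sentinel value `-1e-6`, flagged via the `"sentinel"` attribute so it can
#' be told apart from a genuine 0.
#'
#' @param d_x,d_y non-negative finite distances (vectorized).
#' @return numeric vector of rivality indexes with a logical `"sentinel"`
#'   attribute marking the 0/0 cases.
#' @export
rivality_plain <- function(d_x, d_y) {
  if (length(d_x) != length(d_y))
    stop("'d_x' and 'd_y' must have the same length", call. = FALSE)
  if (any(!is.finite(d_x)) || any(!is.finite(d_y)) ||
      any(d_x < 0) || any(d_y < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  ri <- (d_x - d_y) / (d_x + d_y)
  sentinel <- d_x == 0 & d_y == 0
  ri[d_x == d_y] <- 0        # exact tie, defined as 0
  ri[sentinel] <- RI_SENTINEL
  attr(ri, "sentinel") <- sentinel
  ri
}

#' Neighborhood profile of a molecule for a threshold of neighbors
#'
#' For a threshold of neighbors `TN`, the neighborhood of molecule `i` is the
#' shortest prefix of its ascending-distance rank list that contains at least
#' `TN` same-class and at least `TN` different-class molecules.  Its length
#' is the neighborhood cardinality `CN`; `CN_x` and `CN_y` are the same- and
#' different-class counts inside it (`CN_x + CN_y = CN`).  The weights
#'
#' `w_x = (CN - CN_x) / CN`,  `w_y = (CN - CN_y) / CN`
#'
#' down-weight the distance to the class that dominates the neighborhood;
#' they are strictly positive and always sum to 1.
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels.
#' @param i molecule row index or id.
#' @param tn threshold of neighbors (integer >= 1).
#' @return an object of class `neighborhood_profile`: list with `id`, `tn`,
#'   `cn`, `cn_x`, `cn_y`, `w_x`, `w_y`.
#' @export
neighborhood_profile <- function(model, labels, i, tn) {
  i <- check_molecule(model, labels, i)
  tn <- as.integer(tn)
  if (tn < 1L) stop("'tn' must be >= 1", call. = FALSE)
  rl <- model$ranks[i, ]
  same <- labels[rl] == labels[i]
  n_same <- sum(same); n_diff <- length(rl) - n_same
  if (n_same < tn || n_diff < tn)
    stop("TN = ", tn, " infeasible for molecule ", model$ids[i],
         " (class '", labels[i], "': ", n_same, " same-class and ", n_diff,
         " different-class neighbors available)", call. = FALSE)
  cum_same <- cumsum(same)
  cum_diff <- seq_along(rl) - cum_same
  cn <- which(cum_same >= tn & cum_diff >= tn)[1]
  cn_x <- cum_same[cn]
  cn_y <- cn - cn_x
  structure(list(id = model$ids[i], tn = tn, cn = cn,
                 cn_x = cn_x, cn_y = cn_y,
                 w_x = (cn - cn_x) / cn, w_y = (cn - cn_y) / cn),
            class = "neighborhood_profile")
}

#' Weighted rivality index of a molecule
#'
#' The plain rivality index looks only at the two first nearest neighbors.
#' The weighted variant corrects the two distances by the class composition
#' of the molecule's neighborhood (see [neighborhood_profile()]):
#'
#' `RI = (d_x w_x - d_y w_y) / (d_x w_x + d_y w_y)`
#'
#' so a nearest same-class neighbor surrounded by rivals of the other class
#' counts for less.  The special cases mirror the plain index: an exact tie
#' of the weighted products gives 0, and the both-zero indetermination gives
#' the `-1e-6` sentinel.
#'
#' @inheritParams neighborhood_profile
#' @return scalar rivality index with attributes `"sentinel"` (logical) and
#'   `"profile"` (the `neighborhood_profile` used).
#' @export
rivality_weighted <- function(model, labels, i, tn) {
  prof <- neighborhood_profile(model, labels, i, tn)
  d_x <- first_neighbor(model, labels, i, same_class = TRUE)$distance
  d_y <- first_neighbor(model, labels, i, same_class = FALSE)$distance
  a <- d_x * prof$w_x
  b <- d_y * prof$w_y
  if (a == 0 && b == 0) {
    ri <- RI_SENTINEL; sentinel <- TRUE
  } else if (a == b) {
    ri <- 0; sentinel <- FALSE
  } else {
    ri <- (a - b) / (a + b); sentinel <- FALSE
  }
  attr(ri, "sentinel") <- sentinel
  attr(ri, "profile") <- prof
  ri
}

#' Rivality profile of a dataset over a set of TN values
#'
#' Computes the rivality index of every molecule at every requested
#' threshold of neighbors.  `TN = 0` denotes the plain (unweighted) index;
#' `TN >= 1` the neighborhood-weighted index.  From the per-molecule values
#' the profile derives, per TN: the activity-cliff set (`RI > 0`), the
#' activity-border set (`|RI| <=` border threshold, sentinels excluded), the
#' per-class modelability and the dataset modelability index CMODI.
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels (factor or vector).
#' @param tn integer vector of thresholds, default `0:5`.
#' @param border_threshold positive scalar; default is the standard deviation
#'   of all pairwise scaled distances ([pairwise_distance_sd()]).
#' @return an object of class `rivality_result`: list with `ids`, `labels`,
#'   `tn`, `ri` (molecules x TN matrix), `sentinel` (logical matrix),
#'   `border_threshold`, `cliffs` / `borders` (named lists of id vectors per
#'   TN), `modelability` (classes x TN matrix) and `cmodi` (named vector).
#' @export
rivality_profile <- function(model, labels, tn = 0:5,
                             border_threshold = NULL) {
  stopifnot(inherits(model, "distance_model"))
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (length(labels) != model$n)
    stop("'labels' length does not match the distance model", call. = FALSE)
  tn <- sort(unique(as.integer(tn)))
  if (any(tn < 0L)) stop("'tn' values must be >= 0", call. = FALSE)
  if (is.null(border_threshold)) border_threshold <- pairwise_distance_sd(model)
  if (border_threshold <= 0)
    stop("'border_threshold' must be positive", call. = FALSE)
  n <- model$n
  cols <- paste0("TN", tn)
  ri <- matrix(NA_real_, n, length(tn), dimnames = list(model$ids, cols))
  sentinel <- matrix(FALSE, n, length(tn), dimnames = list(model$ids, cols))
  d_x <- d_y <- numeric(n)
  for (i in seq_len(n)) {
    d_x[i] <- first_neighbor(model, labels, i, TRUE)$distance
    d_y[i] <- first_neighbor(model, labels, i, FALSE)$distance
  }
  for (k in seq_along(tn)) {
    if (tn[k] == 0L) {
      v <- rivality_plain(d_x, d_y)
      ri[, k] <- as.numeric(v)
      sentinel[, k] <- attr(v, "sentinel")
    } else {
      for (i in seq_len(n)) {
        v <- rivality_weighted(model, labels, i, tn[k])
        ri[i, k] <- as.numeric(v)
        sentinel[i, k] <- attr(v, "sentinel")
      }
    }
  }
  cliffs <- borders <- stats::setNames(vector("list", length(tn)), cols)
  modelability <- matrix(NA_real_, nlevels(labels), length(tn),
                         dimnames = list(levels(labels), cols))
  cmodi_tn <- stats::setNames(numeric(length(tn)), cols)
  for (k in seq_along(tn)) {
    cliffs[[k]] <- detect_cliffs(ri[, k], ids = model$ids)
    borders[[k]] <- detect_borders(ri[, k], border_threshold,
                                   ids = model$ids, sentinel = sentinel[, k])
    m <- cmodi(ri[, k], labels)
    modelability[, k] <- m$per_class
    cmodi_tn[k] <- m$cmodi
  }
  structure(list(ids = model$ids, labels = labels, tn = tn, ri = ri,
                 sentinel = sentinel, border_threshold = border_threshold,
                 cliffs = cliffs, borders = borders,
                 modelability = modelability, cmodi = cmodi_tn),
            class = "rivality_result")
}

#' @export
print.rivality_result <- function(x, ...) {
  cat("Rivality profile:", length(x$ids), "molecules, TN =",
      paste(x$tn, collapse = ", "), "(TN0 = plain index)\n")
  cat("CMODI:", paste(sprintf("%s %.4f", names(x$cmodi), x$cmodi),
                      collapse = ", "), "\n")
  cat("Cliffs per TN:", paste(vapply(x$cliffs, length, 1L), collapse = ", "),
      "| borders per TN:", paste(vapply(x$borders, length, 1L),
                                 collapse = ", "),
      sprintf("(threshold %.4g)", x$border_threshold), "\n")
  invisible(x)
}

#' @export
as.data.frame.rivality_result <- function(x, ...) {
  data.frame(id = x$ids, class = as.character(x$labels),
             x$ri, check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Plot rivality index trajectories across TN values
#'
#' One line per molecule, rivality index against the threshold of neighbors;
#' molecules that remain near -1 are reliably classifiable, lines staying
#' above zero are persistent activity cliffs.
#'
#' @param x a `rivality_result` with at least two TN values.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rivality_result <- function(x, ...) {
  graphics::matplot(x$tn, t(x$ri), type = "l", lty = 1,
                    col = grDevices::adjustcolor(
                      ifelse(x$labels == levels(x$labels)[1], "steelblue",
                             "firebrick"), 0.6),
                    xlab = "threshold of neighbors (TN)",
                    ylab = "rivality index", ylim = c(-1, 1), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Dataset modelability index (CMODI)
#'
#' The modelability of a class is the fraction of its molecules whose
#' rivality index is less than or equal to zero (those prognosticated as
#' correctly classifiable; the `-1e-6` sentinel is negative and therefore
#' counts).  CMODI is the unweighted mean of the per-class modelabilities —
#' for binary datasets the class terms estimate sensitivity and specificity,
#' and CMODI estimates the correct classification rate an algorithm can
#' reach.
#'
#' @param ri numeric vector of per-molecule rivality indexes.
#' @param labels per-molecule class labels.
#' @return list with `per_class` (named numeric) and `cmodi` (scalar in
#'   \[0, 1\]).
#' @export
cmodi <- function(ri, labels) {
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (length(ri) != length(labels))
    stop("'ri' and 'labels' must have the same length", call. = FALSE)
  if (anyNA(ri)) stop("missing rivality value", call. = FALSE)
  per_class <- vapply(levels(labels), function(cl)
    mean(ri[labels == cl] <= 0), numeric(1))
  list(per_class = per_class, cmodi = mean(per_class))
}

#' Detect activity cliffs from rivality values
#'
#' Activity cliffs are the molecules with strictly positive rivality index:
#' their nearest (weighted) neighborhood belongs to the other class, so
#' similarity-based models are expected to misclassify them.  A rivality of
#' exactly zero is not a cliff, and sentinel values are negative by
#' construction.
#'
#' @param ri numeric vector of rivality indexes.
#' @param ids molecule identifiers, default `names(ri)`.
#' @return character vector of cliff molecule ids.
#' @export
detect_cliffs <- function(ri, ids = names(ri)) {
  if (is.null(ids)) ids <- as.character(seq_along(ri))
  ids[!is.na(ri) & ri > 0]
}

#' Detect activity borders from rivality values
#'
#' Activity borders are molecules whose rivality index is zero or very close
#' to zero on either side: their classification outcome flips with small
#' changes in training-set composition.  The default threshold (when called
#' through [rivality_profile()]) is the standard deviation of all pairwise
#' scaled distances.  Sentinel molecules (`-1e-6` from the 0/0
#' indetermination) are excluded: their value is an assigned marker, not a
#' measured near-tie.
#'
#' @param ri numeric vector of rivality indexes.
#' @param threshold positive scalar.
#' @param ids molecule identifiers, default `names(ri)`.
#' @param sentinel logical vector flagging sentinel-valued molecules.
#' @return character vector of border molecule ids.
#' @export
detect_borders <- function(ri, threshold, ids = names(ri),
                           sentinel = rep(FALSE, length(ri))) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("'threshold' must be a positive scalar", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(ri))
  ids[!is.na(ri) & abs(ri) <= threshold & !sentinel]
}

#' Write the tabular products of a rivality profile
#'
#' Writes the per-molecule rivality matrix (one column per TN), the cliff and
#' border lists, and a JSON summary (CMODI and per-class modelability per TN,
#' border threshold) into a directory.
#'
#' @param res a `rivality_result`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_rivality_result <- function(res, dir) {
  stopifnot(inherits(res, "rivality_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res), file.path(dir, "rivality.csv"),
                   row.names = FALSE)
  cliff_df <- data.frame(
    tn = rep(names(res$cliffs), vapply(res$cliffs, length, 1L)),
    id = unlist(res$cliffs, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.csv(cliff_df, file.path(dir, "cliffs.csv"), row.names = FALSE)
  border_df <- data.frame(
    tn = rep(names(res$borders), vapply(res$borders, length, 1L)),
    id = unlist(res$borders, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.csv(border_df, file.path(dir, "borders.csv"),
                   row.names = FALSE)
  summary <- list(
    n_molecules = length(res$ids),
    tn = res$tn,
    border_threshold = res$border_threshold,
    cmodi = as.list(res$cmodi),
    modelability = apply(res$modelability, 2, as.list),
    n_cliffs = lapply(res$cliffs, length),
    n_borders = lapply(res$borders, length))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
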