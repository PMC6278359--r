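# Distance model and neighbor-composition analyses.
#
# All neighbor machinery is exact O(n^2): the datasets of interest are at
# most a few thousand molecules and the rivality index depends on exact
# nearest-neighbor ranks, so approximate indexing is deliberately avoided.

# Euclidean distances from every row of X to the point v, with a fixed
# summation order (left-to-right over columns).  Both the in-set distance
# matrix and the external-molecule distances go through this one routine so
# that an external computation of a held-out molecule reproduces its in-set
# distances bit for bit.
euclidean_to_point <- function(X, v) {
  D <- X - matrix(v, nrow(X), length(v), byrow = TRUE)
  sqrt(rowSums(D * D))
}

#' Build the Euclidean distance model of a dataset
#'
#' Computes the symmetric matrix of Euclidean distances between all molecule
#' pairs on the scaled descriptor matrix, sets the diagonal to `Inf` (a
#' molecule is never its own neighbor), and derives for every molecule the
#' full neighbor rank list: all other molecules sorted by ascending distance,
#' ties broken by ascending original row index so results are deterministic
#' across platforms.
#'
#' @param ds a scaled, cleaned `descriptor_dataset` with at least 3 molecules.
#' @return an object of class `distance_model`: list with `n`, `ids`,
#'   `dist` (n x n matrix, `Inf` diagonal) and `ranks` (n x (n-1) integer
#'   matrix; row i holds the rank list of molecule i, 1-based row indices).
#' @export
build_distance_model <- function(ds) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (!ds$scaled)
    stop("build_distance_model() expects a range-scaled dataset", call. = FALSE)
  X <- ds$features
  n <- nrow(X)
  if (n < 3) stop("need at least 3 molecules for a neighborhood", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(ds$ids, ds$ids))
  # column i = distances of all rows to molecule i; (a-b)^2 == (b-a)^2 in
  # IEEE arithmetic and the summation order is fixed, so D is exactly
  # symmetric.
  for (i in seq_len(n)) D[, i] <- euclidean_to_point(X, X[i, ])
  diag(D) <- Inf
  ranks <- matrix(0L, n, n - 1L)
  for (i in seq_len(n)) ranks[i, ] <- order(D[i, ])[seq_len(n - 1L)]
  structure(list(n = n, ids = ds$ids, dist = D, ranks = ranks),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat("Distance model:", x$n, "molecules (Euclidean, Inf diagonal)\n")
  invisible(x)
}

#' Standard deviation of all pairwise distances
#'
#' The default activity-border threshold: the standard deviation of the
#' distances between all molecule pairs of the (scaled) dataset.  Note this
#' compares a distance spread against the dimensionless rivality index; it is
#' the method's stated heuristic, kept literal and overridable everywhere it
#' is used.
#'
#' @param model a `distance_model`.
#' @return a positive scalar.
#' @export
pairwise_distance_sd <- function(model) {
  stopifnot(inherits(model, "distance_model"))
  stats::sd(model$dist[upper.tri(model$dist)])
}

check_molecule <- function(model, labels, i) {
  if (length(labels) != model$n)
    stop("'labels' length does not match the distance model", call. = FALSE)
  if (is.character(i)) {
    j <- match(i, model$ids)
    if (is.na(j)) stop("unknown molecule id: ", i, call. = FALSE)
    return(j)
  }
  i <- as.integer(i)
  if (i < 1L || i > model$n) stop("molecule index out of range", call. = FALSE)
  i
}

#' First same-class or different-class neighbor of a molecule
#'
#' Walks the rank list of molecule `i` and returns its nearest neighbor that
#' belongs to the same class (`same_class = TRUE`, distance `d_ix`) or to any
#' different class (`same_class = FALSE`, distance `d_iy`).
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels (same order as the model).
#' @param i molecule row index or id.
#' @param same_class logical filter.
#' @return list with `distance`, `index`, `id` and `position` (1-based rank).
#' @export
first_neighbor <- function(model, labels, i, same_class = TRUE) {
  i <- check_molecule(model, labels, i)
  rl <- model$ranks[i, ]
  match_class <- (labels[rl] == labels[i]) == same_class
  pos <- which(match_class)[1]
  if (is.na(pos))
    stop("molecule ", model$ids[i], " has no ",
         if (same_class) "same" else "different", "-class neighbor",
         call. = FALSE)
  j <- rl[pos]
  list(distance = model$dist[i, j], index = j, id = model$ids[j],
       position = pos)
}

#' Rank-list position of the n-th same-class neighbor
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels.
#' @param i molecule row index or id.
#' @param n which same-class neighbor (1 = nearest).
#' @return the 1-based position within the rank list of molecule `i`.
#' @export
nth_same_class_ordinal <- function(model, labels, i, n) {
  i <- check_molecule(model, labels, i)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  rl <- model$ranks[i, ]
  same <- which(labels[rl] == labels[i])
  if (length(same) < n)
    stop("molecule ", model$ids[i], " has only ", length(same),
         " same-class neighbors (requested ", n, ")", call. = FALSE)
  same[n]
}

#' Different-class neighbors inside a same-class ordinal window
#'
#' Counts the different-class molecules whose rank position falls strictly
#' between the `(tn_low - 1)`-th and the `tn_high`-th same-class neighbor of
#' molecule `i` (for `tn_low = 1` the window starts at the head of the rank
#' list).  With the default window `(1, 1)` this is the number of
#' different-class molecules closer to `i` than its first same-class
#' neighbor — the direct neighbor-count view of an activity cliff: the count
#' is positive exactly when the plain rivality index of `i` is positive.
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels.
#' @param i molecule row index or id.
#' @param tn_low,tn_high same-class ordinal window, `1 <= tn_low <= tn_high`.
#' @return an object of class `neighbor_composition`: list with `id`,
#'   `window`, `count` and `pairs` (data frame `molecule`, `neighbor`,
#'   `position`, `distance`).
#' @export
diffclass_before_nth <- function(model, labels, i, tn_low = 1, tn_high = 1) {
  i <- check_molecule(model, labels, i)
  tn_low <- as.integer(tn_low); tn_high <- as.integer(tn_high)
  if (tn_low < 1L || tn_high < tn_low)
    stop("require 1 <= tn_low <= tn_high", call. = FALSE)
  lo <- if (tn_low == 1L) 0L else nth_same_class_ordinal(model, labels, i,
                                                         tn_low - 1L)
  hi <- nth_same_class_ordinal(model, labels, i, tn_high)
  rl <- model$ranks[i, ]
  inside <- setdiff(seq_len(model$n - 1L), seq_len(lo))
  inside <- inside[inside < hi]
  offend <- inside[labels[rl[inside]] != labels[i]]
  pairs <- data.frame(molecule = rep(model$ids[i], length(offend)),
                      neighbor = model$ids[rl[offend]],
                      position = offend,
                      distance = model$dist[i, rl[offend]],
                      stringsAsFactors = FALSE)
  structure(list(id = model$ids[i], window = c(tn_low, tn_high),
                 count = length(offend), pairs = pairs),
            class = "neighbor_composition")
}

#' @export
print.neighbor_composition <- function(x, ...) {
  cat("Molecule ", x$id, ": ", x$count,
      " different-class neighbor(s) in same-class window (",
      x$window[1], ", ", x$window[2], ")\n", sep = "")
  invisible(x)
}

#' Table of activity-cliff pairs across a dataset
#'
#' Applies [diffclass_before_nth()] to every molecule and stacks the
#' offending (molecule, different-class neighbor) pairs.  Molecules that
#' appear as the offending neighbor of many others are the ones "responsible"
#' for degraded modelability; removing them is the basis of cliff-erasure
#' curation.
#'
#' @param model a `distance_model`.
#' @param labels per-molecule class labels.
#' @param window integer pair `(tn_low, tn_high)`, default `c(1, 1)`.
#' @return data frame with columns `molecule`, `neighbor`, `position`,
#'   `distance` (zero rows when the dataset has no cliffs).
#' @export
cliff_pair_table <- function(model, labels, window = c(1, 1)) {
  stopifnot(inherits(model, "distance_model"))
  out <- lapply(seq_len(model$n), function(i)
    diffclass_before_nth(model, labels, i, window[1], window[2])$pairs)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
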