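# Independent brute-force oracle: explicit double loops, full sorts and
# direct formula arithmetic, sharing no code with the implementation beyond
# base R.  Everything here is O(n^2) or worse on purpose.

oracle_dist_matrix <- function(X) {
  n <- nrow(X)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

oracle_rank_list <- function(D, i) {
  n <- ncol(D)
  order(D[i, ])[seq_len(n - 1)]   # Inf self-distance sorts last; stable ties
}

oracle_first_dists <- function(D, labels, i) {
  rl <- oracle_rank_list(D, i)
  same <- rl[labels[rl] == labels[i]]
  diff <- rl[labels[rl] != labels[i]]
  list(d_x = D[i, same[1]], d_y = D[i, diff[1]])
}

oracle_plain_ri <- function(D, labels, i) {
  d <- oracle_first_dists(D, labels, i)
  if (d$d_x == 0 && d$d_y == 0) return(-1e-6)
  if (d$d_x == d$d_y) return(0)
  (d$d_x - d$d_y) / (d$d_x + d$d_y)
}

oracle_profile <- function(D, labels, i, tn) {
  rl <- oracle_rank_list(D, i)
  n_same <- n_diff <- 0L
  cn <- 0L
  for (p in seq_along(rl)) {
    if (labels[rl[p]] == labels[i]) n_same <- n_same + 1L
    else n_diff <- n_diff + 1L
    if (n_same >= tn && n_diff >= tn) { cn <- p; break }
  }
  stopifnot(cn > 0L)
  cn_x <- sum(labels[rl[seq_len(cn)]] == labels[i])
  cn_y <- cn - cn_x
  list(cn = cn, cn_x = cn_x, cn_y = cn_y,
       w_x = (cn - cn_x) / cn, w_y = (cn - cn_y) / cn)
}

oracle_weighted_ri <- function(D, labels, i, tn) {
  d <- oracle_first_dists(D, labels, i)
  p <- oracle_profile(D, labels, i, tn)
  a <- d$d_x * p$w_x
  b <- d$d_y * p$w_y
  if (a == 0 && b == 0) return(-1e-6)
  if (a == b) return(0)
  (a - b) / (a + b)
}

oracle_diffclass_count <- function(D, labels, i, tn_low, tn_high) {
  rl <- oracle_rank_list(D, i)
  same_pos <- which(labels[rl] == labels[i])
  lo <- if (tn_low == 1) 0L else same_pos[tn_low - 1]
  hi <- same_pos[tn_high]
  count <- 0L
  for (p in seq_along(rl))
    if (p > lo && p < hi && labels[rl[p]] != labels[i]) count <- count + 1L
  count
}

# LOO 1-nearest-neighbor balanced accuracy, written independently of the
# package's neighbor machinery (stats::dist + which.min).
oracle_loo_1nn_balacc <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  pred <- labels[apply(D, 1, which.min)]
  mean(vapply(unique(labels), function(cl)
    mean(pred[labels == cl] == cl), numeric(1)))
}

# Random scaled dataset with every class guaranteed >= max(2, tn_max + 1)
# members on each side.
random_scaled_dataset <- function(n, dim, seed, min_per_class = 4) {
  set.seed(seed)
  n <- max(n, 2 * min_per_class)
  repeat {
    labels <- sample(c("0", "1"), n, replace = TRUE)
    if (min(table(factor(labels, levels = c("0", "1")))) >= min_per_class)
      break
  }
  X <- matrix(stats::runif(n * dim), n, dim)
  colnames(X) <- paste0("d", seq_len(dim))
  descriptor_dataset(X, labels, scaled = TRUE,
                     scale_params = list(
                       min = stats::setNames(rep(0, dim), colnames(X)),
                       max = stats::setNames(rep(1, dim), colnames(X))))
}

# Tiny 1-D dataset realizing a prescribed rank-list class pattern for the
# first molecule: molecule 1 of class "A" at 0, neighbors at 0.1, 0.2, ...
# with the given classes.
pattern_dataset <- function(pattern) {
  x <- c(0, seq_along(pattern) / 10)
  labels <- c("A", pattern)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "d1"))
  descriptor_dataset(X, labels, scaled = TRUE,
                     scale_params = list(min = c(d1 = 0), max = c(d1 = 1)),
                     check_classes = FALSE)
}
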