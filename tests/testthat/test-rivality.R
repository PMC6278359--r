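test_that("the plain rivality index follows its formula and special cases", {
  expect_equal(as.numeric(rivality_plain(0.1, 0.3)), -0.5)
  expect_identical(as.numeric(rivality_plain(0.2, 0.2)), 0)
  s <- rivality_plain(0, 0)
  expect_identical(as.numeric(s), -1e-6)
  expect_true(attr(s, "sentinel"))
  # a zero same-class distance alone is the best case, not an indetermination
  expect_equal(as.numeric(rivality_plain(0, 0.4)), -1)
  expect_false(attr(rivality_plain(0, 0.4), "sentinel"))
  expect_error(rivality_plain(-0.1, 0.2), "non-negative")
  expect_error(rivality_plain(Inf, 0.2), "finite")
})

test_that("neighborhood profiles apply the shortest-prefix rule", {
  ds <- pattern_dataset(c("B", "B", "A", "A", "B"))
  m <- build_distance_model(ds)
  p <- neighborhood_profile(m, ds$labels, 1, tn = 1)
  expect_equal(p$cn, 3)
  expect_equal(p$cn_x, 1)
  expect_equal(p$cn_y, 2)
  expect_equal(p$w_x, 2 / 3)
  expect_equal(p$w_y, 1 / 3)

  ds2 <- pattern_dataset(c("A", "B", "B", "A"))
  p2 <- neighborhood_profile(build_distance_model(ds2), ds2$labels, 1, 1)
  expect_equal(c(p2$cn, p2$cn_x, p2$cn_y), c(2, 1, 1))
  expect_equal(p2$w_x, 0.5)

  ds3 <- pattern_dataset(c("A", "A", "B", "B"))
  p3 <- neighborhood_profile(build_distance_model(ds3), ds3$labels, 1, 2)
  expect_equal(c(p3$cn, p3$cn_x, p3$cn_y), c(4, 2, 2))
  expect_equal(p3$w_x, p3$w_y)

  expect_error(neighborhood_profile(build_distance_model(ds2), ds2$labels,
                                    1, 5), "infeasible.*mol1")
})

test_that("the weighted rivality index matches hand evaluation and reductions", {
  # d_x = 0.3, d_y = 0.1 with CN = 3, CN_x = 1, CN_y = 2
  ds <- pattern_dataset(c("B", "B", "A", "A", "B"))
  m <- build_distance_model(ds)
  ri <- rivality_weighted(m, ds$labels, 1, tn = 1)
  expect_equal(as.numeric(ri),
               (0.3 * 2 / 3 - 0.1 * 1 / 3) / (0.3 * 2 / 3 + 0.1 * 1 / 3))
  expect_equal(round(as.numeric(ri), 4), 0.7143)

  # balanced neighborhood: the weights cancel and plain = weighted
  bal <- pattern_dataset(c("A", "B", "B", "A"))
  mb <- build_distance_model(bal)
  w <- rivality_weighted(mb, bal$labels, 1, tn = 1)
  d_x <- first_neighbor(mb, bal$labels, 1, TRUE)$distance
  d_y <- first_neighbor(mb, bal$labels, 1, FALSE)$distance
  expect_equal(as.numeric(w), as.numeric(rivality_plain(d_x, d_y)))

  # triple-coincidence indetermination carries the sentinel at TN >= 1 too
  tri <- descriptor_dataset(
    matrix(c(0.5, 0.5, 0.5, 0.1, 0.9, 0.9), ncol = 1,
           dimnames = list(NULL, "d1")),
    c("A", "A", "B", "A", "B", "B"), scaled = TRUE,
    scale_params = list(min = c(d1 = 0), max = c(d1 = 1)))
  mt <- build_distance_model(tri)
  st <- rivality_weighted(mt, tri$labels, 1, tn = 1)
  expect_identical(as.numeric(st), -1e-6)
  expect_true(attr(st, "sentinel"))
})

test_that("rivality profiles separate clusters and expose planted structure", {
  x <- c(0, 0.01, 0.02, 1, 1.01, 1.02) / 1.02
  ds <- descriptor_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "d1")),
                           rep(c("A", "B"), each = 3), scaled = TRUE,
                           scale_params = list(min = c(d1 = 0),
                                               max = c(d1 = 1)))
  m <- build_distance_model(ds)
  res <- rivality_profile(m, ds$labels, tn = c(0, 1))
  expect_true(all(res$ri < 0))
  expect_equal(res$cmodi[["TN0"]], 1)
  expect_equal(res$cmodi[["TN1"]], 1)

  # one A-labeled point moved next to the B cluster becomes the lone cliff
  # (just beyond the last B point, so no B molecule's own neighborhood flips)
  x2 <- c(0, 0.01, 1.035, 1, 1.01, 1.02) / 1.035
  ds2 <- descriptor_dataset(matrix(x2, ncol = 1, dimnames = list(NULL, "d1")),
                            rep(c("A", "B"), each = 3), scaled = TRUE,
                            scale_params = list(min = c(d1 = 0),
                                                max = c(d1 = 1)))
  m2 <- build_distance_model(ds2)
  res2 <- rivality_profile(m2, ds2$labels, tn = 1)
  expect_equal(res2$cliffs$TN1, "mol3")
  expect_true(all(res2$ri[-3, 1] < 0))

  # a single-TN call equals the matching column of a multi-TN call
  multi <- rivality_profile(m2, ds2$labels, tn = c(0, 1, 2))
  single <- rivality_profile(m2, ds2$labels, tn = 2)
  expect_identical(multi$ri[, "TN2"], single$ri[, "TN2"])

  expect_error(rivality_profile(m2, ds2$labels, tn = 4), "infeasible")
})

test_that("CMODI averages per-class fractions of non-positive rivality", {
  labels <- c("0", "0", "1", "1")
  out <- cmodi(c(-0.5, 0.2, -0.1, -1e-6), labels)
  expect_equal(unname(out$per_class), c(0.5, 1.0))
  expect_equal(out$cmodi, 0.75)
  expect_equal(cmodi(c(-1, -0.2, -0.3, -0.9), labels)$cmodi, 1)
  expect_equal(cmodi(c(0.1, 0.2, 0.3, 0.9), labels)$cmodi, 0)
  expect_error(cmodi(c(-1, NA, 0, 0), labels), "missing")
})

test_that("cliff and border detection apply the sign and threshold rules", {
  ri <- c(m1 = -0.9, m2 = 0.01, m3 = 0.8)
  expect_setequal(detect_cliffs(ri), c("m2", "m3"))
  expect_setequal(detect_cliffs(c(a = 0, b = 0.5)), "b") # RI = 0 is no cliff

  ri2 <- c(m1 = -0.005, m2 = 0.5, m3 = 0.002)
  expect_setequal(detect_borders(ri2, 0.01), c("m1", "m3"))
  expect_setequal(detect_borders(ri2, 1.5), c("m1", "m2", "m3"))
  # sentinel molecules are excluded despite their tiny |RI|
  expect_equal(detect_borders(c(s = -1e-6), 0.01,
                              sentinel = TRUE), character(0))
  expect_error(detect_borders(ri2, 0), "positive")
})

test_that("weights, ranges and reductions hold across random datasets", {
  for (seed in 1:40) {
    ds <- random_scaled_dataset(10 + seed %% 21, 1 + seed %% 5, seed = seed)
    m <- build_distance_model(ds)
    for (i in seq_len(n_molecules(ds))) {
      tn <- 1 + seed %% 3
      p <- neighborhood_profile(m, ds$labels, i, tn)
      expect_equal(p$w_x + p$w_y, 1, tolerance = 1e-12)
      expect_true(p$cn_x >= tn && p$cn_y >= tn && p$cn_x + p$cn_y == p$cn)
      w <- as.numeric(rivality_weighted(m, ds$labels, i, tn))
      expect_true(w >= -1 && w <= 1)
      if (p$cn_x == p$cn_y) {
        d_x <- first_neighbor(m, ds$labels, i, TRUE)$distance
        d_y <- first_neighbor(m, ds$labels, i, FALSE)$distance
        expect_equal(w, as.numeric(rivality_plain(d_x, d_y)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("plain rivality sign agrees with the window-(1,1) neighbor count", {
  for (seed in 41:55) {
    ds <- random_scaled_dataset(15, 3, seed = seed)
    m <- build_distance_model(ds)
    res <- rivality_profile(m, ds$labels, tn = 0)
    for (i in seq_len(n_molecules(ds))) {
      cnt <- diffclass_before_nth(m, ds$labels, i, 1, 1)$count
      if (cnt == 0) expect_lte(res$ri[i, 1], 0) else
        expect_gt(res$ri[i, 1], 0)
    }
  }
})

test_that("rivality tables and summaries are written and readable", {
  ds <- random_scaled_dataset(14, 3, seed = 77)
  m <- build_distance_model(ds)
  res <- rivality_profile(m, ds$labels, tn = 0:2)
  dir <- withr::local_tempdir()
  write_rivality_result(res, dir)
  tab <- utils::read.csv(file.path(dir, "rivality.csv"), check.names = FALSE)
  expect_equal(nrow(tab), n_molecules(ds))
  expect_true(all(c("TN0", "TN1", "TN2") %in% names(tab)))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$cmodi$TN1, unname(res$cmodi["TN1"]))
})
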