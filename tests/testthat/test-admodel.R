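scaled_ds <- function(x, labels, check_classes = TRUE)
  descriptor_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "d1")),
                     labels, scaled = TRUE,
                     scale_params = list(min = c(d1 = 0), max = c(d1 = 1)),
                     check_classes = check_classes)

test_that("external rivality handles duplicates, centroids and exact ties", {
  train <- scaled_ds(c(0, 0.25, 0.75, 1), c("A", "A", "B", "B"))

  # duplicate of a training molecule of its own class
  dup <- external_rivality(train, c(d1 = 0.25), "A", tn = 0)
  expect_equal(dup$ri, -1)
  expect_equal(dup$d_x, 0)
  expect_equal(dup$same_id, "mol2")

  # molecule in the heart of the opposite class
  cliff <- external_rivality(train, c(d1 = 0.875), "A", tn = 1)
  expect_gt(cliff$ri, 0)

  # exactly midway between the two nearest cluster members (binary fractions)
  mid <- external_rivality(train, c(d1 = 0.5), "A", tn = 0)
  expect_identical(mid$ri, 0)
  expect_false(mid$sentinel)

  # opposite-class duplicate on top of a same-class duplicate: sentinel
  twin <- scaled_ds(c(0.5, 0.5, 0.1, 0.9), c("A", "B", "A", "B"))
  s <- external_rivality(twin, c(d1 = 0.5), "A", tn = 1)
  expect_identical(s$ri, -1e-6)
  expect_true(s$sentinel)

  expect_error(external_rivality(train, c(bogus = 0.1), "A"),
               "missing column")
  expect_error(external_rivality(train, c(d1 = 0.1), "C"), "unknown class")
  expect_error(external_rivality(train, c(d1 = 0.1), "A", tn = 3),
               "infeasible")
})

test_that("held-out molecules reproduce their in-set rivality exactly", {
  cases <- 0
  for (seed in 1:20) {
    ds <- random_scaled_dataset(16, 4, seed = 100 + seed)
    m <- build_distance_model(ds)
    in_set <- rivality_profile(m, ds$labels, tn = c(0, 1, 2))
    for (i in seq(1, n_molecules(ds), by = 3)) {
      train <- subset_molecules(ds, setdiff(seq_len(n_molecules(ds)), i))
      for (tn in c(0, 1, 2)) {
        ext <- external_rivality(train, ds$features[i, ],
                                 as.character(ds$labels[i]), tn)
        expect_identical(ext$ri, unname(in_set$ri[i, paste0("TN", tn)]))
      }
      cases <- cases + 1
    }
  }
  expect_gte(cases, 100)
})

test_that("a test molecule's rivality never depends on the rest of the test set", {
  ds <- random_scaled_dataset(20, 3, seed = 200)
  train <- subset_molecules(ds, 1:14)
  test_all <- subset_molecules(ds, 15:20, check_classes = FALSE)
  full <- ad_assess(train, test_all, tn = 1, scaling = "none")
  for (k in 15:20) {
    solo <- ad_assess(train, subset_molecules(ds, k, check_classes = FALSE),
                      tn = 1, scaling = "none")
    expect_identical(solo$table$TN1,
                     full$table$TN1[full$table$id == ds$ids[k]])
  }
  shuffled <- ad_assess(train,
                        subset_molecules(ds, c(18, 15, 20, 17, 16, 19),
                                         check_classes = FALSE),
                        tn = 1, scaling = "none")
  expect_identical(sort(shuffled$table$TN1), sort(full$table$TN1))
})

test_that("AD reports carry verdicts that are pure functions of RI", {
  syn <- generate_synthetic(synthetic_spec(n_per_class = c(12, 12), dim = 4,
                                           separation = 10,
                                           n_cliffs_per_class = 2, seed = 9))
  ds <- syn$dataset
  genuine <- setdiff(ds$ids, syn$truth$cliff_ids)
  train <- subset_molecules(ds, genuine[c(1:9, 13:21)])

  # a strongly separable test set sits fully inside the domain
  inside <- subset_molecules(ds, setdiff(genuine, train$ids),
                             check_classes = FALSE)
  rep_in <- ad_assess(train, inside, tn = 1, scaling = "none")
  expect_true(all(rep_in$table$verdict %in% c("inside", "border")))
  expect_equal(rep_in$cmodi, 1)

  # planted cliffs land outside and give test CMODI 0
  cliffs <- subset_molecules(ds, syn$truth$cliff_ids, check_classes = FALSE)
  rep_out <- ad_assess(train, cliffs, tn = 1, scaling = "none")
  expect_true(all(rep_out$table$TN1 > 0))
  expect_true(all(rep_out$table$verdict %in% c("outside", "border")))
  expect_equal(rep_out$cmodi, 0)

  # single-molecule test set: one row, degenerate aggregates flagged
  solo <- ad_assess(train, subset_molecules(ds, syn$truth$cliff_ids[1],
                                            check_classes = FALSE),
                    tn = 1, scaling = "none")
  expect_equal(nrow(solo$table), 1)
  expect_true(solo$stats$incomplete)

  # verdict law on the pooled report
  pooled <- rbind(rep_in$table, rep_out$table)
  thr <- rep_in$border_threshold
  expect_identical(pooled$verdict,
                   ifelse(abs(pooled$TN1) <= thr, "border",
                          ifelse(pooled$TN1 > 0, "outside", "inside")))

  expect_error(ad_assess(train, subset_molecules(ds, character(0),
                                                 check_classes = FALSE)),
               "empty|unknown")
})

test_that("erasing cliffs removes exactly the positive-rivality molecules", {
  clean <- generate_synthetic(synthetic_spec(n_per_class = c(10, 10), dim = 4,
                                             separation = 10, seed = 12))
  m <- build_distance_model(clean$dataset)
  none <- erase_cliffs(clean$dataset, m, tn = 1)
  expect_equal(none$removed, character(0))
  expect_identical(none$dataset$features, clean$dataset$features)

  planted <- generate_synthetic(synthetic_spec(n_per_class = c(10, 10),
                                               dim = 4, separation = 10,
                                               n_cliffs_per_class = 3,
                                               seed = 13))
  mp <- build_distance_model(planted$dataset)
  cur <- erase_cliffs(planted$dataset, mp, tn = 1)
  expect_setequal(cur$removed, planted$truth$cliff_ids)
  m2 <- build_distance_model(cur$dataset)
  res2 <- rivality_profile(m2, cur$dataset$labels, tn = 1)
  expect_equal(res2$cmodi[["TN1"]], 1)

  # erase-then-recompute reaches its fixed point immediately here
  again <- erase_cliffs(cur$dataset, m2, tn = 1)
  expect_equal(again$removed, character(0))
})

test_that("stratified splits are reproducible and respect the fraction", {
  syn <- generate_synthetic(synthetic_spec(n_per_class = c(59, 59), dim = 3,
                                           separation = 6,
                                           n_cliffs_per_class = 3, seed = 2))
  ds <- syn$dataset  # 124 molecules, 62 per class
  sp <- split_dataset(ds, 0.8, seed = 5)
  expect_equal(length(sp$train), 100)  # round(0.8 * 62) per class
  expect_equal(length(sp$test), 24)
  expect_setequal(c(sp$train, sp$test), ds$ids)
  tr_lab <- ds$labels[match(sp$train, ds$ids)]
  expect_equal(as.integer(table(tr_lab)), c(50, 50))

  expect_identical(split_dataset(ds, 0.8, seed = 5), sp)
  expect_false(identical(split_dataset(ds, 0.8, seed = 6)$train, sp$train))

  quad <- scaled_ds(c(0.1, 0.2, 0.8, 0.9), c("A", "A", "B", "B"))
  sq <- split_dataset(quad, 0.5, seed = 1)
  expect_equal(length(sq$train), 2)
  expect_setequal(substr(sq$train, 1, 3), "mol")

  expect_error(split_dataset(quad, 0.9), "unrepresented")
  expect_error(split_dataset(quad, 1.2), "fraction")
})

test_that("AD reports round-trip through their CSV/JSON products", {
  ds <- random_scaled_dataset(18, 3, seed = 300)
  train <- subset_molecules(ds, 1:12)
  test <- subset_molecules(ds, 13:18, check_classes = FALSE)
  rep <- ad_assess(train, test, tn = c(1, 2), scaling = "none")
  dir <- withr::local_tempdir()
  write_ad_report(rep, dir)
  tab <- utils::read.csv(file.path(dir, "ad_report.csv"), check.names = FALSE)
  expect_equal(nrow(tab), 6)
  summ <- jsonlite::read_json(file.path(dir, "ad_summary.json"))
  expect_equal(summ$cmodi, rep$cmodi)
})
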