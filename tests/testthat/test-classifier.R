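# Partitioning, forest training, per-strain evaluation and mixture
# deconvolution on simulated per-object feature tables.

test_that("stratified partition hits 60/20/20 per strain", {
  tab <- simulate_feature_table(1000, seed = 1)
  parts <- partition_objects(tab, seed = 5)
  for (s in unique(tab$strain)) {
    sz <- table(parts$partition[parts$strain == s])
    expect_equal(unname(sz["train"]), 600)
    expect_equal(unname(sz["test"]), 200)
    expect_equal(unname(sz["validation"]), 200)
  }
})

test_that("degenerate fractions and small strata behave", {
  tab <- simulate_feature_table(50, seed = 2)
  all_train <- partition_objects(tab, fractions = c(train = 1, test = 0,
                                                    validation = 0), seed = 1)
  expect_true(all(all_train$partition == "train"))
  tiny <- tab[c(1:3, 51:100, 101:150), ]
  expect_error(partition_objects(tiny, seed = 1), "fewer than 5")
})

test_that("partitions differ across seeds but keep their sizes", {
  tab <- simulate_feature_table(100, seed = 3)
  a <- partition_objects(tab, seed = 1)
  b <- partition_objects(tab, seed = 2)
  expect_equal(table(a$partition), table(b$partition))
  expect_false(identical(a$partition, b$partition))
  a2 <- partition_objects(tab, seed = 1)
  expect_identical(a$partition, a2$partition)
})

test_that("disjoint-range strains are classified perfectly", {
  set.seed(4)
  tab <- tibble::tibble(
    strain = rep(c("a_small", "b_large"), each = 200),
    area_px = c(runif(200, 50, 100), runif(200, 300, 400)),
    form_factor = runif(400, 0.3, 1))
  parts <- partition_objects(tab, seed = 7)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 7)
  val <- parts[parts$partition == "validation", ]
  pred <- predict(model, val)
  expect_equal(mean(pred$strain_predicted == val$strain), 1.0)
})

test_that("shuffled labels give chance-level accuracy", {
  tab <- simulate_feature_table(1000, seed = 6)   # 3 strains, n = 3000
  set.seed(6)
  tab$strain <- sample(tab$strain)
  parts <- partition_objects(tab, seed = 6)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 6)
  val <- parts[parts$partition == "validation", ]
  acc <- mean(predict(model, val)$strain_predicted == val$strain)
  expect_lt(abs(acc - 1 / 3), 0.05)
})

test_that("per-strain rates: rows sum to 1 and a perfect model is diagonal", {
  tab <- simulate_feature_table(300, seed = 8, separation = 10)
  parts <- partition_objects(tab, seed = 8)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 8)
  conf <- evaluate_per_strain(model, tab)
  sums <- tapply(conf$rate, conf$strain, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  diag_rates <- conf$rate[conf$strain == conf$identified_as]
  expect_true(all(diag_rates > 0.95))
})

test_that("moderately overlapping strains land between chance and perfection", {
  tab <- simulate_feature_table(400, seed = 9, separation = 1.2)
  parts <- partition_objects(tab, seed = 9)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 9)
  conf <- evaluate_per_strain(model, tab)
  diag_rates <- conf$rate[conf$strain == conf$identified_as]
  expect_true(all(diag_rates > 1 / 3))
  expect_true(any(diag_rates < 0.999))
})

test_that("mixture composition recovers the mixing proportions", {
  tab <- simulate_feature_table(500, seed = 10)
  parts <- partition_objects(tab, seed = 10)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 10)
  mix <- simulate_feature_table(300, seed = 99)   # fresh draw, balanced thirds
  rep <- classify_mixture(model, mix)
  expect_equal(sum(rep$composition$fraction), 1)
  expect_true(all(abs(rep$composition$fraction - 1 / 3) < 0.05))
  # single object gives a unit vector
  one <- classify_mixture(model, mix[1, ])
  expect_equal(sort(one$composition$fraction), c(0, 0, 1))
  # empty input is flagged
  none <- classify_mixture(model, mix[0, ])
  expect_equal(none$n_objects, 0)
  expect_true("empty_input" %in% none$qc)
})

test_that("identical seed gives an identical report", {
  tab <- simulate_feature_table(200, seed = 11)
  run <- function() {
    parts <- partition_objects(tab, seed = 4)
    model <- train_strain_forest(parts[parts$partition == "train", ], seed = 4)
    evaluate_per_strain(model, tab)
  }
  expect_identical(run(), run())
})

test_that("test and validation objects never enter the bootstrap", {
  tab <- simulate_feature_table(100, seed = 12)
  tab$object_id <- seq_len(nrow(tab))
  parts <- partition_objects(tab, seed = 12)
  train_ids <- parts$object_id[parts$partition == "train"]
  other_ids <- parts$object_id[parts$partition != "train"]
  expect_length(intersect(train_ids, other_ids), 0)
  expect_equal(sort(c(train_ids, other_ids)), seq_len(nrow(tab)))
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 12)
  expect_equal(model$n_train, length(train_ids))
})

test_that("schema mismatch fails naming the missing columns", {
  tab <- simulate_feature_table(100, seed = 13)
  parts <- partition_objects(tab, seed = 13)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 13)
  broken <- tab[setdiff(names(tab), "area_px")]
  expect_error(predict(model, broken), "area_px")
  expect_error(train_strain_forest(tibble::tibble(strain = rep("x", 10),
                                                  a = 1:10)), ">= 2 strains")
  const <- tibble::tibble(strain = rep(c("x", "y"), each = 10), a = 1)
  expect_error(train_strain_forest(const), "constant")
})

test_that("tidy and glance expose forest and mixture summaries", {
  tab <- simulate_feature_table(200, seed = 14)
  parts <- partition_objects(tab, seed = 14)
  model <- train_strain_forest(parts[parts$partition == "train", ], seed = 14)
  td <- tidy(model)
  expect_true(all(c("strain", "identified_as", "rate") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$ntree, 100)
  expect_gt(gl$oob_accuracy, 0.9)
  mix <- classify_mixture(model, simulate_feature_table(60, seed = 15))
  expect_equal(tidy(mix), mix$composition)
  expect_equal(glance(mix)$n_objects, 180)
})
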