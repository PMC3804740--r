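test_that("separable classes are split by the informative feature at zero error", {
  rec <- synthetic_records(n = 60, gap = 600, sd = 30, seed = 2)
  model <- train_rules(rec)
  expect_equal(model$rules$feature[1], "area_cytoplasm")
  expect_equal(model$train_error, 0)
  expect_lte(max(model$rules$rule), model$max_rules)
  # a training exemplar is classified as its own class
  expect_equal(predict(model, rec[1, ]), "spread")
  expect_equal(predict(model, rec[0, ]), character(0))
})

test_that("rule count never exceeds the cap on overlapping data", {
  rec <- synthetic_records(n = 100, gap = 50, sd = 80, seed = 3)
  for (cap in c(5, 20)) {
    model <- train_rules(rec, max_rules = cap)
    expect_lte(max(model$rules$rule), cap)
  }
})

test_that("training is invariant to record order and duplication", {
  rec <- synthetic_records(n = 80, gap = 120, sd = 70, seed = 4)
  m1 <- train_rules(rec, max_rules = 10)
  set.seed(9)
  m2 <- train_rules(rec[sample(nrow(rec)), ], max_rules = 10)
  expect_equal(tidy(m1), tidy(m2))
  m3 <- train_rules(dplyr::bind_rows(rec, rec), max_rules = 10)
  expect_equal(tidy(m1), tidy(m3), tolerance = 1e-10)
})

test_that("classification agrees with generator truth on distinct classes", {
  rec <- synthetic_records(n = 200, gap = 300, sd = 60, seed = 5)
  model <- train_rules(rec, max_rules = 20)
  out <- classify_cells(dplyr::select(rec, -"class"), model)
  expect_gte(mean(out$class == rec$class), 0.95)
})

test_that("degenerate and invalid training inputs error clearly", {
  rec <- synthetic_records(n = 20, seed = 6)
  expect_error(train_rules(rec[rec$class == "spread", ]), "2 classes")
  expect_error(train_rules(rec[0, ]), "empty")
  expect_error(predict(train_rules(rec), rec[, "class", drop = FALSE]),
               "missing feature")
})

test_that("cross-validation: separable ~ 1, permuted labels ~ chance, LOO oracle", {
  sep <- synthetic_records(n = 40, gap = 600, sd = 20, seed = 7)
  expect_equal(crossval_accuracy(sep, folds = 4, seed = 1), 1.0)

  set.seed(8)
  noise <- synthetic_records(n = 100, gap = 0, sd = 60, seed = 8)
  noise$class <- sample(noise$class)
  acc <- crossval_accuracy(noise, folds = 5, seed = 2, max_rules = 5)
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)

  # folds = n equals a hand-rolled leave-one-out evaluation
  small <- synthetic_records(n = 16, gap = 250, sd = 90, seed = 9)
  loo <- crossval_accuracy(small, folds = 16, seed = 3, max_rules = 5)
  manual <- mean(vapply(seq_len(16), function(i) {
    m <- train_rules(small[-i, ], max_rules = 5)
    predict(m, small[i, ]) == small$class[i]
  }, logical(1)))
  expect_equal(loo, manual)
})

test_that("three-class training and vote-tie handling work", {
  set.seed(10)
  rec <- tibble::tibble(
    area_cytoplasm = c(rnorm(20, 200, 20), rnorm(20, 500, 20), rnorm(20, 900, 20)),
    eccentricity = runif(60),
    class = rep(c("unspread", "spread", "giant"), each = 20)
  )
  model <- train_rules(rec, max_rules = 15)
  expect_equal(sort(model$classes), sort(c("unspread", "spread", "giant")))
  expect_lte(model$train_error, 0.1)
  pred <- predict(model, rec)
  expect_gte(mean(pred == rec$class), 0.9)
})

test_that("JSON round-trip preserves the model and its predictions", {
  rec <- synthetic_records(n = 60, gap = 150, sd = 80, seed = 11)
  model <- train_rules(rec, max_rules = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_model(model, path)
  back <- read_rule_model(path)
  expect_equal(predict(back, rec), predict(model, rec))
  expect_equal(glance(back)$n_rules, glance(model)$n_rules)
})
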