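make_separable_samples <- function(n = 120, seed = 2) {
  set.seed(seed)
  bg <- tibble::tibble(r = runif(n, 20, 60), g = runif(n, 20, 60),
                       b = runif(n, 20, 60), label = "background")
  fg <- tibble::tibble(r = runif(n, 160, 220), g = runif(n, 160, 220),
                       b = runif(n, 160, 220), label = "cell")
  out <- dplyr::bind_rows(bg, fg)
  out$label <- factor(out$label, levels = c("background", "cell"))
  out
}

test_that("split_samples gives exact 70/15/15 and a clean partition", {
  s <- split_samples(make_separable_samples(50), rng_seed = 7)  # 100 rows
  expect_equal(unname(table(s$split)), c(70L, 15L, 15L), ignore_attr = TRUE)
  expect_equal(nrow(s), 100L)
  s2 <- split_samples(make_separable_samples(50), rng_seed = 7)
  expect_identical(s$split, s2$split)
  s3 <- split_samples(make_separable_samples(50), rng_seed = 8)
  expect_false(identical(s$split, s3$split))
})

test_that("split_samples boundary behaviour and errors", {
  x <- make_separable_samples(5)  # 10 rows
  all_train <- split_samples(x, c(1, 0, 0), rng_seed = 1)
  expect_equal(sum(all_train$split == "train"), 10L)
  expect_error(split_samples(x[0, ]), "empty")
  expect_error(split_samples(x[1:3, ], c(0.5, 0.4, 0.1)),
               "at least one sample")
  expect_error(split_samples(x, c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("a separable problem is learned to zero test misclassification", {
  s <- split_samples(make_separable_samples(200), rng_seed = 3)
  clf <- train_pixel_classifier(s, rng_seed = 3)
  te <- s[s$split == "test", ]
  pred <- predict(clf, te, type = "class")
  expect_equal(mean(pred != as.integer(te$label == "cell")), 0)
  expect_true(all(predict(clf, te) >= 0 & predict(clf, te) <= 1))
  # independent learner cross-check: nnet reaches zero on the same data too
  skip_if_not_installed("nnet")
  tr <- dplyr::mutate(s[s$split == "train", ], dplyr::across(r:b, ~ .x / 255))
  te_s <- dplyr::mutate(te, dplyr::across(r:b, ~ .x / 255))
  m <- nnet::nnet(label ~ r + g + b, data = tr, size = 3, trace = FALSE,
                  maxit = 500, decay = 1e-4)
  expect_equal(mean(predict(m, te_s, type = "class") !=
                      as.character(te_s$label)), 0)
})

test_that("training is deterministic for fixed data and seed", {
  s <- split_samples(make_separable_samples(100), rng_seed = 4)
  c1 <- train_pixel_classifier(s, rng_seed = 4)
  c2 <- train_pixel_classifier(s, rng_seed = 4)
  expect_identical(c1$theta, c2$theta)
})

test_that("the MSE stopping contract is honoured and reported", {
  s <- split_samples(make_separable_samples(100), rng_seed = 4)
  clf <- train_pixel_classifier(s, rng_seed = 4)
  r <- clf$report
  expect_true(r$mse_train <= r$mse_target || r$epochs >= r$max_epochs ||
                r$stop_reason %in% c("validation_stop", "mu_max"))
  expect_true(is.finite(r$mse_test))  # reported, never used in fitting
  g <- glance(clf)
  expect_equal(g$n_parameters, 3 * 8 + 8 + 8 + 1)
})

test_that("a single-class training split errors unless explicitly allowed", {
  s <- make_separable_samples(60)
  s$label[] <- "cell"
  s <- split_samples(s, rng_seed = 1)
  expect_error(train_pixel_classifier(s, rng_seed = 1), "single class")
  clf <- train_pixel_classifier(s, rng_seed = 1, check_classes = FALSE)
  expect_lte(clf$report$mse_train, 1e-6)
  expect_lte(clf$report$epochs, 25)   # constant predictor converges fast
})

test_that("a serialised classifier reloads to matching predictions", {
  s <- split_samples(make_separable_samples(80), rng_seed = 6)
  clf <- train_pixel_classifier(s, rng_seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  X <- as.matrix(make_separable_samples(40, seed = 99)[, c("r", "g", "b")])
  expect_equal(predict(clf, X), predict(clf2, X), tolerance = 1e-12)
  expect_identical(predict(clf, X, type = "class"),
                   predict(clf2, X, type = "class"))
})
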