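test_that("best-epoch selection is argmax with earliest-tie rule", {
  expect_equal(notescreen:::pick_best_epoch(c(0.6, 0.8, 0.7)), 2L)
  expect_equal(notescreen:::pick_best_epoch(c(0.7, 0.7, 0.6)), 1L)
})

test_that("train_mlp separates a wide-margin toy problem", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, mean = 3, sd = 0.3), 20, 2),
               matrix(rnorm(40, mean = -3, sd = 0.3), 20, 2))
    y <- rep(c(1, 0), each = 20)
  })
  m <- train_mlp(x, y, mlp_spec(hidden = 8),
                 mlp_control(epochs = 30, learning_rate = 5e-2, seed = 2))
  # a linear separator with this margin classifies perfectly; so must
  # the network at its selected epoch
  expect_equal(m$history$train_accuracy[m$best_epoch], 1.0)
  expect_equal(nrow(m$history), 30L)
})

test_that("train_mlp validates inputs and restores best-epoch weights", {
  withr::with_seed(9, {
    x <- matrix(rnorm(120), 60, 2)
    y <- rbinom(60, 1, 0.5)
  })
  expect_error(train_mlp(x, rep(1, 60)), "single class")

  m <- train_mlp(x, y, mlp_spec(hidden = 4),
                 mlp_control(epochs = 6, seed = 3))
  # re-evaluating the restored weights on the internal validation rows
  # reproduces the stored best-epoch validation accuracy
  p_val <- predict(m, x[m$val_idx, , drop = FALSE])
  expect_equal(mean((p_val >= 0.5) == y[m$val_idx]),
               m$history$val_accuracy[m$best_epoch])
})

test_that("prediction is deterministic, bounded, and shape-checked", {
  zero <- manual_linear_model(c(0, 0), 0)
  expect_equal(predict(zero, matrix(rnorm(10), 5, 2)), rep(0.5, 5))

  m <- random_trained_net(21, d = 3)
  x <- matrix(rnorm(30), 10, 3)
  p1 <- predict(m, x)
  expect_identical(p1, predict(m, x))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predict(m, matrix(0, 2, 5)), "width")
})

test_that("identical data and seed give identical weights; test rows never matter", {
  withr::with_seed(31, {
    x <- matrix(rnorm(200), 100, 2)
    y <- rep(c(0, 1), 50)
  })
  m1 <- train_mlp(x[1:80, ], y[1:80], mlp_spec(4), mlp_control(epochs = 3, seed = 7))
  m2 <- train_mlp(x[1:80, ], y[1:80], mlp_spec(4), mlp_control(epochs = 3, seed = 7))
  expect_identical(m1$weights, m2$weights)

  # cross-validation: mutating the rows of one test fold must not change
  # the model trained (on the other folds) for that split
  cv <- cv_config(n_splits = 2, n_repetitions = 1, master_seed = 5)
  r1 <- run_cross_validation(x, y, mlp_spec(4), cv,
                             mlp_control(epochs = 2))
  x_mut <- x
  te1 <- r1$folds$row[r1$folds$fold == 1]
  x_mut[te1, ] <- x_mut[te1, ] + 100
  r2 <- run_cross_validation(x_mut, y, mlp_spec(4), cv,
                             mlp_control(epochs = 2))
  expect_identical(r1$results$model[[1]]$weights,
                   r2$results$model[[1]]$weights)
})

test_that("cross-validation folds partition the cohort evenly and reproducibly", {
  withr::with_seed(42, {
    y <- rbinom(100, 1, 0.55)
    x <- matrix(rnorm(200), 100, 2)
    x[, 1] <- x[, 1] + y
  })
  cv <- cv_config(n_splits = 10, n_repetitions = 1, master_seed = 12)
  res <- run_cross_validation(x, y, mlp_spec(4), cv, mlp_control(epochs = 2))
  sizes <- table(res$folds$fold)
  expect_equal(unname(c(sizes)), rep(10L, 10))
  expect_setequal(res$folds$row, 1:100)

  res2 <- run_cross_validation(x, y, mlp_spec(4), cv, mlp_control(epochs = 2))
  expect_identical(res$folds, res2$folds)

  # model count = splits x repetitions x architectures
  archs <- list(mlp_spec(4, id = "a"), mlp_spec(6, id = "b"))
  cv2 <- cv_config(n_splits = 2, n_repetitions = 2, master_seed = 1)
  res3 <- run_cross_validation(x, y, archs, cv2, mlp_control(epochs = 2))
  expect_equal(nrow(res3$results), 2L * 2L * 2L)
})

test_that("a fold holding the only member of a class raises a named error", {
  x <- matrix(rnorm(16), 8, 2)
  y <- c(1, 1, 1, 1, 1, 1, 1, 0)
  expect_error(
    run_cross_validation(x, y, mlp_spec(2),
                         cv_config(n_splits = 2, n_repetitions = 1,
                                   stratified = FALSE, master_seed = 3),
                         mlp_control(epochs = 1)),
    "fold .* single class")
})

test_that("select_architecture matches a brute-force pick on a hand fixture", {
  # synthetic cv_result: 2 architectures x 2 splits x 2 repetitions
  fix <- tibble::tibble(
    split = rep(c(1, 1, 2, 2), 2),
    repetition = rep(c(1, 2), 4),
    architecture = rep(c("small", "big"), each = 4),
    accuracy = c(0.80, 0.85, 0.70, 0.70, 0.90, 0.60, 0.75, 0.80),
    auc = c(0.8, 0.9, 0.75, 0.80, 0.95, 0.7, 0.8, 0.85),
    n_test = 10, n_parameters = rep(c(10, 20), each = 4),
    probabilities = list(NULL), metrics = list(NULL), model = list(NULL))
  cvr <- structure(list(results = fix,
                        folds = tibble::tibble(row = 1:20, fold = rep(1:2, 10)),
                        cv = cv_config(2, 2, master_seed = 1),
                        architectures = list(mlp_spec(1, id = "small"),
                                             mlp_spec(2, id = "big"))),
                   class = "cv_result")
  sel <- select_architecture(cvr)
  # brute force: small best-per-split = 0.85 (rep 2), 0.70 (tie -> higher
  # auc -> rep 2): mean 0.775; big = 0.90, 0.80: mean 0.85 -> big wins
  expect_equal(sel$architecture, "big")
  expect_equal(sel$summary$mean_accuracy[sel$summary$architecture == "small"],
               0.775)
  expect_equal(sel$summary$mean_accuracy[sel$summary$architecture == "big"],
               0.85)
  tie_split1 <- sel$best_per_split |>
    dplyr::filter(architecture == "small", split == 2)
  expect_equal(tie_split1$repetition, 2)

  single <- cvr
  single$results <- dplyr::filter(fix, architecture == "small")
  single$architectures <- single$architectures[1]
  expect_equal(select_architecture(single)$architecture, "small")

  empty <- cvr
  empty$results <- fix[0, ]
  expect_error(select_architecture(empty), "empty")
})

test_that("logistic baseline reuses folds and behaves sensibly", {
  withr::with_seed(15, {
    y <- rep(c(0, 1), each = 30)[sample(60)]
    x <- cbind(sig = rnorm(60) + 2 * y)
  })
  cv <- cv_config(n_splits = 3, n_repetitions = 1, master_seed = 8)
  cvr <- run_cross_validation(x, y, mlp_spec(4), cv, mlp_control(epochs = 3))
  bl <- train_logistic_baseline(x, y, cvr)
  expect_equal(nrow(bl$per_split), 3L)
  # informative feature (higher in positives) -> positive coefficient
  coefs <- vapply(bl$fits, function(f) coef(f)["sig", 1], numeric(1))
  expect_true(all(coefs > 0))

  # constant feature -> intercept-only model, probabilities ~ prevalence
  xc <- cbind(flat = rep(1, 60))
  cvr2 <- run_cross_validation(xc, y, mlp_spec(2), cv, mlp_control(epochs = 2))
  bl2 <- train_logistic_baseline(xc, y, cvr2)
  fold <- cvr2$folds$fold
  tr <- which(fold != 1)
  probs <- as.vector(predict(bl2$fits[[1]], cbind(flat = rep(1, 2), 0),
                             type = "response"))
  expect_equal(probs, rep(mean(y[tr]), 2), tolerance = 1e-9)
})

test_that("tidiers and autoplot expose cv results in standard shapes", {
  withr::with_seed(5, {
    y <- rep(c(0, 1), 20)
    x <- matrix(rnorm(80), 40, 2) + y
  })
  cvr <- run_cross_validation(x, y, mlp_spec(4),
                              cv_config(2, 2, master_seed = 2),
                              mlp_control(epochs = 3))
  td <- tidy(cvr)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("split", "repetition", "architecture", "accuracy",
                     "auc", "n_test"))
  gl <- glance(cvr)
  expect_equal(gl$n_models, 4L)
  expect_s3_class(autoplot(cvr), "ggplot")

  m <- cvr$results$model[[1]]
  expect_equal(nrow(tidy(m)), 3L)
  expect_equal(glance(m)$best_epoch, m$best_epoch)
})
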