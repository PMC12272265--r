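test_that("evaluation metrics match hand arithmetic and formula oracle", {
  met <- evaluate_predictions(c(1, 2), c(1, 4))
  expect_equal(met$mae, 1.0)
  expect_equal(met$rmse, sqrt(2))
  perfect <- evaluate_predictions(c(3, 5, 9), c(3, 5, 9))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r, 1)
  met2 <- evaluate_predictions(c(1, 2, 3), c(2, 4, 6))
  expect_equal(met2$r, 1)
  set.seed(50)
  for (rep in 1:10) {
    p <- rnorm(30, 500, 40); y <- rnorm(30, 500, 40)
    met <- evaluate_predictions(p, y)
    expect_equal(met$mae, sum(abs(p - y)) / 30, tolerance = 1e-12)
    expect_equal(met$rmse, sqrt(sum((p - y)^2) / 30), tolerance = 1e-12)
    expect_equal(met$r, cor(p, y), tolerance = 1e-12)
    expect_gte(met$rmse, met$mae)        # Jensen
  }
  # zero-variance input flags r as undefined
  flat <- evaluate_predictions(rep(2, 5), 1:5)
  expect_false(flat$r_defined)
  expect_error(evaluate_predictions(1:3, 1:4), "mismatch")
})

test_that("RMSE dominates MAE on random prediction vectors", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    met <- evaluate_predictions(rnorm(n, 500, 60), rnorm(n, 500, 60))
    expect_gte(met$rmse, met$mae - 1e-12)
  }
})

test_that("fold assignment partitions with near-equal sizes", {
  ids <- sprintf("s%02d", 1:34)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_setequal(names(folds), ids)
  sizes <- as.vector(table(folds))
  expect_setequal(sizes, c(7, 7, 7, 7, 6))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_identical(folds, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(folds, make_folds(ids, k = 5, seed = 4)))
  expect_error(make_folds(ids, k = 40, seed = 1), "exceeds")
  # stratified option balances within strata
  strata <- rep(c("young", "old"), c(14, 20))
  fs <- make_folds(ids, k = 5, seed = 1, stratify_by = strata)
  for (g in unique(strata)) {
    sz <- table(fs[strata == g])
    expect_true(max(sz) - min(sz) <= 1)
  }
})

test_that("training is deterministic and reduces the loss", {
  sim <- small_sim(N = 8, seed = 12)
  cfg <- fast_train_config(epochs = 15, seed = 3)
  m1 <- train_model(sim$cohort, cfg)
  m2 <- train_model(sim$cohort, cfg)
  expect_identical(m1$weights$gnn, m2$weights$gnn)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, sim$cohort), predict(m2, sim$cohort))
  expect_lt(m1$history[15], m1$history[1])
})

test_that("two near-identical subjects are learnable", {
  ch <- make_tiny_cohort(N = 2, seed = 1)
  ch$subjects[[2]] <- ch$subjects[[1]]
  ch$subjects[[2]]$id <- "t02"
  m <- train_model(ch, train_config(epochs = 200, seed = 1, batch_size = Inf))
  expect_lt(m$history[200], m$history[1])
})

test_that("ablation flags drop the matching parameter groups", {
  sim <- small_sim(N = 6, seed = 13)
  m1 <- train_model(sim$cohort, fast_train_config(ablation = "comp1"))
  expect_null(m1$weights$qam)
  expect_null(m1$weights$c1)
  expect_null(m1$weights$c2)
  m2 <- train_model(sim$cohort, fast_train_config(ablation = "comp2"))
  expect_false(is.null(m2$weights$qam))
  expect_null(m2$weights$c2)
  m3 <- train_model(sim$cohort, fast_train_config(ablation = "comp3"))
  expect_false(is.null(m3$weights$c2))
  expect_null(m3$weights$c1)
  expect_error(train_config(ablation = "comp9"), NA)  # validated at train
  expect_error(train_model(sim$cohort,
                           fast_train_config(ablation = "comp9")), "comp")
})

test_that("predict validates the atlas against the training atlas", {
  sim <- small_sim(N = 6, seed = 14)
  m <- train_model(sim$cohort, fast_train_config())
  other <- small_sim(N = 4, n = 12L, seed = 15)
  expect_error(predict(m, other$cohort), "atlas")
  p <- predict(m, sim$cohort)
  expect_length(p, 6L)
  expect_true(all(is.finite(p)))
})

test_that("cross-validation tests every subject exactly once per run", {
  sim <- small_sim(N = 11, seed = 16)
  ev <- cross_validate(sim$cohort, fast_train_config(epochs = 3), k = 3,
                       runs = 2)
  for (r in 1:2) {
    pr <- ev$predictions[ev$predictions$run == r, ]
    expect_setequal(pr$id, vapply(sim$cohort$subjects, `[[`, "", "id"))
    expect_equal(nrow(pr), 11L)
  }
  expect_equal(nrow(ev$runs), 2L)
  expect_true(all(ev$runs$rmse >= ev$runs$mae))
  expect_true(ev$ci$mae["lower"] <= mean(ev$runs$mae) &&
              mean(ev$runs$mae) <= ev$ci$mae["upper"])
  expect_error(cross_validate(sim$cohort, fast_train_config(), k = 20),
               "exceeds")
})

test_that("cross-validation is reproducible end to end under a fixed seed", {
  sim <- small_sim(N = 9, seed = 17)
  cfg <- fast_train_config(epochs = 3, seed = 8)
  ev1 <- cross_validate(sim$cohort, cfg, k = 3, runs = 1)
  ev2 <- cross_validate(sim$cohort, cfg, k = 3, runs = 1)
  expect_identical(ev1$predictions$pred, ev2$predictions$pred)
  # identical per-run metrics -> zero-width CI
  ev3 <- ev1
  ev3$runs <- rbind(ev1$runs, ev1$runs)
  ci <- fagnn:::t_interval(c(5, 5, 5))
  expect_equal(unname(ci["lower"]), 5)
  expect_equal(unname(ci["upper"]), 5)
})

test_that("group transfer evaluation computes delta MAE as a difference", {
  sim <- small_sim(N = 14, seed = 18)
  res <- group_transfer_eval(sim$cohort, list(diet = 0), list(diet = 1),
                             fast_train_config(epochs = 3), runs = 1, k = 2)
  expect_equal(res$delta_mae, mean(res$risk_mae) - mean(res$control_mae))
  expect_true(all(is.finite(res$risk_mae)))
  expect_error(group_transfer_eval(sim$cohort, list(diet = 0),
                                   list(diet = 3),
                                   fast_train_config(epochs = 2)),
               "empty")
})

test_that("no subject's own data leaks into its training fold", {
  sim <- small_sim(N = 10, seed = 19)
  ids <- vapply(sim$cohort$subjects, `[[`, "", "id")
  folds <- make_folds(ids, k = 5, seed = 2)
  for (f in 1:5) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    expect_length(intersect(test_ids, train_ids), 0L)
  }
  expect_setequal(unlist(lapply(1:5, function(f) names(folds)[folds == f])),
                  ids)
})
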