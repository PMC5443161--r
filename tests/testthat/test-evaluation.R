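test_that("kappa handles perfect, chance-level and degenerate matrices", {
  perfect <- rpbci:::as_confusion_matrix(diag(c(5, 5, 5)))
  expect_equal(cohen_kappa(perfect), 1)
  # balanced truth, all predictions in one class -> chance level
  chance <- rpbci:::as_confusion_matrix(matrix(c(5, 0, 0, 5, 0, 0, 5, 0, 0),
                                               3, 3, byrow = TRUE))
  expect_equal(cohen_kappa(chance), 0)
  single <- rpbci:::as_confusion_matrix(matrix(c(7, 0, 0, 0), 2, 2))
  expect_error(cohen_kappa(single), "undefined")
})

test_that("kappa equals the observed-vs-expected agreement identity", {
  set.seed(40)
  for (i in 1:25) {
    h <- matrix(rpois(9, 20) + 1, 3, 3)
    k1 <- cohen_kappa(h)
    n <- sum(h)
    po <- sum(diag(h)) / n
    pe <- sum(rowSums(h) * colSums(h)) / n^2
    expect_equal(k1, 1 - (1 - po) / (1 - pe), tolerance = 1e-12)
    expect_true(k1 >= -1 && k1 <= 1)
  }
})

test_that("the bundled reference confusion matrix reproduces its statistics", {
  cm <- reference_confusion_odcs3_ddag()
  expect_equal(sum(cm), 10480)
  expect_equal(round(100 * per_class_accuracy(cm), 2),
               c(R = 72.37, I = 96.24, L = 77.79))
  expect_equal(round(cohen_kappa(cm), 4), 0.7701)
  expect_equal(accuracy(cm), sum(diag(cm)) / sum(cm))
})

test_that("fold plans chunk at the trial level, contiguously and exactly", {
  es <- make_counted_epochs(n_l = 90, n_r = 90, n_i = 180)
  # two epochs per trial: assign shared trial indices
  es$trial_index <- rep(1:180, each = 2)
  plan <- make_folds(es, n_chunks = 10, seed = 1)
  sizes <- vapply(plan$folds, function(f) length(f$test_trials), integer(1))
  expect_equal(sizes, rep(18L, 10))
  all_test <- unlist(lapply(plan$folds, `[[`, "test_trials"))
  expect_equal(sort(all_test), 1:180)
  expect_false(anyDuplicated(all_test) > 0)
  # same seed -> identical plan; contiguous chunks by default
  expect_identical(make_folds(es, 10, seed = 1), plan)
  expect_equal(plan$folds[[1]]$test_trials, 1:18)
  # a trial's epochs can never straddle chunks
  f1 <- plan$folds[[1]]
  epochs_in_test <- which(es$trial_index %in% f1$test_trials)
  expect_equal(length(epochs_in_test) %% 2, 0)
  expect_error(make_folds(subset_epochs(es, 1:8), 10), "at least 10")
})

test_that("a 390-trial dataset splits into chunks of 39", {
  es <- make_counted_epochs(n_l = 98, n_r = 97, n_i = 195)
  es$trial_index <- rep(1:195, each = 2)
  es390 <- subset_epochs(es, 1:390)
  es390$trial_index <- rep(1:390, each = 1)
  plan <- make_folds(es390, 10, seed = 2)
  expect_equal(vapply(plan$folds, function(f) length(f$test_trials),
                      integer(1)),
               rep(39L, 10))
})

test_that("the leakage guard rejects corrupted fold plans", {
  es <- make_counted_epochs(n_l = 20, n_r = 20, n_i = 40)
  es$trial_index <- rep(1:40, each = 2)
  plan <- make_folds(es, 10, seed = 1)
  # deliberately corrupt: copy a test trial into the training side
  bad <- plan
  bad$folds[[1]]$train_trials <- c(bad$folds[[1]]$train_trials,
                                   bad$folds[[1]]$test_trials[1])
  expect_error(rpbci:::check_fold_plan(bad, es), "leakage")
  expect_error(run_protocol(es, method = "ddag", grid = tiny_grid(),
                            plan = bad, seed = 1),
               "leakage")
  # overlapping test chunks
  bad2 <- plan
  bad2$folds[[2]]$test_trials[1] <- bad2$folds[[1]]$test_trials[1]
  expect_error(rpbci:::check_fold_plan(bad2, es), "leakage")
  expect_silent(rpbci:::check_fold_plan(plan, es))
})

test_that("separable synthetic data yields kappa 1 in every fold", {
  sim <- simulate_epochs(small_sim_cfg(n_trials_per_side = 10, seed = 50,
                                       noise_pink = 0.3, noise_alpha = 0.2))
  rt <- run_protocol(sim$epochs, method = "ddag", algorithm = "FLDA",
                     grid = tiny_grid(), n_chunks = 10, seed = 4)
  expect_true(all(rt$folds$kappa == 1))
  expect_equal(rt$mean_kappa, 1)
  expect_equal(rt$pooled_kappa, 1)
  # pooled confusion is the sum of fold confusions
  expect_equal(sum(rt$pooled_confusion), 2 * 20)
  expect_equal(sum(rt$folds[, grep("^h_", names(rt$folds))]),
               sum(rt$pooled_confusion))
})

test_that("shuffling the labels destroys performance to chance level", {
  sim <- simulate_epochs(small_sim_cfg(n_trials_per_side = 15, seed = 51))
  es <- sim$epochs
  # permute the full label vector: any residual kappa is pure overfit
  set.seed(99)
  es$labels <- sample(es$labels)
  rt <- run_protocol(es, method = "ddag", algorithm = "FLDA",
                     grid = tiny_grid(), n_chunks = 10, seed = 4)
  # this dataset scores ~1 with intact labels; destruction means collapse
  # to the (noisy, small-sample) chance band. The tight +/-0.1 bound is
  # exercised on replicated shuffles in the acceptance suite.
  expect_lt(rt$mean_kappa, 0.3)
})

test_that("result tables round-trip through CSV export", {
  sim <- simulate_epochs(small_sim_cfg(n_trials_per_side = 10, seed = 52))
  rt <- run_protocol(sim$epochs, method = "dbt", algorithm = "LPGM",
                     grid = tiny_grid(), n_chunks = 10, seed = 2)
  dir <- withr::local_tempdir()
  files <- write_results(rt, dir)
  expect_true(all(file.exists(file.path(dir, c("dbt_folds.csv",
                                               "dbt_summary.csv")))))
  back <- data.table::fread(file.path(dir, "dbt_folds.csv"))
  expect_equal(nrow(back), 10)
  expect_equal(back$kappa, rt$folds$kappa)
})
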