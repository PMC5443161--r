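test_that("simulation is a pure function of the seed", {
  cfg <- small_sim_cfg(n_trials_per_side = 4, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth$pattern_left, b$ground_truth$pattern_left)
  c <- simulate_dataset(small_sim_cfg(n_trials_per_side = 4, seed = 8))
  expect_false(identical(a$trials[[1]]$eeg, c$trials[[1]]$eeg))
})

test_that("valid-only configurations survive screening completely", {
  cfg <- small_sim_cfg(n_trials_per_side = 10, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_length(sim$trials, 20)
  scr <- screen_trials(sim$trials)
  expect_length(scr$trials, 20)
  expect_equal(scr$report$n_rejected_reactive, 0)
  # epochs: one idle + one movement per valid trial, balanced sides
  es <- epochs_from_trials(scr$trials)
  expect_equal(unname(class_counts(es)[c("R", "I", "L")]), c(10L, 20L, 10L))
  expect_equal(dim(es$data)[2], 100) # 500 ms at 200 Hz
})

test_that("invalid-trial fractions violate screening at the configured rates", {
  cfg <- small_sim_cfg(n_trials_per_side = 20, seed = 3,
                       p_reactive = 0.1, p_multipress = 0.05)
  sim <- simulate_dataset(cfg)
  scr <- screen_trials(sim$trials)
  expect_equal(scr$report$n_rejected_reactive, round(0.1 * 40))
  expect_equal(scr$report$n_rejected_multipress, round(0.05 * 40))
  expect_length(scr$trials, 40 - round(0.1 * 40) - round(0.05 * 40))
})

test_that("planted patterns are lateralized mirrors concentrated on motor channels", {
  cfg <- sim_config(n_trials_per_side = 2, seed = 1)
  gt <- simulate_dataset(cfg)$ground_truth
  nm <- cfg$channel_names
  pl <- gt$pattern_left; pr <- gt$pattern_right
  expect_equal(sqrt(sum(pl^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(pr^2)), 1, tolerance = 1e-12)
  # left-hand movement loads harder on the right hemisphere and vice versa
  expect_gt(pl[match("C2", nm)], pl[match("C1", nm)])
  expect_gt(pr[match("C1", nm)], pr[match("C2", nm)])
  expect_equal(pl[match("C2", nm)] / pl[match("C1", nm)],
               cfg$lateralization_ratio)
  # mirror symmetry
  expect_equal(pl[match(c("C2", "C4", "CP2", "CP4"), nm)],
               pr[match(c("C1", "C3", "CP1", "CP3"), nm)])
  expect_equal(sum(pl[-match(c("C1", "C2", "C3", "C4", "CP1", "CP2", "CP3",
                               "CP4", "Cz", "CPz", "FCz"), nm)]), 0)
})

test_that("press latencies follow the truncated protocol distribution", {
  cfg <- sim_config(n_trials_per_side = 150, fs_acquire = 100, seed = 5,
                    n_channels = 2, n_eog = 2, channel_names = c("a", "b"))
  sim <- simulate_dataset(cfg)
  lat <- vapply(sim$trials, function(tr) tr$press_times[1] - tr$cue_time,
                numeric(1))
  expect_true(all(lat >= 2))
  expect_equal(mean(lat), 5.1, tolerance = 0.35) # truncation raises the mean
  expect_gt(sd(lat), 1)
})

test_that("zero lateralization makes left and right indistinguishable", {
  cfg <- small_sim_cfg(n_trials_per_side = 24, seed = 6,
                       lateralization_ratio = 1)
  sim <- simulate_epochs(cfg)
  es <- sim$epochs
  # held-out evaluation: the PSTF must never see the test trials, otherwise
  # a beamformer fitted on exchangeable noise can separate it spuriously
  trials <- unique(es$trial_index)
  train_es <- subset_epochs(es, which(es$trial_index %in% trials[1:32]))
  test_es <- subset_epochs(es, which(!es$trial_index %in% trials[1:32]))
  fit <- fit_ternary(train_es, method = "dbt", algorithm = "FLDA",
                     grid = tiny_grid(), seed = 2)
  # movement vs idle stays easy
  p_im <- rpbci:::node_probs(fit$problems[["I-M"]], fit, test_es)
  truth_im <- ifelse(test_es$labels == "I", "I", "M")
  acc_im <- mean(ifelse(p_im[, "I"] >= 0.5, "I", "M") == truth_im)
  expect_gt(acc_im, 0.85)
  # left vs right collapses to chance
  mov <- subset_epochs(test_es, which(test_es$labels != "I"))
  p_rl <- rpbci:::node_probs(fit$problems[["R-L"]], fit, mov)
  acc_rl <- mean(ifelse(p_rl[, "R"] >= 0.5, "R", "L") == mov$labels)
  expect_lt(abs(acc_rl - 0.5), 0.25)
})

test_that("the separability suite scales only the planted signal", {
  suite <- make_separability_suite(c(0, 1), small_sim_cfg(n_trials_per_side = 3,
                                                          seed = 9))
  expect_named(suite, c("snr_0", "snr_1"))
  gt0 <- suite[[1]]$ground_truth
  gt1 <- suite[[2]]$ground_truth
  expect_identical(gt0$pattern_left, gt1$pattern_left)
  # level 0 carries no class signal: the trial-mean difference between the
  # two datasets is exactly the planted RP component
  t1 <- suite[[1]]$trials[[1]]; t2 <- suite[[2]]$trials[[1]]
  expect_identical(t1$press_times, t2$press_times)
  diff <- t2$eeg - t1$eeg
  expect_gt(max(abs(diff)), 0) # signal present at level 1
  # the difference lives on the planted pattern direction only
  pat <- if (t1$cue_side == "L") gt1$pattern_left else gt1$pattern_right
  col <- which.max(colSums(abs(diff)))
  expect_equal(abs(cosine(diff[, col], pat)), 1, tolerance = 1e-9)
})

test_that("classification performance is monotone in the signal level", {
  cfg <- small_sim_cfg(n_trials_per_side = 10, seed = 12)
  suite <- make_separability_suite(c(0, 0.4, 2), cfg)
  kappas <- vapply(suite, function(sim) {
    scr <- screen_trials(sim$trials)
    es <- epochs_from_trials(scr$trials, channel_names = cfg$channel_names)
    rt <- run_protocol(es, method = "dbt", algorithm = "FLDA",
                       grid = tiny_grid(), n_chunks = 10, seed = 3)
    rt$mean_kappa
  }, numeric(1))
  expect_lt(abs(kappas[["snr_0"]]), 0.25) # no signal: near chance
  expect_gte(kappas[["snr_2"]], kappas[["snr_0.4"]] - 0.05)
  expect_gte(kappas[["snr_2"]], 0.9)
})
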