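test_that("generated datasets satisfy the data-model invariants", {
  recs <- tiny_recordings()
  for (rec in recs) {
    expect_s3_class(rec, "emo_recording")
    for (tr in rec$trials) {
      expect_gte(tr$valence, 1); expect_lte(tr$valence, 9)
      expect_gte(tr$arousal, 1); expect_lte(tr$arousal, 9)
      expect_equal(ncol(tr$eeg), ncol(tr$peripheral))
      # low/high ranges never straddle the 4.5 cut
      expect_false(tr$valence > 4 && tr$valence < 5)
    }
  }
})

test_that("generation is deterministic and round-trips serialization", {
  spec <- generator_spec(n_subjects = 1L, n_trials = 3L,
                         trial_length_s = 4, rate_hz = 32, seed = 17L)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  dir <- withr::local_tempdir()
  write_dataset(spec, dir)
  files <- list.files(dir, pattern = "\\.h5$", full.names = TRUE)
  expect_length(files, 1L)
  back <- read_recording(files[1])
  expect_equal(back$trials[[2]]$eeg, a[[1]]$trials[[2]]$eeg, tolerance = 0)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("label marginals follow the label rule", {
  spec <- generator_spec(n_subjects = 6L, n_trials = 30L,
                         trial_length_s = 1, rate_hz = 32,
                         label_rule = list(p_high = 0.3), seed = 23L)
  recs <- generate_dataset(spec)
  v <- unlist(lapply(recs, function(r) vapply(r$trials, `[[`, 0, "valence")))
  p_hat <- mean(dichotomize(v) == "high")
  # 180 Bernoulli(0.3) draws: 3 binomial sd ~ 0.102
  expect_lt(abs(p_hat - 0.3), 0.11)
})

test_that("ground truth lists the designated channels and pairs", {
  spec <- generator_spec(n_coupled = 4L)
  gt <- ground_truth(spec)
  expect_identical(gt$coupled_channels, EMOTIV_14[1:4])
  expect_equal(nrow(gt$coupled_pairs), 6L)  # choose(4, 2)
  expect_true(all(gt$coupled_pairs %in% gt$coupled_channels))
  expect_false(any(EMOTIV_14[5:14] %in% gt$coupled_channels))
})

test_that("planted coupling separates classes in MI space", {
  # high-class mixing 0.8 vs low-class 0.1 on the designated subset
  spec <- generator_spec(n_subjects = 4L, n_trials = 20L,
                         trial_length_s = 4, rate_hz = 128, seed = 29L)
  recs <- generate_dataset(spec)
  gt <- ground_truth(spec)
  mi_by_class <- list(low = c(), high = c())
  for (rec in recs) for (tr in rec$trials) {
    win <- slide_windows(tr, rec$rate_hz)[[1]]
    W <- connectivity_matrix(win)
    pairs_mi <- W[gt$coupled_pairs]
    cls <- as.character(dichotomize(tr$valence))
    mi_by_class[[cls]] <- c(mi_by_class[[cls]], mean(pairs_mi))
  }
  pooled_sd <- sqrt((var(mi_by_class$low) + var(mi_by_class$high)) / 2)
  d <- (mean(mi_by_class$high) - mean(mi_by_class$low)) / pooled_sd
  expect_gt(d, 1)  # standardized effect size beyond 1
})

test_that("coupling monotonicity: stronger planted effect, higher accuracy", {
  # end-to-end, averaged over seeds at reduced scale
  accs <- vapply(c(0, 0.35, 0.7), function(eff) {
    mean(vapply(1:2, function(s) {
      spec <- generator_spec(n_subjects = 2L, n_trials = 10L,
                             trial_length_s = 8, rate_hz = 64,
                             coupling_effect = eff, peripheral_effect = 0,
                             seed = 500L + s)
      feats <- extract_features(generate_dataset(spec))
      subject_dependent_eval(feats, "valence", "xgb", seed = s,
                             learner_config = list(nrounds = 30L))$mean
    }, numeric(1)))
  }, numeric(1))
  expect_gte(accs[3], accs[1] - 0.05)
  expect_gte(accs[3], 0.75)   # large coupling alone is learnable
})

test_that("invalid generator specs are rejected", {
  expect_error(generator_spec(coupling_effect = 0.95), "exceed")
  expect_error(generator_spec(label_rule = list(high_range = c(4, 9))),
               "4.5")
  expect_error(generator_spec(trial_length_s = 1.7, rate_hz = 3), "integer")
})
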