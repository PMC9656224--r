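test_that("all learners separate well-separated clusters perfectly", {
  d <- separable_data()
  for (k in c("svm", "rf", "xgb")) {
    m <- train_classifier(k, d$X, d$y, seed = 1,
                          config = list(n_trees = 100L, nrounds = 50L))
    expect_equal(accuracy(predict(m, d$X), d$y), 1.0)
  }
})

test_that("learners are deterministic given a seed and error on one class", {
  d <- separable_data(n = 80L)
  for (k in c("svm", "rf", "xgb")) {
    m1 <- train_classifier(k, d$X, d$y, seed = 3,
                           config = list(n_trees = 25L, nrounds = 20L))
    m2 <- train_classifier(k, d$X, d$y, seed = 3,
                           config = list(n_trees = 25L, nrounds = 20L))
    expect_identical(predict(m1, d$X, type = "prob"),
                     predict(m2, d$X, type = "prob"))
  }
  one <- d$y == "low"
  expect_error(train_classifier("svm", d$X[one, ], d$y[one]),
               "single class")
})

test_that("null-label data scores near chance for svm/rf/xgb", {
  set.seed(21)
  n <- 300L
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("f", 1:20)
  y <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  folds <- rep(1:5, length.out = n)
  for (k in c("svm", "rf", "xgb")) {
    accs <- vapply(1:5, function(f) {
      m <- train_classifier(k, X[folds != f, ], y[folds != f], seed = f,
                            config = list(n_trees = 50L, nrounds = 30L))
      accuracy(predict(m, X[folds == f, ]), y[folds == f])
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.1)
  }
})

test_that("a memorizing forest reproduces its training labels", {
  d <- separable_data(n = 120L, p = 5L)
  m <- train_classifier("rf", d$X, d$y, seed = 2,
                        config = list(n_trees = 200L, min_node = 1L))
  expect_equal(accuracy(predict(m, d$X), d$y), 1.0)
})

test_that("the CNN learns planted separation and stays at chance on noise", {
  d <- separable_data(n = 240L, p = 40L, seed = 12)
  split <- seq_len(200L)
  m <- train_cnn(d$X[split, ], d$y[split],
                 cnn_architecture(epochs = 12L, seed = 1L))
  expect_s3_class(m, "emo_cnn")
  held <- predict_cnn(m, d$X[-split, ])
  expect_gte(accuracy(held, d$y[-split]), 0.9)
  # loss decreases over the first epochs on learnable data
  expect_lt(m$loss_trace[5], m$loss_trace[1])

  set.seed(13)
  ynull <- sample(d$y)
  mn <- train_cnn(d$X[split, ], ynull[split],
                  cnn_architecture(epochs = 6L, seed = 1L))
  expect_lt(abs(accuracy(predict_cnn(mn, d$X[-split, ]), ynull[-split]) - 0.5),
            0.2)
  expect_error(train_cnn(cbind(d$X[split, ], NA), d$y[split]),
               "non-finite")
})

test_that("accuracy is the agreement fraction", {
  expect_equal(accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(accuracy(c(1, 1), c(0, 0)), 0)
  expect_equal(accuracy(c("a", "b", "a", "a"), c("a", "b", "b", "a")), 0.75)
})

test_that("subject-dependent protocol on planted data", {
  feats <- planted_shared_features()
  rep <- subject_dependent_eval(feats, "valence", "xgb", seed = 1,
                                learner_config = list(nrounds = 40L))
  expect_s3_class(rep, "emo_report")
  expect_length(rep$per_unit, 4L)
  expect_gte(rep$mean, 0.9)
  expect_equal(rep$mean, mean(rep$per_unit))
  expect_equal(rep$sd, sd(rep$per_unit))
  # reproducibility
  rep2 <- subject_dependent_eval(feats, "valence", "xgb", seed = 1,
                                 learner_config = list(nrounds = 40L))
  expect_identical(rep$per_unit, rep2$per_unit)
})

test_that("split hygiene: test rows never feed any training stage", {
  feats <- planted_shared_features()
  rep <- subject_dependent_eval(feats, "valence", "svm", seed = 2)
  for (s in names(rep$fingerprint)) {
    fp <- rep$fingerprint[[s]]
    expect_length(intersect(fp$train, fp$test), 0L)
    rows <- which(feats$subject_id == s)
    expect_setequal(c(fp$train, fp$test), rows)
  }
  loo <- loocv_eval(feats, "valence", "svm", seed = 2)
  for (s in names(loo$fingerprint)) {
    fp <- loo$fingerprint[[s]]
    expect_setequal(fp$test, which(feats$subject_id == s))
    expect_setequal(fp$train, which(feats$subject_id != s))
  }
  # scrambling the held-out subject's features must not change the model
  # fitted for that fold: its per-fold accuracy changes only through its
  # own rows, while other folds that train on it do change
  fm <- feature_matrix(feats, "valence")
  s1 <- unique(fm$subject)[1]
  test_idx <- which(fm$subject == s1)
  train_idx <- which(fm$subject != s1)
  m <- train_classifier("svm", fm$X[train_idx, ], fm$y[train_idx], seed = 9)
  X2 <- fm$X
  set.seed(99)
  X2[test_idx, ] <- matrix(rnorm(length(test_idx) * ncol(X2)),
                           length(test_idx))
  m2 <- train_classifier("svm", X2[train_idx, ], fm$y[train_idx], seed = 9)
  probe <- fm$X[train_idx[1:5], ]
  expect_identical(predict(m, probe, type = "prob"),
                   predict(m2, probe, type = "prob"))
})

test_that("LOOCV protocol: fold count, errors, trial grouping option", {
  feats <- tiny_features()
  rep <- loocv_eval(feats, "arousal", "svm", seed = 1)
  expect_length(rep$per_unit, 2L)  # one fold per subject
  one <- feats[feats$subject_id == feats$subject_id[1], ]
  expect_error(loocv_eval(one, "valence", "svm"), "at least 2 subjects")

  g <- subject_dependent_eval(planted_shared_features(), "valence", "svm",
                              group_by_trial = TRUE, seed = 3)
  # grouped split: no trial contributes windows to both sides
  feats2 <- planted_shared_features()
  for (s in names(g$fingerprint)) {
    fp <- g$fingerprint[[s]]
    key <- paste(feats2$subject_id, feats2$trial_id)
    expect_length(intersect(unique(key[fp$train]), unique(key[fp$test])), 0L)
  }
})

test_that("single-class subjects are excluded with a warning", {
  feats <- tiny_features()
  skew <- feats
  # force one subject to a single valence class
  s1 <- skew$subject_id == unique(skew$subject_id)[1]
  skew$valence[s1] <- 8
  expect_warning(
    rep <- subject_dependent_eval(skew, "valence", "svm", seed = 1),
    "single")
  expect_length(rep$per_unit, length(unique(skew$subject_id)) - 1L)
})

test_that("reports serialize to JSON with recomputable aggregates", {
  rep <- loocv_eval(tiny_features(), "valence", "svm", seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$mean, mean(unlist(got$per_unit)))
  expect_equal(got$sd, sd(unlist(got$per_unit)))
  expect_true(all(unlist(got$per_unit) >= 0 & unlist(got$per_unit) <= 1))
})
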