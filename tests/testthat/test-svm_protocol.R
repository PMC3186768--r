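test_that("the RBF kernel matches its closed form and stays in (0, 1]", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 0.7), 1)
  expect_equal(rbf_kernel(c(5, -1), c(0, 4), gamma = 0), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1), tolerance = 1e-12)
  expect_error(rbf_kernel(1:3, 1:4, 1), "equal length")
  set.seed(5)
  for (rep in 1:20) {
    u <- rnorm(4); v <- rnorm(4); g <- runif(1, 0, 5)
    k <- rbf_kernel(u, v, g)
    expect_gt(k, 0); expect_lte(k, 1)
  }
})

test_that("kernel matrices are symmetric positive semi-definite", {
  set.seed(6)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 4), 30, 4)
    gamma <- runif(1, 0.05, 2)
    K <- outer(seq_len(30), seq_len(30),
               Vectorize(function(a, b) rbf_kernel(X[a, ], X[b, ], gamma)))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("feature scaling is exact, reapplied verbatim, and invertible", {
  set.seed(7)
  X <- matrix(rnorm(50 * 3, mean = 5, sd = 3), 50, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sc <- scale_features(X)
  expect_equal(colMeans(sc$X), c(a = 0, b = 0, c = 0), tolerance = 1e-9)
  expect_equal(apply(sc$X, 2, sd), c(a = 1, b = 1, c = 1), tolerance = 1e-9)
  # round trip
  expect_equal(apply_scaler(sc$scaler, sc$X, invert = TRUE), X,
               tolerance = 1e-9, ignore_attr = TRUE)
  # scaling an already-scaled matrix re-centers: not idempotent by design
  resc <- scale_features(sc$X)
  expect_false(isTRUE(all.equal(resc$scaler$center, sc$scaler$center)))
  Xc <- X; Xc[, 2] <- 1
  expect_error(scale_features(Xc), "constant feature")
})

test_that("grid search finds separating parameters and is deterministic", {
  ds <- synthetic_feature_dataset(n_per_class = 50, n_informative = 2,
                                  n_noise = 0, separation = 6, seed = 30)
  cfg <- svm_config(C_grid = c(0.5, 2, 8), gamma_grid = c(0.01, 0.1, 1),
                    folds = 3, seed = 12)
  gs <- grid_search(ds$X, ds$labels, cfg)
  expect_equal(gs$cv_accuracy, 1)          # margin >> noise: some pair is perfect
  gs2 <- grid_search(ds$X, ds$labels, cfg)
  expect_identical(gs, gs2)
  # 1x1 grid returns that pair
  one <- grid_search(ds$X, ds$labels,
                     svm_config(C_grid = 2, gamma_grid = 0.25, folds = 3,
                                seed = 12))
  expect_equal(one$C, 2); expect_equal(one$gamma, 0.25)
  few <- c(1:3, 51:53)                     # 3 per class, fewer than 5 folds
  expect_error(grid_search(ds$X[few, ], ds$labels[few],
                           svm_config(folds = 5, seed = 1)),
               "fold count")
})

test_that("trained models separate well-separated clusters and expose finite decisions", {
  ds <- synthetic_feature_dataset(n_per_class = 40, n_informative = 2,
                                  n_noise = 1, separation = 6, seed = 31)
  model <- train_svm(ds$X, ds$labels, C = 10, gamma = 0.2)
  pred <- predict(model, ds$X)
  expect_equal(pred$label, ds$labels)      # training accuracy 1.0
  expect_true(all(is.finite(pred$decision)))
  expect_true(all(pred$label %in% c(0L, 1L)))
  # decision value is zero midway between one duplicated point per class
  X2 <- matrix(c(1, -1, 1, -1), 4, 1, dimnames = list(NULL, "f1"))
  m2 <- train_svm(X2, c(1, 0, 1, 0), C = 100, gamma = 0.5)
  expect_equal(predict(m2, matrix(0, 1, 1,
                                  dimnames = list(NULL, "f1")))$decision,
               0, tolerance = 1e-6)
})

test_that("model predictions agree with the backing libsvm solver", {
  ds <- synthetic_feature_dataset(n_per_class = 60, n_informative = 2,
                                  n_noise = 4, separation = 1.5, seed = 32)
  model <- train_svm(ds$X, ds$labels, C = 2, gamma = 0.1)
  sc <- scale_features(ds$X)
  ref <- e1071::svm(sc$X, factor(ds$labels, levels = c(0, 1)),
                    kernel = "radial", cost = 2, gamma = 0.1, scale = FALSE)
  expect_equal(predict(model, ds$X)$label,
               as.integer(as.character(predict(ref, sc$X))))
})

test_that("serialized models round-trip through the plain-text container", {
  ds <- synthetic_feature_dataset(n_per_class = 30, n_informative = 2,
                                  n_noise = 2, separation = 2, seed = 33)
  model <- train_svm(ds$X, ds$labels, C = 4, gamma = 0.25)
  f <- tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$features, model$features)
  expect_equal(back$scaler$center, model$scaler$center)
  p1 <- predict(model, ds$X); p2 <- predict(back, ds$X)
  expect_equal(p1$label, p2$label)
  expect_equal(p1$decision, p2$decision, tolerance = 1e-12)
})

test_that("the repeated-split protocol has the stated cardinality and determinism", {
  ds <- study_shaped_dataset(seed = 44, separation = 3, n_noise = 6)
  split <- build_external_set(ds, 16, seed = 44)
  cfg <- protocol_cfg(seed = 13)
  res <- run_protocol(ds, split, n_runs = 8, cfg = cfg, max_features = 6)
  expect_length(res$runs, 8L)
  expect_equal(res$n_runs, 8L)
  res2 <- run_protocol(ds, split, n_runs = 8, cfg = cfg, max_features = 6)
  expect_equal(res$means, res2$means, tolerance = 1e-12)
  expect_equal(res$runs[[3]]$features, res2$runs[[3]]$features)
  # separable data: high test accuracy
  expect_gte(res$means$ACC[res$means$set == "test"], 95)
  # per-run test sets hold 33 of the 165-compound pool
  n_test <- res$runs[[1]]$test$TP + res$runs[[1]]$test$TN +
    res$runs[[1]]$test$FP + res$runs[[1]]$test$FN
  expect_equal(n_test, 33)
})

test_that("a fixed feature set skips per-run selection", {
  ds <- study_shaped_dataset(seed = 45, separation = 3, n_noise = 4)
  split <- build_external_set(ds, 16, seed = 45)
  res <- run_protocol(ds, split, n_runs = 3, cfg = protocol_cfg(14),
                      features = c("inf1", "inf2"))
  expect_true(all(vapply(res$runs, function(r) {
    setequal(r$features, c("inf1", "inf2"))
  }, logical(1))))
})

test_that("the final-model rule filters on gap, then size, then external MCC", {
  cand <- data.frame(train_acc = c(94, 82, 80, 81),
                     test_acc = c(88, 78, 77, 78),
                     n_features = c(48, 12, 6, 6),
                     external_mcc = c(0.60, 0.55, 0.52, 0.49))
  sel <- select_final_model(cand)
  expect_equal(sel$ledger$status[1], "excluded: gap")   # gap 6 is out
  expect_equal(sel$winner, 3L)       # 6 descriptors, higher external MCC
  expect_equal(sel$ledger$status[4], "lost: lower external MCC")
  expect_equal(sel$ledger$status[2], "lost: more descriptors")
  # two survivors with 12 and 6 descriptors and equal MCC: 6 wins
  cand2 <- data.frame(train_acc = c(80, 80), test_acc = c(78, 78),
                      n_features = c(12, 6), external_mcc = c(0.5, 0.5))
  expect_equal(select_final_model(cand2)$winner, 2L)
  # single candidate under threshold returned unchanged
  expect_equal(select_final_model(cand2[2, ])$winner, 1L)
  # no survivor: explicit error, never silently relax
  expect_error(select_final_model(data.frame(train_acc = 95, test_acc = 80,
                                             n_features = 3,
                                             external_mcc = 0.9)),
               "below 5")
})
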