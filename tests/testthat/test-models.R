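test_that("model specs validate hyperparameters against the registry", {
  expect_error(modelSpec("gbt", list(bogus = 1)), "bogus")
  expect_error(modelSpec("banana"), "arg")
  sp <- modelSpec("rmlr", list(C = 10, l1_ratio = 0.5), seed = 3L)
  expect_equal(sp$params$C, 10)
  expect_equal(sp$params$penalty, "elasticnet")
})

test_that("all three families separate noiseless clusters perfectly", {
  train <- separable_examples(60, seed = 1)
  test <- separable_examples(40, seed = 2)
  for (fam in c("rmlr", "gbt", "nn")) {
    # exact split search for the trees: with sigma -> 0 the clusters are
    # point masses and histogram bin edges would sit on cluster boundaries
    spec <- if (fam == "gbt") modelSpec(fam, list(tree_method = "exact"),
                                        seed = 5L)
            else modelSpec(fam, seed = 5L)
    m <- trainModel(spec, train)
    pred <- predictProba(m, test)
    expect_equal(mean(pred$call == test$truth_genotype), 1,
                 label = paste(fam, "holdout accuracy"))
    # simplex contract
    expect_true(all(abs(pred$p_AA + pred$p_AB + pred$p_BB - 1) < 1e-6))
    expect_true(all(pred$p_AA >= 0 & pred$p_AB >= 0 & pred$p_BB >= 0))
  }
})

test_that("prediction aligns with input order and validates features", {
  train <- separable_examples(40, seed = 1)
  m <- trainModel(modelSpec("rmlr"), train)
  test <- separable_examples(20, seed = 3)
  p1 <- predictProba(m, test)
  perm <- sample(nrow(test))
  p2 <- predictProba(m, test[perm, ])
  expect_equal(p2$p_AB, p1$p_AB[perm], tolerance = 1e-12)
  expect_error(predictProba(m, test[setdiff(names(test), "theta")]),
               "theta")
})

test_that("training needs all three classes and fails loudly otherwise", {
  train <- separable_examples(30, seed = 1)
  two <- train[train$truth_genotype != "BB", ]
  expect_error(trainModel(modelSpec("rmlr"), two), "three")
})

test_that("deterministic families reproduce predictions under a fixed seed", {
  train <- separable_examples(50, seed = 4)
  test <- separable_examples(20, seed = 5)
  for (fam in c("rmlr", "gbt")) {
    m1 <- trainModel(modelSpec(fam, seed = 9L), train)
    m2 <- trainModel(modelSpec(fam, seed = 9L), train)
    expect_identical(predictProba(m1, test), predictProba(m2, test),
                     label = fam)
  }
  expect_equal(trainModel(modelSpec("gbt", seed = 9L), train)$meta$data_hash,
               trainModel(modelSpec("gbt", seed = 9L), train)$meta$data_hash)
})

test_that("unit class weights reproduce unweighted training", {
  train <- separable_examples(50, seed = 4)
  test <- separable_examples(20, seed = 5)
  w1 <- c(AA = 1, AB = 1, BB = 1)
  for (fam in c("rmlr", "gbt")) {
    m_u <- trainModel(modelSpec(fam, seed = 2L), train)
    m_w <- trainModel(modelSpec(fam, seed = 2L), train, weights = w1)
    expect_equal(predictProba(m_w, test)$p_AB, predictProba(m_u, test)$p_AB,
                 tolerance = 1e-9, label = fam)
  }
})

test_that("RMLR coefficients stay finite and shrink with regularization", {
  train <- separable_examples(60, seed = 6)
  mag <- vapply(c(10, 0.1, 0.001), function(C) {
    m <- trainModel(modelSpec("rmlr", list(C = C)), train)
    co <- glmnet::coef.glmnet(m$fit$fit, s = m$fit$lambda)
    sum(vapply(co, function(b) sum(abs(as.matrix(b)[-1, ])), numeric(1)))
  }, numeric(1))
  expect_true(all(is.finite(mag)))
  expect_true(mag[1] > mag[2], info = "weaker regularization, larger coefs")
  expect_true(mag[2] > mag[3])
})

test_that("group CV never splits an individual and scores every grid point", {
  train <- separable_examples(80, inds = paste0("i", 1:7), seed = 8)
  gs <- gridSearch("rmlr", list(C = c(1, 0.5)), train, n_folds = 7, seed = 3)
  expect_equal(nrow(gs$scores), 2)
  expect_equal(sort(unique(unname(gs$folds))), 1:7)
  # leave-one-individual-out: each fold holds exactly one individual
  expect_equal(length(gs$folds), 7)
  expect_error(gridSearch("rmlr", list(), train, n_folds = 20), "exceeds")

  # single grid point: that point wins trivially
  g1 <- gridSearch("rmlr", list(C = 1), train, n_folds = 3, seed = 3)
  expect_equal(g1$best$params$C, 1)
})

test_that("the intact grid point dominates a crippled one", {
  train <- separable_examples(80, inds = paste0("i", 1:6), seed = 9)
  # C = 1e-6 regularizes the model into the prior; C = 1 separates cleanly
  gs <- gridSearch("rmlr", list(C = c(1e-6, 1)), train, n_folds = 3, seed = 2)
  expect_equal(gs$best$params$C, 1)
  expect_lt(min(gs$scores$mean_neg_log_loss),
            max(gs$scores$mean_neg_log_loss))
})

test_that("oracle posteriors reach the entropy floor of the fixture", {
  test <- separable_examples(50, seed = 10)
  onehot <- matrix(1e-15, nrow(test), 3,
                   dimnames = list(NULL, c("AA", "AB", "BB")))
  onehot[cbind(seq_len(nrow(test)), match(test$truth_genotype,
                                          c("AA", "AB", "BB")))] <- 1
  # a perfectly calibrated oracle on a noiseless fixture: log loss -> 0
  expect_lt(negLogLoss(onehot / rowSums(onehot), test$truth_genotype), 1e-10)
})

test_that("final fit uses class reweighting over the full training data", {
  train <- separable_examples(50, seed = 11)
  # unbalance the classes
  train <- train[-(1:30), ]
  spec <- modelSpec("gbt", list(n_estimators = 30L))
  m <- fitFinal("gbt", spec, train)
  expect_s3_class(m, "TrainedModel")
  expect_equal(m$meta$n, nrow(train))
  expect_error(fitFinal("rmlr", spec, train), "family")
})

test_that("Platt calibration returns simplex posteriors and helps log loss", {
  sim <- sim_small()
  flt <- qcFilter(sim$x)
  ex <- makeExamples(buildFeatures(flt$kept), buildTruth(flt$kept))
  sp <- splitByIndividual(ex, c("H1", "O3"))
  calib_ind <- sp$test$individual_id == "O3"
  m <- trainModel(modelSpec("gbt", list(n_estimators = 40L), seed = 1L),
                  sp$train)
  mc <- calibrateModel(m, sp$test[calib_ind, ])
  pr <- predictProba(mc, sp$test[!calib_ind, ])
  expect_true(all(abs(pr$p_AA + pr$p_AB + pr$p_BB - 1) < 1e-9))
  raw <- predictProba(m, sp$test[!calib_ind, ])
  truth <- sp$test$truth_genotype[!calib_ind]
  expect_lt(negLogLoss(pr, truth), negLogLoss(raw, truth) + 0.02)
})

test_that("model artifacts round-trip through save/load", {
  train <- separable_examples(40, seed = 12)
  test <- separable_examples(10, seed = 13)
  m <- trainModel(modelSpec("gbt", list(n_estimators = 20L)), train)
  dir <- withr::local_tempdir()
  saveModel(m, dir)
  expect_true(all(file.exists(file.path(dir, c("model.rds",
                                               "normalizer.json",
                                               "manifest.json")))))
  m2 <- loadModel(dir)
  expect_equal(predictProba(m2, test), predictProba(m, test))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$family, "gbt")
})
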