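#' Model specification
#'
#' Three classifier families recall genotypes from the engineered features:
#'
#' * `rmlr` — regularized multinomial logistic regression (elastic net,
#'   via glmnet). Hyperparameters: `C` (inverse regularization strength,
#'   sklearn convention; mapped to `lambda = 1/(C * n)`), `penalty`
#'   (`"elasticnet"`), `l1_ratio` (elastic-net mixing, glmnet `alpha`).
#' * `gbt` — gradient-boosted trees (xgboost, multiclass softmax
#'   cross-entropy objective, per-class probabilities). Hyperparameters:
#'   `n_estimators`, `learning_rate`, `max_depth`, `gamma` (complexity
#'   threshold for further splits), `min_child_weight` (minimum split
#'   size), `subsample`, `tree_method` (`"hist"` default; `"exact"` places
#'   split points mid-gap, which matters for tightly separated clusters).
#' * `nn` — a small feed-forward network (three hidden layers, Leaky ReLU
#'   activations, softmax output) trained with Adam on categorical
#'   cross-entropy; implemented natively in the package. Hyperparameters:
#'   `hidden` (layer sizes, default `c(50, 100, 50)`), `learning_rate`,
#'   `epochs`, `batch_size`.
#'
#' @param family one of `"rmlr"`, `"gbt"`, `"nn"`.
#' @param params named list of family hyperparameters; unknown names are
#'   rejected against the registry above.
#' @param seed integer seed controlling all stochastic elements
#'   (subsampling, initialization, batching).
#' @return a `ModelSpec`.
#' @export
modelSpec <- function(family = c("rmlr", "gbt", "nn"), params = list(),
                      seed = 1L) {
  family <- match.arg(family)
  defaults <- .param_registry[[family]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown ", family, " hyperparameter(s): ",
         paste(unknown, collapse = ", "))
  structure(list(family = family,
                 params = modifyList(defaults, params),
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

.param_registry <- list(
  rmlr = list(C = 1, penalty = "elasticnet", l1_ratio = 0.001),
  gbt = list(n_estimators = 100L, learning_rate = 0.3, max_depth = 6L,
             gamma = 0, min_child_weight = 1, subsample = 1,
             tree_method = "hist"),
  nn = list(hidden = c(50L, 100L, 50L), learning_rate = 0.01,
            epochs = 50L, batch_size = 256L)
)

#' @export
print.ModelSpec <- function(x, ...) {
  cat("ModelSpec<", x$family, "> seed=", x$seed, "\n", sep = "")
  for (p in names(x$params))
    cat("  ", p, " = ", paste(x$params[[p]], collapse = ","), "\n", sep = "")
  invisible(x)
}

.label_factor <- function(labels) {
  y <- factor(labels, levels = GENO_LEVELS)
  if (anyNA(y)) stop("labels must be AA/AB/BB")
  if (nlevels(droplevels(y)) < 3)
    stop("all three genotype classes must be present in training data")
  y
}

.feature_matrix <- function(df, features) {
  miss <- setdiff(features, names(df))
  if (length(miss))
    stop("feature(s) missing from data: ", paste(miss, collapse = ", "))
  as.matrix(df[features])
}

#' Train a genotype classifier
#'
#' Fits one model of the requested family on labeled examples. A z-score
#' [fitNormalizer()] is fit on the *training* data (or supplied prefit) and
#' stored in the model, so prediction-time inputs are raw features. `rmlr`
#' and `gbt` are deterministic under a fixed seed; `nn` is deterministic up
#' to floating-point reduction order.
#'
#' @param spec a [modelSpec()].
#' @param examples labeled examples from [makeExamples()] (feature columns
#'   plus `truth_genotype`).
#' @param features feature columns to use (default [featureNames()]).
#' @param weights optional named class weights (from [classWeights()]);
#'   `NULL` trains unweighted.
#' @param normalizer optional prefit `Normalizer`; default fits on
#'   `examples`.
#' @return a `TrainedModel` holding the fitted backend object, the
#'   normalizer, the feature list and training metadata.
#' @export
trainModel <- function(spec, examples, features = featureNames(),
                       weights = NULL, normalizer = NULL) {
  stopifnot(inherits(spec, "ModelSpec"))
  y <- .label_factor(examples$truth_genotype)
  if (is.null(normalizer))
    normalizer <- fitNormalizer(examples, intersect(features, names(examples)))
  feats <- normalizer$features
  nd <- applyNormalizer(normalizer, examples[feats])
  X <- .feature_matrix(nd, feats)
  w <- if (is.null(weights)) rep(1, nrow(X)) else unname(weights[as.character(y)])

  fit <- switch(spec$family,
    rmlr = .fit_rmlr(spec, X, y, w),
    gbt  = .fit_gbt(spec, X, y, w),
    nn   = .fit_nn(spec, X, y, w)
  )
  structure(list(spec = spec, fit = fit, normalizer = normalizer,
                 features = feats,
                 meta = list(n = nrow(X), seed = spec$seed,
                             classes = GENO_LEVELS,
                             data_hash = .data_fingerprint(X, y),
                             trained = format(Sys.time(), "%Y-%m-%d"))),
            class = "TrainedModel")
}

.data_fingerprint <- function(X, y) {
  sprintf("n%dxd%d-%.6e-%d", nrow(X), ncol(X), sum(X) + sum(X^2) / 7,
          sum(as.integer(y)))
}

.fit_rmlr <- function(spec, X, y, w) {
  p <- spec$params
  lambda <- 1 / (p$C * nrow(X))
  set.seed(spec$seed)
  fit <- glmnet::glmnet(X, y, family = "multinomial", weights = w,
                        alpha = p$l1_ratio,
                        lambda = c(lambda * 4, lambda), # short path, use last
                        standardize = FALSE)
  list(backend = "glmnet", fit = fit, lambda = lambda)
}

.fit_gbt <- function(spec, X, y, w) {
  p <- spec$params
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, weight = w)
  params <- list(objective = "multi:softprob", num_class = 3,
                 eta = p$learning_rate, max_depth = p$max_depth,
                 gamma = p$gamma, min_child_weight = p$min_child_weight,
                 subsample = p$subsample, tree_method = p$tree_method,
                 nthread = 1, seed = spec$seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = p$n_estimators, verbose = 0)
  list(backend = "xgboost", fit = fit)
}

.fit_nn <- function(spec, X, y, w) {
  p <- spec$params
  fit <- .mlp_train(X, as.integer(y) - 1L, hidden = p$hidden,
                    lr = p$learning_rate, epochs = p$epochs,
                    batch_size = p$batch_size, weights = w,
                    seed = spec$seed)
  list(backend = "mlp", fit = fit)
}

#' Predict genotype posteriors
#'
#' Applies a trained model to raw feature records. Posteriors lie on the
#' 3-simplex; the call is the argmax with ties broken in fixed class order
#' AA < AB < BB, and `q` is the Phred genotype quality of the call (see
#' [phredQuality()]).
#'
#' @param model a `TrainedModel`.
#' @param newdata data.frame containing the model's feature columns (raw
#'   scale) and, if present, `sample_id`/`snp_id` identifiers that are
#'   carried through.
#' @return a data.frame with any identifier columns plus `p_AA`, `p_AB`,
#'   `p_BB`, `call`, `q`, row-aligned with `newdata`.
#' @export
predictProba <- function(model, newdata) {
  stopifnot(inherits(model, "TrainedModel"))
  miss <- setdiff(model$features, names(newdata))
  if (length(miss))
    stop("feature name mismatch; missing: ", paste(miss, collapse = ", "))
  nd <- applyNormalizer(model$normalizer, newdata[model$features])
  X <- .feature_matrix(nd, model$features)
  P <- switch(model$fit$backend,
    glmnet = {
      pr <- predict(model$fit$fit, newx = X, type = "response",
                    s = model$fit$lambda)
      matrix(pr, nrow = nrow(X), ncol = 3,
             dimnames = list(NULL, dimnames(pr)[[2]]))
    },
    xgboost = {
      pr <- predict(model$fit$fit, xgboost::xgb.DMatrix(X))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = 3, byrow = TRUE)
      pr
    },
    mlp = .mlp_predict(model$fit$fit, X)
  )
  colnames(P) <- GENO_LEVELS
  P <- P / rowSums(P)
  if (!is.null(model$calibration))
    P <- .apply_calibration(model$calibration, P)
  call_ix <- max.col(P, ties.method = "first")
  ids <- intersect(c("sample_id", "individual_id", "snp_id", "dna_input_ng"),
                   names(newdata))
  out <- cbind(
    newdata[ids],
    data.frame(p_AA = P[, 1], p_AB = P[, 2], p_BB = P[, 3],
               call = GENO_LEVELS[call_ix],
               q = phredQuality(P[cbind(seq_len(nrow(P)), call_ix)]))
  )
  rownames(out) <- NULL
  out
}

#' Mean negative log loss of posterior predictions
#'
#' @param probs matrix of posteriors (columns AA, AB, BB) or a prediction
#'   data.frame from [predictProba()].
#' @param labels true genotypes (AA/AB/BB).
#' @param eps probability floor guarding `log(0)`.
#' @return mean negative log likelihood of the true labels.
#' @export
negLogLoss <- function(probs, labels, eps = 1e-15) {
  if (is.data.frame(probs))
    probs <- as.matrix(probs[c("p_AA", "p_AB", "p_BB")])
  y <- match(labels, GENO_LEVELS)
  stopifnot(!anyNA(y), nrow(probs) == length(y))
  -mean(log(pmax(probs[cbind(seq_along(y), y)], eps)))
}

#' Grid-search hyperparameters with group-wise cross-validation
#'
#' Folds group records by individual — every individual's records live in
#' exactly one fold, so validation individuals are never seen in training.
#' Every grid point is evaluated on every fold; the winner has the lowest
#' mean negative log loss, ties broken by first-in-grid order. With
#' `n_folds` equal to the number of training individuals this is
#' leave-one-individual-out.
#'
#' @param family model family (see [modelSpec()]).
#' @param grid named list of candidate hyperparameter values; the search
#'   covers their full cross product in `expand.grid` order.
#' @param examples labeled training examples.
#' @param n_folds number of folds; must not exceed the number of distinct
#'   individuals.
#' @param seed integer seed (fold assignment and model training).
#' @param features feature columns (default [featureNames()]).
#' @param weights optional class weights applied during fold training.
#' @return list with `best` (the winning [modelSpec()]), `scores` (a
#'   data.frame of grid points with per-fold and mean negative log loss)
#'   and `folds` (individual -> fold assignment).
#' @export
gridSearch <- function(family, grid, examples, n_folds, seed = 1L,
                       features = featureNames(), weights = NULL) {
  inds <- unique(examples$individual_id)
  if (n_folds > length(inds))
    stop("n_folds (", n_folds, ") exceeds the number of individuals (",
         length(inds), ")")
  set.seed(seed)
  fold_of <- setNames(rep_len(seq_len(n_folds), length(inds)),
                      sample(inds))

  pts <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
         else data.frame(row.names = 1)
  specs <- lapply(seq_len(max(nrow(pts), 1L)), function(i) {
    params <- if (ncol(pts)) lapply(pts[i, , drop = FALSE], unlist) else list()
    modelSpec(family, params = params, seed = seed)
  })

  fold_scores <- matrix(NA_real_, length(specs), n_folds)
  for (k in seq_len(n_folds)) {
    val_inds <- names(fold_of)[fold_of == k]
    sp <- splitByIndividual(examples, val_inds)
    for (i in seq_along(specs)) {
      m <- trainModel(specs[[i]], sp$train, features = features,
                      weights = weights)
      pred <- predictProba(m, sp$test)
      fold_scores[i, k] <- negLogLoss(pred, sp$test$truth_genotype)
    }
  }
  mean_nll <- rowMeans(fold_scores)
  best_i <- which.min(mean_nll)  # which.min takes the first minimum: ties
                                 # resolve to first-in-grid order
  scores <- cbind(pts,
                  as.data.frame(fold_scores,
                                col.names = paste0("fold", seq_len(n_folds))),
                  mean_neg_log_loss = mean_nll)
  names(scores)[seq_len(n_folds) + ncol(pts)] <- paste0("fold", seq_len(n_folds))
  list(best = specs[[best_i]], scores = scores, folds = fold_of)
}

#' Fit the final model on all training data with class reweighting
#'
#' The final model is trained on the full training set, without
#' down-sampling; class imbalance is handled by [classWeights()] so the
#' three genotype classes carry equal mass (a flat prior on genotypes).
#'
#' @param family model family.
#' @param spec the winning [modelSpec()] from [gridSearch()] (its family
#'   must match).
#' @param examples the full labeled training set.
#' @param features feature columns.
#' @return a `TrainedModel`.
#' @export
fitFinal <- function(family, spec, examples, features = featureNames()) {
  stopifnot(inherits(spec, "ModelSpec"), spec$family == family)
  w <- classWeights(examples$truth_genotype)
  trainModel(spec, examples, features = features, weights = w)
}

#' Calibrate posterior probabilities by one-vs-rest Platt scaling
#'
#' Tree and network scores need not be calibrated probabilities. This fits
#' one logistic regression per genotype class on a held-out calibration
#' set (logit of the raw posterior as the single predictor) and rescales
#' predictions to the simplex. Off by default throughout the pipeline:
#' the quality filters use posteriors as thresholds, for which raw
#' probabilities suffice; calibrate when the posteriors feed
#' likelihood-aware downstream tools.
#'
#' @param model a `TrainedModel`.
#' @param calib_examples labeled examples held out from training.
#' @return the model with a `calibration` component; subsequent
#'   [predictProba()] calls apply it.
#' @export
calibrateModel <- function(model, calib_examples) {
  stopifnot(inherits(model, "TrainedModel"))
  model$calibration <- NULL
  pred <- predictProba(model, calib_examples)
  eps <- 1e-12
  fits <- lapply(GENO_LEVELS, function(g) {
    p <- pmin(pmax(pred[[paste0("p_", g)]], eps), 1 - eps)
    z <- as.integer(calib_examples$truth_genotype == g)
    stats::glm(z ~ qlogis(p), family = stats::binomial())$coefficients
  })
  model$calibration <- setNames(fits, GENO_LEVELS)
  model
}

.apply_calibration <- function(calibration, P) {
  eps <- 1e-12
  Q <- vapply(GENO_LEVELS, function(g) {
    co <- calibration[[g]]
    stats::plogis(co[1] + co[2] * qlogis(pmin(pmax(P[, g], eps), 1 - eps)))
  }, numeric(nrow(P)))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  Q / rowSums(Q)
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat("TrainedModel<", x$spec$family, "> on ", x$meta$n, " examples, ",
      length(x$features), " features, seed ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

#' Save / load a trained model artifact
#'
#' The artifact is a directory holding the serialized model (`model.rds`),
#' the normalizer as JSON (`normalizer.json`), the feature list and a
#' manifest (family, hyperparameters, seed, data fingerprint) — enough to
#' reproduce standalone prediction.
#'
#' @param model a `TrainedModel`.
#' @param dir artifact directory (created if needed).
#' @return `saveModel()` the directory, invisibly; `loadModel()` the
#'   `TrainedModel`.
#' @export
saveModel <- function(model, dir) {
  stopifnot(inherits(model, "TrainedModel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(features = model$normalizer$features,
         mean = as.list(model$normalizer$mean),
         sd = as.list(model$normalizer$sd),
         dropped = model$normalizer$dropped),
    file.path(dir, "normalizer.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(family = model$spec$family, params = model$spec$params,
         seed = model$spec$seed, meta = model$meta,
         version = as.character(packageVersion("snprecall"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
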