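## Layer-1 characteristic methods (encoder + epsilon-SVR) and layer-2
## fusion mechanisms (SVR, 2-6-1 neural network, GA-evolved weights).

#' Epsilon-SVR configuration for layer-1 and layer-2 regressors
#'
#' The default is an RBF-kernel epsilon-SVR with cost 10, gamma
#' 1/ncol(x) and epsilon 0.1 (via e1071/LIBSVM; the cost default suits
#' the standardized encodings the layer-1 trainers produce). Setting
#' `tune = TRUE` grid-searches cost, gamma and epsilon by inner 5-fold
#' cross-validation; the default grid spans cost 2^-3..2^7, gamma
#' 2^-9..2^1 and epsilon \{0.01, 0.1, 1\} but any subset can be given.
#'
#' @param kernel SVM kernel.
#' @param cost,gamma,epsilon fixed hyperparameters (`gamma = NULL`
#'   means 1/ncol).
#' @param tune logical; grid-search instead of fixed values.
#' @param tune_grid list with vectors cost, gamma, epsilon.
#' @param tune_folds inner CV folds for tuning.
#' @return a named configuration list.
#' @export
svrConfig <- function(kernel = "radial", cost = 10, gamma = NULL,
                      epsilon = 0.1, tune = FALSE,
                      tune_grid = list(cost = 2^seq(-3, 7, by = 2),
                                       gamma = 2^seq(-9, 1, by = 2),
                                       epsilon = c(0.01, 0.1, 1)),
                      tune_folds = 5L) {
  list(kernel = kernel, cost = cost, gamma = gamma, epsilon = epsilon,
       tune = tune, tune_grid = tune_grid, tune_folds = as.integer(tune_folds))
}

## fit an epsilon-SVR on a standardized matrix, optionally tuning
fitSVR <- function(x, y, config, seed = 1L) {
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  if (isTRUE(config$tune)) {
    grid <- expand.grid(cost = config$tune_grid$cost,
                        gamma = config$tune_grid$gamma,
                        epsilon = config$tune_grid$epsilon)
    folds <- makeFolds(length(y), config$tune_folds, seed)
    best <- NULL; best_mse <- Inf
    for (g in seq_len(nrow(grid))) {
      preds <- numeric(length(y))
      for (k in seq_len(config$tune_folds)) {
        tr <- folds != k
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "eps-regression",
                          kernel = config$kernel, cost = grid$cost[g],
                          gamma = grid$gamma[g], epsilon = grid$epsilon[g],
                          scale = FALSE)
        preds[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
      }
      mse <- mean((preds - y)^2)
      if (mse < best_mse) { best_mse <- mse; best <- grid[g, ] }
    }
    config$cost <- best$cost; gamma <- best$gamma; config$epsilon <- best$epsilon
  }
  e1071::svm(x, y, type = "eps-regression", kernel = config$kernel,
             cost = config$cost, gamma = gamma, epsilon = config$epsilon,
             scale = FALSE)
}

encoderCategory <- function(encoder) {
  if (is(encoder, "SequenceEncoder")) "sequence"
  else if (is(encoder, "FeatureEncoder")) "feature"
  else if (is(encoder, "RuleEncoder")) "rule"
  else stop("unknown encoder class")
}

#' Train one layer-1 characteristic method
#'
#' Records the 10-fold cross-validated Pearson r first — refitting the
#' encoder (position weights / feature selection) and the SVR inside
#' every fold so the out-of-fold predictions are leak-free — and then
#' fits the encoder and the epsilon-SVR on the full training set. Fold
#' assignment is a deterministic function of `seed`.
#'
#' @param training labeled [SiRNADataset-class] with at least 20
#'   records and non-constant efficacy.
#' @param method_name label, e.g. "Binary", "Hybrid", "F65", "R12".
#' @param encoder an [Encoder-class] (unfitted is fine).
#' @param config from [svrConfig()].
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @return a [Layer1Model-class] with `cvR` populated.
#' @export
trainLayer1 <- function(training, method_name, encoder,
                        config = svrConfig(), folds = 10L, seed = 1L) {
  stopifnot(is(training, "SiRNADataset"), is(encoder, "Encoder"))
  y <- efficacies(training)
  if (any(is.na(y))) stop("training dataset must be fully labeled")
  if (length(y) < 20L) stop("need at least 20 training records")
  if (stats::sd(y) == 0) stop("degenerate labels: efficacy has zero variance")
  seqs <- siRNASequences(training)

  fold_id <- makeFolds(length(y), folds, seed)
  oof <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    enc_k <- fitEncoder(encoder, training[tr])
    x_tr <- encodeMatrix(enc_k, seqs[tr])
    std <- standardizeFit(x_tr)
    fit_k <- fitSVR(standardizeApply(x_tr, std), y[tr], config, seed)
    x_te <- standardizeApply(encodeMatrix(enc_k, seqs[!tr]), std)
    oof[!tr] <- stats::predict(fit_k, x_te)
  }
  cv_r <- pearsonR(oof, y)

  enc_full <- fitEncoder(encoder, training)
  x <- encodeMatrix(enc_full, seqs)
  std <- standardizeFit(x)
  fit <- fitSVR(standardizeApply(x, std), y, config, seed)
  new("Layer1Model", methodName = method_name,
      category = encoderCategory(encoder), encoder = enc_full, fit = fit,
      center = std$center, scale = std$scale, cvR = cv_r,
      seed = as.integer(seed), config = config)
}

#' @rdname cvR
#' @title Accessors for Layer1Model
#' @param x a [Layer1Model-class].
#' @return `cvR`: the 10-fold cross-validated Pearson r; `methodName`:
#'   the method label; `methodCategory`: "sequence", "feature" or
#'   "rule".
#' @export
setMethod("cvR", "Layer1Model", function(x) x@cvR)

#' @rdname cvR
#' @export
setMethod("methodName", "Layer1Model", function(x) x@methodName)

#' @rdname cvR
#' @export
setMethod("methodCategory", "Layer1Model", function(x) x@category)

setMethod("show", "Layer1Model", function(object) {
  cat(sprintf("Layer1Model '%s' (%s characteristic): 10-fold CV r = %.3f\n",
              object@methodName, object@category, object@cvR))
})

#' Admit layer-1 methods into the fusion layer
#'
#' Keeps methods whose cross-validated r meets the admission threshold
#' (inclusive: r >= threshold, default 0.6) and partitions them into
#' sequence-type and feature-type candidates for pairing. Layer 2 fuses
#' exactly one of each, so with `require_pair = TRUE` (the pipeline
#' default) an empty partition on either side is an error.
#'
#' @param models list of [Layer1Model-class] with `cvR` populated.
#' @param threshold admission cut on cross-validated r.
#' @param require_pair error when no sequence-type or no feature-type
#'   method survives.
#' @return list with elements `admitted`, `sequence`, `feature` (lists
#'   of models) and `pairs` (data.frame of all sequence x feature
#'   combinations).
#' @export
admitMethods <- function(models, threshold = 0.6, require_pair = FALSE) {
  stopifnot(all(vapply(models, is, logical(1), class2 = "Layer1Model")))
  rs <- vapply(models, cvR, numeric(1))
  admitted <- models[rs >= threshold]
  if (!length(admitted))
    stop(sprintf("no method reaches the admission threshold r >= %g (best: %.3f)",
                 threshold, max(rs)))
  cats <- vapply(admitted, methodCategory, character(1))
  seq_m <- admitted[cats == "sequence"]
  feat_m <- admitted[cats == "feature"]
  if (require_pair && (!length(seq_m) || !length(feat_m)))
    stop("fusion pairs one sequence-type with one feature-type method, but ",
         if (!length(seq_m)) "no sequence-type" else "no feature-type",
         " method was admitted; lower the threshold or train more methods")
  pairs <- if (length(seq_m) && length(feat_m))
    expand.grid(sequence = vapply(seq_m, methodName, character(1)),
                feature = vapply(feat_m, methodName, character(1)),
                stringsAsFactors = FALSE)
  else data.frame(sequence = character(), feature = character())
  list(admitted = admitted, sequence = seq_m, feature = feat_m, pairs = pairs)
}

#' Build the out-of-fold stacking frame for a component pair
#'
#' For each of the `folds` folds, both layer-1 methods are refitted
#' (encoder and SVR) on the other folds and predict the held-out fold,
#' so every record appears exactly once as an out-of-fold prediction
#' and layer 2 never trains on leaked in-fold predictions. A fold whose
#' removal leaves zero label variance is merged with its neighbor with
#' a warning.
#'
#' @param training labeled [SiRNADataset-class].
#' @param pair list of two [Layer1Model-class] (sequence-type first by
#'   convention).
#' @param folds number of folds.
#' @param seed integer seed for fold assignment.
#' @return a [StackingFrame-class].
#' @export
buildStackingFrame <- function(training, pair, folds = 10L, seed = 1L) {
  stopifnot(length(pair) == 2L,
            all(vapply(pair, is, logical(1), class2 = "Layer1Model")))
  y <- efficacies(training)
  if (any(is.na(y))) stop("training dataset must be fully labeled")
  seqs <- siRNASequences(training)
  fold_id <- makeFolds(length(y), folds, seed)
  ## merge folds whose complement would have constant labels
  for (k in sort(unique(fold_id))) {
    if (stats::sd(y[fold_id != k]) == 0) {
      warning("fold ", k, " merged with neighbor (zero label variance)")
      fold_id[fold_id == k] <- if (k == max(fold_id)) k - 1L else k + 1L
    }
  }
  oof <- matrix(NA_real_, length(y), 2L)
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    for (j in 1:2) {
      enc_k <- fitEncoder(pair[[j]]@encoder, training[tr])
      x_tr <- encodeMatrix(enc_k, seqs[tr])
      std <- standardizeFit(x_tr)
      fit_k <- fitSVR(standardizeApply(x_tr, std), y[tr], pair[[j]]@config, seed)
      oof[!tr, j] <- stats::predict(
        fit_k, standardizeApply(encodeMatrix(enc_k, seqs[!tr]), std))
    }
  }
  new("StackingFrame",
      frame = data.frame(pred1 = oof[, 1], pred2 = oof[, 2], observed = y,
                         fold = fold_id),
      components = vapply(pair, methodName, character(1)))
}

setMethod("show", "StackingFrame", function(object) {
  cat(sprintf("StackingFrame: %d records, components %s + %s\n",
              nrow(object@frame), object@components[1], object@components[2]))
})

#' Layer-2 fusion by epsilon-SVR
#'
#' Trains an epsilon-SVR from the two out-of-fold component predictions
#' to observed efficacy.
#'
#' @param frame a [StackingFrame-class].
#' @param components list of the two fitted [Layer1Model-class]
#'   components (sequence-type first), used at prediction time.
#' @param config from [svrConfig()].
#' @param seed integer seed (used only when tuning).
#' @return a [FusionModel-class] with mechanism "svr".
#' @export
trainFusionSVR <- function(frame, components, config = svrConfig(),
                           seed = 1L) {
  stopifnot(is(frame, "StackingFrame"))
  f <- frame@frame
  x <- cbind(pred1 = f$pred1, pred2 = f$pred2)
  if (stats::sd(f$observed) == 0) stop("degenerate labels in stacking frame")
  std <- standardizeFit(x)
  fit <- fitSVR(standardizeApply(x, std), f$observed, config, seed)
  new("FusionModel", mechanism = "svr", components = components, fit = fit,
      details = list(center = std$center, scale = std$scale,
                     config = config, components = frame@components))
}

#' Layer-2 fusion by a 2-6-1 neural network
#'
#' A feed-forward network with an input layer of two nodes (the two
#' component predictions), one hidden layer of six sigmoidal nodes and
#' a single sigmoidal output; efficacy is scaled to \[0,1\] internally
#' and rescaled to \[0,100\] on output, so predictions always lie in
#' \[0,100\]. Weight initialization is fixed by `seed`.
#'
#' @param frame a [StackingFrame-class].
#' @param components list of the two fitted [Layer1Model-class].
#' @param maxit maximum training iterations.
#' @param decay weight decay.
#' @param seed integer seed for the initial weights.
#' @return a [FusionModel-class] with mechanism "nn".
#' @export
trainFusionNN <- function(frame, components, maxit = 2000L, decay = 0,
                          seed = 1L) {
  stopifnot(is(frame, "StackingFrame"))
  f <- frame@frame
  x <- cbind(pred1 = f$pred1, pred2 = f$pred2) / 100
  y <- f$observed / 100
  fit <- withSeed(seed, nnet::nnet(x, y, size = 6L, linout = FALSE,
                                   maxit = maxit, decay = decay,
                                   trace = FALSE))
  if (fit$convergence != 0)
    warning("neural network stopped at maxit without convergence; ",
            "returning best-so-far weights")
  new("FusionModel", mechanism = "nn", components = components, fit = fit,
      details = list(seed = as.integer(seed), maxit = maxit, decay = decay,
                     components = frame@components))
}

#' @rdname fusionWeights
#' @title Accessors for FusionModel
#' @param x a [FusionModel-class].
#' @return `fusionMechanism`: "svr", "nn" or "ga_linear";
#'   `fusionWeights`: the evolved (W1, W2) for ga_linear models.
#' @export
setMethod("fusionMechanism", "FusionModel", function(x) x@mechanism)

#' @rdname fusionWeights
#' @export
setMethod("fusionWeights", "FusionModel", function(x) {
  if (x@mechanism != "ga_linear")
    stop("fusion weights exist only for the ga_linear mechanism")
  x@fit
})

setMethod("show", "FusionModel", function(object) {
  comps <- object@details$components
  cat(sprintf("FusionModel [%s]: %s + %s\n", object@mechanism,
              comps[1], comps[2]))
  if (object@mechanism == "ga_linear")
    cat(sprintf("  weights W1 = %.3f, W2 = %.3f (MSE %.3f)\n",
                object@fit["W1"], object@fit["W2"], object@details$mse))
})

## fuse two component prediction vectors with a fitted mechanism
fusePredictions <- function(model, p1, p2) {
  switch(model@mechanism,
    ga_linear = unname(model@fit["W1"] * p1 + model@fit["W2"] * p2),
    svr = {
      x <- standardizeApply(cbind(pred1 = p1, pred2 = p2),
                            list(center = model@details$center,
                                 scale = model@details$scale))
      as.numeric(stats::predict(model@fit, x))
    },
    nn = as.numeric(stats::predict(model@fit,
                                   cbind(pred1 = p1, pred2 = p2) / 100)) * 100)
}

#' @rdname predictEfficacy
#' @export
setMethod("predictEfficacy", "Layer1Model", function(object, seqs) {
  if (is(seqs, "SiRNADataset")) seqs <- siRNASequences(seqs)
  if (is.null(object@fit)) stop("model is not fitted")
  x <- standardizeApply(encodeMatrix(object@encoder, seqs),
                        list(center = object@center, scale = object@scale))
  as.numeric(stats::predict(object@fit, x))
})

#' @rdname predictEfficacy
#' @export
setMethod("predictEfficacy", "FusionModel", function(object, seqs) {
  if (is(seqs, "SiRNADataset")) seqs <- siRNASequences(seqs)
  p1 <- predictEfficacy(object@components[[1]], seqs)
  p2 <- predictEfficacy(object@components[[2]], seqs)
  fusePredictions(object, p1, p2)
})
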