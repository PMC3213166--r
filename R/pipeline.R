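## End-to-end orchestration: train the two-layer predictor, serialize
## and reload model bundles, scan a target mRNA, evaluate.

## Table of the built-in characteristic-method family. The feature
## methods differ only in their |r| selection thresholds
## (single / n-gram); NA means unrestricted beyond p < 0.001.
METHOD_REGISTRY <- list(
  Numeric = list(category = "sequence", type = "numeric"),
  Binary  = list(category = "sequence", type = "binary"),
  Hybrid  = list(category = "sequence", type = "hybrid"),
  F162    = list(category = "feature", ts = NA_real_, tn = NA_real_),
  F85     = list(category = "feature", ts = 0.10, tn = 0.09),
  F65     = list(category = "feature", ts = 0.12, tn = 0.10),
  F47     = list(category = "feature", ts = 0.13, tn = 0.12),
  R12     = list(category = "rule"))

#' Build the encoder for a registered characteristic method
#'
#' Known methods: sequence encodings Numeric, Binary, Hybrid; feature
#' sets F162 (p < 0.001 only), F85 (|r| > 0.10 / 0.09), F65
#' (|r| > 0.12 / 0.10), F47 (|r| > 0.13 / 0.12); and the rule encoding
#' R12.
#'
#' @param method_name one of the registered names.
#' @param params a [ThermoParams-class] (feature methods).
#' @param rules a [RuleTable-class] (R12).
#' @return an unfitted [Encoder-class].
#' @export
methodEncoder <- function(method_name, params = defaultThermoParams(),
                          rules = defaultRuleTable()) {
  reg <- METHOD_REGISTRY[[method_name]]
  if (is.null(reg))
    stop("unknown characteristic method '", method_name, "'; known: ",
         paste(names(METHOD_REGISTRY), collapse = ", "))
  switch(reg$category,
    sequence = sequenceEncoder(reg$type),
    feature = featureEncoder(reg$ts, reg$tn, params, name = method_name),
    rule = ruleEncoder(rules))
}

#' Train the full two-layer predictor
#'
#' Orchestrates the whole procedure on one labeled dataset:
#' 1. splits off a seeded internal validation fraction (default 20%)
#'    used only to compare candidate pairs;
#' 2. trains every requested layer-1 method on the training split,
#'    recording 10-fold cross-validated r;
#' 3. admits methods with r at or above `admission_threshold`
#'    (inclusive) and forms all sequence x feature pairs;
#' 4. for each pair builds the out-of-fold stacking frame, trains the
#'    requested fusion mechanism, and measures r on the held-out split;
#' 5. returns the best pair's fusion model as a [PredictorBundle-class].
#'
#' @param training labeled [SiRNADataset-class].
#' @param methods layer-1 method names (must span both a sequence-type
#'   and a feature-type method).
#' @param mechanism "svr", "nn" or "ga_linear".
#' @param admission_threshold admission cut on cross-validated r.
#' @param folds CV folds for layer-1 training and stacking.
#' @param seed master seed: fold assignment, the validation split and
#'   any stochastic fusion training derive from it.
#' @param svr from [svrConfig()].
#' @param ga from [gaParams()] (mechanism "ga_linear").
#' @param nn_maxit,nn_decay 2-6-1 network training controls.
#' @param validation_fraction held-out fraction for pair selection.
#' @param params a [ThermoParams-class].
#' @param rules a [RuleTable-class].
#' @return a [PredictorBundle-class].
#' @export
trainPipeline <- function(training,
                          methods = c("Binary", "Hybrid", "F85", "F65"),
                          mechanism = c("svr", "nn", "ga_linear"),
                          admission_threshold = 0.6, folds = 10L, seed = 1L,
                          svr = svrConfig(), ga = gaParams(seed = seed),
                          nn_maxit = 2000L, nn_decay = 0,
                          validation_fraction = 0.2,
                          params = defaultThermoParams(),
                          rules = defaultRuleTable()) {
  mechanism <- match.arg(mechanism)
  stopifnot(is(training, "SiRNADataset"))
  cats <- vapply(methods, function(m) {
    if (is.null(METHOD_REGISTRY[[m]]))
      stop("unknown characteristic method '", m, "'")
    METHOD_REGISTRY[[m]]$category
  }, character(1))
  if (!any(cats == "sequence") || !any(cats == "feature"))
    stop("fusion needs at least one sequence-type and one feature-type ",
         "method among: ", paste(methods, collapse = ", "))

  n <- length(training)
  idx_val <- withSeed(seed + 1L,
                      sample(n, size = max(1L, round(validation_fraction * n))))
  ds_train <- training[-idx_val]
  ds_val <- training[idx_val]

  layer1 <- lapply(methods, function(m)
    trainLayer1(ds_train, m, methodEncoder(m, params, rules),
                config = svr, folds = folds, seed = seed))
  names(layer1) <- methods

  adm <- admitMethods(layer1, threshold = admission_threshold,
                      require_pair = TRUE)

  val_obs <- efficacies(ds_val)
  sel <- data.frame(sequence = character(), feature = character(),
                    heldout_r = numeric())
  best <- NULL; best_r <- -Inf
  for (i in seq_len(nrow(adm$pairs))) {
    pr <- list(layer1[[adm$pairs$sequence[i]]], layer1[[adm$pairs$feature[i]]])
    frame <- buildStackingFrame(ds_train, pr, folds = folds, seed = seed)
    fusion <- switch(mechanism,
      svr = trainFusionSVR(frame, pr, config = svr, seed = seed),
      nn = trainFusionNN(frame, pr, maxit = nn_maxit, decay = nn_decay,
                         seed = seed),
      ga_linear = evolveGAWeights(frame, ga = ga, components = pr))
    r_val <- pearsonR(predictEfficacy(fusion, ds_val), val_obs)
    sel <- rbind(sel, data.frame(sequence = adm$pairs$sequence[i],
                                 feature = adm$pairs$feature[i],
                                 heldout_r = r_val))
    if (r_val > best_r) { best_r <- r_val; best <- fusion }
  }

  config <- list(methods = methods, mechanism = mechanism,
                 admission_threshold = admission_threshold,
                 folds = as.integer(folds), seed = as.integer(seed),
                 svr = svr, ga = ga, nn_maxit = nn_maxit, nn_decay = nn_decay,
                 validation_fraction = validation_fraction,
                 training_ids = recordIds(training),
                 validation_ids = recordIds(ds_val))
  new("PredictorBundle", fusion = best, layer1 = layer1, config = config,
      selection = sel, params = params)
}

setMethod("show", "PredictorBundle", function(object) {
  comps <- object@fusion@details$components
  cat(sprintf("PredictorBundle: %s fusion of %s + %s\n",
              object@fusion@mechanism, comps[1], comps[2]))
  cat("  layer-1 methods (10-fold CV r):\n")
  for (m in object@layer1)
    cat(sprintf("    %-8s %s  %.3f\n", methodName(m),
                substr(methodCategory(m), 1, 4), cvR(m)))
  if (nrow(object@selection)) {
    cat("  pair selection (held-out r):\n")
    for (i in seq_len(nrow(object@selection)))
      cat(sprintf("    %s + %s  %.3f\n", object@selection$sequence[i],
                  object@selection$feature[i], object@selection$heldout_r[i]))
  }
})

#' @rdname predictEfficacy
#' @export
setMethod("predictEfficacy", "PredictorBundle", function(object, seqs) {
  predictEfficacy(object@fusion, seqs)
})

#' Serialize / reload a trained predictor bundle
#'
#' A bundle directory contains `model.rds` (the fitted object graph)
#' and `manifest.json` (methods, mechanism, seeds, thresholds and the
#' pair-selection table) so a run is auditable and reloads predict
#' bit-identically.
#'
#' @param bundle a [PredictorBundle-class].
#' @param dir bundle directory (created if needed).
#' @return `saveBundle`: the directory invisibly; `loadBundle`: the
#'   restored [PredictorBundle-class].
#' @export
saveBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "PredictorBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(bundle, file.path(dir, "model.rds"))
  manifest <- bundle@config
  manifest$selection <- bundle@selection
  manifest$mechanism <- bundle@fusion@mechanism
  manifest$cv_r <- lapply(bundle@layer1, cvR)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("not a bundle directory (no model.rds): ", dir)
  bundle <- readRDS(path)
  stopifnot(is(bundle, "PredictorBundle"))
  bundle
}

#' Scan a target mRNA for candidate siRNAs
#'
#' Enumerates every 19-mer window of the target, predicts its efficacy,
#' keeps candidates at or above `efficacy_threshold`, computes each
#' survivor's whole-duplex stacking energy and partitions them at
#' `dG_threshold`: candidates with whole dG at or above the threshold
#' (boundary inclusive) form the recommended high-confidence set.
#' Within each partition candidates are sorted by predicted efficacy
#' descending, start position breaking ties.
#'
#' @param bundle a [PredictorBundle-class] (or any fitted model with a
#'   `predictEfficacy` method, plus `params`).
#' @param mrna_seq target mRNA sequence (character), length >= 19.
#' @param efficacy_threshold minimum predicted efficacy to report (%).
#' @param dG_threshold whole-dG partition point, kcal/mol.
#' @param parent_id id prefix for candidates.
#' @return data.frame with columns id, start, sequence, predicted,
#'   whole_dG, partition ("high_confidence"/"low_confidence"), sorted
#'   within partition; thresholds kept in attributes.
#' @export
scanTarget <- function(bundle, mrna_seq, efficacy_threshold = 70,
                       dG_threshold = -34.6, parent_id = "target") {
  cand <- enumerateCandidates(mrna_seq, parent_id)
  seqs <- siRNASequences(cand)
  pred <- predictEfficacy(bundle, seqs)
  params <- if (is(bundle, "PredictorBundle")) bundle@params
            else defaultThermoParams()
  keep <- pred >= efficacy_threshold
  starts <- seq_along(seqs)
  res <- data.frame(id = recordIds(cand)[keep], start = starts[keep],
                    sequence = seqs[keep], predicted = pred[keep],
                    stringsAsFactors = FALSE)
  res$whole_dG <- if (nrow(res)) wholeDG(res$sequence, params) else numeric(0)
  res$partition <- ifelse(res$whole_dG >= dG_threshold,
                          "high_confidence", "low_confidence")
  res <- res[order(res$partition == "low_confidence", -res$predicted,
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "efficacy_threshold") <- efficacy_threshold
  attr(res, "dG_threshold") <- dG_threshold
  res
}

#' Write a three-part scan report
#'
#' Section 1 lists all candidates above the efficacy threshold;
#' section 2 the recommended set (whole dG at or above the partition
#' threshold, where prediction confidence is higher); section 3 the
#' remaining strong-stacking candidates.
#'
#' @param scan result of [scanTarget()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScanReport <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  eff_thr <- attr(scan, "efficacy_threshold")
  dg_thr <- attr(scan, "dG_threshold")
  fmt <- function(df) {
    if (!nrow(df)) return("  (none)")
    sprintf("  %-20s %s  %6.2f  %7.2f  %s", df$id, df$sequence,
            df$predicted, df$whole_dG, df$partition)
  }
  hi <- scan[scan$partition == "high_confidence", , drop = FALSE]
  lo <- scan[scan$partition == "low_confidence", , drop = FALSE]
  writeLines(c(
    sprintf("siRNA candidate scan (predicted efficacy >= %g%%)", eff_thr),
    sprintf("recommended: the %d candidate(s) with whole dG >= %g kcal/mol (part 2)",
            nrow(hi), dg_thr),
    if (!nrow(scan)) "no candidate passed the efficacy threshold" else character(0),
    "", sprintf("part 1: all %d surviving candidate(s)", nrow(scan)), fmt(scan),
    "", sprintf("part 2: whole dG >= %g kcal/mol (high confidence, %d)",
                dg_thr, nrow(hi)), fmt(hi),
    "", sprintf("part 3: whole dG < %g kcal/mol (low confidence, %d)",
                dg_thr, nrow(lo)), fmt(lo)), con)
  invisible(path)
}

#' Evaluate a bundle on a labeled dataset
#'
#' Runs the full evaluation including whole-dG stratification; when the
#' dataset's record ids coincide with the bundle's training ids the
#' report is flagged as in-sample.
#'
#' @param bundle a [PredictorBundle-class].
#' @param dataset labeled [SiRNADataset-class].
#' @param dG_threshold,efficacy_threshold evaluation thresholds.
#' @return an [EvaluationReport-class].
#' @export
evaluateBundle <- function(bundle, dataset, dG_threshold = -34.6,
                           efficacy_threshold = 70) {
  stopifnot(is(bundle, "PredictorBundle"))
  in_sample <- setequal(recordIds(dataset), bundle@config$training_ids)
  stratifiedEvaluate(bundle, dataset, dG_threshold = dG_threshold,
                     efficacy_threshold = efficacy_threshold,
                     params = bundle@params, in_sample = in_sample)
}
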