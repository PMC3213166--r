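## Evaluation surface: Pearson correlation, threshold classification
## (Acc/Sn/Sp/MCC at >= 70% inhibition) and whole-dG stratification at
## -34.6 kcal/mol.

#' Pearson product-moment correlation
#'
#' A strict variant of `cor()`: equal lengths of at least 3 are
#' required and zero variance in either argument is an error (never
#' silently 0 or NA), because a correlation-based model selection must
#' not mistake a degenerate predictor for an uncorrelated one.
#'
#' @param x,y numeric vectors.
#' @return the correlation, in \[-1,1\].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Tally the confusion counts at an efficacy call threshold
#'
#' A record is positive when its value is at or above the threshold
#' (inclusive, so exactly 70 counts as high-efficacy); the same
#' threshold is applied to observed (truth) and predicted (call) by
#' default, with independent thresholds available for sensitivity
#' analysis.
#'
#' @param predicted,observed numeric vectors of equal length
#'   (% inhibition).
#' @param threshold call cut for both, default 70.
#' @param observed_threshold optional separate cut for the truth.
#' @return named integer vector TP, FP, FN, TN.
#' @export
classifyAndCount <- function(predicted, observed, threshold = 70,
                             observed_threshold = threshold) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  truth <- observed >= observed_threshold
  call <- predicted >= threshold
  c(TP = sum(truth & call), FP = sum(!truth & call),
    FN = sum(truth & !call), TN = sum(!truth & !call))
}

#' Classification metrics from confusion counts
#'
#' Acc = (TP+TN)/total and Sn = TP/(TP+FN), Sp = TN/(TN+FP) as
#' percentages; MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' in \[-1,1\]. Sn (Sp) is NA when the truth contains no positives
#' (negatives) — undefined, not zero. A zero factor in the MCC
#' denominator yields MCC = 0 with a warning (the conventional total
#' extension).
#'
#' @param counts named vector with TP, FP, FN, TN.
#' @return list with acc, sn, sp (percent) and mcc.
#' @export
confusionMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]]); tn <- as.numeric(counts[["TN"]])
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion table")
  acc <- 100 * (tp + tn) / total
  sn <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) {
    warning("MCC denominator has a zero factor; reporting MCC = 0")
    0
  } else (tp * tn - fp * fn) / sqrt(denom)
  list(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

buildReport <- function(predicted, observed, threshold, in_sample = FALSE) {
  counts <- classifyAndCount(predicted, observed, threshold)
  m <- confusionMetrics(counts)
  new("EvaluationReport", r = pearsonR(predicted, observed),
      acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc,
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      n = length(observed), strata = list(), in_sample = in_sample)
}

#' Evaluate a model with whole-dG stratification
#'
#' Computes the overall report (Pearson r plus Acc/Sn/Sp/MCC at the
#' efficacy call threshold) and per-stratum Pearson r after splitting
#' the test records by whole-duplex stacking energy: records with
#' whole dG at or above `dG_threshold` (default -34.6 kcal/mol, the
#' boundary itself inclusive) form the weak-stacking, high-confidence
#' stratum; the rest the strong-stacking stratum. A stratum with fewer
#' than 3 records reports its r as NA.
#'
#' @param model a fitted [Layer1Model-class], [FusionModel-class] or
#'   [PredictorBundle-class].
#' @param test labeled [SiRNADataset-class].
#' @param dG_threshold whole-dG split point, kcal/mol.
#' @param efficacy_threshold call cut (% inhibition).
#' @param params a [ThermoParams-class].
#' @param in_sample flag the report as an in-sample evaluation.
#' @return an [EvaluationReport-class] with two strata sub-reports.
#' @export
stratifiedEvaluate <- function(model, test, dG_threshold = -34.6,
                               efficacy_threshold = 70,
                               params = defaultThermoParams(),
                               in_sample = FALSE) {
  stopifnot(is(test, "SiRNADataset"))
  obs <- efficacies(test)
  if (any(is.na(obs))) stop("test dataset must be fully labeled")
  if (length(obs) < 3L) stop("need at least 3 test records")
  pred <- predictEfficacy(model, test)
  report <- buildReport(pred, obs, efficacy_threshold, in_sample)
  dg <- wholeDG(siRNASequences(test), params)
  hi <- dg >= dG_threshold
  stratum <- function(sel, label) {
    n_s <- sum(sel)
    r_s <- if (n_s >= 3L && stats::sd(pred[sel]) > 0 && stats::sd(obs[sel]) > 0)
      pearsonR(pred[sel], obs[sel]) else NA_real_
    list(label = label, n = n_s, r = r_s)
  }
  report@strata <- list(dG_ge_threshold = stratum(hi, sprintf("whole dG >= %g", dG_threshold)),
                        dG_lt_threshold = stratum(!hi, sprintf("whole dG < %g", dG_threshold)))
  report
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (n = %d)%s\n", object@n,
              if (object@in_sample) "  [IN-SAMPLE: evaluated on training data]" else ""))
  cat(sprintf("  Pearson r = %.3f\n", object@r))
  cat(sprintf("  Acc = %.2f%%  Sn = %s  Sp = %s  MCC = %.3f\n",
              object@acc,
              ifelse(is.na(object@sn), "NA", sprintf("%.2f%%", object@sn)),
              ifelse(is.na(object@sp), "NA", sprintf("%.2f%%", object@sp)),
              object@mcc))
  cat(sprintf("  counts: TP=%d FP=%d FN=%d TN=%d\n", object@counts["TP"],
              object@counts["FP"], object@counts["FN"], object@counts["TN"]))
  for (s in object@strata)
    cat(sprintf("  stratum %s: n = %d, r = %s\n", s$label, s$n,
                ifelse(is.na(s$r), "NA", sprintf("%.3f", s$r))))
})

#' Export an evaluation report as structured text and a flat table
#'
#' @param report an [EvaluationReport-class].
#' @param path output path for the structured report; a sibling
#'   `<path>.tsv` receives the flat delimited export.
#' @return the path, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  txt <- utils::capture.output(show(report))
  writeLines(txt, path)
  flat <- data.frame(metric = c("r", "acc", "sn", "sp", "mcc", "n"),
                     value = c(report@r, report@acc, report@sn, report@sp,
                               report@mcc, report@n))
  for (nm in names(report@strata)) {
    s <- report@strata[[nm]]
    flat <- rbind(flat, data.frame(metric = paste0(nm, c(".r", ".n")),
                                   value = c(s$r, s$n)))
  }
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
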