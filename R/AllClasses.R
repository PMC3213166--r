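#' @import methods
NULL

RNA_BASES <- c("A", "U", "C", "G")

#' SiRNADataset: a validated collection of 19-nt siRNA records
#'
#' Holds sense-strand 19-mers over \{A,U,C,G\} with optional observed
#' efficacy (percent inhibition of the target mRNA, in \[0,100\]).
#' Sequences are the sense strand, i.e. identical to the target-site
#' sequence; the antisense (guide) strand is derived by reverse
#' complementation wherever thermodynamics require it.
#'
#' @slot records data.frame with columns `id` (unique character),
#'   `sequence` (19-character over A/U/C/G) and `efficacy` (numeric in
#'   \[0,100\], `NA` for unlabeled queries).
#' @slot name character scalar naming the dataset.
#' @exportClass SiRNADataset
setClass("SiRNADataset",
  representation(records = "data.frame", name = "character"),
  prototype(records = data.frame(id = character(), sequence = character(),
                                 efficacy = numeric()),
            name = "dataset"))

setValidity("SiRNADataset", function(object) {
  rec <- object@records
  need <- c("id", "sequence", "efficacy")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id))
    return(sprintf("duplicate record id(s): %s",
                   paste(unique(rec$id[duplicated(rec$id)]), collapse = ", ")))
  bad_len <- which(nchar(rec$sequence) != 19L)
  if (length(bad_len))
    return(sprintf("row %d: sequence length %d violates the 19-nt invariant",
                   bad_len[1], nchar(rec$sequence[bad_len[1]])))
  bad_ab <- which(grepl("[^ACGU]", rec$sequence))
  if (length(bad_ab))
    return(sprintf("row %d: sequence contains characters outside {A,C,G,U}",
                   bad_ab[1]))
  eff <- rec$efficacy
  bad_eff <- which(!is.na(eff) & (eff < 0 | eff > 100))
  if (length(bad_eff))
    return(sprintf("row %d: efficacy %g outside [0,100]", bad_eff[1], eff[bad_eff[1]]))
  TRUE
})

#' PositionWeightTable: per-(nucleotide, position) correlation weights
#'
#' The hybrid sequence encoding appends, to each one-hot quartet, the
#' Pearson correlation between the indicator "nucleotide b occupies
#' position n" and observed efficacy, estimated from a training set.
#'
#' @slot weights 4 x 19 numeric matrix, rows named A,U,C,G and columns
#'   1..19; every entry is a correlation in \[-1,1\] (zero-variance cells
#'   are set to 0).
#' @exportClass PositionWeightTable
setClass("PositionWeightTable", representation(weights = "matrix"))

setValidity("PositionWeightTable", function(object) {
  w <- object@weights
  if (!identical(dim(w), c(4L, 19L))) return("weights must be a 4 x 19 matrix")
  if (!identical(rownames(w), RNA_BASES)) return("rows must be named A,U,C,G")
  if (any(!is.finite(w)) || any(abs(w) > 1 + 1e-12))
    return("weights must be finite correlations in [-1,1]")
  TRUE
})

#' RuleTable: published siRNA design-rule verdicts
#'
#' Maps (rule set, sense-strand position 1..19, nucleotide) to a verdict:
#' +1 when the rule set marks that nucleotide favourable at that
#' position, -1 when unfavourable, and 0 (absence from the table) when
#' the set is silent there. Verdict conflicts within a single rule set
#' at one (position, nucleotide) are rejected at load time; conflicts
#' across sets are expected and preserved.
#'
#' @slot verdicts data.frame with columns rule_set, position, nucleotide,
#'   verdict.
#' @slot sets character vector of rule-set names, in encoding order.
#' @exportClass RuleTable
setClass("RuleTable",
  representation(verdicts = "data.frame", sets = "character"))

setValidity("RuleTable", function(object) {
  v <- object@verdicts
  need <- c("rule_set", "position", "nucleotide", "verdict")
  if (!all(need %in% names(v)))
    return(sprintf("verdicts must have columns %s", paste(need, collapse = ", ")))
  if (!all(v$verdict %in% c(-1, 1)))
    return("explicit verdicts must be +1 or -1 (0 means absence)")
  if (!all(v$position %in% 1:19)) return("positions must lie in 1..19")
  if (!all(v$nucleotide %in% RNA_BASES)) return("nucleotides must be A,U,C,G")
  if (!all(v$rule_set %in% object@sets)) return("verdict references unknown rule set")
  key <- paste(v$rule_set, v$position, v$nucleotide)
  if (anyDuplicated(key))
    return(sprintf("conflicting verdicts within a rule set at: %s",
                   key[duplicated(key)][1]))
  TRUE
})

#' ThermoParams: RNA nearest-neighbor stacking parameters
#'
#' Watson-Crick nearest-neighbor parameters for RNA duplexes, keyed by
#' the 5'->3' dinucleotide step of the strand under evaluation (each key
#' denotes the stack that step forms with its Watson-Crick complement).
#'
#' @slot dG37 named numeric(16), stacking free energy at 37 C, kcal/mol.
#' @slot dH named numeric(16), stacking enthalpy, kcal/mol.
#' @slot dS named numeric(16), stacking entropy, cal/(mol K).
#' @exportClass ThermoParams
setClass("ThermoParams",
  representation(dG37 = "numeric", dH = "numeric", dS = "numeric"))

setValidity("ThermoParams", function(object) {
  steps <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  for (slot in c("dG37", "dH", "dS")) {
    v <- slot(object, slot)
    missing <- setdiff(steps, names(v))
    if (length(missing))
      return(sprintf("%s is missing step(s): %s", slot,
                     paste(missing, collapse = ", ")))
    if (any(!is.finite(v[steps]))) return(sprintf("%s has non-finite entries", slot))
  }
  TRUE
})

#' FeatureSetSpec: a frozen, named set of selected feature elements
#'
#' The result of correlation/significance selection over the three
#' candidate families: positional single-nucleotide indicators, n-gram
#' frequencies (n = 2..5), and duplex thermodynamic quantities. Single
#' and n-gram elements must pass p < 0.001 and, when a threshold is set,
#' |r| strictly above it; thermodynamic elements are always retained.
#'
#' @slot name character, e.g. "F162" or a custom label.
#' @slot elements data.frame with columns kind ("single"/"ngram"/"thermo"),
#'   key, r_train, p_value, ordered by (kind, key).
#' @slot threshold_single numeric scalar or NA (no |r| filter).
#' @slot threshold_ngram numeric scalar or NA.
#' @exportClass FeatureSetSpec
setClass("FeatureSetSpec",
  representation(name = "character", elements = "data.frame",
                 threshold_single = "numeric", threshold_ngram = "numeric"))

setValidity("FeatureSetSpec", function(object) {
  el <- object@elements
  need <- c("kind", "key", "r_train", "p_value")
  if (!all(need %in% names(el)))
    return(sprintf("elements must have columns %s", paste(need, collapse = ", ")))
  if (!all(el$kind %in% c("single", "ngram", "thermo")))
    return("element kind must be single, ngram or thermo")
  if (anyDuplicated(el$key)) return("element keys must be unique")
  non_thermo <- el[el$kind != "thermo", , drop = FALSE]
  if (nrow(non_thermo) && any(non_thermo$p_value >= 0.001))
    return("non-thermo elements must satisfy p < 0.001")
  TRUE
})

# ---- encoders -------------------------------------------------------------

#' Virtual parent of all input encoders
#'
#' An encoder turns 19-nt sense sequences into the fixed-width numeric
#' matrix a layer-1 regressor consumes. Encoders that estimate anything
#' from data (hybrid position weights, feature selection) must be fitted
#' with [fitEncoder()] before encoding.
#' @exportClass Encoder
setClass("Encoder", representation("VIRTUAL"))

#' @rdname Encoder-class
#' @slot type "numeric", "binary" or "hybrid".
#' @slot pwt PositionWeightTable or NULL (hybrid only, after fitting).
#' @exportClass SequenceEncoder
setClass("SequenceEncoder", contains = "Encoder",
  representation(type = "character", pwt = "ANY"),
  prototype(pwt = NULL))

#' @rdname Encoder-class
#' @slot threshold_single numeric or NA.
#' @slot threshold_ngram numeric or NA.
#' @slot params ThermoParams used for the thermodynamic elements.
#' @slot spec FeatureSetSpec or NULL before fitting.
#' @slot name label for the resulting feature method.
#' @exportClass FeatureEncoder
setClass("FeatureEncoder", contains = "Encoder",
  representation(threshold_single = "numeric", threshold_ngram = "numeric",
                 params = "ThermoParams", spec = "ANY", name = "character"),
  prototype(spec = NULL))

#' @rdname Encoder-class
#' @slot rules RuleTable.
#' @exportClass RuleEncoder
setClass("RuleEncoder", contains = "Encoder",
  representation(rules = "RuleTable"))

# ---- models ---------------------------------------------------------------

#' Layer1Model: one characteristic method (encoder + epsilon-SVR)
#'
#' @slot methodName label such as "Binary", "Hybrid", "F65", "R12".
#' @slot category "sequence", "feature" or "rule" (layer-2 pairing needs
#'   one sequence-type and one feature-type component).
#' @slot encoder the fitted Encoder.
#' @slot fit trained e1071 epsilon-SVR.
#' @slot center,scale numeric vectors standardizing encoder columns.
#' @slot cvR 10-fold cross-validated Pearson r between pooled
#'   out-of-fold predictions and observed efficacy, recorded before any
#'   layer-2 use.
#' @slot seed integer seed that fixed the fold assignment.
#' @slot config SVR configuration list.
#' @exportClass Layer1Model
setClass("Layer1Model",
  representation(methodName = "character", category = "character",
                 encoder = "Encoder", fit = "ANY",
                 center = "numeric", scale = "numeric",
                 cvR = "numeric", seed = "integer", config = "list"))

#' StackingFrame: out-of-fold layer-1 predictions for layer-2 training
#'
#' Each training record carries predictions from layer-1 models that
#' were refitted without that record's fold, so layer-2 training never
#' sees in-fold (leaked) predictions.
#'
#' @slot frame data.frame with columns pred1, pred2, observed, fold.
#' @slot components character(2), the component method names.
#' @exportClass StackingFrame
setClass("StackingFrame",
  representation(frame = "data.frame", components = "character"))

setValidity("StackingFrame", function(object) {
  need <- c("pred1", "pred2", "observed", "fold")
  if (!all(need %in% names(object@frame)))
    return(sprintf("frame must have columns %s", paste(need, collapse = ", ")))
  if (length(object@components) != 2L) return("exactly two components")
  TRUE
})

#' FusionModel: a layer-2 combiner of two layer-1 methods
#'
#' @slot mechanism "svr", "nn" (a 2-6-1 sigmoidal network) or
#'   "ga_linear" (weights W1, W2 in \[0,1\] evolved by a genetic
#'   algorithm to minimize mean squared error).
#' @slot components list of the two Layer1Model components
#'   (sequence-type first).
#' @slot fit mechanism-specific fitted object (svm, nnet, or named
#'   weight vector).
#' @slot details mechanism-specific extras (e.g. GA best-MSE trajectory,
#'   NN scaling constants, seeds).
#' @exportClass FusionModel
setClass("FusionModel",
  representation(mechanism = "character", components = "list",
                 fit = "ANY", details = "list"))

setValidity("FusionModel", function(object) {
  if (!object@mechanism %in% c("svr", "nn", "ga_linear"))
    return("mechanism must be svr, nn or ga_linear")
  if (length(object@components) != 2L)
    return("layer 2 fuses exactly two components")
  ok <- vapply(object@components, is, logical(1), class2 = "Layer1Model")
  if (!all(ok)) return("components must be Layer1Model objects")
  TRUE
})

#' EvaluationReport: correlation plus threshold-classification metrics
#'
#' @slot r Pearson correlation between predicted and observed efficacy.
#' @slot acc,sn,sp percentages in \[0,100\]; sn/sp may be NA when
#'   undefined (no positives / no negatives in truth).
#' @slot mcc Matthews correlation coefficient in \[-1,1\].
#' @slot counts named integer vector TP, FP, FN, TN.
#' @slot n number of evaluated records.
#' @slot strata list of per-stratum sub-reports (whole-dG split), or
#'   empty.
#' @slot in_sample TRUE when evaluation reused the training data.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(r = "numeric", acc = "numeric", sn = "numeric",
                 sp = "numeric", mcc = "numeric", counts = "integer",
                 n = "integer", strata = "list", in_sample = "logical"),
  prototype(strata = list(), in_sample = FALSE))

#' PredictorBundle: a trained end-to-end two-layer predictor
#'
#' @slot fusion the selected FusionModel.
#' @slot layer1 all trained Layer1Model objects, admitted or not.
#' @slot config the run configuration (seeds, thresholds,
#'   hyperparameters).
#' @slot selection data.frame of candidate pairs with their held-out r.
#' @slot params ThermoParams used for whole-dG computations at scan time.
#' @exportClass PredictorBundle
setClass("PredictorBundle",
  representation(fusion = "FusionModel", layer1 = "list", config = "list",
                 selection = "data.frame", params = "ThermoParams"))
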