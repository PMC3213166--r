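#' Fit an encoder on a labeled training dataset
#'
#' Estimates anything the encoder learns from data: the position-weight
#' table of the hybrid sequence encoding, or the selected feature set of
#' a feature encoder. Encoders with nothing to learn return themselves.
#'
#' @param encoder an [Encoder-class] object.
#' @param training a labeled [SiRNADataset-class].
#' @param ... passed to methods.
#' @return a fitted encoder of the same class.
#' @export
setGeneric("fitEncoder", function(encoder, training, ...)
  standardGeneric("fitEncoder"))

#' Encode sequences into the numeric matrix a regressor consumes
#'
#' @param encoder a fitted [Encoder-class].
#' @param seqs character vector of normalized 19-nt sense sequences.
#' @return numeric matrix, one row per sequence; column count is the
#'   encoder's fixed width (numeric 19, binary 76, hybrid 95, rules
#'   12 x 19 = 228, feature encoders the size of their element set).
#' @export
setGeneric("encodeMatrix", function(encoder, seqs)
  standardGeneric("encodeMatrix"))

#' @rdname siRNASequences
#' @export
setGeneric("siRNASequences", function(x) standardGeneric("siRNASequences"))

#' @rdname siRNASequences
#' @export
setGeneric("efficacies", function(x) standardGeneric("efficacies"))

#' @rdname siRNASequences
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname siRNASequences
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname cvR
#' @export
setGeneric("cvR", function(x) standardGeneric("cvR"))

#' @rdname cvR
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname cvR
#' @export
setGeneric("methodCategory", function(x) standardGeneric("methodCategory"))

#' @rdname fusionWeights
#' @export
setGeneric("fusionMechanism", function(x) standardGeneric("fusionMechanism"))

#' @rdname fusionWeights
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))

#' @rdname positionWeights
#' @export
setGeneric("positionWeights", function(x) standardGeneric("positionWeights"))

#' @rdname featureElements
#' @export
setGeneric("featureElements", function(x) standardGeneric("featureElements"))

#' Predict siRNA efficacy for new sequences
#'
#' @param object a fitted [Layer1Model-class], [FusionModel-class] or
#'   [PredictorBundle-class].
#' @param seqs character vector of 19-nt sense sequences (or an
#'   [SiRNADataset-class]).
#' @return numeric vector of predicted efficacies (% inhibition), one
#'   per sequence.
#' @export
setGeneric("predictEfficacy", function(object, seqs)
  standardGeneric("predictEfficacy"))
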