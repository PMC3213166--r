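## Sequence, hybrid and rule encodings. All encoders accept a character
## vector of normalized 19-nt sense sequences and return one row per
## sequence; positions are 1-based, 5'->3' on the sense strand.

## One-hot bit order within a quartet, left to right: G, C, U, A
## (A = 0 0 0 1, U = 0 0 1 0, C = 0 1 0 0, G = 1 0 0 0).
QUARTET_ORDER <- c("G", "C", "U", "A")

checkSeqs19 <- function(seqs) {
  seqs <- normalizeSequence(seqs)
  bad <- which(nchar(seqs) != 19L)
  if (length(bad)) stop("sequence ", bad[1], " is not 19 nt")
  bad <- which(grepl("[^ACGU]", seqs))
  if (length(bad))
    stop("sequence ", bad[1], " contains characters outside {A,C,G,U}")
  seqs
}

seqCharMatrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Numeric sequence encoding (width 19)
#'
#' Each position carries a code for its nucleotide: A=1, U=2, C=3, G=4.
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @return numeric matrix, `length(seqs)` x 19.
#' @export
encodeNumeric <- function(seqs) {
  seqs <- checkSeqs19(seqs)
  codes <- c(A = 1, U = 2, C = 3, G = 4)
  m <- matrix(codes[seqCharMatrix(seqs)], nrow = length(seqs))
  colnames(m) <- sprintf("pos%02d", 1:19)
  m
}

#' One-hot (binary) sequence encoding (width 76)
#'
#' Concatenates 19 one-hot quartets in position-major order; within a
#' quartet the bit order is G, C, U, A, so A = 0 0 0 1 and G = 1 0 0 0.
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @return numeric matrix, `length(seqs)` x 76.
#' @export
encodeBinary <- function(seqs) {
  seqs <- checkSeqs19(seqs)
  ch <- seqCharMatrix(seqs)
  n <- length(seqs)
  m <- matrix(0, n, 76L)
  slot_of <- stats::setNames(seq_along(QUARTET_ORDER), QUARTET_ORDER)
  for (pos in 1:19) {
    col0 <- (pos - 1L) * 4L
    m[cbind(seq_len(n), col0 + slot_of[ch[, pos]])] <- 1
  }
  colnames(m) <- as.vector(t(outer(1:19, QUARTET_ORDER,
                                   function(p, b) sprintf("pos%02d.%s", p, b))))
  m
}

#' Fit the position-weight table of the hybrid encoding
#'
#' For each (nucleotide b, position n) computes the Pearson correlation
#' between the 0/1 indicator "position n carries b" and observed
#' efficacy across the training records. Cells whose indicator never
#' varies (nucleotide always or never present), or a constant efficacy
#' vector, get weight 0 with a warning, keeping the encoder total.
#'
#' @param training a labeled [SiRNADataset-class] with at least 3
#'   records.
#' @return a [PositionWeightTable-class].
#' @export
fitPositionWeights <- function(training) {
  stopifnot(is(training, "SiRNADataset"))
  eff <- efficacies(training)
  if (any(is.na(eff))) stop("training dataset must be fully labeled")
  if (length(eff) < 3L) stop("need at least 3 labeled records")
  ch <- seqCharMatrix(siRNASequences(training))
  w <- matrix(0, 4L, 19L, dimnames = list(RNA_BASES, NULL))
  eff_const <- stats::sd(eff) == 0
  n_zero <- 0L
  for (b in RNA_BASES) for (pos in 1:19) {
    ind <- as.numeric(ch[, pos] == b)
    if (eff_const || stats::sd(ind) == 0) {
      n_zero <- n_zero + 1L
    } else {
      w[b, pos] <- stats::cor(ind, eff)
    }
  }
  if (n_zero > 0L)
    warning(n_zero, " zero-variance (nucleotide, position) cell(s) set to weight 0")
  new("PositionWeightTable", weights = w)
}

#' @rdname positionWeights
#' @title Extract the 4 x 19 weight matrix
#' @param x a [PositionWeightTable-class].
#' @return numeric matrix, rows A,U,C,G, columns positions 1..19.
#' @export
setMethod("positionWeights", "PositionWeightTable", function(x) x@weights)

setMethod("show", "PositionWeightTable", function(object) {
  cat("PositionWeightTable: 4 x 19 nucleotide/efficacy correlations\n")
  cat(sprintf("  |p| range [%.3f, %.3f]\n",
              min(abs(object@weights)), max(abs(object@weights))))
})

#' Hybrid sequence encoding (width 95)
#'
#' Concatenates 19 quintets: the one-hot quartet of the nucleotide
#' followed by its fitted position weight p(b, n). With an all-zero
#' weight table the hybrid encoding reduces exactly to the binary one
#' with zeroed fifth slots.
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @param pwt a fitted [PositionWeightTable-class].
#' @return numeric matrix, `length(seqs)` x 95.
#' @export
encodeHybrid <- function(seqs, pwt) {
  stopifnot(is(pwt, "PositionWeightTable"))
  seqs <- checkSeqs19(seqs)
  bin <- encodeBinary(seqs)
  ch <- seqCharMatrix(seqs)
  n <- length(seqs)
  m <- matrix(0, n, 95L)
  for (pos in 1:19) {
    m[, (pos - 1L) * 5L + 1:4] <- bin[, (pos - 1L) * 4L + 1:4]
    m[, pos * 5L] <- pwt@weights[cbind(match(ch[, pos], RNA_BASES), pos)]
  }
  colnames(m) <- as.vector(vapply(1:19, function(p)
    c(sprintf("pos%02d.%s", p, QUARTET_ORDER), sprintf("pos%02d.p", p)),
    character(5)))
  m
}

#' Load a rule table from a delimited config file
#'
#' The file has columns `rule_set`, `position` (1-19), `nucleotide`,
#' `verdict` (+1/-1); lines starting with `#` are comments. Positions a
#' set does not mention are encoded 0. By default the loader insists on
#' exactly 12 rule sets (the width-228 rule encoding); pass
#' `require_n_sets = NULL` to allow custom set counts.
#'
#' @param path config path; default is the shipped curated table.
#' @param require_n_sets required number of rule sets or NULL.
#' @return a [RuleTable-class].
#' @export
loadRuleTable <- function(path = system.file("extdata", "rule_sets.tsv",
                                             package = "siStack"),
                          require_n_sets = 12L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rule_set", "position", "nucleotide", "verdict")
  if (!all(need %in% names(tab)))
    stop("rule table must have columns ", paste(need, collapse = ", "))
  tab$nucleotide <- normalizeSequence(tab$nucleotide)
  sets <- unique(tab$rule_set)
  if (!is.null(require_n_sets) && length(sets) != require_n_sets)
    stop("rule table has ", length(sets), " rule sets; expected ",
         require_n_sets, " (pass require_n_sets = NULL to override)")
  new("RuleTable", verdicts = tab, sets = sets)
}

#' @rdname loadRuleTable
#' @export
defaultRuleTable <- function() loadRuleTable()

setMethod("show", "RuleTable", function(object) {
  cat(sprintf("RuleTable: %d rule sets, %d explicit verdicts\n",
              length(object@sets), nrow(object@verdicts)))
  cat("  sets:", paste(object@sets, collapse = ", "), "\n")
})

#' Rule-set encoding (width = 19 x number of rule sets, 228 by default)
#'
#' For every position the nucleotide is looked up in each rule set in
#' turn: +1 if that set marks it favourable there, -1 if unfavourable,
#' 0 if the set is silent. Serialization is position-major (position 1's
#' 12 slots, then position 2's, ...).
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @param rules a [RuleTable-class].
#' @return numeric matrix over \{-1, 0, +1\}.
#' @export
encodeRules <- function(seqs, rules = defaultRuleTable()) {
  stopifnot(is(rules, "RuleTable"))
  seqs <- checkSeqs19(seqs)
  ch <- seqCharMatrix(seqs)
  n_sets <- length(rules@sets)
  ## verdict lookup array: [position, nucleotide, set]
  lut <- array(0, dim = c(19L, 4L, n_sets),
               dimnames = list(NULL, RNA_BASES, rules@sets))
  v <- rules@verdicts
  lut[cbind(v$position, match(v$nucleotide, RNA_BASES),
            match(v$rule_set, rules@sets))] <- v$verdict
  n <- length(seqs)
  m <- matrix(0, n, 19L * n_sets)
  for (pos in 1:19) {
    base_idx <- match(ch[, pos], RNA_BASES)
    m[, (pos - 1L) * n_sets + seq_len(n_sets)] <- lut[pos, base_idx, , drop = TRUE]
  }
  colnames(m) <- as.vector(t(outer(1:19, rules@sets,
                                   function(p, s) sprintf("pos%02d.%s", p, s))))
  m
}

# ---- Encoder objects ------------------------------------------------------

#' Construct encoders for layer-1 characteristic methods
#'
#' `sequenceEncoder("numeric"/"binary"/"hybrid")` wraps the direct
#' sequence encodings (hybrid learns its position-weight table at fit
#' time); `featureEncoder()` wraps correlation-selected feature sets
#' (see [selectFeatures()]); `ruleEncoder()` wraps the rule-set
#' encoding. All are consumed by [trainLayer1()].
#'
#' @param type sequence encoding type.
#' @param threshold_single,threshold_ngram |r| thresholds for feature
#'   selection, or NA for no restriction beyond p < 0.001.
#' @param params a [ThermoParams-class].
#' @param name feature-method label (e.g. "F85").
#' @param rules a [RuleTable-class].
#' @return an [Encoder-class] object.
#' @export
sequenceEncoder <- function(type = c("binary", "hybrid", "numeric")) {
  type <- match.arg(type)
  new("SequenceEncoder", type = type, pwt = NULL)
}

#' @rdname sequenceEncoder
#' @export
featureEncoder <- function(threshold_single = NA_real_,
                           threshold_ngram = NA_real_,
                           params = defaultThermoParams(),
                           name = "features") {
  new("FeatureEncoder", threshold_single = as.numeric(threshold_single),
      threshold_ngram = as.numeric(threshold_ngram), params = params,
      spec = NULL, name = name)
}

#' @rdname sequenceEncoder
#' @export
ruleEncoder <- function(rules = defaultRuleTable()) {
  new("RuleEncoder", rules = rules)
}

#' @rdname fitEncoder
#' @export
setMethod("fitEncoder", "SequenceEncoder", function(encoder, training, ...) {
  if (encoder@type == "hybrid")
    encoder@pwt <- fitPositionWeights(training)
  encoder
})

#' @rdname fitEncoder
#' @export
setMethod("fitEncoder", "FeatureEncoder", function(encoder, training, ...) {
  cand <- rbind(enumerateSingleFeatures(training),
                enumerateNgramFeatures(training),
                enumerateThermoFeatures(training, encoder@params))
  encoder@spec <- selectFeatures(cand,
                                 threshold_single = encoder@threshold_single,
                                 threshold_ngram = encoder@threshold_ngram,
                                 name = encoder@name)
  encoder
})

#' @rdname fitEncoder
#' @export
setMethod("fitEncoder", "RuleEncoder", function(encoder, training, ...) encoder)

#' @rdname encodeMatrix
#' @export
setMethod("encodeMatrix", "SequenceEncoder", function(encoder, seqs) {
  switch(encoder@type,
    numeric = encodeNumeric(seqs),
    binary = encodeBinary(seqs),
    hybrid = {
      if (is.null(encoder@pwt))
        stop("hybrid encoder must be fitted before encoding")
      encodeHybrid(seqs, encoder@pwt)
    })
})

#' @rdname encodeMatrix
#' @export
setMethod("encodeMatrix", "FeatureEncoder", function(encoder, seqs) {
  if (is.null(encoder@spec))
    stop("feature encoder must be fitted before encoding")
  buildFeatureMatrix(seqs, encoder@spec, encoder@params)
})

#' @rdname encodeMatrix
#' @export
setMethod("encodeMatrix", "RuleEncoder", function(encoder, seqs) {
  encodeRules(seqs, encoder@rules)
})
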