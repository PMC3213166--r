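## Feature characteristics: positional single-nucleotide indicators,
## overlapping n-gram frequencies (n = 2..5) and duplex thermodynamics,
## with correlation/significance selection into named feature sets.

#' Count overlapping occurrences of a subword
#'
#' Frequencies are counted with overlap: in "AAAA" the subword "AA"
#' occurs 3 times, and in "AGGAG" the subword "AG" occurs 2 times.
#'
#' @param seq a single sequence (any length).
#' @param subword a 2-5 nt string over \{A,C,G,U\}.
#' @return non-negative integer count.
#' @export
countNgram <- function(seq, subword) {
  seq <- normalizeSequence(seq)
  subword <- normalizeSequence(subword)
  k <- nchar(subword)
  if (k < 2L || k > 5L) stop("subword length must be 2..5")
  if (grepl("[^ACGU]", subword)) stop("subword must be over {A,C,G,U}")
  n <- nchar(seq)
  if (n < k) return(0L)
  starts <- seq_len(n - k + 1L)
  sum(substring(seq, starts, starts + k - 1L) == subword)
}

## two-sided p-value of a Pearson correlation via the exact t test
corPValue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

## correlation + p for each column of a matrix against y, dropping
## zero-variance columns with a single warning
columnCorrelations <- function(m, y, kind, warn_label) {
  sds <- apply(m, 2L, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance ", warn_label,
            " candidate(s) dropped (undefined correlation)")
  m <- m[, keep, drop = FALSE]
  if (!ncol(m))
    return(data.frame(kind = character(), key = character(),
                      r_train = numeric(), p_value = numeric()))
  r <- as.vector(stats::cor(m, y))
  data.frame(kind = kind, key = colnames(m), r_train = r,
             p_value = corPValue(r, length(y)), stringsAsFactors = FALSE)
}

## counts of each subword (columns) per sequence (rows), overlapping
ngramCountMatrix <- function(seqs, subwords) {
  ns <- nchar(subwords)
  out <- matrix(0L, length(seqs), length(subwords),
                dimnames = list(NULL, subwords))
  for (k in sort(unique(ns))) {
    idx <- which(ns == k)
    L <- nchar(seqs[1])
    starts <- seq_len(L - k + 1L)
    ## windows: length(seqs) x length(starts)
    win <- vapply(starts, function(s) substring(seqs, s, s + k - 1L),
                  character(length(seqs)))
    if (is.null(dim(win))) win <- matrix(win, nrow = length(seqs))
    for (j in idx)
      out[, j] <- rowSums(win == subwords[j])
  }
  out
}

#' Enumerate candidate n-gram feature elements
#'
#' For every subword of length 2-5 observed in at least one training
#' sequence, computes the Pearson correlation (and its two-sided exact-t
#' p-value) between the per-record overlapping frequency and efficacy.
#' Subwords with constant frequency across the dataset are dropped with
#' a warning (their correlation is undefined).
#'
#' @param training a labeled [SiRNADataset-class].
#' @return data.frame of candidate elements (kind "ngram", key
#'   "ngram:<subword>", r_train, p_value).
#' @export
enumerateNgramFeatures <- function(training) {
  stopifnot(is(training, "SiRNADataset"))
  eff <- efficacies(training)
  if (any(is.na(eff))) stop("training dataset must be fully labeled")
  seqs <- siRNASequences(training)
  L <- nchar(seqs[1])
  observed <- character(0)
  for (k in 2:5) {
    starts <- seq_len(L - k + 1L)
    win <- unlist(lapply(starts, function(s) substring(seqs, s, s + k - 1L)),
                  use.names = FALSE)
    observed <- c(observed, unique(win))
  }
  observed <- sort(unique(observed))
  counts <- ngramCountMatrix(seqs, observed)
  colnames(counts) <- paste0("ngram:", colnames(counts))
  columnCorrelations(counts, eff, "ngram", "n-gram")
}

#' Enumerate candidate single-nucleotide positional feature elements
#'
#' The 76 (position 1..19) x (A,U,C,G) indicator features: a record
#' contributes 1 when its nucleotide at that position matches, else 0.
#' Pearson r and p-value are computed against efficacy; zero-variance
#' cells are dropped with a warning.
#'
#' @param training a labeled [SiRNADataset-class].
#' @return data.frame of candidate elements (kind "single", key
#'   "pos<NN>:<base>").
#' @export
enumerateSingleFeatures <- function(training) {
  stopifnot(is(training, "SiRNADataset"))
  eff <- efficacies(training)
  if (any(is.na(eff))) stop("training dataset must be fully labeled")
  ch <- seqCharMatrix(siRNASequences(training))
  ind <- matrix(0L, length(eff), 76L)
  keys <- character(76L)
  j <- 0L
  for (pos in 1:19) for (b in RNA_BASES) {
    j <- j + 1L
    ind[, j] <- as.integer(ch[, pos] == b)
    keys[j] <- sprintf("pos%02d:%s", pos, b)
  }
  colnames(ind) <- keys
  columnCorrelations(ind, eff, "single", "single-nucleotide")
}

#' Enumerate thermodynamic feature elements
#'
#' The 21 duplex-stability quantities: the 18 nearest-neighbor stacking
#' energies spanning antisense positions 1-2 ... 18-19, their sum
#' (whole-duplex dG), and the whole-duplex dH and dS. All are retained
#' by [selectFeatures()] regardless of thresholds; r and p are computed
#' for reporting.
#'
#' @param training a labeled [SiRNADataset-class].
#' @param params a [ThermoParams-class].
#' @return data.frame of candidate elements (kind "thermo").
#' @export
enumerateThermoFeatures <- function(training, params = defaultThermoParams()) {
  stopifnot(is(training, "SiRNADataset"))
  eff <- efficacies(training)
  if (any(is.na(eff))) stop("training dataset must be fully labeled")
  m <- thermoFeatureMatrix(siRNASequences(training), params)
  res <- columnCorrelations(m, eff, "thermo", "thermodynamic")
  ## thermo elements are always retained, including degenerate ones
  dropped <- setdiff(colnames(m), res$key)
  if (length(dropped))
    res <- rbind(res, data.frame(kind = "thermo", key = dropped,
                                 r_train = 0, p_value = 1))
  res
}

thermoKeys <- function() {
  c(sprintf("stack:%02d-%02d", 1:18, 2:19), "wholeG", "dH", "dS")
}

thermoFeatureMatrix <- function(seqs, params) {
  n <- length(seqs)
  anti <- reverseComplementRNA(seqs)
  stepm <- vapply(1:18, function(k) substring(anti, k, k + 1L), character(n))
  if (is.null(dim(stepm))) stepm <- matrix(stepm, nrow = n)
  g <- matrix(params@dG37[stepm], n, 18L)
  h <- matrix(params@dH[stepm], n, 18L)
  s <- matrix(params@dS[stepm], n, 18L)
  m <- cbind(g, rowSums(g), rowSums(h), rowSums(s))
  colnames(m) <- thermoKeys()
  m
}

#' Select feature elements into a frozen FeatureSetSpec
#'
#' Keeps single and n-gram candidates that are significant (p < 0.001)
#' and, when an |r| threshold is set for their family, satisfy
#' `|r| > threshold` (strictly). Thermodynamic candidates are all kept
#' unconditionally. Raising either threshold can only shrink the set,
#' which is how nested method families (e.g. decreasingly permissive
#' sets) arise. Element order is deterministic: single, then ngram,
#' then thermo, each sorted by key.
#'
#' @param candidates data.frame of candidate elements as produced by
#'   the `enumerate*Features()` functions (rbind-ed).
#' @param threshold_single,threshold_ngram numeric |r| cut or NA for
#'   unrestricted.
#' @param name label for the resulting spec.
#' @return a [FeatureSetSpec-class].
#' @export
selectFeatures <- function(candidates, threshold_single = NA_real_,
                           threshold_ngram = NA_real_, name = "custom") {
  stopifnot(all(c("kind", "key", "r_train", "p_value") %in% names(candidates)))
  keep_filtered <- function(df, thr) {
    df <- df[df$p_value < 0.001, , drop = FALSE]
    if (!is.na(thr)) df <- df[abs(df$r_train) > thr, , drop = FALSE]
    df
  }
  singles <- keep_filtered(candidates[candidates$kind == "single", , drop = FALSE],
                           threshold_single)
  ngrams <- keep_filtered(candidates[candidates$kind == "ngram", , drop = FALSE],
                          threshold_ngram)
  thermo <- candidates[candidates$kind == "thermo", , drop = FALSE]
  el <- rbind(singles[order(singles$key), , drop = FALSE],
              ngrams[order(ngrams$key), , drop = FALSE],
              thermo[order(thermo$key), , drop = FALSE])
  if (!nrow(el))
    stop("no feature element survives selection; relax the |r| thresholds ",
         "or the training set is uninformative")
  rownames(el) <- NULL
  new("FeatureSetSpec", name = name, elements = el,
      threshold_single = as.numeric(threshold_single),
      threshold_ngram = as.numeric(threshold_ngram))
}

#' @rdname featureElements
#' @title Extract the frozen element table of a FeatureSetSpec
#' @param x a [FeatureSetSpec-class].
#' @return data.frame with columns kind, key, r_train, p_value.
#' @export
setMethod("featureElements", "FeatureSetSpec", function(x) x@elements)

setMethod("show", "FeatureSetSpec", function(object) {
  el <- object@elements
  cat(sprintf("FeatureSetSpec '%s': %d elements (%d single, %d ngram, %d thermo)\n",
              object@name, nrow(el), sum(el$kind == "single"),
              sum(el$kind == "ngram"), sum(el$kind == "thermo")))
  cat(sprintf("  thresholds: |r| > %s (single), |r| > %s (ngram)\n",
              ifelse(is.na(object@threshold_single), "unrestricted",
                     format(object@threshold_single)),
              ifelse(is.na(object@threshold_ngram), "unrestricted",
                     format(object@threshold_ngram))))
})

#' Build the feature vector(s) for a frozen feature set
#'
#' Produces the regressor input in spec element order: single elements
#' contribute a 0/1 match indicator, n-gram elements their overlapping
#' frequency, thermodynamic elements their real value.
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @param spec a [FeatureSetSpec-class].
#' @param params a [ThermoParams-class] (needed when the spec contains
#'   thermodynamic elements).
#' @return numeric matrix, `length(seqs)` x `nrow(featureElements(spec))`.
#' @export
buildFeatureMatrix <- function(seqs, spec, params = defaultThermoParams()) {
  stopifnot(is(spec, "FeatureSetSpec"))
  seqs <- checkSeqs19(seqs)
  el <- spec@elements
  n <- length(seqs)
  m <- matrix(0, n, nrow(el), dimnames = list(NULL, el$key))
  is_single <- el$kind == "single"
  if (any(is_single)) {
    ch <- seqCharMatrix(seqs)
    parts <- regmatches(el$key[is_single],
                        regexec("^pos([0-9]+):([AUCG])$", el$key[is_single]))
    for (k in seq_along(parts)) {
      pos <- as.integer(parts[[k]][2]); b <- parts[[k]][3]
      m[, which(is_single)[k]] <- as.numeric(ch[, pos] == b)
    }
  }
  is_ngram <- el$kind == "ngram"
  if (any(is_ngram)) {
    subs <- sub("^ngram:", "", el$key[is_ngram])
    m[, is_ngram] <- ngramCountMatrix(seqs, subs)
  }
  is_thermo <- el$kind == "thermo"
  if (any(is_thermo)) {
    tm <- thermoFeatureMatrix(seqs, params)
    m[, is_thermo] <- tm[, el$key[is_thermo], drop = FALSE]
  }
  m
}

#' @rdname buildFeatureMatrix
#' @param seq a single 19-nt sequence.
#' @export
buildFeatureVector <- function(seq, spec, params = defaultThermoParams()) {
  drop(buildFeatureMatrix(seq, spec, params))
}

#' Serialize / restore a FeatureSetSpec as structured text
#'
#' A fitted feature set is a reproducible artifact: the file records
#' the name, the thresholds that produced it and the frozen element
#' list with training r and p values.
#'
#' @param spec a [FeatureSetSpec-class].
#' @param path output (input) path.
#' @return `writeFeatureSpec`: the path invisibly; `readFeatureSpec`:
#'   the restored [FeatureSetSpec-class].
#' @export
writeFeatureSpec <- function(spec, path) {
  stopifnot(is(spec, "FeatureSetSpec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# feature_set_name\t%s", spec@name),
               sprintf("# threshold_single\t%s", spec@threshold_single),
               sprintf("# threshold_ngram\t%s", spec@threshold_ngram)), con)
  utils::write.table(spec@elements, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureSpec
#' @export
readFeatureSpec <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  stopifnot(vapply(meta, `[`, character(1), 1) ==
              c("feature_set_name", "threshold_single", "threshold_ngram"))
  el <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3L,
                          stringsAsFactors = FALSE)
  new("FeatureSetSpec", name = meta[[1]][2], elements = el,
      threshold_single = as.numeric(meta[[2]][2]),
      threshold_ngram = as.numeric(meta[[3]][2]))
}
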