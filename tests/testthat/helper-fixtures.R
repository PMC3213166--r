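## Shared fixtures and independent oracles for the test suite.

BASES <- c("A", "U", "C", "G")

`%||%` <- function(a, b) if (is.null(a)) b else a

randomSeqs <- function(n, len = 19L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

## a small rule table with known verdicts, independent of the shipped one
toyRuleTable <- function(n_sets = 12L) {
  sets <- sprintf("set%02d", seq_len(n_sets))
  df <- data.frame(rule_set = c("set01", "set01", "set02"),
                   position = c(3L, 13L, 3L),
                   nucleotide = c("A", "G", "A"),
                   verdict = c(1, -1, -1))
  extra <- data.frame(rule_set = sets[-(1:2)], position = 1L,
                      nucleotide = "G", verdict = 1)
  new("RuleTable", verdicts = rbind(df, extra), sets = sets)
}

## naive regex-based overlapping count: independent of countNgram's scan
oracleCountNgram <- function(seq, subword) {
  length(gregexpr(paste0("(?=", subword, ")"), seq, perl = TRUE)[[1]]) -
    (gregexpr(paste0("(?=", subword, ")"), seq, perl = TRUE)[[1]][1] == -1)
}

## brute-force Pearson r straight from the definition
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## brute-force metrics by recounting every pair
oracleMetrics <- function(truth, call) {
  tp <- sum(truth & call); fp <- sum(!truth & call)
  fn <- sum(truth & !call); tn <- sum(!truth & !call)
  total <- tp + fp + fn + tn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(acc = 100 * (tp + tn) / total,
       sn = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
       sp = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom))
}

## closed-form box-constrained two-weight least squares on a frame:
## check the unconstrained solution and each face of the [0,1]^2 box
oracleBoxLS <- function(r1, r2, y) {
  mse <- function(w) mean((y - w[1] * r1 - w[2] * r2)^2)
  X <- cbind(r1, r2)
  cands <- list()
  w_un <- tryCatch(drop(solve(crossprod(X), crossprod(X, y))),
                   error = function(e) NULL)
  if (!is.null(w_un) && all(w_un >= 0 & w_un <= 1)) cands <- c(cands, list(w_un))
  ## edges: fix one weight at 0 or 1, solve 1-d least squares, clip
  for (j in 1:2) for (v in c(0, 1)) {
    other <- 3 - j
    resid <- y - v * X[, j]
    w_o <- sum(X[, other] * resid) / sum(X[, other]^2)
    w <- numeric(2); w[j] <- v; w[other] <- min(max(w_o, 0), 1)
    cands <- c(cands, list(w))
  }
  for (a in c(0, 1)) for (b in c(0, 1)) cands <- c(cands, list(c(a, b)))
  vals <- vapply(cands, mse, numeric(1))
  best <- cands[[which.min(vals)]]
  list(w = best, mse = min(vals))
}

makeFrame <- function(pred1, pred2, observed) {
  new("StackingFrame",
      frame = data.frame(pred1 = pred1, pred2 = pred2, observed = observed,
                         fold = 1L),
      components = c("c1", "c2"))
}

## standard small training set: planted GC signal, low noise
train_small <- function() {
  syntheticDataset(250, seed = 71, signal_model = "gc_linear",
                   noise_sd = 5, effect_size = 20)
}

writeTempDataset <- function(ids, seqs, eff, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext == "csv") "," else "\t"
  writeLines(c(paste("id", "sequence", "efficacy", sep = sep),
               paste(ids, seqs, eff, sep = sep)), path)
  path
}
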