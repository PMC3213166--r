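test_that("pearsonR matches direct formula evaluation and affine invariance", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, c(1, 3, 2, 4)), 0.8)
  expect_equal(pearsonR(x, 2 * x + 1), 1)
  expect_equal(pearsonR(x, -x), -1)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearsonR(a, b), oraclePearson(a, b), tolerance = 1e-12)
  ## positive affine transforms leave r unchanged
  expect_lt(abs(pearsonR(3 * a + 7, b) - pearsonR(a, b)), 1e-12)
  expect_lt(abs(pearsonR(a, 0.1 * b - 2) - pearsonR(a, b)), 1e-12)
  expect_error(pearsonR(rep(1, 5), 1:5), "zero variance")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
  expect_error(pearsonR(1:4, 1:5), "equal length")
})

test_that("classification counts use an inclusive >= threshold", {
  cc <- classifyAndCount(predicted = c(60, 80), observed = c(80, 60))
  expect_equal(unname(cc), c(0, 1, 1, 0))  # TP FP FN TN: full inversion
  cc2 <- classifyAndCount(predicted = c(70, 69.999), observed = c(70, 70))
  expect_equal(unname(cc2["TP"]), 1L)
  expect_equal(unname(cc2["FN"]), 1L)
  perfect <- classifyAndCount(c(90, 10, 75), c(95, 20, 71))
  expect_equal(unname(perfect[c("FP", "FN")]), c(0L, 0L))
})

test_that("metrics match their closed forms, including MCC = 0.5 case", {
  m <- confusionMetrics(c(TP = 3, FP = 1, FN = 1, TN = 3))
  expect_equal(m$mcc, 0.5)
  expect_equal(m$acc, 75)
  perfect <- confusionMetrics(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$mcc, 1)
  ## undefined sensitivity reported as NA, not zero
  no_pos <- suppressWarnings(confusionMetrics(c(TP = 0, FP = 2, FN = 0, TN = 3)))
  expect_true(is.na(no_pos$sn))
  expect_warning(confusionMetrics(c(TP = 0, FP = 0, FN = 2, TN = 3)),
                 "MCC")
})

test_that("metrics agree with brute-force recounts over all confusion shapes", {
  ## exhaustive over every (TP, FP, FN, TN) composition with total <= 8
  for (total in 2:8) {
    combos <- expand.grid(tp = 0:total, fp = 0:total, fn = 0:total)
    combos <- combos[combos$tp + combos$fp + combos$fn <= total, ]
    for (i in seq_len(nrow(combos))) {
      tp <- combos$tp[i]; fp <- combos$fp[i]; fn <- combos$fn[i]
      tn <- total - tp - fp - fn
      truth <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
      call <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
      got <- suppressWarnings(
        confusionMetrics(c(TP = tp, FP = fp, FN = fn, TN = tn)))
      want <- oracleMetrics(truth, call)
      expect_equal(got$acc, want$acc)
      expect_equal(got$sn, want$sn)
      expect_equal(got$sp, want$sp)
      expect_equal(got$mcc, want$mcc)
    }
  }
})

test_that("MCC is symmetric under swapping the positive and negative classes", {
  set.seed(7)
  for (i in 1:20) {
    cc <- c(TP = sample(0:10, 1), FP = sample(0:10, 1),
            FN = sample(0:10, 1), TN = sample(0:10, 1))
    if (sum(cc) == 0) next
    swapped <- c(TP = cc[["TN"]], FP = cc[["FN"]], FN = cc[["FP"]],
                 TN = cc[["TP"]])
    expect_equal(suppressWarnings(confusionMetrics(cc)$mcc),
                 suppressWarnings(confusionMetrics(swapped)$mcc))
  }
})

test_that("random balanced predictions give MCC near zero", {
  set.seed(11)
  obs <- rep(c(80, 60), each = 500)
  pred <- sample(rep(c(80, 60), each = 500))
  cc <- classifyAndCount(pred, obs)
  expect_lt(abs(confusionMetrics(cc)$mcc), 0.1)
})

test_that("whole-dG stratification partitions the test set at the boundary", {
  ds <- train_small()
  m <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                   folds = 5L, seed = 2L)
  test <- syntheticDataset(120, seed = 79, signal_model = "gc_linear",
                           noise_sd = 5, effect_size = 20)
  rep_all <- stratifiedEvaluate(m, test, dG_threshold = -Inf)
  expect_equal(rep_all@strata$dG_ge_threshold$n, 120L)
  expect_equal(rep_all@strata$dG_lt_threshold$n, 0L)
  expect_true(is.na(rep_all@strata$dG_lt_threshold$r))

  rep_mid <- stratifiedEvaluate(m, test, dG_threshold = -34.6)
  expect_equal(rep_mid@strata$dG_ge_threshold$n +
                 rep_mid@strata$dG_lt_threshold$n, 120L)
  ## labels re-derivable from an independent whole-dG computation
  dg <- wholeDG(siRNASequences(test))
  expect_equal(rep_mid@strata$dG_ge_threshold$n, sum(dg >= -34.6))

  ## a record sitting exactly on the threshold falls in the >= stratum
  seq_at <- siRNASequences(test)[1]
  params_at <- defaultThermoParams()
  shift <- (wholeDG(seq_at, params_at) - (-34.6)) / 18
  params_at@dG37 <- params_at@dG37 - shift
  expect_equal(wholeDG(seq_at, params_at), -34.6, tolerance = 1e-9)
  one <- suppressWarnings(
    stratifiedEvaluate(m, test[1:3], dG_threshold = -34.6,
                       params = params_at))
  dg3 <- wholeDG(siRNASequences(test[1:3]), params_at)
  expect_equal(one@strata$dG_ge_threshold$n, sum(dg3 >= -34.6))
  expect_gte(one@strata$dG_ge_threshold$n, 1L)
})

test_that("planted heteroscedastic noise makes the weak-stacking stratum cleaner", {
  ## build a labeled set whose noise grows for strong-stacking (low dG)
  ## sequences, then check the >= stratum shows higher r
  set.seed(19)
  seqs <- randomSeqs(400)
  dg <- wholeDG(seqs)
  thr <- stats::median(dg)
  base <- 50 + 20 * scale(-dg)[, 1]
  noise <- ifelse(dg >= thr, 2, 18)
  eff <- pmin(pmax(base + rnorm(400, 0, noise), 0), 100)
  ds <- SiRNADataset(sprintf("h%03d", 1:400), seqs, eff)
  m <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                   folds = 5L, seed = 4L)
  rep <- stratifiedEvaluate(m, ds, dG_threshold = thr, in_sample = TRUE)
  expect_gt(rep@strata$dG_ge_threshold$r, rep@strata$dG_lt_threshold$r)
  expect_true(rep@in_sample)
})

test_that("evaluation reports serialize with per-stratum blocks", {
  ds <- train_small()
  m <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                   folds = 5L, seed = 2L)
  rep <- stratifiedEvaluate(m, ds, in_sample = TRUE)
  path <- tempfile()
  writeEvaluationReport(rep, path)
  txt <- readLines(path)
  expect_true(any(grepl("IN-SAMPLE", txt)))
  flat <- read.delim(paste0(path, ".tsv"))
  expect_true(all(c("r", "mcc", "dG_ge_threshold.r") %in% flat$metric))
})
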