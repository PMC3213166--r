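test_that("n-gram counting is overlapping and matches the worked example", {
  expect_equal(countNgram("AGGAG", "AG"), 2L)
  expect_equal(countNgram("AAAA", "AA"), 3L)
  expect_equal(countNgram("ACGUACGUACGUACGUACG", "GG"), 0L)
  expect_error(countNgram("ACGU", "A"), "2..5")
  expect_error(countNgram("ACGU", "ACGUAC"), "2..5")
  expect_error(countNgram("ACGU", "AN"), "A,C,G,U")
})

test_that("n-gram counts agree with an independent regex oracle", {
  set.seed(101)
  seqs <- randomSeqs(40)
  subwords <- c("AA", "GC", "AGG", "UUU", "ACGU", "GGGG", "AUCGA", "AAAAA")
  for (s in seqs) for (w in subwords)
    expect_equal(countNgram(s, w), oracleCountNgram(s, w),
                 info = paste(s, w))
})

test_that("n-gram enumeration ranks a planted subword first", {
  set.seed(7)
  seqs <- randomSeqs(150)
  gg <- vapply(seqs, countNgram, integer(1), subword = "GG")
  eff <- pmin(pmax(50 + 12 * (gg - mean(gg)) / sd(gg) + rnorm(150, 0, 2), 0), 100)
  ds <- SiRNADataset(sprintf("r%03d", 1:150), seqs, eff)
  cand <- suppressWarnings(enumerateNgramFeatures(ds))
  ## universe bounded by 4^2+4^3+4^4+4^5 = 1360 observed subwords
  expect_lte(nrow(cand), 1360L)
  expect_equal(cand$key[which.max(abs(cand$r_train))], "ngram:GG")
  ## brute-force check of the reported correlation
  expect_equal(cand$r_train[cand$key == "ngram:GG"], oraclePearson(gg, eff),
               tolerance = 1e-12)
})

test_that("single-feature enumeration covers the 76 indicators with exact r", {
  ds <- syntheticDataset(80, seed = 43, signal_model = "motif_rules",
                         noise_sd = 5, effect_size = 20)
  cand <- enumerateSingleFeatures(ds)
  expect_lte(nrow(cand), 76L)
  eff <- efficacies(ds)
  ch <- do.call(rbind, strsplit(siRNASequences(ds), ""))
  ## spot-check a planted cell against brute force
  ind <- as.numeric(ch[, 19] == "A")
  expect_equal(cand$r_train[cand$key == "pos19:A"], oraclePearson(ind, eff),
               tolerance = 1e-12)
  ## the planted motif positions carry the smallest p-values
  top <- cand$key[order(cand$p_value)][1:6]
  expect_true(any(grepl("pos01:G|pos10:U|pos19:A", top)))
})

test_that("feature selection applies p < 0.001 and strict |r| thresholds", {
  cand <- data.frame(
    kind = c("single", "single", "single", "ngram", "ngram", "thermo"),
    key = c("pos01:A", "pos02:C", "pos03:G", "ngram:AG", "ngram:GG", "wholeG"),
    r_train = c(0.30, 0.10, 0.05, 0.09, 0.20, 0.02),
    p_value = c(1e-5, 1e-4, 0.5, 1e-4, 1e-6, 0.9))
  ## unrestricted: every p < 0.001 survivor plus all thermo elements
  f_all <- selectFeatures(cand, name = "open")
  expect_setequal(featureElements(f_all)$key,
                  c("pos01:A", "pos02:C", "ngram:AG", "ngram:GG", "wholeG"))
  ## strict > : r = 0.10 does not survive threshold 0.10
  f_thr <- selectFeatures(cand, threshold_single = 0.10,
                          threshold_ngram = 0.09, name = "tight")
  expect_setequal(featureElements(f_thr)$key,
                  c("pos01:A", "ngram:GG", "wholeG"))
  ## thermo retained regardless of its own r/p
  expect_true("wholeG" %in% featureElements(f_thr)$key)
  expect_error(selectFeatures(cand[cand$kind == "single", ][3, ]), "relax")
})

test_that("raising thresholds never adds elements (monotone shrinkage)", {
  ds <- syntheticDataset(250, seed = 47, signal_model = "gc_linear",
                         noise_sd = 5, effect_size = 20)
  cand <- suppressWarnings(rbind(enumerateSingleFeatures(ds),
                                 enumerateNgramFeatures(ds),
                                 enumerateThermoFeatures(ds)))
  sizes <- vapply(list(c(NA, NA), c(0.10, 0.09), c(0.12, 0.10), c(0.13, 0.12)),
                  function(t) nrow(featureElements(
                    selectFeatures(cand, t[1], t[2]))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  ## survivors equal an independent brute-force filter
  f <- selectFeatures(cand, 0.10, 0.09)
  keep <- (cand$kind == "thermo") |
    (cand$p_value < 0.001 &
       abs(cand$r_train) > ifelse(cand$kind == "single", 0.10, 0.09))
  expect_setequal(featureElements(f)$key, cand$key[keep])
})

test_that("feature vectors carry indicator, frequency and thermo semantics", {
  params <- defaultThermoParams()
  cand <- data.frame(kind = c("single", "ngram", "thermo"),
                     key = c("pos03:A", "ngram:AG", "wholeG"),
                     r_train = c(0.5, 0.4, -0.2),
                     p_value = c(1e-6, 1e-6, 0.01))
  spec <- selectFeatures(cand, name = "toy")
  s_match <- paste0("CCA", "AGGAG", strrep("U", 11))
  v <- buildFeatureVector(s_match, spec, params)
  expect_equal(length(v), 3L)
  expect_equal(unname(v["pos03:A"]), 1)
  expect_gte(unname(v["ngram:AG"]), 2)
  expect_equal(unname(v["ngram:AG"]), countNgram(s_match, "AG"))
  expect_equal(unname(v["wholeG"]), computeThermo(s_match, params)$whole_dG)
  s_nomatch <- strrep("C", 19)
  expect_equal(unname(buildFeatureVector(s_nomatch, spec, params)["pos03:A"]), 0)
})

test_that("feature specs serialize and restore exactly", {
  ds <- syntheticDataset(100, seed = 53, signal_model = "gc_linear",
                         noise_sd = 5, effect_size = 20)
  enc <- fitEncoder(featureEncoder(0.1, 0.1, name = "Fx"), ds)
  path <- tempfile(fileext = ".tsv")
  writeFeatureSpec(enc@spec, path)
  back <- readFeatureSpec(path)
  expect_equal(back@name, "Fx")
  expect_equal(featureElements(back)$key, featureElements(enc@spec)$key)
  expect_equal(featureElements(back)$r_train, featureElements(enc@spec)$r_train,
               tolerance = 1e-12)
})

test_that("duplex thermodynamics obey the nearest-neighbor laws", {
  params <- defaultThermoParams()
  ## homopolymer: all 18 stacks equal the single UU/AA step parameter
  tA <- computeThermo(strrep("A", 19), params)
  expect_true(all(tA$stacks == params@dG37[["UU"]]))
  expect_equal(tA$whole_dG, 18 * params@dG37[["UU"]], tolerance = 1e-9)
  ## additivity
  for (s in randomSeqs(20, seed = 59))
    expect_equal(computeThermo(s, params)$whole_dG,
                 sum(computeThermo(s, params)$stacks), tolerance = 1e-9)
  ## GC-rich duplex strictly stabler than AU-rich
  expect_lt(computeThermo(strrep("GC", 10) |> substr(1, 19), params)$whole_dG,
            computeThermo(strrep("AU", 10) |> substr(1, 19), params)$whole_dG)
  ## missing parameter names the step
  p_bad <- params
  p_bad@dG37 <- params@dG37[names(params@dG37) != "UU"]
  expect_error(computeThermo(strrep("A", 19), p_bad), "UU")
})

test_that("stacks are invariant under reverse-complement involution", {
  params <- defaultThermoParams()
  for (s in randomSeqs(15, seed = 61)) {
    anti <- reverseComplementRNA(s)
    expect_equal(reverseComplementRNA(anti), s)
    ## the duplex is the same molecule read from the other strand
    t_s <- computeThermo(s, params)
    t_a <- computeThermo(anti, params)
    expect_equal(t_s$whole_dG, t_a$whole_dG, tolerance = 1e-9)
    expect_equal(t_s$stacks, rev(t_a$stacks), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("whole dG shifts by 18c when every stack parameter shifts by c", {
  params <- defaultThermoParams()
  shifted <- params
  shifted@dG37 <- params@dG37 + 2.5
  for (s in randomSeqs(10, seed = 67))
    expect_equal(computeThermo(s, shifted)$whole_dG,
                 computeThermo(s, params)$whole_dG + 18 * 2.5,
                 tolerance = 1e-9)
})
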