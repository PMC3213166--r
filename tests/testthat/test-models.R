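## Small synthetic datasets keep layer-1 refits cheap; sizes chosen so
## the planted linear signal is comfortably decodable.

test_that("layer-1 training decodes a planted signal and is deterministic", {
  ds <- train_small()
  m <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                   folds = 5L, seed = 2L)
  expect_s4_class(m, "Layer1Model")
  expect_gt(cvR(m), 0.6)
  expect_equal(methodCategory(m), "sequence")
  m2 <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                    folds = 5L, seed = 2L)
  expect_identical(cvR(m), cvR(m2))
  expect_identical(predictEfficacy(m, siRNASequences(ds)[1:10]),
                   predictEfficacy(m2, siRNASequences(ds)[1:10]))
})

test_that("layer-1 cross-validated r stays near zero on pure noise", {
  null_ds <- syntheticDataset(500, seed = 73, signal_model = "gc_linear",
                              noise_sd = 10, effect_size = 0)
  m <- trainLayer1(null_ds, "Binary", sequenceEncoder("binary"),
                   folds = 5L, seed = 3L)
  expect_lt(abs(cvR(m)), 0.2)
})

test_that("layer-1 training rejects degenerate inputs", {
  tiny <- SiRNADataset(sprintf("r%02d", 1:10), randomSeqs(10, seed = 1),
                       runif(10, 20, 80))
  expect_error(trainLayer1(tiny, "Binary", sequenceEncoder("binary")),
               "at least 20")
  const <- SiRNADataset(sprintf("r%02d", 1:30), randomSeqs(30, seed = 2),
                        rep(50, 30))
  expect_error(trainLayer1(const, "Binary", sequenceEncoder("binary")),
               "zero variance")
})

test_that("admission is inclusive at the threshold and partitions by category", {
  mk <- function(name, cat, r) {
    enc <- if (cat == "sequence") sequenceEncoder("binary")
           else featureEncoder(name = name)
    new("Layer1Model", methodName = name, category = cat, encoder = enc,
        fit = NULL, center = numeric(0), scale = numeric(0), cvR = r,
        seed = 1L, config = list())
  }
  res <- admitMethods(list(mk("SeqA", "sequence", 0.61),
                           mk("FeatB", "feature", 0.59)), threshold = 0.6)
  expect_equal(vapply(res$admitted, methodName, character(1)), "SeqA")
  ## boundary: exactly 0.6 is admitted
  res2 <- admitMethods(list(mk("SeqA", "sequence", 0.60),
                            mk("FeatB", "feature", 0.75)), threshold = 0.6)
  expect_equal(nrow(res2$pairs), 1L)
  expect_error(admitMethods(list(mk("SeqA", "sequence", 0.1),
                                 mk("FeatB", "feature", 0.2))),
               "no method")
  expect_error(admitMethods(list(mk("SeqA", "sequence", 0.61),
                                 mk("FeatB", "feature", 0.59)),
                            require_pair = TRUE),
               "feature-type")
})

test_that("stacking frames hold one out-of-fold prediction per record", {
  ds <- train_small()
  m1 <- trainLayer1(ds, "Binary", sequenceEncoder("binary"),
                    folds = 5L, seed = 2L)
  m2 <- trainLayer1(ds, "F85", methodEncoder("F85"), folds = 5L, seed = 2L)
  fr <- buildStackingFrame(ds, list(m1, m2), folds = 5L, seed = 2L)
  f <- fr@frame
  expect_equal(nrow(f), length(ds))
  expect_false(anyNA(f$pred1) || anyNA(f$pred2))
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_equal(as.vector(table(f$fold)), rep(50, 5))
  expect_equal(f$observed, efficacies(ds))
  expect_named(f, c("pred1", "pred2", "observed", "fold"))
})

test_that("every fusion mechanism recovers a perfect component", {
  set.seed(83)
  obs <- runif(120, 5, 95)
  noise <- runif(120, 5, 95)
  fr <- makeFrame(obs, noise, obs)
  dummy <- list(
    new("Layer1Model", methodName = "c1", category = "sequence",
        encoder = sequenceEncoder("binary"), fit = NULL,
        center = numeric(0), scale = numeric(0), cvR = 1, seed = 1L,
        config = list()),
    new("Layer1Model", methodName = "c2", category = "feature",
        encoder = featureEncoder(), fit = NULL, center = numeric(0),
        scale = numeric(0), cvR = 1, seed = 1L, config = list()))
  f_svr <- trainFusionSVR(fr, dummy)
  expect_gt(pearsonR(fusePredictions(f_svr, obs, noise), obs), 0.99)
  f_nn <- trainFusionNN(fr, dummy, seed = 5L)
  expect_gt(pearsonR(fusePredictions(f_nn, obs, noise), obs), 0.99)
  f_ga <- evolveGAWeights(fr, gaParams(generations = 300, seed = 7L), dummy)
  expect_gt(pearsonR(fusePredictions(f_ga, obs, noise), obs), 0.99)
})

test_that("NN fusion output is bounded in [0,100] and reproducible", {
  set.seed(89)
  fr <- makeFrame(runif(80, 0, 100), runif(80, 0, 100), runif(80, 0, 100))
  dummy <- list(
    new("Layer1Model", methodName = "c1", category = "sequence",
        encoder = sequenceEncoder("binary"), fit = NULL,
        center = numeric(0), scale = numeric(0), cvR = 1, seed = 1L,
        config = list()),
    new("Layer1Model", methodName = "c2", category = "feature",
        encoder = featureEncoder(), fit = NULL, center = numeric(0),
        scale = numeric(0), cvR = 1, seed = 1L, config = list()))
  f1 <- trainFusionNN(fr, dummy, seed = 11L)
  f2 <- trainFusionNN(fr, dummy, seed = 11L)
  p <- fusePredictions(f1, seq(0, 100, length.out = 21),
                       seq(100, 0, length.out = 21))
  expect_true(all(p >= 0 & p <= 100))
  expect_identical(f1@fit$wts, f2@fit$wts)
})

test_that("GA weight evolution matches the box-constrained LS oracle", {
  set.seed(97)
  r1 <- rnorm(60, 50, 15)
  r2 <- 0.6 * r1 + rnorm(60, 20, 8)
  y <- 0.35 * r1 + 0.55 * r2 + rnorm(60, 0, 4)
  fr <- makeFrame(r1, r2, y)
  ga <- evolveGAWeights(fr, gaParams(generations = 2000, seed = 13L))
  ls <- oracleBoxLS(r1, r2, y)
  expect_lt(ga@details$mse, ls$mse * 1.05)
  ## correlated components flatten the MSE ridge, so weights are only
  ## loosely identified; the MSE bound above is the sharp check
  expect_true(all(abs(unname(fusionWeights(ga)) - ls$w) < 0.1))
  ## elitism: best fitness is monotone non-increasing
  expect_true(all(diff(ga@details$trajectory) <= 0))
  ## determinism
  ga2 <- evolveGAWeights(fr, gaParams(generations = 2000, seed = 13L))
  expect_identical(fusionWeights(ga), fusionWeights(ga2))
})

test_that("GA recovers a dominant perfect component's LS weight", {
  set.seed(103)
  obs <- runif(80, 10, 90)
  noise <- rnorm(80, 50, 20)
  fr <- makeFrame(obs, noise, obs)
  ga <- evolveGAWeights(fr, gaParams(generations = 1500, seed = 17L))
  ls <- oracleBoxLS(obs, noise, obs)
  expect_equal(unname(fusionWeights(ga))[1], ls$w[1], tolerance = 0.05)
  expect_error(evolveGAWeights(makeFrame(rep(1, 10), 1:10, 1:10)),
               "zero variance")
})

test_that("degenerate GA weights reduce fusion to a single component", {
  dummy <- list(
    new("Layer1Model", methodName = "c1", category = "sequence",
        encoder = sequenceEncoder("binary"), fit = NULL,
        center = numeric(0), scale = numeric(0), cvR = 1, seed = 1L,
        config = list()),
    new("Layer1Model", methodName = "c2", category = "feature",
        encoder = featureEncoder(), fit = NULL, center = numeric(0),
        scale = numeric(0), cvR = 1, seed = 1L, config = list()))
  m <- new("FusionModel", mechanism = "ga_linear", components = dummy,
           fit = c(W1 = 1, W2 = 0), details = list(components = c("c1", "c2")))
  p1 <- c(10, 50, 90)
  expect_identical(fusePredictions(m, p1, c(99, 1, 42)), p1)
})
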