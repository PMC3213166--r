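## Genetic-algorithm search for the two fusion weights W1, W2 in [0,1]
## minimizing MSE(observed, W1*pred1 + W2*pred2). Binary chromosomes,
## fitness-proportional (roulette) selection, one-point crossover,
## per-bit mutation, elitism of one.

#' Genetic-algorithm parameters for linear weight fusion
#'
#' Defaults follow common small-GA practice for this problem: a
#' population of 100 with one-point crossover at rate 0.7 and per-bit
#' mutation at rate 0.001. Each weight is encoded in `bits` bits mapped
#' linearly onto \[0,1\]; weights are deliberately NOT constrained to
#' sum to 1.
#'
#' @param population population size.
#' @param crossover_rate one-point crossover probability per pair.
#' @param mutation_rate per-bit flip probability.
#' @param generations number of generations.
#' @param seed integer seed (fixes the whole evolution).
#' @param bits bits per weight.
#' @return a named list of GA parameters.
#' @export
gaParams <- function(population = 100L, crossover_rate = 0.7,
                     mutation_rate = 0.001, generations = 2000L,
                     seed = 1L, bits = 16L) {
  stopifnot(population >= 2, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, generations >= 1,
            bits >= 1)
  list(population = as.integer(population), crossover_rate = crossover_rate,
       mutation_rate = mutation_rate, generations = as.integer(generations),
       seed = as.integer(seed), bits = as.integer(bits))
}

## decode a logical chromosome matrix (pop x 2*bits) to weights (pop x 2)
decodeChromosomes <- function(pop_matrix, bits) {
  pow <- 2^((bits - 1):0)
  denom <- 2^bits - 1
  w1 <- (pop_matrix[, seq_len(bits), drop = FALSE] %*% pow) / denom
  w2 <- (pop_matrix[, bits + seq_len(bits), drop = FALSE] %*% pow) / denom
  cbind(as.vector(w1), as.vector(w2))
}

#' Evolve linear fusion weights by a genetic algorithm
#'
#' Minimizes the mean squared error between observed efficacy and the
#' weighted sum `W1 * pred1 + W2 * pred2` over the out-of-fold stacking
#' frame, with W1, W2 in \[0,1\]. A generational GA with binary-encoded
#' chromosomes, roulette selection, one-point crossover, per-bit
#' mutation and elitism of one; with elitism the best MSE is monotone
#' non-increasing across generations.
#'
#' @param frame a [StackingFrame-class].
#' @param ga parameters from [gaParams()].
#' @param components optional list of the two fitted
#'   [Layer1Model-class] components (required for later prediction on
#'   new sequences; the frame alone suffices for weight evolution).
#' @return a [FusionModel-class] with mechanism "ga_linear"; `fit` is
#'   the named weight vector and `details$trajectory` the best MSE per
#'   generation.
#' @export
evolveGAWeights <- function(frame, ga = gaParams(), components = NULL) {
  stopifnot(is(frame, "StackingFrame"))
  f <- frame@frame
  X <- cbind(f$pred1, f$pred2)
  y <- f$observed
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("a component's out-of-fold predictions have zero variance")
  bits <- ga$bits
  L <- 2L * bits
  pop <- ga$population

  res <- withSeed(ga$seed, {
    P <- matrix(stats::runif(pop * L) < 0.5, pop, L)
    trajectory <- numeric(ga$generations)
    best_mse <- Inf
    best_chrom <- P[1, ]
    for (gen in seq_len(ga$generations)) {
      W <- decodeChromosomes(P, bits)
      preds <- X %*% t(W)
      mse <- colMeans((preds - y)^2)
      i_best <- which.min(mse)
      if (mse[i_best] < best_mse) {
        best_mse <- mse[i_best]
        best_chrom <- P[i_best, ]
      }
      trajectory[gen] <- best_mse
      if (gen == ga$generations) break
      ## fitness-proportional selection on inverse MSE
      fit <- 1 / (mse + 1e-12)
      parents <- sample.int(pop, pop, replace = TRUE, prob = fit)
      Q <- P[parents, , drop = FALSE]
      ## one-point crossover on consecutive pairs
      for (i in seq(1L, pop - 1L, by = 2L)) {
        if (stats::runif(1) < ga$crossover_rate) {
          cut <- sample.int(L - 1L, 1L)
          tail_idx <- (cut + 1L):L
          tmp <- Q[i, tail_idx]
          Q[i, tail_idx] <- Q[i + 1L, tail_idx]
          Q[i + 1L, tail_idx] <- tmp
        }
      }
      ## per-bit mutation
      flips <- matrix(stats::runif(pop * L) < ga$mutation_rate, pop, L)
      Q <- xor(Q, flips)
      ## elitism of one: best-so-far chromosome survives unchanged
      Q[1L, ] <- best_chrom
      P <- Q
    }
    w <- decodeChromosomes(matrix(best_chrom, 1L), bits)
    list(weights = c(W1 = w[1, 1], W2 = w[1, 2]), mse = best_mse,
         trajectory = trajectory)
  })

  new("FusionModel", mechanism = "ga_linear",
      components = if (is.null(components))
        list(emptyLayer1Placeholder(frame@components[1]),
             emptyLayer1Placeholder(frame@components[2]))
      else components,
      fit = res$weights,
      details = list(trajectory = res$trajectory, mse = res$mse,
                     ga = ga, components = frame@components))
}

## placeholder so weight-only fusion models built from a bare frame are
## still valid objects; prediction on sequences requires real components
emptyLayer1Placeholder <- function(name) {
  new("Layer1Model", methodName = name, category = "sequence",
      encoder = sequenceEncoder("binary"), fit = NULL,
      center = numeric(0), scale = numeric(0), cvR = NA_real_,
      seed = NA_integer_, config = list())
}
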