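# Inheritable bi-objective combinatorial genetic algorithm (IBCGA) for
# wrapper feature selection around the SVM. A chromosome carries n
# binary feature genes plus two 4-bit genes indexing the 16-value C and
# gamma grid. The algorithm evolves populations with exactly r features
# selected, then inherits solutions from r to r-1 by dropping one
# selected feature, sweeping r from rStart down to rEnd; the final
# answer is the best 10-CV accuracy seen at any r.

#' IBCGA configuration
#'
#' @param rStart,rEnd feature-subset sizes swept (inclusive, decreasing).
#' @param generationsPerStage generations evolved at each r.
#' @param populationSize individuals per generation.
#' @param tournamentSize tournament selection size.
#' @param mutationRate per-gene mutation probability.
#' @param nRuns independent runs aggregated by [aggregateRuns()].
#' @param cvFolds folds of the fitness cross-validation.
#' @return list of class `"IBCGAConfig"`.
#' @export
ibcgaConfig <- function(rStart = 13, rEnd = 1, generationsPerStage = 20,
                        populationSize = 50, tournamentSize = 2,
                        mutationRate = 0.05, nRuns = 30, cvFolds = 10) {
  stopifnot(rStart >= rEnd, rEnd >= 1, generationsPerStage >= 1,
            populationSize >= 4)
  structure(list(rStart = rStart, rEnd = rEnd,
                 generationsPerStage = generationsPerStage,
                 populationSize = populationSize,
                 tournamentSize = tournamentSize,
                 mutationRate = mutationRate, nRuns = nRuns,
                 cvFolds = cvFolds),
            class = "IBCGAConfig")
}

newChromosome <- function(bits, cGene, gGene) {
  list(bits = bits, cGene = as.integer(cGene), gGene = as.integer(gGene))
}

randomChromosome <- function(n, r) {
  bits <- rep(FALSE, n)
  bits[sample(n, r)] <- TRUE
  newChromosome(bits, sample(0:15, 1), sample(0:15, 1))
}

chromosomeKey <- function(ch)
  paste(c(ch$bits + 0L, ch$cGene, ch$gGene), collapse = "")

decodeParams <- function(ch)
  list(C = svmParamGrid()[ch$cGene + 1L],
       gamma = svmParamGrid()[ch$gGene + 1L])

# Cached 10-CV fitness of a chromosome on the table.
makeFitness <- function(table, cvFolds, foldSeed) {
  cache <- new.env(parent = emptyenv())
  featNames <- colnames(featureMatrix(table))
  function(ch) {
    if (!any(ch$bits)) return(0)
    key <- chromosomeKey(ch)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    p <- decodeParams(ch)
    acc <- cvAccuracy(table, p$C, p$gamma, folds = cvFolds,
                      seed = foldSeed, features = featNames[ch$bits])
    assign(key, acc, envir = cache)
    acc
  }
}

# Smallest two-level orthogonal array with >= k factor columns:
# m = 2^ceil(log2(k + 1)) rows, m - 1 columns; entry (i, j) is
# parity(popcount(i & j)) over row index i = 0..m-1, column j = 1..m-1.
orthogonalArray <- function(k) {
  m <- 2^ceiling(log2(k + 1))
  rows <- 0:(m - 1)
  oa <- sapply(seq_len(m - 1), function(j)
    vapply(rows, function(i) {
      bits <- bitwAnd(i, j)
      count <- 0L
      while (bits > 0L) { count <- count + bitwAnd(bits, 1L)
        bits <- bitwShiftR(bits, 1L) }
      count %% 2L
    }, 0L))
  matrix(oa, nrow = m)[, seq_len(k), drop = FALSE]
}

# Assemble a chromosome from parent 1, overriding the factor positions
# listed in `factors` with parent levels chosen by `levels` (0 = p1,
# 1 = p2). Factor positions 1..n are feature bits, n+1..n+4 bits of the
# C gene, n+5..n+8 bits of the gamma gene.
composeChild <- function(p1, p2, factors, levels) {
  n <- length(p1$bits)
  ch <- p1
  for (t in seq_along(factors)) {
    f <- factors[t]
    src <- if (levels[t] == 0L) p1 else p2
    if (f <= n) {
      ch$bits[f] <- src$bits[f]
    } else {
      b <- f - n   # 1..4 -> C gene bit, 5..8 -> gamma gene bit
      gene <- if (b <= 4L) "cGene" else "gGene"
      bit <- if (b <= 4L) b else b - 4L
      mask <- bitwShiftL(1L, bit - 1L)
      cur <- ch[[gene]]
      srcBit <- bitwAnd(src[[gene]], mask)
      ch[[gene]] <- bitwOr(bitwAnd(cur, bitwXor(15L, mask)), srcBit)
    }
  }
  ch
}

# Repair a chromosome to exactly r selected features, flipping the bits
# with the weakest main effects first (effects may be NULL -> random).
repairChromosome <- function(ch, r, effects = NULL) {
  n <- length(ch$bits)
  pc <- sum(ch$bits)
  if (pc == r) return(ch)
  pref <- if (is.null(effects)) runif(n) else effects
  if (pc > r) {
    on <- which(ch$bits)
    drop <- on[order(pref[on])][seq_len(pc - r)]
    ch$bits[drop] <- FALSE
  } else {
    off <- which(!ch$bits)
    add <- off[order(-pref[off])][seq_len(r - pc)]
    ch$bits[add] <- TRUE
  }
  ch
}

#' Orthogonal-array crossover
#'
#' Identifies the genes on which the parents differ, lays them on the
#' smallest two-level orthogonal array, evaluates the array's row
#' combinations with the fitness function, and returns (1) the best
#' evaluated row and (2) the combination assembled from the per-factor
#' main-effect winners. Genes shared by both parents pass through
#' unchanged. With `r` given, children are repaired to exactly `r`
#' selected features by flipping the bits with the weakest main effects.
#'
#' @param p1,p2 chromosomes (`list(bits, cGene, gGene)`).
#' @param fitness function of a chromosome returning a numeric score.
#' @param r target number of selected features, or NULL for no repair.
#' @return list of two chromosomes; attribute `"evaluations"` carries
#'   the number of fitness calls spent.
#' @export
oaCrossover <- function(p1, p2, fitness, r = NULL) {
  n <- length(p1$bits)
  diffFeat <- which(p1$bits != p2$bits)
  geneBits <- function(g) bitwAnd(bitwShiftR(g, 0:3), 1L)
  diffC <- which(geneBits(p1$cGene) != geneBits(p2$cGene)) + n
  diffG <- which(geneBits(p1$gGene) != geneBits(p2$gGene)) + n + 4L
  factors <- c(diffFeat, diffC, diffG)
  k <- length(factors)
  if (k == 0L) {
    out <- list(p1, p2)
    attr(out, "evaluations") <- 0L
    return(out)
  }
  oa <- orthogonalArray(k)
  cand <- lapply(seq_len(nrow(oa)), function(i)
    composeChild(p1, p2, factors, oa[i, ]))
  fits <- vapply(cand, fitness, 0)
  # per-factor main effects: mean fitness at level 0 vs level 1
  winners <- integer(k); featEffect <- rep(0, n)
  for (t in seq_len(k)) {
    f0 <- mean(fits[oa[, t] == 0L]); f1 <- mean(fits[oa[, t] == 1L])
    winners[t] <- if (f1 > f0) 1L else 0L
    if (factors[t] <= n) {
      src <- if (winners[t] == 0L) p1 else p2
      # effect size of keeping this feature on, for repair ordering
      featEffect[factors[t]] <- abs(f1 - f0) *
        (if (src$bits[factors[t]]) 1 else -1)
    }
  }
  child1 <- cand[[which.max(fits)]]
  child2 <- composeChild(p1, p2, factors, winners)
  if (!is.null(r)) {
    child1 <- repairChromosome(child1, r, featEffect)
    child2 <- repairChromosome(child2, r, featEffect)
  }
  out <- list(child1, child2)
  attr(out, "evaluations") <- nrow(oa)
  out
}

# Swap mutation preserving the selected-feature count, plus random resets
# of the two parameter genes.
mutateChromosome <- function(ch, rate) {
  n <- length(ch$bits)
  if (runif(1) < rate * n / 2 && any(ch$bits) && !all(ch$bits)) {
    on <- which(ch$bits); off <- which(!ch$bits)
    i <- on[sample.int(length(on), 1)]
    j <- off[sample.int(length(off), 1)]
    ch$bits[i] <- FALSE; ch$bits[j] <- TRUE
  }
  if (runif(1) < rate) ch$cGene <- sample(0:15, 1)
  if (runif(1) < rate) ch$gGene <- sample(0:15, 1)
  ch
}

#' Run the inheritable bi-objective genetic algorithm
#'
#' For each subset size r from `rStart` down to `rEnd`: evolve
#' `generationsPerStage` generations of tournament selection,
#' orthogonal-array crossover and swap mutation (all individuals keep
#' exactly r features; the best individual is carried over unchanged).
#' On inheritance to the next stage every individual drops one randomly
#' chosen selected feature. Returns the best chromosome of every stage
#' and the overall best by cross-validated accuracy (ties prefer fewer
#' features).
#'
#' @param table a [FeatureTable-class].
#' @param config an [ibcgaConfig()].
#' @param seed run seed controlling initialization, evolution and the
#'   fitness folds.
#' @return list: `perStage` (list keyed by r: `chromosome`, `fitness`),
#'   `best` (`features`, `C`, `gamma`, `cvAccuracy`, `r`).
#' @export
ibcgaRun <- function(table, config = ibcgaConfig(), seed = 1L) {
  n <- ncol(featureMatrix(table))
  if (config$rStart > n) stop("rStart exceeds the number of features")
  featNames <- colnames(featureMatrix(table))
  withSeed(seed, {
    foldSeed <- sample.int(1e6, 1)
    fitness <- makeFitness(table, config$cvFolds, foldSeed)
    pop <- lapply(seq_len(config$populationSize), function(i)
      randomChromosome(n, config$rStart))
    perStage <- list()
    for (r in seq(config$rStart, config$rEnd)) {
      fits <- vapply(pop, fitness, 0)
      for (gen in seq_len(config$generationsPerStage)) {
        elite <- pop[[which.max(fits)]]
        newPop <- list(elite)
        while (length(newPop) < config$populationSize) {
          pick <- function() {
            idx <- sample.int(length(pop), config$tournamentSize)
            pop[[idx[which.max(fits[idx])]]]
          }
          kids <- oaCrossover(pick(), pick(), fitness, r = r)
          kids <- lapply(kids, mutateChromosome,
                         rate = config$mutationRate)
          kids <- lapply(kids, repairChromosome, r = r)
          newPop <- c(newPop, kids)
        }
        pop <- newPop[seq_len(config$populationSize)]
        fits <- vapply(pop, fitness, 0)
      }
      bi <- which.max(fits)
      perStage[[as.character(r)]] <-
        list(chromosome = pop[[bi]], fitness = fits[bi])
      if (r > config$rEnd) {
        pop <- lapply(pop, function(ch) {   # inheritance: drop one bit
          on <- which(ch$bits)
          ch$bits[on[sample.int(length(on), 1)]] <- FALSE
          ch
        })
      }
    }
    stageFits <- vapply(perStage, `[[`, 0, "fitness")
    stageR <- as.integer(names(perStage))
    bestIdx <- which(stageFits == max(stageFits))
    bestIdx <- bestIdx[which.min(stageR[bestIdx])]   # fewest features
    bch <- perStage[[bestIdx]]$chromosome
    p <- decodeParams(bch)
    list(perStage = perStage,
         best = list(features = featNames[bch$bits], C = p$C,
                     gamma = p$gamma,
                     cvAccuracy = perStage[[bestIdx]]$fitness,
                     r = sum(bch$bits)))
  })
}

#' Aggregate repeated IBCGA runs into a selection report
#'
#' Counts, per feature, membership in each run's final solution and
#' keeps the single best solution over all runs.
#'
#' @param runs list of [ibcgaRun()] outputs.
#' @param featureNames names of all candidate features.
#' @return A [SelectionReport-class] object.
#' @export
aggregateRuns <- function(runs, featureNames) {
  stopifnot(length(runs) >= 1L)
  counts <- setNames(integer(length(featureNames)), featureNames)
  for (r in runs)
    counts[r$best$features] <- counts[r$best$features] + 1L
  accs <- vapply(runs, function(r) r$best$cvAccuracy, 0)
  best <- runs[[which.max(accs)]]$best
  new("SelectionReport", counts = counts, nRuns = length(runs),
      best = best, runs = lapply(runs, `[[`, "best"))
}
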