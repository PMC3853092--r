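sixDoses <- c(0, 10, 50, 100, 200, 1000)

test_that("Bartlett gate matches the textbook formula and flags extremes", {
  set.seed(10)
  groups <- list(rnorm(5), rnorm(5), rnorm(5))
  dg <- doseGroupedFeature(unlist(groups), rep(c(0, 10, 50), each = 5))
  got <- bartlettGate(dg)
  # direct evaluation of the Bartlett statistic
  k <- 3; n <- rep(5, 3); N <- sum(n)
  s2 <- vapply(groups, var, 0)
  sp2 <- sum((n - 1) * s2) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(s2))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  pOracle <- pchisq(stat, k - 1, lower.tail = FALSE)
  expect_equal(got$bartlettP, pOracle, tolerance = 1e-6)

  # equal variances (shifted copies) pass the gate
  base <- rnorm(36)
  eq <- doseGroupedFeature(c(base, base + 5, base - 2),
                           rep(c(0, 10, 50), each = 36))
  expect_true(bartlettGate(eq)$homoscedastic)

  # gross violation fails it
  set.seed(11)
  bad <- doseGroupedFeature(c(rnorm(36, 0, 1), rnorm(36, 0, 10)),
                            rep(c(0, 10), each = 36))
  expect_false(bartlettGate(bad)$homoscedastic)

  # zero-variance group: heteroscedastic with warning, no failure
  zv <- doseGroupedFeature(c(rep(1, 5), rnorm(5)),
                           rep(c(0, 10), each = 5))
  expect_warning(g <- bartlettGate(zv), "zero-variance")
  expect_false(g$homoscedastic)
})

test_that("ANOVA R-squared and F agree with hand-computed sums of squares", {
  set.seed(12)
  dose <- rep(sixDoses, each = 36)
  y <- 5 - 0.8 * logDose(dose) + rnorm(length(dose))
  dg <- doseGroupedFeature(y, dose)
  got <- onewayAnova(dg, useWelch = FALSE)
  gm <- mean(y)
  ssb <- sum(tapply(y, dose, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, dose, function(v) sum((v - mean(v))^2)))
  fOracle <- (ssb / 5) / (ssw / (length(y) - 6))
  expect_equal(got$fStatistic, fOracle, tolerance = 1e-9)
  expect_equal(got$rSquared, 100 * ssb / (ssb + ssw), tolerance = 1e-9)

  # identical means: R2 near zero; degenerate separation: R2 = 100
  flat <- doseGroupedFeature(rep(c(1, 2, 3), times = 3),
                             rep(c(0, 10, 50), each = 3))
  expect_lt(onewayAnova(flat)$rSquared, 1e-9)
  sep <- doseGroupedFeature(c(0, 0, 1, 1), rep(c(0, 10), each = 2))
  expect_equal(onewayAnova(sep)$rSquared, 100)

  # Welch and standard agree under equal variances and balance
  w <- onewayAnova(dg, useWelch = TRUE)
  expect_equal(w$rSquared, got$rSquared)
  expect_gt(w$fStatistic, 0)
})

test_that("Tukey letters are consistent with the pairwise decisions", {
  set.seed(13)
  # all groups equal: one shared letter
  eq <- doseGroupedFeature(rnorm(60), rep(c(0, 10, 50), each = 20))
  tl <- tukeyHsdLetters(eq)
  expect_true(all(tl$letters == tl$letters[1]))

  # one extreme group earns a unique letter
  ex <- doseGroupedFeature(c(rnorm(20), rnorm(20), rnorm(20, 50)),
                           rep(c(0, 10, 50), each = 20))
  te <- tukeyHsdLetters(ex)
  expect_false(any(strsplit(te$letters[3], "")[[1]] %in%
                     unlist(strsplit(te$letters[1:2], ""))))

  # property: shared letter <=> not significantly different
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    dose <- rep(seq_len(k) * 10, each = 8)
    y <- rnorm(length(dose), mean = rep(sample(0:3, k, TRUE), each = 8))
    dg <- doseGroupedFeature(y, dose)
    got <- tukeyHsdLetters(dg)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      share <- any(strsplit(got$letters[i], "")[[1]] %in%
                     strsplit(got$letters[j], "")[[1]])
      expect_identical(share, !got$differs[i, j])
    }
  }
})

test_that("regression on published group means reproduces the equations", {
  tab <- readDoseGroupMeans()
  fitFor <- function(fn) {
    sub <- tab[tab$feature == fn, ]
    dg <- doseGroupedFeature(sub$mean_value, sub$dose_ng_per_ml, fn)
    fitLogDoseRegression(dg, anovaR2 = sub$anova_r2[1])
  }
  sc <- fitFor("somaCount")
  expect_identical(selectedModel(sc), "quadratic")
  expect_equal(unname(sc@quadratic["a"]), -35.3, tolerance = 0.02)
  expect_equal(unname(sc@quadratic["b"]), 80.4, tolerance = 0.02)
  expect_equal(unname(sc@quadratic["c"]), 219.3, tolerance = 0.02)
  expect_equal(varianceExplained(sc), 95.1, tolerance = 0.01)

  nl <- fitFor("neuriteLength")
  expect_identical(selectedModel(nl), "linear")
  expect_equal(unname(nl@linear["slope"]), -26100, tolerance = 0.02)

  ep <- fitFor("endingPoint#")
  expect_identical(selectedModel(ep), "linear")
  expect_equal(unname(ep@linear["slope"]), -976, tolerance = 0.02)
  expect_equal(varianceExplained(ep), 99.7, tolerance = 0.01)

  as_ <- fitFor("Avg_somaArea")
  expect_identical(selectedModel(as_), "linear")
  expect_equal(unname(as_@linear["slope"]), 69.4, tolerance = 0.02)
})

test_that("exactly linear data select the linear model with full VE", {
  dose <- rep(sixDoses, each = 2)
  y <- 2 * logDose(dose)
  dg <- doseGroupedFeature(y, dose)
  reg <- fitLogDoseRegression(dg)
  expect_identical(selectedModel(reg), "linear")
  expect_equal(unname(reg@linear["slope"]), 2, tolerance = 1e-9)
  expect_equal(unname(reg@linear["intercept"]), 0, tolerance = 1e-9)
  expect_equal(varianceExplained(reg), 100, tolerance = 1e-9)
  expect_true(reg@successful)
})

test_that("pure quadratic trends select the quadratic model", {
  set.seed(14)
  dose <- rep(sixDoses, each = 12)
  x <- logDose(dose)
  y <- -3 * x^2 + 9 * x + 1 + rnorm(length(x), 0, 0.3)
  reg <- fitLogDoseRegression(doseGroupedFeature(y, dose))
  expect_identical(selectedModel(reg), "quadratic")
  expect_equal(unname(reg@quadratic["a"]), -3, tolerance = 0.15)
})

test_that("balanced per-image and group-mean fits share coefficients", {
  set.seed(15)
  dose <- rep(sixDoses, each = 36)
  y <- 4 - 1.5 * logDose(dose) + rnorm(length(dose))
  full <- fitLogDoseRegression(doseGroupedFeature(y, dose))
  means <- tapply(y, dose, mean)
  mdg <- doseGroupedFeature(as.numeric(means), sixDoses)
  red <- fitLogDoseRegression(mdg)
  expect_equal(full@linear[c("intercept", "slope")],
               red@linear[c("intercept", "slope")], tolerance = 1e-9)
  expect_equal(full@quadratic[c("a", "b", "c")],
               red@quadratic[c("a", "b", "c")], tolerance = 1e-9)
  # quadratic never fits worse than linear
  expect_gte(full@quadratic[["r2"]], full@linear[["r2"]])
})

test_that("variance-explained ratio recomputes from the stored fit", {
  tab <- readDoseGroupMeans()
  sub <- tab[tab$feature == "somaCount", ]
  dg <- doseGroupedFeature(sub$mean_value, sub$dose_ng_per_ml, "somaCount")
  fit <- fitLogDoseRegression(dg, anovaR2 = sub$anova_r2[1])
  expect_equal(varianceExplainedRatio(fit, dg), 95.1, tolerance = 0.01)
  # a perfect fit through all means gives exactly 100
  dose <- rep(c(0, 10, 100), each = 2)
  y <- 3 * logDose(dose) + 1
  dgp <- doseGroupedFeature(y, dose)
  expect_equal(varianceExplainedRatio(fitLogDoseRegression(dgp), dgp),
               100, tolerance = 1e-9)
})

test_that("Pearson dose correlation follows the covariance formula", {
  set.seed(16)
  dose <- rep(sixDoses, each = 6)
  x <- logDose(dose)
  y <- 2 * x + rnorm(length(x), 0, 0.5)
  dg <- doseGroupedFeature(y, dose)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonDoseCorrelation(dg), oracle, tolerance = 1e-12)
  # y strictly increasing in x -> r = 1; constant -> NA
  inc <- doseGroupedFeature(3 * logDose(dose) + 2, dose)
  expect_equal(pearsonDoseCorrelation(inc), 1, tolerance = 1e-12)
  cst <- doseGroupedFeature(rep(1, length(dose)), dose)
  expect_true(is.na(pearsonDoseCorrelation(cst)))
})

test_that("analyzeAllFeatures assembles one reconciled row per feature", {
  set.seed(17)
  dose <- rep(sixDoses, each = 10)
  x <- logDose(dose)
  mat <- cbind(lin = -2 * x + rnorm(length(x), 0, 0.2),
               quad = -1.5 * x^2 + 4 * x + rnorm(length(x), 0, 0.2),
               flat = rnorm(length(x)))
  ft <- featureTable(mat, dose)
  rep <- analyzeAllFeatures(ft)
  expect_equal(nrow(rep), 3)
  expect_identical(rep$selected_model[rep$feature == "lin"], "linear")
  expect_identical(rep$selected_model[rep$feature == "quad"], "quadratic")
  expect_true(all(c("anova_r2", "linear_r2", "quad_r2",
                    "variance_explained", "equation", "tukey_letters")
                  %in% names(rep)))
  expect_true(rep$variance_explained[rep$feature == "lin"] > 90)
})
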