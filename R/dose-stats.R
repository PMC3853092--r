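# Dose-grouped statistics: homoscedasticity gate, standard/Welch one-way
# ANOVA, Tukey HSD letter display, and linear/quadratic regression on log
# dose with a 5-percent model-selection rule and a >90 percent
# variance-explained success criterion.

#' Group feature values by dose
#'
#' @param values numeric vector, one value per image.
#' @param dose numeric dose labels (ng/mL), same length.
#' @param feature feature name carried along for reporting.
#' @return list of class `"DoseGroupedFeature"`: `feature`, `doses`
#'   (sorted unique), `groups` (list of value vectors, one per dose).
#' @export
doseGroupedFeature <- function(values, dose, feature = "feature") {
  stopifnot(length(values) == length(dose))
  keep <- is.finite(values)
  values <- values[keep]; dose <- dose[keep]
  doses <- sort(unique(dose))
  if (length(doses) < 2L) stop("need at least two dose groups")
  groups <- lapply(doses, function(d) values[dose == d])
  structure(list(feature = feature, doses = doses, groups = groups),
            class = "DoseGroupedFeature")
}

#' Log-dose design values
#'
#' The regression abscissa: `x = log10(dose)` with the 0-dose control
#' mapped to `x = 0`. This convention reproduces published dose-response
#' coefficients when applied to group means.
#'
#' @param dose numeric doses, ng/mL.
#' @return numeric vector of x values.
#' @export
logDose <- function(dose) ifelse(dose > 0, log10(dose), 0)

#' Bartlett homoscedasticity gate
#'
#' Classical Bartlett test across dose groups; `homoscedastic` when
#' p >= 0.05, which selects the standard rather than the Welch ANOVA. A
#' zero-variance group leaves the statistic undefined; the feature is
#' then flagged heteroscedastic with a warning.
#'
#' @param data a [doseGroupedFeature()].
#' @param alpha gate level.
#' @return list: `bartlettP`, `homoscedastic`.
#' @export
bartlettGate <- function(data, alpha = 0.05) {
  if (any(vapply(data$groups, length, 0L) < 2L))
    stop("Bartlett test needs at least 2 values per group")
  if (any(vapply(data$groups, var, 0) == 0)) {
    warning("zero-variance group: Bartlett statistic undefined; ",
            "flagged heteroscedastic")
    return(list(bartlettP = NA_real_, homoscedastic = FALSE))
  }
  p <- bartlett.test(data$groups)$p.value
  list(bartlettP = p, homoscedastic = p >= alpha)
}

#' One-way ANOVA with between-group R-squared
#'
#' `rSquared` is always the fraction of total variation that lies between
#' groups (100 x SS_between / SS_total); `f` and `p` come from the
#' standard pooled-variance ANOVA or from Welch's variance-weighted
#' variant when `useWelch` is set.
#'
#' @param data a [doseGroupedFeature()].
#' @param useWelch use Welch's heteroscedastic ANOVA.
#' @return list: `rSquared` (percent), `fStatistic`, `pValue`,
#'   `usedWelch`.
#' @export
onewayAnova <- function(data, useWelch = FALSE) {
  if (length(data$groups) < 2L) stop("need >= 2 groups")
  y <- unlist(data$groups)
  g <- factor(rep(seq_along(data$groups),
                  vapply(data$groups, length, 0L)))
  gm <- mean(y)
  ssb <- sum(vapply(data$groups, function(v)
    length(v) * (mean(v) - gm)^2, 0))
  sst <- sum((y - gm)^2)
  r2 <- if (sst > 0) 100 * ssb / sst else 0
  ow <- oneway.test(y ~ g, var.equal = !useWelch)
  list(rSquared = r2, fStatistic = unname(ow$statistic),
       pValue = unname(ow$p.value), usedWelch = useWelch)
}

#' Tukey HSD compact letter display
#'
#' All pairwise comparisons by the Tukey-Kramer studentized-range
#' criterion with the pooled within-group variance; groups whose means do
#' not differ at the `1 - alpha` level share a letter, assigned by the
#' standard insert-and-absorb algorithm.
#'
#' @param data a [doseGroupedFeature()].
#' @param alpha significance level.
#' @return list: `letters` (named by dose), `differs` (logical k x k
#'   matrix of significant pairwise differences).
#' @export
tukeyHsdLetters <- function(data, alpha = 0.05) {
  k <- length(data$groups)
  ns <- vapply(data$groups, length, 0L)
  means <- vapply(data$groups, mean, 0)
  N <- sum(ns)
  msw <- sum(vapply(data$groups, function(v)
    sum((v - mean(v))^2), 0)) / (N - k)
  differs <- matrix(FALSE, k, k)
  if (msw > 0) {
    qcrit <- qtukey(1 - alpha, k, N - k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
      differs[i, j] <- differs[j, i] <-
        abs(means[i] - means[j]) / se > qcrit
    }
  }
  letters <- compactLetterDisplay(differs, order(means, decreasing = TRUE))
  names(letters) <- as.character(data$doses)
  list(letters = letters, differs = differs)
}

# Insert-and-absorb compact letter display: `differs` is the significant-
# difference matrix; `ord` the processing order of the groups.
compactLetterDisplay <- function(differs, ord = seq_len(nrow(differs))) {
  k <- nrow(differs)
  cols <- list(rep(TRUE, k))    # letter columns: membership vectors
  for (i in ord) for (j in ord) {
    if (j <= i || !differs[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        # split the column into one without i and one without j
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb duplicated / contained columns
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(cols[[a]] <= cols[[b]])) keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- rep("", k)
  for (ci in seq_along(cols))
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], LETTERS[ci])
  lab
}

#' Linear and quadratic regression on log dose
#'
#' Ordinary least squares of the per-image values (or group means) on
#' `x = log10(dose)` (control at 0), for both a linear and a quadratic
#' model. The quadratic is selected when its R-squared improvement
#' exceeds 5 percent of the variation left unexplained by the linear
#' model; `varianceExplained` is the share of between-group variation
#' captured by the selected model, and the fit is `successful` when that
#' share exceeds 90 percent.
#'
#' R-squared values are reported on the total-variance scale. When the
#' data carry replication this is direct; when each group holds a single
#' value (group means), supply the feature's ANOVA R-squared via
#' `anovaR2` so the between-group shares can be rescaled onto the total
#' scale before the selection rule is applied.
#'
#' @param data a [doseGroupedFeature()] (per-image values or group
#'   means).
#' @param anovaR2 optional percent of total variation lying between
#'   groups; required for total-scale R-squared when fitting group means.
#' @return A [DoseRegressionResult-class] object.
#' @export
fitLogDoseRegression <- function(data, anovaR2 = NULL) {
  x <- rep(logDose(data$doses), vapply(data$groups, length, 0L))
  y <- unlist(data$groups)
  gm <- mean(y)
  ns <- vapply(data$groups, length, 0L)
  gmeans <- vapply(data$groups, mean, 0)
  grandW <- sum(ns * gmeans) / sum(ns)
  ssb <- sum(ns * (gmeans - grandW)^2)

  fitL <- lm(y ~ x)
  veL <- veFromFit(fitL, data)
  hasQuad <- length(unique(x)) >= 3L
  fitQ <- if (hasQuad) lm(y ~ x + I(x^2)) else NULL
  veQ <- if (hasQuad) veFromFit(fitQ, data) else NA_real_

  meansOnly <- all(ns == 1L)
  toTotal <- function(ve, fit) {
    if (!meansOnly) {
      sst <- sum((y - gm)^2)
      if (sst > 0) 100 * sum((fitted(fit) - gm)^2) / sst else 0
    } else if (!is.null(anovaR2)) anovaR2 * ve / 100 else ve
  }
  r2L <- toTotal(veL, fitL)
  r2Q <- if (hasQuad) toTotal(veQ, fitQ) else NA_real_

  selQuad <- hasQuad && (r2Q - r2L) > 0.05 * (100 - r2L)
  model <- if (selQuad) "quadratic" else "linear"
  ve <- if (selQuad) veQ else veL
  cl <- coef(fitL); cq <- if (hasQuad) coef(fitQ) else c(NA, NA, NA)
  eq <- if (selQuad)
    sprintf("y = %.4gx^2 + %.4gx + %.4g", cq[3], cq[2], cq[1])
  else
    sprintf("y = %.4gx + %.4g", cl[2], cl[1])
  new("DoseRegressionResult",
      feature = data$feature,
      linear = c(intercept = unname(cl[1]), slope = unname(cl[2]),
                 r2 = r2L),
      quadratic = c(a = unname(cq[3]), b = unname(cq[2]),
                    c = unname(cq[1]), r2 = r2Q),
      selectedModel = model,
      varianceExplained = min(ve, 100),
      successful = isTRUE(ve > 90),
      equation = gsub("\\+ -", "- ", eq))
}

# Percent of between-group SS captured by the fitted values at the group
# x positions.
veFromFit <- function(fit, data) {
  ns <- vapply(data$groups, length, 0L)
  gmeans <- vapply(data$groups, mean, 0)
  grand <- sum(ns * gmeans) / sum(ns)
  ssb <- sum(ns * (gmeans - grand)^2)
  if (ssb <= 0) return(NA_real_)
  xg <- logDose(data$doses)
  nd <- data.frame(x = xg)
  yhat <- predict(fit, nd)
  100 * sum(ns * (yhat - grand)^2) / ssb
}

#' Variance-explained ratio of a fitted dose model
#'
#' Recomputes, for an existing fit, the percent of between-group
#' variation accounted for by the model's fitted values at the group
#' log-dose positions. Undefined (NA) when the between-group sum of
#' squares is zero.
#'
#' @param fit a [DoseRegressionResult-class].
#' @param data the [doseGroupedFeature()] the fit refers to.
#' @return percent, possibly above 100 for overshooting fits (the value
#'   stored in the result object is capped).
#' @export
varianceExplainedRatio <- function(fit, data) {
  xg <- logDose(data$doses)
  yhat <- if (fit@selectedModel == "quadratic")
    fit@quadratic["a"] * xg^2 + fit@quadratic["b"] * xg +
      fit@quadratic["c"]
  else fit@linear["slope"] * xg + fit@linear["intercept"]
  ns <- vapply(data$groups, length, 0L)
  gmeans <- vapply(data$groups, mean, 0)
  grand <- sum(ns * gmeans) / sum(ns)
  ssb <- sum(ns * (gmeans - grand)^2)
  if (ssb <= 0) return(NA_real_)
  unname(100 * sum(ns * (yhat - grand)^2) / ssb)
}

#' Pearson correlation between a feature and log dose
#'
#' Per-image correlation on the [logDose()] scale; NA (with no failure)
#' when either variable has zero variance.
#'
#' @param data a [doseGroupedFeature()].
#' @return correlation coefficient, or NA.
#' @export
pearsonDoseCorrelation <- function(data) {
  x <- rep(logDose(data$doses), vapply(data$groups, length, 0L))
  y <- unlist(data$groups)
  if (length(y) < 3L) stop("need at least 3 images")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Dose-response analysis of every feature in a table
#'
#' Runs, per feature: Shapiro-Wilk normality (reported, not gating),
#' the Bartlett gate, standard or Welch ANOVA accordingly, Tukey HSD
#' letters, and the log-dose regression with model selection.
#'
#' @param table a [FeatureTable-class].
#' @param alpha significance level for the gate and HSD.
#' @return data frame, one row per feature, with ANOVA, Tukey letters,
#'   regression coefficients, selected model, variance explained and
#'   success flag.
#' @export
analyzeAllFeatures <- function(table, alpha = 0.05) {
  mat <- featureMatrix(table)
  dose <- doseLabels(table)
  rows <- lapply(colnames(mat), function(fn) {
    vals <- mat[, fn]
    if (all(!is.finite(vals)) || sd(vals[is.finite(vals)]) == 0)
      return(NULL)
    dg <- doseGroupedFeature(vals, dose, fn)
    shp <- tryCatch(shapiro.test(unlist(dg$groups))$p.value,
                    error = function(e) NA_real_)
    gate <- withCallingHandlers(
      bartlettGate(dg, alpha), warning = function(w)
        invokeRestart("muffleWarning"))
    an <- onewayAnova(dg, useWelch = !gate$homoscedastic)
    tk <- tukeyHsdLetters(dg, alpha)
    reg <- fitLogDoseRegression(dg)
    data.frame(
      feature = fn, shapiro_p = shp, bartlett_p = gate$bartlettP,
      used_welch = an$usedWelch, anova_r2 = an$rSquared,
      f_statistic = an$fStatistic, p_value = an$pValue,
      tukey_letters = paste(tk$letters, collapse = "/"),
      linear_r2 = reg@linear[["r2"]], quad_r2 = reg@quadratic[["r2"]],
      selected_model = reg@selectedModel,
      variance_explained = reg@varianceExplained,
      successful = reg@successful, equation = reg@equation,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
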