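#' Fit an OPLS-DA classifier
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' after mean-centering and unit-variance scaling, `nOrtho` response-
#' orthogonal components are removed by orthogonal signal correction and a
#' single predictive PLS component is fitted to the class response
#' (cases coded +1, controls -1). Deterministic given input order.
#'
#' Because the response covariance `X'y` is invariant under orthogonal
#' deflation, the predictive weight vector equals the one-component PLS1
#' weight; the orthogonal components absorb class-independent structured
#' variation (their scores have zero covariance with the response).
#'
#' @param X samples x features M-value matrix (column names = probe ids).
#' @param y class labels (factor/character with `case` level, or +-1 / 0-1).
#' @param nOrtho number of orthogonal components (default 1); must be
#'   smaller than `rank(X)`.
#' @param scale unit-variance scaling (default TRUE, as in standard
#'   chemometrics practice).
#' @return an [OPLSDAModel-class].
#' @export
fitOPLSDA <- function(X, y, nOrtho = 1, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  yv <- 2 * phenotypeTo01(y) - 1
  if (min(table(yv)) < 2) stop("need at least 2 samples per class")
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped")
    X <- X[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (nOrtho >= qr(Xs)$rank) stop("nOrtho must be smaller than rank(X)")
  yc <- yv - mean(yv)
  p <- ncol(Xs)
  Wo <- matrix(0, p, 0); Po <- matrix(0, p, 0)
  for (j in seq_len(nOrtho)) {
    w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
    tt <- drop(Xs %*% w)
    pl <- drop(crossprod(Xs, tt)) / sum(tt^2)
    wo <- pl - drop(crossprod(pl, w)) * w       # part of the loading ⟂ w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break                       # nothing orthogonal left
    wo <- wo / nrm
    to <- drop(Xs %*% wo)
    po <- drop(crossprod(Xs, to)) / sum(to^2)
    Xs <- Xs - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po)
  }
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  tt <- drop(Xs %*% w)
  pl <- drop(crossprod(Xs, tt)) / sum(tt^2)
  cl <- sum(yc * tt) / sum(tt^2)
  new("OPLSDAModel", center = ctr, scale = scl, w = w, pLoad = pl,
      cLoad = cl, Wo = Wo, Po = Po, tTrain = tt,
      nOrtho = ncol(Wo), featureNames = colnames(X))
}

#' Predictive scores for new samples
#'
#' Applies the training centering/scaling, deflates each sample by the
#' model's orthogonal components, and projects onto the predictive weight
#' vector. Positive scores point toward the case class.
#'
#' @param model an [OPLSDAModel-class].
#' @param Xnew samples x features matrix over the training feature set
#'   (matched by column name when available).
#' @return numeric score vector (one per row of `Xnew`).
#' @export
predictScores <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (!is.null(colnames(Xnew))) {
    if (!all(model@featureNames %in% colnames(Xnew)))
      stop("feature mismatch between model and new data")
    Xnew <- Xnew[, model@featureNames, drop = FALSE]
  } else if (ncol(Xnew) != length(model@featureNames)) {
    stop("feature mismatch between model and new data")
  }
  Xs <- sweep(sweep(Xnew, 2, model@center), 2, model@scale, "/")
  for (j in seq_len(model@nOrtho)) {
    to <- drop(Xs %*% model@Wo[, j])
    Xs <- Xs - tcrossprod(to, model@Po[, j])
  }
  drop(Xs %*% model@w)
}

#' @describeIn fitOPLSDA `predict` method, forwarding to [predictScores()].
#' @param object an `OPLSDAModel`.
#' @param newdata samples x features matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "OPLSDAModel", function(object, newdata, ...) {
  predictScores(object, newdata)
})

#' ROC evaluation with median-score thresholding
#'
#' AUC by the Mann-Whitney formulation (ties counted 1/2); sensitivity and
#' specificity at a classification threshold equal to the median of the
#' predicted scores (scores above the threshold are called cases).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels class labels (both classes must be present).
#' @param threshold score cutoff; defaults to `median(scores)`.
#' @return list of class `"ClassifierEval"`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `roc_points` (`data.frame(fpr, tpr)`,
#'   monotone nondecreasing in both coordinates).
#' @export
evaluateROC <- function(scores, labels, threshold = NULL) {
  y <- phenotypeTo01(labels)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores)            # midranks handle ties at weight 1/2
  auc <- (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  if (is.null(threshold)) threshold <- median(scores)
  sens <- mean(scores[y == 1] > threshold)
  spec <- mean(scores[y == 0] <= threshold)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(cuts, function(ct) mean(scores[y == 0] >= ct), 0),
    tpr = vapply(cuts, function(ct) mean(scores[y == 1] >= ct), 0))
  structure(list(auc = auc, sensitivity = sens, specificity = spec,
                 threshold = threshold, roc_points = roc),
            class = "ClassifierEval")
}

#' @export
print.ClassifierEval <- function(x, ...) {
  cat(sprintf(
    "ClassifierEval: AUC %.3f, sensitivity %.2f, specificity %.2f @ %.3g\n",
    x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Elastic-net best-subset selection
#'
#' Penalized binomial regression (glmnet) over standardized features; the
#' features with nonzero coefficients form the best subset. When `lambda`
#' is not given it is chosen by k-fold cross-validation as the most
#' regularized model within one standard error of the minimum deviance.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param mixing elastic-net mixing parameter alpha in `[0, 1]`
#'   (default 0.5).
#' @param lambda fixed penalty, or NULL for cross-validation.
#' @param nfolds folds for cross-validation (default 10).
#' @param typeMeasure cross-validation loss (default `"class"`,
#'   misclassification error — the subset is selected for classification).
#' @param seed integer seed for the fold assignment.
#' @return list of class `"BestSubset"`: `probe_ids`, `coefs` (named,
#'   nonzero exactly for the selected sites), `mixing`, `lambda`.
#' @export
elasticNetSelect <- function(X, y, mixing = 0.5, lambda = NULL,
                             nfolds = 10, typeMeasure = "class",
                             seed = 1L) {
  if (!is.null(lambda) && lambda < 0) stop("lambda must be non-negative")
  yv <- phenotypeTo01(y)
  X <- as.matrix(X)
  if (is.null(lambda)) {
    cvfit <- withSeed(substreamSeed(seed, "glmnet-cv"),
      glmnet::cv.glmnet(X, yv, family = "binomial", alpha = mixing,
                        nfolds = nfolds, type.measure = typeMeasure))
    lambda <- cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, yv, family = "binomial", alpha = mixing)
  }
  cfm <- as.matrix(coef(fit, s = lambda, exact = FALSE))
  cf <- setNames(cfm[-1, 1], rownames(cfm)[-1])          # drop intercept
  nz <- cf != 0
  structure(list(probe_ids = names(cf)[nz], coefs = cf[nz],
                 mixing = mixing, lambda = lambda),
            class = "BestSubset")
}

#' @export
print.BestSubset <- function(x, ...) {
  cat("BestSubset:", length(x$probe_ids), "site(s) at lambda =",
      signif(x$lambda, 3), "(mixing", x$mixing, ")\n")
  invisible(x)
}

#' Compare effect sizes of the best subset against the remaining pool
#'
#' Two-sided two-sample comparison of `|delta_beta|` between the selected
#' sites and the rest of the pooled sites. Default test is the Wilcoxon
#' rank-sum (robust for the skewed effect-size distributions of methylation
#' differences); Welch's t is available.
#'
#' @param deltaBeta named numeric vector of beta-scale effects over all
#'   pooled sites.
#' @param subsetIds probe ids of the best subset (nonempty, proper subset).
#' @param test `"wilcox"` (default) or `"welch"`.
#' @return list with `p`, `test`, group summary statistics.
#' @export
compareEffectSizes <- function(deltaBeta, subsetIds,
                               test = c("wilcox", "welch")) {
  test <- match.arg(test)
  a <- abs(deltaBeta[names(deltaBeta) %in% subsetIds])
  b <- abs(deltaBeta[!names(deltaBeta) %in% subsetIds])
  if (!length(a) || !length(b))
    stop("best subset must be a nonempty, proper subset of the pooled sites")
  p <- if (test == "wilcox") wilcox.test(a, b, exact = FALSE)$p.value
       else stats::t.test(a, b)$p.value
  list(p = p, test = test,
       subset_mean = mean(a), subset_sd = sd(a), n_subset = length(a),
       rest_mean = mean(b), rest_sd = sd(b), n_rest = length(b))
}
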