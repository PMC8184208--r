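# Independent oracles used across the suite. Each is a deliberately naive,
# brute-force implementation kept separate from the package code paths.

# OLS coefficients by the normal equations.
olsOracle <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Logistic regression by plain Newton-Raphson on the log-likelihood.
newtonLogisticOracle <- function(X, y, maxIter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxIter)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  list(coef = beta,
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# Benjamini-Hochberg step-up computed literally from its definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# AUC by exhaustive concordant-pair counting, ties at 1/2.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  aRange <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(aRange, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)), 0)
  pObs <- probs[aRange == tab[1, 1]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# First-order partial correlation from pairwise correlations.
pcorOracle3 <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Small, quick synthetic configuration shared by several tests.
smallConfig <- function(seed = 1L,
                        nFlagged = c(cross_reactive = 6, snp_within_3bp = 4,
                                     smoking_associated = 2),
                        nSexProbes = c(X = 8, Y = 2), ...) {
  syntheticConfig(seed = seed, nProbes = 300, nIslands = 4,
                  nGeneBodies = 4, nPromoters = 4,
                  nCasesDisc = 20, nControlsDisc = 20,
                  nCasesCV = 20, nControlsCV = 20,
                  nFlagged = nFlagged, nSexProbes = nSexProbes, ...)
}

# Demographics with no case/control imbalance, for null-calibration tests.
balancedDemographics <- function() {
  list(ageMean = list(discovery = c(case = 71, control = 71),
                      cv = c(case = 71, control = 71)),
       ageSD = list(discovery = c(case = 8, control = 8),
                    cv = c(case = 8, control = 8)),
       maleProp = list(discovery = c(case = 0.5, control = 0.5),
                       cv = c(case = 0.5, control = 0.5)))
}
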