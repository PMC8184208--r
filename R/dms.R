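#' Per-site linear models for differential methylation
#'
#' Fits, for every probe, the ordinary least-squares model
#' `M ~ phenotype + confounders` and reports the phenotype coefficient on
#' the M scale with its standard error, t statistic and two-sided p-value.
#' The raw effect size `delta_beta` is the group mean difference on the beta
#' scale in the `control - case` orientation (negative values mean
#' hypermethylation in cases).
#'
#' @param M probes x samples M-value matrix.
#' @param phenotype factor/character/0-1 vector; cases are coded 1
#'   (factor level `"case"` or the second level).
#' @param confounders samples x q data.frame/matrix (factors allowed), or
#'   NULL.
#' @param beta optional probes x samples beta matrix for the raw
#'   `delta_beta`; derived from `M` when missing.
#' @return `data.frame` with columns `probe_id`, `coef_M`, `se_M`,
#'   `df_resid`, `t`, `p`, `delta_beta`, plus the unscaled coefficient
#'   standard deviation (`stdev_unscaled`) and residual variance (`s2`)
#'   needed for moderation.
#' @export
fitSiteModels <- function(M, phenotype, confounders = NULL, beta = NULL) {
  y01 <- phenotypeTo01(phenotype)
  X <- cbind(`(Intercept)` = 1, phenotype = y01)
  if (!is.null(confounders)) {
    C <- model.matrix(~ ., data = as.data.frame(confounders))[, -1, drop = FALSE]
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); q <- ncol(X); df <- n - q
  fit <- lm.fit(X, t(M))
  cf <- if (is.matrix(fit$coefficients)) fit$coefficients["phenotype", ]
        else fit$coefficients["phenotype"]
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  u <- sqrt(XtXinv[2, 2])             # unscaled sd of the phenotype coef
  se <- sqrt(s2) * u
  tstat <- cf / se
  p <- 2 * pt(-abs(tstat), df)
  if (is.null(beta)) beta <- expit2(M)
  db <- rowMeans(beta[, y01 == 0, drop = FALSE]) -
        rowMeans(beta[, y01 == 1, drop = FALSE])
  data.frame(probe_id = rownames(M) %||% as.character(seq_len(nrow(M))),
             coef_M = unname(cf), se_M = unname(se), df_resid = df,
             t = unname(tstat), p = unname(p), delta_beta = unname(db),
             stdev_unscaled = u, s2 = unname(s2),
             stringsAsFactors = FALSE, row.names = NULL)
}

phenotypeTo01 <- function(phenotype) {
  if (is.numeric(phenotype)) {
    stopifnot(all(phenotype %in% c(0, 1)))
    return(as.numeric(phenotype))
  }
  f <- as.factor(phenotype)
  if ("case" %in% levels(f)) as.numeric(f == "case")
  else as.numeric(f == levels(f)[2])
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks the per-probe residual variances toward a common prior by the
#' hierarchical model of moderated microarray statistics: the prior
#' `(d0, s0^2)` is estimated by method of moments on `log s^2`
#' (via [limma::squeezeVar()]) and the posterior variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`. Moderated t statistics use
#' `s~` and `d0 + d` degrees of freedom.
#'
#' @param fit output of [fitSiteModels()] (>= 10 probes, equal residual df).
#' @return list with `s0_sq`, `d0`, `s_tilde_sq`, `t_mod`, `p_mod`,
#'   `df_total`.
#' @export
moderateVariance <- function(fit) {
  if (nrow(fit) < 10) stop("need at least 10 probes for moderation")
  if (all(fit$s2 == 0)) stop("zero residual variance everywhere")
  df <- fit$df_resid[1]
  sq <- limma::squeezeVar(fit$s2, df = df)
  d0 <- sq$df.prior
  dfTotal <- if (is.finite(d0)) d0 + df else Inf
  seMod <- sqrt(sq$var.post) * fit$stdev_unscaled
  tMod <- fit$coef_M / seMod
  pMod <- if (is.finite(dfTotal)) 2 * pt(-abs(tMod), dfTotal)
          else 2 * pnorm(-abs(tMod))
  list(s0_sq = sq$var.prior, d0 = d0, s_tilde_sq = sq$var.post,
       t_mod = tMod, p_mod = pMod, df_total = dfTotal)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' order-preserving.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length/order as `p`.
#' @export
bhFDR <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Bonferroni threshold and adjustment
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `bonferroniThreshold`: `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' @rdname bonferroniThreshold
#' @param p p-values to adjust.
#' @return `bonferroniAdjust`: `min(1, m p)`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be at least 1")
  pmin(1, m * p)
}

#' Discovery -> cross-validation replication of site calls
#'
#' Stage 1 keeps probes with discovery FDR `q < qThreshold`; stage 2
#' recomputes FDR in the cross-validation results over that subset only
#' (configurable to genome-wide) and keeps probes replicating at the same
#' level. Effect-direction concordance across stages is flagged per probe.
#'
#' @param disc,cv `data.frame`s with columns `probe_id`, `p`, `coef_M`
#'   (e.g. [fitSiteModels()] rows with moderated p substituted); must share
#'   a probe universe.
#' @param qThreshold FDR level (default 0.05).
#' @param cvScope `"subset"` (default) or `"genome"`: the universe over
#'   which the cross-validation FDR is computed.
#' @return list with `discoverySignificant` (probe ids), `replicated`
#'   (probe ids) and `table` (per stage-1 probe: both stages' p/q, signs,
#'   `concordant`).
#' @export
discoveryReplication <- function(disc, cv, qThreshold = 0.05,
                                 cvScope = c("subset", "genome")) {
  cvScope <- match.arg(cvScope)
  if (!length(intersect(disc$probe_id, cv$probe_id)))
    stop("discovery and cross-validation probe universes are disjoint")
  disc$q <- bhFDR(disc$p)
  stage1 <- disc$probe_id[disc$q < qThreshold]
  cvIdx <- match(stage1, cv$probe_id)
  if (anyNA(cvIdx))
    stop("stage-1 probes missing from the cross-validation results")
  cvQ <- if (cvScope == "subset") bhFDR(cv$p[cvIdx])
         else bhFDR(cv$p)[cvIdx]
  dIdx <- match(stage1, disc$probe_id)
  tab <- data.frame(probe_id = stage1,
                    disc_p = disc$p[dIdx], disc_q = disc$q[dIdx],
                    disc_coef = disc$coef_M[dIdx],
                    cv_p = cv$p[cvIdx], cv_q = cvQ,
                    cv_coef = cv$coef_M[cvIdx], stringsAsFactors = FALSE)
  tab$replicated <- tab$cv_q < qThreshold
  tab$concordant <- sign(tab$disc_coef) == sign(tab$cv_coef)
  list(discoverySignificant = stage1,
       replicated = tab$probe_id[tab$replicated], table = tab)
}

#' Fixed-effect inverse-variance meta-analysis of two stages
#'
#' `w_i = 1/se_i^2`, `beta_meta = sum(w_i beta_i) / sum(w_i)`,
#' `se_meta = sum(w_i)^{-1/2}`, `z = beta_meta / se_meta`, two-sided normal
#' p. A DerSimonian-Laird random-effects variant (two-stage case) is
#' available behind `method = "random"`.
#'
#' @param beta1,se1,beta2,se2 stage estimates and standard errors
#'   (vectorized; `se > 0`).
#' @param method `"fixed"` (default) or `"random"`.
#' @return `data.frame` with `beta_meta`, `se_meta`, `z`, `p_meta`,
#'   `method`.
#' @export
metaFixedEffect <- function(beta1, se1, beta2, se2,
                            method = c("fixed", "random")) {
  method <- match.arg(method)
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be positive")
  w1 <- 1 / se1^2; w2 <- 1 / se2^2
  if (method == "random") {
    # DerSimonian-Laird between-stage variance for k = 2
    bFE <- (w1 * beta1 + w2 * beta2) / (w1 + w2)
    Q <- w1 * (beta1 - bFE)^2 + w2 * (beta2 - bFE)^2
    cc <- (w1 + w2) - (w1^2 + w2^2) / (w1 + w2)
    tau2 <- pmax(0, (Q - 1) / cc)
    w1 <- 1 / (se1^2 + tau2); w2 <- 1 / (se2^2 + tau2)
  }
  betaMeta <- (w1 * beta1 + w2 * beta2) / (w1 + w2)
  seMeta <- 1 / sqrt(w1 + w2)
  z <- betaMeta / seMeta
  data.frame(beta_meta = betaMeta, se_meta = seMeta, z = z,
             p_meta = 2 * pnorm(-abs(z)), method = method,
             stringsAsFactors = FALSE)
}

#' Back out a standard error from a printed two-sided p-value
#'
#' Inverts a two-sided normal test: `se = |beta| / qnorm(1 - p/2)`. Used
#' only to reproduce published meta-analysis arithmetic from printed
#' effect/p pairs.
#'
#' @param beta effect estimate (nonzero).
#' @param p two-sided p-value strictly inside (0, 1).
#' @return the implied standard error.
#' @export
seFromP <- function(beta, p) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (any(beta == 0)) stop("beta must be nonzero")
  abs(beta) / qnorm(1 - p / 2)
}
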