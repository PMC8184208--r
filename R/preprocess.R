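#' M-values from signal intensities
#'
#' `M = log2((meth + 1) / (unmeth + 1))`, elementwise. The +1 offsets keep
#' zero-intensity entries finite (`M = 0` when both channels are 0).
#'
#' @param meth,unmeth non-negative intensity matrices/vectors of equal shape.
#' @return M-values of the same shape.
#' @export
computeMValues <- function(meth, unmeth) {
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative intensities")
  log2((meth + 1) / (unmeth + 1))
}

#' Predict sample sex from X-chromosome methylation
#'
#' Mean beta over X-chromosome probes; X inactivation gives females
#' intermediate values while males stay at the (typically hypomethylated)
#' baseline. Samples below `threshold` are called male.
#'
#' @param object a [MethylationExperiment-class].
#' @param threshold mean-X-beta cutoff (default 0.25).
#' @return character vector (`"M"`/`"F"`), `NA` when no X probes exist.
#' @export
predictSex <- function(object, threshold = 0.25) {
  xp <- probeManifest(object)$chr == "X"
  if (!any(xp)) return(rep(NA_character_, ncol(object)))
  mx <- colMeans(getBeta(object)[xp, , drop = FALSE])
  ifelse(mx < threshold, "M", "F")
}

#' Sample QC filter: intensity and sex concordance
#'
#' Excludes samples whose log2 median methylated OR unmethylated intensity
#' falls below `intensityThreshold` (category `intensity`), then — among the
#' remaining samples — those whose predicted sex disagrees with the reported
#' sex (category `sex`). Samples with a missing reported sex are flagged
#' under `sex`, never passed silently.
#'
#' @param object a [MethylationExperiment-class] with intensity assays.
#' @param intensityThreshold log2 median-intensity cutoff (default 11.0).
#' @param sexThreshold passed to [predictSex()].
#' @return list with `object` (retained samples), `excluded` (named integer
#'   vector `intensity`, `sex`) and `excludedIds`.
#' @export
filterSamples <- function(object, intensityThreshold = 11.0,
                          sexThreshold = 0.25) {
  meth <- assay(object, "Meth"); unmeth <- assay(object, "Unmeth")
  medM <- log2(apply(meth, 2, median))
  medU <- log2(apply(unmeth, 2, median))
  lowInt <- medM < intensityThreshold | medU < intensityThreshold
  reported <- as.character(colData(object)$sex)
  predicted <- predictSex(object, sexThreshold)
  mismatch <- !lowInt &
    (is.na(reported) | (!is.na(predicted) & reported != predicted))
  keep <- !lowInt & !mismatch
  list(object = object[, keep],
       excluded = c(intensity = sum(lowInt), sex = sum(mismatch)),
       excludedIds = colnames(object)[!keep])
}

#' Probe QC filter with first-match category accounting
#'
#' Excludes probes failing detection (detection p > `detectionP` in more
#' than a fraction `detectionProp` of samples), carrying the
#' `cross_reactive` or `snp_within_3bp` manifest flags, mapping to
#' chromosomes X/Y, or flagged `smoking_associated` — in that order, each
#' probe counted once under the first matching category, so the ledger
#' conserves counts exactly.
#'
#' @param object a [MethylationExperiment-class]; its manifest must carry
#'   the flag columns.
#' @param detectionP per-entry detection p-value threshold (default 0.05).
#' @param detectionProp maximum tolerated fraction of samples failing
#'   detection (default 0.05).
#' @return list with `object` (retained probes), `excluded` (named integer
#'   vector over the five categories) and `excludedIds`.
#' @export
filterProbes <- function(object, detectionP = 0.05, detectionProp = 0.05) {
  man <- probeManifest(object)
  det <- getDetectionP(object)
  failDet <- if (is.null(det)) rep(FALSE, nrow(object))
             else rowMeans(det > detectionP) > detectionProp
  cats <- cbind(detection = failDet,
                cross_reactive = man$cross_reactive,
                snp_within_3bp = man$snp_within_3bp,
                sex_chromosome = man$chr %in% c("X", "Y"),
                smoking = man$smoking_associated)
  first <- integer(nrow(cats))
  for (j in rev(seq_len(ncol(cats)))) first[cats[, j]] <- j
  excluded <- setNames(tabulate(first, nbins = ncol(cats)), colnames(cats))
  keep <- first == 0L
  list(object = object[keep, ],
       excluded = excluded, excludedIds = rownames(object)[!keep])
}

#' Run sample + probe QC and assemble the conservation-checked ledger
#'
#' @param object a [MethylationExperiment-class].
#' @param intensityThreshold,sexThreshold see [filterSamples()].
#' @param detectionP,detectionProp see [filterProbes()].
#' @return list with `object` (filtered) and `ledger`
#'   (a [FilterLedger-class]).
#' @export
qcFilter <- function(object, intensityThreshold = 11.0, sexThreshold = 0.25,
                     detectionP = 0.05, detectionProp = 0.05) {
  fs <- filterSamples(object, intensityThreshold, sexThreshold)
  fp <- filterProbes(fs$object, detectionP, detectionProp)
  ledger <- FilterLedger(initialProbes = nrow(object),
                         excludedProbes = fp$excluded,
                         initialSamples = ncol(object),
                         excludedSamples = fs$excluded)
  list(object = fp$object, ledger = ledger)
}

#' Quantile normalization across samples
#'
#' Maps every sample column onto the rank-wise mean reference distribution
#' (after normalization all columns share identical sorted values). This is
#' the package's normalization stand-in for array-specific schemes; it can
#' be switched off upstream. Single-column input is returned unchanged.
#'
#' @param x numeric matrix (probes x samples), no missing values.
#' @return normalized matrix of the same shape.
#' @export
quantileNormalize <- function(x) {
  if (anyNA(x)) stop("missing values are not allowed")
  if (ncol(x) <= 1) return(x)
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Select cell-type discriminating probes from a reference
#'
#' Ranks reference probes by their between-cell-type beta range and keeps
#' the top `nPerType * ncol(reference)` (a simple stand-in for per-type
#' F-statistic selection).
#'
#' @param reference probes x cell-types beta matrix with rownames.
#' @param nPerType probes per cell type (default 100).
#' @return character vector of probe ids.
#' @export
selectDiscriminatingProbes <- function(reference, nPerType = 100) {
  rng <- apply(reference, 1, function(z) diff(range(z)))
  head(rownames(reference)[order(rng, decreasing = TRUE)],
       min(nrow(reference), nPerType * ncol(reference)))
}

#' Reference-based cell-composition estimation
#'
#' Houseman-style deconvolution: for each sample, solves
#' `min || x - R w ||^2` subject to `w >= 0` by non-negative least squares
#' over a discriminating probe set, optionally renormalizing each sample's
#' fractions to sum to 1. Deterministic.
#'
#' @param beta probes x samples beta matrix (rownames = probe ids).
#' @param reference probes x cell-types beta reference (rownames = probe
#'   ids); restricted to probes present in `beta`.
#' @param probes optional probe subset; defaults to
#'   [selectDiscriminatingProbes()] of the reference.
#' @param normalize renormalize fractions to sum exactly to 1
#'   (default FALSE).
#' @return samples x cell-types fraction matrix.
#' @export
estimateCellComposition <- function(beta, reference, probes = NULL,
                                    normalize = FALSE) {
  if (is.null(probes)) probes <- selectDiscriminatingProbes(reference)
  probes <- intersect(intersect(probes, rownames(reference)), rownames(beta))
  if (length(probes) < ncol(reference))
    stop("reference has fewer usable probes than cell types")
  R <- as.matrix(reference[probes, , drop = FALSE])
  X <- as.matrix(beta[probes, , drop = FALSE])
  W <- t(apply(X, 2, function(x) pracma::lsqnonneg(R, x)$x))
  dimnames(W) <- list(colnames(beta), colnames(reference))
  if (normalize) W <- W / pmax(rowSums(W), 1e-12)
  W
}

#' Surrogate components by residual principal-component analysis
#'
#' Projects the phenotype and known covariates out of every probe's M-value
#' profile and extracts the top `k` principal components of the residual
#' matrix (decreasing variance order) as surrogate variables capturing
#' unmeasured structured variation. By construction every component is
#' orthogonal to every column of the covariate design.
#'
#' @param M probes x samples M-value matrix.
#' @param covariates samples x q data.frame/matrix of known covariates
#'   including the phenotype (factors allowed; expanded via
#'   [stats::model.matrix()]).
#' @param k number of components (default 10); `k <= 0` returns a
#'   zero-column matrix.
#' @return samples x k matrix of component scores.
#' @export
surrogateVariables <- function(M, covariates, k = 10) {
  n <- ncol(M)
  if (k <= 0) return(matrix(0, n, 0))
  X <- model.matrix(~ ., data = as.data.frame(covariates))
  if (k >= n - qr(X)$rank)
    stop("k must be smaller than the residual degrees of freedom")
  Q <- qr.Q(qr(X))
  R <- M - (M %*% Q) %*% t(Q)        # residualize every probe profile
  sv <- svd(R, nu = 0, nv = k)
  scores <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- sprintf("SV%d", seq_len(k))
  rownames(scores) <- colnames(M)
  scores
}
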