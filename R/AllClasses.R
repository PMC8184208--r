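#' MethylationExperiment: container for 450K-style methylation cohorts
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' methylated/unmethylated signal intensities and detection p-values (assays
#' `"Meth"`, `"Unmeth"`, `"DetectionP"`), or precomputed `"Beta"`/`"M"`
#' matrices, together with the probe manifest as `rowData` and the sample
#' sheet as `colData`.
#'
#' The manifest (`rowData`) must carry columns `chr`, `pos`, `gene`,
#' `feature`, `island_id` and the logical exclusion flags `cross_reactive`,
#' `snp_within_3bp`, `smoking_associated`. The sample sheet (`colData`) must
#' carry `phenotype` (factor with levels `control`, `case`).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

.manifestCols <- c("chr", "pos", "gene", "feature", "island_id",
                   "cross_reactive", "snp_within_3bp", "smoking_associated")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!(all(c("Meth", "Unmeth") %in% an) || any(c("Beta", "M") %in% an)))
    msg <- c(msg, "need assays Meth+Unmeth, or Beta, or M")
  missingCols <- setdiff(.manifestCols, colnames(rowData(object)))
  if (length(missingCols))
    msg <- c(msg, paste("manifest rowData missing:",
                        paste(missingCols, collapse = ", ")))
  if (!"phenotype" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'phenotype'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probe ids")
  if ("Beta" %in% an) {
    b <- assay(object, "Beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "Beta assay outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param meth,unmeth probes x samples signal-intensity matrices
#'   (non-negative), or `NULL` when `beta` or `M` is given.
#' @param detectionP probes x samples detection p-value matrix, optional.
#' @param beta,M precomputed methylation matrices, optional.
#' @param manifest probe manifest (`DataFrame`/`data.frame`) with the columns
#'   listed under [MethylationExperiment-class]; rownames (or a `probe_id`
#'   column) identify probes.
#' @param sampleSheet per-sample `DataFrame`/`data.frame` with at least a
#'   `phenotype` column (levels `control`, `case`).
#' @return a [MethylationExperiment-class] object.
#' @export
MethylationExperiment <- function(meth = NULL, unmeth = NULL,
                                  detectionP = NULL, beta = NULL, M = NULL,
                                  manifest, sampleSheet) {
  manifest <- DataFrame(manifest)
  if ("probe_id" %in% colnames(manifest) && is.null(rownames(manifest)))
    rownames(manifest) <- manifest$probe_id
  a <- list()
  if (!is.null(meth)) {
    if (any(meth < 0) || any(unmeth < 0))
      stop("signal intensities must be non-negative")
    a$Meth <- meth
    a$Unmeth <- unmeth
  }
  if (!is.null(detectionP)) a$DetectionP <- detectionP
  if (!is.null(beta)) a$Beta <- beta
  if (!is.null(M)) a$M <- M
  se <- SummarizedExperiment(assays = a, rowData = manifest,
                             colData = DataFrame(sampleSheet))
  new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment beta values; computed as
#'   `Meth / (Meth + Unmeth + 2*offset)` when only intensities are stored.
#' @param object,x a `MethylationExperiment`.
#' @param offset intensity offset added to each channel (default 0).
#' @export
getBeta <- function(object, offset = 0) {
  if ("Beta" %in% assayNames(object)) return(assay(object, "Beta"))
  if (all(c("Meth", "Unmeth") %in% assayNames(object))) {
    m <- assay(object, "Meth"); u <- assay(object, "Unmeth")
    return((m + offset) / (m + u + 2 * offset + 1e-100))
  }
  if ("M" %in% assayNames(object)) return(expit2(assay(object, "M")))
  stop("no assay from which beta values can be derived")
}

#' @describeIn MethylationExperiment M-values,
#'   `log2((Meth + 1)/(Unmeth + 1))`.
#' @export
getM <- function(object) {
  if ("M" %in% assayNames(object)) return(assay(object, "M"))
  if (all(c("Meth", "Unmeth") %in% assayNames(object)))
    return(computeMValues(assay(object, "Meth"), assay(object, "Unmeth")))
  if ("Beta" %in% assayNames(object)) return(logit2(assay(object, "Beta")))
  stop("no assay from which M-values can be derived")
}

#' @describeIn MethylationExperiment detection p-value matrix (or NULL).
#' @export
getDetectionP <- function(object) {
  if ("DetectionP" %in% assayNames(object)) assay(object, "DetectionP") else NULL
}

#' @describeIn MethylationExperiment the probe manifest (`rowData`).
#' @export
probeManifest <- function(object) rowData(object)

#' @describeIn MethylationExperiment the sample sheet (`colData`).
#' @export
sampleSheet <- function(object) colData(object)

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment:", nrow(object), "probes x",
      ncol(object), "samples\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  ph <- colData(object)$phenotype
  if (!is.null(ph)) {
    tb <- table(ph)
    cat("  phenotype:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if ("split" %in% colnames(colData(object))) {
    tb <- table(colData(object)$split)
    cat("  split:    ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------

#' FilterLedger: conservation-checked QC accounting
#'
#' Records, for one QC run, how many probes and samples entered, how many
#' were newly excluded by each category (first-match accounting), and how
#' many remain. Validity enforces exact conservation:
#' `retained + sum(excluded) == initial` on both axes.
#'
#' @slot initialProbes,retainedProbes integer counts.
#' @slot excludedProbes named integer vector
#'   (categories: detection, cross_reactive, snp_within_3bp,
#'   sex_chromosome, smoking).
#' @slot initialSamples,retainedSamples integer counts.
#' @slot excludedSamples named integer vector (categories: intensity, sex).
#' @export
setClass("FilterLedger",
  representation(initialProbes = "integer", excludedProbes = "integer",
                 retainedProbes = "integer", initialSamples = "integer",
                 excludedSamples = "integer", retainedSamples = "integer"))

setValidity("FilterLedger", function(object) {
  msg <- character()
  if (object@retainedProbes + sum(object@excludedProbes) !=
      object@initialProbes)
    msg <- c(msg, "probe ledger does not conserve counts")
  if (object@retainedSamples + sum(object@excludedSamples) !=
      object@initialSamples)
    msg <- c(msg, "sample ledger does not conserve counts")
  if (any(object@excludedProbes < 0) || any(object@excludedSamples < 0))
    msg <- c(msg, "negative exclusion counts")
  if (length(msg)) msg else TRUE
})

FilterLedger <- function(initialProbes, excludedProbes, initialSamples,
                         excludedSamples) {
  new("FilterLedger",
      initialProbes = as.integer(initialProbes),
      excludedProbes = setNames(as.integer(excludedProbes),
                                names(excludedProbes)),
      retainedProbes = as.integer(initialProbes - sum(excludedProbes)),
      initialSamples = as.integer(initialSamples),
      excludedSamples = setNames(as.integer(excludedSamples),
                                 names(excludedSamples)),
      retainedSamples = as.integer(initialSamples - sum(excludedSamples)))
}

setMethod("show", "FilterLedger", function(object) {
  cat("FilterLedger\n")
  cat("  probes: ", object@initialProbes, "->", object@retainedProbes, "\n")
  for (nm in names(object@excludedProbes))
    cat(sprintf("    - %-16s %d\n", nm, object@excludedProbes[[nm]]))
  cat("  samples:", object@initialSamples, "->", object@retainedSamples, "\n")
  for (nm in names(object@excludedSamples))
    cat(sprintf("    - %-16s %d\n", nm, object@excludedSamples[[nm]]))
})

#' @describeIn FilterLedger number of probes retained.
#' @param object a `FilterLedger`.
#' @export
retainedProbes <- function(object) object@retainedProbes

#' @describeIn FilterLedger named vector of per-category probe exclusions.
#' @export
excludedProbes <- function(object) object@excludedProbes

#' @describeIn FilterLedger number of samples retained.
#' @export
retainedSamples <- function(object) object@retainedSamples

#' @describeIn FilterLedger named vector of per-category sample exclusions.
#' @export
excludedSamples <- function(object) object@excludedSamples

# ---------------------------------------------------------------------------

#' OPLSDAModel: orthogonal projections to latent structures discriminant model
#'
#' Stores the centering/scaling vectors, the unit-norm predictive weight
#' vector `w`, predictive loading `p`, response loading `c`, orthogonal
#' weights/loadings (`Wo`, `Po`, one column per orthogonal component) and
#' the training predictive scores.
#'
#' @slot center,scale numeric per-feature vectors.
#' @slot w,pLoad numeric predictive weight and loading.
#' @slot cLoad numeric scalar response loading.
#' @slot Wo,Po feature x nOrtho orthogonal weight/loading matrices.
#' @slot tTrain numeric training predictive scores.
#' @slot nOrtho integer number of orthogonal components removed.
#' @slot featureNames character.
#' @export
setClass("OPLSDAModel",
  representation(center = "numeric", scale = "numeric", w = "numeric",
                 pLoad = "numeric", cLoad = "numeric", Wo = "matrix",
                 Po = "matrix", tTrain = "numeric", nOrtho = "integer",
                 featureNames = "character"))

setValidity("OPLSDAModel", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@w^2)) - 1) > 1e-8)
    msg <- c(msg, "predictive weight vector is not unit norm")
  if (object@nOrtho > 0 &&
      max(abs(crossprod(object@Wo, object@w))) > 1e-8)
    msg <- c(msg, "orthogonal weights not orthogonal to w")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OPLSDAModel", function(object) {
  cat("OPLSDAModel:", length(object@w), "features, 1 predictive +",
      object@nOrtho, "orthogonal component(s)\n")
  cat("  |t_train| range:",
      paste(signif(range(object@tTrain), 3), collapse = " .. "), "\n")
})
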