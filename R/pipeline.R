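#' Pipeline configuration
#'
#' Bundles thresholds, stage toggles and the synthetic-cohort configuration
#' for [runPipeline()]. All thresholds must lie in (0, 1).
#'
#' @param seed master seed.
#' @param synthetic a [syntheticConfig()] describing the cohort to
#'   simulate (its own seed is overridden by `seed`).
#' @param fdr FDR level used for site and region discovery/replication.
#' @param alpha family-wise (Bonferroni) level.
#' @param detectionP,detectionProp,intensityThreshold,sexThreshold QC rules,
#'   see [qcFilter()].
#' @param normalize apply [quantileNormalize()] to the M matrix.
#' @param nSurrogate surrogate components per split (default 10).
#' @param nOrtho orthogonal OPLS-DA components (default 1).
#' @param enMixing elastic-net mixing parameter (default 0.5).
#' @param doClassify,doNetwork stage toggles.
#' @param annotation optional keyword -> genes list for the network stage;
#'   `"auto"` generates one from the manifest.
#' @param outDir output directory (default: a fresh temporary directory).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, synthetic = NULL, fdr = 0.05,
                           alpha = 0.05, detectionP = 0.05,
                           detectionProp = 0.05, intensityThreshold = 11.0,
                           sexThreshold = 0.25, normalize = TRUE,
                           nSurrogate = 10, nOrtho = 1, enMixing = 0.5,
                           doClassify = TRUE, doNetwork = TRUE,
                           annotation = NULL, outDir = NULL) {
  for (th in c(fdr, alpha, detectionP, detectionProp))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (is.null(synthetic)) synthetic <- syntheticConfig(seed = seed)
  synthetic$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), synthetic = synthetic, fdr = fdr,
              alpha = alpha, detectionP = detectionP,
              detectionProp = detectionProp,
              intensityThreshold = intensityThreshold,
              sexThreshold = sexThreshold, normalize = normalize,
              nSurrogate = nSurrogate, nOrtho = nOrtho,
              enMixing = enMixing, doClassify = doClassify,
              doNetwork = doNetwork, annotation = annotation,
              outDir = outDir %||% file.path(tempdir(),
                paste0("methylDeviance-run-", seed)))
  class(cfg) <- "PipelineConfig"
  cfg
}

# Assemble the standard confounder table for one split: age, sex, batch,
# 7 of the 8 cell fractions (largest type dropped to avoid the sum-to-one
# near-collinearity with the intercept) and the surrogate components.
splitConfounders <- function(sheet, cells, sv) {
  cells <- cells[, -which.max(colMeans(cells)), drop = FALSE]
  cf <- data.frame(age = sheet$age, sex = factor(sheet$sex),
                   check.names = FALSE)
  if (nlevels(droplevels(factor(sheet$batch))) > 1)
    cf$batch <- droplevels(factor(sheet$batch))
  cbind(cf, as.data.frame(cells), as.data.frame(sv))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> QC -> normalization -> cell composition/surrogate
#' variables -> site analysis (discovery, cross-validation, replication,
#' meta-analysis) -> region analysis (deviance tests, replication,
#' within-region site FDR) -> site pooling -> OPLS-DA classification with
#' elastic-net subset selection -> partial-correlation keyword network,
#' writing per-stage outputs and a run manifest with checksums into
#' `config$outDir`.
#'
#' @param config a [pipelineConfig()].
#' @return list with the per-stage results (`ledger`, `dms`, `meta`, `dmr`,
#'   `pooled`, `classifier`, `network`, `groundTruth`, ...) and
#'   `runManifest` (seed, config hash, per-file md5 checksums, stage counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  out <- tryCatch({
    manifest <- generateManifest(config$synthetic)
    sim <- simulateCohort(config$synthetic, manifest)

    stage <- "qc"
    qc <- qcFilter(sim$experiment,
                   intensityThreshold = config$intensityThreshold,
                   sexThreshold = config$sexThreshold,
                   detectionP = config$detectionP,
                   detectionProp = config$detectionProp)
    obj <- qc$object

    stage <- "preprocess"
    M <- getM(obj)
    if (config$normalize) M <- quantileNormalize(M)
    beta <- expit2(M)
    sheet <- as.data.frame(colData(obj))
    splits <- list(discovery = which(sheet$split == "discovery"),
                   cv = which(sheet$split == "cv"))
    cells <- estimateCellComposition(beta, sim$cellReference,
                                     probes = rownames(sim$cellReference))
    conf <- list(); pheno <- list()
    for (s in names(splits)) {
      at <- splits[[s]]
      pheno[[s]] <- sheet$phenotype[at]
      sv <- surrogateVariables(
        M[, at, drop = FALSE],
        cbind(data.frame(phenotype = pheno[[s]]),
              splitConfounders(sheet[at, ], cells[at, , drop = FALSE],
                               matrix(0, length(at), 0))),
        k = config$nSurrogate)
      conf[[s]] <- splitConfounders(sheet[at, ], cells[at, , drop = FALSE],
                                    sv)
    }

    stage <- "dms"
    fits <- lapply(names(splits), function(s) {
      at <- splits[[s]]
      f <- fitSiteModels(M[, at, drop = FALSE], pheno[[s]], conf[[s]],
                         beta = beta[, at, drop = FALSE])
      mod <- moderateVariance(f)
      f$p <- mod$p_mod           # moderated statistics drive inference
      f$t <- mod$t_mod
      f$se_mod <- sqrt(mod$s_tilde_sq) * f$stdev_unscaled
      f
    })
    names(fits) <- names(splits)
    rep <- discoveryReplication(fits$discovery, fits$cv,
                                qThreshold = config$fdr)
    meta <- metaFixedEffect(fits$discovery$coef_M, fits$discovery$se_mod,
                            fits$cv$coef_M, fits$cv$se_mod)
    meta$probe_id <- fits$discovery$probe_id
    bonf <- bonferroniThreshold(config$alpha, nrow(obj))
    metaSignificant <- meta$probe_id[meta$p_meta < bonf]

    stage <- "dmr"
    regionMap <- buildRegionMap(probeManifest(obj))
    dmr <- regionWorkflow(M[, splits$discovery, drop = FALSE],
                          M[, splits$cv, drop = FALSE],
                          pheno$discovery, pheno$cv,
                          conf$discovery, conf$cv, regionMap,
                          alpha = config$fdr)

    stage <- "pool"
    important <- lapply(
      setNames(dmr$discoverySignificant, dmr$discoverySignificant),
      function(rid) {
        sl <- siteLevelWithinRegion(dmr$discTests[[rid]],
                                    threshold = config$fdr)
        sl$probe_id[sl$important]
      })
    important <- important[lengths(important) > 0]
    pooled <- poolSites(rep$discoverySignificant, important)

    stage <- "classify"
    classifier <- NULL
    if (config$doClassify && nrow(pooled) >= 2) {
      Xd <- t(M[pooled$probe_id, splits$discovery, drop = FALSE])
      Xc <- t(M[pooled$probe_id, splits$cv, drop = FALSE])
      model <- fitOPLSDA(Xd, pheno$discovery, nOrtho = config$nOrtho)
      cvScores <- predictScores(model, Xc)
      eval <- evaluateROC(cvScores, pheno$cv)
      best <- elasticNetSelect(Xd, pheno$discovery,
                               mixing = config$enMixing,
                               seed = substreamSeed(config$seed, "glmnet"))
      effect <- NULL
      if (length(best$probe_ids) > 0 &&
          length(best$probe_ids) < nrow(pooled)) {
        db <- setNames(fits$discovery$delta_beta, fits$discovery$probe_id)
        effect <- compareEffectSizes(db[pooled$probe_id], best$probe_ids)
      }
      classifier <- list(model = model, cvScores = cvScores, eval = eval,
                         bestSubset = best, effectComparison = effect)
    }

    stage <- "network"
    network <- NULL
    if (config$doNetwork && nrow(pooled) >= 3) {
      Xall <- t(M[pooled$probe_id, , drop = FALSE])
      pcor <- estimatePartialCorrelations(Xall)
      ann <- config$annotation
      if (identical(ann, "auto"))
        ann <- simulateKeywordAnnotation(probeManifest(obj),
                                         seed = config$seed)
      kwNet <- NULL
      if (!is.null(ann)) {
        pg <- setNames(probeManifest(obj)$gene, rownames(obj))
        pg <- pg[pg != ""]
        kwNet <- buildKeywordNetwork(pcor, ann, pg,
                                     qThreshold = config$fdr)
      }
      network <- list(pcor = pcor, keywordNetwork = kwNet)
    }

    list(manifest = manifest, groundTruth = sim$groundTruth,
         ledger = qc$ledger, object = obj, M = M,
         cellComposition = cells, confounders = conf,
         dms = list(fits = fits, replication = rep, meta = meta,
                    bonferroniThreshold = bonf,
                    metaSignificant = metaSignificant),
         dmr = dmr, pooled = pooled, classifier = classifier,
         network = network)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })

  # persist the declared outputs and fingerprint them
  files <- character(0)
  files["ledger"] <- writeLedger(out$ledger,
                                 file.path(config$outDir, "ledger.json"))
  dmsTab <- dmsResultTable(out)
  data.table::fwrite(dmsTab, file.path(config$outDir, "dms.tsv"),
                     sep = "\t")
  files["dms"] <- file.path(config$outDir, "dms.tsv")
  data.table::fwrite(out$dmr$results,
                     file.path(config$outDir, "dmr.tsv"), sep = "\t")
  files["dmr"] <- file.path(config$outDir, "dmr.tsv")
  pooledDf <- data.frame(probe_id = out$pooled$probe_id,
                         provenance = vapply(out$pooled$provenance,
                                             paste, "", collapse = ","))
  data.table::fwrite(pooledDf, file.path(config$outDir, "pooled.tsv"),
                     sep = "\t")
  files["pooled"] <- file.path(config$outDir, "pooled.tsv")
  if (!is.null(out$classifier)) {
    files["model"] <- writeOPLSDAModel(out$classifier$model,
                                       file.path(config$outDir,
                                                 "oplsda.json"))
    data.table::fwrite(out$classifier$eval$roc_points,
                       file.path(config$outDir, "roc.tsv"), sep = "\t")
    files["roc"] <- file.path(config$outDir, "roc.tsv")
  }
  if (!is.null(out$network$keywordNetwork) &&
      nrow(out$network$keywordNetwork$edges)) {
    data.table::fwrite(out$network$keywordNetwork$edges,
                       file.path(config$outDir, "keyword_edges.tsv"),
                       sep = "\t")
    files["edges"] <- file.path(config$outDir, "keyword_edges.tsv")
  }

  counts <- list(
    probes_retained = retainedProbes(out$ledger),
    samples_retained = retainedSamples(out$ledger),
    dms_discovery = length(out$dms$replication$discoverySignificant),
    dms_replicated = length(out$dms$replication$replicated),
    dms_meta_significant = length(out$dms$metaSignificant),
    dmr_discovery = length(out$dmr$discoverySignificant),
    dmr_replicated = length(out$dmr$replicated),
    pooled_sites = nrow(out$pooled),
    best_subset = if (!is.null(out$classifier))
      length(out$classifier$bestSubset$probe_ids) else NA_integer_,
    cv_auc = if (!is.null(out$classifier)) out$classifier$eval$auc
             else NA_real_)
  cfgJson <- jsonlite::toJSON(config[setdiff(names(config), "outDir")],
                              auto_unbox = TRUE, digits = NA,
                              force = TRUE)
  tmp <- file.path(config$outDir, "config.json")
  writeLines(cfgJson, tmp)
  out$runManifest <- list(
    tool_version = as.character(utils::packageVersion("methylDeviance")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    checksums = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(out$runManifest[c("tool_version", "seed",
                                         "config_hash", "checksums",
                                         "counts")],
                       file.path(config$outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}

# Table-2-style site result table: per-stage effect/p plus meta columns.
dmsResultTable <- function(out) {
  man <- as.data.frame(probeManifest(out$object))
  d <- out$dms$fits$discovery; cv <- out$dms$fits$cv; meta <- out$dms$meta
  data.frame(probe_id = d$probe_id,
             chr = man$chr[match(d$probe_id, man$probe_id)],
             pos = man$pos[match(d$probe_id, man$probe_id)],
             delta_beta_disc = d$delta_beta, p_disc = d$p,
             delta_beta_cv = cv$delta_beta, p_cv = cv$p,
             beta_meta = meta$beta_meta, p_meta = meta$p_meta,
             gene = man$gene[match(d$probe_id, man$probe_id)],
             stringsAsFactors = FALSE)
}
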