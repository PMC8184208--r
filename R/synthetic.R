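#' Configuration for the synthetic 450K-style cohort generator
#'
#' Builds and validates the parameter set describing a simulated two-group
#' blood-methylation cohort split into discovery and cross-validation sets.
#' Defaults emulate the study conditions of a Paget's-disease-of-bone EWAS:
#' 116 cases / 130 controls per split, case groups slightly older and more
#' male in the discovery split, an 8-part blood cell mixture, batch and chip
#' structure, and logit-normal measurement noise on the M scale.
#'
#' @param seed master integer seed; all generator randomness flows from it
#'   through named substreams.
#' @param nCasesDisc,nControlsDisc,nCasesCV,nControlsCV cohort sizes.
#' @param nProbes total probes on the simulated array.
#' @param nIslands,nGeneBodies,nPromoters number of CpG islands, gene-body
#'   genes and promoter genes laid out on the array.
#' @param sitesPerRegion length-2 integer range; each region draws its probe
#'   count uniformly from this range.
#' @param plantedDMS `data.frame(probe, deltaBeta)` of true differentially
#'   methylated sites; `probe` is a manifest row index or probe id and
#'   `deltaBeta` the case-minus-control difference on the beta scale,
#'   in (-1, 1).
#' @param plantedDMR named list: region key (island id, or gene symbol for
#'   gene-body/promoter regions) -> numeric vector of per-site beta-scale
#'   effects (mixed signs allowed; recycled/padded with 0 to the region size).
#' @param ageMean,ageSD,maleProp per-split, per-group demographics
#'   (lists with `discovery`/`cv` elements, each `c(case=, control=)`).
#' @param nBatches number of processing batches; `batchEffectSD` M-scale SD
#'   of per-(probe, batch) offsets on a `batchProbeFrac` fraction of probes.
#' @param batchEffectSD,batchProbeFrac see `nBatches`.
#' @param cellAlpha list with `case` and `control` 8-vectors of Dirichlet
#'   concentration parameters for the blood cell mixture.
#' @param cellProbeFrac fraction of autosomal probes with cell-type-specific
#'   methylation (these carry the deconvolution signal).
#' @param sexProbeFrac,sexEffectSD autosomal probes with a sex effect.
#' @param ageProbeFrac,ageSlopeSD autosomal probes with a linear age trend.
#' @param noiseSD M-scale residual standard deviation.
#' @param withinRegionCor correlation of residual noise among sites of the
#'   same island (default 0; the within-region dependence of neighbouring
#'   CpGs in real data is not asserted).
#' @param detectionFailRate per-entry probability of a failed detection
#'   p-value (> 0.05).
#' @param log2MedianIntensity,intensityLogSD log2 median and log2 SD of the
#'   total signal intensity T (meth + unmeth).
#' @param nLowIntensitySamples number of samples simulated with degraded
#'   intensity (`lowIntensityLog2Median`), to exercise the sample QC filter.
#' @param lowIntensityLog2Median log2 median intensity of degraded samples.
#' @param nFlagged named integer vector: exact number of probes carrying each
#'   exclusion flag (`cross_reactive`, `snp_within_3bp`,
#'   `smoking_associated`); flag sets are disjoint and autosomal.
#' @param nSexProbes named integer vector `c(X=, Y=)` of sex-chromosome
#'   probes.
#' @param sexBetaThreshold mean-X-beta threshold separating predicted males
#'   (below) from females (above).
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(seed = 1L,
    nCasesDisc = 116, nControlsDisc = 130, nCasesCV = 116, nControlsCV = 130,
    nProbes = 2000, nIslands = 15, nGeneBodies = 15, nPromoters = 15,
    sitesPerRegion = c(3L, 8L),
    plantedDMS = NULL, plantedDMR = NULL,
    ageMean = list(discovery = c(case = 72.1, control = 70.0),
                   cv = c(case = 72.5, control = 72.3)),
    ageSD = list(discovery = c(case = 7.5, control = 7.4),
                 cv = c(case = 8.7, control = 8.2)),
    maleProp = list(discovery = c(case = 0.560, control = 0.369),
                    cv = c(case = 0.509, control = 0.408)),
    nBatches = 2, batchEffectSD = 0.15, batchProbeFrac = 0.2,
    cellAlpha = NULL, cellProbeFrac = 0.2,
    sexProbeFrac = 0.05, sexEffectSD = 0.2,
    ageProbeFrac = 0.05, ageSlopeSD = 0.005,
    noiseSD = 0.5, withinRegionCor = 0,
    detectionFailRate = 0.001,
    log2MedianIntensity = 12.5, intensityLogSD = 0.3,
    nLowIntensitySamples = 0, lowIntensityLog2Median = 10.5,
    nFlagged = c(cross_reactive = 20L, snp_within_3bp = 10L,
                 smoking_associated = 5L),
    nSexProbes = c(X = 20L, Y = 5L),
    sexBetaThreshold = 0.25) {
  if (is.null(cellAlpha)) {
    # whole-blood-like composition, neutrophil-dominated
    a <- c(CD14_monocytes = 5, CD19_B = 2, CD4_T = 8, CD56_NK = 3,
           CD8_T = 5, eosinophils = 1.5, granulocytes = 2.5,
           neutrophils = 33)
    cellAlpha <- list(case = a, control = a)
  }
  cfg <- list(seed = as.integer(seed),
    nCasesDisc = nCasesDisc, nControlsDisc = nControlsDisc,
    nCasesCV = nCasesCV, nControlsCV = nControlsCV,
    nProbes = as.integer(nProbes), nIslands = as.integer(nIslands),
    nGeneBodies = as.integer(nGeneBodies),
    nPromoters = as.integer(nPromoters),
    sitesPerRegion = as.integer(sitesPerRegion),
    plantedDMS = plantedDMS, plantedDMR = plantedDMR,
    ageMean = ageMean, ageSD = ageSD, maleProp = maleProp,
    nBatches = as.integer(nBatches), batchEffectSD = batchEffectSD,
    batchProbeFrac = batchProbeFrac, cellAlpha = cellAlpha,
    cellProbeFrac = cellProbeFrac, sexProbeFrac = sexProbeFrac,
    sexEffectSD = sexEffectSD, ageProbeFrac = ageProbeFrac,
    ageSlopeSD = ageSlopeSD, noiseSD = noiseSD,
    withinRegionCor = withinRegionCor,
    detectionFailRate = detectionFailRate,
    log2MedianIntensity = log2MedianIntensity,
    intensityLogSD = intensityLogSD,
    nLowIntensitySamples = as.integer(nLowIntensitySamples),
    lowIntensityLog2Median = lowIntensityLog2Median,
    nFlagged = nFlagged, nSexProbes = nSexProbes,
    sexBetaThreshold = sexBetaThreshold)
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  counts <- unlist(cfg[c("nCasesDisc", "nControlsDisc", "nCasesCV",
                         "nControlsCV", "nProbes")])
  if (any(counts <= 0)) stop("configuration error: all counts must be positive")
  if (length(cfg$sitesPerRegion) != 2L ||
      cfg$sitesPerRegion[1] > cfg$sitesPerRegion[2] ||
      cfg$sitesPerRegion[1] < 1L)
    stop("configuration error: sitesPerRegion must be an increasing range >= 1")
  if (!is.null(cfg$plantedDMS)) {
    if (any(abs(cfg$plantedDMS$deltaBeta) >= 1))
      stop("configuration error: deltaBeta must lie in (-1, 1)")
  }
  if (!is.null(cfg$plantedDMR) &&
      any(abs(unlist(cfg$plantedDMR)) >= 1))
    stop("configuration error: DMR deltaBeta must lie in (-1, 1)")
  if (any(unlist(cfg$cellAlpha) <= 0))
    stop("configuration error: cell concentration parameters must be positive")
  demand <- (cfg$nIslands + cfg$nGeneBodies + cfg$nPromoters) *
    cfg$sitesPerRegion[2] + sum(cfg$nSexProbes) + sum(cfg$nFlagged)
  if (demand > cfg$nProbes)
    stop("configuration error: region, sex-probe and flag demands exceed nProbes")
  invisible(cfg)
}

#' Generate a synthetic probe manifest
#'
#' Lays out islands, gene-body genes and promoter genes as blocks of adjacent
#' probes on chromosomes 1..22 (round-robin), appends configurable numbers of
#' X/Y probes, fills the remainder with intergenic probes, and assigns exact,
#' mutually disjoint counts of `cross_reactive`, `snp_within_3bp` and
#' `smoking_associated` exclusion flags to autosomal probes. Deterministic
#' given `config$seed`.
#'
#' @param config a [syntheticConfig()] object.
#' @return a `DataFrame` with columns `probe_id`, `chr`, `pos`, `gene`,
#'   `feature`, `island_id` and the three logical flag columns; rownames are
#'   probe ids, every island id groups >= 2 probes.
#' @export
generateManifest <- function(config) {
  validateSyntheticConfig(config)
  withSeed(substreamSeed(config$seed, "manifest"), {
    nP <- config$nProbes
    chr <- character(nP); pos <- integer(nP); gene <- character(nP)
    feature <- character(nP); island <- character(nP)
    chr[] <- ""; gene[] <- ""; island[] <- ""; feature[] <- "intergenic"

    nReg <- config$nIslands + config$nGeneBodies + config$nPromoters
    regType <- rep(c("island", "gene_body", "promoter"),
                   c(config$nIslands, config$nGeneBodies, config$nPromoters))
    regSize <- if (config$sitesPerRegion[1] == config$sitesPerRegion[2])
      rep(config$sitesPerRegion[1], nReg)
    else sample(config$sitesPerRegion[1]:config$sitesPerRegion[2], nReg,
                replace = TRUE)
    # islands must hold >= 2 probes
    regSize[regType == "island"] <- pmax(regSize[regType == "island"], 2L)

    chrCursor <- rep(1e6, 22)
    idx <- 1L
    iIsl <- 0L; iGB <- 0L; iPr <- 0L
    for (r in seq_len(nReg)) {
      k <- regSize[r]
      cNum <- ((r - 1L) %% 22L) + 1L
      at <- idx:(idx + k - 1L)
      chr[at] <- as.character(cNum)
      pos[at] <- as.integer(chrCursor[cNum] + seq(0, by = 100, length.out = k))
      chrCursor[cNum] <- chrCursor[cNum] + 100 * k + 10000
      if (regType[r] == "island") {
        iIsl <- iIsl + 1L
        island[at] <- sprintf("isl%04d", iIsl)
      } else if (regType[r] == "gene_body") {
        iGB <- iGB + 1L
        gene[at] <- sprintf("GB_GENE%03d", iGB)
        feature[at] <- sample(c("Body", "5'UTR"), k, replace = TRUE,
                              prob = c(0.8, 0.2))
      } else {
        iPr <- iPr + 1L
        gene[at] <- sprintf("PR_GENE%03d", iPr)
        feature[at] <- sample(c("TSS200", "TSS1500"), k, replace = TRUE)
      }
      idx <- idx + k
    }
    nSex <- sum(config$nSexProbes)
    nInter <- nP - (idx - 1L) - nSex
    if (nInter > 0) {
      at <- idx:(idx + nInter - 1L)
      cNum <- ((seq_len(nInter) - 1L) %% 22L) + 1L
      chr[at] <- as.character(cNum)
      pos[at] <- as.integer(2e8 + seq_len(nInter) * 137L)
      idx <- idx + nInter
    }
    if (nSex > 0) {
      sexChr <- rep(c("X", "Y"), c(config$nSexProbes[["X"]],
                                   config$nSexProbes[["Y"]]))
      at <- idx:nP
      chr[at] <- sexChr
      pos[at] <- as.integer(1e6 + seq_len(nSex) * 211L)
    }

    flags <- matrix(FALSE, nP, 3,
                    dimnames = list(NULL, c("cross_reactive",
                                            "snp_within_3bp",
                                            "smoking_associated")))
    auto <- which(!chr %in% c("X", "Y"))
    pool <- sample(auto)
    off <- 0L
    for (f in colnames(flags)) {
      nf <- as.integer(config$nFlagged[[f]] %||% 0L)
      if (nf > 0) {
        flags[pool[(off + 1L):(off + nf)], f] <- TRUE
        off <- off + nf
      }
    }
    man <- DataFrame(probe_id = sprintf("cg%08d", seq_len(nP)),
                     chr = chr, pos = pos, gene = gene, feature = feature,
                     island_id = island,
                     cross_reactive = flags[, 1], snp_within_3bp = flags[, 2],
                     smoking_associated = flags[, 3])
    rownames(man) <- man$probe_id
    man
  })
}

# Resolve a plantedDMR key to the manifest probe indices of its region.
resolveRegionProbes <- function(manifest, key) {
  i <- which(manifest$island_id == key)
  if (!length(i)) i <- which(manifest$gene == key)
  if (!length(i))
    stop("configuration error: planted region '", key,
         "' not found in manifest")
  i
}

#' Simulate a discovery + cross-validation methylation cohort
#'
#' Draws per-sample demographics, chip/batch structure and Dirichlet blood
#' cell fractions; builds a probes x samples M-value matrix as baseline +
#' case effects (planted sites/regions, converted from the beta scale via the
#' logit derivative at each probe's baseline) + batch, sex, age and
#' cell-mixture terms + Gaussian noise; then converts to beta values and
#' splits the signal into methylated/unmethylated intensities with lognormal
#' total intensity, so that `log2((meth+1)/(unmeth+1))` recovers the intended
#' M-values. Detection p-values fail (> 0.05) at the configured rate.
#'
#' @param config a [syntheticConfig()] object.
#' @param manifest the matching [generateManifest()] output.
#' @return a list with elements
#'   \describe{
#'     \item{experiment}{a [MethylationExperiment-class] with `Meth`,
#'       `Unmeth` and `DetectionP` assays and the sample sheet in `colData`
#'       (`split`, `phenotype`, `age`, `sex`, `array`, `batch`).}
#'     \item{groundTruth}{list recording `trueDMS` (probe id, case-minus-
#'       control beta difference), `trueDMR`, `cellFractions` (samples x 8,
#'       rows summing to 1), `batchLabels`, `caseLabels`.}
#'     \item{cellReference}{beta-scale reference profiles (cell-sensitive
#'       probes x 8 cell types) from which the samples were mixed.}
#'   }
#' @export
simulateCohort <- function(config, manifest) {
  validateSyntheticConfig(config)
  withSeed(substreamSeed(config$seed, "cohort"), {
    nP <- nrow(manifest)
    grp <- data.frame(
      split = rep(c("discovery", "discovery", "cv", "cv"),
                  c(config$nCasesDisc, config$nControlsDisc,
                    config$nCasesCV, config$nControlsCV)),
      phenotype = rep(c("case", "control", "case", "control"),
                      c(config$nCasesDisc, config$nControlsDisc,
                        config$nCasesCV, config$nControlsCV)),
      stringsAsFactors = FALSE)
    n <- nrow(grp)
    splitKey <- ifelse(grp$split == "discovery", "discovery", "cv")
    age <- numeric(n); sex <- character(n)
    for (s in c("discovery", "cv")) for (g in c("case", "control")) {
      at <- which(splitKey == s & grp$phenotype == g)
      age[at] <- rnorm(length(at), config$ageMean[[s]][[g]],
                       config$ageSD[[s]][[g]])
      sex[at] <- ifelse(runif(length(at)) < config$maleProp[[s]][[g]],
                        "M", "F")
    }
    array <- sample(rep(sprintf("chip%03d", seq_len(ceiling(n / 12))),
                        each = 12)[seq_len(n)])
    batch <- sample(seq_len(config$nBatches), n, replace = TRUE)
    isCase <- grp$phenotype == "case"

    cellTypes <- names(config$cellAlpha$case)
    fractions <- matrix(0, n, 8, dimnames = list(NULL, cellTypes))
    fractions[isCase, ] <- rdirichlet(sum(isCase), config$cellAlpha$case)
    fractions[!isCase, ] <- rdirichlet(sum(!isCase), config$cellAlpha$control)

    # baseline betas: bimodal like real 450K arrays
    comp <- sample.int(3, nP, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    b0 <- numeric(nP)
    b0[comp == 1] <- rbeta(sum(comp == 1), 1.5, 8)
    b0[comp == 2] <- rbeta(sum(comp == 2), 5, 5)
    b0[comp == 3] <- rbeta(sum(comp == 3), 8, 1.5)
    isX <- manifest$chr == "X"
    b0[isX] <- rbeta(sum(isX), 1, 15)    # strongly hypomethylated in males
    b0 <- pmin(pmax(b0, 0.02), 0.98)

    # planted sites keep mid-range baselines so beta-scale effects are
    # representable and the logit-derivative conversion is accurate
    dmsIdx <- integer(0); dmsDelta <- numeric(0)
    if (!is.null(config$plantedDMS)) {
      p <- config$plantedDMS$probe
      dmsIdx <- if (is.character(p)) match(p, manifest$probe_id) else as.integer(p)
      if (anyNA(dmsIdx) || any(dmsIdx < 1 | dmsIdx > nP))
        stop("configuration error: planted DMS probe not in manifest")
      dmsDelta <- config$plantedDMS$deltaBeta
    }
    dmrIdx <- list(); dmrDelta <- list()
    if (!is.null(config$plantedDMR)) {
      for (key in names(config$plantedDMR)) {
        at <- resolveRegionProbes(manifest, key)
        d <- rep_len(c(config$plantedDMR[[key]],
                       rep(0, max(0, length(at) - length(config$plantedDMR[[key]])))),
                     length(at))
        dmrIdx[[key]] <- at; dmrDelta[[key]] <- d
      }
    }
    plantedAll <- unique(c(dmsIdx, unlist(dmrIdx)))
    if (length(plantedAll)) b0[plantedAll] <- runif(length(plantedAll), 0.3, 0.7)

    M <- matrix(logit2(b0), nP, n)

    # cell-type-sensitive probes: betas are true mixtures of reference
    # profiles, so reference-based deconvolution is meaningful
    eligible <- setdiff(which(!manifest$chr %in% c("X", "Y")), plantedAll)
    cellProbes <- sort(sample(eligible,
                              round(config$cellProbeFrac * length(eligible))))
    cellRef <- matrix(0.05 + 0.9 * rbeta(length(cellProbes) * 8, 0.5, 0.5),
                      length(cellProbes), 8,
                      dimnames = list(manifest$probe_id[cellProbes], cellTypes))
    M[cellProbes, ] <- logit2(pmin(pmax(cellRef %*% t(fractions), 0.02), 0.98))

    # batch structure
    rest <- setdiff(eligible, cellProbes)
    batchProbes <- sample(rest, round(config$batchProbeFrac * length(rest)))
    if (config$nBatches > 1 && length(batchProbes)) {
      for (bt in 2:config$nBatches) {
        shift <- rnorm(length(batchProbes), 0, config$batchEffectSD)
        M[batchProbes, batch == bt] <-
          M[batchProbes, batch == bt, drop = FALSE] + shift
      }
    }
    # autosomal sex and age effects
    sexProbes <- sample(rest, round(config$sexProbeFrac * length(rest)))
    if (length(sexProbes)) {
      shift <- rnorm(length(sexProbes), 0, config$sexEffectSD)
      M[sexProbes, sex == "M"] <- M[sexProbes, sex == "M", drop = FALSE] + shift
    }
    ageProbes <- sample(rest, round(config$ageProbeFrac * length(rest)))
    if (length(ageProbes)) {
      slope <- rnorm(length(ageProbes), 0, config$ageSlopeSD)
      M[ageProbes, ] <- M[ageProbes, , drop = FALSE] +
        outer(slope, age - 71)
    }
    # X inactivation pulls female X betas toward 0.5 (M toward 0)
    if (any(isX)) M[isX, sex == "F"] <- M[isX, sex == "F", drop = FALSE] * 0.05

    # planted case effects, beta scale -> M scale at each probe's baseline
    if (length(dmsIdx)) {
      M[dmsIdx, isCase] <- M[dmsIdx, isCase, drop = FALSE] +
        mOffsetForDeltaBeta(dmsDelta, b0[dmsIdx])
    }
    for (key in names(dmrIdx)) {
      at <- dmrIdx[[key]]
      M[at, isCase] <- M[at, isCase, drop = FALSE] +
        mOffsetForDeltaBeta(dmrDelta[[key]], b0[at])
    }

    # residual noise, optionally correlated within islands
    E <- matrix(rnorm(nP * n, 0, config$noiseSD), nP, n)
    rho <- config$withinRegionCor
    if (rho > 0) {
      for (isl in unique(manifest$island_id[manifest$island_id != ""])) {
        at <- which(manifest$island_id == isl)
        shared <- rnorm(n, 0, config$noiseSD)
        E[at, ] <- sqrt(1 - rho) * E[at, , drop = FALSE] +
          sqrt(rho) * matrix(shared, length(at), n, byrow = TRUE)
      }
    }
    M <- M + E
    beta <- expit2(M)

    log2med <- rep(config$log2MedianIntensity, n)
    if (config$nLowIntensitySamples > 0) {
      low <- sample.int(n, config$nLowIntensitySamples)
      log2med[low] <- config$lowIntensityLog2Median
    }
    TT <- 2^(matrix(rnorm(nP * n, 0, config$intensityLogSD), nP, n) +
             matrix(log2med, nP, n, byrow = TRUE))
    meth <- beta * TT
    unmeth <- (1 - beta) * TT

    det <- matrix(runif(nP * n, 0, 0.01), nP, n)
    fail <- matrix(runif(nP * n) < config$detectionFailRate, nP, n)
    det[fail] <- runif(sum(fail), 0.06, 1)

    ids <- sprintf("S%04d", seq_len(n))
    dimnames(meth) <- dimnames(unmeth) <- dimnames(det) <-
      list(manifest$probe_id, ids)
    rownames(fractions) <- ids
    sheet <- DataFrame(sample_id = ids, split = grp$split,
                       phenotype = factor(grp$phenotype,
                                          levels = c("control", "case")),
                       age = age, sex = sex, array = array,
                       batch = factor(batch), row.names = ids)
    exp <- MethylationExperiment(meth = meth, unmeth = unmeth,
                                 detectionP = det, manifest = manifest,
                                 sampleSheet = sheet)
    truth <- list(
      trueDMS = if (length(dmsIdx))
        data.frame(probe_id = manifest$probe_id[dmsIdx],
                   delta_beta = dmsDelta, stringsAsFactors = FALSE)
      else data.frame(probe_id = character(0), delta_beta = numeric(0)),
      trueDMR = if (length(dmrIdx))
        lapply(setNames(names(dmrIdx), names(dmrIdx)), function(k)
          data.frame(probe_id = manifest$probe_id[dmrIdx[[k]]],
                     delta_beta = dmrDelta[[k]], stringsAsFactors = FALSE))
      else list(),
      cellFractions = fractions, batchLabels = batch,
      caseLabels = isCase, splitLabels = grp$split)
    list(experiment = exp, groundTruth = truth, cellReference = cellRef)
  })
}

#' Simulate a keyword -> gene annotation table
#'
#' Small fixture generator for the keyword-network stage: draws keyword gene
#' sets from the manifest's annotated genes with a configurable fraction of
#' genes shared between consecutive keywords.
#'
#' @param manifest a probe manifest with a `gene` column.
#' @param nKeywords number of keywords.
#' @param genesPerKeyword genes per keyword.
#' @param overlapFrac fraction of each keyword's genes shared with the
#'   previous keyword.
#' @param seed integer seed.
#' @return named list keyword -> character vector of gene symbols.
#' @export
simulateKeywordAnnotation <- function(manifest, nKeywords = 6,
                                      genesPerKeyword = 5,
                                      overlapFrac = 0.2, seed = 1L) {
  genes <- unique(manifest$gene[manifest$gene != ""])
  if (length(genes) < genesPerKeyword)
    stop("manifest has too few annotated genes")
  withSeed(substreamSeed(seed, "keywords"), {
    ann <- list()
    prev <- character(0)
    for (k in seq_len(nKeywords)) {
      nShare <- min(length(prev), round(overlapFrac * genesPerKeyword))
      shared <- if (nShare) sample(prev, nShare) else character(0)
      pool <- setdiff(genes, c(prev, shared))
      if (length(pool) < genesPerKeyword - nShare)
        pool <- setdiff(genes, shared)   # small gene universes reuse genes
      fresh <- sample(pool, genesPerKeyword - nShare)
      ann[[sprintf("keyword%02d", k)]] <- c(shared, fresh)
      prev <- ann[[sprintf("keyword%02d", k)]]
    }
    ann
  })
}
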