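test_that("region map groups islands, promoters and gene bodies correctly", {
  man <- data.frame(
    probe_id = paste0("cg", 1:8),
    chr = "1", pos = 1:8 * 100,
    gene = c("G", "G", "G", "", "H", "H", "", ""),
    feature = c("TSS200", "Body", "5'UTR", "intergenic", "TSS1500",
                "TSS200", "Body", "intergenic"),
    island_id = c("", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE)
  expect_warning(rm1 <- buildRegionMap(man), "without gene annotation")
  df <- as.data.frame(rm1[, 1:4])
  expect_setequal(df$region_id,
                  c("promoter:G", "promoter:H", "gene_body:G"))
  expect_setequal(rm1["promoter:G", ]$probe_ids[[1]], "cg1")
  expect_setequal(rm1["gene_body:G", ]$probe_ids[[1]], c("cg2", "cg3"))
  expect_setequal(rm1["promoter:H", ]$probe_ids[[1]], c("cg5", "cg6"))
  expect_equal(attr(rm1, "skipped"), 1L)
  # no island annotation: zero island regions, no error
  expect_false(any(df$region_type == "island"))
  # islands from the manifest island ids
  man$island_id <- c("i1", "i1", "", "", "", "", "", "")
  man$gene <- ""; man$feature <- "intergenic"
  rm2 <- buildRegionMap(man)
  expect_equal(as.data.frame(rm2)$region_type, "island")
  expect_setequal(rm2[1, ]$probe_ids[[1]], c("cg1", "cg2"))
})

test_that("deviance test matches an independent Newton-Raphson logistic fit", {
  set.seed(71)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  S <- matrix(rnorm(n * 2, mean = y * 0.8), n, 2,
              dimnames = list(NULL, c("cgA", "cgB")))
  conf <- data.frame(age = rnorm(n, 70, 5))
  res <- regionDevianceTest(S, y, conf)
  X0 <- cbind(1, conf$age)
  X1 <- cbind(X0, S)
  o0 <- newtonLogisticOracle(X0, y)
  o1 <- newtonLogisticOracle(X1, y)
  expect_equal(res$null_deviance, o0$deviance, tolerance = 1e-6)
  expect_equal(res$full_deviance, o1$deviance, tolerance = 1e-6)
  expect_equal(res$chi2, o0$deviance - o1$deviance, tolerance = 1e-6)
  expect_equal(res$df, 2L)
  expect_equal(res$p, pchisq(res$chi2, 2, lower.tail = FALSE))
  expect_equal(unname(res$site_coefs$coef), unname(o1$coef[3:4]),
               tolerance = 1e-4)
  # deviance difference equals twice the log-likelihood difference
  ll <- function(beta, X) {
    mu <- plogis(drop(X %*% beta)); sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  expect_equal(res$chi2, 2 * (ll(o1$coef, X1) - ll(o0$coef, X0)),
               tolerance = 1e-8)
})

test_that("degenerate and pathological regions are handled by convention", {
  y <- rep(c(0, 1), 10)
  r0 <- regionDevianceTest(NULL, y)
  expect_equal(r0$chi2, 0); expect_equal(r0$df, 0L); expect_equal(r0$p, 1)
  # perfect separation: flagged, p missing, no crash
  sep <- matrix(y * 10 - 5, 20, 1, dimnames = list(NULL, "cgS"))
  rs <- regionDevianceTest(sep, y)
  expect_false(rs$converged)
  expect_true(is.na(rs$p))
  # constant site columns are dropped from the df
  S <- cbind(cgA = rnorm(20), cgC = rep(1, 20))
  r1 <- regionDevianceTest(S, y)
  expect_equal(r1$df, 1L)
})

test_that("adding a pure-noise site never decreases chi2", {
  set.seed(72)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("cg", 1:3)))
  base <- regionDevianceTest(S, y)
  for (i in 1:5) {
    S2 <- cbind(S, extra = rnorm(n))
    colnames(S2)[4] <- "cgX"
    grown <- regionDevianceTest(S2, y)
    expect_gte(grown$chi2, base$chi2 - 1e-8)
    expect_equal(grown$df, base$df + 1L)
  }
})

test_that("within-region site FDR follows the hand-computed step-up", {
  rr <- structure(list(converged = TRUE, df = 3L,
    site_coefs = data.frame(probe_id = c("a", "b", "c"),
                            coef = c(1, 0.1, -0.1), se = 1,
                            p = c(0.001, 0.9, 0.9))),
    class = "RegionTestResult")
  sl <- siteLevelWithinRegion(rr)
  expect_equal(sl$q, c(0.003, 0.9, 0.9))
  expect_equal(sl$important, c(TRUE, FALSE, FALSE))
  # all p = 1: nothing important
  rr$site_coefs$p <- rep(1, 3)
  expect_false(any(siteLevelWithinRegion(rr)$important))
  # single-site region keeps its own p as q
  rr1 <- structure(list(converged = TRUE, df = 1L,
    site_coefs = data.frame(probe_id = "a", coef = 1, se = 1, p = 0.04)),
    class = "RegionTestResult")
  sl1 <- siteLevelWithinRegion(rr1)
  expect_equal(sl1$q, 0.04); expect_true(sl1$important)
  # non-converged region yields an empty set
  rr$converged <- FALSE
  expect_equal(nrow(siteLevelWithinRegion(rr)), 0)
})

test_that("site pooling de-duplicates and keeps multi-tag provenance", {
  pooled <- poolSites(paste0("cg", 1:3),
                      list("island:i1" = c("cg3", "cg4"),
                           "gene_body:G" = "cg3"))
  expect_equal(nrow(pooled), 4)
  expect_false(anyDuplicated(pooled$probe_id) > 0)
  expect_setequal(pooled["cg3", ]$provenance[[1]],
                  c("dms", "dmr_island", "dmr_gene_body"))
  # disjoint sets: union arithmetic
  p2 <- poolSites(paste0("a", 1:400),
                  list("island:x" = paste0("b", 1:2447)))
  expect_equal(nrow(p2), 2847)
  # identical sets: union is either set
  p3 <- poolSites(c("a", "b"), list("island:x" = c("a", "b")))
  expect_equal(nrow(p3), 2)
})

test_that("two-stage region workflow gates CV testing on discovery FDR", {
  dem <- balancedDemographics()
  cfg <- syntheticConfig(seed = 73, nProbes = 400, nIslands = 8,
    nGeneBodies = 4, nPromoters = 4, sitesPerRegion = c(4L, 6L),
    nCasesDisc = 80, nControlsDisc = 80, nCasesCV = 80, nControlsCV = 80,
    nFlagged = c(cross_reactive = 4, snp_within_3bp = 2,
                 smoking_associated = 1), nSexProbes = c(X = 4, Y = 1),
    ageMean = dem$ageMean, ageSD = dem$ageSD, maleProp = dem$maleProp,
    plantedDMR = list(isl0001 = c(0.06, -0.06, 0.06, -0.06, 0.06, -0.06),
                      isl0002 = rep(0.06, 6)))
  sim <- simulateCohort(cfg, generateManifest(cfg))
  sh <- sampleSheet(sim$experiment)
  M <- getM(sim$experiment)
  rmap <- buildRegionMap(probeManifest(sim$experiment))
  d <- sh$split == "discovery"; v <- sh$split == "cv"
  wf <- regionWorkflow(M[, d], M[, v], sh$phenotype[d], sh$phenotype[v],
                       regionMap = rmap)
  expect_true(all(c("island:isl0001", "island:isl0002") %in%
                  wf$discoverySignificant))
  expect_true(all(c("island:isl0001", "island:isl0002") %in% wf$replicated))
  # CV p-values exist only for discovery-significant regions
  res <- wf$results
  expect_true(all(is.na(res$cv_p[!res$region_id %in%
                                 wf$discoverySignificant])))
  # determinism: identical inputs give identical selections
  wf2 <- regionWorkflow(M[, d], M[, v], sh$phenotype[d], sh$phenotype[v],
                        regionMap = rmap)
  expect_identical(wf$replicated, wf2$replicated)
  expect_identical(wf$results, wf2$results)
})

test_that("all-null discovery skips cross-validation testing entirely", {
  set.seed(74)
  n <- 60
  M <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("cg", 1:40), paste0("s", 1:n)))
  man <- data.frame(probe_id = rownames(M), chr = "1",
                    pos = seq_len(40) * 100, gene = "",
                    feature = "intergenic",
                    island_id = rep(paste0("i", 1:8), each = 5),
                    stringsAsFactors = FALSE)
  rmap <- buildRegionMap(man)
  y <- rbinom(n, 1, 0.5)
  wf <- regionWorkflow(M, M, y, y, regionMap = rmap)
  if (length(wf$discoverySignificant) == 0) {
    expect_true(all(is.na(wf$results$cv_p)))
    expect_length(wf$cvTests, 0)
  }
  expect_length(wf$replicated, 0)
})

test_that("mixed-sign region effects are caught where site averaging fails", {
  dem <- balancedDemographics()
  devHits <- 0L; aggHits <- 0L; nRep <- 25L
  for (s in seq_len(nRep)) {
    cfg <- syntheticConfig(seed = 500 + s, nProbes = 80, nIslands = 1,
      nGeneBodies = 1, nPromoters = 1, sitesPerRegion = c(6L, 6L),
      nCasesDisc = 100, nControlsDisc = 100, nCasesCV = 1, nControlsCV = 1,
      nFlagged = c(cross_reactive = 2, snp_within_3bp = 2,
                   smoking_associated = 1), nSexProbes = c(X = 2, Y = 1),
      ageMean = dem$ageMean, ageSD = dem$ageSD, maleProp = dem$maleProp,
      plantedDMR = list(isl0001 = c(0.03, -0.03, 0.03, -0.03, 0.03, -0.03)))
    sim <- simulateCohort(cfg, generateManifest(cfg))
    sh <- sampleSheet(sim$experiment)
    d <- sh$split == "discovery"
    probes <- sim$groundTruth$trueDMR$isl0001$probe_id
    S <- t(getM(sim$experiment)[probes, d])
    y <- as.numeric(sh$phenotype[d] == "case")
    rt <- regionDevianceTest(S, y)
    if (isTRUE(rt$converged) && rt$p < 0.05) devHits <- devHits + 1L
    # mean-aggregate oracle: t-test on the per-sample region mean
    if (stats::t.test(rowMeans(S) ~ y)$p.value < 0.05) aggHits <- aggHits + 1L
  }
  expect_gte(devHits / nRep, 0.8)
  expect_lte(aggHits / nRep, 0.2)
})

test_that("region map exports 0-based half-open BED intervals", {
  man <- data.frame(probe_id = c("cg1", "cg2"), chr = "3",
                    pos = c(1000, 1200), gene = "", feature = "intergenic",
                    island_id = c("i1", "i1"), stringsAsFactors = FALSE)
  rmap <- buildRegionMap(man)
  path <- tempfile(fileext = ".bed")
  regionMapToBED(rmap, man, path)
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed$V1, "chr3")
  expect_equal(bed$V2, 999)     # 1-based 1000 -> 0-based 999
  expect_equal(bed$V3, 1200)
  expect_equal(bed$V4, "island:i1")
})
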