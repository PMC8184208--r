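#' Build the region map from a probe manifest
#'
#' Regions of three types: CpG islands keyed by the manifest `island_id`;
#' promoters = probes with feature `TSS200`/`TSS1500` grouped by gene; gene
#' bodies = probes with feature `5'UTR`/`Body` grouped by gene. Probes with
#' a gene-body or promoter feature but no gene annotation are skipped (their
#' count is recorded in the `skipped` attribute).
#'
#' @param manifest a probe manifest (`DataFrame`/`data.frame`) with columns
#'   `probe_id`, `gene`, `feature`, `island_id`.
#' @return a `DataFrame` with columns `region_id`, `region_type`, `gene`,
#'   `n_sites` and a `CharacterList` column `probe_ids` (probes in manifest
#'   order); attribute `skipped` counts unannotated gene-feature probes.
#' @export
buildRegionMap <- function(manifest) {
  man <- as.data.frame(manifest)
  regions <- list()
  isl <- man$island_id != ""
  for (id in unique(man$island_id[isl])) {
    regions[[length(regions) + 1L]] <-
      list(region_id = paste0("island:", id), region_type = "island",
           gene = "", probes = man$probe_id[man$island_id == id])
  }
  skipped <- 0L
  for (spec in list(c("promoter", "TSS200", "TSS1500"),
                    c("gene_body", "5'UTR", "Body"))) {
    hit <- man$feature %in% spec[-1]
    noGene <- hit & man$gene == ""
    if (any(noGene)) {
      skipped <- skipped + sum(noGene)
      warning(sum(noGene), " ", spec[1],
              "-feature probe(s) without gene annotation skipped")
    }
    hit <- hit & man$gene != ""
    for (g in unique(man$gene[hit])) {
      regions[[length(regions) + 1L]] <-
        list(region_id = paste0(spec[1], ":", g), region_type = spec[1],
             gene = g, probes = man$probe_id[hit & man$gene == g])
    }
  }
  out <- DataFrame(
    region_id = vapply(regions, `[[`, "", "region_id"),
    region_type = vapply(regions, `[[`, "", "region_type"),
    gene = vapply(regions, `[[`, "", "gene"),
    n_sites = vapply(regions, function(r) length(r$probes), 0L),
    probe_ids = CharacterList(lapply(regions, `[[`, "probes")))
  rownames(out) <- out$region_id
  attr(out, "skipped") <- skipped
  out
}

# Logistic regression by iteratively reweighted least squares with an
# optional small ridge penalty (never on the intercept) for numerical
# stability in wide designs. Returns unpenalized binomial deviance at the
# fitted coefficients, plus Wald statistics and convergence/separation
# diagnostics.
irlsLogistic <- function(X, y, ridge = 0, maxIter = 200, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  pen <- rep(ridge, p)
  if (colnames(X)[1] %in% c("(Intercept)", "")) pen[1] <- 0
  devOld <- Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    muC <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(muC) + (1 - y) * log(1 - muC))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + diag(pen, p)
    beta <- tryCatch(drop(solve(H, crossprod(X, w * z))),
                     error = function(e) rep(NA_real_, p))
    if (anyNA(beta)) return(list(converged = FALSE, separated = TRUE,
                                 deviance = NA_real_, coef = beta))
    if (abs(devOld - dev) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    devOld <- dev
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  # (quasi-)separation: a perfect fit, or diverging linear predictors
  separated <- (dev < 1e-4 && ncol(X) > 1) || max(abs(eta)) > 25
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + diag(pen, p)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  list(coef = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
       deviance = dev, converged = converged && !separated,
       separated = separated, iterations = it)
}

#' Region-level deviance-accumulation test
#'
#' The region test at the heart of the package: fits the nested binomial
#' (logistic) models
#' `phenotype ~ confounders` (null) and
#' `phenotype ~ confounders + site_1 + ... + site_n` (full),
#' and refers the deviance difference to a chi-squared distribution with
#' `n` degrees of freedom (one per site actually entered). Because every
#' site contributes its own coefficient, hyper- and hypo-methylated sites
#' along the same region accumulate evidence instead of cancelling.
#'
#' @param Msites samples x n matrix of the region's site M-values (column
#'   names = probe ids).
#' @param phenotype case/control labels (see [fitSiteModels()]).
#' @param confounders samples x q data.frame/matrix or NULL.
#' @param ridge small ridge penalty on the site/confounder coefficients for
#'   numerical stability in wide regions (default 1e-6); never applied to
#'   the intercept.
#' @return list of class `"RegionTestResult"`: `n_sites` (= df),
#'   `null_deviance`, `full_deviance`, `chi2`, `df`, `p`, `site_coefs`
#'   (`data.frame` probe_id/coef/se/p from the full model), `converged`.
#'   Perfect separation is flagged (`converged = FALSE`, `p = NA`), never
#'   an error. A zero-site region returns `chi2 = 0`, `df = 0`, `p = 1`.
#' @export
regionDevianceTest <- function(Msites, phenotype, confounders = NULL,
                               ridge = 1e-6) {
  y <- phenotypeTo01(phenotype)
  X0 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(confounders)) {
    C <- model.matrix(~ ., data = as.data.frame(confounders))[, -1, drop = FALSE]
    X0 <- cbind(X0, C)
  }
  if (is.null(Msites) || NCOL(Msites) == 0L) {
    return(structure(list(n_sites = 0L, null_deviance = NA_real_,
                          full_deviance = NA_real_, chi2 = 0, df = 0L, p = 1,
                          site_coefs = data.frame(probe_id = character(0),
                                                  coef = numeric(0),
                                                  se = numeric(0),
                                                  p = numeric(0)),
                          converged = TRUE),
                     class = "RegionTestResult"))
  }
  Msites <- as.matrix(Msites)
  keep <- apply(Msites, 2, function(z) sd(z) > 0 && !anyNA(z))
  S <- Msites[, keep, drop = FALSE]
  df <- ncol(S)
  null <- irlsLogistic(X0, y, ridge = ridge)
  full <- irlsLogistic(cbind(X0, S), y, ridge = ridge)
  conv <- isTRUE(null$converged) && isTRUE(full$converged)
  chi2 <- if (conv) max(0, null$deviance - full$deviance) else NA_real_
  p <- if (conv) pchisq(chi2, df = df, lower.tail = FALSE) else NA_real_
  siteIdx <- ncol(X0) + seq_len(df)
  sc <- data.frame(probe_id = colnames(S) %||% as.character(seq_len(df)),
                   coef = unname(full$coef[siteIdx]),
                   se = unname(full$se[siteIdx]),
                   stringsAsFactors = FALSE)
  sc$p <- 2 * pnorm(-abs(sc$coef / sc$se))
  structure(list(n_sites = df, null_deviance = null$deviance,
                 full_deviance = full$deviance, chi2 = chi2, df = df, p = p,
                 site_coefs = sc, converged = conv),
            class = "RegionTestResult")
}

#' @export
print.RegionTestResult <- function(x, ...) {
  cat("RegionTestResult:", x$df, "site(s), chi2 =", signif(x$chi2, 4),
      ", p =", signif(x$p, 3),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

testRegions <- function(M, phenotype, confounders, regionMap, ridge = 1e-6) {
  res <- lapply(seq_len(nrow(regionMap)), function(i) {
    probes <- intersect(regionMap$probe_ids[[i]], rownames(M))
    regionDevianceTest(t(M[probes, , drop = FALSE]), phenotype, confounders,
                       ridge = ridge)
  })
  names(res) <- regionMap$region_id
  res
}

#' Two-stage discovery/cross-validation region workflow
#'
#' Runs the deviance test on every region of every type in the discovery
#' set; within each region type, discovery FDR (Benjamini-Hochberg over the
#' regions of that type) selects regions for cross-validation testing, and
#' the cross-validation FDR is computed over that subset only. A parallel
#' Bonferroni track adjusts discovery p-values over all regions of the type
#' and cross-validation p-values over the discovery-Bonferroni-significant
#' subset.
#'
#' @param discM,cvM probes x samples M-value matrices for the two splits.
#' @param discPhenotype,cvPhenotype per-split labels.
#' @param discConfounders,cvConfounders per-split confounder tables (or
#'   NULL).
#' @param regionMap output of [buildRegionMap()].
#' @param alpha FDR / family-wise level (default 0.05).
#' @param ridge passed to [regionDevianceTest()].
#' @return list with `results` (per-region `data.frame`: type, n_sites,
#'   disc/cv p, q and Bonferroni-adjusted p, convergence), `replicated`
#'   (region ids FDR-replicated), `bonferroniReplicated`,
#'   `discoverySignificant`, and `discTests`/`cvTests` (the raw
#'   `RegionTestResult` lists; cross-validation only for tested regions).
#' @export
regionWorkflow <- function(discM, cvM, discPhenotype, cvPhenotype,
                           discConfounders = NULL, cvConfounders = NULL,
                           regionMap, alpha = 0.05, ridge = 1e-6) {
  missing <- !vapply(seq_len(nrow(regionMap)), function(i)
    all(regionMap$probe_ids[[i]] %in% rownames(discM)) &&
    all(regionMap$probe_ids[[i]] %in% rownames(cvM)), TRUE)
  if (any(missing)) {
    warning(sum(missing), " region(s) with probes absent from a split excluded")
    regionMap <- regionMap[!missing, ]
  }
  discTests <- testRegions(discM, discPhenotype, discConfounders, regionMap,
                           ridge)
  res <- data.frame(region_id = regionMap$region_id,
                    region_type = regionMap$region_type,
                    gene = regionMap$gene,
                    n_sites = vapply(discTests, `[[`, 0L, "df"),
                    disc_p = vapply(discTests, `[[`, 0, "p"),
                    disc_converged = vapply(discTests, `[[`, TRUE, "converged"),
                    stringsAsFactors = FALSE)
  res$disc_q <- NA_real_; res$disc_bonf <- NA_real_
  for (ty in unique(res$region_type)) {
    at <- res$region_type == ty
    res$disc_q[at] <- bhFDR(res$disc_p[at])
    res$disc_bonf[at] <- bonferroniAdjust(res$disc_p[at], m = sum(at))
  }
  res$cv_p <- NA_real_; res$cv_q <- NA_real_; res$cv_bonf <- NA_real_
  res$cv_converged <- NA
  toTest <- which(!is.na(res$disc_q) & res$disc_q < alpha)
  cvTests <- list()
  if (length(toTest)) {
    cvTests <- testRegions(cvM, cvPhenotype, cvConfounders,
                           regionMap[toTest, ], ridge)
    res$cv_p[toTest] <- vapply(cvTests, `[[`, 0, "p")
    res$cv_converged[toTest] <- vapply(cvTests, `[[`, TRUE, "converged")
    for (ty in unique(res$region_type[toTest])) {
      at <- toTest[res$region_type[toTest] == ty]
      res$cv_q[at] <- bhFDR(res$cv_p[at])
    }
  }
  # Bonferroni track: CV adjustment over the discovery-Bonferroni subset
  bonfDisc <- which(!is.na(res$disc_bonf) & res$disc_bonf < alpha)
  for (ty in unique(res$region_type[bonfDisc])) {
    at <- bonfDisc[res$region_type[bonfDisc] == ty]
    res$cv_bonf[at] <- bonferroniAdjust(res$cv_p[at], m = length(at))
  }
  list(results = res,
       discoverySignificant = res$region_id[toTest],
       replicated = res$region_id[which(res$cv_q < alpha)],
       bonferroniReplicated = res$region_id[which(res$cv_bonf < alpha)],
       discTests = discTests, cvTests = cvTests)
}

#' Within-region site-level FDR
#'
#' Benjamini-Hochberg correction applied to one region's own full-model
#' site p-values (m = the region's site count only); sites with
#' `q < threshold` are marked important. A non-converged region yields an
#' empty set.
#'
#' @param regionResult a `RegionTestResult`.
#' @param threshold FDR level (default 0.05).
#' @return `data.frame` with `probe_id`, `p`, `q`, `important`.
#' @export
siteLevelWithinRegion <- function(regionResult, threshold = 0.05) {
  if (!isTRUE(regionResult$converged) || regionResult$df == 0L)
    return(data.frame(probe_id = character(0), p = numeric(0),
                      q = numeric(0), important = logical(0)))
  sc <- regionResult$site_coefs
  q <- bhFDR(sc$p)
  data.frame(probe_id = sc$probe_id, p = sc$p, q = q,
             important = q < threshold, stringsAsFactors = FALSE)
}

#' Pool discovery-significant sites and important within-region sites
#'
#' De-duplicated union of the site-level calls and the per-region important
#' sites, with multi-tag provenance (`dms`, `dmr_island`, `dmr_gene_body`,
#' `dmr_promoter`).
#'
#' @param dmsIds character vector of site-level significant probe ids.
#' @param regionImportant named list: region id (prefixed `island:`,
#'   `gene_body:`, `promoter:`) -> character vector of important probe ids.
#' @return `DataFrame` with `probe_id` and a `CharacterList` column
#'   `provenance`; no duplicate probes.
#' @export
poolSites <- function(dmsIds, regionImportant = list()) {
  prov <- lapply(dmsIds, function(p) "dms")
  names(prov) <- dmsIds
  for (rid in names(regionImportant)) {
    tag <- paste0("dmr_", sub(":.*$", "", rid))
    for (p in regionImportant[[rid]]) {
      prov[[p]] <- unique(c(prov[[p]], tag))
    }
  }
  ids <- names(prov)
  out <- DataFrame(probe_id = ids,
                   provenance = CharacterList(unname(prov)))
  rownames(out) <- ids
  out
}

#' Export a region map as BED intervals
#'
#' Writes one 0-based half-open interval per region spanning the region's
#' minimum to maximum probe position, `name` = region id.
#'
#' @param regionMap output of [buildRegionMap()].
#' @param manifest the probe manifest (for chromosome/position lookup).
#' @param path output file.
#' @return the path, invisibly.
#' @export
regionMapToBED <- function(regionMap, manifest, path) {
  man <- as.data.frame(manifest)
  rows <- lapply(seq_len(nrow(regionMap)), function(i) {
    at <- match(regionMap$probe_ids[[i]], man$probe_id)
    data.frame(chrom = paste0("chr", man$chr[at[1]]),
               start = min(man$pos[at]) - 1L,   # 1-based -> 0-based half-open
               end = max(man$pos[at]),
               name = regionMap$region_id[i], stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
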