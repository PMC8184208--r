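#' Shrinkage partial correlations among pooled sites
#'
#' Gaussian-graphical-model partial correlations for a (possibly
#' high-dimensional) set of sites: the sample correlation matrix is shrunk
#' toward the identity with the analytically chosen Schaefer-Strimmer
#' intensity, inverted to a precision matrix `Omega`, and
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`. P-values use the Fisher
#' z transform with effective sample size `n - (k - 2) - 3` (each pair is
#' conditioned on the remaining `k - 2` sites); q-values are
#' Benjamini-Hochberg over the upper triangle.
#'
#' @param X samples x sites matrix (>= 10 samples, >= 3 sites; no constant
#'   columns).
#' @param shrinkage shrinkage intensity in `[0, 1]`; NULL (default) uses
#'   the analytic estimate.
#' @return list of class `"PartialCorrelationResult"`: `site_ids`, `pcor`
#'   (symmetric, unit diagonal), `shrinkage`, `p`, `q` (symmetric
#'   matrices), `n`.
#' @export
estimatePartialCorrelations <- function(X, shrinkage = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (k < 3) stop("need at least 3 sites")
  if (n < 10) stop("need at least 10 samples")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant site column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- cor(X)
  if (is.null(shrinkage)) {
    # Schaefer-Strimmer analytic intensity for shrinkage toward identity:
    # lambda* = sum Var_hat(r_ij) / sum r_ij^2 over off-diagonal entries
    Z <- scale(X)
    num <- 0; den <- 0
    W <- array(0, c(n, 1))
    for (i in seq_len(k - 1)) {
      Wi <- Z[, i] * Z[, (i + 1):k, drop = FALSE]
      wbar <- colMeans(Wi)
      vr <- n / ((n - 1)^3) * colSums(sweep(Wi, 2, wbar)^2)
      num <- num + sum(vr)
      den <- den + sum(R[i, (i + 1):k]^2)
    }
    shrinkage <- if (den > 0) min(1, max(0, num / den)) else 1
  }
  Rs <- (1 - shrinkage) * R + shrinkage * diag(k)
  Omega <- solve(Rs)
  d <- sqrt(diag(Omega))
  pc <- -Omega / tcrossprod(d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  nEff <- n - (k - 2) - 3
  p <- matrix(1, k, k)
  if (nEff > 0) {
    z <- atanh(pmin(pmax(pc, -1 + 1e-12), 1 - 1e-12)) * sqrt(nEff)
    p <- 2 * pnorm(-abs(z))
  }
  diag(p) <- 1
  up <- upper.tri(p)
  q <- matrix(1, k, k)
  q[up] <- bhFDR(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  ids <- colnames(X) %||% sprintf("site%d", seq_len(k))
  dimnames(pc) <- dimnames(p) <- dimnames(q) <- list(ids, ids)
  structure(list(site_ids = ids, pcor = pc, shrinkage = shrinkage,
                 p = p, q = q, n = n),
            class = "PartialCorrelationResult")
}

#' @export
print.PartialCorrelationResult <- function(x, ...) {
  cat("PartialCorrelationResult:", length(x$site_ids), "sites,",
      x$n, "samples, shrinkage", signif(x$shrinkage, 3), "\n")
  invisible(x)
}

# Map a keyword to the pooled-site indices via keyword -> genes -> probes.
keywordSites <- function(keyword, annotation, probeGene, siteIds) {
  genes <- annotation[[keyword]]
  if (is.null(genes)) stop("unknown keyword: ", keyword)
  probes <- names(probeGene)[probeGene %in% genes]
  which(siteIds %in% probes)
}

#' Keyword-pair enrichment of significant partial correlations
#'
#' Tests whether site pairs crossing two functional keywords are enriched
#' for significant partial correlations relative to the remaining pooled-
#' site pairs. The 2x2 table rows are cross-keyword pairs vs background
#' pairs (all pooled-site pairs neither crossing the two keywords nor lying
#' within a single one of them), columns significant vs not; two-sided
#' Fisher exact test.
#'
#' @param pcorResult an [estimatePartialCorrelations()] result.
#' @param annotation named list keyword -> gene symbols.
#' @param probeGene named character vector probe id -> gene symbol.
#' @param keywordA,keywordB the two keywords (each must map to >= 1 pooled
#'   site).
#' @param useQ use BH q-values (default) rather than raw p.
#' @param sigThreshold significance level for a pair (default 0.05).
#' @return list of class `"KeywordEdge"`: `keyword_a`, `keyword_b`,
#'   `table` (2x2), `odds_ratio` (NA when undefined), `fisher_p`.
#' @export
keywordPairEnrichment <- function(pcorResult, annotation, probeGene,
                                  keywordA, keywordB, useQ = TRUE,
                                  sigThreshold = 0.05) {
  ids <- pcorResult$site_ids
  k <- length(ids)
  ia <- keywordSites(keywordA, annotation, probeGene, ids)
  ib <- keywordSites(keywordB, annotation, probeGene, ids)
  if (!length(ia)) stop("keyword maps to zero pooled sites: ", keywordA)
  if (!length(ib)) stop("keyword maps to zero pooled sites: ", keywordB)
  sig <- (if (useQ) pcorResult$q else pcorResult$p) < sigThreshold
  up <- upper.tri(sig)
  inA <- matrix(FALSE, k, k); inA[ia, ] <- TRUE
  inB <- matrix(FALSE, k, k); inB[ib, ] <- TRUE
  cross <- (inA & t(inB)) | (inB & t(inA))
  withinA <- inA & t(inA); withinB <- inB & t(inB)
  crossPair <- cross & !withinA & !withinB & up
  bgPair <- !cross & !withinA & !withinB & up
  tab <- matrix(c(sum(crossPair & sig), sum(crossPair & !sig),
                  sum(bgPair & sig), sum(bgPair & !sig)),
                2, 2, byrow = TRUE,
                dimnames = list(c("cross", "background"),
                                c("significant", "not")))
  if (sum(tab[, "significant"]) == 0) {
    p <- 1; orr <- NA_real_
  } else {
    ft <- fisher.test(tab)
    p <- ft$p.value
    orr <- unname(ft$estimate)
  }
  structure(list(keyword_a = keywordA, keyword_b = keywordB, table = tab,
                 odds_ratio = orr, fisher_p = p),
            class = "KeywordEdge")
}

#' Build the keyword network
#'
#' Runs [keywordPairEnrichment()] for every unordered keyword pair, adjusts
#' the Fisher p-values by Benjamini-Hochberg over all pairs, and retains
#' edges with `q < qThreshold`. Node degrees identify hub keywords.
#'
#' @param pcorResult an [estimatePartialCorrelations()] result over the
#'   pooled sites.
#' @param annotation named list keyword -> gene symbols (>= 2 keywords with
#'   mapped sites are required for any edge).
#' @param probeGene named character vector probe id -> gene.
#' @param qThreshold edge FDR threshold (default 0.05).
#' @param useQ,sigThreshold pair-significance rule, see
#'   [keywordPairEnrichment()].
#' @return list with `edges` (`data.frame`: keyword_a, keyword_b, counts,
#'   odds_ratio, p, q, retained), `retained` (edge subset), `degree`
#'   (named vector over keywords).
#' @export
buildKeywordNetwork <- function(pcorResult, annotation, probeGene,
                                qThreshold = 0.05, useQ = TRUE,
                                sigThreshold = 0.05) {
  kws <- names(annotation)
  kws <- kws[vapply(kws, function(kw)
    length(keywordSites(kw, annotation, probeGene, pcorResult$site_ids)) > 0,
    TRUE)]
  if (length(kws) < 2)
    return(list(edges = data.frame(), retained = data.frame(),
                degree = setNames(rep(0L, length(kws)), kws)))
  pairs <- utils::combn(kws, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    e <- keywordPairEnrichment(pcorResult, annotation, probeGene,
                               pairs[1, j], pairs[2, j], useQ, sigThreshold)
    data.frame(keyword_a = e$keyword_a, keyword_b = e$keyword_b,
               cross_sig = e$table["cross", "significant"],
               cross_total = sum(e$table["cross", ]),
               bg_sig = e$table["background", "significant"],
               bg_total = sum(e$table["background", ]),
               odds_ratio = e$odds_ratio, p = e$fisher_p,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges$q <- bhFDR(edges$p)
  edges$retained <- edges$q < qThreshold
  retained <- edges[edges$retained, , drop = FALSE]
  deg <- setNames(rep(0L, length(kws)), kws)
  if (nrow(retained)) {
    tb <- table(c(retained$keyword_a, retained$keyword_b))
    deg[names(tb)] <- as.integer(tb)
  }
  list(edges = edges, retained = retained, degree = deg)
}

#' Write a keyword network as GraphML
#'
#' @param network a [buildKeywordNetwork()] result.
#' @param path output file (Cytoscape-compatible GraphML).
#' @return the path, invisibly.
#' @export
writeNetworkGraphML <- function(network, path) {
  ed <- network$retained
  g <- igraph::graph_from_data_frame(
    ed[, c("keyword_a", "keyword_b", "odds_ratio", "p", "q")],
    directed = FALSE,
    vertices = data.frame(name = names(network$degree),
                          degree = unname(network$degree)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
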