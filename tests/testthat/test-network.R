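test_that("partial correlation matches the closed form at zero shrinkage", {
  set.seed(91)
  n <- 400
  Z <- matrix(rnorm(n * 3), n, 3)
  # induce roughly equal pairwise correlation via a shared factor
  f <- rnorm(n)
  X <- sqrt(0.5) * Z + sqrt(0.5) * f
  colnames(X) <- c("x", "y", "z")
  res <- estimatePartialCorrelations(X, shrinkage = 0)
  R <- cor(X)
  expect_equal(res$pcor["x", "y"],
               pcorOracle3(R["x", "y"], R["x", "z"], R["y", "z"]),
               tolerance = 1e-10)
  expect_equal(res$pcor, t(res$pcor))
  expect_equal(unname(diag(res$pcor)), rep(1, 3))
  # exact equicorrelation 0.5 gives pcor exactly 1/3
  expect_equal(pcorOracle3(0.5, 0.5, 0.5), 1 / 3)
})

test_that("chain dependence is removed by conditioning", {
  set.seed(92)
  n <- 2000
  x <- rnorm(n)
  z <- 0.8 * x + rnorm(n, 0, 0.6)
  y <- 0.8 * z + rnorm(n, 0, 0.6)   # y depends on x only through z
  X <- cbind(x = x, y = y, z = z)
  res <- estimatePartialCorrelations(X, shrinkage = 0)
  expect_gt(abs(cor(x, y)), 0.3)
  expect_lt(abs(res$pcor["x", "y"]), 0.05)
})

test_that("independent sites are calibrated and the precision matrix is PD", {
  set.seed(93)
  n <- 150; k <- 20
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, sprintf("cg%02d", 1:k)))
  res <- estimatePartialCorrelations(X)
  up <- upper.tri(res$p)
  frac <- mean(res$p[up] < 0.05)
  m <- sum(up)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
  # shrunk correlation matrix is positive definite
  Rs <- (1 - res$shrinkage) * cor(X) + res$shrinkage * diag(k)
  expect_true(all(eigen(Rs, only.values = TRUE)$values > 0))
  expect_true(res$shrinkage >= 0 && res$shrinkage <= 1)
  # errors: constant column, too few sites/samples
  Xbad <- X; Xbad[, 2] <- 1
  expect_error(estimatePartialCorrelations(Xbad), "cg02")
  expect_error(estimatePartialCorrelations(X[, 1:2]), "at least 3")
  expect_error(estimatePartialCorrelations(X[1:5, ]), "at least 10")
})

test_that("Fisher keyword-pair test matches hypergeometric enumeration", {
  # cross pairs: 3 of 4 significant; background: 1 of 4
  tab <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
  expect_equal(fisherEnumOracle(tab), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher.test(tab)$p.value, 34 / 70, tolerance = 1e-10)
  set.seed(94)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 3), 2, 2)
    if (sum(tab) > 30 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisher.test(tab)$p.value, fisherEnumOracle(tab),
                 tolerance = 1e-9)
  }
})

# Construct a pooled-site system where two keywords share a planted
# correlated module: genes g1 (keyword A) and g2 (keyword B) carry sites
# driven by one latent factor; remaining genes are independent noise.
plantedKeywordSystem <- function(seed, nPerGene = 2, nNoiseGenes = 4,
                                 n = 200) {
  set.seed(seed)
  f <- rnorm(n)
  genes <- c("g1", "g2", paste0("n", seq_len(nNoiseGenes)))
  X <- NULL; probeGene <- character(0)
  for (g in genes) {
    driven <- g %in% c("g1", "g2")
    block <- vapply(seq_len(nPerGene), function(i) {
      if (driven) sqrt(0.8) * f + sqrt(0.2) * rnorm(n) else rnorm(n)
    }, numeric(n))
    colnames(block) <- paste0(g, "_s", seq_len(nPerGene))
    probeGene[colnames(block)] <- g
    X <- cbind(X, block)
  }
  ann <- c(list(kwA = "g1", kwB = "g2"),
           setNames(as.list(paste0("n", seq_len(nNoiseGenes))),
                    paste0("kw", seq_len(nNoiseGenes) + 2)))
  list(X = X, probeGene = probeGene, annotation = ann)
}

test_that("keyword network recovers a planted cross-keyword module", {
  hits <- 0L; falseEdges <- 0L
  for (s in 1:10) {
    sys <- plantedKeywordSystem(seed = 940 + s)
    pc <- estimatePartialCorrelations(sys$X)
    net <- buildKeywordNetwork(pc, sys$annotation, sys$probeGene)
    ed <- net$retained
    hasAB <- any((ed$keyword_a == "kwA" & ed$keyword_b == "kwB") |
                 (ed$keyword_a == "kwB" & ed$keyword_b == "kwA"))
    if (hasAB) hits <- hits + 1L
    falseEdges <- falseEdges + sum(!(ed$keyword_a %in% c("kwA", "kwB") &
                                     ed$keyword_b %in% c("kwA", "kwB")))
  }
  expect_gte(hits, 8)
  expect_lte(falseEdges / 10, 0.5)
})

test_that("keyword pair arithmetic, symmetry and degenerate cases", {
  sys <- plantedKeywordSystem(seed = 95)
  pc <- estimatePartialCorrelations(sys$X)
  e1 <- keywordPairEnrichment(pc, sys$annotation, sys$probeGene,
                              "kwA", "kwB")
  e2 <- keywordPairEnrichment(pc, sys$annotation, sys$probeGene,
                              "kwB", "kwA")
  expect_equal(e1$fisher_p, e2$fisher_p)
  expect_equal(e1$table["cross", ], e2$table["cross", ])
  # margins consistent with the pair universe: within-keyword pairs are
  # excluded from both rows
  k <- length(pc$site_ids)
  nPairs <- k * (k - 1) / 2
  withinA <- 1; withinB <- 1
  expect_equal(sum(e1$table), nPairs - withinA - withinB)
  expect_error(keywordPairEnrichment(pc, c(sys$annotation,
                                           list(empty = "nope")),
                                     sys$probeGene, "kwA", "empty"),
               "zero mapped|zero pooled")
  # zero significant pairs anywhere: p = 1, odds ratio missing
  set.seed(96)
  Xind <- matrix(rnorm(200 * 9), 200, 9,
                 dimnames = list(NULL, names(sys$probeGene)[1:9]))
  pcInd <- estimatePartialCorrelations(Xind, shrinkage = 0.5)
  pcInd$q[] <- 1
  e0 <- keywordPairEnrichment(pcInd, sys$annotation, sys$probeGene,
                              "kwA", "kwB")
  expect_equal(e0$fisher_p, 1)
  expect_true(is.na(e0$odds_ratio))
})

test_that("a single mapped keyword yields an empty edge list", {
  sys <- plantedKeywordSystem(seed = 97)
  pc <- estimatePartialCorrelations(sys$X)
  net <- buildKeywordNetwork(pc, sys$annotation["kwA"], sys$probeGene)
  expect_equal(nrow(net$edges), 0)
})

test_that("shuffled annotations produce few edges on average", {
  sys <- plantedKeywordSystem(seed = 98)
  pc <- estimatePartialCorrelations(sys$X)
  set.seed(98)
  nEdges <- replicate(50, {
    shuffled <- sys$probeGene
    names(shuffled) <- sample(names(shuffled))
    nrow(buildKeywordNetwork(pc, sys$annotation, shuffled)$retained)
  })
  nKw <- length(sys$annotation)
  expect_lte(mean(nEdges), 0.05 * choose(nKw, 2) + 0.15)
})

test_that("GraphML export writes a Cytoscape-readable graph", {
  sys <- plantedKeywordSystem(seed = 99)
  pc <- estimatePartialCorrelations(sys$X)
  net <- buildKeywordNetwork(pc, sys$annotation, sys$probeGene)
  path <- tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$degree))
  expect_equal(igraph::ecount(g), nrow(net$retained))
})
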