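test_that("site-model coefficients match the normal-equations oracle", {
  set.seed(61)
  n <- 5
  pheno <- c(0, 1, 0, 1, 1)
  conf <- data.frame(age = c(60, 71, 55, 80, 66))
  M <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("cg", 1:3), paste0("s", 1:n)))
  fit <- fitSiteModels(M, pheno, conf)
  X <- cbind(1, pheno, conf$age)
  for (i in 1:3) {
    expect_equal(fit$coef_M[i], unname(olsOracle(X, M[i, ])[2]),
                 tolerance = 1e-10)
  }
  expect_equal(fit$df_resid[1], n - 3)
  expect_true(all(sign(fit$t) == sign(fit$coef_M)))
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  M <- matrix(rnorm(20), 2, 10)
  pheno <- rep(c(0, 1), 5)
  expect_error(fitSiteModels(M, pheno, data.frame(dup = pheno)),
               "rank deficient.*dup")
})

test_that("null simulations give uniform p-values", {
  set.seed(62)
  n <- 60
  pheno <- rep(c(0, 1), n / 2)
  M <- matrix(rnorm(1000 * n), 1000, n)
  fit <- fitSiteModels(M, pheno)
  expect_gt(ks.test(fit$p, "punif")$p.value, 0.01)
})

test_that("a planted site is detected below the Bonferroni threshold", {
  hits <- 0L
  thr <- bonferroniThreshold(0.05, 150)
  dem <- balancedDemographics()
  for (s in seq_len(20)) {
    cfg <- syntheticConfig(seed = 300 + s, nProbes = 150, nIslands = 2,
      nGeneBodies = 2, nPromoters = 2,
      nCasesDisc = 200, nControlsDisc = 200, nCasesCV = 1, nControlsCV = 1,
      nFlagged = c(cross_reactive = 2, snp_within_3bp = 2,
                   smoking_associated = 1),
      nSexProbes = c(X = 4, Y = 1), noiseSD = 0.5,
      ageMean = dem$ageMean, ageSD = dem$ageSD, maleProp = dem$maleProp,
      plantedDMS = data.frame(probe = 100, deltaBeta = 0.05))
    sim <- simulateCohort(cfg, generateManifest(cfg))
    sh <- sampleSheet(sim$experiment)
    disc <- sh$split == "discovery"
    fit <- fitSiteModels(getM(sim$experiment)[, disc], sh$phenotype[disc])
    if (fit$p[100] < thr) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})

test_that("variance moderation shrinks toward the prior correctly", {
  set.seed(63)
  n <- 20
  pheno <- rep(c(0, 1), n / 2)
  # identical sample variances: the posterior equals the common value
  M <- matrix(rnorm(50 * n), 50, n)
  s2 <- fitSiteModels(M, pheno)$s2
  M <- M / sqrt(s2)                    # rescale every row to equal s2
  fit <- fitSiteModels(M, pheno)
  mod <- moderateVariance(fit)
  expect_equal(unname(mod$s_tilde_sq), fit$s2, tolerance = 1e-8)
  # posterior variance lies between the sample variance and the prior
  M2 <- matrix(rnorm(200 * n, sd = rep(c(0.5, 2), each = 100)), 200, n)
  fit2 <- fitSiteModels(M2, pheno)
  mod2 <- moderateVariance(fit2)
  lo <- pmin(fit2$s2, mod2$s0_sq); hi <- pmax(fit2$s2, mod2$s0_sq)
  expect_true(all(mod2$s_tilde_sq >= lo - 1e-12 &
                  mod2$s_tilde_sq <= hi + 1e-12))
  # moderated p ranks agree with ordinary p when variances are equal
  expect_gt(cor(mod$p_mod, fit$p, method = "spearman"), 0.9999)
})

test_that("moderation recovers the prior parameters from simulated variances", {
  n <- 20; df <- n - 2
  d0True <- 4; s0True <- 1
  d0Est <- numeric(20); s0Est <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(400 + s)
    sigma2 <- s0True * d0True / rchisq(1000, d0True)
    s2 <- sigma2 * rchisq(1000, df) / df
    fit <- data.frame(probe_id = as.character(1:1000),
                      coef_M = rnorm(1000), se_M = 1, df_resid = df,
                      t = 0, p = 1, delta_beta = 0,
                      stdev_unscaled = 1, s2 = s2)
    mod <- moderateVariance(fit)
    d0Est[s] <- mod$d0; s0Est[s] <- mod$s0_sq
  }
  expect_gt(mean(d0Est), 2.5); expect_lt(mean(d0Est), 6)
  expect_gt(mean(s0Est), 0.8); expect_lt(mean(s0Est), 1.25)
})

test_that("moderation rejects degenerate inputs", {
  fit <- data.frame(probe_id = "a", coef_M = 1, se_M = 1, df_resid = 5,
                    t = 1, p = 0.3, delta_beta = 0, stdev_unscaled = 1,
                    s2 = 0)
  expect_error(moderateVariance(fit), "at least 10")
  fit10 <- fit[rep(1, 10), ]
  expect_error(moderateVariance(fit10), "zero residual variance")
})

test_that("BH FDR equals the brute-force step-up", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bhFDR(numeric(0)), numeric(0))
  set.seed(64)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    q <- bhFDR(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("Bonferroni arithmetic matches the published threshold", {
  expect_equal(signif(bonferroniThreshold(0.05, 429156), 3), 1.17e-7)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniAdjust(0.2, m = 10), 1)
  expect_error(bonferroniThreshold(0.05, 0), "at least 1")
  expect_error(bonferroniAdjust(0.2, m = 0), "at least 1")
})

test_that("discovery/replication uses subset-wise FDR and flags concordance", {
  disc <- data.frame(probe_id = paste0("cg", 1:6),
                     p = c(1e-5, 2e-5, 0.9, 0.8, 0.7, 3e-5),
                     coef_M = c(1, -1, 1, 1, 1, 0.5))
  cv <- data.frame(probe_id = paste0("cg", 1:6),
                   p = c(1e-4, 0.9, 0.5, 0.5, 0.5, 1e-3),
                   coef_M = c(0.8, -0.7, 1, 1, 1, -0.4))
  out <- discoveryReplication(disc, cv)
  expect_setequal(out$discoverySignificant, c("cg1", "cg2", "cg6"))
  # cv FDR computed over the 3-probe subset only
  expect_equal(out$table$cv_q, bhFDR(cv$p[c(1, 2, 6)]))
  expect_setequal(out$replicated, c("cg1", "cg6"))
  expect_equal(out$table$concordant, c(TRUE, TRUE, FALSE))
  # all-null discovery: empty
  disc0 <- transform(disc, p = 0.9)
  expect_length(discoveryReplication(disc0, cv)$replicated, 0)
  # probe with strong discovery but weak cv stays in stage 1 only
  expect_true("cg2" %in% out$discoverySignificant &&
              !"cg2" %in% out$replicated)
  expect_error(discoveryReplication(disc,
    transform(cv, probe_id = paste0("x", 1:6))), "disjoint")
})

test_that("fixed-effect meta-analysis matches closed forms and metafor", {
  # equal inputs: convexity forces the common value
  m <- metaFixedEffect(-0.024, 0.005, -0.024, 0.008)
  expect_equal(m$beta_meta, -0.024)
  m2 <- metaFixedEffect(1, 1, 3, 1)
  expect_equal(m2$beta_meta, 2)
  expect_equal(m2$se_meta, 1 / sqrt(2))
  # estimate always inside the input interval and stage-order invariant
  set.seed(65)
  for (i in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.1, 2)
    mm <- metaFixedEffect(b[1], s[1], b[2], s[2])
    expect_gte(mm$beta_meta, min(b)); expect_lte(mm$beta_meta, max(b))
    mrev <- metaFixedEffect(b[2], s[2], b[1], s[1])
    expect_equal(mm$beta_meta, mrev$beta_meta)
    expect_equal(mm$p_meta, mrev$p_meta)
  }
  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = c(-0.018, -0.015),
                      sei = c(seFromP(-0.018, 1.2e-6),
                              seFromP(-0.015, 1.4e-4)), method = "FE")
  mine <- metaFixedEffect(-0.018, seFromP(-0.018, 1.2e-6),
                          -0.015, seFromP(-0.015, 1.4e-4))
  expect_equal(mine$beta_meta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$p_meta, as.numeric(ref$pval), tolerance = 1e-10)
})

test_that("printed two-stage estimates reproduce the published meta effect", {
  # stages (-0.018, p=1.2e-6) and (-0.015, p=1.4e-4): combined prints -0.017
  m <- metaFixedEffect(-0.018, seFromP(-0.018, 1.2e-6),
                       -0.015, seFromP(-0.015, 1.4e-4))
  expect_equal(round(m$beta_meta, 3), -0.017)
  expect_error(seFromP(0.01, 0), "strictly inside")
  expect_error(seFromP(0.01, 1), "strictly inside")
  expect_error(metaFixedEffect(1, 0, 1, 1), "positive")
})
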