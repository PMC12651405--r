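test_that("invalid configurations are rejected naming the field", {
  expect_error(simConfig(nLines = 0), "nLines")
  expect_error(simConfig(eraProportions = c(0.5, 0.5, 0.5)), "eraProportions")
  expect_error(simConfig(missingRate = 0.3), "missingRate")
  expect_error(simConfig(hetRate = 0.2), "hetRate")
  expect_error(simConfig(varianceComponents = c(var_sca = -1)),
               "varianceComponents")
  expect_error(simConfig(varianceComponents = c(var_bogus = 1)), "var_bogus")
})

test_that("genotype simulation is reproducible bit for bit", {
  cfg <- simConfig(nLines = 15, nSnps = 30, traits = "YPP", seed = 11)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g1$panel), dosages(g2$panel))
  expect_identical(g1$eras, g2$eras)
  t1 <- simulateTestcrossTrial(cfg, g1)
  t2 <- simulateTestcrossTrial(cfg, g2)
  expect_identical(t1$plots, t2$plots)
})

test_that("trial dimensions match the NCII design", {
  cfg <- simConfig(nLines = 218, nTesters = 2, nLocations = 3, nBlocks = 3,
                   nSnps = 40, nCausalPerTrait = 2, traits = "YPP", seed = 4)
  g <- simulateGenotypes(cfg)
  tr <- simulateTestcrossTrial(cfg, g)
  expect_equal(nrow(tr$plots), 218 * 2 * 3 * 3)
  crosses <- unique(paste(tr$plots$line_id, tr$plots$tester_id))
  expect_equal(length(crosses), 436)
})

test_that("ground truth satisfies the zero-sum constraints exactly", {
  tr <- smallTrial(seed = 3, nLines = 10, traits = c("YPP", "TBN"))
  for (t in tr$truth$perTrait) {
    expect_equal(sum(t$lineGca), 0, tolerance = 1e-12)
    expect_equal(sum(t$testerGca), 0, tolerance = 1e-12)
    expect_lt(max(abs(rowSums(t$sca))), 1e-12)
    expect_lt(max(abs(colSums(t$sca))), 1e-12)
  }
})

test_that("degenerate variances give constant plots at the grand mean", {
  vc <- c(var_gca_line = 0, var_gca_tester = 0, var_sca = 0, var_loc = 0,
          var_block_within_loc = 0, var_line_x_loc = 0, var_residual = 0)
  cfg <- simConfig(nLines = 6, nSnps = 20, traits = "YPP", seed = 2,
                   varianceComponents = vc, markerEffectScale = 0,
                   grandMean = 42)
  tr <- simulateTestcrossTrial(cfg, simulateGenotypes(cfg))
  expect_true(all(tr$plots$YPP == 42))
})

test_that("without an era shift, causal frequencies are era-homogeneous", {
  # chi-square homogeneity across eras should reject at about its nominal
  # alpha = 0.01 rate; require non-significance for >= 95% of causal SNPs
  nSig <- 0; nTot <- 0
  for (rep in 1:200) {
    cfg <- simConfig(nLines = 90, nSnps = 5, nCausalPerTrait = 5,
                     traits = "YPP", eraFreqShift = 0, hetRate = 0,
                     missingRate = 0, causalBaseFreq = 0.3, seed = rep)
    g <- simulateGenotypes(cfg)
    d <- dosages(g$panel)
    e <- factor(g$eras, eraLevels())
    for (s in seq_len(nrow(d))) {
      tab <- table(factor(d[s, ] > 0, c(FALSE, TRUE)), e)
      if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
      p <- suppressWarnings(chisq.test(tab)$p.value)
      nTot <- nTot + 1
      if (!is.na(p) && p < 0.01) nSig <- nSig + 1
    }
  }
  expect_gte((nTot - nSig) / nTot, 0.95)
})

test_that("a causal allele absent in AGE1 appears at the shifted frequency", {
  freqs <- matrix(NA_real_, 50, 3)
  for (rep in 1:50) {
    cfg <- simConfig(nLines = 219, nSnps = 10, nCausalPerTrait = 1,
                     traits = "YPP", causalBaseFreq = 0, eraFreqShift = 0.15,
                     hetRate = 0, missingRate = 0,
                     eraProportions = c(1, 1, 1) / 3, seed = 100 + rep)
    g <- simulateGenotypes(cfg)
    snp <- g$causal$YPP
    d <- dosages(g$panel)[snp, ]
    e <- factor(g$eras, eraLevels())
    freqs[rep, ] <- tapply(d, e, function(x) mean(x) / 2)
  }
  expect_true(all(freqs[, 1] == 0))          # strictly absent early
  # realized AGE2/AGE3 frequencies consistent with 0.15 / 0.30
  expect_equal(mean(freqs[, 2]), 0.15, tolerance = 0.02)
  expect_equal(mean(freqs[, 3]), 0.30, tolerance = 0.02)
})

test_that("realized causal era frequencies track the configured values", {
  # binomial 99% CI coverage in at least 95% of seeded replicates
  inCI <- 0; total <- 0
  for (rep in 1:150) {
    cfg <- simConfig(nLines = 218, nSnps = 6, nCausalPerTrait = 3,
                     traits = "YPP", causalBaseFreq = 0.2,
                     eraFreqShift = 0.1, hetRate = 0, missingRate = 0,
                     seed = 3000 + rep)
    g <- simulateGenotypes(cfg)
    e <- factor(g$eras, eraLevels())
    d <- dosages(g$panel)
    z <- qnorm(0.995)
    for (snp in g$causal$YPP) {
      for (k in 1:3) {
        n <- sum(e == eraLevels()[k])
        if (n == 0) next
        fTarget <- 0.2 + (k - 1) * 0.1
        fHat <- mean(d[snp, e == eraLevels()[k]]) / 2
        half <- z * sqrt(fTarget * (1 - fTarget) / n)
        total <- total + 1
        if (abs(fHat - fTarget) <= half) inCI <- inCI + 1
      }
    }
  }
  expect_gte(inCI / total, 0.95)
})

test_that("plot residual variance is calibrated", {
  # residuals after removing all true effects should have variance ~ 1
  pooled <- numeric(0)
  for (rep in 1:100) {
    vc <- c(var_residual = 1)
    cfg <- simConfig(nLines = 8, nTesters = 2, nLocations = 2, nBlocks = 2,
                     nSnps = 20, traits = "YPP", seed = 500 + rep,
                     varianceComponents = c(vc))
    g <- simulateGenotypes(cfg)
    tr <- simulateTestcrossTrial(cfg, g)
    p <- tr$plots
    t1 <- tr$truth$perTrait$YPP
    li <- p$line_id; ti <- p$tester_id; lo <- p$location
    pred <- tr$truth$grandMean + t1$locEffects[lo] +
      t1$blockEffects[paste(lo, p$block)] + t1$lineGca[li] +
      t1$testerGca[ti] + t1$sca[cbind(li, ti)] + t1$lineLoc[cbind(li, lo)]
    pooled <- c(pooled, p$YPP - pred)
  }
  expect_equal(var(pooled), 1, tolerance = 0.1)
})

test_that("vanishing SCA variance drives estimated SCA to the noise floor", {
  vc <- c(var_sca = 0, var_residual = 1e-6, var_gca_line = 2,
          var_gca_tester = 1, var_loc = 1, var_block_within_loc = 1,
          var_line_x_loc = 0)
  cfg <- simConfig(nLines = 10, nSnps = 20, traits = "YPP", seed = 9,
                   varianceComponents = vc)
  tr <- simulateTestcrossTrial(cfg, simulateGenotypes(cfg))
  ca <- estimateCombiningAbility(tr$plots, "YPP")
  expect_lt(max(abs(sca(ca))), 1e-2)
})

test_that("era-mean GCA generator hits its configured means", {
  x <- simulateEraGca(nPerEra = 2000, eraMeans = c(2.51, 0.6, -1.28),
                      sd = 1, seed = 42)
  m <- tapply(x$gca, factor(x$eras, eraLevels()), mean)
  expect_equal(as.numeric(m), c(2.51, 0.6, -1.28), tolerance = 0.1)
  expect_identical(x, simulateEraGca(nPerEra = 2000,
                                     eraMeans = c(2.51, 0.6, -1.28),
                                     sd = 1, seed = 42))
})
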