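twoByTwo <- function() {
  data.frame(line_id = rep(c("L1", "L2"), each = 2),
             tester_id = rep(c("T1", "T2"), 2),
             location = "LOC1", block = "B1",
             YPP = c(1, 2, 3, 4))
}

test_that("totals accumulate hand-computed marginals", {
  tot <- crossTotals(twoByTwo(), "YPP")
  expect_equal(unname(tot$Tf), c(3, 7))
  expect_equal(unname(tot$Tm), c(4, 6))
  expect_equal(tot$grand, 10)
  expect_equal(rowSums(tot$Tij), tot$Tf)
  expect_equal(colSums(tot$Tij), tot$Tm)
  expect_error(crossTotals(twoByTwo(), "HKW"), "trait")
})

test_that("totals equal a brute-force pass over raw records", {
  tr <- smallTrial(seed = 31, nLines = 8)
  tot <- crossTotals(tr$plots, "YPP")
  brute <- 0 * tot$Tij
  for (i in seq_len(nrow(tr$plots))) {
    r <- tr$plots[i, ]
    brute[r$line_id, r$tester_id] <- brute[r$line_id, r$tester_id] + r$YPP
  }
  expect_equal(tot$Tij, brute, tolerance = 1e-12)
  expect_equal(sum(tot$Tf), tot$grand)
  expect_equal(sum(tot$Tm), tot$grand)
})

test_that("hand-computed 2x2 effects come out of the four formulas", {
  ca <- estimateCombiningAbility(twoByTwo(), "YPP")
  expect_equal(grandMean(ca), 2.5)
  expect_equal(unname(gcaLines(ca)), c(-1, 1))
  expect_equal(unname(gcaTesters(ca)), c(-0.5, 0.5))
  expect_true(all(sca(ca) == 0))
})

test_that("constant data yield null effects", {
  pl <- twoByTwo(); pl$YPP <- 10
  ca <- estimateCombiningAbility(pl, "YPP")
  expect_equal(grandMean(ca), 10)
  expect_true(all(gcaLines(ca) == 0) && all(gcaTesters(ca) == 0) &&
                all(sca(ca) == 0))
})

test_that("totals estimators match the cell-means oracle on random tables", {
  worst <- 0
  set.seed(77)
  for (rep in 1:200) {
    f <- sample(2:6, 1); m <- sample(1:3, 1)
    pl <- randomPlotTable(f, m, locs = sample(1:2, 1),
                          blocks = sample(1:3, 1), seed = rep)
    ca <- estimateCombiningAbility(pl, "Y")
    o <- oracleCombining(pl, "Y")
    scale <- max(1, abs(o$grandMean))
    worst <- max(worst,
                 abs(grandMean(ca) - o$grandMean) / scale,
                 max(abs(gcaLines(ca) - o$gcaLines)) / scale,
                 max(abs(gcaTesters(ca) - o$gcaTesters)) / scale,
                 max(abs(sca(ca) - o$sca)) / scale)
    # zero-sum and reconstruction identities
    expect_lt(abs(sum(gcaLines(ca))), 1e-10)
    expect_lt(abs(sum(gcaTesters(ca))), 1e-10)
    expect_lt(max(abs(rowSums(sca(ca)))), 1e-10)
    recon <- grandMean(ca) + outer(gcaLines(ca), gcaTesters(ca), `+`) +
      sca(ca)
    expect_equal(unname(recon), unname(o$sca * 0 + o$grandMean +
      outer(o$gcaLines, o$gcaTesters, `+`) + o$sca), tolerance = 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("effects are scale-equivariant", {
  pl <- randomPlotTable(5, 2, locs = 2, blocks = 2, seed = 3)
  ca1 <- estimateCombiningAbility(pl, "Y")
  pl$Y <- pl$Y * 7
  ca7 <- estimateCombiningAbility(pl, "Y")
  expect_equal(gcaLines(ca7), 7 * gcaLines(ca1), tolerance = 1e-10)
  expect_equal(sca(ca7), 7 * sca(ca1), tolerance = 1e-10)
  expect_equal(grandMean(ca7), 7 * grandMean(ca1), tolerance = 1e-10)
})

test_that("full default design yields a 218 x 2 SCA matrix", {
  cfg <- simConfig(nSnps = 30, nCausalPerTrait = 2, traits = "YPP", seed = 8)
  tr <- simulateTestcrossTrial(cfg, simulateGenotypes(cfg))
  ca <- estimateCombiningAbility(tr$plots, "YPP")
  expect_equal(dim(sca(ca)), c(218L, 2L))
  expect_equal(length(sca(ca)), 436L)
})

test_that("estimated line GCA recovers the simulated truth", {
  cfg <- simConfig(nSnps = 60, nCausalPerTrait = 5, traits = "YPP",
                   seed = 12)
  tr <- simulateTestcrossTrial(cfg, simulateGenotypes(cfg))
  ca <- estimateCombiningAbility(tr$plots, "YPP")
  truth <- tr$truth$perTrait$YPP$lineGca
  expect_gte(cor(gcaLines(ca)[names(truth)], truth), 0.9)
})

test_that("unbalanced replication errors strictly and falls back on request", {
  pl <- randomPlotTable(3, 2, blocks = 2, seed = 5)
  pl <- pl[-1, ]  # drop one plot
  expect_error(estimateCombiningAbility(pl, "Y"), "balance error")
  expect_warning(ca <- estimateCombiningAbility(pl, "Y",
                                                onUnbalanced = "means"),
                 "cross means")
  o <- oracleCombining(pl, "Y")
  expect_equal(gcaLines(ca), o$gcaLines, tolerance = 1e-10)
  one <- randomPlotTable(1, 2, seed = 6)
  expect_error(estimateCombiningAbility(one, "Y"), "f >= 2")
})

test_that("BLUP-value route reproduces the means decomposition", {
  pl <- randomPlotTable(6, 2, locs = 2, blocks = 2, seed = 9)
  means <- tapply(pl$Y, list(pl$line_id, pl$tester_id), mean)
  vals <- stats::setNames(as.vector(means),
                          as.vector(outer(rownames(means), colnames(means),
                                          paste, sep = ":")))
  ca <- combiningFromHybridValues(vals, "Y")
  o <- oracleCombining(pl, "Y")
  expect_equal(gcaLines(ca), o$gcaLines, tolerance = 1e-10)
  expect_equal(sca(ca), unclass(o$sca), tolerance = 1e-10)
})

test_that("GCA ranking is ordered with lexicographic tie-breaks", {
  ca <- new("CombiningAbility", trait = "Y", scope = "pooled",
            grandMean = 0,
            gcaLines = c(La = 3, Lb = 1, Lc = 2) - 2,
            gcaTesters = c(T1 = 0),
            sca = matrix(0, 3, 1, dimnames = list(c("La", "Lb", "Lc"), "T1")),
            nReps = 1)
  expect_identical(rankByGca(ca, 2, "high"), c("La", "Lc"))
  expect_identical(rankByGca(ca, 2, "low"), c("Lb", "Lc"))
  tie <- new("CombiningAbility", trait = "Y", scope = "pooled",
             grandMean = 0, gcaLines = c(Lz = 0, La = 0, Lm = 0),
             gcaTesters = c(T1 = 0),
             sca = matrix(0, 3, 1,
                          dimnames = list(c("Lz", "La", "Lm"), "T1")),
             nReps = 1)
  expect_identical(rankByGca(tie, 3), c("La", "Lm", "Lz"))
  expect_error(rankByGca(tie, 5), "topK")
  # random vectors agree with a brute-force sort
  set.seed(10)
  for (i in 1:20) {
    g <- rnorm(8); names(g) <- sprintf("L%02d", sample(8))
    g <- g - mean(g)
    ca <- new("CombiningAbility", trait = "Y", scope = "pooled",
              grandMean = 0, gcaLines = g, gcaTesters = c(T1 = 0),
              sca = matrix(0, 8, 1, dimnames = list(names(g), "T1")),
              nReps = 1)
    expect_identical(rankByGca(ca, 8), names(g)[order(-g, names(g))])
  }
})

test_that("tidy serialization covers every effect", {
  ca <- estimateCombiningAbility(twoByTwo(), "YPP")
  df <- combiningAbilityTable(ca)
  expect_equal(nrow(df), 1 + 2 + 2 + 4)
  expect_setequal(unique(df$effect_type),
                  c("grand_mean", "gca_line", "gca_tester", "sca"))
})
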