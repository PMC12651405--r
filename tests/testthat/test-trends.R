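test_that("identical era distributions yield all-ns comparisons", {
  vals <- rep(c(1, 2, 3, 4), 3)
  gca <- stats::setNames(vals, sprintf("L%02d", 1:12))
  eras <- stats::setNames(rep(eraLevels(), each = 4), names(gca))
  rep1 <- gcaTrend(gca, eras, "TBN")
  expect_true(all(rep1$comparisons$label == "ns"))
  expect_equal(rep1$summary$n, rep(4L, 3))
  expect_equal(rep1$summary$mean, rep(2.5, 3))
})

test_that("a configured era decline is detected with Welch or Wilcoxon", {
  x <- simulateEraGca(nPerEra = 73, eraMeans = c(2.51, 0.6, -1.28), sd = 1,
                      seed = 5)
  for (tst in c("welch", "wilcoxon")) {
    rep1 <- gcaTrend(x$gca, x$eras, "TBN", test = tst)
    i13 <- which(rep1$comparisons$era_a == "AGE1" &
                   rep1$comparisons$era_b == "AGE3")
    expect_lt(rep1$comparisons$p[i13], 0.01)
    expect_equal(rep1$comparisons$label[i13], "**")
  }
  # an era with < 2 lines is marked not computable
  few <- gcaTrend(x$gca[c(1, 74:80, 150:156)], x$eras[c(1, 74:80, 150:156)],
                  "TBN")
  expect_true(any(is.na(few$comparisons$p)))
  expect_true(any(few$comparisons$label == "na"))
})

test_that("label shuffling destroys significance at the nominal rate", {
  x <- simulateEraGca(nPerEra = 50, eraMeans = c(2, 0, -2), sd = 1, seed = 9)
  set.seed(11)
  sig <- 0; n <- 200
  for (i in seq_len(n)) {
    shuffled <- stats::setNames(sample(x$eras), names(x$eras))
    rep1 <- gcaTrend(x$gca, shuffled, "T")
    i13 <- which(rep1$comparisons$era_a == "AGE1" &
                   rep1$comparisons$era_b == "AGE3")
    if (rep1$comparisons$p[i13] < 0.05) sig <- sig + 1
  }
  expect_gt(sig / n, 0.01)
  expect_lt(sig / n, 0.12)
})

test_that("type-I error of the era comparison is near nominal", {
  sig <- 0; n <- 1000
  for (i in seq_len(n)) {
    x <- simulateEraGca(nPerEra = 30, eraMeans = c(0, 0, 0), sd = 1,
                        seed = 9000 + i)
    rep1 <- gcaTrend(x$gca, x$eras, "T")
    i13 <- which(rep1$comparisons$era_a == "AGE1" &
                   rep1$comparisons$era_b == "AGE3")
    if (rep1$comparisons$p[i13] < 0.05) sig <- sig + 1
  }
  expect_gte(sig / n, 0.03)
  expect_lte(sig / n, 0.07)
})

test_that("trait correlations match the direct formula and are PSD", {
  set.seed(21)
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  out <- gcaCorrelationMatrix(m)
  expect_equal(diag(out$r), c(A = 1, B = 1, C = 1))
  expect_equal(out$r, t(out$r))
  # direct covariance-formula oracle
  oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(out$r["A", "B"], oracle(m[, 1], m[, 2]), tolerance = 1e-12)
  expect_gte(min(eigen(out$r, symmetric = TRUE)$values), -1e-10)
  # duplicated and anti-correlated columns
  m2 <- cbind(x = m[, 1], same = m[, 1], neg = -m[, 1])
  out2 <- gcaCorrelationMatrix(m2)
  expect_equal(out2$r["x", "same"], 1)
  expect_equal(out2$r["x", "neg"], -1)
})

trajPanel <- function(classByEra, nPerEra = 40, seed = 3, het = 0) {
  # classByEra: per-era frequency of the alt homozygote
  set.seed(seed)
  era <- rep(eraLevels(), each = nPerEra)
  n <- length(era)
  dose <- unlist(lapply(1:3, function(k)
    2L * (runif(nPerEra) < classByEra[k])))
  if (het > 0) dose[sample(n, het)] <- 1L
  ids <- sprintf("L%03d", seq_len(n))
  d <- matrix(dose, nrow = 1, dimnames = list("S1_100", ids))
  list(panel = GenotypePanel(d, chrom = "1", pos = 100, ref = "C",
                             alt = "T", era = stats::setNames(era, ids)),
       eras = stats::setNames(era, ids), ids = ids)
}

test_that("trajectory frequencies match a brute-force count", {
  tp <- trajPanel(c(0.3, 0.5, 0.8), seed = 7, het = 5)
  gca <- stats::setNames(rnorm(length(tp$ids)), tp$ids)
  tr <- alleleTrajectory(tp$panel, tp$eras, "S1_100", gca)
  d <- dosages(tp$panel)[1, ]
  for (era in eraLevels()) {
    keep <- tp$eras == era & !is.na(d) & d != 1
    fTT <- sum(d[keep] == 2) / sum(keep)
    got <- tr$classes[tr$classes$era == era & tr$classes$class == "T/T", ]
    expect_equal(got$frequency, fTT, tolerance = 1e-12)
    expect_equal(got$n, sum(d[keep] == 2))
    # frequencies over the two homozygote classes sum to 1
    expect_equal(sum(tr$classes$frequency[tr$classes$era == era]), 1)
  }
  expect_equal(unname(tr$excluded[["het"]]), 5)
})

test_that("an allele seeded absent early is reported absent then present", {
  tp <- trajPanel(c(0, 0.2, 0.25), nPerEra = 60, seed = 8)
  gca <- stats::setNames(rnorm(length(tp$ids)), tp$ids)
  tr <- alleleTrajectory(tp$panel, tp$eras, "S1_100", gca)
  tt <- tr$classes[tr$classes$class == "T/T", ]
  expect_true(tt$absent[tt$era == "AGE1"])
  expect_equal(tt$frequency[tt$era == "AGE1"], 0)
  expect_gt(tt$frequency[tt$era == "AGE2"], 0)
  expect_gt(tt$frequency[tt$era == "AGE3"], 0)
})

test_that("single-class and all-het degenerate inputs are handled", {
  tp <- trajPanel(c(1, 1, 1), nPerEra = 10, seed = 9)
  gca <- stats::setNames(rnorm(length(tp$ids)), tp$ids)
  tr <- alleleTrajectory(tp$panel, tp$eras, "S1_100", gca)
  tt <- tr$classes[tr$classes$class == "T/T", ]
  expect_equal(tt$frequency, rep(1, 3))
  # all calls heterozygous in one era -> marked not computable
  d <- dosages(tp$panel)
  d[1, tp$eras == "AGE1"] <- 1L
  p2 <- GenotypePanel(d, chrom = "1", pos = 100, ref = "C", alt = "T",
                      era = tp$eras)
  tr2 <- alleleTrajectory(p2, tp$eras, "S1_100", gca)
  expect_false(tr2$eraComputable[["AGE1"]])
  expect_error(alleleTrajectory(tp$panel, tp$eras, "S9_9", gca), "SNP")
})

test_that("elite-allele labeling follows GCA advantage and favorability", {
  tp <- trajPanel(c(0.2, 0.4, 0.6), nPerEra = 50, seed = 12)
  d <- dosages(tp$panel)[1, ]
  gca <- stats::setNames(ifelse(d == 2, 1, 0) + rnorm(length(d), 0, 0.1),
                         tp$ids)
  tr <- alleleTrajectory(tp$panel, tp$eras, "S1_100", gca)
  repHigh <- eliteAlleleReport(tr, "high")
  expect_identical(repHigh$favorable_class, "T/T")
  expect_gt(repHigh$freq_change, 0)
  repLow <- eliteAlleleReport(tr, "low")
  expect_identical(repLow$favorable_class, "C/C")
  # exact tie -> flagged, unlabeled
  trTie <- tr
  trTie$classes$gca_mean <- 1
  tie <- eliteAlleleReport(trTie)
  expect_true(tie$tie)
  expect_true(is.na(tie$favorable_class))
})

test_that("a simulated causal effect determines the favorable class", {
  hits <- 0; n <- 60
  for (i in seq_len(n)) {
    tp <- trajPanel(c(0.3, 0.4, 0.5), nPerEra = 60, seed = 100 + i)
    d <- dosages(tp$panel)[1, ]
    beta <- ifelse(i %% 2 == 0, 0.8, -0.8)
    set.seed(200 + i)
    gca <- stats::setNames(beta * d + rnorm(length(d), 0, 1), tp$ids)
    tr <- alleleTrajectory(tp$panel, tp$eras, "S1_100", gca)
    fav <- eliteAlleleReport(tr, "high")$favorable_class
    if (identical(fav, if (beta > 0) "T/T" else "C/C")) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})
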