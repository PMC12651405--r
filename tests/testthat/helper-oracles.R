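# Independent oracles used across the suite. These never call the code paths
# they check: combining ability is recomputed from cell means, ANOVA sums of
# squares from stats::aov / explicit projections.

# cell-means combining-ability oracle: line GCA = mean over the line's
# crosses minus grand mean, etc.
oracleCombining <- function(plots, trait) {
  mns <- tapply(plots[[trait]], list(plots$line_id, plots$tester_id), mean)
  mns <- mns[sort(rownames(mns)), sort(colnames(mns)), drop = FALSE]
  mu <- mean(mns)
  gF <- rowMeans(mns) - mu
  gM <- colMeans(mns) - mu
  scaM <- sweep(sweep(mns, 1, rowMeans(mns)), 2, colMeans(mns)) + mu
  list(grandMean = mu, gcaLines = gF, gcaTesters = gM, sca = scaM)
}

# sequential-aov oracle for the joint combining layout (balanced => equals
# the marginal-totals decomposition)
oracleJointAov <- function(plots, trait) {
  d <- data.frame(y = plots[[trait]], Loc = factor(plots$location),
                  Blo = factor(plots$block), Line = factor(plots$line_id),
                  Tester = factor(plots$tester_id))
  a <- stats::anova(stats::lm(
    y ~ Loc + Blo + Line + Line:Loc + Tester + Tester:Loc +
      Line:Tester + Line:Tester:Loc, data = d))
  ss <- stats::setNames(a[["Sum Sq"]], rownames(a))
  c(Loc = ss[["Loc"]], Blo = ss[["Blo"]], Line = ss[["Line"]],
    `Line x Loc` = ss[["Loc:Line"]], Tester = ss[["Tester"]],
    `Tester x Loc` = ss[["Loc:Tester"]],
    `Line x Tester` = ss[["Line:Tester"]],
    `Line x Tester x Loc` = ss[["Loc:Line:Tester"]],
    Error = ss[["Residuals"]])
}

# sequential-aov oracle for the per-tester layout
oraclePerTesterAov <- function(plots, testerId, trait) {
  pl <- plots[plots$tester_id == testerId, ]
  d <- data.frame(y = pl[[trait]], Blo = factor(pl$block),
                  Loc = factor(pl$location), Cro = factor(pl$line_id))
  a <- suppressWarnings(stats::anova(stats::lm(y ~ Blo * Loc * Cro,
                                               data = d)))
  ss <- stats::setNames(a[["Sum Sq"]], rownames(a))
  c(Blo = ss[["Blo"]], Loc = ss[["Loc"]], Cro = ss[["Cro"]],
    `Blo x Loc` = ss[["Blo:Loc"]], `Blo x Cro` = ss[["Blo:Cro"]],
    `Loc x Cro` = ss[["Loc:Cro"]], `Blo x Loc x Cro` = ss[["Blo:Loc:Cro"]])
}

# random balanced plot table for property tests
randomPlotTable <- function(f, m, locs = 1, blocks = 1, seed = 1,
                            mu = 10, sd = 2) {
  set.seed(seed)
  grid <- expand.grid(line_id = sprintf("L%02d", seq_len(f)),
                      tester_id = sprintf("T%02d", seq_len(m)),
                      location = sprintf("LOC%d", seq_len(locs)),
                      block = sprintf("B%d", seq_len(blocks)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$Y <- rnorm(nrow(grid), mu, sd)
  grid
}

# small trial simulation wrapper used by several files
smallTrial <- function(seed = 1, nLines = 12, traits = "YPP", ...) {
  cfg <- simConfig(nLines = nLines, nSnps = 40, traits = traits,
                   seed = seed, ...)
  g <- simulateGenotypes(cfg)
  c(list(config = cfg, genotypes = g), simulateTestcrossTrial(cfg, g))
}

# brute-force per-variant statistics on a dosage matrix
oracleVariantStats <- function(d) {
  t(apply(d, 1, function(g) {
    ok <- !is.na(g)
    af <- sum(g[ok]) / (2 * sum(ok))
    maf <- min(af, 1 - af)
    minor <- if (af <= 0.5) sum(g[ok] >= 1) else sum(g[ok] <= 1)
    c(maf = maf, missing_rate = mean(!ok),
      het_rate = sum(g[ok] == 1) / sum(ok),
      minor_allele_individuals = minor)
  }))
}
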