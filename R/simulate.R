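#' Construct a GenotypePanel from a dosage matrix
#'
#' @param dosage variants x lines matrix of alternate-allele counts (0/1/2,
#'   `NA` missing). Rownames are SNP ids (default `S<chrom>_<pos>`), colnames
#'   line ids.
#' @param chrom,pos,ref,alt per-variant metadata; `alt` may contain commas
#'   for multi-allelic records, which are flagged non-biallelic.
#' @param era optional named (or positionally matched) era assignment of the
#'   lines.
#' @return A [GenotypePanel-class].
#' @export
GenotypePanel <- function(dosage, chrom, pos, ref, alt, era = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have line ids as colnames")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", chrom, "_", pos)
  rd <- S4Vectors::DataFrame(chrom = as.character(chrom),
                             pos = as.integer(pos),
                             ref = as.character(ref),
                             alt = as.character(alt),
                             biallelic = !grepl(",", alt, fixed = TRUE))
  cd <- S4Vectors::DataFrame(row.names = colnames(dosage))
  if (!is.null(era)) {
    if (!is.null(names(era))) era <- era[colnames(dosage)]
    cd$era <- factor(as.character(era), levels = ERA_LEVELS)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("GenotypePanel", se)
}

# per-era minor-allele frequency of a causal SNP: the AGE1 base frequency is
# used as given (an allele may be genuinely absent early on); shifted
# frequencies are clamped into [0.01, 0.99]
eraFrequencies <- function(base, shift) {
  f <- base + (0:2) * shift
  f[1] <- min(max(f[1], 0), 0.99)
  f[2:3] <- pmin(pmax(f[2:3], 0.01), 0.99)
  f
}

#' Simulate an era-structured inbred genotype panel
#'
#' Draws a biallelic SNP panel for `nLines` inbred lines assigned to three
#' breeding eras. Lines are homozygous by default (dosage 0 or 2 from a
#' per-SNP alternate-allele frequency); heterozygous calls are then injected
#' uniformly at rate `hetRate` and calls are masked missing at rate
#' `missingRate`. Non-causal SNP frequencies are constant across eras;
#' causal SNPs (those underlying any trait) have era-`k` frequency
#' `base + k * eraFreqShift` (k = 0, 1, 2), emulating the gradual
#' appearance of favourable alleles over the breeding stages.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `panel` (a [GenotypePanel-class] whose
#'   `colData` carries the era factor), `eras` (named character vector),
#'   and `causal` (list per trait of causal SNP ids). Fully reproducible
#'   from `config@seed`.
#' @export
#' @examples
#' g <- simulateGenotypes(simConfig(nLines = 12, nSnps = 30, seed = 3))
#' g$panel
simulateGenotypes <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nLines
  p <- config@nSnps
  lines <- sprintf("L%03d", seq_len(n))
  era <- sample(ERA_LEVELS, n, replace = TRUE, prob = config@eraProportions)
  names(era) <- lines
  eraIdx <- match(era, ERA_LEVELS)

  nCausalTotal <- config@nCausalPerTrait * length(config@traits)
  if (nCausalTotal > p)
    stop("configuration error: 'nSnps' smaller than nCausalPerTrait * traits")
  causalIdx <- sample.int(p, nCausalTotal)
  causal <- split(causalIdx,
                  rep(config@traits, each = config@nCausalPerTrait))
  isCausal <- seq_len(p) %in% causalIdx

  baseFreq <- runif(p, 0.05, 0.5)
  if (!is.na(config@causalBaseFreq)) {
    baseFreq[isCausal] <- config@causalBaseFreq
  } else {
    baseFreq[isCausal] <- runif(sum(isCausal), 0.1, 0.4)
  }

  dosage <- matrix(0L, nrow = p, ncol = n)
  for (s in seq_len(p)) {
    f <- if (isCausal[s]) eraFrequencies(baseFreq[s], config@eraFreqShift)
         else rep(baseFreq[s], 3)
    dosage[s, ] <- 2L * (runif(n) < f[eraIdx])
  }
  if (config@hetRate > 0) {
    hetMask <- matrix(runif(p * n) < config@hetRate, p, n)
    dosage[hetMask] <- 1L
  }
  complete <- dosage
  if (config@missingRate > 0) {
    misMask <- matrix(runif(p * n) < config@missingRate, p, n)
    dosage[misMask] <- NA_integer_
  }
  chrom <- as.character(1 + (seq_len(p) - 1) %% 10)
  pos <- 1000L * seq_len(p)
  colnames(dosage) <- lines
  rownames(dosage) <- paste0("S", chrom, "_", pos)
  dimnames(complete) <- dimnames(dosage)
  panel <- GenotypePanel(dosage, chrom, pos,
                         ref = rep("A", p), alt = rep("T", p), era = era)
  S4Vectors::metadata(panel)$causal <- lapply(causal, function(i) rownames(dosage)[i])
  # truth downstream is built from the pre-masking calls, not the observed ones
  S4Vectors::metadata(panel)$completeDosage <- complete
  list(panel = panel,
       eras = era,
       causal = S4Vectors::metadata(panel)$causal)
}

# double-center a matrix so rows and columns sum to zero exactly
doubleCenter <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  sweep(m, 2, colMeans(m))
}

#' Simulate plot-level testcross phenotypes
#'
#' Generates one plot record per line x tester x location x block under the
#' model `y = grand mean + loc + block(loc) + line GCA + tester GCA + SCA +
#' line:loc + residual`. The true line GCA of each trait is the centered sum
#' of causal dosages times drawn effects, topped up with an independent
#' polygenic deviate (or rescaled) so that its variance matches
#' `var_gca_line`; tester GCA, SCA, location, block and line-by-location
#' effects are drawn from their configured variances and centered so the
#' ground truth satisfies exact zero-sum constraints.
#'
#' @param config the [SimConfig-class] used for [simulateGenotypes()].
#' @param genotypes the list returned by [simulateGenotypes()] (or a
#'   [GenotypePanel-class] with matching dimensions).
#' @return A list with `plots` (data.frame: `line_id`, `tester_id`,
#'   `location`, `block`, one column per trait) and `truth` (per-trait list
#'   of `lineGca`, `testerGca`, `sca`, `lineLoc`, `locEffects`,
#'   `blockEffects`, `causalSnps`, `causalEffects`, plus `grandMean`).
#' @export
simulateTestcrossTrial <- function(config, genotypes) {
  validObject(config)
  panel <- if (is.list(genotypes)) genotypes$panel else genotypes
  if (!is(panel, "GenotypePanel"))
    stop("input error: 'genotypes' must come from simulateGenotypes()")
  if (ncol(panel) != config@nLines)
    stop("input error: genotype panel has ", ncol(panel),
         " lines but config expects ", config@nLines)
  causal <- S4Vectors::metadata(panel)$causal
  set.seed(config@seed + 1L)

  f <- config@nLines; m <- config@nTesters
  L <- config@nLocations; B <- config@nBlocks
  lines <- colnames(panel)
  testers <- sprintf("T%02d", seq_len(m))
  locs <- sprintf("LOC%d", seq_len(L))
  vc <- config@varianceComponents
  dose <- S4Vectors::metadata(panel)$completeDosage
  if (is.null(dose)) {
    dose <- dosages(panel)
    dose[is.na(dose)] <- 1L  # user-supplied panel: expected dose for missing
  }

  grid <- expand.grid(block = sprintf("B%d", seq_len(B)), location = locs,
                      tester_id = testers, line_id = lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("line_id", "tester_id", "location", "block")]
  li <- match(grid$line_id, lines)
  ti <- match(grid$tester_id, testers)
  oi <- match(grid$location, locs)
  bi <- match(paste(grid$location, grid$block),
              as.vector(outer(locs, sprintf("B%d", seq_len(B)), paste)))

  centered <- function(x) x - mean(x)
  truth <- list(grandMean = config@grandMean, perTrait = list())
  for (tr in config@traits) {
    ids <- causal[[tr]]
    eff <- rnorm(length(ids), 0, config@markerEffectScale)
    markerG <- if (length(ids))
      centered(as.numeric(crossprod(dose[ids, , drop = FALSE], eff)))
    else rep(0, f)
    vM <- if (f > 1) sum(markerG^2) / (f - 1) else 0
    vTarget <- vc[["var_gca_line"]]
    if (vM > vTarget && vM > 0) {
      lineGca <- markerG * sqrt(vTarget / vM)
    } else {
      lineGca <- markerG + rnorm(f, 0, sqrt(max(vTarget - vM, 0)))
    }
    lineGca <- centered(lineGca)
    testerGca <- centered(rnorm(m, 0, sqrt(vc[["var_gca_tester"]])))
    if (m == 1) testerGca <- 0
    scaMat <- doubleCenter(matrix(rnorm(f * m, 0, sqrt(vc[["var_sca"]])), f, m))
    locEff <- centered(rnorm(L, 0, sqrt(vc[["var_loc"]])))
    blkEff <- centered(rnorm(L * B, 0, sqrt(vc[["var_block_within_loc"]])))
    lineLoc <- matrix(rnorm(f * L, 0, sqrt(vc[["var_line_x_loc"]])), f, L)
    lineLoc <- sweep(lineLoc, 2, colMeans(lineLoc))
    resid <- rnorm(nrow(grid), 0, sqrt(vc[["var_residual"]]))
    y <- config@grandMean + locEff[oi] + blkEff[bi] + lineGca[li] +
      testerGca[ti] + scaMat[cbind(li, ti)] + lineLoc[cbind(li, oi)] + resid
    grid[[tr]] <- y
    dimnames(scaMat) <- list(lines, testers)
    dimnames(lineLoc) <- list(lines, locs)
    truth$perTrait[[tr]] <- list(
      lineGca = stats::setNames(lineGca, lines),
      testerGca = stats::setNames(testerGca, testers),
      sca = scaMat, lineLoc = lineLoc,
      locEffects = stats::setNames(locEff, locs),
      blockEffects = stats::setNames(
        blkEff, as.vector(outer(locs, sprintf("B%d", seq_len(B)), paste))),
      causalSnps = ids, causalEffects = stats::setNames(eff, ids))
  }
  list(plots = grid, truth = truth)
}

#' Simulate per-line GCA values with configured era means
#'
#' Direct generator for era-trend studies: draws independent normal GCA
#' values for three breeding-era groups with specified means and a common
#' standard deviation. This isolates the trend-testing machinery from the
#' genotype-driven simulator, whose era trends arise indirectly through
#' causal allele-frequency shifts.
#'
#' @param nPerEra integer vector (length 3 or 1) of lines per era.
#' @param eraMeans length-3 means of GCA in AGE1/AGE2/AGE3.
#' @param sd common within-era standard deviation.
#' @param seed integer seed.
#' @return list with `gca` (named numeric) and `eras` (named character).
#' @export
#' @examples
#' x <- simulateEraGca(eraMeans = c(2.51, 0.6, -1.28), nPerEra = 73, seed = 1)
#' tapply(x$gca, x$eras, mean)
simulateEraGca <- function(nPerEra = 73, eraMeans = c(0, 0, 0), sd = 1,
                           seed = 1L) {
  stopifnot(length(eraMeans) == 3, sd >= 0)
  nPerEra <- rep(as.integer(nPerEra), length.out = 3)
  set.seed(as.integer(seed))
  era <- rep(ERA_LEVELS, nPerEra)
  gca <- rnorm(sum(nPerEra), mean = rep(eraMeans, nPerEra), sd = sd)
  ids <- sprintf("L%03d", seq_along(gca))
  list(gca = stats::setNames(gca, ids), eras = stats::setNames(era, ids))
}
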