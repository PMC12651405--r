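#' @import methods
#' @importFrom stats var sd rnorm rbinom runif aov pf pt pchisq t.test
#'   wilcox.test cor cor.test p.adjust prcomp lm complete.cases setNames
#'   quantile qnorm
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

utils::globalVariables(".data")  # tidy-eval pronoun used in plot helpers

# names of the 16 yield-related traits scored on the testcross plots
TRAIT_NAMES <- c("PH", "EH", "SDR", "SL", "TBN", "TL", "EL", "ED",
                 "SD", "KRN", "KNPR", "HKW", "KL", "KW", "GT", "YPP")

#' Trait names used by the testcross pipeline
#'
#' Returns the ordered names of the 16 yield-related traits collected in the
#' emulated trial: plant height (PH), ear height (EH), stem diameter (SDR),
#' stem length (SL), tassel branch number (TBN), tassel main axis length (TL),
#' ear length (EL), ear diameter (ED), shaft diameter (SD), kernel row number
#' (KRN), kernel number per row (KNPR), hundred kernel weight (HKW), kernel
#' length (KL), kernel width (KW), grain thickness (GT) and yield per plant
#' (YPP).
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' traitNames()
traitNames <- function() TRAIT_NAMES

#' Configuration of the synthetic testcross trial
#'
#' An S4 class holding every knob of the synthetic-data generator: design
#' sizes (lines, testers, locations, blocks), breeding-era composition, SNP
#' panel size and causal architecture, the era-wise causal allele-frequency
#' shift, variance components of the plot model, and observational noise
#' (heterozygous and missing call rates). Construct with [simConfig()].
#'
#' @slot nLines number of tested inbred lines (f).
#' @slot nTesters number of testers (m).
#' @slot nLocations number of trial locations.
#' @slot nBlocks blocks (replicates) per location.
#' @slot eraProportions length-3 proportions of lines in AGE1/AGE2/AGE3.
#' @slot nSnps number of simulated biallelic SNPs.
#' @slot nCausalPerTrait causal SNPs underlying each trait's line GCA.
#' @slot eraFreqShift signed causal minor-allele frequency increment per era
#'   step (AGE1 -> AGE2 -> AGE3).
#' @slot causalBaseFreq AGE1 causal minor-allele frequency; `NA` draws one
#'   uniformly in \[0.1, 0.4\] per causal SNP.
#' @slot varianceComponents named numeric vector with elements
#'   `var_gca_line`, `var_gca_tester`, `var_sca`, `var_loc`,
#'   `var_block_within_loc`, `var_line_x_loc`, `var_residual` (trait units^2).
#' @slot markerEffectScale standard deviation of per-causal-allele effects.
#' @slot missingRate fraction of genotype calls masked as missing, in \[0, 0.2).
#' @slot hetRate fraction of genotype calls set heterozygous, in \[0, 0.1).
#' @slot grandMean trial grand mean added to every plot value.
#' @slot traits character vector of trait names to simulate.
#' @slot seed integer seed making every draw reproducible.
#' @export
setClass("SimConfig",
  representation(
    nLines = "numeric", nTesters = "numeric", nLocations = "numeric",
    nBlocks = "numeric", eraProportions = "numeric", nSnps = "numeric",
    nCausalPerTrait = "numeric", eraFreqShift = "numeric",
    causalBaseFreq = "numeric", varianceComponents = "numeric",
    markerEffectScale = "numeric", missingRate = "numeric",
    hetRate = "numeric", grandMean = "numeric", traits = "character",
    seed = "integer"
  )
)

VARCOMP_NAMES <- c("var_gca_line", "var_gca_tester", "var_sca", "var_loc",
                   "var_block_within_loc", "var_line_x_loc", "var_residual")

setValidity("SimConfig", function(object) {
  msgs <- character()
  chkCount <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x))
      msgs <<- c(msgs, sprintf("'%s' must be a single integer >= 1", nm))
  }
  chkCount(object@nLines, "nLines")
  chkCount(object@nTesters, "nTesters")
  chkCount(object@nLocations, "nLocations")
  chkCount(object@nBlocks, "nBlocks")
  chkCount(object@nSnps, "nSnps")
  chkCount(object@nCausalPerTrait, "nCausalPerTrait")
  if (length(object@eraProportions) != 3 || any(object@eraProportions < 0) ||
      abs(sum(object@eraProportions) - 1) > 1e-12)
    msgs <- c(msgs, "'eraProportions' must be 3 non-negative values summing to 1")
  if (!identical(sort(names(object@varianceComponents)), sort(VARCOMP_NAMES)) ||
      any(!is.finite(object@varianceComponents)) ||
      any(object@varianceComponents < 0))
    msgs <- c(msgs, sprintf(
      "'varianceComponents' must be non-negative and named %s",
      paste(VARCOMP_NAMES, collapse = ", ")))
  if (length(object@missingRate) != 1 || object@missingRate < 0 ||
      object@missingRate >= 0.2)
    msgs <- c(msgs, "'missingRate' must lie in [0, 0.2)")
  if (length(object@hetRate) != 1 || object@hetRate < 0 || object@hetRate >= 0.1)
    msgs <- c(msgs, "'hetRate' must lie in [0, 0.1)")
  if (length(object@eraFreqShift) != 1 || !is.finite(object@eraFreqShift) ||
      abs(object@eraFreqShift) > 0.5)
    msgs <- c(msgs, "'eraFreqShift' must be a single value in [-0.5, 0.5]")
  if (length(object@causalBaseFreq) != 1 ||
      (!is.na(object@causalBaseFreq) &&
       (object@causalBaseFreq < 0 || object@causalBaseFreq > 0.99)))
    msgs <- c(msgs, "'causalBaseFreq' must be NA or in [0, 0.99]")
  if (length(object@markerEffectScale) != 1 || object@markerEffectScale < 0)
    msgs <- c(msgs, "'markerEffectScale' must be a single value >= 0")
  if (length(object@traits) < 1 || anyDuplicated(object@traits))
    msgs <- c(msgs, "'traits' must be a non-empty set of unique names")
  if (length(object@seed) != 1 || is.na(object@seed))
    msgs <- c(msgs, "'seed' must be a single integer")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Genotype panel of inbred lines
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for a
#' biallelic SNP panel: the `"dosage"` assay holds per-variant, per-line
#' counts of the alternate allele (0/1/2, `NA` for missing), `rowData`
#' carries `chrom`, `pos`, `ref`, `alt` and a `biallelic` flag, and `colData`
#' optionally carries the breeding-era assignment (`era`). Rows are variants,
#' columns are inbred lines, following Bioconductor convention.
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d[!is.na(d)] %in% 0:2))
      msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  }
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("rowData lacks:", paste(miss, collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "line ids (colnames) must be present and unique")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Combining-ability estimates for one trait
#'
#' Holds the Griffing-style decomposition of testcross means for a single
#' trait: the grand mean, per-line and per-tester general combining ability
#' (GCA, deviations from the grand mean), and the line x tester specific
#' combining ability (SCA) matrix. Effects satisfy the usual constraints:
#' line GCAs and tester GCAs each sum to zero, and every row and column of
#' the SCA matrix sums to zero, so that for complete balanced data
#' `cross mean(i, j) = grandMean + gcaLines[i] + gcaTesters[j] + sca[i, j]`.
#'
#' @slot trait trait name.
#' @slot scope `"pooled"`, `"per-location:<loc>"` or `"blup"`.
#' @slot grandMean grand mean in trait units.
#' @slot gcaLines named per-line GCA effects.
#' @slot gcaTesters named per-tester GCA effects.
#' @slot sca lines x testers SCA matrix.
#' @slot nReps number of plot observations behind each cross total.
#' @export
setClass("CombiningAbility",
  representation(trait = "character", scope = "character",
                 grandMean = "numeric", gcaLines = "numeric",
                 gcaTesters = "numeric", sca = "matrix", nReps = "numeric")
)

setValidity("CombiningAbility", function(object) {
  msgs <- character()
  tol <- 1e-9 * max(1, abs(object@grandMean),
                    max(abs(object@gcaLines), 0), max(abs(object@gcaTesters), 0))
  if (abs(sum(object@gcaLines)) > tol * length(object@gcaLines))
    msgs <- c(msgs, "line GCA effects must sum to zero")
  if (abs(sum(object@gcaTesters)) > tol * length(object@gcaTesters))
    msgs <- c(msgs, "tester GCA effects must sum to zero")
  if (nrow(object@sca) != length(object@gcaLines) ||
      ncol(object@sca) != length(object@gcaTesters))
    msgs <- c(msgs, "sca matrix must be lines x testers")
  else {
    stol <- tol * max(dim(object@sca))
    if (max(abs(rowSums(object@sca))) > stol ||
        max(abs(colSums(object@sca))) > stol)
      msgs <- c(msgs, "sca rows and columns must sum to zero")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Multi-environment BLUP fit for one trait
#'
#' Result of fitting the hybrid plot model
#' `y = mu + Env + Line + Line:Env + Env:Rep + error` by REML, where `Line`
#' indexes hybrid combinations (tested line x tester), `Env` the locations
#' (fixed), and `Line`, `Line:Env` and `Env:Rep` are random. `blupValues`
#' are `mu + Line` predictions, the shrunken hybrid values used downstream
#' as phenotypes for pooled combining ability and GWAS.
#'
#' @slot trait trait name.
#' @slot grandMean fixed-effect grand mean mu.
#' @slot lineEffects named hybrid (line x tester) BLUPs.
#' @slot envEffects named fixed location effects (sum-to-zero coding).
#' @slot interactionEffects named hybrid-by-location BLUPs.
#' @slot repWithinEnv named location:block BLUPs.
#' @slot varianceComponents named REML estimates
#'   (`var_line`, `var_line_env`, `var_env_rep`, `var_error`).
#' @slot blupValues named per-hybrid values `mu + lineEffects`.
#' @export
setClass("BlupFit",
  representation(trait = "character", grandMean = "numeric",
                 lineEffects = "numeric", envEffects = "numeric",
                 interactionEffects = "numeric", repWithinEnv = "numeric",
                 varianceComponents = "numeric", blupValues = "numeric")
)

setValidity("BlupFit", function(object) {
  msgs <- character()
  need <- c("var_line", "var_line_env", "var_env_rep", "var_error")
  if (!all(need %in% names(object@varianceComponents)))
    msgs <- c(msgs, "varianceComponents must include var_line, var_line_env, var_env_rep, var_error")
  else if (any(object@varianceComponents[need] < 0))
    msgs <- c(msgs, "variance components must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nLines, "lines x", object@nTesters, "testers,",
      object@nLocations, "locations x", object@nBlocks, "blocks\n")
  cat("  SNPs:", object@nSnps, "(", object@nCausalPerTrait,
      "causal/trait, era shift", object@eraFreqShift, ")\n")
  cat("  traits:", paste(object@traits, collapse = " "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object), "variants x", ncol(object), "lines\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missing calls: %.3f  heterozygous: %.3f\n",
              mean(is.na(d)), mean(d == 1, na.rm = TRUE)))
  if ("era" %in% colnames(SummarizedExperiment::colData(object))) {
    tb <- table(SummarizedExperiment::colData(object)$era)
    cat("  eras:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "CombiningAbility", function(object) {
  cat("CombiningAbility for", object@trait, "(", object@scope, ")\n")
  cat(sprintf("  grand mean %.4f; %d lines, %d testers, r = %g\n",
              object@grandMean, length(object@gcaLines),
              length(object@gcaTesters), object@nReps))
  top <- sort(object@gcaLines, decreasing = TRUE)
  cat("  top line GCA:", paste(sprintf("%s=%.3f", names(top)[seq_len(min(3, length(top)))],
                                       top[seq_len(min(3, length(top)))]), collapse = ", "), "\n")
})

setMethod("show", "BlupFit", function(object) {
  cat("BlupFit for", object@trait, "\n")
  cat(sprintf("  mu = %.4f; %d hybrids\n", object@grandMean,
              length(object@lineEffects)))
  vc <- object@varianceComponents
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(vc), vc), collapse = " "), "\n")
})
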