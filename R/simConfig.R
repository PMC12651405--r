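#' Build a synthetic-trial configuration
#'
#' Creates a validated [SimConfig-class] describing the testcross trial the
#' generator emulates. The defaults reproduce the dimensions of a 218-line,
#' 2-tester, 3-location trial with three blocks per location, a moderate SNP
#' panel, and an era-wise causal allele-frequency shift of 0.055 per breeding
#' stage (an 11-point change from the earliest to the latest of the three
#' eras). Variance-component defaults make line GCA the dominant genetic
#' signal, with smaller SCA and line-by-location variation and substantial
#' location effects, as is typical of multi-environment maize trials.
#'
#' @param nLines,nTesters,nLocations,nBlocks design sizes (lines f, testers m,
#'   locations, blocks per location).
#' @param eraProportions proportions of lines in eras AGE1/AGE2/AGE3; must sum
#'   to 1.
#' @param nSnps,nCausalPerTrait SNP panel size and causal SNPs per trait.
#' @param eraFreqShift signed causal minor-allele frequency increment per era
#'   step.
#' @param causalBaseFreq AGE1 causal minor-allele frequency; `NA` (default)
#'   draws one uniformly in \[0.1, 0.4\] per causal SNP.
#' @param varianceComponents named non-negative numeric vector; see
#'   [SimConfig-class] for the required names. Omitted names keep defaults.
#' @param markerEffectScale standard deviation of per-causal-allele effects
#'   (trait units per alternate-allele dose).
#' @param missingRate,hetRate observational missing/heterozygous call rates,
#'   bounded by the QC thresholds applied downstream (\[0, 0.2) and \[0, 0.1)).
#' @param grandMean trial grand mean.
#' @param traits trait names to simulate (default: the 16 of [traitNames()]).
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nLines = 20, nSnps = 50, seed = 7)
#' cfg
simConfig <- function(nLines = 218, nTesters = 2, nLocations = 3, nBlocks = 3,
                      eraProportions = c(1, 1, 1) / 3,
                      nSnps = 500, nCausalPerTrait = 5,
                      eraFreqShift = 0.055, causalBaseFreq = NA_real_,
                      varianceComponents = NULL,
                      markerEffectScale = 0.5,
                      missingRate = 0.05, hetRate = 0.02,
                      grandMean = 100, traits = traitNames(),
                      seed = 1L) {
  vc <- c(var_gca_line = 6, var_gca_tester = 2, var_sca = 1, var_loc = 8,
          var_block_within_loc = 1, var_line_x_loc = 1, var_residual = 2)
  if (!is.null(varianceComponents)) {
    bad <- setdiff(names(varianceComponents), names(vc))
    if (length(bad))
      stop("unknown variance component(s): ", paste(bad, collapse = ", "))
    vc[names(varianceComponents)] <- varianceComponents
  }
  new("SimConfig",
      nLines = nLines, nTesters = nTesters, nLocations = nLocations,
      nBlocks = nBlocks, eraProportions = eraProportions, nSnps = nSnps,
      nCausalPerTrait = nCausalPerTrait, eraFreqShift = eraFreqShift,
      causalBaseFreq = as.numeric(causalBaseFreq),
      varianceComponents = vc, markerEffectScale = markerEffectScale,
      missingRate = missingRate, hetRate = hetRate, grandMean = grandMean,
      traits = traits, seed = as.integer(seed))
}

ERA_LEVELS <- c("AGE1", "AGE2", "AGE3")

#' Era levels in breeding order
#'
#' @return `c("AGE1", "AGE2", "AGE3")`, the early (1960s-70s), mid
#'   (1980s-90s) and recent (2000s-10s) breeding stages.
#' @export
eraLevels <- function() ERA_LEVELS
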