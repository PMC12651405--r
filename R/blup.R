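#' Multi-environment BLUP of hybrid values
#'
#' Fits, by REML, the hybrid plot model
#' `y = mu + Env + (1 | Hybrid) + (1 | Hybrid:Env) + (1 | Env:Rep) + error`
#' where hybrids are line x tester combinations, `Env` the locations
#' (fixed, sum-to-zero coded so the intercept is the grand mean mu) and
#' `Rep` the blocks within location. The per-hybrid BLUP value `mu +
#' Hybrid_i` is the shrunken genetic value used downstream as the phenotype
#' for pooled combining ability and GWAS. Fitting is deterministic for
#' fixed data (bobyqa-free default lme4 optimizer with a fixed convergence
#' tolerance); variance-component estimates proposed negative by the
#' optimizer are clamped at zero by lme4's bounded parameterisation.
#'
#' @param plots plot data.frame (see [writePlotTable()]).
#' @param trait trait column.
#' @return A [BlupFit-class].
#' @export
#' @examples
#' cfg <- simConfig(nLines = 15, nSnps = 30, traits = "YPP", seed = 2)
#' trial <- simulateTestcrossTrial(cfg, simulateGenotypes(cfg))
#' fit <- fitMultienvBlup(trial$plots, "YPP")
#' head(blupValues(fit))
fitMultienvBlup <- function(plots, trait) {
  validatePlotTable(plots)
  if (!trait %in% names(plots))
    stop("input error: trait '", trait, "' absent from plot table")
  d <- data.frame(
    y = plots[[trait]],
    hyb = factor(paste(plots$line_id, plots$tester_id, sep = ":")),
    env = factor(plots$location),
    rep = factor(paste(plots$location, plots$block, sep = ":")))
  d <- d[!is.na(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$env)) < 2)
    stop("input error: need >= 2 locations for the multi-environment model")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lme4::lmer(
    y ~ env + (1 | hyb) + (1 | hyb:env) + (1 | env:rep),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  if (!is.null(fit@optinfo$conv$lme4$code) &&
      fit@optinfo$conv$lme4$code < 0)
    stop("non-convergence in REML fit; last objective ",
         format(fit@devcomp$cmp[["REML"]]))
  vcDf <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    v <- vcDf$vcov[vcDf$grp == g]
    if (length(v)) v else 0
  }
  vc <- c(var_line = pick("hyb"), var_line_env = pick("hyb:env"),
          var_env_rep = pick("env:rep"), var_error = pick("Residual"))
  re <- lme4::ranef(fit)
  lineEff <- stats::setNames(re$hyb[[1]], rownames(re$hyb))
  mu <- unname(lme4::fixef(fit)[1])
  # fixed env effects on the sum-to-zero scale, completed for the last level
  envLv <- levels(d$env)
  fe <- lme4::fixef(fit)
  envEff <- c(fe[-1], -sum(fe[-1]))
  names(envEff) <- envLv
  new("BlupFit", trait = trait, grandMean = mu,
      lineEffects = lineEff,
      envEffects = envEff,
      interactionEffects = stats::setNames(re$`hyb:env`[[1]],
                                           rownames(re$`hyb:env`)),
      repWithinEnv = stats::setNames(re$`env:rep`[[1]],
                                     rownames(re$`env:rep`)),
      varianceComponents = vc,
      blupValues = mu + lineEff)
}

#' Assemble hybrid x trait BLUP matrix
#'
#' @param fits list of [BlupFit-class] objects (e.g. one per trait).
#' @return Numeric matrix, hybrids in rows, one column per fitted trait.
#'   Hybrids absent from some fit get `NA` there.
#' @export
blupTable <- function(fits) {
  stopifnot(length(fits) > 0)
  if (is(fits, "BlupFit")) fits <- list(fits)
  traits <- vapply(fits, function(f) f@trait, "")
  hybrids <- sort(unique(unlist(lapply(fits, function(f)
    names(blupValues(f))))))
  out <- matrix(NA_real_, length(hybrids), length(fits),
                dimnames = list(hybrids, traits))
  for (i in seq_along(fits)) {
    v <- blupValues(fits[[i]])
    out[names(v), i] <- v
  }
  out
}

#' Closed-form BLUP shrinkage in the balanced one-way case
#'
#' For a single environment with `n` replicate observations per hybrid and
#' known variance components, the BLUP of a hybrid effect is
#' `k * (hybrid mean - mu)` with `k = var_line / (var_line + var_error /
#' n)`. Exposed as the analytic reference against which the mixed-model
#' solver is checked.
#'
#' @param hybridMeans named per-hybrid raw means.
#' @param mu grand mean.
#' @param varLine,varError variance components.
#' @param n replicates per hybrid.
#' @return Named per-hybrid shrunken effects.
#' @export
shrinkageBlup <- function(hybridMeans, mu, varLine, varError, n) {
  k <- varLine / (varLine + varError / n)
  k * (hybridMeans - mu)
}
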