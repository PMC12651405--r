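#' Per-variant summary statistics
#'
#' Computes, for every variant of a panel, the statistics the QC filters
#' act on: minor allele frequency (from non-missing calls; minor allele is
#' whichever allele is rarer, so `maf <= 0.5`), missing-call rate,
#' heterozygosity rate among non-missing calls, the number of lines
#' carrying at least one copy of the minor allele, and the biallelic flag.
#'
#' @param panel a [GenotypePanel-class].
#' @return data.frame with one row per variant: `snp`, `chrom`, `pos`,
#'   `maf`, `missing_rate`, `het_rate`, `minor_allele_individuals`,
#'   `biallelic`.
#' @export
variantStats <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  n <- ncol(d)
  nonMiss <- rowSums(!is.na(d))
  altFreq <- rowSums(d, na.rm = TRUE) / (2 * pmax(nonMiss, 1))
  minorIsAlt <- altFreq <= 0.5
  maf <- pmin(altFreq, 1 - altFreq)
  hetRate <- rowSums(d == 1, na.rm = TRUE) / pmax(nonMiss, 1)
  minorCarriers <- ifelse(
    minorIsAlt,
    rowSums(d >= 1, na.rm = TRUE),   # carries >= 1 alt (minor) allele
    rowSums(d <= 1, na.rm = TRUE))   # carries >= 1 ref (minor) allele
  info <- snpInfo(panel)
  data.frame(snp = info$snp, chrom = info$chrom, pos = info$pos,
             maf = unname(maf),
             missing_rate = unname(1 - nonMiss / n),
             het_rate = unname(hetRate),
             minor_allele_individuals = unname(minorCarriers),
             biallelic = info$biallelic,
             stringsAsFactors = FALSE)
}

#' Variant-level quality control
#'
#' Applies, in order, the five variant filters used on inbred-line panels:
#' (1) biallelic records only, (2) missing rate < 0.2, (3) minor-allele
#' individuals >= 5, (4) heterozygosity rate < 0.1 and (5) minor allele
#' frequency > 0.05 (variants with MAF <= 0.05 are removed). Removal counts
#' are reported per criterion in application order, each criterion counting
#' only variants that survived the previous ones, so filtering is
#' idempotent.
#'
#' @param panel a [GenotypePanel-class].
#' @param minMinorCarriers,maxMissing,maxHet,minMaf filter thresholds
#'   (defaults: 5, 0.2, 0.1, 0.05).
#' @return List with `panel` (filtered [GenotypePanel-class]) and `removed`
#'   (named integer vector of per-criterion removal counts).
#' @export
qcFilterVariants <- function(panel, minMinorCarriers = 5, maxMissing = 0.2,
                             maxHet = 0.1, minMaf = 0.05) {
  st <- variantStats(panel)
  keep <- rep(TRUE, nrow(st))
  removed <- integer(0)
  applyCrit <- function(pass, name) {
    newlyOut <- keep & !pass
    removed[[name]] <<- sum(newlyOut)
    keep <<- keep & pass
  }
  applyCrit(st$biallelic, "not_biallelic")
  applyCrit(st$missing_rate < maxMissing, "missing_rate")
  applyCrit(st$minor_allele_individuals >= minMinorCarriers,
            "minor_allele_individuals")
  applyCrit(st$het_rate < maxHet, "het_rate")
  applyCrit(st$maf > minMaf, "maf")
  if (!any(keep)) warning("no variants survive QC")
  list(panel = panel[keep, ], removed = unlist(removed))
}

#' Principal components of a genotype panel
#'
#' Mean-imputes missing dosages per variant and returns the top
#' principal-component scores of the lines, used as population-structure
#' covariates in [runGwas()].
#'
#' @param panel a [GenotypePanel-class].
#' @param nPcs number of components (0 returns a 0-column matrix).
#' @return lines x `nPcs` score matrix.
#' @export
genotypePCs <- function(panel, nPcs = 3) {
  d <- dosages(panel)
  if (nPcs == 0)
    return(matrix(0, ncol(d), 0, dimnames = list(colnames(d), NULL)))
  rm <- rowMeans(d, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  imp <- d
  idx <- which(is.na(imp), arr.ind = TRUE)
  if (nrow(idx)) imp[idx] <- rm[idx[, 1]]
  keep <- apply(imp, 1, sd) > 0
  x <- t(imp[keep, , drop = FALSE])
  nPcs <- min(nPcs, ncol(x) - 1, nrow(x) - 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  pc$x[, seq_len(nPcs), drop = FALSE]
}

#' Single-marker association of GCA with SNP dosages
#'
#' For each variant, regresses the per-line GCA values on the
#' alternate-allele dosage (additive coding, heterozygote = 1) by ordinary
#' least squares, optionally adjusting for the top genotype principal
#' components, and reports a two-sided t-test on the dosage coefficient.
#' Lines missing the genotype at a variant are dropped for that variant
#' only. Variants with zero dosage variance after dropping are flagged
#' `degenerate` and reported with `beta = 0`, `p = 1`.
#'
#' This is a deliberate, documented single-marker engine: it does not
#' reimplement multi-locus iterative marker-selection models (such as
#' BLINK) sometimes used for combining-ability GWAS.
#'
#' @param gca named per-line GCA values (names must match panel line ids).
#' @param panel a [GenotypePanel-class] (ideally QC-filtered).
#' @param nPcs number of principal-component covariates (default 3).
#' @param trait trait label carried into the result.
#' @param threshold significance threshold for `hits` (default 3.5e-5).
#' @return List of class `gwasResult`: `results` (data.frame with `snp`,
#'   `chrom`, `pos`, `beta`, `se`, `t`, `p`, `maf`, `n`, `degenerate`),
#'   `trait`, `threshold`, `nLinesUsed`, `hits` (rows with `p <
#'   threshold`, sorted by chrom/pos).
#' @export
runGwas <- function(gca, panel, nPcs = 3, trait = "trait",
                    threshold = 3.5e-5) {
  stopifnot(is(panel, "GenotypePanel"), !is.null(names(gca)))
  common <- intersect(colnames(panel), names(gca))
  if (length(common) < 3)
    stop("input error: fewer than 3 lines shared between gca and panel")
  panel <- panel[, common]
  y <- unname(gca[common])
  d <- dosages(panel)
  covar <- genotypePCs(panel, nPcs)
  st <- variantStats(panel)
  p <- nrow(d)
  beta <- se <- tstat <- pval <- numeric(p)
  nUsed <- integer(p)
  degen <- logical(p)
  for (s in seq_len(p)) {
    g <- d[s, ]
    ok <- !is.na(g) & !is.na(y)
    X <- cbind(1, g[ok], covar[ok, , drop = FALSE])
    nOk <- sum(ok)
    dfres <- nOk - ncol(X)
    if (nOk >= 3 && stats::sd(y[ok]) == 0) {
      beta[s] <- 0; se[s] <- NA_real_; tstat[s] <- 0; pval[s] <- 1
      nUsed[s] <- nOk
      next
    }
    if (nOk < 3 || stats::sd(g[ok]) == 0 || dfres < 1) {
      beta[s] <- 0; se[s] <- NA_real_; tstat[s] <- 0; pval[s] <- 1
      degen[s] <- TRUE; nUsed[s] <- nOk
      next
    }
    fit <- stats::lm.fit(X, y[ok])
    r <- fit$residuals
    sigma2 <- sum(r^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(X)))
    b <- fit$coefficients[2]
    sb <- sqrt(sigma2 * XtXinv[2, 2])
    beta[s] <- b; se[s] <- sb
    tstat[s] <- if (sb > 0) b / sb else 0
    pval[s] <- if (sb > 0) 2 * pt(abs(tstat[s]), dfres, lower.tail = FALSE)
               else as.numeric(abs(b) < 1e-12)
    if (sb == 0) { pval[s] <- ifelse(abs(b) < 1e-12, 1, .Machine$double.xmin) }
    nUsed[s] <- nOk
  }
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  res <- data.frame(snp = st$snp, chrom = st$chrom, pos = st$pos,
                    beta = beta, se = se, t = tstat, p = pval, maf = st$maf,
                    n = nUsed, degenerate = degen, stringsAsFactors = FALSE)
  out <- list(results = res, trait = trait, threshold = threshold,
              nLinesUsed = length(common),
              hits = significantHits(res, threshold, trait))
  class(out) <- "gwasResult"
  out
}

#' @export
print.gwasResult <- function(x, ...) {
  cat("GWAS of", x$trait, "GCA:", nrow(x$results), "variants,",
      x$nLinesUsed, "lines\n")
  cat(sprintf("  threshold %.3g: %d hit(s)\n", x$threshold, nrow(x$hits)))
  invisible(x)
}

#' Variants passing the significance threshold
#'
#' @param result a `gwasResult` (or its `results` data.frame).
#' @param threshold p-value threshold in (0, 1); defaults to the result's
#'   own threshold (a declared analysis constant, commonly 3.5e-5).
#' @param trait trait label for the output.
#' @return data.frame with columns `trait`, `snp`, `chrom`, `pos`, `p`,
#'   `maf`, sorted by chromosome then position.
#' @export
significantHits <- function(result, threshold = NULL, trait = NULL) {
  if (inherits(result, "gwasResult")) {
    if (is.null(threshold)) threshold <- result$threshold
    if (is.null(trait)) trait <- result$trait
    result <- result$results
  }
  if (is.null(threshold)) threshold <- 3.5e-5
  if (is.null(trait)) trait <- "trait"
  stopifnot(threshold > 0, threshold <= 1)
  hits <- result[result$p < threshold, , drop = FALSE]
  suppressWarnings(chromNum <- as.numeric(hits$chrom))
  ord <- order(ifelse(is.na(chromNum), Inf, chromNum), hits$chrom, hits$pos)
  hits <- hits[ord, c("snp", "chrom", "pos", "p", "maf"), drop = FALSE]
  rownames(hits) <- NULL
  cbind(trait = rep(trait, nrow(hits)), hits)
}
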