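sigLabel <- function(p) {
  ifelse(is.na(p), "na", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

pairTest <- function(x, y, test) {
  if (length(x) < 2 || length(y) < 2 ||
      (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)))
    return(c(statistic = NA_real_,
             p = if (length(x) >= 2 && length(y) >= 2) 1 else NA_real_))
  out <- if (test == "welch") stats::t.test(x, y)
         else suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  c(statistic = unname(out$statistic), p = unname(out$p.value))
}

#' GCA trend across breeding eras
#'
#' Summarises per-line GCA values by breeding era (n, mean, sd) and tests
#' the pairwise differences AGE1-AGE2, AGE2-AGE3 and AGE1-AGE3 with
#' Welch's two-sample t-test (default) or the Mann-Whitney test.
#' Significance labels follow the usual convention: `ns`, `*` (p < 0.05),
#' `**` (p < 0.01). No multiplicity correction is applied by default; set
#' `adjust = "bonferroni"` to correct the three comparisons.
#'
#' @param gca named per-line GCA values.
#' @param eras named era assignment (`line_id -> AGE1/AGE2/AGE3`).
#' @param trait trait label.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param adjust p adjustment method (`"none"` default; any
#'   [stats::p.adjust()] method).
#' @return List of class `trendReport` with `summary` (era, n, mean, sd)
#'   and `comparisons` (trait, era_a, era_b, statistic, p, label).
#'   Comparisons involving an era with fewer than 2 lines carry `NA`/`na`.
#' @export
gcaTrend <- function(gca, eras, trait = "trait",
                     test = c("welch", "wilcoxon"), adjust = "none") {
  test <- match.arg(test)
  stopifnot(!is.null(names(gca)))
  common <- intersect(names(gca), names(eras))
  if (!length(common)) stop("input error: no lines shared by gca and eras")
  g <- gca[common]
  e <- factor(eras[common], levels = ERA_LEVELS)
  summ <- data.frame(
    era = ERA_LEVELS,
    n = as.integer(table(e)),
    mean = as.numeric(tapply(g, e, mean)),
    sd = as.numeric(tapply(g, e, sd)),
    stringsAsFactors = FALSE)
  pairs <- list(c("AGE1", "AGE2"), c("AGE2", "AGE3"), c("AGE1", "AGE3"))
  cmp <- do.call(rbind, lapply(pairs, function(pr) {
    r <- pairTest(g[e == pr[1]], g[e == pr[2]], test)
    data.frame(trait = trait, era_a = pr[1], era_b = pr[2],
               statistic = r[["statistic"]], p = r[["p"]],
               stringsAsFactors = FALSE)
  }))
  if (adjust != "none") cmp$p <- p.adjust(cmp$p, method = adjust)
  cmp$label <- sigLabel(cmp$p)
  out <- list(trait = trait, test = test, summary = summ, comparisons = cmp)
  class(out) <- "trendReport"
  out
}

#' @export
print.trendReport <- function(x, ...) {
  cat("GCA trend for", x$trait, sprintf("(%s test)\n", x$test))
  print.data.frame(format(x$summary, digits = 4), row.names = FALSE)
  print.data.frame(format(x$comparisons, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Pairwise Pearson correlation of GCA across traits
#'
#' @param gcaByTrait lines x traits matrix (or data.frame) of per-line GCA
#'   values.
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `p` (two-sided correlation-test p-values, `NA` diagonal). Pairs are
#'   computed on complete observations.
#' @export
gcaCorrelationMatrix <- function(gcaByTrait) {
  m <- as.matrix(gcaByTrait)
  if (nrow(m) < 3) stop("input error: need >= 3 lines")
  r <- stats::cor(m, use = "pairwise.complete.obs")
  k <- ncol(m)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- complete.cases(m[, c(i, j)])
    if (sum(ok) >= 3 && sd(m[ok, i]) > 0 && sd(m[ok, j]) > 0) {
      p[i, j] <- p[j, i] <- stats::cor.test(m[ok, i], m[ok, j])$p.value
    }
  }
  list(r = r, p = p)
}

#' Homozygote allele-class trajectory at one SNP
#'
#' For an inbred-line panel, traces the per-era frequencies of the two
#' homozygote genotype classes (e.g. `T/T` vs `C/C`) at a SNP, together
#' with per-era, per-class GCA summaries and a within-era class comparison
#' using the same test machinery as [gcaTrend()]. Heterozygous and missing
#' calls are excluded (and counted), following the convention for inbred
#' panels in which only homozygote classes are interpreted. A class with
#' zero frequency in an era that contains included lines is flagged
#' `absent`.
#'
#' @param panel a [GenotypePanel-class].
#' @param eras named era assignment.
#' @param snpId variant id (rowname of the panel).
#' @param gca named per-line GCA values.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return List of class `alleleTrajectory`: `snp`, `classes` (data.frame:
#'   era, class, n, frequency, gca_mean, gca_sd, absent), `comparisons`
#'   (within-era class difference tests), `excluded` (het/missing counts),
#'   `eraComputable` (logical per era).
#' @export
alleleTrajectory <- function(panel, eras, snpId, gca,
                             test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(is(panel, "GenotypePanel"))
  if (!snpId %in% rownames(panel))
    stop("input error: SNP '", snpId, "' not in panel")
  info <- snpInfo(panel)
  i <- match(snpId, rownames(panel))
  refClass <- paste(info$ref[i], info$ref[i], sep = "/")
  altClass <- paste(info$alt[i], info$alt[i], sep = "/")
  d <- dosages(panel)[i, ]
  common <- intersect(names(d), intersect(names(eras), names(gca)))
  d <- d[common]; e <- factor(eras[common], ERA_LEVELS); g <- gca[common]
  het <- sum(d == 1, na.rm = TRUE)
  mis <- sum(is.na(d))
  keep <- !is.na(d) & d != 1
  cls <- ifelse(d == 2, altClass, refClass)
  rows <- list(); cmps <- list()
  computable <- stats::setNames(logical(3), ERA_LEVELS)
  for (era in ERA_LEVELS) {
    inEra <- keep & e == era
    nIncl <- sum(inEra)
    computable[era] <- nIncl > 0
    for (cl in c(refClass, altClass)) {
      sel <- inEra & cls == cl
      rows[[paste(era, cl)]] <- data.frame(
        era = era, class = cl, n = sum(sel),
        frequency = if (nIncl > 0) sum(sel) / nIncl else NA_real_,
        gca_mean = if (sum(sel)) mean(g[sel]) else NA_real_,
        gca_sd = if (sum(sel) > 1) sd(g[sel]) else NA_real_,
        absent = nIncl > 0 && sum(sel) == 0,
        stringsAsFactors = FALSE)
    }
    r <- pairTest(g[inEra & cls == refClass], g[inEra & cls == altClass],
                  test)
    cmps[[era]] <- data.frame(era = era, class_a = refClass,
                              class_b = altClass,
                              statistic = r[["statistic"]], p = r[["p"]],
                              label = sigLabel(r[["p"]]),
                              stringsAsFactors = FALSE)
  }
  out <- list(snp = snpId, classes = do.call(rbind, c(rows, make.row.names = FALSE)),
              comparisons = do.call(rbind, c(cmps, make.row.names = FALSE)),
              excluded = c(het = het, missing = mis),
              eraComputable = computable)
  class(out) <- "alleleTrajectory"
  out
}

#' @export
print.alleleTrajectory <- function(x, ...) {
  cat("Allele trajectory at", x$snp,
      sprintf("(excluded: %d het, %d missing)\n",
              x$excluded[["het"]], x$excluded[["missing"]]))
  print.data.frame(format(x$classes, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Rank favorable homozygote classes at significant SNPs
#'
#' For each trajectory, labels as favorable the homozygote class whose
#' lines show the better mean GCA pooled over eras (higher when the
#' trait's favorability direction is `"high"`, lower when `"low"`), and
#' reports the AGE3 - AGE1 change in that class's frequency together with
#' the pooled GCA advantage. Exact ties are flagged and left unlabeled.
#'
#' @param trajectories list of `alleleTrajectory` objects.
#' @param favorability per-trajectory direction: single value or vector
#'   (`"high"`/`"low"`), recycled.
#' @return data.frame: `snp`, `favorable_class`, `freq_change`,
#'   `gca_advantage`, `tie`; rows ordered by decreasing |gca_advantage|.
#' @export
eliteAlleleReport <- function(trajectories, favorability = "high") {
  if (inherits(trajectories, "alleleTrajectory"))
    trajectories <- list(trajectories)
  fav <- rep(favorability, length.out = length(trajectories))
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    cl <- tr$classes
    pool <- sapply(split(cl, cl$class), function(s) {
      n <- sum(s$n)
      if (n == 0) NA_real_ else sum(s$gca_mean * s$n, na.rm = TRUE) / n
    })
    pool <- pool[!is.na(pool)]
    if (length(pool) < 2) {
      return(data.frame(snp = tr$snp, favorable_class = NA_character_,
                        freq_change = NA_real_, gca_advantage = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    }
    diffGca <- pool[1] - pool[2]
    if (diffGca == 0)
      return(data.frame(snp = tr$snp, favorable_class = NA_character_,
                        freq_change = NA_real_, gca_advantage = 0,
                        tie = TRUE, stringsAsFactors = FALSE))
    best <- if (fav[i] == "high") names(pool)[which.max(pool)]
            else names(pool)[which.min(pool)]
    adv <- abs(diffGca)
    f1 <- cl$frequency[cl$era == "AGE1" & cl$class == best]
    f3 <- cl$frequency[cl$era == "AGE3" & cl$class == best]
    data.frame(snp = tr$snp, favorable_class = best,
               freq_change = f3 - f1, gca_advantage = adv, tie = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$gca_advantage), -Inf, out$gca_advantage)), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Tidy rows of trend and trajectory reports
#'
#' @param x a `trendReport` or `alleleTrajectory`.
#' @return data.frame suitable for CSV export.
#' @export
tidyReport <- function(x) {
  if (inherits(x, "trendReport")) {
    cbind(trait = x$trait, x$summary)
  } else if (inherits(x, "alleleTrajectory")) {
    cbind(snp = x$snp, x$classes[, c("era", "class", "n", "frequency",
                                     "gca_mean", "gca_sd")])
  } else stop("unsupported report type")
}
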