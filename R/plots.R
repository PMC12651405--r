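needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package")
}

#' Boxplot of per-era GCA values
#'
#' @param gca named per-line GCA values.
#' @param eras named era assignment.
#' @param trait trait label for the title.
#' @return A ggplot object.
#' @export
plotGcaTrend <- function(gca, eras, trait = "trait") {
  needGgplot()
  common <- intersect(names(gca), names(eras))
  df <- data.frame(era = factor(eras[common], ERA_LEVELS),
                   gca = unname(gca[common]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$era, y = .data$gca)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "breeding era", y = paste0(trait, " GCA")) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of GWAS results
#'
#' @param result a `gwasResult` from [runGwas()].
#' @return A ggplot object with -log10(p) against genome order and the
#'   significance threshold as a horizontal line.
#' @export
plotManhattan <- function(result) {
  needGgplot()
  df <- result$results
  suppressWarnings(cn <- as.numeric(df$chrom))
  df <- df[order(ifelse(is.na(cn), Inf, cn), df$chrom, df$pos), ]
  df$index <- seq_len(nrow(df))
  df$logp <- -log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$logp,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(result$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "SNP (genome order)", y = expression(-log[10](p)),
                  title = paste("GCA GWAS:", result$trait)) +
    ggplot2::theme_minimal()
}

#' Stacked per-era frequency bars of homozygote classes
#'
#' @param trajectory an `alleleTrajectory`.
#' @return A ggplot object.
#' @export
plotAlleleTrajectory <- function(trajectory) {
  needGgplot()
  cl <- trajectory$classes
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$era, y = .data$frequency,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "breeding era", y = "class frequency",
                  title = trajectory$snp) +
    ggplot2::theme_minimal()
}
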