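# --- balanced complete factorial SS by inclusion-exclusion over ------------
# factor subsets: raw(S) = sum over cells of S of total^2 / cell size,
# raw(empty) = G^2/N;  SS(T) = sum_{S subset T} (-1)^{|T|-|S|} raw(S).

rawSS <- function(y, fac, subset) {
  if (!length(subset)) return(sum(y)^2 / length(y))
  g <- interaction(fac[subset], drop = FALSE, lex.order = TRUE)
  tot <- tapply(y, g, sum)
  cnt <- tapply(y, g, length)
  keep <- !is.na(tot)
  sum(tot[keep]^2 / cnt[keep])
}

subsetsOf <- function(term) {
  n <- length(term)
  out <- list(character(0))
  for (k in seq_len(n))
    out <- c(out, utils::combn(term, k, simplify = FALSE))
  out
}

balancedSS <- function(y, fac, term) {
  ss <- 0
  for (s in subsetsOf(term))
    ss <- ss + (-1)^(length(term) - length(s)) * rawSS(y, fac, s)
  max(ss, 0)  # guard tiny negative round-off
}

termDf <- function(fac, term) {
  if (!length(term)) return(0L)
  as.integer(prod(vapply(term, function(f) nlevels(fac[[f]]) - 1L,
                         integer(1))))
}

starsFor <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

assembleAnova <- function(y, fac, terms, designName, errorTerm = NULL) {
  N <- length(y)
  totalSS <- sum((y - mean(y))^2)
  rows <- data.frame(source = names(terms),
                     df = vapply(terms, function(t) termDf(fac, t), integer(1)),
                     ss = vapply(terms, function(t) balancedSS(y, fac, t),
                                 numeric(1)),
                     stringsAsFactors = FALSE)
  if (is.null(errorTerm)) {
    errDf <- N - 1L - sum(rows$df)
    errSS <- max(totalSS - sum(rows$ss), 0)
  } else {
    i <- match(errorTerm, rows$source)
    errDf <- rows$df[i]; errSS <- rows$ss[i]
    rows <- rows[-i, , drop = FALSE]
  }
  rows$ms <- ifelse(rows$df > 0, rows$ss / rows$df, NA_real_)
  errMS <- if (errDf > 0) errSS / errDf else NA_real_
  rows$f_stat <- rows$ms / errMS
  rows$p <- ifelse(is.na(rows$f_stat) | errDf == 0, NA_real_,
                   pf(rows$f_stat, rows$df, errDf, lower.tail = FALSE))
  rows$stars <- starsFor(rows$p)
  err <- data.frame(source = if (is.null(errorTerm)) "Error" else errorTerm,
                    df = errDf, ss = errSS, ms = errMS,
                    f_stat = NA_real_, p = NA_real_, stars = "",
                    stringsAsFactors = FALSE)
  out <- rbind(rows, err)
  rownames(out) <- NULL
  attr(out, "design_name") <- designName
  attr(out, "total_df") <- N - 1L
  attr(out, "total_ss") <- totalSS
  class(out) <- c("anovaTable", "data.frame")
  out
}

#' @export
print.anovaTable <- function(x, ...) {
  cat("Balanced ANOVA:", attr(x, "design_name"),
      sprintf("(total df %d)\n", attr(x, "total_df")))
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}

#' Degrees of freedom of the testcross ANOVA layouts
#'
#' Returns the source-by-source degrees of freedom for the two table layouts
#' of a balanced NCII trial analysis: `"per_tester"` (sources Blo, Loc, Cro
#' and all their interactions, crosses analysed within one tester) and
#' `"joint_combining"` (Loc, Blo, Line, Line x Loc, Tester, Tester x Loc,
#' Line x Tester, Line x Tester x Loc). Main-effect df is levels minus one;
#' every interaction df is the product of its components' dfs.
#'
#' @param designName `"per_tester"` or `"joint_combining"`.
#' @param levels named list/vector of level counts. For `per_tester`:
#'   `blocks`, `locations`, `crosses`. For `joint_combining`: `blocks`,
#'   `locations`, `lines`, `testers`.
#' @return Named integer vector in the layout's source order.
#' @export
#' @examples
#' anovaDf("joint_combining",
#'         c(blocks = 4, locations = 3, lines = 218, testers = 2))
anovaDf <- function(designName = c("per_tester", "joint_combining"), levels) {
  designName <- match.arg(designName)
  lv <- as.list(levels)
  need <- if (designName == "per_tester") c("blocks", "locations", "crosses")
          else c("blocks", "locations", "lines", "testers")
  miss <- setdiff(need, names(lv))
  if (length(miss))
    stop("configuration error: 'levels' lacks ", paste(miss, collapse = ", "))
  if (any(unlist(lv[need]) < 1))
    stop("configuration error: all level counts must be >= 1")
  d <- lapply(lv, function(x) as.integer(x) - 1L)
  if (designName == "per_tester") {
    c(Blo = d$blocks, Loc = d$locations, Cro = d$crosses,
      `Blo x Loc` = d$blocks * d$locations,
      `Blo x Cro` = d$blocks * d$crosses,
      `Loc x Cro` = d$locations * d$crosses,
      `Blo x Loc x Cro` = d$blocks * d$locations * d$crosses)
  } else {
    c(Loc = d$locations, Blo = d$blocks, Line = d$lines,
      `Line x Loc` = d$lines * d$locations, Tester = d$testers,
      `Tester x Loc` = d$testers * d$locations,
      `Line x Tester` = d$lines * d$testers,
      `Line x Tester x Loc` = d$lines * d$testers * d$locations)
  }
}

checkComplete <- function(fac, what) {
  g <- interaction(fac, drop = FALSE, lex.order = TRUE)
  cnt <- table(g)
  if (length(unique(as.vector(cnt))) != 1 || any(cnt == 0)) {
    missing <- names(cnt)[cnt == 0]
    stop("balance error: incomplete ", what, " layout",
         if (length(missing)) paste0("; empty cell(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ..."))
  }
}

#' Per-tester joint ANOVA of one trait
#'
#' Restricted to a single tester, the crosses form a balanced
#' block x location x cross factorial; sums of squares are computed by
#' inclusion-exclusion over marginal totals, and every source is tested
#' against the highest-order (Blo x Loc x Cro) mean square, which acts as
#' the residual stratum in this unreplicated-within-cell layout.
#'
#' @param plots plot data.frame.
#' @param testerId tester whose crosses are analysed.
#' @param trait trait column.
#' @return An `anovaTable` data.frame (source, df, ss, ms, f_stat, p, stars)
#'   with the error row last.
#' @export
perTesterAnova <- function(plots, testerId, trait) {
  validatePlotTable(plots)
  if (!trait %in% names(plots))
    stop("input error: trait '", trait, "' absent from plot table")
  pl <- plots[plots$tester_id == testerId, , drop = FALSE]
  if (!nrow(pl)) stop("input error: no plots for tester '", testerId, "'")
  fac <- list(Blo = factor(pl$block), Loc = factor(pl$location),
              Cro = factor(pl$line_id))
  checkComplete(fac, "Blo x Loc x Cro")
  terms <- list(Blo = "Blo", Loc = "Loc", Cro = "Cro",
                `Blo x Loc` = c("Blo", "Loc"),
                `Blo x Cro` = c("Blo", "Cro"),
                `Loc x Cro` = c("Loc", "Cro"),
                `Blo x Loc x Cro` = c("Blo", "Loc", "Cro"))
  assembleAnova(pl[[trait]], fac, terms,
                paste0("per_tester:", testerId),
                errorTerm = "Blo x Loc x Cro")
}

#' Joint combining-ability ANOVA of one trait
#'
#' Partitions the plot variation of the full line x tester x location
#' layout into Loc, Blo, Line, Line x Loc, Tester, Tester x Loc,
#' Line x Tester and Line x Tester x Loc, with the within-cell block
#' replication providing the error stratum. Line, Tester and Line x Tester
#' sums of squares add up to the between-cross SS, i.e. the GCA/SCA
#' decomposition of cross variation. By default every source is tested
#' against the residual mean square; `testAgainstInteraction = TRUE` tests
#' Line and Tester against their x Loc interactions instead (the
#' mixed-model convention for multi-environment trials).
#'
#' @param plots plot data.frame.
#' @param trait trait column.
#' @param testAgainstInteraction test Line/Tester against Line x Loc and
#'   Tester x Loc mean squares.
#' @return An `anovaTable` data.frame.
#' @export
jointCombiningAnova <- function(plots, trait, testAgainstInteraction = FALSE) {
  validatePlotTable(plots)
  if (!trait %in% names(plots))
    stop("input error: trait '", trait, "' absent from plot table")
  fac <- list(Loc = factor(plots$location), Blo = factor(plots$block),
              Line = factor(plots$line_id), Tester = factor(plots$tester_id))
  checkComplete(fac[c("Line", "Tester", "Loc", "Blo")],
                "Line x Tester x Loc x Blo")
  terms <- list(Loc = "Loc", Blo = "Blo", Line = "Line",
                `Line x Loc` = c("Line", "Loc"), Tester = "Tester",
                `Tester x Loc` = c("Tester", "Loc"),
                `Line x Tester` = c("Line", "Tester"),
                `Line x Tester x Loc` = c("Line", "Tester", "Loc"))
  tab <- assembleAnova(plots[[trait]], fac, terms, "joint_combining")
  if (testAgainstInteraction) {
    for (pair in list(c("Line", "Line x Loc"), c("Tester", "Tester x Loc"))) {
      i <- match(pair[1], tab$source); j <- match(pair[2], tab$source)
      tab$f_stat[i] <- tab$ms[i] / tab$ms[j]
      tab$p[i] <- pf(tab$f_stat[i], tab$df[i], tab$df[j], lower.tail = FALSE)
      tab$stars[i] <- starsFor(tab$p[i])
    }
  }
  tab
}

#' Write an ANOVA table as CSV
#'
#' @param table an `anovaTable` from [perTesterAnova()] or
#'   [jointCombiningAnova()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeAnovaTable <- function(table, path) {
  df <- as.data.frame(table)
  df$design <- attr(table, "design_name")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
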