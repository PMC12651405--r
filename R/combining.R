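resolveScope <- function(plots, scope, location) {
  if (scope == "per-location") {
    if (is.null(location)) stop("input error: per-location scope needs 'location'")
    plots <- plots[plots$location == location, , drop = FALSE]
    if (!nrow(plots)) stop("input error: no plots in location '", location, "'")
    label <- paste0("per-location:", location)
  } else label <- "pooled"
  list(plots = plots, label = label)
}

#' Cross, line, tester and grand totals of a trait
#'
#' Accumulates the marginal totals that drive the Griffing line x tester
#' estimators: the per-cross totals `Tij` over all plots in scope, the
#' per-line totals `Tf`, the per-tester totals `Tm`, and the grand total.
#' Marginal consistency (`rowSums(Tij) = Tf`, `colSums(Tij) = Tm`,
#' `sum(Tij) = grand`) holds by construction.
#'
#' @param plots plot data.frame (see [writePlotTable()]).
#' @param trait trait column name.
#' @param scope `"pooled"` (all locations) or `"per-location"`.
#' @param location location id when `scope = "per-location"`.
#' @return List with `Tij` (lines x testers matrix), `Tf`, `Tm`, `grand`,
#'   `counts` (plots per cross) and `scope`.
#' @export
crossTotals <- function(plots, trait, scope = c("pooled", "per-location"),
                        location = NULL) {
  scope <- match.arg(scope)
  validatePlotTable(plots)
  if (!trait %in% names(plots))
    stop("input error: trait '", trait, "' absent from plot table")
  sc <- resolveScope(plots, scope, location)
  plots <- sc$plots
  lines <- sort(unique(plots$line_id))
  testers <- sort(unique(plots$tester_id))
  lf <- factor(plots$line_id, levels = lines)
  tf <- factor(plots$tester_id, levels = testers)
  y <- plots[[trait]]
  Tij <- tapply(y, list(lf, tf), sum)
  counts <- table(lf, tf)
  Tij[is.na(Tij)] <- 0
  Tij <- matrix(as.numeric(Tij), length(lines), length(testers),
                dimnames = list(lines, testers))
  list(Tij = Tij, Tf = rowSums(Tij), Tm = colSums(Tij), grand = sum(Tij),
       counts = matrix(as.numeric(counts), length(lines), length(testers),
                       dimnames = list(lines, testers)),
       scope = sc$label)
}

# core totals -> effects step shared by all entry points
griffingFromTotals <- function(Tij, r) {
  f <- nrow(Tij); m <- ncol(Tij)
  if (f < 2) stop("design error: need at least 2 tested lines (f >= 2)")
  mu <- sum(Tij) / (m * f * r)
  gF <- rowSums(Tij) / (r * m) - mu
  gM <- colSums(Tij) / (r * f) - mu
  scaM <- Tij / r - outer(gF + mu, rep(1, m)) -
    outer(rep(1, f), gM + mu) + mu
  dimnames(scaM) <- dimnames(Tij)
  list(grandMean = mu, gcaLines = gF, gcaTesters = gM, sca = scaM)
}

#' Estimate combining ability by the NCII totals method
#'
#' Computes the grand mean, line GCA, tester GCA and line x tester SCA for
#' one trait from balanced plot data, using the totals form of the Griffing
#' line x tester estimators:
#' \deqn{Gca_f(i) = T_f(i)/(rm) - T../(mfr), \quad
#'       Gca_m(j) = T_m(j)/(rf) - T../(mfr),}
#' \deqn{Sca_{ij} = T_{ij}/r - T_f(i)/(rm) - T_m(j)/(rf) + T../(mfr),}
#' where `f` lines, `m` testers and `r` replicate plots per cross contribute
#' to the totals. Every cross must be observed in the same number of plots;
#' with `onUnbalanced = "means"` unbalanced or missing-valued data fall back
#' to cross means (replicate count 1) with a warning.
#'
#' @inheritParams crossTotals
#' @param onUnbalanced `"error"` (default) or `"means"`.
#' @return A [CombiningAbility-class].
#' @export
#' @examples
#' plots <- data.frame(line_id = rep(c("L1", "L2"), each = 2),
#'                     tester_id = rep(c("T1", "T2"), 2),
#'                     location = "LOC1", block = "B1",
#'                     YPP = c(1, 2, 3, 4))
#' ca <- estimateCombiningAbility(plots, "YPP")
#' gcaLines(ca)
estimateCombiningAbility <- function(plots, trait,
                                     scope = c("pooled", "per-location"),
                                     location = NULL,
                                     onUnbalanced = c("error", "means")) {
  scope <- match.arg(scope)
  onUnbalanced <- match.arg(onUnbalanced)
  validatePlotTable(plots)
  if (!trait %in% names(plots))
    stop("input error: trait '", trait, "' absent from plot table")
  sc <- resolveScope(plots, scope, location)
  hasNA <- any(is.na(sc$plots[[trait]]))
  tot <- crossTotals(plots, trait, scope, location)
  r <- unique(as.vector(tot$counts))
  balanced <- length(r) == 1 && r[1] >= 1 && !hasNA
  if (!balanced) {
    if (onUnbalanced == "error")
      stop("balance error: unequal replication (or missing values) across ",
           "crosses; use onUnbalanced = \"means\" to fall back to cross means")
    warning("unbalanced replication: falling back to cross means (r = 1)")
    pl <- sc$plots
    lines <- rownames(tot$Tij); testers <- colnames(tot$Tij)
    mn <- tapply(pl[[trait]],
                 list(factor(pl$line_id, lines), factor(pl$tester_id, testers)),
                 mean, na.rm = TRUE)
    if (any(is.na(mn))) stop("balance error: empty cross cell(s)")
    Tij <- matrix(as.numeric(mn), length(lines), length(testers),
                  dimnames = list(lines, testers))
    r <- 1
  } else {
    Tij <- tot$Tij
    r <- r[1]
  }
  g <- griffingFromTotals(Tij, r)
  new("CombiningAbility", trait = trait, scope = tot$scope,
      grandMean = g$grandMean, gcaLines = g$gcaLines,
      gcaTesters = g$gcaTesters, sca = g$sca, nReps = as.numeric(r))
}

#' Combining ability from BLUP-adjusted hybrid values
#'
#' Applies the Griffing decomposition to one shrunken value per hybrid
#' (replicate count 1), the mode used to feed per-line GCA into GWAS.
#' Hybrid ids must
#' be `"<line>:<tester>"` as produced by [fitMultienvBlup()].
#'
#' @param values named per-hybrid values (e.g. [blupValues()]).
#' @param trait trait label carried into the result.
#' @return A [CombiningAbility-class] with scope `"blup"`.
#' @export
combiningFromHybridValues <- function(values, trait = "trait") {
  ids <- strsplit(names(values), ":", fixed = TRUE)
  if (any(lengths(ids) != 2))
    stop("input error: hybrid ids must be '<line>:<tester>'")
  lines <- sort(unique(vapply(ids, `[`, "", 1)))
  testers <- sort(unique(vapply(ids, `[`, "", 2)))
  Tij <- matrix(NA_real_, length(lines), length(testers),
                dimnames = list(lines, testers))
  Tij[cbind(vapply(ids, `[`, "", 1), vapply(ids, `[`, "", 2))] <- values
  if (any(is.na(Tij)))
    stop("balance error: hybrid values missing for some line x tester cells")
  g <- griffingFromTotals(Tij, 1)
  new("CombiningAbility", trait = trait, scope = "blup",
      grandMean = g$grandMean, gcaLines = g$gcaLines,
      gcaTesters = g$gcaTesters, sca = g$sca, nReps = 1)
}

#' Rank lines by GCA
#'
#' @param result a [CombiningAbility-class].
#' @param topK number of lines to return (at most the number of lines).
#' @param direction `"high"` (descending GCA, default) or `"low"`.
#' @return Character vector of line ids; ties broken by lexicographic line
#'   id.
#' @export
rankByGca <- function(result, topK = 10, direction = c("high", "low")) {
  direction <- match.arg(direction)
  g <- gcaLines(result)
  if (topK > length(g)) stop("input error: topK exceeds number of lines")
  ord <- order(if (direction == "high") -g else g, names(g))
  names(g)[ord][seq_len(topK)]
}

#' Serialize combining-ability results as tidy CSV rows
#'
#' @param result a [CombiningAbility-class].
#' @return data.frame with columns trait, scope, effect_type, line_id,
#'   tester_id, value.
#' @export
combiningAbilityTable <- function(result) {
  stopifnot(is(result, "CombiningAbility"))
  rows <- rbind(
    data.frame(effect_type = "grand_mean", line_id = NA, tester_id = NA,
               value = result@grandMean),
    data.frame(effect_type = "gca_line", line_id = names(result@gcaLines),
               tester_id = NA, value = unname(result@gcaLines)),
    data.frame(effect_type = "gca_tester", line_id = NA,
               tester_id = names(result@gcaTesters),
               value = unname(result@gcaTesters)),
    data.frame(effect_type = "sca",
               line_id = rep(rownames(result@sca), ncol(result@sca)),
               tester_id = rep(colnames(result@sca), each = nrow(result@sca)),
               value = as.vector(result@sca)))
  cbind(trait = result@trait, scope = result@scope, rows)
}
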