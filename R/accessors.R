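#' @rdname GenotypePanel-class
#' @param object,x a package object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @describeIn GenotypePanel-class variants x lines dosage matrix (alternate
#'   allele counts; `NA` = missing call).
#' @export
setMethod("dosages", "GenotypePanel", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypePanel-class per-variant metadata as a data.frame
#'   (snp id, chrom, pos, ref, alt, biallelic flag).
#' @export
snpInfo <- function(x) {
  stopifnot(is(x, "GenotypePanel"))
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(snp = rownames(x), df, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @describeIn GenotypePanel-class line identifiers.
#' @export
lineIds <- function(x) {
  stopifnot(is(x, "GenotypePanel"))
  colnames(x)
}

#' @describeIn GenotypePanel-class breeding-era factor (`NULL` when the panel
#'   carries no era assignment).
#' @export
eras <- function(x) {
  stopifnot(is(x, "GenotypePanel"))
  cd <- SummarizedExperiment::colData(x)
  if (!"era" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$era), colnames(x))
}

#' @rdname CombiningAbility-class
#' @param x a `CombiningAbility` object.
#' @export
gcaLines <- function(x) { stopifnot(is(x, "CombiningAbility")); x@gcaLines }

#' @rdname CombiningAbility-class
#' @export
gcaTesters <- function(x) { stopifnot(is(x, "CombiningAbility")); x@gcaTesters }

#' @rdname CombiningAbility-class
#' @export
sca <- function(x) { stopifnot(is(x, "CombiningAbility")); x@sca }

#' @rdname CombiningAbility-class
#' @export
grandMean <- function(x) {
  stopifnot(is(x, "CombiningAbility") || is(x, "BlupFit"))
  x@grandMean
}

#' @rdname BlupFit-class
#' @param x a `BlupFit` object.
#' @export
blupValues <- function(x) { stopifnot(is(x, "BlupFit")); x@blupValues }

#' @rdname BlupFit-class
#' @export
varianceComponents <- function(x) {
  stopifnot(is(x, "BlupFit"))
  x@varianceComponents
}
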