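#' Write a genotype panel to a minimal VCF v4.2
#'
#' Emits GT-only unphased genotypes (`0/0`, `0/1`, `1/1`, `./.` for missing),
#' one sample column per line, suitable for round-tripping through
#' [readGenotypeVcf()].
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  info <- snpInfo(panel)
  d <- dosages(panel)
  gtOf <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtOf[d[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(info$chrom, info$pos, info$snp, info$ref, info$alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read line genotypes from a VCF
#'
#' Parses a VCF (v4.2, GT field) into a [GenotypePanel-class] of
#' alternate-allele dosages. Heterozygous calls become dosage 1, `./.`
#' missing. Multi-allelic records are retained with `biallelic = FALSE` in
#' the variant metadata so [qcFilterVariants()] can remove them.
#'
#' @param path VCF file path.
#' @param era optional named era assignment to attach; line ids absent from
#'   it are reported via a warning, not an error.
#' @return A [GenotypePanel-class].
#' @export
readGenotypeVcf <- function(path, era = NULL) {
  if (!file.exists(path)) stop("I/O error: no such VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alleleDose <- function(g) {
    out <- rep(NA_integer_, length(g))
    clean <- gsub("|", "/", g, fixed = TRUE)
    ok <- !is.na(clean) & grepl("^[0-9]+/[0-9]+$", clean)
    parts <- strsplit(clean[ok], "/", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) sum(as.integer(p) > 0L), integer(1))
    out
  }
  d <- apply(gt, 2, alleleDose)
  d <- matrix(as.integer(pmin(d, 2L)), nrow = nrow(gt),
              dimnames = list(rownames(gt), colnames(gt)))
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0("S", fix[noId, "CHROM"], "_", fix[noId, "POS"])
  rownames(d) <- ids
  if (!is.null(era)) {
    unmatched <- setdiff(colnames(d), names(era))
    if (length(unmatched))
      warning("no era assignment for line(s): ",
              paste(unmatched, collapse = ", "))
    era <- era[intersect(colnames(d), names(era))]
    full <- stats::setNames(rep(NA_character_, ncol(d)), colnames(d))
    full[names(era)] <- era
    era <- full
  }
  GenotypePanel(d, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                ref = fix[, "REF"], alt = fix[, "ALT"], era = era)
}

#' Read and write plot-level phenotype tables
#'
#' The plot CSV is long format: one row per plot with columns `line_id`,
#' `tester_id`, `location`, `block`, then one numeric column per trait.
#' `validatePlotTable()` enforces uniqueness of the
#' (line, tester, location, block) key and finiteness of present values.
#'
#' @param plots a plot data.frame.
#' @param path CSV path.
#' @return `readPlotTable` returns the validated data.frame; writers return
#'   the path invisibly.
#' @export
writePlotTable <- function(plots, path) {
  validatePlotTable(plots)
  write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlotTable
#' @export
readPlotTable <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such plot table: ", path)
  plots <- read.csv(path, stringsAsFactors = FALSE)
  validatePlotTable(plots)
  plots
}

#' @rdname writePlotTable
#' @export
validatePlotTable <- function(plots) {
  need <- c("line_id", "tester_id", "location", "block")
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("plot table lacks column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(plots[need], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (line, tester, location, block) keys in plot table")
  traitCols <- setdiff(names(plots), need)
  for (tc in traitCols) {
    v <- plots[[tc]]
    if (!is.numeric(v)) stop("trait column '", tc, "' is not numeric")
    if (any(!is.na(v) & !is.finite(v)))
      stop("non-finite values in trait column '", tc, "'")
  }
  invisible(plots)
}

#' Read and write breeding-era assignments
#'
#' Era CSVs have columns `line_id` and `era` with era values among
#' AGE1/AGE2/AGE3.
#'
#' @param eras named character vector (`line_id -> era`).
#' @param path CSV path.
#' @return `readEraTable` returns a named character vector; the writer
#'   returns the path invisibly.
#' @export
writeEraTable <- function(eras, path) {
  stopifnot(!is.null(names(eras)))
  write.csv(data.frame(line_id = names(eras), era = as.character(eras)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEraTable
#' @export
readEraTable <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such era table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "era") %in% names(df)))
    stop("era table needs columns line_id, era")
  bad <- setdiff(unique(df$era), ERA_LEVELS)
  if (length(bad))
    stop("unknown era label(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$era, df$line_id)
}

#' Write the synthetic fixtures of one simulated trial
#'
#' Writes genotypes (VCF), plot phenotypes (CSV) and era labels (CSV) so that
#' they round-trip through [readGenotypeVcf()], [readPlotTable()] and
#' [readEraTable()] with value equality.
#'
#' @param genotypes result of [simulateGenotypes()] (or a
#'   [GenotypePanel-class]).
#' @param plots plot data.frame from [simulateTestcrossTrial()].
#' @param outDir output directory (created if absent).
#' @return Named character vector of written paths (`vcf`, `plots`, `eras`).
#' @export
writeFixtures <- function(genotypes, plots, outDir) {
  panel <- if (is.list(genotypes)) genotypes$panel else genotypes
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", outDir)
  paths <- c(vcf = file.path(outDir, "genotypes.vcf"),
             plots = file.path(outDir, "plots.csv"),
             eras = file.path(outDir, "eras.csv"))
  writeGenotypeVcf(panel, paths[["vcf"]])
  writePlotTable(plots, paths[["plots"]])
  er <- eras(panel)
  if (is.null(er)) stop("genotype panel carries no era assignment")
  writeEraTable(er, paths[["eras"]])
  paths
}
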