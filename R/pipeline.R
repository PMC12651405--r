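#' Validate a pipeline configuration
#'
#' A run configuration is a named list (or a YAML file with the same
#' structure) with exactly one of:
#' * `simulate`: a list of [simConfig()] arguments, or
#' * `input`: a list with paths `plots`, `vcf`, `eras`;
#'
#' plus optional elements `traits` (subset to analyse), `gwas`
#' (`threshold`, `nPcs`), `trend` (`test`), `favorability` (named
#' `"high"`/`"low"` per trait), `outDir` and `seed`. Referenced files must
#' exist at validation time.
#'
#' @param config list or YAML path.
#' @return The normalised configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  hasSim <- !is.null(config$simulate)
  hasIn <- !is.null(config$input)
  if (hasSim == hasIn)
    stop("config must contain exactly one of 'simulate' or 'input'")
  if (hasIn) {
    need <- c("plots", "vcf", "eras")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("config$input lacks: ", paste(miss, collapse = ", "))
    for (p in unlist(config$input[need]))
      if (!file.exists(p)) stop("validation error: missing input file: ", p)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$outDir <- config$outDir %||% tempfile("nciiGCA_run_")
  config$gwas <- utils::modifyList(list(threshold = 3.5e-5, nPcs = 3),
                                   config$gwas %||% list())
  config$trend <- utils::modifyList(list(test = "welch"),
                                    config$trend %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end testcross analysis pipeline
#'
#' Orchestrates: simulate (or ingest) genotypes, eras and plot phenotypes;
#' fit the multi-environment BLUP per trait; estimate pooled combining
#' ability from plot totals and from BLUP hybrid values; run the
#' per-tester and joint combining-ability ANOVAs; QC-filter variants and
#' run the single-marker GCA GWAS; and compute era trends and allele
#' trajectories at the significant SNPs. All tabular outputs are written
#' as CSV under `outDir`, genotypes as VCF, and a JSON manifest records
#' the seed, a config echo, input hashes and the analysis caveats
#' (single-marker engine; the printed 3.5e-5 threshold is one of several
#' defensible readings of a Bonferroni cut-off). Rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config list or YAML path; see [validateRunConfig()].
#' @return The manifest (named list), invisibly written to
#'   `outDir/manifest.json`.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  caveats <- c(
    "GWAS engine is a single-marker OLS with PC covariates, not an iterative multi-locus model",
    "significance threshold is configurable; the default 3.5e-5 is the conventional printed value and is not a Bonferroni bound for large panels")
  stageDone <- character(0)
  manifest <- list(seed = config$seed, config = config, caveats = caveats,
                   outputs = list(), stages = character(0))
  finishStage <- function(name) stageDone <<- c(stageDone, name)

  # --- stage 1: data ----------------------------------------------------
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% config$seed
    cfg <- do.call(simConfig, simArgs)
    geno <- simulateGenotypes(cfg)
    trial <- simulateTestcrossTrial(cfg, geno)
    plots <- trial$plots
    panel <- geno$panel
    eraMap <- geno$eras
    fixturePaths <- writeFixtures(geno, plots, outDir)
    manifest$outputs <- c(manifest$outputs, as.list(fixturePaths))
  } else {
    plots <- readPlotTable(config$input$plots)
    eraMap <- readEraTable(config$input$eras)
    panel <- readGenotypeVcf(config$input$vcf, era = eraMap)
    manifest$input_hashes <- as.list(tools::md5sum(unlist(config$input)))
  }
  finishStage("data")
  traitsAll <- setdiff(names(plots),
                       c("line_id", "tester_id", "location", "block"))
  traits <- config$traits %||% traitsAll
  traits <- intersect(traits, traitsAll)
  if (!length(traits)) stop("no requested trait present in the plot table")

  runStage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages <<- stageDone
      manifest$failed_stage <<- list(stage = name,
                                     message = conditionMessage(res))
      path <- file.path(outDir, "manifest.json")
      jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    finishStage(name)
    res
  }

  # --- stage 2: BLUP ----------------------------------------------------
  fits <- runStage("blup", lapply(stats::setNames(traits, traits),
                                  function(tr) fitMultienvBlup(plots, tr)))
  bt <- blupTable(fits)
  write.csv(data.frame(hybrid_id = rownames(bt), bt, check.names = FALSE),
            file.path(outDir, "blup_table.csv"), row.names = FALSE)
  vcDf <- do.call(rbind, lapply(fits, function(f)
    data.frame(trait = f@trait, t(varianceComponents(f)))))
  write.csv(vcDf, file.path(outDir, "variance_components.csv"),
            row.names = FALSE)

  # --- stage 3: combining ability --------------------------------------
  caBlup <- runStage("combining", lapply(
    stats::setNames(traits, traits),
    function(tr) combiningFromHybridValues(bt[, tr], trait = tr)))
  caPlot <- lapply(stats::setNames(traits, traits),
                   function(tr) estimateCombiningAbility(plots, tr))
  caRows <- do.call(rbind, c(lapply(caBlup, combiningAbilityTable),
                             lapply(caPlot, combiningAbilityTable)))
  write.csv(caRows, file.path(outDir, "combining_ability.csv"),
            row.names = FALSE)

  # --- stage 4: ANOVA ---------------------------------------------------
  anovaRows <- runStage("anova", {
    rows <- list()
    for (tr in traits) {
      for (tid in sort(unique(plots$tester_id))) {
        at <- perTesterAnova(plots, tid, tr)
        rows[[paste(tr, tid)]] <- cbind(trait = tr, design =
          attr(at, "design_name"), as.data.frame(at))
      }
      jt <- jointCombiningAnova(plots, tr)
      rows[[paste(tr, "joint")]] <- cbind(trait = tr, design =
        attr(jt, "design_name"), as.data.frame(jt))
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  write.csv(anovaRows, file.path(outDir, "anova_tables.csv"),
            row.names = FALSE)

  # --- stage 5: GWAS ----------------------------------------------------
  gwasOut <- runStage("gwas", {
    qc <- qcFilterVariants(panel)
    res <- list()
    for (tr in traits) {
      res[[tr]] <- runGwas(gcaLines(caBlup[[tr]]), qc$panel,
                           nPcs = config$gwas$nPcs, trait = tr,
                           threshold = config$gwas$threshold)
    }
    list(qc = qc, res = res)
  })
  gwasRows <- do.call(rbind, lapply(gwasOut$res, function(r)
    cbind(trait = r$trait, r$results)))
  write.csv(gwasRows, file.path(outDir, "gwas_results.csv"),
            row.names = FALSE)
  hitRows <- do.call(rbind, lapply(gwasOut$res, function(r) r$hits))
  write.csv(hitRows, file.path(outDir, "gwas_hits.csv"), row.names = FALSE)
  manifest$qc_removed <- as.list(gwasOut$qc$removed)

  # --- stage 6: trends and trajectories --------------------------------
  trendOut <- runStage("trends", {
    trendRows <- list(); cmpRows <- list(); trajRows <- list()
    elites <- list()
    for (tr in traits) {
      g <- gcaLines(caBlup[[tr]])
      rep <- gcaTrend(g, eraMap, trait = tr, test = config$trend$test)
      trendRows[[tr]] <- tidyReport(rep)
      cmpRows[[tr]] <- rep$comparisons
      hits <- gwasOut$res[[tr]]$hits
      for (s in hits$snp) {
        tj <- alleleTrajectory(gwasOut$qc$panel, eraMap, s, g,
                               test = config$trend$test)
        trajRows[[paste(tr, s)]] <- cbind(trait = tr, tidyReport(tj))
        fav <- (config$favorability %||% list())[[tr]] %||% "high"
        elites[[paste(tr, s)]] <- cbind(trait = tr,
                                        eliteAlleleReport(tj, fav))
      }
    }
    gm <- sapply(caBlup, gcaLines)
    corr <- if (is.matrix(gm) && ncol(gm) >= 2) gcaCorrelationMatrix(gm)
            else NULL
    list(trend = do.call(rbind, c(trendRows, make.row.names = FALSE)),
         cmp = do.call(rbind, c(cmpRows, make.row.names = FALSE)),
         traj = if (length(trajRows))
           do.call(rbind, c(trajRows, make.row.names = FALSE)) else NULL,
         elites = if (length(elites))
           do.call(rbind, c(elites, make.row.names = FALSE)) else NULL,
         corr = corr)
  })
  write.csv(trendOut$trend, file.path(outDir, "gca_trend_summary.csv"),
            row.names = FALSE)
  write.csv(trendOut$cmp, file.path(outDir, "gca_trend_tests.csv"),
            row.names = FALSE)
  if (!is.null(trendOut$traj))
    write.csv(trendOut$traj, file.path(outDir, "allele_trajectories.csv"),
              row.names = FALSE)
  if (!is.null(trendOut$elites))
    write.csv(trendOut$elites, file.path(outDir, "elite_alleles.csv"),
              row.names = FALSE)
  if (!is.null(trendOut$corr))
    write.csv(data.frame(trait = rownames(trendOut$corr$r), trendOut$corr$r,
                         check.names = FALSE),
              file.path(outDir, "gca_correlations.csv"), row.names = FALSE)

  # --- manifest ---------------------------------------------------------
  outFiles <- list.files(outDir, full.names = TRUE)
  outFiles <- outFiles[!grepl("manifest\\.json$", outFiles)]
  manifest$stages <- stageDone
  manifest$outputs <- as.list(stats::setNames(outFiles, basename(outFiles)))
  manifest$output_hashes <- as.list(tools::md5sum(outFiles))
  manifest$package_version <- as.character(utils::packageVersion("nciiGCA"))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(manifest)
}
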