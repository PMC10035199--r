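#' Pipeline configuration
#'
#' Bundles a simulation configuration (or paths to an existing peptide
#' report and validation statistics) with all stage parameters and a
#' single global seed. Every stage derives its own sub-seed from the
#' global one, so a run is fully reproducible.
#'
#' @param sim a [simConfig()] object, or `NULL` when `report_path` is
#'   given.
#' @param report_path optional path to a peptide report TSV.
#' @param validation_paths optional named character vector of validation
#'   contrast TSVs (used instead of simulated validation cohorts).
#' @param contrasts list of `c(case, reference)` pairs; `NULL` derives
#'   all case-vs-control and case-vs-case pairs from the groups present.
#' @param n_validation_cohorts number of simulated validation cohorts
#'   (default 2; ignored when `validation_paths` is given; 0 skips the
#'   validation stage).
#' @param soft_power soft-thresholding power (default 7).
#' @param min_size,deep_split module detection parameters.
#' @param fdr_levels FDR levels mapped to p-value thresholds.
#' @param gsea_sets number of synthetic annotation terms for the
#'   enrichment stage (0 skips it).
#' @param n_perm_gsea,n_perm_gess,n_perm_hotnet,n_boot permutation and
#'   bootstrap counts.
#' @param edge_threshold,beta module-graph and diffusion parameters.
#' @param gess_thresholds GESS p-value thresholds.
#' @param seed global integer seed.
#' @return a `PipelineConfig` (validated list).
#' @export
pipelineConfig <- function(sim = simConfig(),
                           report_path = NULL,
                           validation_paths = NULL,
                           contrasts = NULL,
                           n_validation_cohorts = 2L,
                           soft_power = 7L,
                           min_size = 15L,
                           deep_split = 2L,
                           fdr_levels = c(0.05, 0.1, 0.2),
                           gsea_sets = 40L,
                           n_perm_gsea = 1000L,
                           n_perm_gess = 1000L,
                           n_perm_hotnet = 100L,
                           n_boot = 20000L,
                           edge_threshold = 0.5,
                           beta = 0.5,
                           gess_thresholds = c(0.1, 0.2, 0.5, 0.8),
                           seed = 1L) {
  if (is.null(sim) && is.null(report_path))
    stop("either a simulation config or a report path is required")
  if (!is.null(report_path) && !file.exists(report_path))
    stop("missing input file: ", report_path)
  if (!is.null(validation_paths) && !all(file.exists(validation_paths)))
    stop("missing input file: ",
         paste(validation_paths[!file.exists(validation_paths)],
               collapse = ", "))
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; an optional
#' `sim:` block holds [simConfig()] arguments.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  y$sim <- NULL
  sim <- if (is.null(simArgs)) simConfig() else {
    if (!is.null(simArgs$n_per_case))
      simArgs$n_per_case <- unlist(simArgs$n_per_case)
    do.call(simConfig, simArgs)
  }
  do.call(pipelineConfig, c(list(sim = sim), y))
}

.logStage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste(sprintf(...), collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> quantify -> differential abundance (+ BUM
#' thresholds, sample clustering) -> module detection -> module
#' dysregulation -> enrichment -> hot subnetworks -> cross-cohort GESS
#' validation -> cell-type enrichment. All artifacts are written as TSV
#' or JSON under `out_dir`, and a machine-readable run report
#' (parameters, per-stage counts, file digests) is returned and written
#' as `report.json`. Rerunning with an identical configuration and seed
#' reproduces byte-identical artifacts.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @return the run report (list, invisibly the same as `report.json`).
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log <- character()
  report <- list(parameters = list(seed = seed,
                                   soft_power = config$soft_power,
                                   min_size = config$min_size,
                                   edge_threshold = config$edge_threshold,
                                   beta = config$beta),
                 counts = list(), stages = character())

  ## stage: input (simulate or load)
  truth <- NULL
  if (!is.null(config$report_path)) {
    pepReport <- readPeptideReport(config$report_path)
    log <- .logStage(log, "input", "loaded %d peptide records",
                     nrow(pepReport))
  } else {
    sim <- simulatePeptideReport(config$sim, seed = seed)
    pepReport <- sim$report
    truth <- sim$truth
    writePeptideReport(pepReport, file.path(out_dir, "peptide_report.tsv"))
    jsonlite::write_json(
      list(module_of = as.list(truth$module_of),
           concordant_modules = truth$concordant_modules),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      pretty = TRUE)
    log <- .logStage(log, "simulate", "%d peptide records, %d proteins",
                     nrow(pepReport), config$sim$n_proteins)
  }
  report$stages <- c(report$stages, "input")

  ## stage: quantify
  se <- quantifyProteins(pepReport)
  writeProteinMatrix(se, file.path(out_dir, "protein_matrix"))
  report$counts$proteins_quantified <- nrow(se)
  report$counts$samples <- ncol(se)
  log <- .logStage(log, "quantify", "%d proteins x %d samples",
                   nrow(se), ncol(se))
  report$stages <- c(report$stages, "quantify")

  ## stage: differential abundance
  groups <- unique(as.character(se$group))
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    cases <- setdiff(groups, "control")
    contrasts <- lapply(cases, function(g) c(g, "control"))
    if (length(cases) >= 2L)
      contrasts <- c(contrasts, list(cases[1:2]))
  }
  names(contrasts) <- vapply(contrasts, paste, character(1),
                             collapse = "_vs_")
  diffres <- list()
  bumInfo <- list()
  for (nm in names(contrasts)) {
    res <- betaBinomialTest(se, contrasts[[nm]])
    diffres[[nm]] <- res
    writeContrast(res, file.path(out_dir, paste0("contrast_", nm, ".tsv")))
    fit <- fitBum(res$pvalue)
    taus <- vapply(config$fdr_levels, function(f) fdrThreshold(fit, f),
                   numeric(1))
    names(taus) <- paste0("fdr_", config$fdr_levels)
    nsig <- vapply(taus, function(tau) sum(res$pvalue <= tau), integer(1))
    bumInfo[[nm]] <- list(lambda = fit@lambda, a = fit@a,
                          pi_ub = piUpperBound(fit),
                          thresholds = as.list(taus),
                          n_significant = as.list(nsig))
    log <- .logStage(log, "diffexp",
                     "%s: pi_ub %.3f; significant at %s: %s", nm,
                     piUpperBound(fit),
                     paste(names(taus), collapse = "/"),
                     paste(nsig, collapse = "/"))
  }
  jsonlite::write_json(bumInfo, file.path(out_dir, "bum_fits.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  clust <- clusterSamples(se, diffres)
  writeLines(clust$sampleTree$labels[clust$sampleTree$order],
             file.path(out_dir, "sample_cluster_order.txt"))
  report$counts$contrasts <- length(diffres)
  report$stages <- c(report$stages, "diffexp")

  ## stage: modules
  similarity <- buildSimilarity(se, config$soft_power)
  assignment <- detectModules(similarity, config$min_size,
                              config$deep_split)
  writeModuleAssignment(assignment, file.path(out_dir, "modules.tsv"))
  nModules <- length(setdiff(names(moduleSizes(assignment)), "M00"))
  report$counts$modules_detected <- nModules
  log <- .logStage(log, "modules", "%d modules (min size %d)",
                   nModules, config$min_size)
  modStats <- list()
  for (nm in names(diffres)) {
    st <- testModuleDysregulation(assignment, diffres[[nm]])
    st$contrast <- nm
    modStats[[nm]] <- st
  }
  modStatsAll <- do.call(rbind, modStats)
  data.table::fwrite(modStatsAll, file.path(out_dir, "module_stats.tsv"),
                     sep = "\t")
  primary <- names(diffres)[1]
  report$counts$modules_dysregulated <-
    sum(modStats[[primary]]$dysregulated)
  report$stages <- c(report$stages, "module_stats")

  ## stage: enrichment (needs ground truth for synthetic annotation sets)
  if (!is.null(truth) && config$gsea_sets > 0L) {
    sets <- simulateAnnotationSets(truth, n_terms = config$gsea_sets,
                                   seed = seed + 1L)
    writeGmt(sets, file.path(out_dir, "annotation_sets.gmt"))
    background <- rownames(se)
    oraTop <- lapply(setdiff(names(moduleSizes(assignment)), "M00"),
                     function(m) {
      res <- goOverrepresentation(moduleMembers(assignment, m), sets,
                                  background)
      cbind(module = m, head(res, 3L))
    })
    data.table::fwrite(do.call(rbind, oraTop),
                       file.path(out_dir, "module_ora.tsv"), sep = "\t")
    rnk <- setNames(diffres[[primary]]$log2fc, diffres[[primary]]$protein)
    writeRnk(rnk, file.path(out_dir, paste0(primary, ".rnk")))
    gsea <- gseaPreranked(rnk, sets, n_perm = config$n_perm_gsea,
                          seed = seed + 2L)
    data.table::fwrite(gsea, file.path(out_dir, "gsea.tsv"), sep = "\t")
    log <- .logStage(log, "enrichment", "%d sets, %d GSEA rows",
                     length(sets), nrow(gsea))
    report$stages <- c(report$stages, "enrichment")
  }

  ## stage: hot subnetworks (primary contrast scores)
  scores <- vertexScores(diffres[[primary]])
  subnetRows <- list()
  for (m in setdiff(names(moduleSizes(assignment)), "M00")) {
    members <- moduleMembers(assignment, m)
    g <- suppressWarnings(
      buildModuleGraph(se, members, config$edge_threshold))
    hn <- findHotSubnetworks(g, scores[members], beta = config$beta,
                             n_perm = config$n_perm_hotnet,
                             seed = seed + 3L)
    subnets <- hotSubnetworks(hn)
    if (length(subnets)) {
      writeSubnetworks(hn, g, file.path(out_dir, paste0("subnet_", m)))
      subnetRows[[m]] <- data.frame(
        module = m, subnetwork_size = length(subnets[[1]]),
        permutation_p = hn@permutationP)
    }
  }
  subnetTab <- if (length(subnetRows)) do.call(rbind, subnetRows) else
    data.frame(module = character(), subnetwork_size = integer(),
               permutation_p = numeric())
  data.table::fwrite(subnetTab, file.path(out_dir, "subnetworks.tsv"),
                     sep = "\t")
  report$counts$subnetworks_found <- nrow(subnetTab)
  log <- .logStage(log, "subnet", "%d modules with a hot subnetwork",
                   nrow(subnetTab))
  report$stages <- c(report$stages, "subnetworks")

  ## stage: GESS validation
  validations <- list()
  if (!is.null(config$validation_paths)) {
    validations <- lapply(config$validation_paths, readContrast)
  } else if (!is.null(truth) && config$n_validation_cohorts > 0L) {
    for (ci in seq_len(config$n_validation_cohorts))
      validations[[paste0("cohort", ci)]] <-
        simulateValidationStats(truth, config$sim, seed = seed + 10L + ci)
  }
  if (length(validations)) {
    gess <- validateAllModules(assignment, diffres[[primary]],
                               validations, seed = seed + 20L,
                               thresholds = config$gess_thresholds,
                               n_perm = config$n_perm_gess)
    data.table::fwrite(gess, file.path(out_dir, "gess.tsv"), sep = "\t")
    report$counts$modules_validated <-
      sum(tapply(gess$validated, gess$module, any))
    log <- .logStage(log, "gess", "%d modules validated in >=1 cohort",
                     report$counts$modules_validated)
    report$stages <- c(report$stages, "gess")
  } else {
    log <- .logStage(log, "gess", "skipped (no validation cohort)")
    report$counts$modules_validated <- NA
  }

  ## stage: cell-type enrichment
  if (!is.null(truth)) {
    ct <- simulateCelltypeInputs(truth, config$sim, seed = seed + 30L)
    spec <- computeSpecificity(ct$expression)
    background <- intersect(rownames(se), rownames(spec))
    ewceRows <- list()
    dirRows <- list()
    for (m in setdiff(names(moduleSizes(assignment)), "M00")) {
      members <- intersect(moduleMembers(assignment, m), background)
      if (length(members) < 3L) next
      ew <- ewceBootstrap(members, spec, background,
                          n_boot = config$n_boot, seed = seed + 40L)
      ewceRows[[m]] <- cbind(module = m, ew)
      dr <- suppressWarnings(markerDirectionEnrichment(
        members, diffres[[primary]], ct$markers))
      if (nrow(dr)) dirRows[[m]] <- cbind(module = m, dr)
    }
    if (length(ewceRows))
      data.table::fwrite(do.call(rbind, ewceRows),
                         file.path(out_dir, "ewce.tsv"), sep = "\t")
    if (length(dirRows))
      data.table::fwrite(do.call(rbind, dirRows),
                         file.path(out_dir, "celltype_direction.tsv"),
                         sep = "\t")
    log <- .logStage(log, "ewce", "%d modules profiled",
                     length(ewceRows))
    report$stages <- c(report$stages, "celltype")
  }

  ## report with artifact digests
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "report.json"]
  report$digests <- as.list(tools::md5sum(files))
  names(report$digests) <- basename(files)
  report$log <- log
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
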