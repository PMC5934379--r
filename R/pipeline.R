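#' Pipeline configuration
#'
#' Flat configuration for [runPipeline()]: input paths, module parameters
#' and the seed. All defaults are embedded; the effective configuration is
#' stamped (seed + MD5 hash) into every JSON artifact for reproducibility.
#'
#' @param outdir output directory (stage artifacts are written to
#'   `outdir/{simulate,model,preprocess,selection,report}`).
#' @param seed integer seed used by every stochastic stage.
#' @param inputs named list of input paths (`sets`, `edges`, `annotations`,
#'   `exprGenes`, `exprProbes`, `probe2gene`, `cohort`); the simulate stage
#'   fills these in.
#' @param mcode MCODE parameters ([mcodeParams()]).
#' @param enrichMode,enrichBackground,qThreshold enrichment options.
#' @param summarizeStat,outlierSD,inputScale preprocessing options.
#' @param sa simulated annealing configuration ([saConfig()]).
#' @param alpha significance threshold for pruning.
#' @param quasiNested allow the quasi-nested ANOVA fallback when the
#'   selected combined model does not strictly nest the clinical one.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(outdir, seed = 1L, inputs = list(),
                           mcode = mcodeParams(),
                           enrichMode = "standard",
                           enrichBackground = "annotation",
                           qThreshold = 0.05,
                           summarizeStat = "median", outlierSD = 3,
                           inputScale = "log2",
                           sa = saConfig(seed = seed),
                           alpha = 0.05, quasiNested = TRUE) {
  structure(list(outdir = outdir, seed = as.integer(seed), inputs = inputs,
                 mcode = mcode, enrichMode = enrichMode,
                 enrichBackground = enrichBackground,
                 qThreshold = qThreshold, summarizeStat = summarizeStat,
                 outlierSD = outlierSD, inputScale = inputScale, sa = sa,
                 alpha = alpha, quasiNested = quasiNested),
            class = "PipelineConfig")
}

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[setdiff(names(config),
                                             c("outdir", "inputs",
                                               "results"))],
                              auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.writeJSON <- function(x, path, config) {
  x$seed <- config$seed
  x$config_md5 <- .configHash(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets named list, set name -> gene id vector.
#' @param path output path.
#' @param description description field (recycled).
#' @return the path, invisibly.
#' @export
writeGeneSetsGMT <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects the clinical column dictionary used throughout the package:
#' `sample_id, donor_age, donor_gender (m/f), last_donor_creatinine,
#' cold_ischemia_time, recipient_age, recipient_gender (m/f),
#' transplantation_number (1st/2nd), panel_reactive_antibodies
#' (0%, <20%, >20%, NA), hla_mismatches (0-6), rejection (yes/no/NA),
#' dgf (0/1/2), egfr_12m`.
#'
#' @param path CSV path.
#' @return validated cohort data.frame.
#' @export
readCohortCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohort(d)
  rownames(d) <- d$sample_id
  d
}

#' @rdname readCohortCSV
#' @param cohort a cohort data.frame.
#' @export
validateCohort <- function(cohort) {
  need <- c("sample_id", "donor_age", "donor_gender",
            "last_donor_creatinine", "cold_ischemia_time", "recipient_age",
            "recipient_gender", "transplantation_number",
            "panel_reactive_antibodies", "hla_mismatches", "rejection",
            "dgf", "egfr_12m")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (any(cohort$donor_age <= 0) || any(cohort$recipient_age <= 0))
    stop("ages must be positive")
  if (any(cohort$egfr_12m < 0, na.rm = TRUE)) stop("egfr_12m must be >= 0")
  if (!all(cohort$dgf %in% c(0, 1, 2))) stop("dgf must be 0, 1 or 2")
  invisible(TRUE)
}

.stageDir <- function(config, stage) {
  d <- file.path(config$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the analysis pipeline
#'
#' Orchestrates the workflow stages behind a single entry point. Commands:
#' \describe{
#'   \item{simulate}{generate all synthetic inputs plus a ground-truth
#'     JSON under `outdir/simulate` and register them in the config.}
#'   \item{build-model}{feature catalog -> induced subgraph -> MCODE ->
#'     enrichment; writes clusters, enrichment and a stage-count summary.}
#'   \item{preprocess}{quantile normalization, probe-to-gene summarization,
#'     outlier flagging of the probe-level matrix.}
#'   \item{select-model}{exhaustive clinical search, simulated-annealing
#'     marker selection, pruning, nested ANOVA, correlation matrix,
#'     post-operative add-on analysis.}
#'   \item{report}{consolidates the stage summaries into one report.}
#' }
#' Every JSON artifact is stamped with the seed and a hash of the
#' configuration; rerunning with an identical config and seed reproduces
#' artifacts byte for byte.
#'
#' @param command one of `"simulate"`, `"build-model"`, `"preprocess"`,
#'   `"select-model"`, `"report"`.
#' @param config a [pipelineConfig()] list.
#' @return the (possibly updated) config, invisibly, with stage results in
#'   `config$results`.
#' @export
runPipeline <- function(command = c("simulate", "build-model", "preprocess",
                                    "select-model", "report"),
                        config) {
  command <- match.arg(command)
  stopifnot(inherits(config, "PipelineConfig"))
  switch(command,
         "simulate" = .stageSimulate(config),
         "build-model" = .stageBuildModel(config),
         "preprocess" = .stagePreprocess(config),
         "select-model" = .stageSelectModel(config),
         "report" = .stageReport(config))
}

.stageSimulate <- function(config) {
  d <- .stageDir(config, "simulate")
  seed <- config$seed
  net <- simulatePlantedGraph(seed = seed)
  ann <- simulateAnnotations(V(net$graph)$name,
                             planted = setNames(net$clusters,
                                                paste0("PLANTED",
                                                       seq_along(net$clusters))),
                             seed = seed)
  sig <- simulateSignatureSets(net$clusters,
                               backgroundGenes = grep("^BG",
                                                      V(net$graph)$name,
                                                      value = TRUE),
                               graph = net$graph, seed = seed)
  cs <- simulateCohort(seed = seed)
  pr <- simulateProbeLevel(cs$markers, seed = seed)

  edges <- igraph::as_edgelist(net$graph)
  write.table(data.frame(from = edges[, 1], to = edges[, 2]),
              file.path(d, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeGeneSetsGMT(sig$sets, file.path(d, "signature_sets.gmt"))
  writeGeneSetsGMT(annotationTerms(ann), file.path(d, "annotations.gmt"))
  writeExpressionTSV(cs$markers, file.path(d, "expression_genes.tsv"))
  writeExpressionTSV(pr$probes, file.path(d, "expression_probes.tsv"))
  write.table(data.frame(probe = names(pr$probe2gene),
                         gene = unname(pr$probe2gene)),
              file.path(d, "probe2gene.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  utils::write.csv(cs$cohort, file.path(d, "cohort.csv"), row.names = FALSE)
  .writeJSON(list(
    planted_clusters = net$clusters,
    expected_retained = sig$expectedRetained,
    causal_markers = cs$truth$causal,
    planted_betas = as.list(cs$truth$betas),
    noise_sd = cs$truth$sigma,
    population_r2 = cs$truth$populationR2,
    clinical_r2 = cs$truth$clinicalR2,
    planted_outliers = pr$outlierIds),
    file.path(d, "truth.json"), config)
  config$inputs <- list(
    sets = file.path(d, "signature_sets.gmt"),
    edges = file.path(d, "edges.tsv"),
    annotations = file.path(d, "annotations.gmt"),
    exprGenes = file.path(d, "expression_genes.tsv"),
    exprProbes = file.path(d, "expression_probes.tsv"),
    probe2gene = file.path(d, "probe2gene.tsv"),
    cohort = file.path(d, "cohort.csv"))
  invisible(config)
}

.checkInput <- function(config, key) {
  p <- config$inputs[[key]]
  if (is.null(p) || !file.exists(p))
    stop("missing pipeline input '", key, "'",
         if (!is.null(p)) paste0(": ", p))
  p
}

.stageBuildModel <- function(config) {
  d <- .stageDir(config, "model")
  sets <- parseGeneSets(.checkInput(config, "sets"))
  net <- loadEdgeList(.checkInput(config, "edges"))
  ann <- readAnnotationGMT(.checkInput(config, "annotations"))
  catalog <- mergeFeatureSets(sets)
  model <- buildMolecularModel(net, catalog, ann, params = config$mcode,
                               qThreshold = config$qThreshold,
                               mode = config$enrichMode,
                               background = config$enrichBackground)
  writeCatalog(catalog, file.path(d, "catalog.tsv"))
  writeClusters(model, file.path(d, "clusters.tsv"))
  write.table(enrichedTerms(model), file.path(d, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .writeJSON(list(stage_counts = as.list(stageCounts(model))),
             file.path(d, "model_summary.json"), config)
  config$results$model <- model
  invisible(config)
}

.stagePreprocess <- function(config) {
  d <- .stageDir(config, "preprocess")
  probes <- readExpressionTSV(.checkInput(config, "exprProbes"),
                              level = "probe",
                              log2Transform = config$inputScale == "raw")
  p2g <- read.delim(.checkInput(config, "probe2gene"),
                    stringsAsFactors = FALSE)
  norm <- quantileNormalize(probes)
  genes <- summarizeToGene(norm, p2g, stat = config$summarizeStat)
  fl <- flagOutlierSamples(genes, thresholdSD = config$outlierSD)
  keep <- setdiff(colnames(assay(genes)), fl$flagged)
  out <- genes[, keep]
  writeExpressionTSV(out, file.path(d, "expression_gene_level.tsv"))
  write.table(data.frame(sample_id = names(fl$meanCor),
                         mean_correlation = fl$meanCor,
                         flagged = names(fl$meanCor) %in% fl$flagged),
              file.path(d, "outliers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  .writeJSON(list(n_probes = nrow(assay(probes)),
                  n_genes = nrow(assay(genes)),
                  n_samples_in = ncol(assay(probes)),
                  n_samples_retained = length(keep),
                  flagged = fl$flagged, cutoff = fl$cutoff),
             file.path(d, "preprocess_summary.json"), config)
  config$results$preprocess <- list(expression = out, flagged = fl$flagged)
  invisible(config)
}

.coefList <- function(fit) {
  co <- coefTable(fit)
  lapply(rownames(co), function(r)
    list(predictor = r, estimate = co[r, "estimate"], p = co[r, "p"]))
}

.stageSelectModel <- function(config) {
  d <- .stageDir(config, "selection")
  cohort <- readCohortCSV(.checkInput(config, "cohort"))
  markers <- readExpressionTSV(.checkInput(config, "exprGenes"),
                               level = "gene")
  mk <- assay(markers)[, cohort$sample_id, drop = FALSE]

  clin <- bestClinicalModel(cohort)
  candidates <- c(clinicalCandidates(), rownames(mk))
  sa <- config$sa
  sa$seed <- config$seed
  comb <- saSubsetSearch(candidates, cohort, markers = mk, config = sa)
  comb <- pruneNonsignificant(comb, alpha = config$alpha)

  cmp <- NULL
  if (clin$fit@n == comb@n &&
      isTRUE(all.equal(clin$fit@response, comb@response))) {
    nested <- all(clin$fit@predictors %in% comb@predictors)
    if (nested || config$quasiNested)
      cmp <- anovaNested(clin$fit, comb, quasi = !nested)
  }

  contVars <- cohort[, c("donor_age", "recipient_age",
                         "last_donor_creatinine", "cold_ischemia_time")]
  mkSel <- intersect(comb@predictors, rownames(mk))
  cm <- correlationMatrixBonferroni(cbind(contVars,
                                          t(mk[mkSel, , drop = FALSE])))
  postop <- postopAddonAnalysis(comb, cohort, markers = mk,
                                alpha = config$alpha)

  writeModelTSV <- function(fit, path) {
    co <- coefTable(fit)
    write.table(data.frame(predictor = rownames(co),
                           estimate = co[, "estimate"], p = co[, "p"]),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeModelTSV(clin$fit, file.path(d, "clinical_model.tsv"))
  writeModelTSV(comb, file.path(d, "combined_model.tsv"))
  write.table(data.frame(cm$r, check.names = FALSE),
              file.path(d, "correlations.tsv"), sep = "\t", quote = FALSE)
  maxAbsMarkerR <- if (length(mkSel) > 1) {
    sub <- cm$r[mkSel, mkSel]
    max(abs(sub[upper.tri(sub)]))
  } else NA_real_
  .writeJSON(list(
    clinical = list(predictors = clin$fit@predictors,
                    coefficients = .coefList(clin$fit),
                    adj_r2 = adjR2(clin$fit),
                    loocv_r2 = loocvR2(clin$fit),
                    loocv_rmse = loocvRMSE(clin$fit),
                    overall_p = fitPValue(clin$fit), n = clin$fit@n),
    combined = list(predictors = comb@predictors,
                    coefficients = .coefList(comb),
                    adj_r2 = adjR2(comb), loocv_r2 = loocvR2(comb),
                    loocv_rmse = loocvRMSE(comb),
                    overall_p = fitPValue(comb), n = comb@n),
    anova_clinical_vs_combined = cmp,
    marker_correlation_gate = list(
      max_abs_marker_r = maxAbsMarkerR,
      passes_0.5_rule = isTRUE(maxAbsMarkerR <= 0.5)),
    postop = list(
      dgf = postop$dgf[c("adjR2Base", "adjR2Augmented", "deltaAdjR2")],
      dgf_anova_p = postop$dgf$anova$p,
      rejection = postop$rejection[c("adjR2Base", "adjR2Augmented",
                                     "deltaAdjR2")],
      rejection_anova_p = postop$rejection$anova$p)),
    file.path(d, "model_summary.json"), config)
  config$results$selection <- list(clinical = clin, combined = comb,
                                   anova = cmp, correlations = cm,
                                   postop = postop)
  invisible(config)
}

.stageReport <- function(config) {
  d <- .stageDir(config, "report")
  stages <- c(simulate = "simulate/truth.json",
              model = "model/model_summary.json",
              preprocess = "preprocess/preprocess_summary.json",
              selection = "selection/model_summary.json")
  found <- list()
  for (s in names(stages)) {
    p <- file.path(config$outdir, stages[[s]])
    if (file.exists(p)) found[[s]] <- jsonlite::read_json(p)
  }
  if (!length(found))
    stop("report: no stage artifacts found under ", config$outdir)
  .writeJSON(list(stages = found), file.path(d, "report.json"), config)
  lines <- c("donorNet pipeline report", "=======================")
  if (!is.null(found$model))
    lines <- c(lines, "", "Molecular model stage counts:",
               vapply(names(found$model$stage_counts), function(k)
                 sprintf("  %-20s %s", k, found$model$stage_counts[[k]]),
                 character(1)))
  if (!is.null(found$selection))
    lines <- c(lines, "",
               sprintf("Clinical model adj R2:  %.3f",
                       found$selection$clinical$adj_r2),
               sprintf("Combined model adj R2:  %.3f",
                       found$selection$combined$adj_r2))
  writeLines(lines, file.path(d, "report.txt"))
  invisible(config)
}
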