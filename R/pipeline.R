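#' @importFrom tools md5sum
#' @importFrom utils packageVersion head write.csv
NULL

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(md5sum(f))
}

.writeManifest <- function(outdir, stage, config, seed, files) {
  manifest <- list(stage = stage, seed = seed,
                   config_hash = .hashObject(config),
                   package_version = as.character(packageVersion("CSFPeptidomics")),
                   r_version = R.version.string,
                   files = as.list(md5sum(files)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## Default PRM panel drawn from a simulated dataset: planted-effect
## peptides first, padded with well-observed ones; 10 transitions each.
.defaultPanel <- function(catalog, trueState, obsFrac, nPeptides = 8L,
                          nTransitions = 10L) {
  well <- names(obsFrac)[obsFrac >= 0.8]
  pref <- intersect(trueState$differentialSet, well)
  obsOk <- intersect(names(sort(obsFrac, decreasing = TRUE)),
                     catalog$peptide_id[!catalog$is_standard])
  ids <- head(unique(c(pref, obsOk)), nPeptides)
  lapply(ids, function(pid) {
    list(peptide_id = pid,
         transitions = data.frame(
           transition = sprintf("%s_y%d", pid, seq_len(nTransitions)),
           rel_intensity = exp(-(seq_len(nTransitions) - 1) / 4)),
         reference_rt = 10 + (match(pid, ids) - 1) * 2.5)
  })
}

#' Simulate a complete dataset to disk
#'
#' Generates the proteome, peptide catalog, cohort quantification matrix,
#' clinical covariates and a transition-level PRM report from one
#' [SimConfig()], and writes them as plain-text files (FASTA, TSV, CSV,
#' JSON) plus a manifest with file digests sufficient to verify an exact
#' reproduction.
#'
#' @param config a [SimConfig()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
runSimulate <- function(config, outdir) {
  validObject(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  proteins <- simulateProteome(config@nProteins, config@seed)
  sim <- simulatePeptidome(proteins, config)
  pe <- simulateCohort(sim$catalog, sim$trueState, config)
  clinical <- simulateClinical(pe, config)

  ## PRM report over a small panel, light ratios from the cohort signal
  obsFrac <- rowMeans(!is.na(abundance(pe)))
  panel <- .defaultPanel(sim$catalog, sim$trueState, obsFrac)
  panelIds <- vapply(panel, `[[`, character(1), "peptide_id")
  ab <- abundance(pe)[panelIds, , drop = FALSE]
  ref <- rowMeans(ab, na.rm = TRUE)
  ratios <- t(ab / ref)
  below <- which(is.na(ratios), arr.ind = TRUE)
  belowLimit <- if (nrow(below))
    data.frame(sample_id = rownames(ratios)[below[, 1]],
               peptide_id = colnames(ratios)[below[, 2]]) else NULL
  ratios[is.na(ratios)] <- 1  # placeholder; these samples emit no light peak
  prmReport <- simulatePRM(panel, ratios, seed = config@seed,
                           belowLimit = belowLimit)

  paths <- c(
    fasta = file.path(outdir, "proteins.fasta"),
    catalog = file.path(outdir, "peptide_catalog.tsv"),
    quant = file.path(outdir, "quant_matrix.tsv"),
    samples = file.path(outdir, "sample_sheet.tsv"),
    prm = file.path(outdir, "prm_report.csv"),
    truth = file.path(outdir, "true_state.json"),
    panel = file.path(outdir, "panel.json"))
  writeXStringSet(proteins, paths["fasta"])
  write.table(sim$catalog, paths["catalog"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  writeQuantTable(pe, paths["quant"])
  ss <- merge(as.data.frame(colData(pe)), clinical[, setdiff(colnames(clinical), "group")],
              by = "sample_id", sort = FALSE)
  write.table(ss, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.csv(prmReport, paths["prm"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(log10Mean = as.list(sim$trueState$log10Mean),
         groupFold = as.data.frame(sim$trueState$groupFold),
         trypticFlag = as.list(sim$trueState$trypticFlag),
         differentialSet = sim$trueState$differentialSet,
         standardIds = config@standardIds),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(panel, paths["panel"], auto_unbox = TRUE, digits = NA)
  cfgList <- list(seed = config@seed, nProteins = config@nProteins,
                  nPeptides = config@nPeptides,
                  nPerGroup = as.list(config@nPerGroup),
                  dynamicRangeOrders = config@dynamicRangeOrders,
                  technicalCV = config@technicalCV)
  .writeManifest(outdir, "simulate", cfgList, config@seed, paths)
  invisible(list(proteins = proteins, catalog = sim$catalog,
                 trueState = sim$trueState, pe = pe, clinical = clinical,
                 prmReport = prmReport, panel = panel, paths = paths))
}

#' Run the discovery-stage analysis on a dataset directory
#'
#' Normalization, QC metrics, dynamic range, differential analysis with
#' permutation FDR, tryptic-like statistics, the candidate-criteria
#' union and (when possible) the clustering/PCA separation summary; all
#' tables are written under `outdir` with a manifest.
#'
#' @param datasetDir directory written by [runSimulate()] (or files of
#'   the same layout).
#' @param params a [diffParams()].
#' @param groups character(2) test/reference group labels.
#' @param normalization `"stdpep"`, `"tic"` or `"none"`.
#' @param outdir output directory.
#' @param trypticMode `"and"` or `"or"`.
#' @return invisibly, a list of stage results.
#' @export
runDiscovery <- function(datasetDir, params = diffParams(),
                         groups = c("ALS", "Con"),
                         normalization = "stdpep",
                         outdir = file.path(datasetDir, "discovery"),
                         trypticMode = "and") {
  truth <- jsonlite::read_json(file.path(datasetDir, "true_state.json"),
                               simplifyVector = TRUE)
  pe <- readQuantTable(file.path(datasetDir, "quant_matrix.tsv"),
                       standardIds = truth$standardIds, verbose = TRUE)
  ss <- readSampleSheet(file.path(datasetDir, "sample_sheet.tsv"))
  catalog <- read.delim(file.path(datasetDir, "peptide_catalog.tsv"),
                        stringsAsFactors = FALSE, na.strings = "")
  colData(pe)$group <- ss$group[match(colnames(pe), ss$sample_id)]
  rd <- catalog[match(rownames(pe), catalog$peptide_id), ]
  rownames(rd) <- rownames(pe)
  rowData(pe) <- rd
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  norm <- normalizeQuant(pe, normalization)
  qc <- if (any(ss$group == "QC")) qcSummary(norm) else NULL
  dr <- dynamicRange(norm)

  prep <- prepareMatrix(norm, groups, params)
  imp <- imputeGaussian(prep$matrix, params)
  diff <- permutationFDR(imp, prep$labels, params)

  tstats <- trypticCounts(norm, catalog, mode = trypticMode)
  grpOfSample <- ss$group[match(tstats$sample_id, ss$sample_id)]
  tkeep <- grpOfSample %in% groups
  tcomp <- compareTryptic(tstats[tkeep, ], grpOfSample[tkeep])

  union <- runCriteriaUnion(norm, groups, params)
  sep <- NULL
  sig <- diff$peptide_id[diff$significant]
  if (length(sig) >= 2L)
    sep <- separationSummary(imp[sig, , drop = FALSE],
                             as.character(prep$labels),
                             controlLabel = groups[2])

  files <- c(diff = file.path(outdir, "differential_results.tsv"),
             tryp = file.path(outdir, "tryptic_stats.tsv"),
             union = file.path(outdir, "candidate_union.tsv"))
  write.table(diff, files["diff"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tstats, files["tryp"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(union, files["union"], sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_peptides_tested = nrow(diff), n_significant = sum(diff$significant),
    dynamic_range_orders = dr$orders,
    median_qc_cv = if (!is.null(qc)) qc$medianPeptideCVQC else NA,
    tryptic_p_count = tcomp$pCount, tryptic_p_percent = tcomp$pPercent,
    clustering_specificity = if (!is.null(sep)) sep$specificity else NA)
  jsonlite::write_json(summary, file.path(outdir, "discovery_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeManifest(outdir, "discovery",
                 list(params = unclass(params), groups = groups,
                      normalization = normalization),
                 params$seed, c(files, file.path(outdir, "discovery_summary.json")))
  invisible(list(pe = norm, qc = qc, dynamicRange = dr, differential = diff,
                 tryptic = tstats, trypticComparison = tcomp,
                 candidateUnion = union, separation = sep, summary = summary))
}

#' Run the validation-stage analysis on a dataset directory
#'
#' PRM light/heavy quantification with transition QC, group statistics,
#' per-peptide and combined-panel ROC, and (optionally) correlation with
#' an external assay; outputs written under `outdir` with a manifest.
#'
#' @param datasetDir dataset directory containing `prm_report.csv`,
#'   `sample_sheet.tsv` and `panel.json`.
#' @param panel optional panel list; defaults to `panel.json` in the
#'   dataset.
#' @param groups character(2) reference/test labels for the binary ROC,
#'   e.g. `c("Con", "ALS")` (the second label is the positive class).
#' @param outdir output directory.
#' @param external optional numeric vector named by sample id; external
#'   assay values to correlate with the first panel peptide.
#' @return invisibly, a list of stage results.
#' @export
runValidation <- function(datasetDir, panel = NULL,
                          groups = c("Con", "ALS"),
                          outdir = file.path(datasetDir, "validation"),
                          external = NULL) {
  if (is.null(panel)) {
    pf <- file.path(datasetDir, "panel.json")
    if (!file.exists(pf)) stop("no panel given and no panel.json in dataset")
    raw <- jsonlite::read_json(pf, simplifyVector = TRUE)
    panel <- lapply(seq_len(nrow(raw)), function(i)
      list(peptide_id = raw$peptide_id[i],
           transitions = as.data.frame(raw$transitions[[i]]),
           reference_rt = raw$reference_rt[i]))
  }
  report <- readPRMReport(file.path(datasetDir, "prm_report.csv"), verbose = TRUE)
  panelIds <- vapply(panel, `[[`, character(1), "peptide_id")
  unknown <- setdiff(panelIds, unique(report$peptide_id))
  if (length(unknown))
    stop("panel references peptide(s) absent from the PRM report: ",
         paste(unknown, collapse = ", "))
  ss <- readSampleSheet(file.path(datasetDir, "sample_sheet.tsv"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  prm <- quantifyPRM(report, panel)
  grp <- ss$group[match(rownames(prm$ratios), ss$sample_id)]
  keep <- grp %in% groups
  stats <- groupStats(prm$ratios[keep, , drop = FALSE],
                      factor(grp[keep], levels = groups))
  model <- rocCombined(prm$ratios[keep, , drop = FALSE],
                       factor(grp[keep], levels = groups),
                       positive = groups[2])
  corr <- NULL
  if (!is.null(external)) {
    v <- prm$ratios[keep, 1]
    corr <- correlateExternal(v, external[rownames(prm$ratios)[keep]])
  }
  files <- c(ratios = file.path(outdir, "prm_ratios.tsv"),
             stats = file.path(outdir, "group_stats.tsv"))
  writeQuantTable(t(prm$ratios), files["ratios"])
  write.table(stats, files["stats"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(peptides = model$peptides,
         coefficients = as.list(model$coefficients),
         combined_auc = model$combinedAUC, combined_ci = model$combinedCI,
         per_peptide = model$perPeptide, ridge = model$ridge,
         external_r = if (!is.null(corr)) corr$r else NULL),
    file.path(outdir, "panel_model.json"), auto_unbox = TRUE, digits = NA)
  .writeManifest(outdir, "validation", list(groups = groups), 0L,
                 c(files, file.path(outdir, "panel_model.json")))
  invisible(list(prm = prm, groupStats = stats, model = model,
                 correlation = corr))
}
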