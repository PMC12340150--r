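#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData rowData<- colData colData<-
NULL

## Closed set of sample group labels used throughout the workflow.
.GROUP_LABELS <- c("Con", "ALS", "sALS", "gALS", "C9orf72", "SOD1",
                   "AD", "bvFTD", "PD", "QC")

.NORM_STATES <- c("raw", "none", "tic", "stdpep", "log2")

#' Peptide-by-sample quantification container
#'
#' `PeptidomeExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with a declared
#' normalization state and the identities of the spike-in standard
#' peptides (StdPep). Rows are peptides, columns are samples; the single
#' assay `"abundance"` holds peak areas (`NA` = not detected, never zero).
#' `rowData` carries the peptide catalog columns (sequence, parent
#' accession, 1-based inclusive start/end, flanking residues, quality
#' score); `colData` carries the sample sheet (group, cohort, sex, age,
#' clinical covariates, run order).
#'
#' The normalization state may only move through the declared operations:
#' a matrix starts `"raw"`, [normalizeQuant()] sets `"none"`, `"tic"` or
#' `"stdpep"`, and [prepareMatrix()] sets `"log2"`.
#'
#' @slot ... inherited from SummarizedExperiment; state lives in
#'   `metadata(x)$normalizationState` and `metadata(x)$standardIds`.
#' @export
setClass("PeptidomeExperiment", contains = "SummarizedExperiment")

setValidity("PeptidomeExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "assay 'abundance' is required")
  st <- metadata(object)$normalizationState
  if (is.null(st) || length(st) != 1L || !st %in% .NORM_STATES)
    msg <- c(msg, sprintf("normalizationState must be one of %s",
                          paste(.NORM_STATES, collapse = ", ")))
  sid <- metadata(object)$standardIds
  if (!is.null(sid) && identical(st, "raw") &&
      !all(sid %in% rownames(object)))
    msg <- c(msg, "standardIds must be row names while the matrix is raw")
  if ("group" %in% colnames(colData(object))) {
    bad <- setdiff(unique(as.character(colData(object)$group)), .GROUP_LABELS)
    if (length(bad))
      msg <- c(msg, sprintf("unknown group label(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(.GROUP_LABELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptidomeExperiment
#'
#' @param abundance numeric matrix, peptides x samples; `NA` for
#'   non-detected entries. Row and column names are required.
#' @param rowData optional `DataFrame`/`data.frame` of peptide metadata.
#' @param colData optional `DataFrame`/`data.frame` of sample annotations;
#'   a `group` column must use the closed label set
#'   (Con, ALS, sALS, gALS, C9orf72, SOD1, AD, bvFTD, PD, QC).
#' @param standardIds character vector of spike-in standard peptide ids.
#' @param normalizationState one of `"raw"`, `"none"`, `"tic"`,
#'   `"stdpep"`, `"log2"`.
#' @return a `PeptidomeExperiment`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' pe <- PeptidomeExperiment(m)
#' normalizationState(pe)
#' @export
PeptidomeExperiment <- function(abundance, rowData = NULL, colData = NULL,
                                standardIds = character(),
                                normalizationState = "raw") {
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have row (peptide) and column (sample) names")
  args <- list(assays = list(abundance = abundance))
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment, args)
  metadata(se)$normalizationState <- normalizationState
  metadata(se)$standardIds <- as.character(standardIds)
  new("PeptidomeExperiment", se)
}

#' @describeIn PeptidomeExperiment normalization state accessor
#' @param x a `PeptidomeExperiment`
#' @export
normalizationState <- function(x) metadata(x)$normalizationState

#' @describeIn PeptidomeExperiment spike-in standard peptide ids
#' @export
standardIds <- function(x) metadata(x)$standardIds

#' @describeIn PeptidomeExperiment abundance assay accessor
#' @export
abundance <- function(x) assay(x, "abundance")

setMethod("show", "PeptidomeExperiment", function(object) {
  cat(sprintf("PeptidomeExperiment: %d peptides x %d samples [%s]\n",
              nrow(object), ncol(object), normalizationState(object)))
  nmiss <- sum(is.na(assay(object)))
  cat(sprintf("  missing entries: %d (%.1f%%); standards: %s\n",
              nmiss, 100 * nmiss / max(1, length(assay(object))),
              if (length(standardIds(object)))
                paste(standardIds(object), collapse = ", ") else "none"))
  if ("group" %in% colnames(colData(object))) {
    tab <- table(colData(object)$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(object)
})

#' Simulation configuration for the synthetic CSF peptidome generator
#'
#' Holds all knobs of the generative model; see [simulatePeptidome()] and
#' the package vignette for the model itself. Defaults emulate the
#' discovery-cohort design: 24 samples per group, ~10^4 peptides spanning
#' eight orders of magnitude of abundance, ~20% technical CV,
#' abundance-dependent (left-censored) missingness and five spike-in
#' standard peptides.
#'
#' @slot seed master seed; each generator stage derives its own stream
#'   from it by a fixed labeled offset.
#' @slot nProteins,nPeptides catalog sizes.
#' @slot nPerGroup named integer vector of samples per group label.
#' @slot dynamicRangeOrders log10 span of true mean abundances.
#' @slot technicalCV fraction in (0, 1): lognormal per-entry CV.
#' @slot sampleFactorCV CV of the global per-sample intensity factor
#'   (injection/loading variation) that StdPep normalization removes.
#' @slot effectTable data.frame with columns `peptide`, `group`, `fold`
#'   (fold >= 1 up or in (0,1] down is expressed as `fold` and
#'   `direction`); see [simulateCohort()].
#' @slot missingness numeric `c(midpoint, steepness)` of the logistic
#'   detection-probability curve in log10 abundance.
#' @slot standardIds,standardNominal,standardRunCV the five spike-in
#'   standards: ids, nominal log10 abundances, and the CV of the shared
#'   per-sample run factor they receive on top of the sample factor.
#' @slot trypticLikeFraction target fraction of tryptic-like peptides in
#'   the catalog; optionally named per group to plant a group difference
#'   in the observed fraction.
#' @slot clinicalEffects data.frame with columns `covariate`, `peptide`,
#'   `r` (target Spearman correlation).
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nProteins = "integer",
  nPeptides = "integer",
  nPerGroup = "integer",
  dynamicRangeOrders = "numeric",
  technicalCV = "numeric",
  sampleFactorCV = "numeric",
  effectTable = "data.frame",
  missingness = "numeric",
  standardIds = "character",
  standardNominal = "numeric",
  standardRunCV = "numeric",
  trypticLikeFraction = "numeric",
  clinicalEffects = "data.frame"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
  if (object@nPeptides < 1L) msg <- c(msg, "nPeptides must be >= 1")
  if (is.null(names(object@nPerGroup)) ||
      !all(names(object@nPerGroup) %in% .GROUP_LABELS))
    msg <- c(msg, "nPerGroup must be named with allowed group labels")
  if (any(object@nPerGroup < 2L))
    msg <- c(msg, "group sizes must be >= 2")
  if (object@technicalCV <= 0 || object@technicalCV >= 1)
    msg <- c(msg, "technicalCV must be in (0, 1)")
  if (nrow(object@effectTable) &&
      any(object@effectTable$fold <= 0))
    msg <- c(msg, "fold changes must be positive")
  if (length(object@missingness) != 2L || object@missingness[2] <= 0)
    msg <- c(msg, "missingness must be c(midpoint, steepness) with steepness > 0 (detection increasing with abundance)")
  if (any(object@trypticLikeFraction < 0 | object@trypticLikeFraction > 1))
    msg <- c(msg, "trypticLikeFraction must be in [0, 1]")
  if (nrow(object@clinicalEffects) && any(abs(object@clinicalEffects$r) > 1))
    msg <- c(msg, "clinical correlation targets must satisfy |r| <= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed integer master seed.
#' @param nProteins,nPeptides catalog sizes.
#' @param nPerGroup named integer vector, samples per group (>= 2 each).
#' @param dynamicRangeOrders log10 span of true mean abundances.
#' @param technicalCV per-entry lognormal CV, in (0, 1).
#' @param sampleFactorCV CV of the shared per-sample intensity factor.
#' @param effectTable data.frame(peptide, group, fold); empty = global null.
#' @param missingness c(midpoint on log10 scale, logistic steepness).
#' @param standardIds,standardNominal,standardRunCV spike-in standards.
#' @param trypticLikeFraction catalog tryptic-like target fraction,
#'   optionally named per group.
#' @param clinicalEffects data.frame(covariate, peptide, r).
#' @export
SimConfig <- function(seed = 1L,
                      nProteins = 200L,
                      nPeptides = 10000L,
                      nPerGroup = c(Con = 24L, ALS = 24L),
                      dynamicRangeOrders = 8,
                      technicalCV = 0.2,
                      sampleFactorCV = 0.25,
                      effectTable = data.frame(peptide = character(),
                                               group = character(),
                                               fold = numeric()),
                      missingness = c(midpoint = 1.5, steepness = 1.5),
                      standardIds = paste0("STD", 1:5),
                      standardNominal = seq(5, 7, length.out = 5),
                      standardRunCV = 0.05,
                      trypticLikeFraction = 0.25,
                      clinicalEffects = data.frame(covariate = character(),
                                                   peptide = character(),
                                                   r = numeric())) {
  new("SimConfig",
      seed = as.integer(seed), nProteins = as.integer(nProteins),
      nPeptides = as.integer(nPeptides),
      nPerGroup = structure(as.integer(nPerGroup), names = names(nPerGroup)),
      dynamicRangeOrders = dynamicRangeOrders, technicalCV = technicalCV,
      sampleFactorCV = sampleFactorCV, effectTable = effectTable, missingness = as.numeric(missingness),
      standardIds = standardIds, standardNominal = standardNominal,
      standardRunCV = standardRunCV,
      trypticLikeFraction = trypticLikeFraction,
      clinicalEffects = clinicalEffects)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d proteins, %d peptides, %s; %.0f orders, cv=%.2f, seed=%d\n",
    object@nProteins, object@nPeptides,
    paste(sprintf("%s=%d", names(object@nPerGroup), object@nPerGroup),
          collapse = "/"),
    object@dynamicRangeOrders, object@technicalCV, object@seed))
  invisible(object)
})
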