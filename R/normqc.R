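#' Normalize a quantification matrix
#'
#' Three declared methods, applied to a `raw` matrix only:
#' \describe{
#'   \item{`none`}{values unchanged; the state is marked so downstream
#'     stages know normalization was considered.}
#'   \item{`tic`}{each sample divided by its total observed (non-missing)
#'     signal, then rescaled by the mean total over samples so magnitudes
#'     are preserved.}
#'   \item{`stdpep`}{each sample divided by its spike-in factor: the
#'     median over the five standard peptides of (standard abundance in
#'     the sample / that standard's mean across samples). The median
#'     makes the factor robust to one aberrant standard. Standards stay
#'     in the matrix.}
#' }
#' The missingness pattern and peptide/sample identity are preserved by
#' all methods.
#'
#' @param pe a [PeptidomeExperiment] in state `"raw"`.
#' @param method `"none"`, `"tic"` or `"stdpep"`.
#' @param standardIds spike-in ids; defaults to those recorded in `pe`.
#' @return the normalized `PeptidomeExperiment`, with the per-sample
#'   factors in `metadata(.)$normFactor`.
#' @export
normalizeQuant <- function(pe, method = c("stdpep", "tic", "none"),
                           standardIds = NULL) {
  method <- match.arg(method)
  if (!identical(normalizationState(pe), "raw"))
    stop("normalize expects a raw matrix; state is ", normalizationState(pe))
  m <- abundance(pe)
  if (method == "none") {
    fac <- rep(1, ncol(m))
  } else if (method == "tic") {
    tot <- colSums(m, na.rm = TRUE)
    empty <- colnames(m)[colSums(!is.na(m)) == 0L]
    if (length(empty))
      stop("TIC normalization impossible for all-missing sample(s): ",
           paste(empty, collapse = ", "))
    fac <- tot / mean(tot)
  } else {
    sid <- if (is.null(standardIds)) standardIds(pe) else standardIds
    sid <- intersect(sid, rownames(m))
    if (length(sid) < 1L)
      stop("stdpep normalization requires >= 1 standard peptide in the matrix")
    std <- m[sid, , drop = FALSE]
    ref <- rowMeans(std, na.rm = TRUE)
    ratio <- std / ref
    fac <- apply(ratio, 2, median, na.rm = TRUE)
    bad <- colnames(m)[!is.finite(fac)]
    if (length(bad))
      stop("all standards missing in sample(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(m, 2, fac, "/")
  res <- .setAbundance(pe, out)
  metadata(res)$normalizationState <- method
  metadata(res)$normFactor <- structure(fac, names = colnames(m))
  validObject(res)
  res
}

## assay<- on the derived SE class, kept in one place
.setAbundance <- function(pe, m) {
  SummarizedExperiment::assay(pe, "abundance") <- m
  pe
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` on the given (linear) scale; missing values are
#' removed first. Scale-invariant: `computeCV(k * x) == computeCV(x)` for
#' `k > 0`.
#'
#' @param values numeric vector with >= 2 non-missing values and a
#'   positive mean.
#' @return percent CV.
#' @examples
#' computeCV(c(1, 2, 3))  # 50
#' @export
computeCV <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need >= 2 non-missing values")
  if (mean(v) <= 0) stop("CV undefined for non-positive mean")
  100 * sd(v) / mean(v)
}

#' Analytical QC summary
#'
#' Identification counts per sample (with their CV), the per-peptide CV
#' distribution over QC replicates (median reported), and the
#' standard-peptide CVs in QC and study samples — the metrics used to
#' compare normalization strategies.
#'
#' @param pe a [PeptidomeExperiment]; QC samples carry group `"QC"` in
#'   `colData` (or pass `qcSamples`).
#' @param qcSamples optional explicit QC sample ids.
#' @return list: `idCounts`, `idCountCV`, `peptideCVsQC` (vector),
#'   `medianPeptideCVQC`, `standardCVQC`, `standardCVStudy`.
#' @export
qcSummary <- function(pe, qcSamples = NULL) {
  m <- abundance(pe)
  if (is.null(qcSamples)) {
    if (!"group" %in% colnames(colData(pe)))
      stop("no group annotations and no explicit QC samples")
    qcSamples <- colnames(pe)[colData(pe)$group == "QC"]
  }
  if (length(qcSamples) == 0L)
    stop("QC metrics requested but no QC samples present")
  idCounts <- colSums(!is.na(m))
  qc <- m[, qcSamples, drop = FALSE]
  inAll <- rowSums(is.na(qc)) == 0L
  pepCV <- apply(qc[inAll & rowSums(qc > 0, na.rm = TRUE) > 0, , drop = FALSE],
                 1, function(x) 100 * sd(x) / mean(x))
  sid <- intersect(standardIds(pe), rownames(m))
  study <- setdiff(colnames(m), qcSamples)
  stdCV <- function(cols) if (length(sid) && length(cols) >= 2)
    apply(m[sid, cols, drop = FALSE], 1, function(x)
      if (sum(!is.na(x)) >= 2 && mean(x, na.rm = TRUE) > 0)
        100 * sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE) else NA_real_)
  else NULL
  list(idCounts = idCounts,
       idCountCV = computeCV(idCounts),
       peptideCVsQC = pepCV,
       medianPeptideCVQC = median(pepCV),
       standardCVQC = stdCV(qcSamples),
       standardCVStudy = stdCV(study))
}

#' Abundance dynamic range
#'
#' Orders of magnitude spanned by per-peptide mean abundances,
#' `log10(max mean / min mean)`, plus the ranked-abundance curve
#' (log10 mean vs abundance rank).
#'
#' @param pe a [PeptidomeExperiment] or numeric matrix.
#' @param excludeStandards drop spike-in standards first (default TRUE).
#' @return list: `orders`, `curve` (data.frame rank / log10_mean /
#'   peptide_id).
#' @export
dynamicRange <- function(pe, excludeStandards = TRUE) {
  m <- if (is(pe, "SummarizedExperiment")) abundance(pe) else pe
  if (excludeStandards && is(pe, "SummarizedExperiment")) {
    drop <- intersect(standardIds(pe), rownames(m))
    if (length(drop)) m <- m[setdiff(rownames(m), drop), , drop = FALSE]
  }
  mu <- rowMeans(m, na.rm = TRUE)
  mu <- mu[is.finite(mu) & mu > 0]
  if (length(mu) < 2L) stop("need >= 2 peptides with positive mean abundance")
  ord <- order(mu, decreasing = TRUE)
  list(orders = log10(max(mu) / min(mu)),
       curve = data.frame(rank = seq_along(mu),
                          log10_mean = log10(mu[ord]),
                          peptide_id = names(mu)[ord]))
}

#' Assess recovery against a control limit
#'
#' Recovery is `100 * treated / reference` per paired measurement; the
#' condition passes iff every |recovery - 100| is strictly within the
#' limit band (e.g. the ±30% assay-acceptance band).
#'
#' @param reference,treated paired positive values.
#' @param limitPercent half-width of the acceptance band (default 30).
#' @param condition label for the report.
#' @return list: `condition`, `recovery` (percent vector), `limit`,
#'   `maxDeviation`, `pass`.
#' @export
stabilityAssess <- function(reference, treated, limitPercent = 30,
                            condition = "") {
  if (length(reference) != length(treated))
    stop("reference and treated must be paired")
  if (any(reference <= 0)) stop("reference values must be positive")
  rec <- 100 * treated / reference
  dev <- abs(rec - 100)
  list(condition = condition, recovery = rec, limit = limitPercent,
       maxDeviation = max(dev), pass = all(dev < limitPercent))
}

#' Dilution linearity check
#'
#' For each dilution point, deviation = `100 * |measured * factor -
#' undiluted| / undiluted`; the series passes iff all deviations are
#' strictly below `limitPercent` (default 20).
#'
#' @param factors dilution factors (>= 1; must include the undiluted 1).
#' @param measured measured values at each factor.
#' @param limitPercent strict deviation bound (default 20).
#' @return list: `deviation` (percent per point), `maxDeviation`, `pass`.
#' @export
dilutionLinearity <- function(factors, measured, limitPercent = 20) {
  if (!any(factors == 1)) stop("series must include the undiluted point (factor 1)")
  if (any(factors < 1)) stop("dilution factors must be >= 1")
  und <- measured[which(factors == 1)[1]]
  dev <- 100 * abs(measured * factors - und) / und
  list(deviation = dev, maxDeviation = max(dev), pass = all(dev < limitPercent))
}
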