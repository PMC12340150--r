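#' Candidate-selection configuration
#'
#' Settings of the selection cascade that turns discovery statistics into
#' a targeted panel: the five presence-policy criteria to union over,
#' the freeze--thaw stability exclusion limit (variation over 100% of the
#' recovery scale excludes a peptide), protein blacklist (albumin as
#' blood-derived; keratins as contaminants) and blood-derived annotation
#' tags.
#'
#' @param criteria presence policies to run (default: all five).
#' @param stabilityExclusionLimit percentage points of |recovery - 100|
#'   above which a candidate is excluded (default 100).
#' @param blacklistProteins regular expressions matched against accession,
#'   entry name and gene.
#' @param bloodDerivedTags annotation tags that exclude a candidate.
#' @return list of class `SelectionConfig`.
#' @export
selectionConfig <- function(criteria = .PRESENCE_POLICIES,
                            stabilityExclusionLimit = 100,
                            blacklistProteins = c("ALBU", "^ALB$", "KRT",
                                                  "K1C", "K2C", "keratin",
                                                  "albumin"),
                            bloodDerivedTags = "blood-derived") {
  stopifnot(stabilityExclusionLimit > 0, length(criteria) >= 1L)
  criteria <- match.arg(criteria, .PRESENCE_POLICIES, several.ok = TRUE)
  structure(list(criteria = criteria,
                 stabilityExclusionLimit = stabilityExclusionLimit,
                 blacklistProteins = blacklistProteins,
                 bloodDerivedTags = bloodDerivedTags),
            class = "SelectionConfig")
}

#' Union of significant peptides over selection criteria
#'
#' Runs the differential analysis once per presence-policy criterion and
#' unions the significant peptides. The `min3` policies run without
#' imputation (the statistic uses the observed values only); the `70pct`
#' policies impute missing values first. Each candidate is annotated
#' with the criteria that flagged it and its direction; direction
#' conflicts across criteria are flagged for review.
#'
#' @param pe a normalized [PeptidomeExperiment].
#' @param groups character(2) test/reference labels.
#' @param params base [diffParams()]; the policy field is overridden per
#'   criterion.
#' @param config a [selectionConfig()].
#' @return data.frame: `peptide_id`, `direction`, `criteria`
#'   (;-separated), `n_criteria`, `conflict`.
#' @export
runCriteriaUnion <- function(pe, groups = c("ALS", "Con"),
                             params = diffParams(),
                             config = selectionConfig()) {
  if (length(config$criteria) == 0L) stop("no criterion configured")
  hits <- list()
  for (crit in config$criteria) {
    p <- params; p$presencePolicy <- crit
    prep <- prepareMatrix(pe, groups, p)
    if (nrow(prep$matrix) == 0L) next
    m <- prep$matrix
    if (!startsWith(crit, "min3")) m <- imputeGaussian(m, p)
    res <- permutationFDR(m, prep$labels, p)
    sig <- res[res$significant, c("peptide_id", "direction")]
    if (nrow(sig)) { sig$criterion <- crit; hits[[crit]] <- sig }
  }
  if (!length(hits))
    return(data.frame(peptide_id = character(), direction = character(),
                      criteria = character(), n_criteria = integer(),
                      conflict = logical(), stringsAsFactors = FALSE))
  all <- do.call(rbind, hits)
  out <- do.call(rbind, lapply(split(all, all$peptide_id), function(d) {
    dirs <- unique(d$direction)
    data.frame(peptide_id = d$peptide_id[1],
               direction = if (length(dirs) == 1L) dirs else "conflict",
               criteria = paste(sort(unique(d$criterion)), collapse = ";"),
               n_criteria = length(unique(d$criterion)),
               conflict = length(dirs) > 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$peptide_id), ]
}

#' Apply exclusion rules to a candidate list
#'
#' Removes candidates that are unstable over freeze--thaw (variation
#' above the configured limit), derive from blacklisted proteins
#' (albumin, keratins), or carry a blood-derived tag. Every removal is
#' recorded in an exclusion ledger with the rule and the offending value;
#' candidates without stability data are kept and logged.
#'
#' @param candidates data.frame with `peptide_id` and optional
#'   `accession`, `entry_name`, `gene`, `tags` columns.
#' @param stability optional data.frame `peptide_id`, `variation`
#'   (percentage points of |recovery - 100|).
#' @param config a [selectionConfig()].
#' @return list: `kept` (filtered data.frame), `ledger` (data.frame
#'   peptide_id / rule / value), `noStabilityData` (ids).
#' @export
applyExclusions <- function(candidates, stability = NULL,
                            config = selectionConfig()) {
  ledger <- data.frame(peptide_id = character(), rule = character(),
                       value = character(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, ledger = ledger,
                noStabilityData = character()))
  drop <- rep(FALSE, nrow(candidates))
  note <- function(id, rule, value)
    rbind(ledger, data.frame(peptide_id = id, rule = rule,
                             value = as.character(value),
                             stringsAsFactors = FALSE))
  noStab <- character()
  if (!is.null(stability)) {
    v <- stability$variation[match(candidates$peptide_id, stability$peptide_id)]
    noStab <- candidates$peptide_id[is.na(v)]
    unstable <- !is.na(v) & v > config$stabilityExclusionLimit
    for (i in which(unstable))
      ledger <- note(candidates$peptide_id[i],
                     sprintf("freeze-thaw variation > %s%%",
                             config$stabilityExclusionLimit), v[i])
    drop <- drop | unstable
  } else noStab <- candidates$peptide_id
  protCols <- intersect(c("accession", "entry_name", "gene"),
                        colnames(candidates))
  if (length(protCols) && length(config$blacklistProteins)) {
    txt <- do.call(paste, candidates[protCols])
    hit <- Reduce(`|`, lapply(config$blacklistProteins,
                              function(p) grepl(p, txt, ignore.case = FALSE)))
    for (i in which(hit & !drop))
      ledger <- note(candidates$peptide_id[i], "blacklisted protein", txt[i])
    drop <- drop | hit
  }
  if ("tags" %in% colnames(candidates) && length(config$bloodDerivedTags)) {
    hit <- vapply(candidates$tags, function(tg)
      any(config$bloodDerivedTags %in% strsplit(as.character(tg), ";")[[1]]),
      logical(1))
    for (i in which(hit & !drop))
      ledger <- note(candidates$peptide_id[i], "blood-derived tag",
                     candidates$tags[i])
    drop <- drop | hit
  }
  list(kept = candidates[!drop, , drop = FALSE], ledger = ledger,
       noStabilityData = noStab)
}

#' Normalized spectral contrast dot product (dotp)
#'
#' `sum(m * r) / sqrt(sum(m^2) * sum(r^2))` between measured and
#' reference transition-intensity vectors; 1 for identical shapes, 0 for
#' orthogonal ones.
#'
#' @param measured,reference equal-length non-negative vectors with >= 2
#'   transitions.
#' @return value in [0, 1].
#' @examples
#' dotp(c(1, 2), c(2, 1))  # 0.8
#' @export
dotp <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("vectors must have equal length")
  if (length(measured) < 2L) stop("need >= 2 transitions")
  nm <- sqrt(sum(measured^2)); nr <- sqrt(sum(reference^2))
  if (nm == 0 || nr == 0) stop("zero intensity vector")
  sum(measured * reference) / (nm * nr)
}

#' Peak quality-control rule for targeted data
#'
#' @param minDotp strict lower bound on dotp (default 0.7).
#' @param minTransitions minimum transition count (default 10).
#' @param rtTolerance allowed |apex RT - reference RT| in minutes
#'   (default 1.0; an identity is rejected when the peak elutes more than
#'   a minute from the reference).
#' @param coelutionTolerance max pairwise apex-RT spread in minutes
#'   (default 0.1).
#' @param requireCoelution enforce the co-elution clause (default TRUE).
#' @return list of class `PeakQCRule`.
#' @export
peakQCRule <- function(minDotp = 0.7, minTransitions = 10L,
                       rtTolerance = 1.0, coelutionTolerance = 0.1,
                       requireCoelution = TRUE) {
  stopifnot(minDotp >= 0, minDotp <= 1)
  structure(list(minDotp = minDotp,
                 minTransitions = as.integer(minTransitions),
                 rtTolerance = rtTolerance,
                 coelutionTolerance = coelutionTolerance,
                 requireCoelution = requireCoelution),
            class = "PeakQCRule")
}

#' Peak QC for one peptide's transition data
#'
#' Pass iff dotp against the reference intensities is strictly above the
#' rule's bound, the transition count meets the minimum, all transition
#' apexes co-elute within tolerance, and the peak apex matches the
#' reference retention time. Diagnostics list each failed clause.
#'
#' @param measured data.frame with columns `transition`, `area`,
#'   `rt_min`.
#' @param reference list: `intensities` (named by transition), `rt`.
#' @param rule a [peakQCRule()].
#' @return list: `pass`, `dotp`, `nTransitions`, `rtSpread`, `rtDelta`,
#'   `failures`.
#' @export
peakQC <- function(measured, reference, rule = peakQCRule()) {
  if (nrow(measured) == 0L) stop("no transitions")
  fails <- character()
  ref <- reference$intensities[match(measured$transition,
                                     names(reference$intensities))]
  if (anyNA(ref)) stop("reference intensities missing for some transitions")
  dp <- dotp(measured$area, as.numeric(ref))
  if (!(dp > rule$minDotp))
    fails <- c(fails, sprintf("dotp %.3f <= %.2f", dp, rule$minDotp))
  if (nrow(measured) < rule$minTransitions)
    fails <- c(fails, sprintf("only %d transitions (< %d)",
                              nrow(measured), rule$minTransitions))
  spread <- diff(range(measured$rt_min))
  if (rule$requireCoelution && spread > rule$coelutionTolerance)
    fails <- c(fails, sprintf("co-elution spread %.3f min > %.2f",
                              spread, rule$coelutionTolerance))
  delta <- abs(median(measured$rt_min) - reference$rt)
  if (delta > rule$rtTolerance)
    fails <- c(fails, sprintf("apex RT off by %.2f min (> %.2f)",
                              delta, rule$rtTolerance))
  list(pass = length(fails) == 0L, dotp = dp, nTransitions = nrow(measured),
       rtSpread = spread, rtDelta = delta, failures = fails)
}

#' Assemble the final panel from candidates and reviewed edits
#'
#' Applies an explicit, reasoned edit list (remove/add) to the
#' label-free significant candidates: the scientific judgment calls of
#' panel design are config, not inference. Removing a non-member is an
#' error; adding an existing member keeps a single membership with a
#' warning. The result is ordered and de-duplicated, and every edit is
#' logged.
#'
#' @param candidates character vector of candidate peptide ids.
#' @param edits data.frame with columns `action` ("remove"/"add"),
#'   `peptide_id`, `reason`.
#' @return list: `panel` (character), `log` (data.frame).
#' @examples
#' assemblePanel(c("a", "b"), data.frame(action = "remove", peptide_id = "a",
#'                                       reason = "unstable"))
#' @export
assemblePanel <- function(candidates, edits = NULL) {
  panel <- unique(as.character(candidates))
  log <- data.frame(action = character(), peptide_id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  if (!is.null(edits) && nrow(edits)) {
    for (k in seq_len(nrow(edits))) {
      e <- edits[k, ]
      if (e$action == "remove") {
        if (!e$peptide_id %in% panel)
          stop("cannot remove non-member peptide: ", e$peptide_id)
        panel <- setdiff(panel, e$peptide_id)
      } else if (e$action == "add") {
        if (e$peptide_id %in% panel)
          warning("duplicate addition of ", e$peptide_id,
                  "; keeping single membership")
        panel <- union(panel, e$peptide_id)
      } else stop("unknown edit action: ", e$action)
      log <- rbind(log, data.frame(action = e$action,
                                   peptide_id = e$peptide_id,
                                   reason = as.character(e$reason),
                                   stringsAsFactors = FALSE))
    }
  }
  list(panel = panel, log = log)
}
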