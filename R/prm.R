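#' @importFrom stats glm.fit binomial plogis mad cor.test setNames aggregate
NULL

#' Quantify PRM light/heavy ratios from a transition report
#'
#' Per sample and peptide, retained transition areas are summed per
#' channel and the ratio is `light / heavy`. Transitions showing matrix
#' interference — a light/heavy log-ratio deviating from the other
#' transitions' median by more than `interferenceK` times their spread —
#' are excluded from both channels' sums, as are transitions named in
#' `excludeTransitions`. Samples without light peaks are reported missing
#' with reason `"no peak"`; a peptide present without its heavy channel
#' is an assay failure and raises an error. Ratios are invariant to
#' transition order and to a common scale factor on both channels.
#'
#' @param report transition data.frame (see [readPRMReport()]).
#' @param panel optional list of panel entries (with `peptide_id`,
#'   `transitions`, `reference_rt`); defaults to the peptides found in
#'   the report.
#' @param qcRule optional [peakQCRule()] applied to the light channel
#'   when the panel provides reference intensities; failing peptides are
#'   missing with reason `"peak QC failed"`.
#' @param interferenceK outlier multiplier for automatic interference
#'   flagging (default 3; `Inf` disables).
#' @param excludeTransitions optional data.frame `peptide_id`,
#'   `transition` of transitions to drop a priori.
#' @return list of class `PRMResult`: `ratios` (samples x peptides, NA =
#'   missing), `missing` (data.frame sample_id / peptide_id / reason),
#'   `excludedTransitions` (data.frame peptide_id / transition / reason).
#' @export
quantifyPRM <- function(report, panel = NULL, qcRule = NULL,
                        interferenceK = 3, excludeTransitions = NULL) {
  peptides <- if (is.null(panel)) unique(report$peptide_id)
  else vapply(panel, `[[`, character(1), "peptide_id")
  samples <- unique(report$sample_id)
  ratios <- matrix(NA_real_, length(samples), length(peptides),
                   dimnames = list(samples, peptides))
  missing <- data.frame(sample_id = character(), peptide_id = character(),
                        reason = character(), stringsAsFactors = FALSE)
  excl <- data.frame(peptide_id = character(), transition = character(),
                     reason = character(), stringsAsFactors = FALSE)
  refByPep <- if (!is.null(panel)) setNames(panel, peptides) else NULL

  for (pid in peptides) {
    sub <- report[report$peptide_id == pid, ]
    ## a-priori exclusions apply to the peptide across all samples
    drop0 <- character()
    if (!is.null(excludeTransitions)) {
      drop0 <- excludeTransitions$transition[excludeTransitions$peptide_id == pid]
      if (length(drop0))
        excl <- rbind(excl, data.frame(peptide_id = pid, transition = drop0,
                                       reason = "excluded by config",
                                       stringsAsFactors = FALSE))
    }
    ## automatic interference flagging pools the evidence across samples
    both <- intersect(unique(sub$transition[sub$channel == "light"]),
                      unique(sub$transition[sub$channel == "heavy"]))
    autoDrop <- character()
    if (is.finite(interferenceK) && length(both) >= 3L) {
      lh <- vapply(both, function(tr) {
        la <- sub[sub$channel == "light" & sub$transition == tr,
                  c("sample_id", "area")]
        ha <- sub[sub$channel == "heavy" & sub$transition == tr,
                  c("sample_id", "area")]
        mm <- merge(la, ha, by = "sample_id")
        if (nrow(mm) == 0L) return(NA_real_)
        median(log(mm$area.x / mm$area.y), na.rm = TRUE)
      }, numeric(1))
      for (tr in both) {
        others <- lh[setdiff(both, tr)]
        spread <- max(mad(others, na.rm = TRUE), 1e-6)
        if (is.finite(lh[tr]) &&
            abs(lh[tr] - median(others, na.rm = TRUE)) > interferenceK * spread)
          autoDrop <- c(autoDrop, tr)
      }
      if (length(autoDrop))
        excl <- rbind(excl, data.frame(peptide_id = pid, transition = autoDrop,
                                       reason = "interference",
                                       stringsAsFactors = FALSE))
    }
    dropped <- union(drop0, autoDrop)

    for (s in unique(sub$sample_id)) {
      ss <- sub[sub$sample_id == s, ]
      heavy <- ss[ss$channel == "heavy" & !ss$transition %in% dropped, ]
      light <- ss[ss$channel == "light" & !ss$transition %in% dropped, ]
      if (nrow(heavy) == 0L)
        stop(sprintf("assay failure: heavy channel absent for %s in %s",
                     pid, s))
      if (nrow(light) == 0L) {
        missing <- rbind(missing, data.frame(sample_id = s, peptide_id = pid,
                                             reason = "no peak",
                                             stringsAsFactors = FALSE))
        next
      }
      if (!is.null(qcRule) && !is.null(refByPep) &&
          !is.null(refByPep[[pid]]$transitions$rel_intensity)) {
        refInt <- setNames(refByPep[[pid]]$transitions$rel_intensity,
                           refByPep[[pid]]$transitions$transition)
        refInt <- refInt[!names(refInt) %in% dropped]
        qc <- peakQC(data.frame(transition = light$transition,
                                area = light$area, rt_min = light$rt_min),
                     list(intensities = refInt,
                          rt = refByPep[[pid]]$reference_rt), qcRule)
        if (!qc$pass) {
          missing <- rbind(missing,
                           data.frame(sample_id = s, peptide_id = pid,
                                      reason = "peak QC failed",
                                      stringsAsFactors = FALSE))
          next
        }
      }
      ratios[s, pid] <- sum(light$area) / sum(heavy$area)
    }
  }
  structure(list(ratios = ratios, missing = missing,
                 excludedTransitions = unique(excl)),
            class = "PRMResult")
}

#' Group statistics on PRM ratios
#'
#' Per peptide: two groups get a two-sided Wilcoxon rank-sum p; more than
#' two get Kruskal--Wallis plus Dunn pairwise adjusted p values. Missing
#' ratios are excluded pairwise and the per-group n reported; a peptide
#' absent from an entire group is reported, not an error.
#'
#' @param prm a `PRMResult` from [quantifyPRM()], or a samples x
#'   peptides ratio matrix.
#' @param groups group label per sample (named or in sample order).
#' @return data.frame per peptide: `peptide_id`, `test`, `p`,
#'   `direction`, `n` (;-joined per group), `note`; attribute
#'   `"pairwise"` holds the Dunn tables for >2 groups.
#' @export
groupStats <- function(prm, groups) {
  ratios <- if (inherits(prm, "PRMResult")) prm$ratios else prm
  groups <- as.factor(groups)
  if (!is.null(names(groups))) groups <- groups[rownames(ratios)]
  out <- list(); pw <- list()
  for (pid in colnames(ratios)) {
    x <- ratios[, pid]
    keep <- !is.na(x)
    g <- droplevels(groups[keep])
    ns <- table(factor(groups[keep], levels = levels(groups)))
    note <- ""
    absent <- setdiff(levels(groups), names(table(g))[table(g) >= 2])
    if (length(absent))
      note <- paste("insufficient data in:", paste(absent, collapse = ","))
    ## direction: last-level median relative to the first (reference) level
    med <- tapply(x[keep], g, median)
    dir <- if (length(med) >= 2L && !anyNA(med[c(1, length(med))]))
      ifelse(unname(med[length(med)] - med[1]) > 0, "up", "down")
    else NA_character_
    if (nlevels(g) < 2L || min(table(g)) < 2L) {
      out[[pid]] <- data.frame(peptide_id = pid, test = "none", p = NA_real_,
                               direction = dir,
                               n = paste(ns, collapse = ";"),
                               note = if (nzchar(note)) note else "group of one sample",
                               stringsAsFactors = FALSE)
      next
    }
    if (nlevels(g) == 2L) {
      p <- wilcoxonRankSum(x[keep][g == levels(g)[1]],
                           x[keep][g == levels(g)[2]])$p
      test <- "wilcoxon"
    } else {
      kd <- kruskalDunn(x[keep], g)
      p <- kd$omnibusP
      pw[[pid]] <- kd$pairwise
      test <- "kruskal-dunn"
    }
    out[[pid]] <- data.frame(peptide_id = pid, test = test, p = p,
                             direction = dir, n = paste(ns, collapse = ";"),
                             note = note, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pairwise") <- pw
  res
}

## Rank-based AUC (Mann-Whitney identity, ties averaged)
.aucRank <- function(values, positive) {
  r <- rank(values)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of a single marker
#'
#' Rank-based AUC (equivalent to Mann--Whitney U / (n1*n0), ties
#' averaged) with a DeLong 95% confidence interval. Orientation is
#' chosen so AUC >= 0.5; the recorded `sign` is +1 when the positive
#' class has larger values, -1 otherwise.
#'
#' @param values numeric marker values (NAs dropped with their labels).
#' @param labels binary labels; `positive` names the positive class.
#' @param positive positive class label (default: second factor level).
#' @return list: `auc`, `ci` (length 2), `sign`, `n` (per class).
#' @export
rocSingle <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.factor(as.character(labels[keep]))
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  if (sum(pos) < 3L || sum(!pos) < 3L) stop("need >= 3 observations per class")
  a <- .aucRank(values, pos)
  sgn <- if (a >= 0.5) 1L else -1L
  roc <- pROC::roc(response = labels, predictor = values,
                   levels = c(setdiff(levels(labels), positive), positive),
                   direction = if (sgn > 0) "<" else ">", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(roc, method = "delong")))
  list(auc = max(a, 1 - a), ci = ci[c(1, 3)], sign = sgn,
       n = c(positive = sum(pos), negative = sum(!pos)))
}

## Logistic regression by IRLS with an optional ridge penalty on slopes.
.ridgeLogistic <- function(X, y, lambda = 0) {
  X1 <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(X1))
  for (it in seq_len(200L)) {
    eta <- drop(X1 %*% beta)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X1, X1 * W) + pen
    g <- crossprod(X1, y - p) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) {
      names(beta) <- colnames(X1)
      return(list(coef = beta, converged = TRUE, iterations = it))
    }
  }
  names(beta) <- colnames(X1)
  list(coef = beta, converged = FALSE, iterations = 200L)
}

#' Combined-panel logistic ROC
#'
#' Binary logistic regression by maximum likelihood on standardized log2
#' ratios of the panel peptides (a two-class multinomial model reduces to
#' exactly this); the combined ROC is computed from the fitted
#' probabilities and reported as an in-sample AUC alongside the
#' per-peptide AUCs. On (quasi-)separation a tiny ridge penalty (1e-6,
#' escalated tenfold as needed) stabilizes the fit and is logged in the
#' result. Samples with a missing ratio are dropped listwise (reported);
#' peptides must have <= 30% missingness.
#'
#' @param x samples x peptides matrix of L/H ratios (or log2 ratios, see
#'   `log2Transform`).
#' @param labels binary class labels per sample.
#' @param positive positive class (default second level).
#' @param log2Transform take log2 of `x` first (default TRUE).
#' @param maxMissing maximum tolerated per-peptide missing fraction.
#' @return list of class `PanelModel`: `peptides`, `coefficients`,
#'   `combinedAUC`, `combinedCI`, `perPeptide` (data.frame), `fitted`
#'   (probabilities), `ridge` (penalty used; 0 = plain MLE),
#'   `nDropped` (listwise deletions), `scaling` (centers/scales).
#' @export
rocCombined <- function(x, labels, positive = NULL, log2Transform = TRUE,
                        maxMissing = 0.3) {
  x <- as.matrix(x)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  missFrac <- colMeans(is.na(x))
  bad <- colnames(x)[missFrac > maxMissing]
  if (length(bad))
    stop("peptide(s) exceed ", 100 * maxMissing, "% missingness: ",
         paste(bad, collapse = ", "))
  keep <- rowSums(is.na(x)) == 0L & !is.na(labels)
  nDropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]; labels <- droplevels(labels[keep])
  if (log2Transform) x <- log2(x)
  xs <- scale(x)
  y <- as.integer(labels == positive)

  perPep <- do.call(rbind, lapply(colnames(x), function(p) {
    rs <- rocSingle(x[, p], labels, positive)
    data.frame(peptide_id = p, auc = rs$auc, ci_low = rs$ci[1],
               ci_high = rs$ci[2], sign = rs$sign, stringsAsFactors = FALSE)
  }))

  fit <- NULL; lambda <- 0
  g <- suppressWarnings(glm.fit(cbind(1, xs), y, family = binomial()))
  separated <- !g$converged || !all(is.finite(g$coefficients)) ||
    max(abs(g$coefficients)) > 15
  if (!separated && all(is.finite(g$coefficients))) {
    fit <- list(coef = setNames(g$coefficients,
                                c("(Intercept)", colnames(xs))),
                converged = TRUE)
  } else {
    for (lambda in 10^seq(-6, -2)) {
      fit <- .ridgeLogistic(xs, y, lambda)
      if (!is.null(fit) && fit$converged) break
    }
    if (is.null(fit) || !fit$converged)
      stop("logistic fit did not converge after ridge escalation")
  }
  prob <- plogis(drop(cbind(1, xs) %*% fit$coef))
  a <- .aucRank(prob, y == 1L)
  roc <- pROC::roc(response = labels, predictor = prob,
                   levels = c(setdiff(levels(labels), positive), positive),
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(roc, method = "delong")))
  structure(list(peptides = colnames(x), coefficients = fit$coef,
                 combinedAUC = a, combinedCI = ci[c(1, 3)],
                 perPeptide = perPep, fitted = prob, ridge = lambda,
                 nDropped = nDropped,
                 scaling = list(center = attr(xs, "scaled:center"),
                                scale = attr(xs, "scaled:scale"))),
            class = "PanelModel")
}

#' Correlate panel measurements with an external assay
#'
#' Spearman rank correlation (tie-corrected) between a peptide's values
#' and an external assay's values on complete pairs, plus the pairs
#' table for plotting.
#'
#' @param peptideValues,externalValues paired numeric vectors.
#' @return list: `r`, `p`, `n`, `pairs` (data.frame).
#' @export
correlateExternal <- function(peptideValues, externalValues) {
  cc <- complete.cases(peptideValues, externalValues)
  if (sum(cc) < 3L) stop("need >= 3 complete pairs")
  ct <- suppressWarnings(cor.test(peptideValues[cc], externalValues[cc],
                                  method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(cc),
       pairs = data.frame(peptide = peptideValues[cc],
                          external = externalValues[cc]))
}
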