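#' @importFrom stats wilcox.test kruskal.test p.adjust cor hclust cutree
#'   dist prcomp var pt complete.cases
#' @importFrom utils combn
NULL

.PRESENCE_POLICIES <- c("in_70pct_each_group", "in_70pct_any_group",
                        "in_70pct_all", "min3_each_group", "min3_any_group")

#' Parameters of the differential analysis
#'
#' Defaults are the Perseus-style settings the workflow is built around:
#' `s0 = 0.1`, permutation FDR at 0.05 with 250 permutations, Gaussian
#' imputation width 0.3 and down-shift 1.8 (in units of the per-sample
#' SD), and the 70%-in-either-group presence policy.
#'
#' @param s0 non-negative moderation constant added to the standard error.
#' @param fdr target FDR level in (0, 1).
#' @param nPermutations number of label permutations (>= 1).
#' @param imputeWidth imputation SD as a fraction of the sample SD.
#' @param imputeDownshift imputation mean shift in sample SDs.
#' @param presencePolicy one of `in_70pct_each_group`,
#'   `in_70pct_any_group`, `in_70pct_all`, `min3_each_group`,
#'   `min3_any_group`; the `min3` policies are used without imputation.
#' @param qualityThreshold identification-quality cutoff (kept iff >=).
#' @param seed seed for imputation and permutation streams.
#' @return validated parameter list of class `DiffParams`.
#' @export
diffParams <- function(s0 = 0.1, fdr = 0.05, nPermutations = 250L,
                       imputeWidth = 0.3, imputeDownshift = 1.8,
                       presencePolicy = "in_70pct_any_group",
                       qualityThreshold = 5, seed = 1L) {
  stopifnot(s0 >= 0, fdr > 0, fdr < 1, nPermutations >= 1, imputeWidth > 0)
  presencePolicy <- match.arg(presencePolicy, .PRESENCE_POLICIES)
  structure(list(s0 = s0, fdr = fdr, nPermutations = as.integer(nPermutations),
                 imputeWidth = imputeWidth, imputeDownshift = imputeDownshift,
                 presencePolicy = presencePolicy,
                 qualityThreshold = qualityThreshold, seed = as.integer(seed)),
            class = "DiffParams")
}

#' Filter and log2-transform a quantification matrix for testing
#'
#' Applies the identification-quality filter (kept iff quality >= 5 by
#' default), removes spike-in standards, applies the presence policy with
#' `>=` semantics on the 70% bound (17/24 = 70.8% is retained), and
#' log2-transforms. A per-rule drop report is returned.
#'
#' @param pe a normalized [PeptidomeExperiment].
#' @param groups character(2): the two group labels to compare, in
#'   (test, reference) order, e.g. `c("ALS", "Con")`.
#' @param params a [diffParams()].
#' @return list: `matrix` (log2, NA = missing), `labels` (factor over the
#'   retained samples), `report` (data.frame rule / dropped).
#' @export
prepareMatrix <- function(pe, groups = c("ALS", "Con"),
                          params = diffParams()) {
  if (normalizationState(pe) == "raw")
    stop("normalize the matrix before testing (state is 'raw')")
  stopifnot(length(groups) == 2L)
  keepS <- colData(pe)$group %in% groups
  if (!any(colData(pe)$group == groups[1]) || !any(colData(pe)$group == groups[2]))
    stop("both groups must be present in the sample annotations")
  m <- abundance(pe)[, keepS, drop = FALSE]
  labels <- factor(as.character(colData(pe)$group[keepS]), levels = groups)
  report <- data.frame(rule = character(), dropped = integer())
  note <- function(rule, n) rbind(report, data.frame(rule = rule, dropped = n))

  std <- intersect(standardIds(pe), rownames(m))
  if (length(std)) {
    m <- m[setdiff(rownames(m), std), , drop = FALSE]
    report <- note("spike-in standard", length(std))
  }
  rd <- rowData(pe)
  if ("quality" %in% colnames(rd)) {
    q <- rd$quality[match(rownames(m), rownames(pe))]
    bad <- !is.na(q) & q < params$qualityThreshold
    report <- note(sprintf("quality < %s", params$qualityThreshold), sum(bad))
    m <- m[!bad, , drop = FALSE]
  }
  obs <- !is.na(m)
  nA <- sum(labels == groups[1]); nB <- sum(labels == groups[2])
  oA <- rowSums(obs[, labels == groups[1], drop = FALSE])
  oB <- rowSums(obs[, labels == groups[2], drop = FALSE])
  keep <- switch(params$presencePolicy,
    in_70pct_each_group = oA >= 0.7 * nA & oB >= 0.7 * nB,
    in_70pct_any_group  = oA >= 0.7 * nA | oB >= 0.7 * nB,
    in_70pct_all        = (oA + oB) >= 0.7 * (nA + nB),
    min3_each_group     = oA >= 3L & oB >= 3L,
    min3_any_group      = oA >= 3L | oB >= 3L)
  report <- note(params$presencePolicy, sum(!keep))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    warning("no peptides left after filtering")
  list(matrix = log2(m), labels = labels, report = report)
}

#' Gaussian down-shift imputation of missing values
#'
#' Per sample (column) of a log2 matrix, missing entries are drawn from
#' `Normal(mean - downshift * sd, (width * sd)^2)` where mean and sd are
#' computed over that column's observed values — the standard
#' left-censored imputation for abundance-dependent missingness. Observed
#' values are untouched; the draw is deterministic given the seed.
#' Columns with fewer than 2 observed values fall back to the global
#' observed distribution (flagged in the `fallback` attribute).
#'
#' @param m log2 matrix with NAs.
#' @param params a [diffParams()] (uses width, down-shift, seed).
#' @param seed overrides the params seed when given.
#' @return completed matrix; attribute `"fallback"` lists columns imputed
#'   from the global distribution.
#' @export
imputeGaussian <- function(m, params = diffParams(), seed = params$seed) {
  out <- m
  fallback <- character()
  .withSeed(.streamSeed(seed, "impute"), {
    gm <- mean(m, na.rm = TRUE); gs <- sd(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      miss <- is.na(x)
      if (!any(miss)) next
      if (sum(!miss) >= 2L) {
        mu <- mean(x[!miss]); sdev <- sd(x[!miss])
      } else {
        mu <- gm; sdev <- gs
        fallback <- c(fallback, colnames(m)[j])
      }
      out[miss, j] <- rnorm(sum(miss),
                            mean = mu - params$imputeDownshift * sdev,
                            sd = params$imputeWidth * sdev)
    }
  })
  attr(out, "fallback") <- fallback
  out
}

#' s0-moderated two-sample statistic
#'
#' `difference = mean(a) - mean(b)`; `statistic = difference /
#' (pooled-variance two-sample standard error + s0)`. With `s0 = 0` this
#' is the classic Student t statistic; a positive s0 damps the
#' significance of tiny-variance peptides.
#'
#' @param a,b numeric vectors (>= 2 values each; NAs dropped).
#' @param s0 non-negative moderation constant.
#' @return list: `difference`, `statistic`, `se`, `df`.
#' @examples
#' s0TTest(c(1, 2, 3), c(3, 4, 5), s0 = 0.1)$statistic  # -2.182
#' @export
s0TTest <- function(a, b, s0 = 0.1) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0 && s0 == 0)
    stop("degenerate variance: statistic is infinite at s0 = 0")
  d <- mean(a) - mean(b)
  list(difference = d, statistic = d / (se + s0), se = se, df = na + nb - 2)
}

## Row-wise s0 statistics, NA-aware; idxA/idxB are column indices.
.s0StatMatrix <- function(m, idxA, idxB, s0) {
  statRow <- function(x) {
    a <- x[idxA]; b <- x[idxB]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(c(NA_real_, NA_real_))
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    d <- mean(a) - mean(b)
    c(d, d / (se + s0))
  }
  if (anyNA(m)) {
    r <- t(apply(m, 1, statRow))
    list(difference = r[, 1], statistic = r[, 2])
  } else {
    A <- m[, idxA, drop = FALSE]; B <- m[, idxB, drop = FALSE]
    na <- length(idxA); nb <- length(idxB)
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- rowSums((A - mA)^2) / (na - 1)
    vB <- rowSums((B - mB)^2) / (nb - 1)
    sp2 <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    d <- mA - mB
    list(difference = d, statistic = d / (se + s0))
  }
}

#' s0-moderated test with permutation-based FDR
#'
#' Observed s0 statistics per peptide are compared with a pooled null
#' built from label permutations (SAM-style estimator). For peptide i
#' with observed |t_i|, `q_i = [mean over permutations of the number of
#' null |t| >= |t_i|] / [number of observed |t| >= |t_i|]`, then
#' monotonized so q never increases with |t|, and capped at 1. A peptide
#' is significant iff `q <= fdr`. When the requested number of
#' permutations exceeds the number of distinct label arrangements, the
#' full enumeration is used instead (logged via a message).
#'
#' @param m numeric log2 matrix (complete, or NA-aware for the
#'   no-imputation policies).
#' @param labels factor of length `ncol(m)` with exactly two levels; the
#'   first level is the test group (differences are level1 - level2).
#' @param params a [diffParams()].
#' @return data.frame (one row per peptide): `peptide_id`, `difference`,
#'   `statistic`, `p`, `q`, `significant`, `direction` (up/down/ns).
#' @export
permutationFDR <- function(m, labels, params = diffParams()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  idxA <- which(labels == levels(labels)[1])
  idxB <- which(labels == levels(labels)[2])
  obs <- .s0StatMatrix(m, idxA, idxB, params$s0)
  tobs <- obs$statistic
  n <- ncol(m); na <- length(idxA)
  nArr <- choose(n, na)
  perms <- NULL
  if (nArr <= params$nPermutations) {
    message(sprintf("full enumeration: %d distinct label arrangements", nArr))
    perms <- combn(n, na, simplify = FALSE)
  }
  nulls <- .withSeed(.streamSeed(params$seed, "permute"), {
    if (is.null(perms))
      perms <- lapply(seq_len(params$nPermutations),
                      function(i) sample(n, na))
    vapply(perms, function(ia)
      abs(.s0StatMatrix(m, ia, setdiff(seq_len(n), ia),
                        params$s0)$statistic),
      numeric(nrow(m)))
  })
  nPerm <- length(perms)
  pool <- sort(as.vector(nulls))
  pool <- pool[!is.na(pool)]
  at <- abs(tobs)
  ## #null >= |t| via binary search on the sorted pool
  nGE <- length(pool) - findInterval(at - 1e-12, pool)
  meanNull <- nGE / nPerm
  rObs <- vapply(at, function(x) sum(at >= x - 1e-12, na.rm = TRUE), numeric(1))
  q <- meanNull / rObs
  p <- nGE / length(pool)
  ## step-down monotonization: a more significant peptide never gets a
  ## larger q; with peptides sorted by |t| descending, q must be
  ## non-decreasing down the list
  ok <- !is.na(at)
  ord <- order(at[ok], decreasing = TRUE)
  qm <- pmin(q[ok][ord], 1)
  qm <- rev(cummin(rev(qm)))
  q[ok][ord] <- qm
  q <- pmin(q, 1)
  sig <- !is.na(q) & q <= params$fdr
  data.frame(peptide_id = rownames(m),
             difference = obs$difference, statistic = tobs,
             p = p, q = q, significant = sig,
             direction = ifelse(!sig, "ns",
                                ifelse(obs$difference > 0, "up", "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided, normal approximation with tie correction. Degenerate input
#' (all pooled values identical) returns p = 1 with a `degenerate` flag.
#'
#' @param a,b numeric vectors (>= 2 observations each; NAs dropped).
#' @return list: `p`, `statistic` (W), `degenerate`.
#' @export
wilcoxonRankSum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 observations per group")
  if (length(unique(c(a, b))) == 1L)
    return(list(p = 1, statistic = length(a) * length(b) / 2, degenerate = TRUE))
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), degenerate = FALSE)
}

#' Kruskal--Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal--Wallis p, plus Dunn pairwise z statistics on
#' mean ranks with Holm-adjusted two-sided p values (the adjustment is
#' configurable).
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @param adjust p.adjust method for the pairwise p values (default holm).
#' @return list: `omnibusP`, `pairwise` (data.frame group1 / group2 / z /
#'   p / p_adj).
#' @export
kruskalDunn <- function(values, groups, adjust = "holm") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  kw <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tieCorr
  cmb <- combn(levels(groups), 2)
  z <- apply(cmb, 2, function(gg) {
    (rbar[gg[1]] - rbar[gg[2]]) /
      sqrt(sigma2 * (1 / ng[gg[1]] + 1 / ng[gg[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  list(omnibusP = kw$p.value,
       pairwise = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                             z = as.numeric(z), p = p,
                             p_adj = p.adjust(p, method = adjust),
                             stringsAsFactors = FALSE))
}

#' Spearman correlation matrix with pairwise-complete handling
#'
#' Symmetric matrix with unit diagonal; p values from the t
#' approximation. Pairs with fewer than 3 complete observations are
#' flagged as missing.
#'
#' @param x numeric matrix or data.frame, variables in columns.
#' @return list: `r`, `p`, `n` (pairwise complete counts).
#' @export
spearmanMatrix <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k)) for (j in i:k) {
    cc <- complete.cases(x[, i], x[, j])
    n[i, j] <- n[j, i] <- sum(cc)
    if (sum(cc) >= 3L) {
      rij <- cor(x[cc, i], x[cc, j], method = "spearman")
      r[i, j] <- r[j, i] <- rij
      if (i == j) { p[i, j] <- 0; next }
      tt <- rij * sqrt((sum(cc) - 2) / max(1e-300, 1 - rij^2))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df = sum(cc) - 2)
    }
  }
  diag(r)[!is.na(diag(n)) & diag(n) >= 1] <- 1
  list(r = r, p = p, n = n)
}

#' Clustering specificity and PCA separation summary
#'
#' Rows (peptides) are standardized, samples are clustered by Ward
#' (ward.D2) agglomeration on Euclidean distance and cut at two clusters.
#' Specificity is the fraction of control samples falling in the cluster
#' whose majority label is the control label. The first two principal
#' components of the standardized matrix are returned with their
#' explained-variance fractions.
#'
#' @param m log2 matrix restricted to significant peptides (rows) over
#'   samples (columns); >= 2 rows.
#' @param labels group label per sample.
#' @param controlLabel the label counted for specificity (default "Con").
#' @return list: `clusters` (named integer), `specificity` (percent),
#'   `pca` (data.frame PC1/PC2/label), `explained` (fractions).
#' @export
separationSummary <- function(m, labels, controlLabel = "Con") {
  if (nrow(m) < 2L) stop("need >= 2 significant peptides")
  labels <- as.character(labels)
  if (min(table(labels)) < 2L) stop("need >= 2 samples per group")
  z <- t(scale(t(m)))
  z <- z[apply(z, 1, function(x) all(is.finite(x))), , drop = FALSE]
  hc <- hclust(dist(t(z)), method = "ward.D2")
  cl <- cutree(hc, k = 2)
  conIdx <- labels == controlLabel
  correct <- 0L
  for (k in 1:2) {
    inK <- cl == k
    maj <- names(which.max(table(labels[inK])))
    if (maj == controlLabel) correct <- correct + sum(inK & conIdx)
  }
  spec <- 100 * correct / sum(conIdx)
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(clusters = cl, specificity = spec,
       pca = data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2], label = labels),
       explained = ev[1:2])
}
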