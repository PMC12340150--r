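test_that("s0 statistic matches hand computation and reduces to Student t", {
  r <- s0TTest(c(1, 2, 3), c(3, 4, 5), s0 = 0.1)
  expect_equal(r$difference, -2)
  expect_equal(r$se, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$statistic, -2 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), -2.182)

  set.seed(4)
  for (k in 1:25) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    expect_equal(s0TTest(a, b, s0 = 0)$statistic,
                 unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
  expect_equal(s0TTest(c(1, 1), c(2, 2), s0 = 0.1)$statistic, -1 / 0.1)
  expect_error(s0TTest(c(1, 1), c(2, 2), s0 = 0), "degenerate")
  expect_equal(s0TTest(c(1, 2), c(1, 2), 0.1)$statistic, 0)
})

test_that("|statistic| is non-increasing in s0", {
  set.seed(9)
  a <- rnorm(8, 1); b <- rnorm(8)
  s0s <- c(0, 0.05, 0.1, 0.5, 1, 2)
  stats <- vapply(s0s, function(s) abs(s0TTest(a, b, s)$statistic), numeric(1))
  expect_true(all(diff(stats) <= 0))
})

test_that("presence policies use >= semantics on the 70% bound", {
  nA <- 24L; nB <- 24L
  m <- matrix(rlnorm(3 * 48, 8), nrow = 3,
              dimnames = list(c("p17", "p16", "pLowQ"),
                              sprintf("s%02d", 1:48)))
  ## p17: 17/24 (70.8%) in Con only; p16: 16/24 (66.7%) in each group
  m["p17", 18:48] <- NA
  m["p16", c(17:24, 41:48)] <- NA
  rd <- data.frame(quality = c(10, 10, 4.9),
                   row.names = rownames(m))
  cd <- S4Vectors::DataFrame(group = rep(c("Con", "ALS"), each = 24),
                             row.names = colnames(m))
  pe <- PeptidomeExperiment(m, rowData = rd, colData = cd,
                            normalizationState = "stdpep")
  keep <- function(policy) rownames(prepareMatrix(
    pe, c("ALS", "Con"), diffParams(presencePolicy = policy))$matrix)
  expect_true("p17" %in% keep("in_70pct_any_group"))
  expect_false("p17" %in% keep("in_70pct_each_group"))
  expect_false("p16" %in% keep("in_70pct_any_group"))
  expect_false("p16" %in% keep("in_70pct_each_group"))
  expect_false("p16" %in% keep("in_70pct_all"))
  ## quality 4.9 fails the >= 5 threshold under every policy
  expect_false("pLowQ" %in% keep("min3_any_group"))
  ## log2 transform applied
  pm <- prepareMatrix(pe, c("ALS", "Con"), diffParams())
  expect_equal(pm$matrix["p17", "s01"], log2(m["p17", "s01"]))
})

test_that("Gaussian down-shift imputation is deterministic and well-calibrated", {
  set.seed(11)
  m <- matrix(rnorm(200 * 6, 20, 2), 200,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:6)))
  complete <- imputeGaussian(m, diffParams(seed = 3))
  expect_identical(complete[, ], m[, ])  # nothing to impute
  miss <- m
  miss[sample(length(m), 300)] <- NA
  i1 <- imputeGaussian(miss, diffParams(seed = 3))
  i2 <- imputeGaussian(miss, diffParams(seed = 3))
  expect_identical(i1, i2)
  expect_identical(i1[!is.na(miss)], miss[!is.na(miss)])  # observed untouched
  ## large column: imputed mean near mean - 1.8 sd
  big <- matrix(rnorm(20000, 20, 2), ncol = 2)
  colnames(big) <- c("x", "y"); rownames(big) <- sprintf("p%05d", 1:10000)
  big[sample(10000, 4000), 1] <- NA
  obs <- big[, 1]
  imp <- imputeGaussian(big, diffParams(seed = 8))
  target <- mean(obs, na.rm = TRUE) - 1.8 * sd(obs, na.rm = TRUE)
  expect_lt(abs(mean(imp[is.na(big[, 1]), 1]) - target), 0.05)
  expect_lt(abs(sd(imp[is.na(big[, 1]), 1]) - 0.3 * sd(obs, na.rm = TRUE)), 0.05)
})

test_that("permutation FDR is deterministic, monotone, and enumerates small designs", {
  set.seed(21)
  m <- matrix(rnorm(50 * 12), 50, dimnames = list(sprintf("p%02d", 1:50),
                                                  sprintf("s%02d", 1:12)))
  m[1:3, 1:6] <- m[1:3, 1:6] + 4
  lab <- factor(rep(c("ALS", "Con"), each = 6), levels = c("ALS", "Con"))
  p <- diffParams(seed = 5, nPermutations = 200)
  r1 <- permutationFDR(m, lab, p)
  r2 <- permutationFDR(m, lab, p)
  expect_identical(r1, r2)
  ## q non-increasing in |statistic|
  ord <- order(abs(r1$statistic), decreasing = TRUE)
  expect_true(all(diff(r1$q[ord]) >= -1e-12))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
  ## the three planted effects are the top hits
  expect_true(all(c("p01", "p02", "p03") %in%
                    r1$peptide_id[r1$significant]))
  expect_true(all(r1$direction[match(c("p01", "p02", "p03"),
                                     r1$peptide_id)] == "up"))
  ## more permutations than arrangements triggers full enumeration
  small <- m[, 1:6]
  labS <- factor(rep(c("ALS", "Con"), each = 3))
  expect_message(permutationFDR(small, labS,
                                diffParams(nPermutations = 250)),
                 "full enumeration")
})

test_that("rank tests: degenerate input, KW/Wilcoxon agreement, Dunn oracle", {
  expect_equal(wilcoxonRankSum(c(2, 2, 2), c(2, 2))$p, 1)
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12, 1)
  pw <- wilcoxonRankSum(a, b)$p
  pk <- kruskalDunn(c(a, b), rep(c("A", "B"), each = 12))$omnibusP
  expect_lt(abs(pw - pk), 0.01)

  ## fixed 3-group toy against brute-force rank arithmetic
  vals <- c(1.2, 3.4, 2.2, 5.0, 4.1,   2.0, 6.5, 5.5, 7.2, 6.0,
            8.1, 9.4, 7.9, 10.2, 9.0)
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  kd <- kruskalDunn(vals, grp)
  r <- rank(vals); N <- 15
  rb <- tapply(r, grp, mean)
  sg2 <- N * (N + 1) / 12            # no ties here
  zOracle <- c((rb[1] - rb[2]) / sqrt(sg2 * (2 / 5)),
               (rb[1] - rb[3]) / sqrt(sg2 * (2 / 5)),
               (rb[2] - rb[3]) / sqrt(sg2 * (2 / 5)))
  expect_equal(kd$pairwise$z, unname(zOracle), tolerance = 1e-12)
  expect_equal(kd$pairwise$p_adj,
               unname(p.adjust(2 * pnorm(-abs(zOracle)), "holm")),
               tolerance = 1e-12)
})

test_that("Spearman matrix honors monotone invariance and tie correction", {
  set.seed(7)
  x <- rnorm(30)
  df <- cbind(x = x, expx = exp(x), negx = -x)
  sm <- spearmanMatrix(df)
  expect_equal(sm$r["x", "expx"], 1)
  expect_equal(sm$r["x", "negx"], -1)
  expect_equal(unname(diag(sm$r)), rep(1, 3))
  expect_equal(sm$r, t(sm$r))
  ## 10-point toy with ties against the rank-based formula
  a <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  b <- c(2, 1, 3, 3, 5, 4, 6, 7, 7, 9)
  sm2 <- spearmanMatrix(cbind(a = a, b = b))
  expect_equal(sm2$r["a", "b"], cor(rank(a), rank(b)), tolerance = 1e-12)
  ## too few complete pairs flagged missing
  c3 <- cbind(u = c(1, NA, NA, 4), v = c(NA, 2, 3, NA))
  expect_true(is.na(spearmanMatrix(c3)$r["u", "v"]))
})

test_that("separation summary: constructed separation, permuted labels, twins", {
  set.seed(13)
  nS <- 20L
  lab <- rep(c("Con", "ALS"), each = nS / 2)
  m <- matrix(rnorm(10 * nS), 10,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%02d", 1:nS)))
  m[, lab == "ALS"] <- m[, lab == "ALS"] + 8  # 8-sd separation
  s <- separationSummary(m, lab)
  expect_equal(s$specificity, 100)
  expect_gt(s$explained[1], 0.5)
  ## randomly permuted labels: specificity collapses well below the
  ## aligned case (the cluster-majority assignment keeps it above 50%
  ## by construction, so the informative comparison is against 100%)
  specs <- vapply(1:30, function(i) {
    separationSummary(m, sample(lab))$specificity
  }, numeric(1))
  expect_lt(mean(specs), 85)
  ## a duplicated sample co-clusters with its twin
  m2 <- cbind(m, twin = m[, 1] + rnorm(10, 0, 1e-3))
  s2 <- separationSummary(m2, c(lab, lab[1]))
  expect_identical(unname(s2$clusters["twin"]), unname(s2$clusters[1]))
})
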