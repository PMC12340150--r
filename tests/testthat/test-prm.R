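mkReport <- function(ratioA = 1, nT = 5, samples = "s1",
                     lightScale = 1, heavyScale = 1) {
  do.call(rbind, lapply(samples, function(s) {
    base <- 100 * seq_len(nT)
    rbind(data.frame(sample_id = s, peptide_id = "A",
                     transition = sprintf("y%d", seq_len(nT)),
                     channel = "heavy", rt_min = 10, area = base * heavyScale),
          data.frame(sample_id = s, peptide_id = "A",
                     transition = sprintf("y%d", seq_len(nT)),
                     channel = "light", rt_min = 10,
                     area = base * ratioA * lightScale))
  }))
}

test_that("L/H quantification: unit ratio, scale and order invariance", {
  q <- quantifyPRM(mkReport(1), interferenceK = Inf)
  expect_equal(unname(q$ratios["s1", "A"]), 1)
  ## common scale factor on both channels cancels
  q2 <- quantifyPRM(mkReport(2.5, lightScale = 7, heavyScale = 7),
                    interferenceK = Inf)
  expect_equal(unname(q2$ratios["s1", "A"]), 2.5)
  ## transition order is irrelevant
  rep <- mkReport(3)
  repShuf <- rep[sample(nrow(rep)), ]
  expect_equal(quantifyPRM(repShuf, interferenceK = Inf)$ratios,
               quantifyPRM(rep, interferenceK = Inf)$ratios)
})

test_that("interference exclusion is symmetric across channels", {
  rep <- mkReport(2, nT = 6, samples = c("s1", "s2", "s3"))
  ## corrupt one transition's light area in every sample
  hit <- rep$channel == "light" & rep$transition == "y3"
  rep$area[hit] <- rep$area[hit] * 8
  q <- quantifyPRM(rep)
  expect_identical(unique(q$excludedTransitions$transition), "y3")
  expect_identical(unique(q$excludedTransitions$reason), "interference")
  ## with y3 dropped from both sums the clean ratio is restored
  expect_equal(unname(q$ratios[, "A"]), rep(2, 3))
  ## the same exclusion given a priori yields the same ratios
  qPre <- quantifyPRM(rep, interferenceK = Inf,
                      excludeTransitions = data.frame(peptide_id = "A",
                                                      transition = "y3"))
  expect_equal(qPre$ratios, q$ratios)
})

test_that("missing light channel is 'no peak'; absent heavy channel is an error", {
  rep <- mkReport(1, samples = c("s1", "s2"))
  rep <- rep[!(rep$sample_id == "s2" & rep$channel == "light"), ]
  q <- quantifyPRM(rep, interferenceK = Inf)
  expect_true(is.na(q$ratios["s2", "A"]))
  expect_identical(q$missing$reason, "no peak")
  expect_identical(q$missing$sample_id, "s2")
  repBad <- mkReport(1)[mkReport(1)$channel == "light", ]
  expect_error(quantifyPRM(repBad, interferenceK = Inf), "assay failure")
})

test_that("group statistics recover directions and handle degenerate groups", {
  set.seed(5)
  n <- c(Con = 42L, ALS = 67L)
  grp <- factor(rep(names(n), n), levels = names(n))
  ratios <- cbind(
    up1 = exp(rnorm(109, ifelse(grp == "ALS", 1, 0), 0.5)),
    dn1 = exp(rnorm(109, ifelse(grp == "ALS", -1, 0), 0.5)))
  rownames(ratios) <- sprintf("s%03d", 1:109)
  gs <- groupStats(ratios, grp)
  expect_identical(gs$direction, c("up", "down"))
  expect_true(all(gs$p < 0.01))
  expect_identical(unique(gs$test), "wilcoxon")
  ## identical group distributions: p ~ 1
  same <- cbind(flat = c(1:10, 1:10))
  rownames(same) <- sprintf("s%02d", 1:20)
  gsSame <- groupStats(same, rep(c("Con", "ALS"), each = 10))
  expect_gt(gsSame$p, 0.9)
  ## three groups use Kruskal-Wallis + Dunn
  g3 <- factor(rep(c("Con", "sALS", "gALS"), c(10, 10, 10)))
  r3 <- cbind(x = exp(rnorm(30, as.numeric(g3), 0.3)))
  rownames(r3) <- sprintf("s%02d", 1:30)
  gs3 <- groupStats(r3, g3)
  expect_identical(gs3$test, "kruskal-dunn")
  expect_identical(nrow(attr(gs3, "pairwise")$x), 3L)
  ## a group of one sample is flagged, not an error
  g1 <- factor(rep(c("Con", "ALS"), c(1, 9)), levels = c("Con", "ALS"))
  r1 <- cbind(x = exp(rnorm(10)))
  rownames(r1) <- sprintf("s%02d", 1:10)
  expect_match(groupStats(r1, g1)$note, "insufficient|one sample")
})

test_that("single-marker AUC matches the Mann-Whitney identity (brute force)", {
  ## perfect separation
  expect_equal(rocSingle(c(1, 2, 3, 10, 11, 12),
                         rep(c("Con", "ALS"), each = 3), "ALS")$auc, 1)
  ## orientation symmetry
  set.seed(31)
  v <- rnorm(20); lab <- rep(c("Con", "ALS"), 10)
  r1 <- rocSingle(v, lab, "ALS")
  r2 <- rocSingle(-v, lab, "ALS")
  expect_equal(r1$auc, r2$auc)
  expect_identical(r1$sign, -r2$sign)
  ## all label arrangements on 3-6 samples per class vs pair counting
  set.seed(7)
  for (k in 1:50) {
    n1 <- sample(3:6, 1); n0 <- sample(3:6, 1)
    v <- sample(seq_len(8), n1 + n0, replace = TRUE)  # ties likely
    lab <- c(rep("ALS", n1), rep("Con", n0))
    pos <- v[lab == "ALS"]; neg <- v[lab == "Con"]
    pairAUC <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(rocSingle(v, lab, "ALS")$auc, max(pairAUC, 1 - pairAUC),
                 tolerance = 1e-12)
  }
  expect_error(rocSingle(1:4, rep("ALS", 4)), "two classes")
})

test_that("null AUC stays near 0.5 and the DeLong CI covers it", {
  set.seed(12)
  v <- rnorm(500); lab <- sample(rep(c("Con", "ALS"), 250))
  r <- rocSingle(v, lab, "ALS")
  expect_lt(r$auc, 0.55)
  expect_gte(r$auc, 0.5)
  expect_true(r$ci[1] <= 0.55 & r$ci[2] >= 0.5)
})

test_that("combined logistic ROC: reduction, separation handling, listwise deletion", {
  set.seed(41)
  lab <- rep(c("Con", "ALS"), each = 30)
  one <- cbind(p1 = exp(rnorm(60, ifelse(lab == "ALS", 0.8, 0), 0.6)))
  rownames(one) <- sprintf("s%02d", 1:60)
  single <- rocSingle(log2(one[, 1]), lab, "ALS")
  comb <- rocCombined(one, lab, positive = "ALS")
  expect_equal(comb$combinedAUC, single$auc, tolerance = 1e-9)
  ## completely separable data converge via the ridge and reach AUC 1
  sep <- cbind(p1 = exp(c(rnorm(30, -3, 0.2), rnorm(30, 3, 0.2))),
               p2 = exp(rnorm(60, 0, 0.2)))
  rownames(sep) <- rownames(one)
  cs <- rocCombined(sep, lab, positive = "ALS")
  expect_equal(cs$combinedAUC, 1)
  expect_gt(cs$ridge, 0)
  ## missingness guard and listwise deletion
  hole <- one
  hole[1:25, 1] <- NA
  expect_error(rocCombined(hole, lab, positive = "ALS"), "missingness")
  two <- cbind(one, p2 = exp(rnorm(60, ifelse(lab == "ALS", 0.8, 0), 0.6)))
  two[1:3, 2] <- NA
  ct <- rocCombined(two, lab, positive = "ALS")
  expect_identical(ct$nDropped, 3L)
})

test_that("fitted coefficient signs recover the generating model at n = 109", {
  set.seed(53)
  hits <- vapply(1:20, function(k) {
    lab <- rep(c("Con", "ALS"), c(42, 67))
    x <- cbind(up = exp(rnorm(109, ifelse(lab == "ALS", 0.9, 0), 0.7)),
               dn = exp(rnorm(109, ifelse(lab == "ALS", -0.9, 0), 0.7)))
    rownames(x) <- sprintf("s%03d", 1:109)
    cf <- rocCombined(x, lab, positive = "ALS")$coefficients
    cf[["up"]] > 0 && cf[["dn"]] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("external-assay correlation behaves across signal regimes", {
  set.seed(19)
  x <- rlnorm(100, 8, 1)
  expect_equal(correlateExternal(x, log(x))$r, 1)  # monotone transform
  shared <- rlnorm(100, 8, 1)
  a <- shared * rlnorm(100, 0, 0.1)
  b <- shared * rlnorm(100, 0, 0.1)
  expect_gt(correlateExternal(a, b)$r, 0.9)
  expect_lt(abs(correlateExternal(rnorm(100), rnorm(100))$r), 0.25)
  expect_error(correlateExternal(c(1, 2), c(3, 4)), "3 complete")
})
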