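test_that("proteome generation is deterministic, unique, and guarded", {
  p1 <- simulateProteome(1, seed = 7)
  p2 <- simulateProteome(1, seed = 7)
  expect_identical(as.character(p1), as.character(p2))
  p10 <- simulateProteome(10, seed = 1)
  expect_length(unique(names(p10)), 10L)
  expect_true(all(Biostrings::width(p10) >= 100 & Biostrings::width(p10) <= 1500))
  expect_error(simulateProteome(0), "positive")
})

test_that("peptide catalog entries are true substrings with correct flanks", {
  sim <- tinySim()
  real <- sim$catalog[!sim$catalog$is_standard, ]
  protSeq <- as.character(sim$proteins)
  for (i in seq_len(nrow(real))) {
    r <- real[i, ]
    rep <- validatePeptideRecord(r, protSeq[[r$accession]])
    expect_true(rep$pass,
                info = paste(r$peptide_id, paste(rep$failures, collapse = "; ")))
  }
})

test_that("realized dynamic range and tryptic fraction match the config", {
  sim <- tinySim()
  lm <- sim$trueState$log10Mean[!sim$catalog$is_standard]
  expect_gte(max(lm) - min(lm), 7.5)
  expect_lte(max(lm) - min(lm), 8.5)
  frac <- mean(sim$catalog$tryptic_like[!sim$catalog$is_standard])
  expect_lt(abs(frac - 0.25), 0.05)
})

test_that("trypticLikeFraction = 0 forbids and-mode tryptic peptides", {
  cfg <- SimConfig(seed = 5L, nProteins = 10L, nPeptides = 100L,
                   nPerGroup = c(Con = 2L, ALS = 2L),
                   trypticLikeFraction = 0)
  sim <- simulatePeptidome(simulateProteome(10, 5), cfg)
  real <- sim$catalog[!sim$catalog$is_standard, ]
  expect_false(any(isTrypticLike(real$preceding_residue, real$sequence, "and")))
})

test_that("cohort simulation is deterministic and respects the catalog", {
  sim <- tinySim()
  pe2 <- simulateCohort(sim$catalog, sim$trueState, sim$cfg)
  expect_identical(abundance(sim$pe), abundance(pe2))
  expect_true(all(rownames(sim$pe) %in% sim$catalog$peptide_id))
  ## standards present in >= 99% of samples
  std <- abundance(sim$pe)[standardIds(sim$pe), ]
  expect_gte(mean(!is.na(std)), 0.99)
})

test_that("detection rate is non-increasing across descending abundance deciles", {
  sim <- tinySim()
  real <- !sim$catalog$is_standard
  lm <- sim$trueState$log10Mean[real]
  obs <- rowMeans(!is.na(abundance(sim$pe)[real, ]))
  dec <- cut(lm, quantile(lm, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  rate <- tapply(obs, dec, mean)   # decile 1 = lowest abundance
  expect_true(all(diff(rate) >= -0.02))  # monotone up in abundance
})

test_that("null simulation recovers zero log2 difference, effects recover their fold", {
  cfg <- SimConfig(seed = 9L, nProteins = 20L, nPeptides = 60L,
                   nPerGroup = c(Con = 24L, ALS = 24L))
  prot <- simulateProteome(cfg@nProteins, cfg@seed)
  sim <- simulatePeptidome(prot, cfg)
  ## focus on well-detected peptides
  ids <- names(sort(sim$trueState$log10Mean, decreasing = TRUE))[1:20]
  ids <- setdiff(ids, cfg@standardIds)[1:10]
  nrep <- 50L
  dmat <- vapply(seq_len(nrep), function(r) {
    pe <- simulateCohort(sim$catalog, sim$trueState, cfg, seed = 1000L + r)
    norm <- normalizeQuant(pe, "stdpep")
    m <- log2(abundance(norm)[ids, ])
    g <- colData(pe)$group
    rowMeans(m[, g == "ALS"], na.rm = TRUE) -
      rowMeans(m[, g == "Con"], na.rm = TRUE)
  }, numeric(length(ids)))
  mc <- rowMeans(dmat)
  se <- apply(dmat, 1, sd) / sqrt(nrep)
  expect_true(all(abs(mc) < 3 * se + 1e-3))

  ## planted 2-fold effect recovers log2 difference 1.0 +/- 0.15
  cfg2 <- SimConfig(seed = 9L, nProteins = 20L, nPeptides = 60L,
                    nPerGroup = c(Con = 24L, ALS = 24L),
                    effectTable = data.frame(peptide = ids[1], group = "ALS",
                                             fold = 2))
  sim2 <- simulatePeptidome(prot, cfg2)
  d2 <- vapply(seq_len(20L), function(r) {
    pe <- simulateCohort(sim2$catalog, sim2$trueState, cfg2, seed = 2000L + r)
    norm <- normalizeQuant(pe, "stdpep")
    m <- log2(abundance(norm)[ids[1], , drop = FALSE])
    g <- colData(pe)$group
    mean(m[, g == "ALS"], na.rm = TRUE) - mean(m[, g == "Con"], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(d2) - 1), 0.15)
})

test_that("PRM simulation honors ratios, interference and below-limit flags", {
  panel <- tinyPanel()
  ratios <- matrix(c(2, 0.5, 1, 1), 2, 2,
                   dimnames = list(c("s1", "s2"), c("A", "B")))
  ## no noise: L/H identical across transitions and equal to the true ratio
  rep0 <- simulatePRM(panel, ratios, seed = 1, noiseCV = 0, rtJitter = 0)
  q <- quantifyPRM(rep0, panel, interferenceK = Inf)
  expect_equal(q$ratios[c("s1", "s2"), "A"], c(s1 = 2, s2 = 0.5))
  lh <- with(subset(rep0, peptide_id == "A" & sample_id == "s1"),
             tapply(area, list(transition, channel), identity))
  expect_equal(unname(lh[, "light"] / lh[, "heavy"]), rep(2, 10))

  ## injected interference deviates from the other transitions' spread
  repI <- simulatePRM(panel, ratios, seed = 1, noiseCV = 0.02,
                      interference = data.frame(peptide_id = "A",
                                                transition = "A_y3",
                                                factor = 5))
  sub <- subset(repI, peptide_id == "A" & sample_id == "s1")
  lhr <- vapply(unique(sub$transition), function(tr)
    sub$area[sub$transition == tr & sub$channel == "light"] /
      sub$area[sub$transition == tr & sub$channel == "heavy"], numeric(1))
  others <- lhr[names(lhr) != "A_y3"]
  expect_gt(abs(log(lhr[["A_y3"]]) - median(log(others))),
            3 * (max(log(others)) - min(log(others))))

  ## below-limit sample emits no light peaks for that peptide
  repB <- simulatePRM(panel, ratios, seed = 1,
                      belowLimit = data.frame(sample_id = "s2",
                                              peptide_id = "B"))
  expect_equal(nrow(subset(repB, sample_id == "s2" & peptide_id == "B" &
                             channel == "light")), 0L)
  expect_gt(nrow(subset(repB, sample_id == "s2" & peptide_id == "B" &
                          channel == "heavy")), 0L)
})

test_that("clinical covariates realize the configured Spearman targets", {
  cfg <- SimConfig(seed = 21L, nProteins = 20L, nPeptides = 100L,
                   nPerGroup = c(Con = 30L, ALS = 37L),
                   missingness = c(-2, 1.5),  # near-complete detection
                   clinicalEffects = data.frame(covariate = "qalb",
                                                peptide = "PEP00010",
                                                r = -0.4))
  prot <- simulateProteome(cfg@nProteins, cfg@seed)
  sim <- simulatePeptidome(prot, cfg)
  pe <- simulateCohort(sim$catalog, sim$trueState, cfg)
  cl <- simulateClinical(pe, cfg)
  r <- cor(log2(abundance(pe)["PEP00010", ]), cl$qalb,
           method = "spearman", use = "pairwise.complete.obs")
  expect_true(r > -0.55 && r < -0.25)
  ## untargeted covariate stays near zero
  r0 <- cor(log2(abundance(pe)["PEP00011", ]), cl$age,
            method = "spearman", use = "pairwise.complete.obs")
  expect_lt(abs(r0), 0.25)
  ## unrealizable target rejected at construction
  expect_error(SimConfig(clinicalEffects = data.frame(
    covariate = "age", peptide = "x", r = 1.5)), "r")
})

test_that("SimConfig validity rejects malformed settings", {
  expect_error(SimConfig(technicalCV = 1.2), "technicalCV")
  expect_error(SimConfig(nPerGroup = c(Con = 1L, ALS = 24L)), "group sizes")
  expect_error(SimConfig(nPerGroup = c(Foo = 5L, ALS = 5L)), "label")
})
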