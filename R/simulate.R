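#' @importFrom Biostrings AAStringSet
#' @importFrom stats rlnorm rnorm runif plogis qnorm rbinom median sd quantile
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic protein set
#'
#' Random amino-acid sequences over the 20-letter alphabet with lengths
#' uniform in 100--1500 residues, as a stand-in parent proteome for the
#' peptide catalog. Accessions are unique and deterministic given the seed.
#'
#' @param nProteins number of proteins (>= 1).
#' @param seed integer seed.
#' @return an [Biostrings::AAStringSet] named by accession.
#' @examples
#' prot <- simulateProteome(3, seed = 7)
#' names(prot)
#' @export
simulateProteome <- function(nProteins, seed = 1L) {
  if (length(nProteins) != 1L || is.na(nProteins) || nProteins < 1)
    stop("nProteins must be a positive count")
  nProteins <- as.integer(nProteins)
  .withSeed(.streamSeed(seed, "proteome"), {
    lens <- sample(100:1500, nProteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(.AA20, L, replace = TRUE), collapse = ""), character(1))
    aa <- AAStringSet(seqs)
    names(aa) <- sprintf("SIMP%04d", seq_len(nProteins))
    aa
  })
}

## Sample one tryptic-like window (preceded by K/R, ending in K/R) from a
## protein; returns c(start, end) or NULL if none fits the length bounds.
.sampleTrypticWindow <- function(seq, minLen, maxLen) {
  ch <- strsplit(seq, "")[[1]]
  kr <- which(ch %in% c("K", "R"))
  if (length(kr) < 2L) return(NULL)
  starts <- kr + 1L                      # position after a K/R
  starts <- starts[starts <= length(ch)]
  for (i in sample(seq_along(starts))) {
    s <- starts[i]
    ends <- kr[kr >= s + minLen - 1L & kr <= s + maxLen - 1L]
    if (length(ends)) return(c(s, sample(rep(ends, 2L), 1L)))
  }
  NULL
}

#' Generate a synthetic peptide catalog with ground truth
#'
#' Draws `nPeptides` endogenous peptides as true substrings of the given
#' proteins (length 7--40), with flanking residues recorded, a controlled
#' fraction of tryptic-like peptides (preceded by K/R and ending in K/R),
#' true mean abundances log10-uniform over the configured dynamic range,
#' and the five spike-in standard peptides appended. Planted group effects
#' (`effectTable`) and per-group tryptic-fraction differences become part
#' of the returned ground truth.
#'
#' @param proteins an `AAStringSet` from [simulateProteome()].
#' @param config a [SimConfig()].
#' @param seed integer; defaults to the config's master seed.
#' @return list with elements `catalog` (data.frame: peptide_id,
#'   accession, sequence, start, end, preceding_residue, following_residue,
#'   quality, is_standard, tryptic_like) and `trueState` (list: log10Mean,
#'   groupFold matrix, trypticFlag, differentialSet, suppressed).
#' @export
simulatePeptidome <- function(proteins, config, seed = config@seed) {
  if (length(proteins) == 0L) stop("proteins must be non-empty")
  validObject(config)
  nPep <- config@nPeptides
  groups <- names(config@nPerGroup)
  fTarget <- config@trypticLikeFraction
  fCat <- max(fTarget)
  .withSeed(.streamSeed(seed, "peptidome"), {
    nTryp <- round(fCat * nPep)
    seqsChr <- as.character(proteins)
    acc <- names(proteins)
    recs <- vector("list", nPep)
    i <- 0L
    guard <- 0L
    while (i < nPep) {
      guard <- guard + 1L
      if (guard > 200L * nPep)
        stop("unsatisfiable trypticLikeFraction given the protein sequences")
      p <- sample(length(proteins), 1L)
      ps <- seqsChr[[p]]
      L <- nchar(ps)
      wantTryptic <- i < nTryp
      if (wantTryptic) {
        w <- .sampleTrypticWindow(ps, 7L, 40L)
        if (is.null(w)) next
        s <- w[1]; e <- w[2]
      } else {
        len <- sample(7:40, 1L)
        if (L < len + 1L) next
        s <- sample(seq_len(L - len + 1L), 1L)
        e <- s + len - 1L
      }
      pep <- substr(ps, s, e)
      prev <- if (s > 1L) substr(ps, s - 1L, s - 1L) else NA_character_
      foll <- if (e < L) substr(ps, e + 1L, e + 1L) else NA_character_
      isTryp <- !is.na(prev) && prev %in% c("K", "R") &&
        substr(pep, nchar(pep), nchar(pep)) %in% c("K", "R")
      if (wantTryptic != isTryp) next   # rejection keeps the fraction exact
      i <- i + 1L
      recs[[i]] <- data.frame(
        peptide_id = sprintf("PEP%05d", i), accession = acc[p],
        sequence = pep, start = s, end = e,
        preceding_residue = prev, following_residue = foll,
        stringsAsFactors = FALSE)
    }
    catalog <- do.call(rbind, recs)
    catalog$quality <- round(runif(nPep, 5, 60), 1)  # all pass the >= 5 filter
    catalog$is_standard <- FALSE
    catalog$tryptic_like <- c(rep(TRUE, nTryp), rep(FALSE, nPep - nTryp))
    ## randomize row order so peptide index carries no signal
    ord <- sample(nPep)
    catalog <- catalog[ord, , drop = FALSE]
    catalog$peptide_id <- sprintf("PEP%05d", seq_len(nPep))
    rownames(catalog) <- NULL

    ## spike-in standards: non-human, no parent protein in the FASTA
    nStd <- length(config@standardIds)
    std <- data.frame(
      peptide_id = config@standardIds, accession = NA_character_,
      sequence = vapply(seq_len(nStd), function(k)
        paste(sample(.AA20, 12, replace = TRUE), collapse = ""), character(1)),
      start = NA_integer_, end = NA_integer_,
      preceding_residue = NA_character_, following_residue = NA_character_,
      quality = 60, is_standard = TRUE, tryptic_like = FALSE,
      stringsAsFactors = FALSE)
    catalog <- rbind(catalog, std)

    ## true log10 mean abundances: uniform over the configured span
    log10Mean <- c(runif(nPep, 0, config@dynamicRangeOrders),
                   config@standardNominal)
    names(log10Mean) <- catalog$peptide_id

    groupFold <- matrix(1, nrow(catalog), length(groups),
                        dimnames = list(catalog$peptide_id, groups))
    if (nrow(config@effectTable)) {
      bad <- setdiff(config@effectTable$group, groups)
      if (length(bad))
        stop("effectTable group(s) not in nPerGroup: ",
             paste(bad, collapse = ", "))
      for (k in seq_len(nrow(config@effectTable))) {
        et <- config@effectTable[k, ]
        if (!et$peptide %in% catalog$peptide_id)
          stop("effectTable peptide not in catalog: ", et$peptide)
        groupFold[et$peptide, et$group] <- et$fold
      }
    }

    ## per-group tryptic-fraction differences: suppress a subset of
    ## tryptic-like peptides in the lower-fraction groups so they fall
    ## below the detection curve there
    suppressed <- list()
    if (!is.null(names(fTarget)) && length(fTarget) > 1L) {
      trypIds <- catalog$peptide_id[catalog$tryptic_like]
      for (g in names(fTarget)) {
        drop <- round((fCat - fTarget[[g]]) / fCat * length(trypIds))
        if (drop > 0) {
          ids <- sample(trypIds, drop)
          groupFold[ids, g] <- groupFold[ids, g] * 1e-4
          suppressed[[g]] <- ids
        }
      }
    }

    diffSet <- rownames(groupFold)[apply(groupFold != 1, 1, any)]
    diffSet <- setdiff(diffSet, unlist(suppressed))
    list(catalog = catalog,
         trueState = list(log10Mean = log10Mean, groupFold = groupFold,
                          trypticFlag = structure(catalog$tryptic_like,
                                                  names = catalog$peptide_id),
                          differentialSet = diffSet,
                          suppressed = suppressed))
  })
}

#' Simulate a cohort quantification matrix
#'
#' Each abundance entry is `true mean x group fold x sample factor x
#' lognormal noise`; spike-in standards additionally carry a shared
#' per-sample run factor (spiking variation), which is what makes StdPep
#' normalization a non-trivial correction. An entry is observed with
#' probability given by a logistic detection curve in log10 abundance
#' (missing-not-at-random, left-censored); standards are always detected.
#' QC samples, if present in `nPerGroup`, are drawn at group fold 1.
#'
#' @param catalog,trueState from [simulatePeptidome()].
#' @param config a [SimConfig()].
#' @param seed integer; defaults to the config's master seed.
#' @return a [PeptidomeExperiment] in state `"raw"`, with the sample
#'   technical factors and standard run factors stored in `metadata()`.
#' @export
simulateCohort <- function(catalog, trueState, config, seed = config@seed) {
  validObject(config)
  if (!identical(catalog$peptide_id, names(trueState$log10Mean)))
    stop("catalog and trueState are inconsistent")
  groups <- names(config@nPerGroup)
  if (!all(colnames(trueState$groupFold) %in% groups))
    stop("trueState group label absent from config nPerGroup")
  .withSeed(.streamSeed(seed, "cohort"), {
    sampleGroup <- rep(groups, config@nPerGroup)
    sampleIds <- unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(config@nPerGroup[[g]]))))
    nS <- length(sampleIds); nP <- nrow(catalog)
    isStd <- catalog$is_standard

    sampleFactor <- .rlnormCV(nS, config@sampleFactorCV)
    runFactor <- .rlnormCV(nS, config@standardRunCV)
    names(sampleFactor) <- names(runFactor) <- sampleIds

    base <- 10^trueState$log10Mean
    fold <- trueState$groupFold[, sampleGroup, drop = FALSE]
    mu <- base * fold                        # peptides x samples
    mu <- sweep(mu, 2, sampleFactor, "*")
    mu[isStd, ] <- sweep(mu[isStd, , drop = FALSE], 2, runFactor, "*")
    noise <- matrix(.rlnormCV(nP * nS, config@technicalCV), nP, nS)
    ab <- mu * noise

    pDet <- plogis(config@missingness[2] * (log10(ab) - config@missingness[1]))
    pDet[isStd, ] <- 1
    det <- matrix(rbinom(nP * nS, 1L, pDet), nP, nS) == 1L
    ab[!det] <- NA_real_
    dimnames(ab) <- list(catalog$peptide_id, sampleIds)

    cd <- DataFrame(sample_id = sampleIds, group = sampleGroup,
                    run_order = seq_len(nS), row.names = sampleIds)
    pe <- PeptidomeExperiment(ab, rowData = catalog, colData = cd,
                              standardIds = config@standardIds)
    metadata(pe)$sampleFactor <- sampleFactor
    metadata(pe)$standardRunFactor <- runFactor
    pe
  })
}

#' Simulate a transition-level PRM report
#'
#' Emits light/heavy peak areas per sample x peptide x transition. The
#' heavy (stable isotope-labeled standard) channel follows the peptide's
#' reference transition-intensity pattern up to technical noise; the light
#' (endogenous) channel is the same pattern scaled by the sample's true
#' light/heavy ratio. Interference can be injected on a named transition
#' (light channel multiplied by a factor), and below-limit samples lose
#' their light peaks entirely.
#'
#' @param panel list of panel entries, each
#'   `list(peptide_id, transitions = data.frame(transition, rel_intensity),
#'   reference_rt)` with >= 3 transitions.
#' @param ratios numeric matrix samples x peptides of true L/H ratios.
#' @param seed integer seed.
#' @param noiseCV per-area lognormal CV (default 0.05).
#' @param interference optional data.frame(peptide_id, transition, factor).
#' @param belowLimit optional data.frame(sample_id, peptide_id).
#' @param rtJitter SD (minutes) of the shared per-sample peak-apex shift.
#' @return data.frame with columns sample_id, peptide_id, transition,
#'   channel, rt_min, area.
#' @export
simulatePRM <- function(panel, ratios, seed = 1L, noiseCV = 0.05,
                        interference = NULL, belowLimit = NULL,
                        rtJitter = 0.02) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  for (p in panel)
    if (nrow(p$transitions) < 3L)
      stop("each panel peptide must declare >= 3 transitions: ", p$peptide_id)
  sampleIds <- rownames(ratios)
  .withSeed(.streamSeed(seed, "prm"), {
    out <- list()
    for (p in panel) {
      pid <- p$peptide_id
      tr <- p$transitions
      heavyBase <- 1e5
      for (s in sampleIds) {
        apex <- p$reference_rt + rnorm(1, 0, rtJitter)
        nT <- nrow(tr)
        hArea <- heavyBase * tr$rel_intensity * .rlnormCV(nT, noiseCV)
        lArea <- heavyBase * tr$rel_intensity * ratios[s, pid] *
          .rlnormCV(nT, noiseCV)
        if (!is.null(interference)) {
          hit <- interference$peptide_id == pid
          if (any(hit)) {
            j <- match(interference$transition[hit], tr$transition)
            lArea[j] <- lArea[j] * interference$factor[hit]
          }
        }
        below <- !is.null(belowLimit) &&
          any(belowLimit$sample_id == s & belowLimit$peptide_id == pid)
        rt <- apex + rnorm(nT, 0, rtJitter / 10)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, peptide_id = pid, transition = tr$transition,
          channel = "heavy", rt_min = rt, area = hArea,
          stringsAsFactors = FALSE)
        if (!below)
          out[[length(out) + 1L]] <- data.frame(
            sample_id = s, peptide_id = pid, transition = tr$transition,
            channel = "light", rt_min = rt, area = lArea,
            stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate clinical covariates with targeted peptide correlations
#'
#' Generates age, sex, ALSFRS-r, disease duration and Qalb for the cohort.
#' Covariates named in the config's `clinicalEffects` are built by a
#' Gaussian copula against the designated peptide's observed log2
#' abundance, so the realized Spearman correlation matches the configured
#' sign and approximate magnitude; ALSFRS-r and disease duration are only
#' defined for ALS-spectrum patients.
#'
#' @param pe a [PeptidomeExperiment] from [simulateCohort()].
#' @param config a [SimConfig()] (uses `clinicalEffects`).
#' @param seed integer; defaults to the config's master seed.
#' @return data.frame of per-sample covariates.
#' @export
simulateClinical <- function(pe, config, seed = config@seed) {
  ce <- config@clinicalEffects
  if (nrow(ce) && any(abs(ce$r) > 1))
    stop("clinical correlation targets must satisfy |r| <= 1")
  samples <- colnames(pe)
  grp <- as.character(colData(pe)$group)
  n <- length(samples)
  alsLike <- grp %in% c("ALS", "sALS", "gALS", "C9orf72", "SOD1")
  .withSeed(.streamSeed(seed, "clinical"), {
    ## latent standard-normal score per targeted covariate
    latent <- function(peptide, r) {
      x <- log2(abundance(pe)[peptide, ])
      if (all(is.na(x))) stop("target peptide has no observed values")
      z <- qnorm(rank(x, na.last = "keep", ties.method = "average") /
                   (sum(!is.na(x)) + 1))
      z[is.na(z)] <- rnorm(sum(is.na(z)))
      rp <- 2 * sin(pi * r / 6)            # Spearman -> Pearson (copula)
      rp * z + sqrt(1 - rp^2) * rnorm(n)
    }
    zdef <- function(cov) {
      hit <- which(ce$covariate == cov)
      if (length(hit) >= 1L) latent(ce$peptide[hit[1]], ce$r[hit[1]])
      else rnorm(n)
    }
    toMarginal <- function(z, qfun) qfun(pnorm(z))
    age <- round(toMarginal(zdef("age"), function(u) qnorm(u, 62, 9)))
    alsfrs <- pmin(48, pmax(0, round(toMarginal(zdef("alsfrs_r"),
                                                function(u) qnorm(u, 40, 5)))))
    dur <- round(toMarginal(zdef("disease_duration"),
                            function(u) exp(qnorm(u, log(12), 0.6))), 1)
    qalb <- round(toMarginal(zdef("qalb"),
                             function(u) exp(qnorm(u, log(6), 0.35))), 2)
    alsfrs[!alsLike] <- NA; dur[!alsLike] <- NA
    data.frame(sample_id = samples, group = grp,
               sex = sample(c("f", "m"), n, replace = TRUE),
               age = age, alsfrs_r = alsfrs, disease_duration = dur,
               qalb = qalb, stringsAsFactors = FALSE)
  })
}
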