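#' Classify a peptide as tryptic-like
#'
#' A tryptic-like peptide is preceded by K/R in its precursor protein and
#' ends with K/R — the basic-residue specificity of trypsin and of
#' several endogenous proteases. Two modes: `"and"` (both conditions;
#' the default definition) and `"or"` (either condition suffices). A
#' peptide at the protein N-terminus (no preceding residue) fails the
#' N-side condition.
#'
#' @param precedingResidue single residue or `NA` at the N-terminus.
#' @param sequence peptide sequence.
#' @param mode `"and"` (default) or `"or"`.
#' @return logical.
#' @examples
#' isTrypticLike("K", "ALEXR")              # TRUE
#' isTrypticLike("K", "SETFQKVKEKLKIDS")    # FALSE in and-mode (ends S)
#' @export
isTrypticLike <- function(precedingResidue, sequence, mode = c("and", "or")) {
  mode <- match.arg(mode)
  nterm <- !is.na(precedingResidue) & precedingResidue %in% c("K", "R")
  nterm[is.na(precedingResidue)] <- FALSE
  cterm <- substr(sequence, nchar(sequence), nchar(sequence)) %in% c("K", "R")
  if (mode == "and") nterm & cterm else nterm | cterm
}

#' Per-sample tryptic-like peptide counts and percentages
#'
#' A peptide counts as observed in a sample when its quantification is
#' non-missing. Percent is `100 * tryptic-like observed / all observed`.
#'
#' @param pe a [PeptidomeExperiment]; `rowData` must carry
#'   `preceding_residue` and `sequence` (the simulator catalog does), or
#'   pass `catalog`.
#' @param catalog optional data.frame with `peptide_id`,
#'   `preceding_residue`, `sequence` covering every quantified peptide.
#' @param mode `"and"` or `"or"`.
#' @param excludeStandards drop spike-ins before counting (default TRUE).
#' @return data.frame: `sample_id`, `count`, `observed`, `percent`.
#' @export
trypticCounts <- function(pe, catalog = NULL, mode = c("and", "or"),
                          excludeStandards = TRUE) {
  mode <- match.arg(mode)
  m <- abundance(pe)
  if (is.null(catalog)) {
    catalog <- as.data.frame(rowData(pe))
    catalog$peptide_id <- rownames(pe)
  }
  miss <- setdiff(rownames(m), catalog$peptide_id)
  if (length(miss))
    stop("catalog misses quantified peptide id(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (excludeStandards) {
    drop <- intersect(standardIds(pe), rownames(m))
    m <- m[setdiff(rownames(m), drop), , drop = FALSE]
  }
  idx <- match(rownames(m), catalog$peptide_id)
  tryp <- isTrypticLike(catalog$preceding_residue[idx],
                        catalog$sequence[idx], mode = mode)
  obs <- !is.na(m)
  count <- colSums(obs & tryp)
  total <- colSums(obs)
  data.frame(sample_id = colnames(m), count = count, observed = total,
             percent = ifelse(total > 0, 100 * count / total, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare tryptic-like statistics between two groups
#'
#' Two-sided Wilcoxon rank-sum p values for both the per-sample count
#' and the per-sample percentage of tryptic-like peptides.
#'
#' @param stats data.frame from [trypticCounts()].
#' @param groups group label per row of `stats` (exactly two levels,
#'   >= 2 samples each).
#' @return list: `pCount`, `pPercent`, `medians` (per group, count and
#'   percent).
#' @export
compareTryptic <- function(stats, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  g1 <- groups == levels(groups)[1]
  list(pCount = wilcoxonRankSum(stats$count[g1], stats$count[!g1])$p,
       pPercent = wilcoxonRankSum(stats$percent[g1], stats$percent[!g1])$p,
       medians = data.frame(
         group = levels(groups),
         count = as.numeric(tapply(stats$count, groups, median)),
         percent = as.numeric(tapply(stats$percent, groups, median))))
}
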