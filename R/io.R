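#' @importFrom Biostrings readAAStringSet writeXStringSet width
#' @importFrom utils read.delim write.table read.csv
#' @importFrom stats pnorm
NULL

#' Read / write a peptide quantification table
#'
#' TSV with a header row of sample ids and the peptide id in the first
#' column. Empty cells are missing values (`NA`), never zero; zeros are
#' measured values. `readQuantTable(writeQuantTable(x))` is the identity,
#' including the missingness pattern.
#'
#' @param path file path.
#' @param standardIds,normalizationState passed to [PeptidomeExperiment()].
#' @param verbose log the row count read.
#' @return a [PeptidomeExperiment] (reader) / `path`, invisibly (writer).
#' @export
readQuantTable <- function(path, standardIds = character(),
                           normalizationState = "raw", verbose = FALSE) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = "")
  if (ncol(df) < 2L) stop("quant table needs a peptide id column and >= 1 sample")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate peptide id(s): ", paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at peptide '%s', sample '%s': '%s'",
                 ids[w[1]], colnames(vals)[w[2]], vals[w[1], w[2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  .msg(verbose, "read %s: %d peptides x %d samples", path, nrow(num), ncol(num))
  PeptidomeExperiment(num, standardIds = standardIds,
                      normalizationState = normalizationState)
}

#' @rdname readQuantTable
#' @param x a `PeptidomeExperiment` or a numeric matrix.
#' @export
writeQuantTable <- function(x, path) {
  m <- if (is(x, "SummarizedExperiment")) abundance(x) else x
  df <- data.frame(peptide_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read protein records from FASTA
#'
#' Accessions are the first whitespace-delimited token of each header;
#' sequences are uppercased. Wrapped sequence lines are concatenated.
#'
#' @param path FASTA file.
#' @param verbose log the record count.
#' @return an [Biostrings::AAStringSet] named by accession.
#' @export
readFasta <- function(path, verbose = FALSE) {
  aa <- tryCatch(readAAStringSet(path),
                 error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  if (any(width(aa) == 0L))
    stop("header without sequence in ", path)
  aa <- Biostrings::AAStringSet(toupper(as.character(aa)))
  names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  .msg(verbose, "read %s: %d protein records", path, length(aa))
  aa
}

#' Validate a peptide record against its parent protein
#'
#' Checks, 1-based inclusive coordinate convention throughout: (i) the
#' stated length `end - start + 1` equals the sequence length; (ii) the
#' protein subsequence at `[start, end]` equals the peptide sequence;
#' (iii) recorded flanking residues match the protein context (a peptide
#' at a protein terminus must record no flank on that side). Failures are
#' report entries, not errors; the function is pure.
#'
#' @param peptide list or one-row data.frame with fields `sequence`,
#'   `start`, `end`, optionally `preceding_residue`, `following_residue`.
#' @param proteinSeq the parent protein sequence (character).
#' @return list: `pass` (logical), `length` (the coordinate-implied
#'   length), `failures` (character vector of failed checks).
#' @examples
#' validatePeptideRecord(list(sequence = "PEPK", start = 2, end = 5),
#'                       "APEPKR")
#' @export
validatePeptideRecord <- function(peptide, proteinSeq) {
  fails <- character()
  s <- as.integer(peptide$start); e <- as.integer(peptide$end)
  pepSeq <- as.character(peptide$sequence)
  if (is.na(s) || is.na(e) || s < 1L || e < s) {
    fails <- c(fails, "coordinate-order violation (need 1 <= start <= end)")
    len <- NA_integer_
  } else {
    len <- e - s + 1L
    if (len != nchar(pepSeq))
      fails <- c(fails, sprintf("length mismatch: coordinates imply %d, sequence has %d",
                                len, nchar(pepSeq)))
    if (!is.null(proteinSeq) && !is.na(proteinSeq)) {
      proteinSeq <- as.character(proteinSeq)
      if (e > nchar(proteinSeq)) {
        fails <- c(fails, "coordinates exceed protein length")
      } else {
        if (substr(proteinSeq, s, e) != pepSeq)
          fails <- c(fails, "sequence does not match protein at stated coordinates")
        prev <- peptide$preceding_residue
        if (!is.null(prev) && !all(is.na(prev))) {
          expected <- if (s > 1L) substr(proteinSeq, s - 1L, s - 1L) else NA_character_
          if (is.na(expected))
            fails <- c(fails, "peptide at protein N-terminus must record no preceding residue")
          else if (expected != prev)
            fails <- c(fails, sprintf("preceding residue '%s' != protein context '%s'",
                                      prev, expected))
        }
        foll <- peptide$following_residue
        if (!is.null(foll) && !all(is.na(foll))) {
          expected <- if (e < nchar(proteinSeq))
            substr(proteinSeq, e + 1L, e + 1L) else NA_character_
          if (is.na(expected))
            fails <- c(fails, "peptide at protein C-terminus must record no following residue")
          else if (expected != foll)
            fails <- c(fails, sprintf("following residue '%s' != protein context '%s'",
                                      foll, expected))
        }
      }
    }
  }
  list(pass = length(fails) == 0L, length = len, failures = fails)
}

#' Parse inline modification syntax from a peptide sequence string
#'
#' Sequences may carry modifications inline, e.g.
#' `"APKKDVKK(trimethylation)PVA"`: the parenthesized name follows the
#' modified residue. Returns the plain sequence and a table of
#' (position within peptide, name).
#'
#' @param seqString sequence with optional `(name)` annotations.
#' @return list: `sequence` (plain), `modifications`
#'   (data.frame position/name).
#' @export
parseModifiedSequence <- function(seqString) {
  mods <- data.frame(position = integer(), name = character(),
                     stringsAsFactors = FALSE)
  plain <- ""
  rest <- seqString
  repeat {
    m <- regexpr("\\(([^)]*)\\)", rest)
    if (m == -1L) { plain <- paste0(plain, rest); break }
    plain <- paste0(plain, substr(rest, 1L, m - 1L))
    name <- substr(rest, m + 1L, m + attr(m, "match.length") - 2L)
    mods <- rbind(mods, data.frame(position = nchar(plain), name = name,
                                   stringsAsFactors = FALSE))
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  list(sequence = plain, modifications = mods)
}

#' Read a transition-level PRM report
#'
#' CSV with mandatory columns `sample_id, peptide_id, transition, channel,
#' area` (optional `rt_min`); `channel` must be `light` or `heavy`.
#' Unknown columns are preserved.
#'
#' @param path CSV file.
#' @param verbose log row count.
#' @return data.frame of typed transition records.
#' @export
readPRMReport <- function(path, verbose = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "peptide_id", "transition", "channel", "area")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("PRM report missing mandatory column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$channel), c("light", "heavy"))
  if (length(bad))
    stop("channel must be 'light' or 'heavy'; found: ", paste(bad, collapse = ", "))
  df$area <- as.numeric(df$area)
  .msg(verbose, "read %s: %d transition rows", path, nrow(df))
  df
}

#' Read a sample sheet
#'
#' TSV with mandatory columns `sample_id` and `group` (closed label set);
#' clinical covariate columns are typed if present, unknown columns kept.
#'
#' @param path TSV file.
#' @param verbose log row count.
#' @return data.frame of sample annotations.
#' @export
readSampleSheet <- function(path, verbose = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("", "NA"))
  miss <- setdiff(c("sample_id", "group"), colnames(df))
  if (length(miss))
    stop("sample sheet missing mandatory column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), .GROUP_LABELS)
  if (length(bad))
    stop(sprintf("unknown group label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(.GROUP_LABELS, collapse = ", ")))
  for (cc in intersect(c("age", "alsfrs_r", "disease_duration", "qalb",
                         "run_order"), colnames(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  if ("run_order" %in% colnames(df)) {
    key <- if ("cohort" %in% colnames(df)) df$cohort
    else rep("all", nrow(df))
    if (any(unlist(tapply(df$run_order, key, duplicated))))
      stop("run_order must be unique within a cohort")
  }
  .msg(verbose, "read %s: %d samples", path, nrow(df))
  df
}

.CONFIG_DEFAULTS <- list(
  s0 = 0.1, fdr = 0.05, n_permutations = 250L,
  impute_width = 0.3, impute_downshift = 1.8,
  presence_policy = "in_70pct_any_group",
  normalization = "stdpep", tryptic_mode = "and",
  min_dotp = 0.7, min_transitions = 10L,
  rt_tolerance = 1.0, coelution_tolerance = 0.1,
  stability_exclusion_limit = 100)

#' Load and validate an analysis configuration
#'
#' YAML or JSON; unknown keys are rejected, omitted keys are filled from
#' the documented defaults (e.g. `s0 = 0.1`, `fdr = 0.05`,
#' `n_permutations = 250`, imputation width 0.3 / down-shift 1.8). The
#' returned list records which values were defaulted.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`), or `NULL` for pure
#'   defaults.
#' @return named list of validated settings with attribute `"defaulted"`.
#' @export
loadConfig <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  cfg[names(user)] <- user
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must be in (0, 1)")
  if (cfg$s0 < 0) stop("s0 must be non-negative")
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  if (!cfg$presence_policy %in% .PRESENCE_POLICIES)
    stop("presence_policy must be one of: ",
         paste(.PRESENCE_POLICIES, collapse = ", "))
  attr(cfg, "defaulted") <- setdiff(names(.CONFIG_DEFAULTS), names(user))
  cfg
}
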