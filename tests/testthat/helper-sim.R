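# Shared small simulated objects, built once per test run.

.fixtures <- new.env(parent = emptyenv())

tinySim <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- SimConfig(seed = 42L, nProteins = 30L, nPeptides = 400L,
                     nPerGroup = c(Con = 12L, ALS = 12L, QC = 3L),
                     effectTable = data.frame(
                       peptide = c("PEP00050", "PEP00060"),
                       group = "ALS", fold = c(4, 0.25)))
    prot <- simulateProteome(cfg@nProteins, cfg@seed)
    sim <- simulatePeptidome(prot, cfg)
    pe <- simulateCohort(sim$catalog, sim$trueState, cfg)
    .fixtures$tiny <- list(cfg = cfg, proteins = prot,
                           catalog = sim$catalog,
                           trueState = sim$trueState, pe = pe)
  }
  .fixtures$tiny
}

# minimal 2-peptide PRM panel with 10 transitions each
tinyPanel <- function(ids = c("A", "B"), nT = 10L) {
  lapply(seq_along(ids), function(i)
    list(peptide_id = ids[i],
         transitions = data.frame(
           transition = sprintf("%s_y%d", ids[i], seq_len(nT)),
           rel_intensity = exp(-(seq_len(nT) - 1) / 4)),
         reference_rt = 10 + 2 * i))
}

extdata <- function(f)
  system.file("extdata", f, package = "CSFPeptidomics", mustWork = TRUE)
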