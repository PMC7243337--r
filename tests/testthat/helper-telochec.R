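## Minimal templates built directly from the class constructor, used to probe
## the simulator and caller with fully controlled ground truth.

emptyOccupants <- function() {
  data.frame(protein = character(0), start = integer(0), end = integer(0),
             protection = numeric(0))
}

.toyFeatures <- function(name, len, probeEnd, terminal) {
  df <- data.frame(
    name = c("anchor", "probe", if (terminal) "TG_tract" else "closing"),
    kind = c("restriction_site", "probe",
             if (terminal) "TG_tract" else "restriction_site"),
    start = c(0L, 0L, if (terminal) len - 400L else len - 1L),
    end = c(1L, probeEnd, len),
    source = "reconstructed", citation = NA_character_)
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$kind <- df$kind
  S4Vectors::mcols(gr)$source <- df$source
  S4Vectors::mcols(gr)$citation <- df$citation
  gr
}

makeToyTemplate <- function(len = 1000L, probeEnd = 100L,
                            occupants = emptyOccupants(),
                            terminal = FALSE, name = "toy") {
  new("SubtelomereTemplate",
      name = name, length = as.integer(len), anchor = "anchor",
      features = .toyFeatures(name, as.integer(len), as.integer(probeEnd),
                              terminal),
      occupants = occupants,
      probe = IRanges::IRanges(start = 1L, end = as.integer(probeEnd)),
      terminal = terminal,
      tgMean = if (terminal) 300 else NA_real_,
      tgSD = if (terminal) 75 else NA_real_,
      sites = data.frame(label = character(0), offset = numeric(0),
                         window = numeric(0), source = character(0),
                         citation = character(0)),
      gaps = data.frame(from = character(0), to = character(0),
                        primary = character(0)))
}

## A template whose only accessible DNA is a single window at offset q.
toySingleWindow <- function(q, len = 1500L, probeEnd = 100L,
                            window = 8L, protection = 0.99) {
  occ <- data.frame(
    protein = c("Tbf1", "Reb1"),
    start = as.integer(c(0L, q + window)),
    end = as.integer(c(q - window, len - 1L)),
    protection = protection)
  makeToyTemplate(len, probeEnd, occ, name = sprintf("toy_q%d", q))
}

## A positioned nucleosome array with accessible linkers.
toyNucArray <- function(nNuc = 8L, linker = 15L, probeEnd = 100L) {
  repeatLen <- 146L + linker
  starts <- probeEnd + (seq_len(nNuc) - 1L) * repeatLen
  len <- probeEnd + nNuc * repeatLen + 50L
  occ <- data.frame(protein = "nucleosome", start = as.integer(starts),
                    end = as.integer(starts + 146L), protection = 0.995)
  makeToyTemplate(len, probeEnd, occ, name = "toy_array")
}

## Consensus-with-background count matrix (strong base 17, others 1).
consensusCounts <- function(consensus, id = "TEST") {
  b <- strsplit(consensus, "")[[1L]]
  m <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) m[b[j], j] <- 17
  countMatrix(m, id = id)
}

defaultConstructs <- function() c("GBD-MN", "NLS-MN", "MN-Rap1", "H2A-MN")

runGroundTruthExperiment <- function(name, seed, nMolecules = 2000L,
                                     constructs = defaultConstructs()) {
  tpl <- buildTemplate(name)
  params <- digestionParams(nMolecules = nMolecules, seed = seed)
  lanes <- simulateExperiment(tpl, constructs, params,
                              design = defaultLaneDesign())
  c(processExperiment(lanes, tpl), list(template = tpl))
}
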