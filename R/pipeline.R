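#' @include AllClasses.R AllGenerics.R chec-sim.R gel.R caller.R inference.R
NULL

## ---------------------------------------------------------------------------
## End-to-end driver: simulate -> render -> call -> consolidate -> classify
## -> reconstruct (-> ratios, fold-back), with flat-file configuration and a
## run manifest. All randomness flows from the single master seed through
## laneSeed(); no stage consults ambient entropy.
## ---------------------------------------------------------------------------

#' Call bands and consolidate sites for a simulated experiment
#'
#' Renders every lane, detects bands (excluding the uncut input band),
#' converts sizes to cut offsets by indirect end-labeling, pools the
#' observations and consolidates them into preferential sites. H2A-MN
#' lanes contribute cut sites only from the 4 C regime, called with a
#' lower prominence threshold: the very partial nucleosomal digestion on
#' ice is what makes probe-distal sites detectable, whereas the 30 C
#' H2A-MN lanes run to complete digestion and carry end-point
#' mono-nucleosomal products instead of site information. Only clusters
#' supported by at least `minSupport` observations are reported as
#' preferential sites (reproducibility across lanes).
#'
#' @param lanes list of [FragmentPopulation-class] from
#'   [simulateExperiment()].
#' @param template the simulated [SubtelomereTemplate-class].
#' @param calibration a [GelCalibration-class].
#' @param bandSigma band width used for rendering, profile units.
#' @param minProminence default band-calling threshold.
#' @param coldH2AProminence threshold for H2A-MN lanes at 4 C.
#' @param tolerance consolidation tolerance, bp.
#' @param minSupport minimal supporting observations per site.
#' @return list: `bands` (pooled band table with offsets), `sites`
#'   (consolidated), `profiles` (list of [LaneProfile-class]).
#' @export
processExperiment <- function(lanes, template,
                              calibration = defaultCalibration(),
                              bandSigma = 0.25, minProminence = 0.05,
                              coldH2AProminence = 0.03, tolerance = 25,
                              minSupport = 2L) {
  cutoff <- uncutThreshold(template)
  minSize <- IRanges::end(probeRegion(template))
  profiles <- lapply(lanes, renderLane, calibration = calibration,
                     bandSigma = bandSigma)
  bands <- lapply(seq_along(lanes), function(i) {
    ln <- lanes[[i]]
    if (ln@time == 0) return(NULL)     # uncut lane: nothing sub-full-length
    if (ln@construct == "H2A-MN" && ln@temperature != "4C") return(NULL)
    mp <- if (ln@construct == "H2A-MN") coldH2AProminence else minProminence
    b <- detectBands(profiles[[i]], calibration, minProminence = mp,
                     excludeAboveSize = cutoff, excludeBelowSize = minSize)
    if (!nrow(b)) return(NULL)
    sizesToCutOffsets(b, template)
  })
  bands <- do.call(rbind, bands)
  if (is.null(bands))
    bands <- data.frame(template = character(0), construct = character(0),
                        time = numeric(0), temperature = character(0),
                        position = numeric(0), size = numeric(0),
                        percentSignal = numeric(0), prominence = numeric(0),
                        offset = numeric(0))
  sites <- consolidateSites(bands, template, tolerance = tolerance,
                            minSupport = minSupport)
  list(bands = bands, sites = sites, profiles = profiles)
}

#' Assemble a pipeline configuration
#'
#' @param templates template names to analyze.
#' @param constructs MNase-fusion construct names.
#' @param nMolecules molecules per lane.
#' @param baseRate cuts per accessible bp per minute at 30 C.
#' @param seed master seed.
#' @param bandSigma gel band width, profile units.
#' @param tolerance consolidation tolerance, bp.
#' @param minProminence band-calling threshold.
#' @param threshold nucleosome-footprint classifier threshold, bp.
#' @param foldback also run the fold-back discrimination experiment.
#' @return a named list of class `ChecRunConfig`.
#' @export
runConfig <- function(templates = c("YpTRF", "TEL03L", "TEL06R",
                                    "X05R_AF", "X16R_AF"),
                      constructs = c("GBD-MN", "NLS-MN", "MN-Rap1",
                                     "H2A-MN"),
                      nMolecules = 2000L, baseRate = 0.025, seed = 1L,
                      bandSigma = 0.25, tolerance = 25,
                      minProminence = 0.05, threshold = 146,
                      foldback = FALSE) {
  stopifnot(all(templates %in% templateNames()), threshold > 0)
  structure(list(templates = templates, constructs = constructs,
                 nMolecules = as.integer(nMolecules), baseRate = baseRate,
                 seed = as.integer(seed), bandSigma = bandSigma,
                 tolerance = tolerance, minProminence = minProminence,
                 threshold = threshold, foldback = isTRUE(foldback)),
            class = "ChecRunConfig")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines of the form `key = value`; comma-separated values for the list
#' keys `templates` and `constructs`; `#` starts a comment. Unknown keys
#' are rejected with their line numbers.
#' @param file path.
#' @return a `ChecRunConfig`.
#' @export
readRunConfig <- function(file) {
  lines <- readLines(file)
  base <- runConfig()
  numKeys <- c("nMolecules", "baseRate", "seed", "bandSigma", "tolerance",
               "minProminence", "threshold")
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line ", i, ": '", lines[i], "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key %in% c("templates", "constructs")) {
      base[[key]] <- trimws(strsplit(val, ",")[[1L]])
    } else if (key %in% numKeys) {
      base[[key]] <- as.numeric(val)
    } else if (key == "foldback") {
      base[[key]] <- toupper(val) %in% c("TRUE", "YES", "1")
    } else {
      stop("unknown config key '", key, "' at line ", i)
    }
  }
  base$nMolecules <- as.integer(base$nMolecules)
  base$seed <- as.integer(base$seed)
  stopifnot(all(base$templates %in% templateNames()))
  base
}

#' Write a pipeline configuration as a flat key-value file
#' @param config a `ChecRunConfig`.
#' @param file path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, file) {
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = ", ")
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, "")), file)
  invisible(file)
}

## Stable short hash of a configuration (rolling 31-bit polynomial).
.configHash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  sprintf("%08x", h)
}

#' Run the full ChEC analysis pipeline
#'
#' For every configured template: simulate the ChEC experiment (all
#' configured constructs over the default lane design), render lanes,
#' call bands, consolidate preferential sites, classify the inter-site
#' intervals, reconstruct the chromatin model, and compute the junction
#' accessibility ratio per construct where defined. Deterministic for a
#' fixed configuration: rerunning with the same seed reproduces every
#' output exactly.
#'
#' @param config a `ChecRunConfig` from [runConfig()].
#' @return list with one entry per template (`sites`, `bands`,
#'   `intervals`, `model`, `ratios`), plus `foldback` (if requested) and
#'   a `manifest` recording the configuration hash and seed.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "ChecRunConfig"))
  design <- defaultLaneDesign()
  params <- digestionParams(nMolecules = config$nMolecules,
                            timePoints = sort(unique(c(0, design$time))),
                            baseRate = config$baseRate,
                            seed = config$seed)
  out <- list()
  for (nm in config$templates) {
    tpl <- buildTemplate(nm)
    lanes <- tryCatch(
      simulateExperiment(tpl, config$constructs, params, design = design),
      error = function(e) stop("stage simulate, template ", nm, ": ",
                               conditionMessage(e), call. = FALSE))
    res <- tryCatch(
      processExperiment(lanes, tpl, bandSigma = config$bandSigma,
                        minProminence = config$minProminence,
                        tolerance = config$tolerance),
      error = function(e) stop("stage call, template ", nm, ": ",
                               conditionMessage(e), call. = FALSE))
    intervals <- classifyIntervals(res$sites, tpl,
                                   threshold = config$threshold)
    model <- reconstructModel(intervals, tpl)
    ratios <- NULL
    if (!is.null(accessRatioSpec(nm))) {
      ratios <- lapply(config$constructs, function(con)
        accessibilityRatio(res$bands, res$sites, tpl, con,
                           tolerance = config$tolerance))
      names(ratios) <- config$constructs
    }
    out[[nm]] <- list(sites = res$sites, bands = res$bands,
                      intervals = intervals, model = model,
                      ratios = ratios)
  }
  if (config$foldback) {
    fb <- list()
    for (mode in c("direct_binding", "foldback"))
      for (cond in list(c("WT", "chromosomal"), c("sirD", "chromosomal"),
                        c("WT", "plasmid")))
        fb[[paste(mode, cond[1L], cond[2L], sep = ".")]] <-
          foldbackTest(mode, cond[1L], cond[2L], params, design,
                       tolerance = config$tolerance,
                       minProminence = config$minProminence)
    out$foldback <- fb
  }
  out$manifest <- list(configHash = .configHash(config),
                       seed = config$seed,
                       nMolecules = config$nMolecules,
                       templates = config$templates,
                       constructs = config$constructs)
  out
}

#' Write pipeline results to a directory
#'
#' One TSV per table (sites, bands, intervals), a BED track of inferred
#' occupants per template, and a manifest recording the configuration
#' hash and seed.
#' @param results list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePipelineResults <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(results), c("manifest", "foldback"))) {
    r <- results[[nm]]
    writeSitesTSV(r$sites, file.path(dir, paste0(nm, "_sites.tsv")))
    utils::write.table(r$bands, file.path(dir, paste0(nm, "_bands.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeIntervalsTSV(r$intervals,
                      file.path(dir, paste0(nm, "_intervals.tsv")))
    if (nrow(r$model@intervals))
      writeModelBED(r$model, r$sites,
                    file.path(dir, paste0(nm, "_model.bed")))
  }
  mf <- results$manifest
  writeLines(c(sprintf("configHash = %s", mf$configHash),
               sprintf("seed = %d", mf$seed),
               sprintf("nMolecules = %d", mf$nMolecules),
               sprintf("templates = %s",
                       paste(mf$templates, collapse = ", ")),
               sprintf("constructs = %s",
                       paste(mf$constructs, collapse = ", "))),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}
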