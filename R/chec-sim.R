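#' @include AllClasses.R AllGenerics.R templates.R
NULL

## ---------------------------------------------------------------------------
## Forward ChEC model. Cuts are an inhomogeneous Poisson process with per-bp
## mean k * a(x) * c(x) * temperatureFactor * time, where a(x) is occupancy-
## derived accessibility and c(x) the relative local concentration of the
## MNase fusion. Restriction cuts at the declared restriction_site features
## are deterministic; probe-overlapping fragments are the detected ones.
## ---------------------------------------------------------------------------

#' MNase fusion construct presets
#'
#' Presets for the five fusion constructs used in the analysis. `GBD-MN`
#' and `NLS-MN` are untargeted nuclear nucleases (free, uniform
#' concentration). `MN-Rap1` is delivered to Rap1-bound DNA: the terminal
#' TG tract and any annotated Rap1 sites. `H2A-MN` is incorporated into
#' nucleosomes and cuts nearby linkers. `Yku70-MN` is loaded at the
#' physical chromosome end.
#'
#' @param name one of `GBD-MN`, `NLS-MN`, `MN-Rap1`, `H2A-MN`,
#'   `Yku70-MN`.
#' @param lambda,reach,floor override the preset enhancement amplitude,
#'   box-kernel half-width (bp) and untethered baseline rate. A strongly
#'   sequestered fusion such as MN-Rap1 has a minute free pool (low
#'   floor) and a correspondingly large local enhancement where it is
#'   bound, which is why its cuts away from its binding sites appear only
#'   very late in a time course.
#' @return an [MNConstruct-class].
#' @export
mnConstruct <- function(name, lambda = NULL, reach = NULL, floor = NULL) {
  preset <- switch(name,
    "GBD-MN"   = list(tether = "free", anchorKind = character(0),
                      lambda = 0, reach = 0, floor = 1),
    "NLS-MN"   = list(tether = "free", anchorKind = character(0),
                      lambda = 0, reach = 0, floor = 1),
    "MN-Rap1"  = list(tether = "site",
                      anchorKind = c("Rap1_site", "TG_tract"),
                      lambda = 600, reach = 185, floor = 0.005),
    "H2A-MN"   = list(tether = "nucleosome", anchorKind = character(0),
                      lambda = 8, reach = 146, floor = 0.15),
    "Yku70-MN" = list(tether = "chromosome_end", anchorKind = character(0),
                      lambda = 60, reach = 150, floor = 0.05),
    stop("unknown construct '", name, "'"))
  if (!is.null(lambda)) preset$lambda <- lambda
  if (!is.null(reach)) preset$reach <- reach
  if (!is.null(floor)) preset$floor <- floor
  new("MNConstruct", name = name, tether = preset$tether,
      anchorKind = preset$anchorKind, lambda = preset$lambda,
      reach = preset$reach, floor = preset$floor)
}

#' Digestion time-course parameters
#'
#' @param nMolecules molecules per lane.
#' @param timePoints minutes of calcium-induced MNase activity.
#' @param temperatureFactor named rate multipliers; digestion on ice is
#'   about twentyfold slower than at 30 C.
#' @param baseRate cuts per accessible bp per minute at 30 C. The default
#'   makes a typical 16-20 bp accessible linker near-certain to be cut
#'   within 5 min at 30 C (complete digestion).
#' @param seed master seed; per-lane streams are derived from it with
#'   [laneSeed()].
#' @return a [DigestionParams-class].
#' @export
digestionParams <- function(nMolecules = 2000L,
                            timePoints = c(0, 1, 2, 5, 15),
                            temperatureFactor = c("30C" = 1, "4C" = 0.05),
                            baseRate = 0.025, seed = 1L) {
  new("DigestionParams", nMolecules = as.integer(nMolecules),
      timePoints = timePoints, temperatureFactor = temperatureFactor,
      baseRate = baseRate, seed = as.integer(seed))
}

#' Per-bp accessibility profile of a template
#'
#' Accessibility is 1 on unoccupied DNA and `1 - protection` inside each
#' occupant footprint.
#' @param template a [SubtelomereTemplate-class].
#' @return numeric vector of length `templateLength(template)`; element i
#'   is the accessibility of base offset i - 1.
#' @export
accessibilityProfile <- function(template) {
  stopifnot(is(template, "SubtelomereTemplate"))
  a <- rep(1, templateLength(template))
  occ <- occupants(template)
  for (i in seq_len(nrow(occ)))
    a[(occ$start[i] + 1L):occ$end[i]] <- 1 - occ$protection[i]
  a
}

## Anchors (center, reach) for a construct on a template; zero rows means
## no anchors (uniform floor for tethered constructs). The telomeric tract
## is an extended source -- hundreds of bp of Rap1-covered DNA -- so it
## carries a wider kernel than a single binding site.
.constructAnchors <- function(template, construct, anchorsOverride = NULL,
                              tractReach = 500, tractFarField = 1 / 10) {
  anchorDf <- function(center, reach, lambda)
    data.frame(center = as.numeric(center),
               reach = rep_len(reach, length(center)),
               lambda = rep_len(lambda, length(center)))
  lam <- construct@lambda
  if (!is.null(anchorsOverride))
    return(anchorDf(anchorsOverride, construct@reach, lam))
  none <- anchorDf(numeric(0), numeric(0), numeric(0))
  if (construct@tether == "free") return(none)
  if (construct@tether == "nucleosome") {
    occ <- occupants(template)
    nuc <- occ[occ$protein == "nucleosome", , drop = FALSE]
    return(anchorDf((nuc$start + nuc$end) / 2, construct@reach, lam))
  }
  if (construct@tether == "chromosome_end") {
    if (!isTerminal(template)) return(none)
    return(anchorDf(templateLength(template), construct@reach, lam))
  }
  ## tether == "site": annotated features of the anchor kinds
  fe <- templateFeatures(template)
  k <- S4Vectors::mcols(fe)$kind
  keep <- k %in% construct@anchorKind
  if (!any(keep)) return(none)
  f <- fe[keep]
  ctr <- (GenomicRanges::start(f) - 1 + GenomicRanges::end(f)) / 2
  out <- anchorDf(ctr, construct@reach, lam)
  ## the TG tract is an extended Rap1-covered source: density is full over
  ## the tract plus the construct's own reach (near field) and decays to a
  ## weak far field further into the subtelomere
  tg <- S4Vectors::mcols(f)$kind == "TG_tract"
  if (any(tg) && isTerminal(template)) {
    tgCtr <- (GenomicRanges::start(f)[tg][1L] - 1) +
      tgModel(template)["mean"] / 2
    near <- tgModel(template)["mean"] / 2 + construct@reach
    out <- rbind(out[!tg, , drop = FALSE],
                 anchorDf(tgCtr, near, lam),
                 anchorDf(tgCtr, max(tractReach, near), lam * tractFarField))
  }
  out
}

#' Relative MNase concentration profile
#'
#' Free constructs return a flat profile of 1. A tethered construct has a
#' small untethered pool (its `floor`) and a local enhancement that
#' scales that pool: c(x) = floor * (1 + lambda * K((x - anchor)/reach))
#' summed over anchors, with K a box kernel of half-width `reach`.
#' Anchors are Rap1 sites and the TG tract (MN-Rap1), nucleosome
#' footprints (H2A-MN), or the chromosome end (Yku70-MN). Single binding
#' sites use the construct's own reach and amplitude. The telomeric
#' tract is an extended Rap1-covered source whose fusion density decays
#' with distance: a near-field box at full amplitude spanning the mean
#' tract plus the construct reach, and a weak far field (amplitude
#' scaled by `tractFarField`) out to `tractReach`. The far field is what
#' makes the ACS-flanking sites a few hundred bp into the subtelomere
#' visible to the telomere-tethered fusion, while the junction site
#' remains its dominant early cut.
#'
#' @param template a [SubtelomereTemplate-class].
#' @param construct an [MNConstruct-class].
#' @param anchorsOverride optional numeric vector of anchor centers (bp),
#'   replacing the construct's own anchor rule (used by the fold-back
#'   experiment).
#' @param tractReach far-field box half-width (bp) of the TG-tract
#'   anchor.
#' @param tractFarField far-field amplitude as a fraction of the
#'   construct's enhancement.
#' @return numeric vector of per-bp relative concentrations.
#' @export
concentrationProfile <- function(template, construct,
                                 anchorsOverride = NULL, tractReach = 500,
                                 tractFarField = 1 / 10) {
  stopifnot(is(template, "SubtelomereTemplate"),
            is(construct, "MNConstruct"))
  L <- templateLength(template)
  if (construct@tether == "free") return(rep(1, L))
  anchors <- .constructAnchors(template, construct, anchorsOverride,
                               tractReach, tractFarField)
  cc <- rep(1, L)
  x <- seq_len(L) - 0.5
  for (i in seq_len(nrow(anchors)))
    cc <- cc + anchors$lambda[i] *
      (abs(x - anchors$center[i]) <= anchors$reach[i])
  construct@floor * cc
}

#' Deterministic per-lane seed
#'
#' Streams are keyed by the lane identity so that lanes are reproducible
#' individually and independent of simulation order: the lane id string
#' is hashed with a 31-based polynomial rolling hash and combined with
#' the master seed modulo a 31-bit prime.
#'
#' @param master master seed (integer).
#' @param template,construct,time,temperature the lane identity.
#' @return an integer seed in \[0, 2^31).
#' @export
laneSeed <- function(master, template, construct, time, temperature) {
  id <- paste(template, construct, format(time), temperature, sep = "|")
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(master) * 7919) %% 2147483629)
}

## Truncated-normal telomeric tract lengths (mean 300, sd 75, bounds
## mean +/- 2 sd).
.drawTgLengths <- function(n, mean, sd) {
  lo <- mean - 2 * sd; hi <- mean + 2 * sd
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  round(x)
}

#' Simulate one ChEC lane
#'
#' Per molecule, a telomeric tract length is drawn (terminal templates),
#' MNase cuts are placed as an inhomogeneous Poisson process with per-bp
#' mean `baseRate * a(x) * c(x) * temperatureFactor * time`, restriction
#' cuts close the fragment, the molecule is split at the cuts, and
#' fragments overlapping the probe are retained.
#'
#' @param template a [SubtelomereTemplate-class].
#' @param construct an [MNConstruct-class].
#' @param params a [DigestionParams-class].
#' @param time minutes; must be one of `params@timePoints`.
#' @param temperature regime name in `params@temperatureFactor`.
#' @param anchorsOverride see [concentrationProfile()].
#' @param keepAll retain all fragments instead of probe-detected ones
#'   (used to check mass conservation).
#' @return a [FragmentPopulation-class].
#' @export
simulateLane <- function(template, construct, params, time,
                         temperature = "30C", anchorsOverride = NULL,
                         keepAll = FALSE) {
  stopifnot(is(template, "SubtelomereTemplate"),
            is(construct, "MNConstruct"),
            is(params, "DigestionParams"))
  if (!any(abs(params@timePoints - time) < 1e-9))
    stop("time ", time, " is not in the declared time course (",
         paste(params@timePoints, collapse = ", "), ")")
  if (!temperature %in% names(params@temperatureFactor))
    stop("unknown temperature regime '", temperature, "'")
  tf <- params@temperatureFactor[[temperature]]
  n <- params@nMolecules
  L <- templateLength(template)
  probe <- c(IRanges::start(probeRegion(template)) - 1L,
             IRanges::end(probeRegion(template)))
  rate <- params@baseRate * accessibilityProfile(template) *
    concentrationProfile(template, construct, anchorsOverride) * tf * time
  seed <- laneSeed(params@seed, templateName(template), construct@name,
                   time, temperature)
  .withSeed(seed, {
    if (isTerminal(template)) {
      tg <- tgModel(template)
      jx <- junctionOffset(template)
      molLen <- jx + .drawTgLengths(n, tg["mean"], tg["sd"])
    } else {
      molLen <- rep(L, n)
    }
    frag <- vector("list", n)
    if (time > 0 && sum(rate) > 0) {
      ## shared cut density on the body of the fragment; the variable
      ## telomeric tail is handled per molecule below
      jx <- if (isTerminal(template)) junctionOffset(template) else L
      bodyRate <- rate[seq_len(jx)]
      lamBody <- sum(bodyRate)
      nBody <- stats::rpois(n, lamBody)
      totBody <- sum(nBody)
      posBody <- if (totBody)
        sample.int(jx, totBody, replace = TRUE, prob = bodyRate) - 0.5
        else numeric(0)
      molBody <- rep.int(seq_len(n), nBody)
      if (isTerminal(template)) {
        tailRatePerBp <- rate[jx + 1L]       # Rap1-covered tract, uniform
        lamTail <- tailRatePerBp * (molLen - jx)
        nTail <- stats::rpois(n, lamTail)
        totTail <- sum(nTail)
        molTail <- rep.int(seq_len(n), nTail)
        posTail <- if (totTail)
          jx + stats::runif(totTail) * (molLen[molTail] - jx)
          else numeric(0)
        cutPos <- c(posBody, posTail)
        cutMol <- c(molBody, molTail)
      } else {
        cutPos <- posBody
        cutMol <- molBody
      }
      o <- order(cutMol, cutPos)
      cutPos <- cutPos[o]; cutMol <- cutMol[o]
      cutsByMol <- split(cutPos, factor(cutMol, levels = seq_len(n)))
    } else {
      cutsByMol <- rep(list(numeric(0)), n)
    }
    detected <- lapply(seq_len(n), function(i) {
      cuts <- c(0, unique(cutsByMol[[i]]), molLen[i])
      lo <- cuts[-length(cuts)]
      hi <- cuts[-1L]
      keep <- if (keepAll) rep(TRUE, length(lo))
              else lo < probe[2L] & hi > probe[1L]
      hi[keep] - lo[keep]
    })
    new("FragmentPopulation",
        template = templateName(template), construct = construct@name,
        time = time, temperature = temperature,
        fragments = round(unlist(detected), 1), nMolecules = n,
        fullLengths = as.numeric(molLen))
  })
}

#' Simulate a full ChEC experiment
#'
#' Convenience product over constructs, time points and temperature
#' regimes; one lane each.
#'
#' @param template a [SubtelomereTemplate-class].
#' @param constructs list of [MNConstruct-class] (or construct names).
#' @param params a [DigestionParams-class].
#' @param design optional data.frame with columns `time` and
#'   `temperature` selecting lanes; default is the full product of
#'   `params@timePoints` over the 30 C regime.
#' @param anchorsOverride see [concentrationProfile()].
#' @return list of [FragmentPopulation-class], one per lane.
#' @export
simulateExperiment <- function(template, constructs, params,
                               design = NULL, anchorsOverride = NULL) {
  if (is.character(constructs))
    constructs <- lapply(constructs, mnConstruct)
  if (is(constructs, "MNConstruct")) constructs <- list(constructs)
  if (is.null(design))
    design <- data.frame(time = params@timePoints, temperature = "30C")
  lanes <- list()
  for (con in constructs)
    for (r in seq_len(nrow(design)))
      lanes[[length(lanes) + 1L]] <-
        simulateLane(template, con, params, design$time[r],
                     design$temperature[r], anchorsOverride)
  lanes
}

#' Default lane design of a ChEC time course
#'
#' Calcium-induction aliquots at 1, 2 and 5 min at 30 C plus slow
#' digestions on ice (2, 5 and 15 min at 4 C), the very partial digests
#' needed to read out cut sites distant from the probe.
#' @return data.frame with columns `time`, `temperature`.
#' @export
defaultLaneDesign <- function() {
  data.frame(time = c(1, 2, 5, 2, 5, 15),
             temperature = c("30C", "30C", "30C", "4C", "4C", "4C"))
}

#' Write a fragment population as TSV
#'
#' Columns: template, construct, time, temperature, length, count.
#' @param population a [FragmentPopulation-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeLaneTSV <- function(population, file) {
  tab <- table(population@fragments)
  df <- data.frame(template = population@template,
                   construct = population@construct,
                   time = population@time,
                   temperature = population@temperature,
                   length = as.numeric(names(tab)),
                   count = as.integer(tab))
  attr(df, "nMolecules") <- population@nMolecules
  utils::write.table(
    cbind(df, nMolecules = population@nMolecules), file,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a fragment population from TSV
#' @param file path written by [writeLaneTSV()].
#' @return a [FragmentPopulation-class].
#' @export
readLaneTSV <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("template", "construct", "time", "temperature", "length",
            "count", "nMolecules")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed lane TSV '", file, "': missing column(s) ",
         paste(miss, collapse = ", "))
  new("FragmentPopulation",
      template = df$template[1L], construct = df$construct[1L],
      time = as.numeric(df$time[1L]), temperature = df$temperature[1L],
      fragments = rep(df$length, df$count),
      nMolecules = as.integer(df$nMolecules[1L]),
      fullLengths = numeric(0))
}
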