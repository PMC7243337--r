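#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges start end width
#' @importFrom GenomicRanges GRanges seqnames
NULL

## Feature kinds allowed on a template. Coordinates are 0-based, half-open
## offsets from the probe-proximal restriction cut, increasing toward the
## telomere (terminal fragments) or the distal restriction cut.
.FEATURE_KINDS <- c("restriction_site", "probe", "ACS", "Abf1_site",
                    "Tbf1_site", "Reb1_site", "Rap1_site", "TG_tract",
                    "element_boundary")

.OCCUPANT_KINDS <- c("nucleosome", "ORC", "Abf1", "Tbf1", "Reb1",
                     "Rap1_array", "Yku")

.NUCLEOSOME_BP <- 146L

#' SubtelomereTemplate: an analyzed restriction fragment with ground truth
#'
#' A terminal or internal restriction fragment from a budding-yeast
#' subtelomeric region, carrying annotated sequence features (restriction
#' sites, probe, ACS, GRF binding sites, TG tract), a ground-truth protein
#' occupancy map used by the digestion simulator, and the planted
#' MNase-accessible site positions the inverse pipeline is expected to
#' recover.
#'
#' @slot name template identifier (one of [templateNames()]).
#' @slot length fragment length in bp. For terminal templates this is the
#'   junction offset plus the maximal telomeric-tract draw.
#' @slot anchor label of the probe-proximal restriction cut ("HindIII",
#'   "XhoI", "PvuI", ...); all offsets are measured from it.
#' @slot features [GenomicRanges::GRanges] with metadata columns `name`,
#'   `kind` (see feature kinds above) and `source` (one of
#'   `published`, `reconstructed`, `pwm_predicted`), plus `citation`
#'   for printed features.
#' @slot occupants data.frame with columns `protein`, `start`, `end`,
#'   `protection`: ground-truth protein footprints (half-open, bp) and the
#'   fraction by which the MNase cut rate is suppressed inside each.
#' @slot probe [IRanges::IRanges] of length one, the Southern probe.
#' @slot terminal logical; `TRUE` if the fragment ends in a physical DNA
#'   end (telomere).
#' @slot tgMean,tgSD telomeric tract length model (Normal, bp), present
#'   only for terminal templates (NA otherwise).
#' @slot sites data.frame of planted accessible cut windows: `label`,
#'   `offset` (window center, bp from anchor), `window` (half-width, bp),
#'   `source`.
#' @slot gaps data.frame of ground-truth inter-site intervals: `from`,
#'   `to` (site labels), `primary` (diagnostic occupant kind of the gap).
#' @export
setClass("SubtelomereTemplate",
  representation(
    name      = "character",
    length    = "integer",
    anchor    = "character",
    features  = "GRanges",
    occupants = "data.frame",
    probe     = "IRanges",
    terminal  = "logical",
    tgMean    = "numeric",
    tgSD      = "numeric",
    sites     = "data.frame",
    gaps      = "data.frame"
  )
)

setValidity("SubtelomereTemplate", function(object) {
  msg <- character()
  L <- object@length
  if (length(L) != 1L || is.na(L) || L < 1L)
    msg <- c(msg, "length must be a single positive integer")
  occ <- object@occupants
  if (nrow(occ)) {
    if (any(!occ$protein %in% .OCCUPANT_KINDS))
      msg <- c(msg, "unknown occupant protein kind")
    if (any(occ$start < 0 | occ$end > L | occ$start >= occ$end))
      msg <- c(msg, "occupant footprints must lie within [0, length)")
    if (any(occ$protection < 0 | occ$protection > 1))
      msg <- c(msg, "protection must be in [0, 1]")
    o <- occ[order(occ$start), , drop = FALSE]
    if (nrow(o) > 1L && any(o$start[-1L] < o$end[-nrow(o)]))
      msg <- c(msg, "occupant footprints overlap")
    nuc <- occ$protein == "nucleosome"
    if (any((occ$end - occ$start)[nuc] != .NUCLEOSOME_BP))
      msg <- c(msg, sprintf("nucleosome footprints must be exactly %d bp",
                            .NUCLEOSOME_BP))
    orc <- occ$protein == "ORC"
    if (any((occ$end - occ$start)[orc] < 38 | (occ$end - occ$start)[orc] > 44))
      msg <- c(msg, "ORC footprints must span 38-44 bp")
  }
  fk <- S4Vectors::mcols(object@features)$kind
  if (any(!fk %in% .FEATURE_KINDS))
    msg <- c(msg, "unknown feature kind")
  fs <- GenomicRanges::start(object@features) - 1L  # GRanges is 1-based
  fe <- GenomicRanges::end(object@features)
  if (length(fk) && any(fs < 0 | fe > L))
    msg <- c(msg, "features must lie within [0, length)")
  src <- S4Vectors::mcols(object@features)$source
  cit <- S4Vectors::mcols(object@features)$citation
  if (length(src) && any(src == "published" & (is.na(cit) | cit == "")))
    msg <- c(msg, "published features must carry a citation")
  ntg <- sum(fk == "TG_tract")
  if (isTRUE(object@terminal)) {
    if (ntg != 1L)
      msg <- c(msg, "a terminal template must have exactly one TG_tract")
    else if (fe[fk == "TG_tract"] != L)
      msg <- c(msg, "the TG_tract must abut the telomeric end")
    if (is.na(object@tgMean) || is.na(object@tgSD))
      msg <- c(msg, "terminal templates require a TG length model")
  } else {
    if (ntg != 0L)
      msg <- c(msg, "internal templates carry no TG_tract")
    if (!is.na(object@tgMean) || !is.na(object@tgSD))
      msg <- c(msg, "tg length model is only valid for terminal templates")
    if (sum(fk == "restriction_site") < 2L)
      msg <- c(msg, "internal templates need a closing restriction_site")
  }
  if (length(object@probe) != 1L ||
      IRanges::start(object@probe) - 1L < 0L ||
      IRanges::end(object@probe) > L)
    msg <- c(msg, "probe must be a single interval within the template")
  if (length(msg)) msg else TRUE
})

#' MNConstruct: an MNase fusion construct
#'
#' @slot name construct label (e.g. "MN-Rap1").
#' @slot tether one of `free`, `site` (sequence-specific DNA binder),
#'   `nucleosome`, `chromosome_end`.
#' @slot anchorKind for `tether = "site"`, the feature kinds the fusion is
#'   delivered to (e.g. Rap1_site + TG_tract for MN-Rap1).
#' @slot lambda local rate-enhancement amplitude (0 for free constructs).
#' @slot reach half-width of the box enhancement kernel, bp.
#' @slot floor relative cut rate away from any anchor. Free constructs
#'   have floor 1; tethered fusions have a small free-nuclear pool and cut
#'   untethered DNA late in a time course, modeled as floor < 1.
#' @export
setClass("MNConstruct",
  representation(name = "character", tether = "character",
                 anchorKind = "character", lambda = "numeric",
                 reach = "numeric", floor = "numeric"))

setValidity("MNConstruct", function(object) {
  msg <- character()
  if (!object@tether %in% c("free", "site", "nucleosome", "chromosome_end"))
    msg <- c(msg, "unknown tether")
  if (object@tether == "free") {
    if (object@lambda != 0) msg <- c(msg, "free constructs must have lambda 0")
    if (object@floor != 1) msg <- c(msg, "free constructs must have floor 1")
  } else {
    if (object@lambda <= 0 || object@reach <= 0)
      msg <- c(msg, "tethered constructs need lambda > 0 and reach > 0")
  }
  if (object@floor < 0 || object@floor > 1)
    msg <- c(msg, "floor must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DigestionParams: kinetic parameters of a ChEC time course
#'
#' @slot nMolecules molecules simulated per lane.
#' @slot timePoints minutes after calcium addition at which aliquots are
#'   taken.
#' @slot temperatureFactor named rate multipliers per regime; digestion on
#'   ice is far slower than at 30 C.
#' @slot baseRate k, cuts per accessible bp per minute at 30 C.
#' @slot seed master seed; per-lane streams are derived from it.
#' @export
setClass("DigestionParams",
  representation(nMolecules = "integer", timePoints = "numeric",
                 temperatureFactor = "numeric", baseRate = "numeric",
                 seed = "integer"))

setValidity("DigestionParams", function(object) {
  msg <- character()
  if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
  if (any(object@timePoints < 0)) msg <- c(msg, "time points must be >= 0")
  if (object@baseRate <= 0) msg <- c(msg, "baseRate must be > 0")
  if (is.null(names(object@temperatureFactor)) ||
      any(object@temperatureFactor <= 0))
    msg <- c(msg, "temperatureFactor must be a named positive vector")
  if (length(msg)) msg else TRUE
})

#' FragmentPopulation: probe-detected fragments of one lane
#'
#' @slot template,construct,time,temperature the lane identity.
#' @slot fragments multiset of probe-detected fragment lengths, bp.
#' @slot nMolecules molecules simulated.
#' @slot fullLengths per-molecule full restriction-fragment lengths (for
#'   terminal templates these vary with the telomeric tract draw).
#' @export
setClass("FragmentPopulation",
  representation(template = "character", construct = "character",
                 time = "numeric", temperature = "character",
                 fragments = "numeric", nMolecules = "integer",
                 fullLengths = "numeric"))

setValidity("FragmentPopulation", function(object) {
  if (length(object@fragments) &&
      any(object@fragments <= 0))
    return("fragment lengths must be positive")
  TRUE
})

#' GelCalibration: log-linear migration law of a virtual gel
#'
#' Migration follows m(s) = a - b log10(s) with m in profile units and s
#' in bp; larger fragments migrate less (b > 0).
#'
#' @slot intercept a.
#' @slot slope b (> 0).
#' @slot rms residual RMS of the ladder fit, profile units.
#' @slot ladderRange size span (bp) covered by the ladder; sizing outside
#'   it is extrapolation and is flagged.
#' @export
setClass("GelCalibration",
  representation(intercept = "numeric", slope = "numeric", rms = "numeric",
                 ladderRange = "numeric"))

setValidity("GelCalibration", function(object) {
  if (object@slope <= 0) return("slope must be > 0 (large fragments migrate less)")
  TRUE
})

#' LaneProfile: 1-D densitometry profile of one lane
#'
#' @slot axis migration coordinates (profile units, increasing).
#' @slot intensity non-negative signal per axis position; total area equals
#'   the number of detected fragments.
#' @slot laneId list with template/construct/time/temperature.
#' @slot ladder data.frame (size, position) of the marker lane.
#' @slot bandSigma Gaussian band width used at render time, profile units.
#' @export
setClass("LaneProfile",
  representation(axis = "numeric", intensity = "numeric", laneId = "list",
                 ladder = "data.frame", bandSigma = "numeric"))

setValidity("LaneProfile", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@intensity))
    msg <- c(msg, "axis and intensity must have equal length")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  ld <- object@ladder
  if (nrow(ld) > 1L) {
    o <- order(ld$size)
    if (any(diff(ld$position[o]) >= 0))
      msg <- c(msg, "ladder positions must strictly decrease with size")
  }
  if (length(msg)) msg else TRUE
})

#' ChromatinModel: ordered occupant reconstruction over a template
#'
#' @slot template template name.
#' @slot intervals data.frame of classified inter-site intervals with the
#'   inferred occupant hypothesis per interval.
#' @slot flags named logical vector: `terminalNFR`, `orcSite`, `abf1Site`.
#' @export
setClass("ChromatinModel",
  representation(template = "character", intervals = "data.frame",
                 flags = "logical"))
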