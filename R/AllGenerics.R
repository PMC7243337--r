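#' @include AllClasses.R
NULL

#' @rdname SubtelomereTemplate-class
#' @param x a SubtelomereTemplate
#' @export
setGeneric("templateName", function(x) standardGeneric("templateName"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("templateLength", function(x) standardGeneric("templateLength"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("templateFeatures", function(x) standardGeneric("templateFeatures"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("occupants", function(x) standardGeneric("occupants"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("probeRegion", function(x) standardGeneric("probeRegion"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("isTerminal", function(x) standardGeneric("isTerminal"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("anchorLabel", function(x) standardGeneric("anchorLabel"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("tgModel", function(x) standardGeneric("tgModel"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("siteTruth", function(x) standardGeneric("siteTruth"))
#' @rdname SubtelomereTemplate-class
#' @export
setGeneric("gapTruth", function(x) standardGeneric("gapTruth"))
#' Junction offset (start of the TG tract or X-Y' boundary), bp from anchor
#' @param x a SubtelomereTemplate
#' @export
setGeneric("junctionOffset", function(x) standardGeneric("junctionOffset"))

#' @rdname FragmentPopulation-class
#' @param x a FragmentPopulation
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname FragmentPopulation-class
#' @export
setGeneric("laneId", function(x) standardGeneric("laneId"))
#' @rdname FragmentPopulation-class
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

setMethod("templateName", "SubtelomereTemplate", function(x) x@name)
setMethod("templateLength", "SubtelomereTemplate", function(x) x@length)
setMethod("templateFeatures", "SubtelomereTemplate", function(x) x@features)
setMethod("occupants", "SubtelomereTemplate", function(x) x@occupants)
setMethod("probeRegion", "SubtelomereTemplate", function(x) x@probe)
setMethod("isTerminal", "SubtelomereTemplate", function(x) x@terminal)
setMethod("anchorLabel", "SubtelomereTemplate", function(x) x@anchor)
setMethod("tgModel", "SubtelomereTemplate",
          function(x) c(mean = x@tgMean, sd = x@tgSD))
setMethod("siteTruth", "SubtelomereTemplate", function(x) x@sites)
setMethod("gapTruth", "SubtelomereTemplate", function(x) x@gaps)
setMethod("junctionOffset", "SubtelomereTemplate", function(x) {
  f <- x@features
  k <- S4Vectors::mcols(f)$kind
  nm <- S4Vectors::mcols(f)$name
  if (x@terminal)
    return(GenomicRanges::start(f)[k == "TG_tract"][1L] - 1L)
  j <- which(k == "element_boundary" & nm == "XY_junction")
  if (!length(j)) return(NA_real_)
  GenomicRanges::start(f)[j][1L] - 1L
})

setMethod("fragments", "FragmentPopulation", function(x) x@fragments)
setMethod("nMolecules", "FragmentPopulation", function(x) x@nMolecules)
setMethod("laneId", "FragmentPopulation", function(x)
  list(template = x@template, construct = x@construct,
       time = x@time, temperature = x@temperature))

setMethod("show", "SubtelomereTemplate", function(object) {
  cat(sprintf("SubtelomereTemplate '%s' (%s fragment, %d bp, anchor %s)\n",
              object@name, if (object@terminal) "terminal" else "internal",
              object@length, object@anchor))
  cat(sprintf("  %d features, %d occupants, %d planted accessible sites\n",
              length(object@features), nrow(object@occupants),
              nrow(object@sites)))
  if (object@terminal)
    cat(sprintf("  TG tract: Normal(%g, %g) bp from offset %d\n",
                object@tgMean, object@tgSD, junctionOffset(object)))
  invisible(NULL)
})

setMethod("show", "MNConstruct", function(object) {
  cat(sprintf("MNConstruct '%s' (tether %s", object@name, object@tether))
  if (object@tether != "free")
    cat(sprintf(", lambda %g, reach %g bp, floor %g",
                object@lambda, object@reach, object@floor))
  cat(")\n")
  invisible(NULL)
})

setMethod("show", "FragmentPopulation", function(object) {
  cat(sprintf(
    "FragmentPopulation %s / %s, t = %g min (%s): %d fragments from %d molecules\n",
    object@template, object@construct, object@time, object@temperature,
    length(object@fragments), object@nMolecules))
  invisible(NULL)
})

setMethod("show", "GelCalibration", function(object) {
  cat(sprintf("GelCalibration m(s) = %.3f - %.3f log10(s)  [rms %.3g, ladder %g-%g bp]\n",
              object@intercept, object@slope, object@rms,
              object@ladderRange[1L], object@ladderRange[2L]))
  invisible(NULL)
})

setMethod("show", "LaneProfile", function(object) {
  cat(sprintf("LaneProfile %s / %s t = %g (%s): %d points, area %.1f\n",
              object@laneId$template, object@laneId$construct,
              object@laneId$time, object@laneId$temperature,
              length(object@axis), profileArea(object)))
  invisible(NULL)
})

setMethod("show", "ChromatinModel", function(object) {
  cat(sprintf("ChromatinModel for %s: %d intervals\n",
              object@template, nrow(object@intervals)))
  cat(sprintf("  terminal NFR: %s | ORC site: %s | Abf1 site: %s\n",
              object@flags["terminalNFR"], object@flags["orcSite"],
              object@flags["abf1Site"]))
  invisible(NULL)
})
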