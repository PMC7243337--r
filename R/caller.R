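#' @include AllClasses.R AllGenerics.R gel.R
NULL

## ---------------------------------------------------------------------------
## Inverse analysis: band detection on lane profiles, indirect end-labeling
## conversion of band sizes to cut offsets, and consolidation of preferential
## MNase-sensitive sites across lanes, time points and constructs.
## ---------------------------------------------------------------------------

## Topographic prominence of peak indices in an intensity vector.
.peakProminence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    ## walk left to the nearest point higher than the peak
    li <- which(y[seq_len(p - 1L)] > h)
    lmin <- if (length(li)) min(y[(max(li) + 1L):(p - 1L)]) else
      min(y[seq_len(max(p - 1L, 1L))])
    ri <- which(y[(p + 1L):length(y)] > h)
    rmin <- if (length(ri)) min(y[(p + 1L):(p + min(ri) - 1L)]) else
      min(y[min(p + 1L, length(y)):length(y)])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Size above which a band is treated as the uncut input fragment
#'
#' Indirect end-labeling reads cut positions from sub-full-length bands;
#' the uncut restriction fragment must be excluded. For terminal
#' templates the full-length band is a smear of heterogeneous telomeric
#' tract lengths, so everything beyond the junction plus a margin is
#' excluded; internal templates exclude a fixed fraction of the full
#' fragment length.
#' @param template a [SubtelomereTemplate-class].
#' @param margin bp beyond the junction (terminal templates).
#' @return size threshold in bp.
#' @export
uncutThreshold <- function(template, margin = 100) {
  if (isTerminal(template)) junctionOffset(template) + margin
  else 0.97 * templateLength(template)
}

#' Detect bands in a lane profile
#'
#' Local intensity maxima with topographic prominence at least
#' `minProminence` of the lane maximum are called as bands; the
#' full-length (uncut) band is excluded via `excludeAboveSize`. The
#' percent signal of a band integrates the profile over +/- 2 band sigma
#' around the peak, relative to total lane signal (invariant under
#' uniform intensity scaling).
#'
#' @param profile a [LaneProfile-class].
#' @param calibration a [GelCalibration-class].
#' @param minProminence prominence threshold as a fraction of the lane
#'   maximum, in (0, 1). Lanes digested very partially (H2A fusion on
#'   ice) benefit from a lower threshold.
#' @param excludeAboveSize bp; bands sizing above this are dropped as
#'   uncut input (see [uncutThreshold()]). `Inf` keeps everything.
#' @param excludeBelowSize bp; bands sizing below this are dropped.
#'   Fragments shorter than the probe (end-point mono-nucleosomal
#'   products near the probe) cannot be read as anchored cut sites.
#' @param minPercent detection limit: a band carrying less than this
#'   percent of the total lane signal is below what a blot exposure can
#'   score and is not called.
#' @return data.frame: `template`, `construct`, `time`, `temperature`,
#'   `position`, `size`, `percentSignal`, `prominence`.
#' @export
detectBands <- function(profile, calibration = defaultCalibration(),
                        minProminence = 0.05, excludeAboveSize = Inf,
                        excludeBelowSize = 0, minPercent = 1) {
  stopifnot(is(profile, "LaneProfile"))
  if (minProminence <= 0 || minProminence >= 1)
    stop("minProminence must be in (0, 1)")
  y <- profile@intensity
  x <- profile@axis
  empty <- data.frame(template = character(0), construct = character(0),
                      time = numeric(0), temperature = character(0),
                      position = numeric(0), size = numeric(0),
                      percentSignal = numeric(0), prominence = numeric(0))
  if (!length(y) || max(y) <= 0) return(empty)
  d <- diff(y)
  peaks <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(peaks)) return(empty)
  prom <- .peakProminence(y, peaks) / max(y)
  keep <- prom >= minProminence
  peaks <- peaks[keep]; prom <- prom[keep]
  if (!length(peaks)) return(empty)
  sizes <- as.numeric(sizeOf(x[peaks], calibration))
  inRange <- sizes <= excludeAboveSize & sizes >= excludeBelowSize
  peaks <- peaks[inRange]; prom <- prom[inRange]; sizes <- sizes[inRange]
  if (!length(peaks)) return(empty)
  total <- profileArea(profile)
  win <- 2 * profile@bandSigma
  pct <- vapply(x[peaks], function(p) {
    sel <- x >= p - win & x <= p + win
    xs <- x[sel]; ys <- y[sel]
    100 * sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2) / total
  }, numeric(1))
  id <- profile@laneId
  out <- data.frame(template = id$template, construct = id$construct,
                    time = id$time, temperature = id$temperature,
                    position = x[peaks], size = sizes,
                    percentSignal = pct, prominence = prom)
  out[out$percentSignal >= minPercent, , drop = FALSE]
}

#' Convert band sizes to cut-site offsets
#'
#' Indirect end-labeling logic: the probe abuts the anchor restriction
#' cut, so under the single-cut assumption of a partial digest, a
#' probe-detected fragment of size s implies a MNase cut at offset s
#' from the anchor.
#'
#' @param bands data.frame from [detectBands()].
#' @param template a [SubtelomereTemplate-class].
#' @return the band data.frame with an `offset` column (bp from anchor).
#' @export
sizesToCutOffsets <- function(bands, template) {
  stopifnot(is(template, "SubtelomereTemplate"))
  pr <- probeRegion(template)
  if (IRanges::start(pr) - 1L > 5L)
    stop("sizes map to offsets only when the probe abuts the anchor")
  if (nrow(bands) && any(bands$size > templateLength(template)))
    stop("fragment larger than the template")
  bands$offset <- bands$size
  bands
}

## Region prefix of an offset on an internal X-Y' fragment.
.regionPrefix <- function(offset, xStart, junction) {
  ifelse(offset < xStart, "S",
         ifelse(offset < junction, "X", "Y'"))
}

.roman <- function(i) as.character(utils::as.roman(i))

#' Consolidate cut-site observations into preferential sites
#'
#' Offsets observed across lanes, time points and constructs are
#' clustered by single linkage with linkage distance `tolerance`
#' (implemented as gap splitting on the sorted offsets, equivalent in one
#' dimension); each cluster is reported as a preferential MNase-sensitive
#' site with mean and SD. Sites are labeled with Roman numerals: terminal
#' templates number from the telomere junction inward (site I nearest the
#' junction, as on the original blots), internal fragments number
#' ascending from the anchor, prefixed by region (S- upstream of the X
#' element, X- on it, Y'- beyond the junction) when element boundaries
#' are annotated. A site supported by every free construct present is
#' flagged `common`; sites with a single observation are flagged
#' `singleSupport` instead of carrying an SD.
#'
#' @param observations data.frame with at least `offset` and `construct`
#'   (typically [sizesToCutOffsets()] output pooled over lanes).
#' @param template optional [SubtelomereTemplate-class] driving the
#'   labeling convention.
#' @param tolerance linkage distance, bp.
#' @param minSupport minimal number of supporting observations for a
#'   cluster to be reported (a preferential site is a reproducible one;
#'   the default keeps single-observation clusters but flags them).
#' @return data.frame: `label`, `meanOffset`, `sdOffset`, `n`,
#'   `constructs`, `common`, `singleSupport`, `meanPercent`.
#' @export
consolidateSites <- function(observations, template = NULL,
                             tolerance = 25, minSupport = 1L) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  empty <- data.frame(label = character(0), meanOffset = numeric(0),
                      sdOffset = numeric(0), n = integer(0),
                      constructs = character(0), common = logical(0),
                      singleSupport = logical(0), meanPercent = numeric(0))
  if (is.null(observations) || !nrow(observations)) return(empty)
  o <- observations[order(observations$offset), , drop = FALSE]
  cl <- cumsum(c(1, diff(o$offset) > tolerance))
  if (!("percentSignal" %in% names(o))) o$percentSignal <- NA_real_
  freePresent <- intersect(unique(o$construct), c("GBD-MN", "NLS-MN"))
  agg <- lapply(split(o, cl), function(g) {
    data.frame(meanOffset = mean(g$offset),
               sdOffset = if (nrow(g) > 1L) stats::sd(g$offset) else NA_real_,
               n = nrow(g),
               constructs = paste(sort(unique(g$construct)), collapse = ","),
               common = length(freePresent) > 0L &&
                 all(freePresent %in% g$construct),
               singleSupport = nrow(g) == 1L,
               meanPercent = mean(g$percentSignal))
  })
  out <- do.call(rbind, agg)
  out <- out[out$n >= minSupport, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$meanOffset), , drop = FALSE]
  k <- nrow(out)
  if (is.null(template)) {
    out$label <- .roman(seq_len(k))
  } else if (isTerminal(template)) {
    out$label <- .roman(rev(seq_len(k)))     # I = junction-proximal
  } else {
    fe <- templateFeatures(template)
    mc <- S4Vectors::mcols(fe)
    xs <- GenomicRanges::start(fe)[mc$kind == "element_boundary" &
                                     mc$name == "X_start"] - 1L
    jx <- junctionOffset(template)
    if (length(xs) == 1L && !is.na(jx)) {
      pre <- .regionPrefix(out$meanOffset, xs, jx)
      num <- stats::ave(seq_len(k), pre, FUN = seq_along)
      out$label <- paste0(pre, "-", .roman(num))
    } else {
      out$label <- .roman(seq_len(k))
    }
  }
  rownames(out) <- NULL
  out[, c("label", "meanOffset", "sdOffset", "n", "constructs", "common",
          "singleSupport", "meanPercent")]
}

#' Flag diffuse cutting between adjacent bands
#'
#' A region between two called bands is reported diffuse when the
#' inter-peak baseline exceeds half the height of the lower flanking
#' peak, operationalizing a non-negligible diffuse cutting signal.
#'
#' @param profile a [LaneProfile-class].
#' @param bands data.frame from [detectBands()] for that profile.
#' @return data.frame: `fromSize`, `toSize`, `baselineRatio`, `diffuse`.
#' @export
diffuseRegions <- function(profile, bands) {
  if (nrow(bands) < 2L)
    return(data.frame(fromSize = numeric(0), toSize = numeric(0),
                      baselineRatio = numeric(0), diffuse = logical(0)))
  b <- bands[order(bands$position), , drop = FALSE]
  x <- profile@axis; y <- profile@intensity
  out <- lapply(seq_len(nrow(b) - 1L), function(i) {
    sel <- x > b$position[i] & x < b$position[i + 1L]
    base <- if (any(sel)) min(y[sel]) else NA_real_
    hA <- y[which.min(abs(x - b$position[i]))]
    hB <- y[which.min(abs(x - b$position[i + 1L]))]
    ratio <- base / min(hA, hB)
    data.frame(fromSize = b$size[i], toSize = b$size[i + 1L],
               baselineRatio = ratio, diffuse = is.finite(ratio) &&
                 ratio > 0.5)
  })
  do.call(rbind, out)
}

#' Write consolidated sites as TSV
#' @param sites data.frame from [consolidateSites()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSitesTSV <- function(sites, file) {
  utils::write.table(sites, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write consolidated sites as BED
#'
#' Sites are written as 1-bp features at their mean offset (0-based
#' half-open), score = number of supporting observations.
#' @param sites data.frame from [consolidateSites()].
#' @param template the [SubtelomereTemplate-class] the sites belong to.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSitesBED6 <- function(sites, template, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = templateName(template),
    ranges = IRanges::IRanges(start = round(sites$meanOffset) + 1L,
                              width = 1L))
  S4Vectors::mcols(gr)$name <- sites$label
  S4Vectors::mcols(gr)$score <- sites$n
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
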