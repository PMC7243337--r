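#' @include AllClasses.R AllGenerics.R caller.R
NULL

## ---------------------------------------------------------------------------
## Interpretive layer: the 146-bp nucleosome-footprint classifier, feature
## association of inter-site intervals, junction accessibility ratios,
## chromatin-model reconstruction, and the in-silico fold-back experiment.
## ---------------------------------------------------------------------------

.featureCenters <- function(template, kinds) {
  fe <- templateFeatures(template)
  k <- S4Vectors::mcols(fe)$kind
  f <- fe[k %in% kinds]
  (GenomicRanges::start(f) - 1 + GenomicRanges::end(f)) / 2
}

#' Classify inter-site intervals with the 146-bp rule
#'
#' Consecutive consolidated sites define MNase-protected intervals. An
#' interval whose mean spacing is below 146 bp cannot host a positioned
#' nucleosome and is `sub_nucleosomal`; 146 bp or more is
#' `nucleosome_compatible` (146 is the minimal nucleosome footprint, so
#' the boundary itself is compatible). Interval SDs propagate from the
#' flanking site SDs in quadrature. Each interval is associated with the
#' template feature it covers: `ORC_ACS` if an ACS center lies inside,
#' else `Abf1` for an Abf1 site, else `Tbf1_Reb1_array` when at least two
#' Tbf1/Reb1 sites do, else `TG_junction` for the interval abutting the
#' telomeric tract (terminal templates only; an internal X-Y' boundary is
#' not a physical DNA end); feature centers must lie at least
#' `assocMargin` bp inside the interval.
#'
#' @param sites data.frame from [consolidateSites()] (>= 2 rows).
#' @param template a [SubtelomereTemplate-class].
#' @param threshold minimal nucleosome footprint, bp.
#' @param assocMargin bp a feature center must lie inside the interval.
#' @param junctionMargin bp within which the distal flanking site must
#'   approach the junction for the interval to count as junction-proximal.
#' @return data.frame: `from`, `to` (site labels, ascending offsets),
#'   `spacing`, `sdSpacing`, `class`, `association`, `junctionProximal`.
#' @export
classifyIntervals <- function(sites, template, threshold = 146,
                              assocMargin = 10, junctionMargin = 60) {
  stopifnot(is(template, "SubtelomereTemplate"))
  if (threshold <= 0) stop("threshold must be > 0")
  empty <- data.frame(from = character(0), to = character(0),
                      spacing = numeric(0), sdSpacing = numeric(0),
                      class = character(0), association = character(0),
                      junctionProximal = logical(0))
  if (is.null(sites) || nrow(sites) < 2L) return(empty)
  s <- sites[order(sites$meanOffset), , drop = FALSE]
  acs  <- .featureCenters(template, "ACS")
  abf1 <- .featureCenters(template, "Abf1_site")
  grf  <- .featureCenters(template, c("Tbf1_site", "Reb1_site"))
  jx <- junctionOffset(template)
  out <- lapply(seq_len(nrow(s) - 1L), function(i) {
    lo <- s$meanOffset[i]; hi <- s$meanOffset[i + 1L]
    spacing <- hi - lo
    sds <- c(s$sdOffset[i], s$sdOffset[i + 1L])
    sdS <- if (all(is.na(sds))) NA_real_ else sqrt(sum(sds^2, na.rm = TRUE))
    inside <- function(ctr) ctr >= lo + assocMargin & ctr <= hi - assocMargin
    assoc <- if (any(inside(acs))) "ORC_ACS"
      else if (any(inside(abf1))) "Abf1"
      else if (sum(inside(grf)) >= 2L) "Tbf1_Reb1_array"
      else "unassigned"
    jp <- isTerminal(template) && !is.na(jx) &&
      hi >= jx - junctionMargin && i + 1L == nrow(s)
    if (assoc == "unassigned" && jp) assoc <- "TG_junction"
    data.frame(from = s$label[i], to = s$label[i + 1L], spacing = spacing,
               sdSpacing = sdS,
               class = if (spacing < threshold) "sub_nucleosomal"
                       else "nucleosome_compatible",
               association = assoc, junctionProximal = jp)
  })
  do.call(rbind, out)
}

#' Template-specific accessibility-ratio band sets
#'
#' The junction accessibility ratio compares cleavage at the
#' subtelomere-telomere junction (site I) with cleavage around the
#' element's ACS: bands II + III on the Y' fragment, V + VI on TEL03L,
#' III on TEL06R.
#' @param templateName template name.
#' @return list with `num` and `den` site labels, or NULL.
#' @export
accessRatioSpec <- function(templateName) {
  switch(templateName,
         YpTRF  = list(num = "I", den = c("II", "III")),
         TEL03L = list(num = "I", den = c("V", "VI")),
         TEL06R = list(num = "I", den = "III"),
         NULL)
}

## Assign each band observation to the nearest consolidated site label.
.assignBandSites <- function(bands, sites, tolerance = 25) {
  if (!nrow(bands)) {
    bands$site <- character(0)
    return(bands)
  }
  idx <- vapply(bands$offset, function(o) {
    d <- abs(sites$meanOffset - o)
    j <- which.min(d)
    if (d[j] <= tolerance) j else NA_integer_
  }, integer(1))
  bands$site <- ifelse(is.na(idx), NA_character_, sites$label[idx])
  bands
}

#' Junction accessibility ratio for one construct
#'
#' Per lane, the percent signal of the numerator band(s) is divided by
#' the summed percent signal of the denominator band(s); lane ratios are
#' averaged. A lane whose numerator is absent contributes 0; lanes
#' without detectable denominator signal are dropped, and if no lane has
#' denominator signal the ratio is flagged as below the detection limit.
#'
#' @param bands pooled band table with `offset` and `percentSignal`
#'   (from [sizesToCutOffsets()]).
#' @param sites consolidated sites for the template.
#' @param template a [SubtelomereTemplate-class].
#' @param construct construct name to evaluate.
#' @param tolerance band-to-site assignment tolerance, bp.
#' @return list: `value` (mean over lanes, NA when flagged), `sd`,
#'   `nLanes`, `detectionLimited`.
#' @export
accessibilityRatio <- function(bands, sites, template, construct,
                               tolerance = 25) {
  spec <- accessRatioSpec(templateName(template))
  if (is.null(spec))
    stop("no accessibility-ratio specification for template '",
         templateName(template), "'")
  b <- bands[bands$construct == construct, , drop = FALSE]
  b <- .assignBandSites(b, sites, tolerance)
  laneKey <- paste(b$time, b$temperature)
  ratios <- vapply(unique(laneKey), function(k) {
    g <- b[laneKey == k, , drop = FALSE]
    num <- sum(g$percentSignal[g$site %in% spec$num], na.rm = TRUE)
    den <- sum(g$percentSignal[g$site %in% spec$den], na.rm = TRUE)
    if (den <= 0) NA_real_ else num / den
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios))
    return(list(value = NA_real_, sd = NA_real_, nLanes = 0L,
                detectionLimited = TRUE))
  list(value = mean(ratios),
       sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
       nLanes = length(ratios), detectionLimited = FALSE)
}

#' Reconstruct a chromatin model from classified intervals
#'
#' Maps every interval to an occupant hypothesis: a junction-proximal
#' interval held by a Tbf1/Reb1 array (or abutting the TG tract while
#' sub-nucleosomal) is a GRF-bound nucleosome-free region; other
#' nucleosome-compatible intervals are positioned nucleosomes;
#' sub-nucleosomal intervals become ORC (on an ACS), Abf1 (on an Abf1
#' site), or an unknown non-histone factor.
#'
#' @param intervals data.frame from [classifyIntervals()].
#' @param template a [SubtelomereTemplate-class].
#' @return a [ChromatinModel-class].
#' @export
reconstructModel <- function(intervals, template) {
  stopifnot(is(template, "SubtelomereTemplate"))
  iv <- intervals
  occupant <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    jpGRF <- iv$junctionProximal[i] &&
      (iv$association[i] %in% c("Tbf1_Reb1_array", "TG_junction") ||
         iv$class[i] == "sub_nucleosomal")
    occupant[i] <-
      if (jpGRF) "GRF_NFR"
      else if (iv$class[i] == "nucleosome_compatible") "nucleosome"
      else if (iv$association[i] == "ORC_ACS") "ORC"
      else if (iv$association[i] == "Abf1") "Abf1"
      else if (iv$association[i] == "Tbf1_Reb1_array") "GRF_NFR"
      else "unknown_factor"
  }
  iv$occupant <- occupant
  flags <- c(
    terminalNFR = isTerminal(template) && nrow(iv) > 0L &&
      any(iv$junctionProximal & iv$occupant != "nucleosome"),
    orcSite = any(iv$association == "ORC_ACS"),
    abf1Site = any(iv$association == "Abf1"))
  new("ChromatinModel", template = templateName(template),
      intervals = iv, flags = flags)
}

#' Pattern divergence between two consolidated site sets
#'
#' Sites are matched greedily by offset within `tolerance`; matched pairs
#' contribute the absolute difference of their mean percent signal,
#' unmatched sites contribute their full percent signal as a penalty.
#'
#' @param a,b data.frames from [consolidateSites()].
#' @param tolerance matching tolerance, bp.
#' @return non-negative numeric divergence (percent-signal units).
#' @export
patternDivergence <- function(a, b, tolerance = 25) {
  pa <- ifelse(is.na(a$meanPercent), 0, a$meanPercent)
  pb <- ifelse(is.na(b$meanPercent), 0, b$meanPercent)
  usedB <- rep(FALSE, nrow(b))
  div <- 0
  for (i in seq_len(nrow(a))) {
    d <- abs(b$meanOffset - a$meanOffset[i])
    d[usedB] <- Inf
    j <- if (length(d)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= tolerance) {
      div <- div + abs(pa[i] - pb[j])
      usedB[j] <- TRUE
    } else {
      div <- div + pa[i]
    }
  }
  div + sum(pb[!usedB])
}

#' Count consolidated sites on the X element
#'
#' Sites within `margin` bp of the element start still count as
#' X-element sites: a consolidated mean can sit a few bp outside the
#' annotated boundary when the flanking cut window straddles it.
#' @param sites data.frame from [consolidateSites()].
#' @param template an internal X-Y' [SubtelomereTemplate-class].
#' @param margin boundary slack, bp.
#' @return integer count of sites with offsets inside the X element.
#' @export
xElementSiteCount <- function(sites, template, margin = 20) {
  fe <- templateFeatures(template)
  mc <- S4Vectors::mcols(fe)
  xs <- GenomicRanges::start(fe)[mc$kind == "element_boundary" &
                                   mc$name == "X_start"] - 1L
  jx <- junctionOffset(template)
  sum(sites$meanOffset >= xs - margin & sites$meanOffset < jx)
}

.condSeed <- function(master, mode, genotype, context) {
  id <- paste("foldback", mode, genotype, context, sep = "|")
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(master) * 104729) %% 2147483629)
}

## Run the MN-Rap1 arm of the fold-back experiment for one condition.
.foldbackCondition <- function(mode, genotype, context, params,
                               design, tolerance, minProminence) {
  template <- buildTemplate(if (context == "chromosomal") "X05R_AF"
                            else "p05RA")
  ## direct binding: Rap1 sits on its X-element sites in every genotype
  ## and context. fold-back: the terminal Rap1 molecules are delivered to
  ## the X element only with an intact SIR/yKu pathway on a chromosome;
  ## otherwise the fusion has no anchor on this fragment (its TG tract is
  ## elsewhere or absent).
  anchors <- if (mode == "direct_binding") NULL
    else if (genotype == "WT" && context == "chromosomal") NULL
    else numeric(0)
  condParams <- digestionParams(
    nMolecules = params@nMolecules, timePoints = params@timePoints,
    temperatureFactor = params@temperatureFactor,
    baseRate = params@baseRate,
    seed = .condSeed(params@seed, mode, genotype, context))
  lanes <- simulateExperiment(template, list(mnConstruct("MN-Rap1")),
                              condParams, design = design,
                              anchorsOverride = anchors)
  res <- processExperiment(lanes, template, tolerance = tolerance,
                           minProminence = minProminence)
  list(template = template, sites = res$sites, bands = res$bands)
}

#' In-silico fold-back discrimination experiment
#'
#' Simulates the MN-Rap1 ChEC pattern on the TEL05R X-Y' junction under
#' two hypotheses. Under `direct_binding`, Rap1 binds its X-element sites
#' directly, so the cutting enhancement is anchored there in every
#' genotype and context. Under `foldback`, the enhancement over the X
#' element comes from terminal telomeric Rap1 delivered by a SIR/yKu-
#' dependent loop, so it is present only for a wild-type chromosomal
#' locus and is lost in sir / yku deletions and on a plasmid. The
#' consolidated pattern of each condition is compared to the wild-type
#' chromosomal reference of the same mode via [patternDivergence()].
#'
#' @param mode `direct_binding` or `foldback`.
#' @param genotype `WT`, `sirD` or `yku80D`.
#' @param context `chromosomal` or `plasmid`.
#' @param params a [DigestionParams-class].
#' @param design lane design (see [defaultLaneDesign()]).
#' @param tolerance consolidation tolerance, bp.
#' @param minProminence band-calling threshold.
#' @return list: `sites`, `reference` (WT chromosomal sites of the same
#'   mode), `divergence`, `xSiteCount`, `refXSiteCount`.
#' @export
foldbackTest <- function(mode = c("direct_binding", "foldback"),
                         genotype = c("WT", "sirD", "yku80D"),
                         context = c("chromosomal", "plasmid"),
                         params = digestionParams(),
                         design = defaultLaneDesign(),
                         tolerance = 25, minProminence = 0.05) {
  mode <- match.arg(mode)
  genotype <- match.arg(genotype)
  context <- match.arg(context)
  cond <- .foldbackCondition(mode, genotype, context, params, design,
                             tolerance, minProminence)
  ref <- .foldbackCondition(mode, "WT", "chromosomal", params, design,
                            tolerance, minProminence)
  list(sites = cond$sites, reference = ref$sites,
       divergence = patternDivergence(cond$sites, ref$sites, tolerance),
       xSiteCount = xElementSiteCount(cond$sites, cond$template),
       refXSiteCount = xElementSiteCount(ref$sites, ref$template))
}

#' Write classified intervals as TSV
#' @param intervals data.frame from [classifyIntervals()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeIntervalsTSV <- function(intervals, file) {
  utils::write.table(intervals, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a chromatin model as a BED track of inferred occupants
#'
#' Each interval is exported with its occupant hypothesis in the name
#' column. Interval bounds are the flanking consolidated sites, so a
#' sites table is required.
#' @param model a [ChromatinModel-class].
#' @param sites data.frame from [consolidateSites()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeModelBED <- function(model, sites, file) {
  iv <- model@intervals
  lo <- sites$meanOffset[match(iv$from, sites$label)]
  hi <- sites$meanOffset[match(iv$to, sites$label)]
  gr <- GenomicRanges::GRanges(
    seqnames = model@template,
    ranges = IRanges::IRanges(start = round(lo) + 1L, end = round(hi)))
  S4Vectors::mcols(gr)$name <- iv$occupant
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
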