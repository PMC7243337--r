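#' @include AllClasses.R AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Ground-truth template construction.
##
## Offsets are 0-based bp from the probe-proximal restriction cut, increasing
## toward the telomere (terminal fragments) or the distal restriction cut
## (internal fragments); intervals are half-open. Printed coordinates from the
## source study are tagged source = "published" with a citation; positions
## shown only graphically are chained from printed spacings and tagged
## "reconstructed".
##
## Each template plants narrow MNase-accessible windows centered on the
## known preferential cut sites and fills all remaining DNA with protein
## footprints (nucleosomes of exactly 146 bp, a 41-bp ORC on each ACS, Abf1,
## and Tbf1/Reb1 blocks as general-regulatory-factor filler), so that the
## forward simulator reproduces the observed banding and the inverse pipeline
## can be scored against the planted positions.
## ---------------------------------------------------------------------------

#' Default occupant protections
#'
#' Fraction by which the per-bp cut rate is suppressed inside a footprint.
#' Telomeric Rap1-covered DNA is nearly inert (it is difficult to access by
#' MNase even for the Rap1 fusion), nucleosomal DNA slightly less so, and
#' single-factor footprints least. The defaults are tight enough that the
#' cumulative leakage hazard over a kilobase-scale occupied approach stays
#' small against the planted accessible windows, which is what keeps
#' partial-digest lanes crisp (discrete bands over a clean background)
#' instead of smeared; all values are configurable per template build.
#' @return named numeric vector of protection fractions in \[0, 1\].
#' @export
defaultProtections <- function() {
  c(nucleosome = 0.995, ORC = 0.99, Abf1 = 0.99, Tbf1 = 0.99,
    Reb1 = 0.99, Rap1_array = 0.998, Yku = 0.99)
}

#' Names of the built-in templates
#' @return character vector of supported template names.
#' @export
templateNames <- function() {
  c("YpTRF", "TEL03L", "TEL06R", "X05R_AF", "X16R_AF", "TRP1ARS1", "p05RA")
}

## -- occupant block helpers (all half-open [start, end), integer bp) --------

.blk <- function(protein, start, end, protection) {
  if (end - start < 1L) return(NULL)
  data.frame(protein = protein, start = as.integer(round(start)),
             end = as.integer(round(end)), protection = protection)
}

## Tile [lo, hi) with alternating Tbf1/Reb1 blocks (no accessible gaps).
.grfFill <- function(lo, hi, prot, protection = NULL) {
  lo <- round(lo); hi <- round(hi)
  if (hi - lo < 1L) return(NULL)
  k <- max(1L, ceiling((hi - lo) / 24))
  b <- round(seq(lo, hi, length.out = k + 1L))
  protein <- rep_len(c("Tbf1", "Reb1"), k)
  p <- if (is.null(protection)) prot[protein] else rep(protection, k)
  do.call(rbind, lapply(seq_len(k), function(i)
    .blk(protein[i], b[i], b[i + 1L], p[[i]])))
}

## Fill [lo, hi) with a continuous nucleosome array (abutting 146 bp
## cores, GRF filler for the remainder), leaving no accessible DNA. The
## unmapped flanks of each fragment are modeled as uniformly occupied:
## linker positions there were not read out in the source experiments, so
## no cut windows are planted.
.nucArrayFill <- function(lo, hi, prot) {
  lo <- round(lo); hi <- round(hi)
  out <- list()
  pos <- lo
  while (hi - pos >= .NUCLEOSOME_BP) {
    out[[length(out) + 1L]] <-
      .blk("nucleosome", pos, pos + .NUCLEOSOME_BP, prot[["nucleosome"]])
    pos <- pos + .NUCLEOSOME_BP
  }
  if (hi - pos >= 1L)
    out[[length(out) + 1L]] <- .grfFill(pos, hi, prot)
  do.call(rbind, out)
}

## One centered nucleosome, optionally an Abf1 footprint at abf1Center,
## GRF filler for the residue.
.gapNuc <- function(lo, hi, prot, abf1Center = NULL) {
  out <- list()
  if (!is.null(abf1Center)) {
    a0 <- round(abf1Center - 8); a1 <- a0 + 16L
    nlo <- lo; nhi <- a0
    ctr <- (nlo + nhi) / 2
    ns <- round(ctr - .NUCLEOSOME_BP / 2)
    out <- c(out, list(.grfFill(lo, ns, prot),
                       .blk("nucleosome", ns, ns + .NUCLEOSOME_BP,
                            prot[["nucleosome"]]),
                       .grfFill(ns + .NUCLEOSOME_BP, a0, prot),
                       .blk("Abf1", a0, a1, prot[["Abf1"]]),
                       .grfFill(a1, hi, prot)))
  } else {
    ctr <- (lo + hi) / 2
    ns <- round(ctr - .NUCLEOSOME_BP / 2)
    ns <- max(lo, min(ns, hi - .NUCLEOSOME_BP))
    out <- c(out, list(.grfFill(lo, ns, prot),
                       .blk("nucleosome", ns, ns + .NUCLEOSOME_BP,
                            prot[["nucleosome"]]),
                       .grfFill(ns + .NUCLEOSOME_BP, hi, prot)))
  }
  do.call(rbind, out)
}

## A 41-bp ORC footprint on the ACS, GRF filler for the residue.
.gapORC <- function(lo, hi, prot, acsCenter, orcWidth = 41L) {
  o0 <- round(acsCenter - orcWidth / 2)
  o0 <- max(lo, min(o0, hi - orcWidth))
  rbind(.grfFill(lo, o0, prot),
        .blk("ORC", o0, o0 + orcWidth, prot[["ORC"]]),
        .grfFill(o0 + orcWidth, hi, prot))
}

## -- feature helper ---------------------------------------------------------

.featDf <- function(name, kind, start, end, source, citation = NA_character_) {
  data.frame(name = name, kind = kind, start = as.integer(start),
             end = as.integer(end), source = source, citation = citation)
}

.makeFeatures <- function(df, templateName) {
  gr <- GenomicRanges::GRanges(
    seqnames = templateName,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$kind <- df$kind
  S4Vectors::mcols(gr)$source <- df$source
  S4Vectors::mcols(gr)$citation <- df$citation
  gr
}

.siteDf <- function(label, offset, window, source,
                    citation = NA_character_) {
  data.frame(label = label, offset = offset, window = window,
             source = source, citation = citation,
             stringsAsFactors = FALSE)
}

.gapDf <- function(from, to, primary) {
  data.frame(from = from, to = to, primary = primary,
             stringsAsFactors = FALSE)
}

## Motif widths used for features and planted consensus (fixture matrices).
.MOTIF_WIDTHS <- c(ACS = 11L, Abf1_site = 13L, Tbf1_site = 6L,
                   Reb1_site = 7L, Rap1_site = 12L)

.motifFeat <- function(name, kind, center, source, citation = NA_character_) {
  w <- .MOTIF_WIDTHS[[kind]]
  s <- as.integer(round(center - w / 2))
  .featDf(name, kind, s, s + w, source, citation)
}

## ---------------------------------------------------------------------------

#' Build one of the encoded subtelomere templates
#'
#' Returns a fully populated [SubtelomereTemplate-class] for one of the
#' analyzed restriction fragments: the generic terminal Y' fragment
#' (`YpTRF`, XhoI anchor), the two terminal X fragments (`TEL03L`,
#' HindIII; `TEL06R`, XhoI), the two internal X-Y' junction fragments
#' (`X05R_AF`, PvuI; `X16R_AF`, BamHI), the euchromatic replication-origin
#' control (`TRP1ARS1`, XbaI) and the plasmid-borne copy of the TEL05R
#' X-Y' junction (`p05RA`, PstI/NsiI).
#'
#' @param name one of [templateNames()].
#' @param protections named protection fractions, see
#'   [defaultProtections()].
#' @param window default accessible half-width (bp) of a planted cut
#'   window; tight linkers use narrower windows so every nucleosome keeps
#'   its full 146-bp footprint.
#' @param yprimeVariant for `YpTRF` only: occupant of the short protected
#'   interval distal to the ORC-bound ACS. `"factor"` places an unknown
#'   non-histone factor (modeled as a GRF block); `"orc_only"` leaves the
#'   interval weakly protected (an unstable particle).
#' @return a validated [SubtelomereTemplate-class].
#' @examples
#' tpl <- buildTemplate("TEL03L")
#' siteTruth(tpl)
#' @export
buildTemplate <- function(name,
                          protections = defaultProtections(),
                          window = 8,
                          yprimeVariant = c("factor", "orc_only")) {
  if (length(name) != 1L || !name %in% templateNames())
    stop("unknown template '", name, "'; valid names: ",
         paste(templateNames(), collapse = ", "))
  yprimeVariant <- match.arg(yprimeVariant)
  prot <- protections
  builder <- switch(name,
    YpTRF    = .buildYpTRF,
    TEL03L   = .buildTEL03L,
    TEL06R   = .buildTEL06R,
    X05R_AF  = .buildX05R,
    X16R_AF  = .buildX16R,
    TRP1ARS1 = .buildTRP1ARS1,
    p05RA    = .buildP05RA)
  builder(prot, window, yprimeVariant)
}

.assemble <- function(name, length, anchor, terminal, tgMean, tgSD,
                      featDf, occ, probe, sites, gaps) {
  occ <- occ[!vapply(seq_len(nrow(occ)), function(i) is.na(occ$start[i]),
                     logical(1)), , drop = FALSE]
  occ <- occ[order(occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  new("SubtelomereTemplate",
      name = name, length = as.integer(length), anchor = anchor,
      features = .makeFeatures(featDf, name), occupants = occ,
      probe = IRanges::IRanges(start = probe[1L] + 1L, end = probe[2L]),
      terminal = terminal,
      tgMean = if (terminal) tgMean else NA_real_,
      tgSD = if (terminal) tgSD else NA_real_,
      sites = sites, gaps = gaps)
}

## -- the generic terminal Y' restriction fragment ---------------------------

.buildYpTRF <- function(prot, w, yprimeVariant) {
  junction <- 1000
  len <- junction + 525      # mean 300 +/- 75 bp tract, truncated at +3 SD
  s <- .siteDf(
    label  = c("V", "IV", "III", "II", "I"),
    offset = c(390, 555, 684, 790, 990),
    window = w,
    source = c("reconstructed", "reconstructed", "reconstructed",
               "reconstructed", "reconstructed"),
    citation = c(NA, NA,
                 "spacing III-IV 129 +/- 11 bp",
                 "spacing II-III 106 +/- 15 bp",
                 "junction site, main early Rap1-fusion cleavage"))
  s <- s[order(s$offset), ]
  occ <- rbind(
    .nucArrayFill(0, s$offset[1] - w, prot),                       # probe side
    .gapNuc(s$offset[1] + w, s$offset[2] - w, prot),               # V-IV
    if (yprimeVariant == "factor")
      .grfFill(s$offset[2] + w, s$offset[3] - w, prot)             # IV-III
    else
      .grfFill(s$offset[2] + w, s$offset[3] - w, prot,
               protection = 0.5),
    .gapORC(s$offset[3] + w, s$offset[4] - w, prot, acsCenter = 737.5),
    .grfFill(s$offset[4] + w, s$offset[5] - w, prot),              # II-I
    .grfFill(s$offset[5] + w, junction, prot),
    .blk("Rap1_array", junction, len, prot[["Rap1_array"]]))
  fe <- rbind(
    .featDf("XhoI", "restriction_site", 0, 1, "published",
            "conserved XhoI site on all Y' elements"),
    .featDf("YPX_probe", "probe", 0, 150, "reconstructed"),
    .motifFeat("Y_ACS", "ACS", 737.5, "reconstructed",
               "verified Y'-ACS between cut sites II and III"),
    .motifFeat("Tbf1_a", "Tbf1_site", 808, "reconstructed"),
    .motifFeat("Reb1_a", "Reb1_site", 823.5, "reconstructed",
               "two Reb1 sites spaced by 137 bp"),
    .motifFeat("Tbf1_b", "Tbf1_site", 883, "reconstructed"),
    .motifFeat("Tbf1_c", "Tbf1_site", 913, "reconstructed"),
    .motifFeat("Reb1_b", "Reb1_site", 960.5, "reconstructed",
               "two Reb1 sites spaced by 137 bp"),
    .motifFeat("Tbf1_d", "Tbf1_site", 968, "reconstructed"),
    .featDf("TG_tract", "TG_tract", junction, len, "published",
            "300 +/- 75 bp of heterogeneous telomeric repeats"))
  gaps <- .gapDf(from = c("I", "II", "III", "IV"),
                 to   = c("II", "III", "IV", "V"),
                 primary = c("grf_array", "ORC",
                             if (yprimeVariant == "factor") "factor"
                             else "unstable", "nucleosome"))
  .assemble("YpTRF", len, "XhoI", TRUE, 300, 75, fe, occ, c(0, 150), s, gaps)
}

## -- terminal X-only fragment, majority class (TEL03L) ----------------------

.buildTEL03L <- function(prot, w, ...) {
  junction <- 1264
  len <- junction + 525
  s <- .siteDf(
    label  = c("VIII", "VII", "VI", "V", "IV", "III", "II", "I"),
    offset = c(189, 354, 519, 605, 804, 991, 1143, 1249),
    window = c(w, w, w, w, w, 3, 3, w),
    source = c("reconstructed", "reconstructed", "reconstructed",
               "reconstructed", "published", "reconstructed",
               "reconstructed", "reconstructed"),
    citation = c(NA, NA, "ACS-flanking, spacing V-VI 87 +/- 10 bp", NA,
                 "cut site IV: 804 +/- 21 bp from the HindIII site",
                 "spacing III-IV 187 +/- 16 bp",
                 "spacing II-III 152 +/- 12 bp",
                 "15.2 bp from the start of the TG repeats"))
  off <- s$offset; win <- s$window
  occ <- rbind(
    .nucArrayFill(0, off[1] - win[1], prot),
    .gapNuc(off[1] + win[1], off[2] - win[2], prot),      # VIII-VII
    .gapNuc(off[2] + win[2], off[3] - win[3], prot),      # VII-VI
    .gapORC(off[3] + win[3], off[4] - win[4], prot, acsCenter = 562.5),
    .gapNuc(off[4] + win[4], off[5] - win[5], prot, abf1Center = 783.5),
    .gapNuc(off[5] + win[5], off[6] - win[6], prot),      # IV-III
    .gapNuc(off[6] + win[6], off[7] - win[7], prot),      # III-II
    .grfFill(off[7] + win[7], off[8] - win[8], prot),     # II-I
    .grfFill(off[8] + win[8], junction, prot),
    .blk("Rap1_array", junction, len, prot[["Rap1_array"]]))
  fe <- rbind(
    .featDf("HindIII", "restriction_site", 0, 1, "published",
            "HindIII-digested genomic DNA, TEL03L probe"),
    .featDf("TEL03L_probe", "probe", 0, 150, "reconstructed"),
    .motifFeat("X_ACS", "ACS", 562.5, "published",
               "ACS-Abf1 spacing 221 +/- 1 bp; Abf1 centered at 783"),
    .motifFeat("X_Abf1", "Abf1_site", 783.5, "published",
               "Abf1 site centered at 783 bp from the HindIII site"),
    .motifFeat("Tbf1_a", "Tbf1_site", 1153, "reconstructed"),
    .motifFeat("Reb1_a", "Reb1_site", 1163.5, "reconstructed"),
    .motifFeat("Tbf1_b", "Tbf1_site", 1198, "reconstructed"),
    .motifFeat("Tbf1_c", "Tbf1_site", 1218, "reconstructed"),
    .motifFeat("Reb1_b", "Reb1_site", 1233.5, "reconstructed"),
    .featDf("TG_tract", "TG_tract", junction, len, "published",
            "300 +/- 75 bp of heterogeneous telomeric repeats"))
  gaps <- .gapDf(from = c("I", "II", "III", "IV", "V", "VI", "VII"),
                 to   = c("II", "III", "IV", "V", "VI", "VII", "VIII"),
                 primary = c("grf_array", "nucleosome", "nucleosome",
                             "nucleosome", "ORC", "nucleosome",
                             "nucleosome"))
  .assemble("TEL03L", len, "HindIII", TRUE, 300, 75, fe, occ,
            c(0, 150), s, gaps)
}

## -- terminal X-only fragment, exceptional class (TEL06R) -------------------

.buildTEL06R <- function(prot, w, ...) {
  junction <- 1026
  len <- junction + 525
  s <- .siteDf(
    label  = c("V", "IV", "III", "II", "I"),
    offset = c(260, 425, 590, 857, 1000),
    window = w,
    source = c("reconstructed", "reconstructed", "reconstructed",
               "reconstructed", "reconstructed"),
    citation = c(NA, NA, "ACS-proximal site (denominator of the X06R ratio)",
                 "spacing I-II 143 +/- 9 bp",
                 "26.0 bp from the start of the TG repeats"))
  off <- s$offset
  ## III-II interval: ORC on the ACS, one positioned nucleosome, Abf1 at
  ## ACS + 221. The junction-proximal II-I interval is poorly protected
  ## (diffuse cutting), held by single Reb1/Abf1-class factors.
  occ <- rbind(
    .nucArrayFill(0, off[1] - w, prot),
    .gapNuc(off[1] + w, off[2] - w, prot),
    .gapNuc(off[2] + w, off[3] - w, prot),
    .blk("ORC", off[3] + w, off[3] + w + 41, prot[["ORC"]]),
    .grfFill(off[3] + w + 41, 649, prot),
    .blk("nucleosome", 649, 795, prot[["nucleosome"]]),
    .grfFill(795, 828, prot),
    .blk("Abf1", 828, 844, prot[["Abf1"]]),
    .grfFill(844, off[4] - w, prot),
    .grfFill(off[4] + w, off[5] - w, prot, protection = 0.9),
    .grfFill(off[5] + w, junction, prot),
    .blk("Rap1_array", junction, len, prot[["Rap1_array"]]))
  fe <- rbind(
    .featDf("XhoI", "restriction_site", 0, 1, "published",
            "XhoI-digested genomic DNA, TEL06R probe"),
    .featDf("TEL06R_probe", "probe", 0, 150, "reconstructed"),
    .motifFeat("X_ACS", "ACS", 615.5, "reconstructed",
               "ACS-Abf1 spacing 221 +/- 1 bp on X-only telomeres"),
    .motifFeat("X_Abf1", "Abf1_site", 836.5, "reconstructed",
               "ACS-Abf1 spacing 221 +/- 1 bp on X-only telomeres"),
    .motifFeat("Reb1_a", "Reb1_site", 925.5, "reconstructed",
               "junction area bound by one Reb1 and one Abf1"),
    .featDf("TG_tract", "TG_tract", junction, len, "published",
            "300 +/- 75 bp of heterogeneous telomeric repeats"))
  gaps <- .gapDf(from = c("I", "II", "III", "IV"),
                 to   = c("II", "III", "IV", "V"),
                 primary = c("grf_diffuse", "nucleosome", "nucleosome",
                             "nucleosome"))
  .assemble("TEL06R", len, "XhoI", TRUE, 300, 75, fe, occ, c(0, 150), s, gaps)
}

## -- internal X-Y' junction fragments ---------------------------------------

.buildX05R <- function(prot, w, ...) {
  xStart <- 1281; junction <- 1756
  len <- junction + 4467
  s <- .siteDf(
    label  = c("S-I", "S-II", "S-III", "X-I", "X-II", "X-III", "X-IV",
               "Y'-I", "Y'-II", "Y'-III", "Y'-IV", "Y'-V", "Y'-VI"),
    offset = c(780, 945, 1110, 1282, 1367, 1594, 1700,
               1826, 2010, 2175, 2340, 2505, 2670),
    window = w,
    source = c(rep("reconstructed", 3), "reconstructed", "reconstructed",
               "published", "reconstructed", "published",
               rep("reconstructed", 5)),
    citation = c(NA, NA, NA,
                 "ACS-flanking, protected area of about 85 bp",
                 "ACS-flanking, protected area of about 85 bp",
                 "X-III centered at 1594 +/- 19 bp from the PvuI site",
                 NA,
                 "Y'-I at 70 +/- 20 bp from the X-Y' junction",
                 NA, NA, NA, NA, NA))
  off <- s$offset
  occ <- rbind(
    .nucArrayFill(0, off[1] - w, prot),
    .gapNuc(off[1] + w, off[2] - w, prot),
    .gapNuc(off[2] + w, off[3] - w, prot),
    .gapNuc(off[3] + w, off[4] - w, prot),
    .gapORC(off[4] + w, off[5] - w, prot, acsCenter = 1325.5),
    .gapNuc(off[5] + w, off[6] - w, prot, abf1Center = 1545.5),
    .grfFill(off[6] + w, off[7] - w, prot),
    .grfFill(off[7] + w, junction, prot),
    .grfFill(junction, off[8] - w, prot),
    .blk("Abf1", off[8] + w, off[8] + w + 16, prot[["Abf1"]]),
    .blk("nucleosome", off[8] + w + 16, off[8] + w + 16 + 146,
         prot[["nucleosome"]]),
    .grfFill(off[8] + w + 162, off[9] - w, prot),
    .gapNuc(off[9] + w, off[10] - w, prot),
    .gapNuc(off[10] + w, off[11] - w, prot),
    .gapNuc(off[11] + w, off[12] - w, prot),
    .gapNuc(off[12] + w, off[13] - w, prot),
    .nucArrayFill(off[13] + w, len, prot))
  fe <- rbind(
    .featDf("PvuI_distal", "restriction_site", 0, 1, "published",
            "offsets plotted with respect to the telomere-distal PvuI site"),
    .featDf("TEL05R_probe", "probe", 0, 150, "published",
            "probe 1281 bp from the start of the X element"),
    .featDf("X_start", "element_boundary", xStart, xStart + 1,
            "published", "probe 1281 bp from the start of the X element"),
    .motifFeat("X_ACS", "ACS", 1325.5, "published",
               "X(TEL05R)-ACS located at 1325 bp from the PvuI site"),
    .motifFeat("Rap1_a", "Rap1_site", 1310, "pwm_predicted"),
    .motifFeat("Rap1_b", "Rap1_site", 1630, "pwm_predicted"),
    .motifFeat("X_Abf1", "Abf1_site", 1545.5, "published",
               "X-Abf1 site at 1545 bp from the PvuI site"),
    .motifFeat("Tbf1_a", "Tbf1_site", 1613, "reconstructed"),
    .motifFeat("Tbf1_b", "Tbf1_site", 1645, "reconstructed"),
    .motifFeat("Rap1_c", "Rap1_site", 1918, "pwm_predicted"),
    .motifFeat("Reb1_a", "Reb1_site", 1668.5, "reconstructed"),
    .motifFeat("Tbf1_c", "Tbf1_site", 1718, "reconstructed"),
    .motifFeat("Tbf1_d", "Tbf1_site", 1738, "reconstructed"),
    .featDf("XY_junction", "element_boundary", junction, junction + 1,
            "published", "X-Y' junction without interstitial TG repeats"),
    .motifFeat("Yp_Abf1", "Abf1_site", 1831.5, "published",
               "potential Abf1 site centered at 75 bp from the X-Y' junction"),
    .featDf("PvuI_proximal", "restriction_site", len - 1, len,
            "published", "analyzed fragment closed by PvuI"))
  gaps <- .gapDf(
    from = s$label[-nrow(s)], to = s$label[-1L],
    primary = c("nucleosome", "nucleosome", "nucleosome", "ORC",
                "nucleosome", "grf_array", "grf_array", "nucleosome",
                "nucleosome", "nucleosome", "nucleosome", "nucleosome"))
  .assemble("X05R_AF", len, "PvuI", FALSE, NA, NA, fe, occ, c(0, 150),
            s, gaps)
}

.buildX16R <- function(prot, w, ...) {
  xStart <- 1306; junction <- 1781
  len <- 2600
  s <- .siteDf(
    label  = c("S-I", "S-II", "S-III", "X-I", "X-II", "Y'-I"),
    offset = c(800, 965, 1130, 1322, 1563, 1846),
    window = w,
    source = c(rep("reconstructed", 4), "reconstructed", "published"),
    citation = c(NA, NA, NA,
                 "broad cleavage centered on or close to the X-ACS",
                 "Abf1-adjacent cleavage",
                 "Y'-I at 65 +/- 4 bp from the X-Y' junction"))
  off <- s$offset
  occ <- rbind(
    .nucArrayFill(0, off[1] - w, prot),
    .gapNuc(off[1] + w, off[2] - w, prot),
    .gapNuc(off[2] + w, off[3] - w, prot),
    .gapNuc(off[3] + w, off[4] - w, prot),
    .blk("ORC", off[4] + w, off[4] + w + 41, prot[["ORC"]]),
    .grfFill(off[4] + w + 41, 1379, prot),
    .blk("nucleosome", 1379, 1525, prot[["nucleosome"]]),
    .grfFill(1525, 1539, prot),
    .blk("Abf1", 1539, 1555, prot[["Abf1"]]),
    .gapNuc(off[5] + w, off[6] - w, prot),
    .blk("Abf1", off[6] + w, off[6] + w + 16, prot[["Abf1"]]),
    .nucArrayFill(off[6] + w + 16, len, prot))
  fe <- rbind(
    .featDf("BamHI", "restriction_site", 0, 1, "published",
            "genomic digestion with BamHI and XhoI"),
    .featDf("TEL16R_probe", "probe", 0, 150, "published",
            "probe hybridizing at 1306 bp from the X element start"),
    .featDf("X_start", "element_boundary", xStart, xStart + 1,
            "published", "probe at 1306 bp from the X element start"),
    .motifFeat("X_ACS", "ACS", 1350.5, "reconstructed",
               "X(TEL16R) ACS-Abf1 spacing of 192 bp"),
    .motifFeat("Rap1_a", "Rap1_site", 1460, "pwm_predicted"),
    .motifFeat("X_Abf1", "Abf1_site", 1542.5, "published",
               "X(TEL16R) ACS-Abf1 spacing of 192 bp"),
    .motifFeat("Tbf1_a", "Tbf1_site", 1603, "reconstructed",
               "only one potential Tbf1 site within the X element"),
    .featDf("XY_junction", "element_boundary", junction, junction + 1,
            "published", "X-Y'(short) junction"),
    .motifFeat("Yp_Abf1", "Abf1_site", 1854.5, "reconstructed"),
    .featDf("XhoI_closing", "restriction_site", len - 1, len,
            "published", "genomic digestion with BamHI and XhoI"))
  gaps <- .gapDf(from = s$label[-nrow(s)], to = s$label[-1L],
                 primary = c("nucleosome", "nucleosome", "nucleosome",
                             "nucleosome", "nucleosome"))
  .assemble("X16R_AF", len, "BamHI", FALSE, NA, NA, fe, occ, c(0, 150),
            s, gaps)
}

## -- euchromatic replication-origin control ---------------------------------

.buildTRP1ARS1 <- function(prot, w, ...) {
  len <- 1453
  s <- .siteDf(
    label  = c("I", "II", "III", "IV", "V"),
    offset = c(300, 465, 575, 740, 905),
    window = w,
    source = c("reconstructed", "reconstructed", "reconstructed",
               "reconstructed", "reconstructed"),
    citation = c(NA, "ACS-flanking (nucleosome-free area, sites II to III)",
                 "ACS-flanking; a short 110-bp fragment next to the ACS",
                 NA, NA))
  off <- s$offset
  occ <- rbind(
    .nucArrayFill(0, off[1] - w, prot),
    .gapNuc(off[1] + w, off[2] - w, prot),
    .gapORC(off[2] + w, off[3] - w, prot, acsCenter = 520.5),
    .gapNuc(off[3] + w, off[4] - w, prot),
    .gapNuc(off[4] + w, off[5] - w, prot),
    .nucArrayFill(off[5] + w, len, prot))
  fe <- rbind(
    .featDf("XbaI", "restriction_site", 0, 1, "published",
            "XbaI-digested genomic DNA, TRP1 probe"),
    .featDf("TRP1_probe", "probe", 0, 150, "reconstructed"),
    .motifFeat("ARS1_ACS", "ACS", 520.5, "published",
               "well-documented ACS of the ARS1 locus"),
    .featDf("XbaI_closing", "restriction_site", len - 1, len,
            "published", "XbaI fragment of the TRP1ARS1 locus"))
  gaps <- .gapDf(from = c("I", "II", "III", "IV"),
                 to   = c("II", "III", "IV", "V"),
                 primary = c("nucleosome", "ORC", "nucleosome",
                             "nucleosome"))
  .assemble("TRP1ARS1", len, "XbaI", FALSE, NA, NA, fe, occ, c(0, 150),
            s, gaps)
}

## -- plasmid-borne copy of the TEL05R X-Y' junction -------------------------

.buildP05RA <- function(prot, w, ...) {
  xStart <- 1100; junction <- xStart + 475
  len <- junction + 1487
  sh <- xStart - 1281                     # shift from the chromosomal copy
  s <- .siteDf(
    label  = c("X-I", "X-II", "X-III", "X-IV", "Y'-I", "Y'-II"),
    offset = c(1282, 1367, 1594, 1700, 1826, 2010) + sh,
    window = w,
    source = "reconstructed",
    citation = c("same X-relative position as the chromosomal locus",
                 NA, NA, NA,
                 "Y'-I confounded with a non-specific band on the plasmid",
                 NA))
  off <- s$offset
  occ <- rbind(
    .nucArrayFill(0, off[1] - w, prot),
    .gapORC(off[1] + w, off[2] - w, prot, acsCenter = 1325.5 + sh),
    .gapNuc(off[2] + w, off[3] - w, prot, abf1Center = 1545.5 + sh),
    .grfFill(off[3] + w, off[4] - w, prot),
    .grfFill(off[4] + w, junction, prot),
    .grfFill(junction, off[5] - w, prot),
    .blk("Abf1", off[5] + w, off[5] + w + 16, prot[["Abf1"]]),
    .blk("nucleosome", off[5] + w + 16, off[5] + w + 162,
         prot[["nucleosome"]]),
    .grfFill(off[5] + w + 162, off[6] - w, prot),
    .nucArrayFill(off[6] + w, len, prot))
  fe <- rbind(
    .featDf("PstI", "restriction_site", 0, 1, "published",
            "PstI- and NsiI-digested DNA, plasmid probe next to PstI"),
    .featDf("p05RA_probe", "probe", 0, 150, "published",
            "oligonucleotide probe next to the PstI site"),
    .featDf("X_start", "element_boundary", xStart, xStart + 1,
            "reconstructed"),
    .motifFeat("X_ACS", "ACS", 1325.5 + sh, "published",
               "same X element as the chromosomal TEL05R locus"),
    .motifFeat("Rap1_a", "Rap1_site", 1310 + sh, "pwm_predicted"),
    .motifFeat("Rap1_b", "Rap1_site", 1630 + sh, "pwm_predicted"),
    .motifFeat("X_Abf1", "Abf1_site", 1545.5 + sh, "published",
               "same X element as the chromosomal TEL05R locus"),
    .motifFeat("Tbf1_a", "Tbf1_site", 1613 + sh, "reconstructed"),
    .motifFeat("Tbf1_b", "Tbf1_site", 1645 + sh, "reconstructed"),
    .motifFeat("Rap1_c", "Rap1_site", 1918 + sh, "pwm_predicted"),
    .motifFeat("Reb1_a", "Reb1_site", 1668.5 + sh, "reconstructed"),
    .featDf("XY_junction", "element_boundary", junction, junction + 1,
            "published", "plasmid insert spans the X-Y' junction"),
    .motifFeat("Yp_Abf1", "Abf1_site", 1831.5 + sh, "reconstructed"),
    .featDf("NsiI", "restriction_site", len - 1, len, "published",
            "PstI- and NsiI-digested DNA"))
  gaps <- .gapDf(from = s$label[-nrow(s)], to = s$label[-1L],
                 primary = c("ORC", "nucleosome", "grf_array", "grf_array",
                             "nucleosome"))
  .assemble("p05RA", len, "PstI", FALSE, NA, NA, fe, occ, c(0, 150),
            s, gaps)
}

## ---------------------------------------------------------------------------
## Sequence synthesis and export
## ---------------------------------------------------------------------------

.MOTIF_KINDS <- c("ACS", "Abf1_site", "Tbf1_site", "Reb1_site", "Rap1_site")

.KIND_TO_MATRIX <- c(ACS = "ACS", Abf1_site = "MA0265.1",
                     Tbf1_site = "MA0403.1", Reb1_site = "MA0363.1",
                     Rap1_site = "MA0359.1")

## Telomeric repeat grammar (TG2-3 (TG)1-6)n, emitted until >= n bp.
.tgRepeat <- function(n) {
  out <- character(0)
  total <- 0L
  while (total < n) {
    unit <- paste0("T", strrep("G", sample(2:3, 1L)),
                   strrep("TG", sample(1:6, 1L)))
    out[length(out) + 1L] <- unit
    total <- total + nchar(unit)
  }
  substr(paste(out, collapse = ""), 1L, n)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Synthesize a nucleotide sequence for a template
#'
#' Generates a deterministic sequence of the template's length: motif
#' features carry the consensus of the corresponding fixture matrix, the
#' TG tract is filled with the telomeric repeat grammar
#' (TG2-3(TG)1-6)n, and the background is drawn uniformly over ACGT from
#' the seeded generator.
#'
#' @param template a [SubtelomereTemplate-class].
#' @param seed integer seed; the output is a pure function of
#'   `(template, seed)`.
#' @return a [Biostrings::DNAString] of the template length.
#' @export
synthesizeSequence <- function(template, seed) {
  stopifnot(is(template, "SubtelomereTemplate"))
  L <- templateLength(template)
  fe <- templateFeatures(template)
  k <- S4Vectors::mcols(fe)$kind
  mot <- fe[k %in% .MOTIF_KINDS]
  if (length(mot) > 1L) {
    ov <- IRanges::findOverlaps(IRanges::ranges(mot), IRanges::ranges(mot))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    bad <- qh < sh &
      S4Vectors::mcols(mot)$kind[qh] != S4Vectors::mcols(mot)$kind[sh]
    if (any(bad))
      stop("overlapping motif features of different kinds; cannot plant both")
  }
  mats <- fixtureMatrices()
  .withSeed(seed, {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (length(mot)) {
      for (i in seq_along(mot)) {
        id <- .KIND_TO_MATRIX[[S4Vectors::mcols(mot)$kind[i]]]
        cons <- strsplit(matrixConsensus(mats[[id]]), "")[[1L]]
        s0 <- GenomicRanges::start(mot)[i]          # 1-based
        base[seq(s0, length.out = length(cons))] <- cons
      }
    }
    tg <- fe[k == "TG_tract"]
    if (length(tg)) {
      s0 <- GenomicRanges::start(tg)[1L]
      n <- GenomicRanges::end(tg)[1L] - s0 + 1L
      base[seq(s0, length.out = n)] <- strsplit(.tgRepeat(n), "")[[1L]]
    }
    Biostrings::DNAString(paste(base, collapse = ""))
  })
}

#' Export template features as BED
#'
#' Features are written 0-based half-open with `kind:name` in the name
#' column.
#' @param template a [SubtelomereTemplate-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportTemplateBED <- function(template, file) {
  gr <- templateFeatures(template)
  nm <- paste(S4Vectors::mcols(gr)$kind, S4Vectors::mcols(gr)$name, sep = ":")
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr))
  S4Vectors::mcols(out)$name <- nm
  S4Vectors::mcols(out)$score <- 0
  GenomeInfoDb::seqlengths(out) <- stats::setNames(
    templateLength(template), templateName(template))
  rtracklayer::export(out, file, format = "BED")
  invisible(file)
}

#' Export a synthesized template sequence as FASTA
#' @param template a [SubtelomereTemplate-class].
#' @param file output path.
#' @param seed seed passed to [synthesizeSequence()].
#' @return the path, invisibly.
#' @export
exportTemplateFASTA <- function(template, file, seed = 1L) {
  seqs <- Biostrings::DNAStringSet(synthesizeSequence(template, seed))
  names(seqs) <- templateName(template)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
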