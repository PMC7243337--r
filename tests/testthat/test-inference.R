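.sitesAt <- function(tpl, offsets = NULL, sd = 2) {
  if (is.null(offsets)) offsets <- sort(siteTruth(tpl)$offset)
  obs <- data.frame(offset = c(offsets - sd, offsets + sd),
                    construct = rep(c("GBD-MN", "NLS-MN"), each =
                                      length(offsets)))
  consolidateSites(obs, tpl)
}

test_that("the 146-bp rule classifies spacings with its stated boundary", {
  tpl <- buildTemplate("TEL03L")
  sites <- data.frame(label = c("a", "b", "c", "d"),
                      meanOffset = c(100, 206, 352, 498),
                      sdOffset = c(3, 4, 2, 2))
  iv <- classifyIntervals(sites, tpl)
  expect_identical(iv$class, c("sub_nucleosomal",       # 106
                               "nucleosome_compatible", # 146 exactly
                               "nucleosome_compatible")) # 146
  expect_equal(iv$spacing, c(106, 146, 146))
  expect_equal(iv$sdSpacing[1], 5)                      # sqrt(3^2 + 4^2)
  one <- classifyIntervals(sites[1, ], tpl)
  expect_identical(nrow(one), 0L)
  sub <- classifyIntervals(data.frame(label = c("a", "b"),
                                      meanOffset = c(100, 252),
                                      sdOffset = c(2, 2)), tpl)
  expect_identical(sub$class, "nucleosome_compatible")  # 152
})

test_that("intervals associate with the features they cover", {
  tpl <- buildTemplate("TEL03L")
  iv <- classifyIntervals(.sitesAt(tpl), tpl)
  byPair <- function(lo, hi) iv[iv$from == lo & iv$to == hi, ]
  expect_identical(byPair("VI", "V")$association, "ORC_ACS")
  expect_identical(byPair("V", "IV")$association, "Abf1")
  junctionIv <- iv[nrow(iv), ]
  expect_identical(junctionIv$association, "Tbf1_Reb1_array")
  expect_true(junctionIv$junctionProximal)
  expect_false(any(iv$junctionProximal[-nrow(iv)]))
})

test_that("classification is a pure function of the site set", {
  tpl <- buildTemplate("TEL06R")
  s <- .sitesAt(tpl)
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(classifyIntervals(s, tpl), classifyIntervals(shuffled, tpl))
})

test_that("accessibility ratios follow the printed arithmetic", {
  tpl <- buildTemplate("YpTRF")
  sites <- .sitesAt(tpl)
  off <- function(lab) sites$meanOffset[sites$label == lab]
  bands <- data.frame(construct = "MN-Rap1", time = 2, temperature = "30C",
                      offset = c(off("I"), off("II"), off("III")),
                      percentSignal = c(17.4, 12, 8))
  r <- accessibilityRatio(bands, sites, tpl, "MN-Rap1")
  expect_equal(r$value, 0.87, tolerance = 1e-9)
  expect_false(r$detectionLimited)
  ## absent numerator counts as zero cleavage at the junction
  noI <- bands[-1, ]
  expect_equal(accessibilityRatio(noI, sites, tpl, "MN-Rap1")$value, 0)
  ## absent denominator is below the detection limit, not a number
  onlyI <- bands[1, ]
  dl <- accessibilityRatio(onlyI, sites, tpl, "MN-Rap1")
  expect_true(dl$detectionLimited)
  expect_true(is.na(dl$value))
  expect_error(accessibilityRatio(bands, sites, buildTemplate("TRP1ARS1"),
                                  "MN-Rap1"), "no accessibility-ratio")
})

test_that("tethering at the telomere raises the junction ratio", {
  res <- runGroundTruthExperiment("YpTRF", seed = 3, nMolecules = 1500)
  rRap <- accessibilityRatio(res$bands, res$sites, res$template, "MN-Rap1")
  rGBD <- accessibilityRatio(res$bands, res$sites, res$template, "GBD-MN")
  expect_false(rRap$detectionLimited)
  expect_false(rGBD$detectionLimited)
  expect_gt(rRap$value, rGBD$value)
})

test_that("model reconstruction maps intervals to occupant hypotheses", {
  t3 <- buildTemplate("TEL03L")
  m3 <- reconstructModel(classifyIntervals(.sitesAt(t3), t3), t3)
  expect_true(m3@flags[["terminalNFR"]])
  expect_true(m3@flags[["orcSite"]])
  expect_true(m3@flags[["abf1Site"]])
  expect_identical(m3@intervals$occupant[nrow(m3@intervals)], "GRF_NFR")
  ## replication-origin control: ORC flanked by two positioned nucleosomes
  ta <- buildTemplate("TRP1ARS1")
  ma <- reconstructModel(classifyIntervals(.sitesAt(ta), ta), ta)
  occ <- ma@intervals$occupant
  i <- which(occ == "ORC")
  expect_identical(length(i), 1L)
  expect_identical(occ[c(i - 1L, i + 1L)], c("nucleosome", "nucleosome"))
  expect_false(ma@flags[["terminalNFR"]])
  ## a featureless uniform array is all nucleosomes, no NFR
  toy <- makeToyTemplate(len = 1200L)
  sites <- consolidateSites(
    data.frame(offset = rep(seq(200, 860, by = 165), each = 2),
               construct = "GBD-MN"), toy)
  mt <- reconstructModel(classifyIntervals(sites, toy), toy)
  expect_true(all(mt@intervals$occupant == "nucleosome"))
  expect_false(mt@flags[["terminalNFR"]])
})

test_that("ground-truth simulations reconstruct the planted occupancy", {
  expected <- c(nucleosome = "nucleosome", ORC = "ORC",
                grf_array = "GRF_NFR", grf_diffuse = "GRF_NFR",
                factor = "unknown_factor")
  templates <- c("YpTRF", "TEL03L", "TEL06R", "X05R_AF", "X16R_AF")
  passes <- 0L
  nSeeds <- 10L
  for (seed in seq_len(nSeeds)) {
    ok <- TRUE
    for (nm in templates) {
      res <- runGroundTruthExperiment(nm, seed = 100 + seed,
                                      nMolecules = 1200)
      tpl <- res$template
      iv <- classifyIntervals(res$sites, tpl)
      model <- reconstructModel(iv, tpl)
      if (isTerminal(tpl) && !model@flags[["terminalNFR"]]) ok <- FALSE
      ## compare interval hypotheses to the planted gap occupants wherever
      ## both flanking truth sites were recovered
      truth <- siteTruth(tpl)
      gaps <- gapTruth(tpl)
      mIv <- model@intervals
      lo <- res$sites$meanOffset[match(mIv$from, res$sites$label)]
      hi <- res$sites$meanOffset[match(mIv$to, res$sites$label)]
      good <- 0L; scored <- 0L
      for (g in seq_len(nrow(gaps))) {
        o1 <- truth$offset[truth$label == gaps$from[g]]
        o2 <- truth$offset[truth$label == gaps$to[g]]
        j <- which(abs(lo - min(o1, o2)) <= 25 & abs(hi - max(o1, o2)) <= 25)
        if (length(j) != 1L) next
        scored <- scored + 1L
        if (mIv$occupant[j] == expected[[gaps$primary[g]]])
          good <- good + 1L
      }
      if (scored < nrow(gaps) * 0.7 || good < scored * 0.9) ok <- FALSE
    }
    if (ok) passes <- passes + 1L
  }
  expect_gte(passes, 9L)
})

test_that("pattern divergence is a matched-band L1 with unmatched penalty", {
  s <- data.frame(meanOffset = c(100, 400), meanPercent = c(10, 5))
  expect_equal(patternDivergence(s, s), 0)
  a <- data.frame(meanOffset = 100, meanPercent = 10)
  b <- data.frame(meanOffset = 400, meanPercent = 5)
  expect_equal(patternDivergence(a, b), 15)      # both unmatched
  b2 <- data.frame(meanOffset = 110, meanPercent = 4)
  expect_equal(patternDivergence(a, b2), 6)      # matched within tolerance
})

test_that("the fold-back experiment discriminates its two hypotheses", {
  params <- digestionParams(nMolecules = 800, seed = 5)
  ## identical condition and reference lanes diverge by zero
  ref <- foldbackTest("direct_binding", "WT", "chromosomal", params)
  expect_equal(ref$divergence, 0)
  ## direct binding keeps the X-element sites on a plasmid
  dP <- foldbackTest("direct_binding", "WT", "plasmid", params)
  expect_identical(dP$xSiteCount, dP$refXSiteCount)
  expect_identical(dP$refXSiteCount, 4L)
  ## the fold-back hypothesis loses them without SIR or telomeric repeats
  fP <- foldbackTest("foldback", "WT", "plasmid", params)
  fS <- foldbackTest("foldback", "sirD", "chromosomal", params)
  expect_gte(fP$refXSiteCount - fP$xSiteCount, 4L)
  expect_gte(fS$refXSiteCount - fS$xSiteCount, 4L)
  dS <- foldbackTest("direct_binding", "sirD", "chromosomal", params)
  expect_lt(dS$divergence, fS$divergence)
})

test_that("interval tables and occupant tracks serialize", {
  tpl <- buildTemplate("TEL03L")
  sites <- .sitesAt(tpl)
  iv <- classifyIntervals(sites, tpl)
  tsv <- tempfile(fileext = ".tsv")
  writeIntervalsTSV(iv, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$spacing, iv$spacing)
  model <- reconstructModel(iv, tpl)
  bed <- tempfile(fileext = ".bed")
  writeModelBED(model, sites, bed)
  gr <- rtracklayer::import(bed, format = "BED")
  expect_identical(length(gr), nrow(iv))
})
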