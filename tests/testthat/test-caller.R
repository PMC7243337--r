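.popOf <- function(fragments, construct = "GBD-MN", time = 1) {
  new("FragmentPopulation", template = "toy", construct = construct,
      time = time, temperature = "30C", fragments = fragments,
      nMolecules = length(fragments), fullLengths = numeric(0))
}

test_that("a single rendered band is called at its center", {
  cal <- defaultCalibration()
  prof <- renderLane(.popOf(rep(700, 200)), cal)
  b <- detectBands(prof, cal)
  expect_identical(nrow(b), 1L)
  expect_lt(abs(b$size - 700) / 700, 0.01)
  expect_gt(b$percentSignal, 90)   # +/- 2 sigma captures ~95% of the band
})

test_that("well-separated bands size within 2% of truth", {
  cal <- defaultCalibration()
  prof <- renderLane(.popOf(rep(c(500, 800), each = 150)), cal)
  b <- detectBands(prof, cal)
  expect_identical(nrow(b), 2L)
  expect_lt(max(abs(sort(b$size) - c(500, 800)) / c(500, 800)), 0.02)
})

test_that("flat profiles and uncut-only lanes give no calls", {
  cal <- defaultCalibration()
  empty <- renderLane(.popOf(numeric(0)))
  expect_identical(nrow(detectBands(empty, cal)), 0L)
  ## a time-0 lane carries only the full-length fragment, excluded by size
  uncut <- renderLane(.popOf(rep(1453, 300), time = 0), cal)
  expect_identical(nrow(detectBands(uncut, cal,
                                    excludeAboveSize = 0.97 * 1453)), 0L)
  expect_error(detectBands(empty, cal, minProminence = 0), "minProminence")
})

test_that("percent signal is invariant under uniform intensity scaling", {
  cal <- defaultCalibration()
  prof <- renderLane(.popOf(rep(c(400, 900), c(100, 200))), cal)
  b1 <- detectBands(prof, cal)
  scaled <- prof
  scaled@intensity <- prof@intensity * 7.3
  b2 <- detectBands(scaled, cal)
  expect_equal(b1$percentSignal, b2$percentSignal, tolerance = 1e-9)
})

test_that("band sizes map to cut offsets by indirect end-labeling", {
  tpl <- buildTemplate("TEL03L")
  bands <- data.frame(size = c(804, 189))
  out <- sizesToCutOffsets(bands, tpl)
  expect_equal(out$offset, c(804, 189))
  expect_error(sizesToCutOffsets(data.frame(size = 5000), tpl),
               "larger than the template")
})

test_that("consolidation computes cluster statistics and splits by gap", {
  obs <- data.frame(offset = c(500, 505, 498), construct = "GBD-MN")
  s <- consolidateSites(obs)
  expect_identical(nrow(s), 1L)
  expect_equal(s$meanOffset, 501)
  expect_equal(s$sdOffset, sd(c(500, 505, 498)), tolerance = 1e-9)
  s2 <- consolidateSites(data.frame(offset = c(500, 505, 900),
                                    construct = "GBD-MN"))
  expect_identical(nrow(s2), 2L)
  expect_identical(nrow(consolidateSites(data.frame(offset = numeric(0),
                                                    construct = character(0)))),
                   0L)
  single <- consolidateSites(data.frame(offset = c(100, 400),
                                        construct = "GBD-MN"))
  expect_true(all(single$singleSupport))
  expect_true(all(is.na(single$sdOffset)))
  expect_identical(nrow(consolidateSites(data.frame(offset = c(100, 400),
                                                    construct = "GBD-MN"),
                                         minSupport = 2L)), 0L)
  expect_error(consolidateSites(obs, tolerance = 0), "tolerance")
})

test_that("site labels follow the blot conventions", {
  ## terminal fragments number from the junction inward
  yp <- buildTemplate("YpTRF")
  obs <- data.frame(offset = rep(sort(siteTruth(yp)$offset), each = 2),
                    construct = rep(c("GBD-MN", "NLS-MN"), 5))
  s <- consolidateSites(obs, yp)
  expect_identical(s$label, c("V", "IV", "III", "II", "I"))
  expect_identical(s$label[which.max(s$meanOffset)], "I")
  expect_true(all(s$common))
  ## internal X-Y' fragments get region prefixes, ascending
  x5 <- buildTemplate("X05R_AF")
  obs5 <- data.frame(offset = rep(c(780, 1282, 1594, 1826), each = 2),
                     construct = "GBD-MN")
  s5 <- consolidateSites(obs5, x5)
  expect_identical(s5$label, c("S-I", "X-I", "X-II", "Y'-I"))
})

test_that("diffuse regions are flagged by the inter-peak baseline rule", {
  cal <- defaultCalibration()
  bandsOnly <- .popOf(rep(c(500, 800), each = 200))
  profClean <- renderLane(bandsOnly, cal)
  bClean <- detectBands(profClean, cal)
  dClean <- diffuseRegions(profClean, bClean)
  expect_false(any(dClean$diffuse))
  ## add a dense uniform smear between the bands
  set.seed(3)
  smear <- .popOf(c(rep(c(500, 800), each = 200),
                    round(runif(2400, 520, 780))))
  profSmear <- renderLane(smear, cal)
  bSmear <- detectBands(profSmear, cal)
  pair <- diffuseRegions(profSmear, bSmear)
  expect_true(any(pair$diffuse))
  ## ground truth: the TEL06R junction interval is poorly protected
  ## relative to the corresponding TEL03L interval
  a6 <- accessibilityProfile(buildTemplate("TEL06R"))
  a3 <- accessibilityProfile(buildTemplate("TEL03L"))
  expect_gt(mean(a6[866:992]), 5 * mean(a3[1152:1240]))
})

test_that("the full inverse pipeline recovers planted single cuts", {
  for (q in c(300, 700, 1200)) {
    tpl <- toySingleWindow(q)
    hits <- 0L
    for (seed in 1:4) {
      params <- digestionParams(nMolecules = 2000, seed = seed)
      lanes <- simulateExperiment(tpl, list(mnConstruct("GBD-MN")), params,
                                  design = data.frame(time = c(1, 2),
                                                      temperature = "30C"))
      res <- processExperiment(lanes, tpl)
      if (nrow(res$sites) >= 1L &&
          min(abs(res$sites$meanOffset - q)) <= 15) hits <- hits + 1L
    }
    expect_identical(hits, 4L)
  }
})

test_that("consolidated sites export as TSV and BED", {
  yp <- buildTemplate("YpTRF")
  obs <- data.frame(offset = rep(sort(siteTruth(yp)$offset), each = 2),
                    construct = "GBD-MN")
  s <- consolidateSites(obs, yp)
  tsv <- tempfile(fileext = ".tsv")
  writeSitesTSV(s, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$meanOffset, s$meanOffset)
  bed <- tempfile(fileext = ".bed")
  writeSitesBED6(s, yp, bed)
  gr <- rtracklayer::import(bed, format = "BED")
  expect_identical(length(gr), nrow(s))
  expect_setequal(S4Vectors::mcols(gr)$name, s$label)
})
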