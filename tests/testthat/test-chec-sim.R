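test_that("accessibility reflects occupancy exactly", {
  bare <- makeToyTemplate()
  expect_equal(accessibilityProfile(bare), rep(1, templateLength(bare)))
  occ <- data.frame(protein = "nucleosome", start = 100L, end = 246L,
                    protection = 0.98)
  tpl <- makeToyTemplate(len = 500L, occupants = occ)
  a <- accessibilityProfile(tpl)
  expect_equal(a[101:246], rep(0.02, 146))
  expect_equal(a[c(1:100, 247:500)], rep(1, 354))
  yp <- buildTemplate("YpTRF")
  ra <- occupants(yp)
  ra <- ra[ra$protein == "Rap1_array", ]
  expect_true(all(accessibilityProfile(yp)[(ra$start + 1):ra$end] < 0.1))
})

test_that("concentration profiles follow the box-kernel construction", {
  tpl <- makeToyTemplate(len = 1200L, terminal = TRUE)
  for (nm in c("GBD-MN", "NLS-MN"))
    expect_equal(concentrationProfile(tpl, mnConstruct(nm)),
                 rep(1, templateLength(tpl)))
  ## a tract-anchored fusion with unit free pool: full enhancement over
  ## the near-field box, the far-field fraction over the annulus, the
  ## bare pool beyond
  con <- mnConstruct("MN-Rap1", lambda = 20, reach = 150, floor = 1)
  cc <- concentrationProfile(tpl, con, tractReach = 600)
  anchor <- junctionOffset(tpl) + 150            # center of the mean tract
  near <- 150 + 150                              # mean tract / 2 + reach
  x <- seq_len(templateLength(tpl)) - 0.5
  d <- abs(x - anchor)
  expect_equal(unique(cc[d <= near]), 1 + 20 + 20 / 10)
  expect_equal(unique(cc[d > near & d <= 600]), 1 + 20 / 10)
  expect_equal(unique(cc[d > 600]), 1)
  ## annotated Rap1 sites anchor the fusion on the internal X element
  x5 <- buildTemplate("X05R_AF")
  cc5 <- concentrationProfile(x5, mnConstruct("MN-Rap1"))
  fe <- templateFeatures(x5)
  rap1 <- fe[S4Vectors::mcols(fe)$kind == "Rap1_site"]
  ctr <- round((GenomicRanges::start(rap1) + GenomicRanges::end(rap1)) / 2)
  expect_true(all(cc5[ctr] > 1))
  expect_error(mnConstruct("GBD-MN", lambda = 3), "lambda 0")
})

test_that("time zero yields only full-length detected fragments", {
  tpl <- buildTemplate("TEL03L")
  params <- digestionParams(nMolecules = 200, seed = 4)
  lane <- simulateLane(tpl, mnConstruct("GBD-MN"), params, 0)
  expect_identical(length(fragments(lane)), 200L)
  expect_equal(sort(fragments(lane)), sort(lane@fullLengths))
  expect_error(simulateLane(tpl, mnConstruct("GBD-MN"), params, 3),
               "time course")
  expect_error(simulateLane(tpl, mnConstruct("GBD-MN"), params, 1, "37C"),
               "temperature")
})

test_that("fragment mass is conserved per molecule before probe filtering", {
  tpl <- buildTemplate("YpTRF")
  for (seed in 1:10) {
    params <- digestionParams(nMolecules = 1L, timePoints = c(0, 5),
                              seed = seed)
    lane <- simulateLane(tpl, mnConstruct("GBD-MN"), params, 5,
                         keepAll = TRUE)
    expect_equal(sum(fragments(lane)), lane@fullLengths)
  }
})

test_that("mean cut count matches the Poisson closed form within 3 SE", {
  tpl <- makeToyTemplate(len = 1000L)          # fully accessible
  k <- 0.002; tt <- 1
  params <- digestionParams(nMolecules = 2000, timePoints = c(0, tt),
                            baseRate = k, seed = 8)
  lane <- simulateLane(tpl, mnConstruct("GBD-MN"), params, tt,
                       keepAll = TRUE)
  cuts <- length(fragments(lane)) - nMolecules(lane)
  lambda <- k * tt * templateLength(tpl)       # a = c = 1 everywhere
  expect_lt(abs(cuts / nMolecules(lane) - lambda),
            3 * sqrt(lambda / nMolecules(lane)))
})

test_that("mean detected fragment length decreases with digestion time", {
  tpl <- buildTemplate("YpTRF")
  params <- digestionParams(nMolecules = 1500, seed = 21)
  m <- vapply(c(1, 2, 5), function(tt)
    mean(fragments(simulateLane(tpl, mnConstruct("GBD-MN"), params, tt))),
    numeric(1))
  expect_true(all(diff(m) < 0.02 * m[-length(m)]))
})

test_that("experiments enumerate constructs x lanes", {
  tpl <- buildTemplate("TRP1ARS1")
  params <- digestionParams(nMolecules = 50, seed = 1)
  design <- data.frame(time = c(1, 2, 5), temperature = "30C")
  lanes <- simulateExperiment(tpl, defaultConstructs(), params, design)
  expect_identical(length(lanes), 12L)
  ids <- vapply(lanes, function(l) paste(laneId(l), collapse = "|"), "")
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("complete nucleosomal digestion peaks at the nucleosome repeat", {
  params <- digestionParams(nMolecules = 2000, seed = 5)
  lane <- simulateLane(buildTemplate("YpTRF"), mnConstruct("H2A-MN"),
                       params, 5, "30C", keepAll = TRUE)
  f <- fragments(lane)
  f <- f[f > 50 & f < 400]
  h <- hist(f, breaks = seq(0, 400, 20), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 146), 40)
})

test_that("the junction fragment dominates early Rap1-fusion lanes", {
  tpl <- buildTemplate("YpTRF")
  params <- digestionParams(nMolecules = 2000, seed = 5)
  lane <- simulateLane(tpl, mnConstruct("MN-Rap1"), params, 2, "30C")
  b <- detectBands(renderLane(lane), excludeAboveSize = uncutThreshold(tpl),
                   excludeBelowSize = 150)
  top <- b$size[which.max(b$percentSignal)]
  siteI <- max(siteTruth(tpl)$offset)
  expect_lt(abs(top - siteI), 30)
})

test_that("free constructs are statistically exchangeable", {
  tpl <- buildTemplate("TEL06R")
  rejections <- 0L
  for (seed in 1:10) {
    params <- digestionParams(nMolecules = 500, seed = seed)
    a <- fragments(simulateLane(tpl, mnConstruct("GBD-MN"), params, 2))
    b <- fragments(simulateLane(tpl, mnConstruct("NLS-MN"), params, 2))
    p <- suppressWarnings(stats::ks.test(a, b))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("per-lane seeds are deterministic and lane-specific", {
  s1 <- laneSeed(42, "YpTRF", "GBD-MN", 2, "30C")
  expect_identical(s1, laneSeed(42, "YpTRF", "GBD-MN", 2, "30C"))
  expect_false(s1 == laneSeed(42, "YpTRF", "GBD-MN", 5, "30C"))
  expect_false(s1 == laneSeed(43, "YpTRF", "GBD-MN", 2, "30C"))
  tpl <- buildTemplate("TRP1ARS1")
  params <- digestionParams(nMolecules = 300, seed = 9)
  l1 <- simulateLane(tpl, mnConstruct("GBD-MN"), params, 2)
  l2 <- simulateLane(tpl, mnConstruct("GBD-MN"), params, 2)
  expect_identical(fragments(l1), fragments(l2))
})

test_that("lane TSV serialization round-trips", {
  tpl <- buildTemplate("TRP1ARS1")
  params <- digestionParams(nMolecules = 300, seed = 2)
  lane <- simulateLane(tpl, mnConstruct("NLS-MN"), params, 2)
  tmp <- tempfile(fileext = ".tsv")
  writeLaneTSV(lane, tmp)
  back <- readLaneTSV(tmp)
  expect_equal(sort(fragments(back)), sort(fragments(lane)))
  expect_identical(laneId(back), laneId(lane))
  bad <- tempfile(fileext = ".tsv")
  writeLines("foo\tbar\n1\t2", bad)
  expect_error(readLaneTSV(bad), "missing column")
})
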