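test_that("log-odds construction matches its closed form", {
  uni <- countMatrix(matrix(1, 4, 1), "uni")
  lo <- logOdds(uni, pseudocount = 0)
  expect_equal(unname(lo[, 1]), rep(0, 4))
  onlyA <- countMatrix(matrix(c(1, 0, 0, 0), 4, 1), "A")
  loA <- logOdds(onlyA, pseudocount = 0)
  expect_equal(unname(loA["A", 1]), 2)            # log2(1 / 0.25)
  expect_equal(unname(loA["C", 1]), -Inf)
  expect_error(logOdds(onlyA, pseudocount = -1), "pseudocount")
  expect_error(logOdds(countMatrix(matrix(0, 4, 1), "z"), pseudocount = 0),
               "pseudocount")
  expect_error(logOdds(uni, background = c(0.5, 0.5, 0, 0)), "background")
})

test_that("expected background score agrees with Monte-Carlo sampling", {
  set.seed(11)
  counts <- countMatrix(matrix(rpois(4 * 6, 6) + 1, 4, 6), "rand")
  lo <- logOdds(counts)
  closed <- sum(colSums(lo * 0.25))
  n <- 20000
  draws <- matrix(sample.int(4, n * 6, replace = TRUE), n, 6)
  scores <- vapply(seq_len(n), function(i)
    sum(lo[cbind(draws[i, ], seq_len(6))]), numeric(1))
  expect_lt(abs(mean(scores) - closed), 3 * sd(scores) / sqrt(n))
})

test_that("exact DP p-values equal brute-force enumeration for short motifs", {
  g <- 0.01
  for (L in c(3L, 5L, 7L)) {
    set.seed(L)
    counts <- countMatrix(matrix(rpois(4 * L, 5) + 1, 4, L), "bf")
    lo <- logOdds(counts)
    grid <- round(lo / g)
    windows <- as.matrix(expand.grid(rep(list(1:4), L)))
    allScores <- rowSums(matrix(grid[cbind(as.vector(windows),
                                           rep(seq_len(L), each = 4^L))],
                                nrow = 4^L))
    for (q in quantile(allScores, c(0, 0.25, 0.5, 0.9, 1))) {
      expect_equal(pwmPValue(lo, q * g, granularity = g),
                   mean(allScores >= q), tolerance = 1e-9)
    }
    expect_equal(pwmPValue(lo, min(allScores) * g - 1, granularity = g), 1)
    expect_equal(pwmPValue(lo, max(allScores) * g + 1, granularity = g), 0)
  }
})

test_that("p-value is 1 below the minimum and monotone in score", {
  onlyA <- countMatrix(matrix(c(1, 0, 0, 0), 4, 1), "A")
  lo <- logOdds(onlyA, pseudocount = 0.01)
  expect_equal(pwmPValue(lo, max(lo[, 1])), 0.25)   # only A attains the max
  expect_equal(pwmPValue(lo, min(lo[, 1]) - 1), 1)
  counts <- consensusCounts("TTAGGG")
  lo6 <- logOdds(counts)
  scores <- seq(min(colSums(lo6 * 0)), sum(apply(lo6, 2, max)),
                length.out = 25)
  pv <- vapply(scores, function(s) pwmPValue(lo6, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("scanning finds a planted consensus on both strands", {
  counts <- fixtureMatrices()[["MA0363.1"]]
  cons <- matrixConsensus(counts)
  hits <- callSites(cons, counts, pThreshold = 0.001)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 0L)
  expect_identical(hits$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  hitsRC <- callSites(rc, counts, pThreshold = 0.001)
  expect_identical(nrow(hitsRC), 1L)
  expect_identical(hitsRC$position, 0L)
  expect_identical(hitsRC$strand, "-")
  expect_identical(nrow(callSites("ACG", counts)), 0L)   # shorter than motif
})

test_that("strand symmetry: calls on the reverse complement are mirrored", {
  counts <- fixtureMatrices()[["MA0403.1"]]
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  fwd <- callSites(seq, counts)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- callSites(rc, counts)
  L <- ncol(counts)
  mirrored <- data.frame(position = nchar(seq) - L - rev$position,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score, p.value = rev$p.value)
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  rownames(mirrored) <- NULL
  expect_equal(fwd, mirrored, tolerance = 1e-12)
})

test_that("planted motifs on synthesized templates are all recovered", {
  yp <- buildTemplate("YpTRF")
  chr <- as.character(synthesizeSequence(yp, 3))
  fe <- templateFeatures(yp)
  mats <- fixtureMatrices()
  for (kind in c("Reb1_site", "Tbf1_site")) {
    id <- c(Reb1_site = "MA0363.1", Tbf1_site = "MA0403.1")[[kind]]
    planted <- GenomicRanges::start(fe[S4Vectors::mcols(fe)$kind == kind]) - 1L
    hits <- callSites(chr, mats[[id]])
    expect_true(all(planted %in% hits$position[hits$strand == "+"]),
                info = kind)
  }
})

test_that("empirical false-positive rate matches the exact tail probability", {
  counts <- fixtureMatrices()[["MA0403.1"]]
  lo <- logOdds(counts)
  g <- 0.01
  grid <- round(lo / g)
  dist <- telochec:::.scoreDistribution(grid, rep(0.25, 4))
  ## realized alpha of the p < 0.005 rule on the score grid
  support <- dist$offset + seq_along(dist$p) - 1L
  tails <- rev(cumsum(rev(dist$p)))
  sMin <- support[min(which(tails < 0.005))]
  alpha <- tails[min(which(tails < 0.005))]
  set.seed(17)
  N <- 40000
  seq <- paste(sample(c("A", "C", "G", "T"), N, replace = TRUE),
               collapse = "")
  hits <- callSites(seq, counts, pThreshold = 0.005)
  nWin <- 2 * (N - ncol(counts) + 1)        # both strands
  expect_lt(abs(nrow(hits) - nWin * alpha),
            3 * sqrt(nWin * alpha * (1 - alpha)))
})

test_that("forward-strand calls agree with Biostrings matchPWM", {
  counts <- fixtureMatrices()[["MA0363.1"]]
  lo <- logOdds(counts)
  g <- 0.001
  grid <- round(lo / g)
  dist <- telochec:::.scoreDistribution(grid, rep(0.25, 4))
  support <- dist$offset + seq_along(dist$p) - 1L
  tails <- rev(cumsum(rev(dist$p)))
  sMin <- support[min(which(tails < 0.001))]
  set.seed(23)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  mine <- callSites(seq, counts, pThreshold = 0.001, granularity = g)
  mine <- mine$position[mine$strand == "+"]
  ref <- Biostrings::matchPWM(lo, Biostrings::DNAString(seq),
                              min.score = (sMin - 0.5) * g)
  expect_identical(sort(mine), sort(GenomicRanges::start(ref) - 1L))
})

test_that("JASPAR fixtures read back with the documented shapes", {
  mats <- fixtureMatrices()
  expect_setequal(names(mats),
                  c("MA0359.1", "MA0403.1", "MA0363.1", "MA0265.1", "ACS"))
  widths <- vapply(mats, ncol, integer(1))
  expect_identical(widths[["MA0403.1"]], 6L)
  expect_identical(widths[["MA0359.1"]], 12L)
  expect_identical(widths[["ACS"]], 11L)
  expect_identical(unname(mats[["MA0403.1"]][, 1L]), c(1, 1, 1, 17))
  tmp <- tempfile(fileext = ".jaspar")
  writeJASPAR(mats, tmp)
  back <- readJASPAR(tmp)
  for (id in names(mats))
    expect_equal(unclass(back[[id]]), unclass(mats[[id]]),
                 ignore_attr = TRUE)
  expect_equal(defaultPThreshold("MA0403.1"), 0.005)
  expect_equal(defaultPThreshold("ACS"), 1e-6)
  expect_equal(defaultPThreshold("MA0359.1"), 0.001)
})

test_that("PWM calls export as BED6 with capped -log10 p scores", {
  counts <- fixtureMatrices()[["MA0363.1"]]
  cons <- matrixConsensus(counts)
  hits <- callSites(paste0("AAAA", cons, "AAAA"), counts)
  bed <- tempfile(fileext = ".bed")
  writeSitesBED(hits, bed, "toy", ncol(counts))
  back <- rtracklayer::import(bed, format = "BED")
  expect_identical(length(back), nrow(hits))
  expect_true(all(S4Vectors::mcols(back)$score <= 1000))
})
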