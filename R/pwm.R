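#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Position-weight-matrix scanning: log-odds scoring from count matrices and
## exact p-values by dynamic programming over a rounded score grid. This is a
## self-contained re-implementation of the scanning step usually delegated to
## web tools, so binding-site annotation needs no network access.
## ---------------------------------------------------------------------------

.DNA_BASES <- c("A", "C", "G", "T")

#' Construct a count matrix
#'
#' @param counts 4 x L numeric matrix of non-negative counts; rows are
#'   A, C, G, T.
#' @param id matrix identifier (e.g. a JASPAR accession).
#' @param name optional factor name.
#' @return the validated matrix with rownames ACGT and attributes `id`
#'   and `name`.
#' @export
countMatrix <- function(counts, id, name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("a count matrix needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("a count matrix needs at least one column")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  rownames(counts) <- .DNA_BASES
  attr(counts, "id") <- id
  attr(counts, "name") <- name
  counts
}

#' Read JASPAR-format count matrices
#'
#' Parses the plain-text JASPAR format (`>ID name` header followed by
#' four `A [ ... ]` rows).
#'
#' @param file path to a JASPAR-format file.
#' @return named list of count matrices (names are the matrix IDs).
#' @export
readJASPAR <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in '", file, "'")
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    hdr <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1L]]
    id <- hdr[1L]
    nm <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else id
    rows <- lines[(i + 1L):(i + 4L)]
    parsed <- lapply(seq_along(rows), function(r) {
      ln <- rows[r]
      base <- sub("^\\s*([ACGT]).*$", "\\1", ln)
      if (!base %in% .DNA_BASES)
        stop("malformed JASPAR record for ", id, " at line ", i + r,
             ": expected a base row, got '", ln, "'")
      nums <- sub("^\\s*[ACGT]\\s*\\[?", "", ln)
      nums <- sub("\\]\\s*$", "", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (anyNA(vals))
        stop("malformed counts for ", id, " at line ", i + r)
      list(base = base, vals = vals)
    })
    m <- do.call(rbind, lapply(parsed, `[[`, "vals"))
    rownames(m) <- vapply(parsed, `[[`, "", "base")
    m <- m[.DNA_BASES, , drop = FALSE]
    out[[id]] <- countMatrix(m, id = id, name = nm)
  }
  out
}

#' Write count matrices in JASPAR format
#' @param matrices named list of count matrices.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeJASPAR <- function(matrices, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in matrices) {
    writeLines(sprintf(">%s %s", attr(m, "id"), attr(m, "name")), con)
    for (b in .DNA_BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(file)
}

#' Bundled fixture count matrices
#'
#' Small fixture matrices labeled with the JASPAR accessions of the four
#' general regulatory factors (Rap1 MA0359.1, Tbf1 MA0403.1, Reb1
#' MA0363.1, Abf1 MA0265.1) plus a fixture ACS weight matrix standing in
#' for an ORC-binding-site matrix. They are synthetic stand-ins built
#' around the canonical consensus of each factor, adequate for planting
#' and recovering motifs on synthetic sequences; genome-scale site counts
#' obtained with them are not comparable to scans with the curated
#' matrices.
#'
#' @return named list of count matrices.
#' @export
fixtureMatrices <- function() {
  path <- system.file("extdata", "fixture_matrices.jaspar",
                      package = "telochec", mustWork = TRUE)
  readJASPAR(path)
}

#' Consensus string of a count matrix
#' @param counts a count matrix.
#' @return character scalar, the column-wise majority base.
#' @export
matrixConsensus <- function(counts) {
  paste(.DNA_BASES[apply(counts, 2L, which.max)], collapse = "")
}

#' Log-odds matrix from counts
#'
#' entry(b, j) = log2((count(b,j) + pseudocount * background(b)) /
#' (column_total(j) + pseudocount)) - log2(background(b)).
#'
#' @param counts a count matrix (see [countMatrix()]).
#' @param background base frequencies over ACGT, summing to 1, all > 0.
#' @param pseudocount total pseudocount split by background; must be > 0
#'   if any count is zero.
#' @return 4 x L log2-odds matrix (attributes `id`, `background`
#'   preserved).
#' @export
logOdds <- function(counts, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(length(background) == 4L)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8)
    stop("background must be positive and sum to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  tot <- colSums(counts)
  if (pseudocount == 0 && any(tot == 0))
    stop("zero column totals require a positive pseudocount")
  p <- sweep(counts + pseudocount * background, 2L, tot + pseudocount, "/")
  lo <- log2(p) - log2(background)
  rownames(lo) <- .DNA_BASES
  attr(lo, "id") <- attr(counts, "id")
  attr(lo, "background") <- background
  lo
}

## Integer score grid and exact distribution of the window score of a
## background-drawn sequence, by column-wise convolution. -Inf entries
## (zero counts without pseudocount) are capped far below the attainable
## range so the grid stays finite.
.pwmGrid <- function(lo, granularity) {
  if (any(!is.finite(lo))) {
    floorScore <- min(lo[is.finite(lo)]) - 1000 * granularity * ncol(lo)
    lo[!is.finite(lo)] <- floorScore
  }
  g <- round(lo / granularity)
  storage.mode(g) <- "integer"
  g
}

.scoreDistribution <- function(grid, background) {
  dist <- 1
  offset <- 0L
  for (j in seq_len(ncol(grid))) {
    vals <- grid[, j]
    lo_j <- min(vals)
    new <- numeric(length(dist) + (max(vals) - lo_j))
    for (i in 1:4) {
      sh <- vals[i] - lo_j
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[i]
    }
    dist <- new
    offset <- offset + lo_j
  }
  list(p = dist, offset = offset)   # P(grid score == offset + k - 1) = p[k]
}

## P(grid score >= target) from a distribution object.
.tailProb <- function(dist, target) {
  k <- target - dist$offset + 1L
  if (k <= 1L) return(1)
  if (k > length(dist$p)) return(0)
  sum(dist$p[k:length(dist$p)])
}

#' Exact PWM score p-value by dynamic programming
#'
#' Probability that a random window drawn from the background model
#' scores at least `score`, computed exactly by convolving the per-column
#' score distributions on a rounded grid. The grid introduces a score
#' error bounded by L * granularity.
#'
#' @param lo log-odds matrix from [logOdds()].
#' @param score score threshold (log2-odds units).
#' @param background base frequencies (default uniform).
#' @param granularity score grid step, log2-odds units.
#' @return a probability in \[0, 1\].
#' @export
pwmPValue <- function(lo, score, background = rep(0.25, 4),
                      granularity = 0.01) {
  if (granularity <= 0) stop("granularity must be > 0")
  grid <- .pwmGrid(lo, granularity)
  dist <- .scoreDistribution(grid, background)
  .tailProb(dist, as.integer(round(score / granularity)))
}

#' Default p-value threshold for a matrix
#'
#' The scanning thresholds are bound to matrix identity: 0.001 for the
#' Rap1, Reb1 and Abf1 matrices, 0.005 for Tbf1, 1e-6 for the ACS weight
#' matrix.
#' @param id matrix identifier.
#' @return a probability.
#' @export
defaultPThreshold <- function(id) {
  switch(id,
         "MA0403.1" = 0.005,
         "ACS" = 1e-6,
         0.001)
}

## Score a coded sequence (values 1..4, NA for ambiguity) against an
## integer grid; ambiguity columns take the background-weighted average.
.windowScores <- function(code, grid, bgAvg) {
  L <- ncol(grid)
  n <- length(code) - L + 1L
  if (n < 1L) return(integer(0))
  total <- numeric(n)
  for (j in seq_len(L)) {
    v <- grid[, j][code[j:(j + n - 1L)]]
    v[is.na(v)] <- bgAvg[j]
    total <- total + v
  }
  as.integer(round(total))
}

.encodeDNA <- function(sequence) {
  s <- toupper(as.character(sequence))
  match(strsplit(s, "")[[1L]], .DNA_BASES)
}

#' Scan a sequence for PWM matches with exact p-values
#'
#' Both strands are scanned with the log-odds matrix built from `counts`;
#' every window whose exact p-value is below the threshold is reported.
#' Overlapping calls are all reported. Ambiguity codes score as the
#' background-weighted average column score.
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param counts a count matrix.
#' @param pThreshold p-value cutoff in (0, 1); default bound to the
#'   matrix id via [defaultPThreshold()].
#' @param background base frequencies.
#' @param pseudocount see [logOdds()].
#' @param granularity see [pwmPValue()].
#' @return data.frame with `position` (0-based start on the forward
#'   strand), `strand`, `score` (log2-odds), `p.value`, sorted by
#'   position.
#' @export
callSites <- function(sequence, counts, pThreshold = NULL,
                      background = rep(0.25, 4), pseudocount = 0.8,
                      granularity = 0.01) {
  if (is.null(pThreshold)) pThreshold <- defaultPThreshold(attr(counts, "id"))
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must be in (0, 1)")
  lo <- logOdds(counts, background, pseudocount)
  grid <- .pwmGrid(lo, granularity)
  dist <- .scoreDistribution(grid, background)
  bgAvg <- colSums(grid * background)
  L <- ncol(grid)
  fwd <- .encodeDNA(sequence)
  N <- length(fwd)
  if (N < L)
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), p.value = numeric(0)))
  rev <- 5L - rev(fwd)                       # reverse complement coding
  scan1 <- function(code, strand) {
    sc <- .windowScores(code, grid, bgAvg)
    pv <- vapply(sc, function(s) .tailProb(dist, s), numeric(1))
    hit <- which(pv < pThreshold)
    if (!length(hit))
      return(data.frame(position = integer(0), strand = character(0),
                        score = numeric(0), p.value = numeric(0)))
    pos <- if (strand == "+") hit - 1L else N - L - (hit - 1L)
    data.frame(position = pos, strand = strand,
               score = sc[hit] * granularity, p.value = pv[hit])
  }
  out <- rbind(scan1(fwd, "+"), scan1(rev, "-"))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write PWM calls as BED6
#'
#' The BED score column carries -log10(p), capped at 1000.
#' @param sites data.frame from [callSites()].
#' @param file output path.
#' @param seqname sequence name for the BED records.
#' @param width motif width (bp).
#' @return the path, invisibly.
#' @export
writeSitesBED <- function(sites, file, seqname, width) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = width),
    strand = sites$strand)
  S4Vectors::mcols(gr)$name <- sprintf("site_%d", seq_len(nrow(sites)))
  S4Vectors::mcols(gr)$score <- pmin(1000, round(-log10(sites$p.value), 2))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
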