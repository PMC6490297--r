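# Independent oracles and fixture builders used across the suite.
# Every oracle here is a deliberately naive, separate implementation of the
# quantity it checks; none shares code with the package internals.

library(GenomicRanges)
library(Biostrings)

uniformBg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

# truncated-window lower-median smoother, one sort per window
naiveMovingMedian <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - h):min(n, i + h)]
    win <- win[!is.na(win)]
    if (!length(win)) return(NA_real_)
    sort(win)[ceiling(length(win) / 2)]
  }, numeric(1))
}

# Spearman rho via explicit average ranks and the covariance formula
naiveSpearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# BH step-up with an explicit per-rank minimum, denominator N
naiveBH <- function(p, N) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(n), function(i) min(ps[i:n] * N / (i:n)), numeric(1))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# brute-force exact tail probabilities: enumerate all 4^L words under bg at
# the table's integer discretization; returns score -> P(S >= score)
bruteTail <- function(intScores, bg) {
  L <- ncol(intScores)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- rep(0, nrow(grid))
  pr <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    tot <- tot + intScores[grid[, j], j]
    pr <- pr * bg[grid[, j]]
  }
  agg <- rowsum(pr, tot)
  sc <- as.numeric(rownames(agg))
  o <- order(sc, decreasing = TRUE)
  data.frame(score = sc[o], tail = cumsum(agg[o, 1L]))
}

# local linear tricube regression solved through lm() at each target point
naiveTricube <- function(y, span) {
  n <- length(y)
  obs <- which(!is.na(y))
  xo <- as.numeric(obs)
  yo <- y[obs]
  q <- max(2L, as.integer(ceiling(span * length(obs))))
  fit <- vapply(seq_len(n), function(x0) {
    d <- abs(xo - x0)
    o <- order(d)[seq_len(q)]
    h <- d[o[q]]
    wts <- (1 - pmin(1, d[o] / h)^3)^3
    df <- data.frame(xx = xo[o], yy = yo[o])
    m <- stats::lm(yy ~ xx, data = df, weights = wts)
    unname(stats::predict(m, newdata = data.frame(xx = x0)))
  }, numeric(1))
  pmax(fit, 0)
}

# standard synthetic bundle matching the package's study conditions
makeCoupledBundle <- function(seed, chromLengthBp = 5e6, nChrom = 2,
                              baseIntensity = 0.2, coupling = 0.5,
                              noiseCV = 0.3, motif = "[CA]6",
                              shape = "sim_like") {
  lens <- as.list(setNames(rep(chromLengthBp, nChrom),
                           paste0("chr", seq_len(nChrom))))
  generateFixture(list(
    seed = seed, chromLengths = lens,
    landscape = list(shape = shape, noiseCV = noiseCV),
    plant = list(motif = motif, baseIntensity = baseIntensity,
                 coupling = coupling)))
}

# scan -> q -> density -> multi-scale association, the analysis chain the
# pipeline runs after smoothing
bundleAssociationGrid <- function(bundle, motif = "[CA]6", scalesKb = 1,
                                  densityBin = 1000) {
  bg <- estimateBackground(bundle@genome)
  occ <- computeQvalues(scanGenome(bundle@genome, motif, bg))
  lens <- setNames(width(bundle@genome), names(bundle@genome))
  tr <- densityTrack(occ, densityBin, lens)
  maps <- lapply(scalesKb, function(s) movingMedian(bundle@map, s))
  names(maps) <- scalesKb
  associationGrid(maps, tr, bhColumn = FALSE)
}

# occurrences with prescribed q-scores, for density-track tests
fakeOccurrences <- function(chrom, starts, q, L = 12L, lens = NULL) {
  gr <- GRanges(rep_len(chrom, length(starts)),
                IRanges(starts, width = L),
                strand = rep_len("+", length(starts)),
                motif = rep("M", length(starts)),
                pvalue = rep_len(pmin(q, 1) / 2, length(starts)),
                qvalue = rep_len(q, length(starts)))
  if (!is.null(lens)) {
    seqlevels(gr) <- names(lens)
    seqlengths(gr) <- lens
  }
  gr
}
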