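#' Construct a RecombinationMap from per-chromosome rate vectors
#'
#' @param rates a named list of numeric per-bin rate vectors (one element per
#'   chromosome, in bin order), or a single numeric vector together with
#'   \code{chromName}.
#' @param binSize bin width in bp (default 1000).
#' @param chromLengths optional named vector of chromosome lengths in bp;
#'   defaults to \code{nbins * binSize} per chromosome.
#' @param units \code{"cM_per_Mb"} or \code{"rho"}.
#' @param chromName chromosome name used when \code{rates} is a bare vector.
#' @return a [RecombinationMap-class] object.
#' @examples
#' RecombinationMap(list(chr1 = c(1, 2, 3, 2)), binSize = 1000)
#' @export
RecombinationMap <- function(rates, binSize = 1000L, chromLengths = NULL,
                             units = c("cM_per_Mb", "rho"),
                             chromName = "chr1") {
  units <- match.arg(units)
  if (!is.list(rates)) rates <- setNames(list(rates), chromName)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("rates must be a named list (one element per chromosome)")
  binSize <- as.integer(binSize)
  if (is.na(binSize) || binSize < 1L) stop("binSize must be a positive integer")
  if (is.null(chromLengths))
    chromLengths <- setNames(lengths(rates) * binSize, names(rates))
  chromLengths <- chromLengths[names(rates)]
  gr <- .tileBins(chromLengths, binSize)
  rate <- unlist(rates, use.names = FALSE)
  if (length(gr) != length(rate))
    stop("rate vectors do not match ceiling(chromLengths/binSize) bins")
  mcols(gr)$rate <- as.numeric(rate)
  new("RecombinationMap", bins = gr, binSize = binSize, rateUnits = units)
}

# ---- accessors ---------------------------------------------------------

#' Accessors for recmotifs S4 classes
#'
#' Small accessor generics: \code{binSize}, \code{rateUnits},
#' \code{rateValues}, \code{densityValues}, \code{trackBins},
#' \code{chromNames}, \code{chromLengths}, \code{motifName},
#' \code{motifProbs}, \code{motifLength}, \code{matrixDialect},
#' \code{scoreValues}.
#'
#' @param x a recmotifs object.
#' @param chrom optional chromosome name; when given, \code{rateValues} /
#'   \code{densityValues} return that chromosome's numeric vector, otherwise
#'   a named list over all chromosomes.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("binSize", "RecombinationMap", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("rateUnits", "RecombinationMap", function(x) x@rateUnits)

#' @rdname accessors
#' @export
setMethod("trackBins", "RecombinationMap", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("chromNames", "RecombinationMap", function(x) seqlevels(x@bins))

#' @rdname accessors
#' @export
setMethod("chromLengths", "RecombinationMap", function(x) seqlengths(x@bins))

#' @rdname accessors
#' @export
setMethod("rateValues", "RecombinationMap", function(x, chrom = NULL) {
  r <- mcols(x@bins)$rate
  ch <- as.character(seqnames(x@bins))
  if (!is.null(chrom)) {
    if (!chrom %in% seqlevels(x@bins)) stop("unknown chromosome: ", chrom)
    return(r[ch == chrom])
  }
  split(r, factor(ch, levels = seqlevels(x@bins)))
})

setMethod("show", "RecombinationMap", function(object) {
  cat(sprintf("RecombinationMap: %d chromosome(s), %d bins of %d bp [%s]\n",
              length(seqlevels(object@bins)), length(object@bins),
              object@binSize, object@rateUnits))
  r <- mcols(object@bins)$rate
  cat(sprintf("  rate: median %.4g (range %.4g..%.4g), %d missing bin(s)\n",
              stats::median(r, na.rm = TRUE), suppressWarnings(min(r, na.rm = TRUE)),
              suppressWarnings(max(r, na.rm = TRUE)), sum(is.na(r))))
})

# replace rates, keeping geometry (internal)
.withRates <- function(map, newRates) {
  mcols(map@bins)$rate <- newRates
  validObject(map)
  map
}

# ---- I/O ---------------------------------------------------------------

#' Read a binned recombination map from CSV
#'
#' Expects a CSV with header \code{chrom,start,end,rate} and 0-based
#' half-open fixed-width bins (the last bin of a chromosome may be shorter).
#' Rows may be in any order; gaps in the tiling are filled with missing
#' (\code{NA}) rates. Non-uniform bin widths, overlapping bins and negative
#' rates are format errors.
#'
#' @param path CSV file path.
#' @param units unit flag to attach, \code{"cM_per_Mb"} (default) or
#'   \code{"rho"}.
#' @return a [RecombinationMap-class].
#' @seealso [writeRecombinationMap()]
#' @export
readRecombinationMap <- function(path, units = c("cM_per_Mb", "rho")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(df)))
    stop("map CSV must have header chrom,start,end,rate")
  if (any(df$end <= df$start)) stop("malformed bin with end <= start")
  if (any(df$rate < 0, na.rm = TRUE)) stop("negative rate in map CSV")
  w <- df$end - df$start
  binSize <- max(w)
  rates <- list(); lens <- numeric(0)
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (anyDuplicated(d$start) || any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bins on ", chr)
    chromLen <- max(d$end)
    full <- d$end < chromLen          # all but the (possibly partial) last bin
    if (any((d$end - d$start)[full] != binSize))
      stop("non-uniform bin width on ", chr,
           " (every bin but the last must span binSize)")
    if (any(d$start %% binSize != 0))
      stop("bins on ", chr, " are not aligned to the bin grid")
    nb <- ceiling(chromLen / binSize)
    r <- rep(NA_real_, nb)
    r[d$start %/% binSize + 1L] <- d$rate
    rates[[chr]] <- r
    lens[chr] <- chromLen
  }
  RecombinationMap(rates, binSize = binSize, chromLengths = lens,
                   units = units)
}

#' Write a RecombinationMap as CSV
#'
#' Writes 0-based half-open bins with header \code{chrom,start,end,rate};
#' rates are printed with full double precision so that read/write
#' round-trips are lossless. Missing bins are omitted.
#'
#' @param map a [RecombinationMap-class].
#' @param path output file.
#' @param windowKb optional smoothing window provenance, recorded as a
#'   \code{# window_kb:} comment line.
#' @return \code{path}, invisibly.
#' @export
writeRecombinationMap <- function(map, path, windowKb = NULL) {
  b <- map@bins
  r <- mcols(b)$rate
  keep <- !is.na(r)
  lines <- c(
    if (!is.null(windowKb)) sprintf("# window_kb: %s", windowKb),
    sprintf("# units: %s", map@rateUnits),
    "chrom,start,end,rate",
    sprintf("%s,%d,%d,%s", as.character(seqnames(b))[keep],
            start(b)[keep] - 1L, end(b)[keep],
            sprintf("%.17g", r[keep])))
  writeLines(lines, path)
  invisible(path)
}

#' Read genetic anchors (marker intervals with known cM lengths)
#'
#' CSV with header \code{chrom,start,end,cM}, 0-based half-open intervals.
#' Intervals must be non-overlapping per chromosome and cM values
#' non-negative.
#'
#' @param path CSV file path.
#' @return a data frame with columns chrom, start, end, cM.
#' @export
readAnchors <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "cM") %in% names(df)))
    stop("anchor CSV must have header chrom,start,end,cM")
  .checkAnchors(df)
  df
}

.checkAnchors <- function(anchors) {
  if (any(anchors$cM < 0)) stop("anchor cM lengths must be >= 0")
  if (any(anchors$end <= anchors$start)) stop("malformed anchor interval")
  for (chr in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == chr, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1] < a$end[-nrow(a)]))
      stop("overlapping anchors on ", chr)
  }
  invisible(anchors)
}

# ---- normalization -----------------------------------------------------

#' Normalize a rho map to cM/Mb against genetic anchors
#'
#' Rescales a population-scaled (\eqn{\rho}) map by the single constant
#' \eqn{c = \sum \textrm{anchor cM} / \sum \textrm{map genetic length over
#' the anchor intervals}}, so that the total genetic length across all
#' anchor intervals equals the anchored total. Relative bin-to-bin ratios
#' are untouched; the output map is flagged \code{"cM_per_Mb"}. Bins
#' partially covered by an anchor contribute proportionally to their
#' overlap.
#'
#' @param map a [RecombinationMap-class] in \code{"rho"} units.
#' @param anchors a data frame with columns chrom, start, end (0-based
#'   half-open, bp) and cM, as from [readAnchors()].
#' @return a [RecombinationMap-class] in cM/Mb.
#' @export
normalizeToCM <- function(map, anchors) {
  if (rateUnits(map) != "rho")
    stop("normalizeToCM expects a map in rho units")
  .checkAnchors(anchors)
  agr <- GRanges(anchors$chrom, IRanges(anchors$start + 1L, anchors$end))
  b <- map@bins
  hits <- findOverlaps(b, agr)
  if (length(hits) == 0L) stop("anchors do not overlap the map")
  ov <- width(pintersect(b[queryHits(hits)], agr[subjectHits(hits)]))
  r <- mcols(b)$rate[queryHits(hits)]
  geneticLen <- sum(r * ov / 1e6, na.rm = TRUE)  # rate interpreted per Mb
  if (!is.finite(geneticLen) || geneticLen <= 0)
    stop("zero rho mass over the anchor intervals; cannot normalize")
  cc <- sum(anchors$cM) / geneticLen
  out <- .withRates(map, mcols(b)$rate * cc)
  out@rateUnits <- "cM_per_Mb"
  out
}

# ---- smoothing ---------------------------------------------------------

#' Moving-median smoothing of a recombination map
#'
#' Order-statistic smoother: each interior bin receives the median of the
#' \code{w} surrounding raw values, where \code{w = windowKb / binKb} must be
#' an odd integer. Because the window size is odd, every full-window output
#' value is a member of its raw window multiset, i.e. only values present in
#' the raw map can appear in the smoothed map. At chromosome ends the window
#' is truncated (output length equals input length) and the lower of the two
#' central order statistics is taken for even-sized windows, preserving the
#' membership property there too. Missing values are excluded from each
#' window's multiset; a bin is missing in the output only if its whole
#' window is missing. \code{w = 1} is the identity.
#'
#' @param map a [RecombinationMap-class].
#' @param windowKb window size in kb; \code{windowKb * 1000 / binSize} must
#'   be an odd integer, at least 1 and at most the smallest chromosome's bin
#'   count.
#' @return a smoothed [RecombinationMap-class] with identical geometry.
#' @examples
#' m <- RecombinationMap(list(chr1 = c(1, 5, 2, 8, 3)), binSize = 1000)
#' rateValues(movingMedian(m, 3), "chr1")  # interior: 2, 5, 3
#' @export
movingMedian <- function(map, windowKb) {
  binKb <- binSize(map) / 1000
  w <- windowKb / binKb
  if (abs(w - round(w)) > 1e-9)
    stop("windowKb must be a multiple of the bin size")
  w <- as.integer(round(w))
  if (w < 1L || w %% 2L == 0L)
    stop("window must be an odd number of bins (got ", w, ")")
  rl <- rateValues(map)
  if (any(lengths(rl) < w))
    stop("window exceeds chromosome bin count")
  sm <- lapply(rl, .movingMedianVec, w = w)
  .withRates(map, unlist(sm, use.names = FALSE))
}

.movingMedianVec <- function(x, w) {
  n <- length(x)
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  if (!anyNA(x)) {
    out <- stats::runmed(x, w, endrule = "keep")
    edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
    for (i in edge)
      out[i] <- .lowerMedian(x[max(1L, i - h):min(n, i + h)])
    out
  } else {
    vapply(seq_len(n),
           function(i) .lowerMedian(x[max(1L, i - h):min(n, i + h)]),
           numeric(1))
  }
}

#' Local-regression (tricube) smoothing of a recombination map
#'
#' Classic local linear regression: at each bin, the \code{q =
#' ceiling(span * n)} nearest non-missing bins (by bin index) are fitted by
#' weighted least squares with tricube weights
#' \eqn{(1 - (d/h)^3)^3}, \eqn{h} the distance to the q-th nearest
#' neighbour, and the fit is evaluated at the bin. Negative fitted values
#' are clipped to 0. An exactly linear input is reproduced exactly.
#'
#' @param map a [RecombinationMap-class].
#' @param span neighbourhood fraction, in (0, 1].
#' @return a smoothed [RecombinationMap-class].
#' @export
loessSmooth <- function(map, span) {
  if (length(span) != 1L || !is.finite(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  rl <- rateValues(map)
  sm <- lapply(rl, .loessVec, span = span)
  .withRates(map, unlist(sm, use.names = FALSE))
}

.loessVec <- function(y, span) {
  n <- length(y)
  obs <- which(!is.na(y))
  m <- length(obs)
  if (m < 10L) stop("need at least 10 non-missing bins for loessSmooth")
  xo <- as.numeric(obs)
  if (length(unique(xo)) < 2L) stop("degenerate design: all one x")
  yo <- y[obs]
  q <- max(2L, as.integer(ceiling(span * m)))
  q <- min(q, m)
  fit <- vapply(seq_len(n), function(x0) {
    d <- abs(xo - x0)
    o <- order(d)[seq_len(q)]
    h <- d[o[q]]
    if (h <= 0) return(mean(yo[o]))
    wts <- (1 - pmin(1, d[o] / h)^3)^3
    sw <- sum(wts)
    if (sw <= 0) return(yo[which.min(d)])
    xs <- xo[o]; ys <- yo[o]
    xm <- sum(wts * xs) / sw
    ym <- sum(wts * ys) / sw
    sxx <- sum(wts * (xs - xm)^2)
    b1 <- if (sxx > 0) sum(wts * (xs - xm) * (ys - ym)) / sxx else 0
    ym + b1 * (x0 - xm)
  }, numeric(1))
  pmax(fit, 0)
}

# ---- segmentation ------------------------------------------------------

#' Split each chromosome into high- and low-recombining bins
#'
#' Per chromosome, the median m of the non-missing bin rates is taken; bins
#' with rate strictly greater than m are labelled \code{high}, bins with
#' rate \code{<= m} are \code{low}, and missing bins are \code{excluded}.
#' High and low together partition the non-missing bins exactly. If all
#' rates on a chromosome are equal, \code{high} is empty (downstream
#' discovery refuses such a degenerate split).
#'
#' @param map a [RecombinationMap-class] with at least 2 non-missing bins
#'   per chromosome.
#' @return a \link[GenomicRanges]{GRanges} of the map's bins with metadata
#'   columns \code{label} (factor high/low/excluded) and \code{rate}.
#' @examples
#' m <- RecombinationMap(list(chr1 = c(1, 2, 2, 3)), binSize = 1000)
#' splitHighLow(m)$label   # low low low high
#' @export
splitHighLow <- function(map) {
  rl <- rateValues(map)
  labs <- lapply(names(rl), function(chr) {
    r <- rl[[chr]]
    nm <- sum(!is.na(r))
    if (nm == 0L) stop("all bins missing on ", chr, "; cannot label")
    if (nm < 2L) stop("need >= 2 non-missing bins on ", chr)
    m <- stats::median(r, na.rm = TRUE)
    ifelse(is.na(r), "excluded", ifelse(r > m, "high", "low"))
  })
  gr <- map@bins
  mcols(gr)$label <- factor(unlist(labs, use.names = FALSE),
                            levels = c("high", "low", "excluded"))
  gr
}

#' Write region labels as BED
#'
#' 6-column BED (0-based half-open) with the label (high/low/excluded) in the
#' name field.
#'
#' @param labels a labelled GRanges from [splitHighLow()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegionLabels <- function(labels, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                   as.character(seqnames(labels)), start(labels) - 1L,
                   end(labels), as.character(labels$label))
  writeLines(lines, path)
  invisible(path)
}
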