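#' Build a q-discounted motif density track
#'
#' Assigns every occurrence to exactly one bin by its start coordinate and
#' sums \eqn{1 - q} over the occurrences of each bin; bins with no
#' occurrences hold 0. Because each occurrence lands in exactly one bin,
#' the sum over all bins equals the genome-wide discounted count
#' ([totalCount()]) of the occurrence set (conservation).
#'
#' @param occurrences a GRanges with a \code{qvalue} column (see
#'   [computeQvalues()]).
#' @param binSize bin width in bp (default 1000, i.e. 1-kb windows).
#' @param chromLengths named chromosome lengths in bp; defaults to
#'   \code{seqlengths(occurrences)}.
#' @param motifName track label; defaults to the occurrences' motif.
#' @return a [DensityTrack-class].
#' @seealso [rebinTrack()], [totalCount()]
#' @export
densityTrack <- function(occurrences, binSize = 1000L, chromLengths = NULL,
                         motifName = NULL) {
  if (binSize < 1L) stop("binSize must be positive")
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(occurrences)
    if (any(is.na(chromLengths)))
      stop("chromLengths missing and seqlengths(occurrences) incomplete")
  }
  if (is.null(motifName))
    motifName <- metadata(occurrences)$motif %||%
      (if (length(occurrences)) occurrences$motif[1] else "motif")
  if (length(occurrences) &&
      is.null(occurrences$qvalue))
    stop("occurrences must carry q-scores; run computeQvalues() first")
  gr <- .tileBins(chromLengths, binSize)
  dens <- numeric(length(gr))
  if (length(occurrences)) {
    ch <- as.character(seqnames(occurrences))
    if (!all(ch %in% names(chromLengths)))
      stop("occurrence on a chromosome absent from chromLengths")
    if (any(start(occurrences) < 1L) ||
        any(end(occurrences) > chromLengths[ch]))
      stop("occurrence outside chromosome bounds")
    offset <- setNames(c(0L, cumsum(ceiling(
      as.numeric(chromLengths) / binSize)))[seq_along(chromLengths)],
      names(chromLengths))
    idx <- offset[ch] + (start(occurrences) - 1L) %/% binSize + 1L
    contrib <- 1 - occurrences$qvalue
    agg <- rowsum(contrib, idx)
    dens[as.integer(rownames(agg))] <- agg[, 1L]
  }
  mcols(gr)$density <- dens
  new("DensityTrack", bins = gr, binSize = as.integer(binSize),
      motifName = motifName)
}

#' Genome-wide discounted motif count
#'
#' The total \eqn{\sum (1 - q)} over all occurrences of a motif, all
#' chromosomes: a quality-weighted genome-wide occurrence count. Equals the
#' sum over any density track built from the same occurrence set.
#'
#' @param occurrences a GRanges with a \code{qvalue} column, or a
#'   [DensityTrack-class] (summed over bins).
#' @return a single number.
#' @export
totalCount <- function(occurrences) {
  if (is(occurrences, "DensityTrack"))
    return(sum(mcols(occurrences@bins)$density))
  if (length(occurrences) == 0L) return(0)
  if (is.null(occurrences$qvalue))
    stop("occurrences must carry q-scores; run computeQvalues() first")
  sum(1 - occurrences$qvalue)
}

#' @rdname accessors
#' @export
setMethod("binSize", "DensityTrack", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("motifName", "DensityTrack", function(x) x@motifName)

#' @rdname accessors
#' @export
setMethod("trackBins", "DensityTrack", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("chromNames", "DensityTrack", function(x) seqlevels(x@bins))

#' @rdname accessors
#' @export
setMethod("chromLengths", "DensityTrack", function(x) seqlengths(x@bins))

#' @rdname accessors
#' @export
setMethod("densityValues", "DensityTrack", function(x, chrom = NULL) {
  d <- mcols(x@bins)$density
  ch <- as.character(seqnames(x@bins))
  if (!is.null(chrom)) {
    if (!chrom %in% seqlevels(x@bins)) stop("unknown chromosome: ", chrom)
    return(d[ch == chrom])
  }
  split(d, factor(ch, levels = seqlevels(x@bins)))
})

setMethod("show", "DensityTrack", function(object) {
  cat(sprintf("DensityTrack '%s': %d bins of %d bp, total %.4f\n",
              object@motifName, length(object@bins), object@binSize,
              sum(mcols(object@bins)$density)))
})

#' Coarsen a density track by an integer factor
#'
#' Sums consecutive groups of \code{factor} fine bins into one coarse bin;
#' a trailing partial group is kept as its own (shorter) bin, so totals are
#' conserved exactly. \code{factor = 1} is the identity.
#'
#' @param track a [DensityTrack-class].
#' @param factor positive integer rebinning factor.
#' @return a [DensityTrack-class] at \code{binSize * factor}.
#' @examples
#' # a track [1,2,3,4,5] rebinned by 2 becomes [3,7,5]
#' @export
rebinTrack <- function(track, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(track)
  lens <- chromLengths(track)
  vals <- densityValues(track)
  newSize <- track@binSize * factor
  gr <- .tileBins(lens, newSize)
  dens <- unlist(lapply(vals, function(v) {
    g <- (seq_along(v) - 1L) %/% factor
    as.numeric(rowsum(v, g))
  }), use.names = FALSE)
  stopifnot(length(dens) == length(gr))
  mcols(gr)$density <- dens
  new("DensityTrack", bins = gr, binSize = newSize,
      motifName = track@motifName)
}

#' Sliding-window q-discounted density
#'
#' Overlapping-window variant of [densityTrack()]: windows of \code{window}
#' bp advance by \code{stride} bp and each window sums \eqn{1 - q} over the
#' occurrences starting inside it. With \code{stride = window} this
#' reproduces the tiled track (the default analysis path); with
#' \code{stride < window} an occurrence contributes to several windows, so
#' window sums are not conserved against [totalCount()].
#'
#' @param occurrences a GRanges with a \code{qvalue} column.
#' @param window window width in bp (default 1000).
#' @param stride window step in bp (default \code{window}).
#' @param chromLengths named chromosome lengths; defaults to
#'   \code{seqlengths(occurrences)}.
#' @return a \link[GenomicRanges]{GRanges} of windows with a
#'   \code{density} metadata column.
#' @export
slidingDensity <- function(occurrences, window = 1000L, stride = window,
                           chromLengths = NULL) {
  if (window < 1L || stride < 1L) stop("window and stride must be positive")
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(occurrences)
    if (any(is.na(chromLengths)))
      stop("chromLengths missing and seqlengths(occurrences) incomplete")
  }
  if (length(occurrences) && is.null(occurrences$qvalue))
    stop("occurrences must carry q-scores; run computeQvalues() first")
  res <- lapply(names(chromLengths), function(chr) {
    len <- as.integer(chromLengths[[chr]])
    st <- seq.int(1L, max(1L, len), by = stride)
    st <- st[st <= len]
    gr <- GRanges(chr, IRanges(st, pmin(st + window - 1L, len)))
    occ <- occurrences[seqnames(occurrences) == chr]
    dens <- numeric(length(gr))
    if (length(occ)) {
      anchors <- GRanges(chr, IRanges(start(occ), width = 1L))
      hits <- findOverlaps(anchors, gr)
      agg <- rowsum((1 - occ$qvalue)[queryHits(hits)], subjectHits(hits))
      dens[as.integer(rownames(agg))] <- agg[, 1L]
    }
    mcols(gr)$density <- dens
    gr
  })
  out <- suppressWarnings(do.call(c, res))
  seqlevels(out) <- names(chromLengths)
  seqlengths(out) <- as.integer(chromLengths)
  out
}

#' Read a density track from a CSV written by [writeDensityTrack()]
#'
#' @param path CSV with header \code{chrom,start,end,density} over 0-based
#'   half-open fixed-width bins.
#' @param motifName track label (default: the file name stem).
#' @return a [DensityTrack-class].
#' @export
readDensityTrack <- function(path, motifName = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "density") %in% names(df)))
    stop("density CSV must have header chrom,start,end,density")
  binSize <- max(df$end - df$start)
  lens <- tapply(df$end, df$chrom, max)
  gr <- .tileBins(setNames(as.integer(lens), names(lens)), binSize)
  dens <- numeric(length(gr))
  key <- paste(as.character(seqnames(gr)), start(gr) - 1L)
  dens[match(paste(df$chrom, df$start), key)] <- df$density
  mcols(gr)$density <- dens
  new("DensityTrack", bins = gr, binSize = as.integer(binSize),
      motifName = motifName %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a density track as CSV or bedGraph
#'
#' CSV uses header \code{chrom,start,end,density} with 0-based half-open
#' bins; bedGraph writes the same columns tab-separated with a track line.
#'
#' @param track a [DensityTrack-class].
#' @param path output file.
#' @param format \code{"csv"} (default) or \code{"bedgraph"}.
#' @return \code{path}, invisibly.
#' @export
writeDensityTrack <- function(track, path, format = c("csv", "bedgraph")) {
  format <- match.arg(format)
  b <- track@bins
  if (format == "csv") {
    lines <- c("chrom,start,end,density",
               sprintf("%s,%d,%d,%.17g", as.character(seqnames(b)),
                       start(b) - 1L, end(b), mcols(b)$density))
  } else {
    lines <- c(sprintf("track type=bedGraph name=%s", track@motifName),
               sprintf("%s\t%d\t%d\t%.17g", as.character(seqnames(b)),
                       start(b) - 1L, end(b), mcols(b)$density))
  }
  writeLines(lines, path)
  invisible(path)
}
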