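#' Exact p-value table for a score matrix
#'
#' Builds the exact null distribution of window scores under the 0-order
#' background by dynamic programming. Per-column scores are discretized to
#' integer multiples of \code{granularity} (bits) and the per-column score
#' distributions are convolved position by position, giving the exact
#' probability mass function of the total score of a random background word
#' at that discretization. The stored table maps every achievable
#' discretized score s to its tail probability \eqn{P(S \ge s)}.
#'
#' @param sm a [ScoreMatrix-class].
#' @param granularity discretization step in bits (default 1e-3).
#' @return a [PvalueTable-class].
#' @examples
#' bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
#' tbl <- scorePvalueTable(logOdds(consensusToMatrix("A"), bg))
#' lookupPvalue(tbl, maxAttainableScore(tbl))  # 0.25
#' @export
scorePvalueTable <- function(sm, granularity = 1e-3) {
  stopifnot(is(sm, "ScoreMatrix"))
  if (granularity <= 0) stop("granularity must be > 0")
  s <- scoreValues(sm)
  ints <- round(s / granularity)
  span <- sum(apply(ints, 2L, max) - apply(ints, 2L, min))
  if (span > 5e7)
    stop("score range / granularity too large; increase granularity")
  storage.mode(ints) <- "integer"
  bg <- sm@background
  pmf <- 1
  off <- 0L
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    smin <- min(col)
    newlen <- length(pmf) + max(col) - smin
    acc <- numeric(newlen)
    for (b in 1:4) {
      sh <- col[b] - smin
      idx <- (1L + sh):(length(pmf) + sh)
      acc[idx] <- acc[idx] + pmf * bg[b]
    }
    pmf <- acc
    off <- off + smin
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  new("PvalueTable", name = motifName(sm), granularity = granularity,
      minScore = as.integer(off), pvalues = tail, intScores = ints)
}

#' @describeIn scorePvalueTable largest attainable score of a table, in bits.
#' @param tbl a [PvalueTable-class].
#' @export
maxAttainableScore <- function(tbl) {
  (tbl@minScore + length(tbl@pvalues) - 1L) * tbl@granularity
}

#' Look up tail p-values for scores
#'
#' Maps scores (bits) to \eqn{P(S \ge s)} under the table's exact null,
#' after discretizing the query to the table's granularity. Scores below
#' the attainable minimum return 1; scores above the attainable maximum
#' return 0 (they cannot arise from a scan that shares the table's
#' discretized score matrix).
#'
#' @param tbl a [PvalueTable-class].
#' @param score numeric vector of scores in bits.
#' @return numeric vector of tail probabilities.
#' @export
lookupPvalue <- function(tbl, score) {
  k <- round(score / tbl@granularity)
  .lookupPvalueInt(tbl, k)
}

.lookupPvalueInt <- function(tbl, k) {
  idx <- k - tbl@minScore + 1
  p <- rep(NA_real_, length(k))
  ok <- !is.na(idx)
  below <- ok & idx < 1
  above <- ok & idx > length(tbl@pvalues)
  inside <- ok & !below & !above
  p[below] <- 1
  p[above] <- 0
  p[inside] <- tbl@pvalues[idx[inside]]
  p
}

setMethod("show", "PvalueTable", function(object) {
  cat(sprintf(
    "PvalueTable '%s': %d achievable scores at %.4g-bit granularity\n",
    object@name, length(object@pvalues), object@granularity))
  cat(sprintf("  max score %.4f bits, p at max = %.4g\n",
              maxAttainableScore(object),
              object@pvalues[length(object@pvalues)]))
})

# score all windows of a coded chromosome with a discretized score matrix;
# windows containing non-ACGT letters propagate NA and are skipped
.windowIntScores <- function(codes, ints) {
  n <- length(codes)
  L <- ncol(ints)
  if (n < L) return(numeric(0))
  m <- n - L + 1L
  tot <- as.numeric(ints[, 1L][codes[seq_len(m)]])
  if (L > 1L) for (j in 2:L)
    tot <- tot + ints[, j][codes[j:(m + j - 1L)]]
  tot
}

# one chromosome x one strand: find windows whose discretized score reaches
# kstar (the smallest integer score passing the p threshold). The heavy
# window scoring is delegated to Biostrings::matchPWM with the discretized
# matrix and a margin below kstar, then every candidate window is rescored
# exactly against the integer score matrix, so the hit set is identical to
# scoring every window directly. Windows containing non-ACGT letters are
# dropped. Returns starts and exact integer scores.
.strandHits <- function(chromSeq, codes, tbl, kstar) {
  ints <- tbl@intScores
  g <- tbl@granularity
  L <- ncol(ints)
  m <- length(codes) - L + 1L
  if (m < 1L || is.na(kstar)) return(list(start = integer(0), k = numeric(0)))
  pwm <- ints * g
  hits <- suppressWarnings(
    Biostrings::matchPWM(pwm, chromSeq, min.score = (kstar - 0.25) * g))
  st <- BiocGenerics::start(hits)
  if (length(st) == 0L) return(list(start = integer(0), k = numeric(0)))
  k <- as.numeric(ints[, 1L][codes[st]])
  if (L > 1L) for (j in 2:L) k <- k + ints[, j][codes[st + j - 1L]]
  keep <- !is.na(k) & k >= kstar
  list(start = st[keep], k = k[keep])
}

# number of scoreable (N-free) windows of width L per strand
.countScannable <- function(codes, L) {
  m <- length(codes) - L + 1L
  if (m < 1L) return(0L)
  bad <- which(is.na(codes))
  if (length(bad) == 0L) return(m)
  cov <- IRanges::reduce(IRanges(pmax(1L, bad - L + 1L), pmin(m, bad)))
  m - sum(width(cov))
}

#' Scan a genome for motif occurrences
#'
#' Scores every position of every chromosome on both strands with the
#' pseudocount-regularized log-odds of the motif (the reverse strand is
#' scored with the reverse-complemented matrix at the same coordinates) and
#' reports all windows whose exact-null p-value is at or below
#' \code{pThreshold}. Overlapping matches are all reported; windows
#' containing N are skipped. Occurrences come back sorted by (chromosome,
#' start, strand) with metadata columns \code{motif}, \code{score} (bits,
#' at table granularity) and \code{pvalue}; the total number of scanned
#' (scoreable) positions over both strands is recorded in
#' \code{metadata(x)$nScannedPositions} for the multiple-testing step.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} (or character vector /
#'   FASTA path).
#' @param motif a [MotifMatrix-class], or a consensus string (hard dialect).
#' @param background named A/C/G/T frequencies; estimated from the genome
#'   when omitted.
#' @param pThreshold report occurrences with p-value at or below this
#'   (default 1e-4).
#' @param pseudocount log-odds regularization (default 0.1).
#' @param granularity score discretization in bits (default 1e-3).
#' @param maxStoredScores cap on the number of reported occurrences; when
#'   exceeded, only the highest-scoring occurrences are kept (default 5e7).
#' @return a \link[GenomicRanges]{GRanges} of occurrences.
#' @seealso [computeQvalues()], [densityTrack()]
#' @export
scanGenome <- function(genome, motif, background = NULL, pThreshold = 1e-4,
                       pseudocount = 0.1, granularity = 1e-3,
                       maxStoredScores = 5e7) {
  genome <- .asDNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  if (is.character(motif)) motif <- consensusToMatrix(motif)
  stopifnot(is(motif, "MotifMatrix"))
  if (pThreshold <= 0 || pThreshold > 1) stop("pThreshold must be in (0, 1]")
  if (is.null(background)) background <- estimateBackground(genome)
  bg <- .checkBackground(background)
  if (motifLength(motif) > min(width(genome)))
    stop("motif longer than the shortest chromosome")

  fwd <- logOdds(motif, bg, pseudocount)
  rcm <- new("MotifMatrix", name = motifName(motif),
             probs = .revCompProbs(motifProbs(motif)),
             dialect = matrixDialect(motif))
  rev <- logOdds(rcm, bg, pseudocount)
  tblF <- scorePvalueTable(fwd, granularity)
  tblR <- scorePvalueTable(rev, granularity)

  # smallest discretized score whose exact-null tail reaches the threshold
  .kstar <- function(tbl) {
    idx <- which(tbl@pvalues <= pThreshold)
    if (length(idx) == 0L) return(NA_integer_)
    tbl@minScore + idx[1L] - 1L
  }
  kF <- .kstar(tblF)
  kR <- .kstar(tblR)

  hitsList <- list()
  nScanned <- 0L
  L <- motifLength(motif)
  for (chr in names(genome)) {
    codes <- .dnaCodes(genome[[chr]])
    nScanned <- nScanned + 2L * .countScannable(codes, L)
    for (str in c("+", "-")) {
      tbl <- if (str == "+") tblF else tblR
      h <- .strandHits(genome[[chr]], codes, tbl,
                       if (str == "+") kF else kR)
      if (length(h$start)) {
        hitsList[[length(hitsList) + 1L]] <- GRanges(
          chr, IRanges(h$start, width = L), strand = str,
          motif = motifName(motif), score = h$k * granularity,
          pvalue = .lookupPvalueInt(tbl, h$k))
      }
    }
  }
  occ <- if (length(hitsList)) suppressWarnings(do.call(c, hitsList))
         else {
           e <- GRanges()
           mcols(e) <- DataFrame(motif = character(0), score = numeric(0),
                                 pvalue = numeric(0))
           e
         }
  seqlevels(occ) <- names(genome)
  seqlengths(occ) <- width(genome)
  occ <- sort(occ)
  if (length(occ) > maxStoredScores)
    occ <- sort(occ[order(occ$score, decreasing = TRUE)[seq_len(maxStoredScores)]])
  metadata(occ)$nScannedPositions <- nScanned
  metadata(occ)$pThreshold <- pThreshold
  metadata(occ)$motif <- motifName(motif)
  occ
}

#' Benjamini-Hochberg q-scores for motif occurrences
#'
#' Step-up false-discovery-rate correction over the occurrence p-values with
#' denominator \code{nTests}, the total number of scanned positions over
#' both strands (not merely the number of reported occurrences):
#' \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} \cdot nTests / j)}, capped at 1.
#' q is monotone non-decreasing in p within an occurrence set.
#'
#' @param occurrences a GRanges from [scanGenome()] with a \code{pvalue}
#'   column.
#' @param nTests number of tests; defaults to
#'   \code{metadata(occurrences)$nScannedPositions}.
#' @return the occurrences with an added \code{qvalue} metadata column.
#' @export
computeQvalues <- function(occurrences,
                           nTests = metadata(occurrences)$nScannedPositions) {
  if (is.null(nTests))
    stop("nTests missing and not recorded in metadata(occurrences)")
  n <- length(occurrences)
  if (nTests < n) stop("nTests must be >= the number of occurrences")
  q <- numeric(n)
  if (n > 0L) {
    p <- occurrences$pvalue
    o <- order(p)
    qs <- p[o] * nTests / seq_len(n)
    qs <- rev(cummin(rev(qs)))
    q[o] <- pmin(qs, 1)
  }
  occurrences$qvalue <- q
  occurrences
}

#' Read motif occurrences from a TSV written by [writeOccurrences()]
#'
#' @param path TSV file with columns chrom, source, motif, start, end,
#'   score, strand, pvalue, qvalue.
#' @param nTests optional scanned-position count to restore into
#'   \code{metadata()} (needed to recompute q-scores).
#' @return a \link[GenomicRanges]{GRanges} of occurrences.
#' @export
readOccurrences <- function(path, nTests = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                motif = df$motif, score = df$score, pvalue = df$pvalue,
                qvalue = df$qvalue)
  if (!is.null(nTests)) metadata(gr)$nScannedPositions <- nTests
  if (nrow(df)) metadata(gr)$motif <- df$motif[1]
  sort(gr)
}

#' Write motif occurrences to disk
#'
#' \code{"tsv"} writes a GFF-like table (chrom, source, motif, 1-based
#' inclusive start/end, score, strand, p, q); \code{"bed"} writes BED6+2
#' (0-based half-open, p and q as extra columns).
#'
#' @param occurrences a GRanges with \code{motif}, \code{score},
#'   \code{pvalue} and optionally \code{qvalue} columns.
#' @param path output file.
#' @param format \code{"tsv"} (default) or \code{"bed"}.
#' @return \code{path}, invisibly.
#' @export
writeOccurrences <- function(occurrences, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  q <- occurrences$qvalue %||% rep(NA_real_, length(occurrences))
  if (format == "tsv") {
    lines <- c(paste("chrom", "source", "motif", "start", "end", "score",
                     "strand", "pvalue", "qvalue", sep = "\t"),
               sprintf("%s\trecmotifs\t%s\t%d\t%d\t%.6g\t%s\t%.6g\t%.6g",
                       as.character(seqnames(occurrences)),
                       occurrences$motif, start(occurrences),
                       end(occurrences), occurrences$score,
                       as.character(strand(occurrences)),
                       occurrences$pvalue, q))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%s\t%.6g\t%.6g",
                     as.character(seqnames(occurrences)),
                     start(occurrences) - 1L, end(occurrences),
                     occurrences$motif, occurrences$score,
                     as.character(strand(occurrences)),
                     occurrences$pvalue, q)
  }
  writeLines(lines, path)
  invisible(path)
}
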