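#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import Biostrings
NULL

#' RecombinationMap: a binned per-chromosome recombination-rate track
#'
#' The central track type of the package: every chromosome is tiled with
#' fixed-width genomic bins (the last bin of a chromosome may be shorter) and
#' each bin carries one recombination-rate value, either a population-scaled
#' rate (\code{"rho"}) or a genetic rate in centimorgan per megabase
#' (\code{"cM_per_Mb"}). Missing bins are carried as \code{NA} rates so that a
#' map always covers its chromosomes completely.
#'
#' @slot bins a \link[GenomicRanges]{GRanges} of bins, sorted, with a numeric
#'   metadata column \code{rate} (values \eqn{\ge 0} or \code{NA}).
#' @slot binSize integer, the bin width in bp.
#' @slot rateUnits \code{"rho"} or \code{"cM_per_Mb"}.
#'
#' @seealso [RecombinationMap()], [readRecombinationMap()], [movingMedian()],
#'   [splitHighLow()]
#' @export
setClass("RecombinationMap",
         slots = c(bins = "GRanges", binSize = "integer",
                   rateUnits = "character"))

setValidity("RecombinationMap", function(object) {
  msg <- character(0)
  b <- object@bins
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (!identical(length(object@rateUnits), 1L) ||
      !object@rateUnits %in% c("rho", "cM_per_Mb"))
    msg <- c(msg, "rateUnits must be exactly one of 'rho', 'cM_per_Mb'")
  if (!"rate" %in% names(mcols(b)))
    msg <- c(msg, "bins must carry a 'rate' metadata column")
  else {
    r <- mcols(b)$rate
    if (!is.numeric(r))
      msg <- c(msg, "rate must be numeric")
    else if (any(r < 0, na.rm = TRUE))
      msg <- c(msg, "rates must be >= 0 or NA")
  }
  if (length(msg)) return(msg)
  # per-chromosome tiling: contiguous fixed-width bins from position 1,
  # bin count = ceiling(length / binSize)
  bs <- as.integer(object@binSize)
  for (chr in seqlevels(b)) {
    bc <- b[seqnames(b) == chr]
    if (length(bc) == 0L) next
    st <- start(bc)
    if (is.unsorted(st))
      return(sprintf("bins on %s are not sorted", chr))
    if (st[1L] != 1L ||
        !all(st == seq.int(1L, by = bs, length.out = length(bc))))
      return(sprintf("bins on %s do not tile the chromosome", chr))
    w <- width(bc)
    if (any(w[-length(w)] != bs) || w[length(w)] > bs)
      return(sprintf("non-uniform bin width on %s", chr))
    sl <- seqlengths(b)[chr]
    if (!is.na(sl) && length(bc) != ceiling(sl / bs))
      return(sprintf("bin count on %s != ceiling(length/binSize)", chr))
  }
  TRUE
})

#' DensityTrack: per-bin q-discounted motif density
#'
#' Stores, for one motif, the sum of (1 - q) over motif occurrences assigned
#' to each genomic bin, where q is the per-occurrence multiple-testing
#' corrected match score. Confident matches (q near 0) count almost fully; a
#' fully discounted match (q = 1) contributes nothing. The sum over all bins
#' equals the genome-wide discounted count of the occurrence set.
#'
#' @slot bins a \link[GenomicRanges]{GRanges} of bins with a numeric metadata
#'   column \code{density} (all values \eqn{\ge 0}).
#' @slot binSize integer bin width in bp.
#' @slot motifName the motif the track belongs to.
#'
#' @seealso [densityTrack()], [rebinTrack()], [totalCount()]
#' @export
setClass("DensityTrack",
         slots = c(bins = "GRanges", binSize = "integer",
                   motifName = "character"))

setValidity("DensityTrack", function(object) {
  b <- object@bins
  if (!"density" %in% names(mcols(b)))
    return("bins must carry a 'density' metadata column")
  d <- mcols(b)$density
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    return("density values must be numeric and >= 0")
  if (length(object@binSize) != 1L || object@binSize < 1L)
    return("binSize must be a single positive integer")
  if (length(object@motifName) != 1L)
    return("motifName must be a single string")
  TRUE
})

#' MotifMatrix: a letter-probability matrix over A, C, G, T
#'
#' One probability column per motif position. Two dialects are supported:
#' \code{"hard"} gives the consensus base probability 1 and all others 0;
#' \code{"soft"} gives the consensus base 0.97 and the three others 0.01 each.
#'
#' @slot name motif name (by default the consensus string).
#' @slot probs 4 x L numeric matrix, rows named A, C, G, T; every column sums
#'   to 1 (within 1e-12).
#' @slot dialect \code{"hard"} or \code{"soft"}.
#'
#' @seealso [consensusToMatrix()], [logOdds()], [scanGenome()]
#' @export
setClass("MotifMatrix",
         slots = c(name = "character", probs = "matrix",
                   dialect = "character"))

setValidity("MotifMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || nrow(p) != 4L || ncol(p) < 1L)
    return("probs must be a 4 x L numeric matrix")
  if (!identical(rownames(p), c("A", "C", "G", "T")))
    return("probs rows must be named A, C, G, T")
  if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-12))
    return("every column must be a probability vector summing to 1")
  if (!object@dialect %in% c("hard", "soft"))
    return("dialect must be 'hard' or 'soft'")
  if (object@dialect == "hard" &&
      !all(apply(p, 2L, function(co) sum(co == 1) == 1L && sum(co == 0) == 3L)))
    return("hard dialect columns must be a permutation of (1,0,0,0)")
  if (object@dialect == "soft" &&
      !all(apply(p, 2L, function(co)
        sum(abs(sort(co) - c(0.01, 0.01, 0.01, 0.97)) < 1e-12) == 4L)))
    return("soft dialect columns must be (0.97, 0.01, 0.01, 0.01)")
  TRUE
})

#' ScoreMatrix: position-specific log-odds scores (bits)
#'
#' Derived from a [MotifMatrix-class] and a 0-order background by
#' pseudocount-regularized log-odds: \eqn{s_{b,i} = \log_2(p'_{b,i}/bg_b)}
#' with \eqn{p' = (p + \epsilon\, bg_b)/(1+\epsilon)}. All scores are finite.
#'
#' @slot name motif name.
#' @slot scores 4 x L numeric matrix of scores in bits, rows A, C, G, T.
#' @slot pseudocount the regularization \eqn{\epsilon} used.
#' @slot background the background frequencies used (named, A C G T).
#' @seealso [logOdds()], [scorePvalueTable()]
#' @export
setClass("ScoreMatrix",
         slots = c(name = "character", scores = "matrix",
                   pseudocount = "numeric", background = "numeric"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s) || nrow(s) != 4L)
    return("scores must be a 4 x L numeric matrix")
  if (!all(is.finite(s)))
    return("scores must be finite everywhere")
  if (length(object@pseudocount) != 1L)
    return("pseudocount must be a single number")
  TRUE
})

#' PvalueTable: exact null distribution of discretized match scores
#'
#' Scores are discretized to integer multiples of \code{granularity} (bits);
#' the position-wise convolution of the per-column score distributions under
#' the background yields the exact probability mass function of the window
#' score of a random background word, from which the tail probability
#' \eqn{P(S \ge s)} at every achievable discretized score is stored.
#'
#' @slot name motif name.
#' @slot granularity score discretization step in bits.
#' @slot minScore integer, the smallest achievable discretized total score
#'   (in granularity units).
#' @slot pvalues numeric vector; \code{pvalues[k]} is the tail probability at
#'   integer score \code{minScore + k - 1}.
#' @slot intScores the 4 x L integer matrix of discretized per-column scores
#'   the table was built from (shared by the scanner, so scan scores always
#'   hit the table support exactly).
#' @seealso [scorePvalueTable()], [lookupPvalue()]
#' @export
setClass("PvalueTable",
         slots = c(name = "character", granularity = "numeric",
                   minScore = "integer", pvalues = "numeric",
                   intScores = "matrix"))

#' FixtureBundle: a synthetic genome with matched map and planted truth
#'
#' The output of the synthetic-data generator: a multi-chromosome genome drawn
#' from a 0-order background, the simulated recombination map it was coupled
#' to, the ground-truth intervals of every planted motif copy, and the full
#' parameter manifest (including seeds) from which the bundle can be
#' regenerated bit-identically.
#'
#' @slot genome a \link[Biostrings]{DNAStringSet}, one entry per chromosome.
#' @slot map a [RecombinationMap-class] at the generator's bin size.
#' @slot truth a \link[GenomicRanges]{GRanges} of planted occurrences with
#'   metadata column \code{motif}; the plus-strand genome substring at every
#'   truth interval equals the motif string exactly.
#' @slot manifest named list of all generation parameters and seeds.
#' @seealso [plantMotifs()], [generateFixture()], [makeFixture()]
#' @export
setClass("FixtureBundle",
         slots = c(genome = "DNAStringSet", map = "RecombinationMap",
                   truth = "GRanges", manifest = "list"))

setValidity("FixtureBundle", function(object) {
  tr <- object@truth
  if (length(tr)) {
    if (!"motif" %in% names(mcols(tr)))
      return("truth must carry a 'motif' metadata column")
    lens <- setNames(width(object@genome), names(object@genome))
    bad <- start(tr) < 1L | end(tr) > lens[as.character(seqnames(tr))]
    if (any(bad))
      return("truth intervals must lie within chromosome bounds")
  }
  TRUE
})
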