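#' Convert a consensus motif to a letter-probability matrix
#'
#' One probability column per consensus character. The \code{"hard"} dialect
#' assigns the expected base probability 1 and the others 0; the
#' \code{"soft"} dialect assigns the expected base 0.97 and each unexpected
#' base 0.01. Ambiguity codes are unsupported.
#'
#' @param consensus a non-empty string over A, C, G, T (bracket shorthand
#'   such as \code{"[CA]6"} is accepted and expanded first).
#' @param dialect \code{"hard"} (default) or \code{"soft"}.
#' @param name motif name; defaults to the consensus string.
#' @return a [MotifMatrix-class].
#' @examples
#' consensusToMatrix("CA", dialect = "soft")
#' @export
consensusToMatrix <- function(consensus, dialect = c("hard", "soft"),
                              name = NULL) {
  dialect <- match.arg(dialect)
  consensus <- parseMotifNotation(consensus)
  .assertDNAString(consensus, "consensus")
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(ch)
  p <- if (dialect == "hard")
    matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  else
    matrix(0.01, 4L, L, dimnames = list(DNA_BASES, NULL))
  hit <- if (dialect == "hard") 1 else 0.97
  p[cbind(match(ch, DNA_BASES), seq_len(L))] <- hit
  new("MotifMatrix", name = name %||% consensus, probs = p, dialect = dialect)
}

#' @rdname accessors
#' @export
setMethod("motifName", "MotifMatrix", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("motifProbs", "MotifMatrix", function(x) x@probs)

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifMatrix", function(x) ncol(x@probs))

#' @rdname accessors
#' @export
setMethod("matrixDialect", "MotifMatrix", function(x) x@dialect)

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s': %d positions, %s dialect\n",
              object@name, ncol(object@probs), object@dialect))
  cat("  consensus:", paste(DNA_BASES[apply(object@probs, 2L, which.max)],
                            collapse = ""), "\n")
})

#' @rdname accessors
#' @export
setMethod("motifName", "ScoreMatrix", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("motifLength", "ScoreMatrix", function(x) ncol(x@scores))

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix '%s': %d positions, pseudocount %.3g\n",
              object@name, ncol(object@scores), object@pseudocount))
  cat(sprintf("  max attainable score: %.4f bits\n",
              sum(apply(object@scores, 2L, max))))
})

# reverse complement of a letter-probability matrix: reverse the columns and
# swap complementary rows (A<->T, C<->G == reversing the ACGT row order)
.revCompProbs <- function(p) {
  out <- p[4:1, rev(seq_len(ncol(p))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Estimate a 0-order background model from a genome
#'
#' Empirical A/C/G/T frequencies over the sequence and its reverse
#' complement (strand symmetrization), skipping N and other non-ACGT
#' letters. Frequencies of zero are regularized to 1e-6 and the vector is
#' renormalized, so the background is strictly positive everywhere.
#'
#' @param genome a \link[Biostrings]{DNAStringSet}, a
#'   \link[Biostrings]{DNAString}, a character vector of sequences, or a
#'   FASTA file path.
#' @return named numeric frequencies (A, C, G, T) summing to 1.
#' @examples
#' estimateBackground("ACGTACGT")
#' @export
estimateBackground <- function(genome) {
  genome <- .asDNAStringSet(genome)
  counts <- colSums(Biostrings::letterFrequency(genome, DNA_BASES))
  if (sum(counts) == 0) stop("no A/C/G/T content in genome")
  sym <- (counts + counts[4:1]) / 2          # strand symmetrize: A~T, C~G
  freq <- sym / sum(sym)
  freq[freq == 0] <- 1e-6
  freq <- freq / sum(freq)
  setNames(as.numeric(freq), DNA_BASES)
}

.asDNAStringSet <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) return(Biostrings::DNAStringSet(genome))
  if (is.character(genome)) {
    if (length(genome) == 1L && file.exists(genome) &&
        !grepl("^[ACGTNacgtn]+$", genome))
      return(Biostrings::readDNAStringSet(genome))
    return(Biostrings::DNAStringSet(genome))
  }
  stop("cannot interpret genome argument")
}

#' Log-odds score matrix from a letter-probability matrix
#'
#' Standard pseudocount-regularized log-odds construction:
#' \eqn{p'_{b,i} = (p_{b,i} + \epsilon\, bg_b) / (1 + \epsilon)} and
#' \eqn{s_{b,i} = \log_2(p'_{b,i} / bg_b)} (bits). The pseudocount keeps
#' hard-matrix scores finite; with \eqn{\epsilon \le 0} and any zero
#' probability the construction is refused.
#'
#' @param motif a [MotifMatrix-class] (or consensus string, converted with
#'   the hard dialect).
#' @param background named A/C/G/T frequencies, e.g. from
#'   [estimateBackground()].
#' @param pseudocount regularization \eqn{\epsilon > 0}; default 0.1.
#' @return a [ScoreMatrix-class].
#' @examples
#' bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
#' logOdds(consensusToMatrix("AAA"), bg)
#' @export
logOdds <- function(motif, background, pseudocount = 0.1) {
  if (is.character(motif)) motif <- consensusToMatrix(motif)
  stopifnot(is(motif, "MotifMatrix"))
  bg <- .checkBackground(background)
  p <- motifProbs(motif)
  if (pseudocount <= 0 && any(p == 0))
    stop("pseudocount must be > 0 for matrices containing zero probabilities")
  pp <- sweep(p, 1L, pseudocount * bg, "+") / (1 + pseudocount)
  s <- log2(sweep(pp, 1L, bg, "/"))
  new("ScoreMatrix", name = motifName(motif), scores = s,
      pseudocount = pseudocount, background = bg)
}
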