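# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

.codeLookup <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("AaCcGgTt")] <- rep(1:4, each = 2L)
  tab
})

# 1..4 integer codes for A,C,G,T; NA for anything else (N, gaps, ...)
.dnaCodes <- function(seq) {
  .codeLookup[utf8ToInt(as.character(seq))]
}

.codesToString <- function(codes) intToUtf8(c(65L, 67L, 71L, 84L)[codes])

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors.
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of the same length.
#' @examples
#' revComp(c("CACA", "GGTT"))
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rotations <- function(u) {
  n <- nchar(u)
  vapply(seq_len(n),
         function(i) paste0(substr(u, i, n), substr(u, 1L, i - 1L)),
         character(1))
}

.assertDNAString <- function(s, what = "motif") {
  if (length(s) != 1L || is.na(s) || !nzchar(s))
    stop(what, " must be a non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop(what, " may only contain A, C, G, T (ambiguity codes unsupported)",
         call. = FALSE)
  invisible(s)
}

# background = named frequencies over A,C,G,T; reordered and checked
.checkBackground <- function(background) {
  if (is.null(names(background)) || !all(DNA_BASES %in% names(background)))
    stop("background must be named with A, C, G, T", call. = FALSE)
  bg <- as.numeric(background[DNA_BASES])
  names(bg) <- DNA_BASES
  if (any(!is.finite(bg)) || any(bg <= 0))
    stop("background frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(bg) - 1) > 1e-12)
    stop("background frequencies must sum to 1 (within 1e-12)", call. = FALSE)
  bg
}

# fixed-width genomic bin tiling shared by maps, density tracks and labels
.tileBins <- function(chromLengths, binSize) {
  binSize <- as.integer(binSize)
  stopifnot(!is.null(names(chromLengths)), binSize >= 1L)
  grl <- lapply(names(chromLengths), function(cn) {
    len <- as.integer(chromLengths[[cn]])
    nb <- as.integer(ceiling(len / binSize))
    st <- seq.int(1L, by = binSize, length.out = nb)
    GRanges(cn, IRanges(st, pmin(st + binSize - 1L, len)))
  })
  gr <- suppressWarnings(do.call(c, grl))
  seqlevels(gr) <- names(chromLengths)
  seqlengths(gr) <- as.integer(chromLengths[seqlevels(gr)])
  gr
}

# seed expansion: one global integer seed -> fixed per-component offsets
.componentSeed <- function(seed, offset) {
  s <- as.integer(seed) + as.integer(offset)
  if (is.na(s) || s >= .Machine$integer.max)
    stop("seed out of integer range", call. = FALSE)
  s
}

# lower median: the lower of the two central order statistics for even-sized
# multisets, the exact middle for odd ones; NA values are excluded first.
# Keeps the membership property (output is an element of the input) at
# truncated edge windows too.
.lowerMedian <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  k <- as.integer(ceiling(n / 2))
  sort(v, partial = k)[k]
}
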