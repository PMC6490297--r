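#' Minimal repeat unit of a string
#'
#' Finds the shortest unit u such that the string is a prefix of u repeated
#' (so truncated repeats like "CACAC" still reduce to "CA"), and returns the
#' lexicographically smallest rotation of u.
#'
#' @param s a non-empty string over A, C, G, T.
#' @return the canonical (smallest-rotation) minimal repeat unit.
#' @examples
#' minimalRepeatUnit("CACACA")        # "AC"
#' minimalRepeatUnit("GCAGCAGCAGCA")  # "AGC"
#' @export
minimalRepeatUnit <- function(s) {
  .assertDNAString(s, "string")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  p <- n
  for (k in seq_len(n - 1L)) {
    if (all(ch[(k + 1L):n] == ch[seq_len(n - k)])) { p <- k; break }
  }
  u <- substr(s, 1L, p)
  min(.rotations(u))
}

#' Canonical repeat unit up to rotation and reverse complement
#'
#' The grouping key used for candidate deduplication and consensus
#' construction: the lexicographically smallest string among all rotations
#' of the minimal repeat unit and all rotations of its reverse complement.
#' Strand-flipped and phase-shifted versions of the same tandem repeat
#' (e.g. CACACA..., ACACAC..., GTGTGT...) share one canonical unit.
#'
#' @param s a repeat string over A, C, G, T.
#' @return canonical unit string.
#' @examples
#' canonicalUnit("GTGTGTGTGTGT")  # "AC"
#' @export
canonicalUnit <- function(s) {
  u <- minimalRepeatUnit(s)
  min(c(.rotations(u), .rotations(revComp(u))))
}

#' Enumerate tandem-repeat candidate motifs
#'
#' All pure tandem repeats unit^k with unit length in \code{unitLengths} and
#' total length within \code{lengthRange}, deduplicated by canonical unit
#' (rotation and reverse complement) and restricted to primitive units (a
#' unit that is itself a repeat of a shorter unit is dropped). This is the
#' candidate space for [differentialEnrichment()]; it is shaped to the short
#' repeat family that recombination-associated motifs in \emph{Drosophila}
#' fall into.
#'
#' @param unitLengths repeat-unit lengths to consider (default 1:3).
#' @param lengthRange inclusive total length range (default c(8, 12)).
#' @return character vector of candidate motif strings, sorted.
#' @examples
#' enumerateCandidates(1, c(8, 8))   # "AAAAAAAA" "CCCCCCCC"
#' @export
enumerateCandidates <- function(unitLengths = 1:3, lengthRange = c(8L, 12L)) {
  if (length(unitLengths) == 0L || length(lengthRange) != 2L ||
      lengthRange[2] < lengthRange[1])
    return(character(0))
  units <- character(0)
  for (ul in sort(unique(as.integer(unitLengths)))) {
    words <- do.call(paste0, expand.grid(rep(list(DNA_BASES), ul),
                                         stringsAsFactors = FALSE))
    words <- words[vapply(words, function(w)
      nchar(minimalRepeatUnit(w)) == ul, logical(1))]
    units <- c(units, unique(vapply(words, canonicalUnit, character(1))))
  }
  units <- unique(units)
  out <- character(0)
  for (u in units) {
    ul <- nchar(u)
    ks <- seq.int(ceiling(lengthRange[1] / ul), floor(lengthRange[2] / ul))
    ks <- ks[ks >= 1L]
    out <- c(out, vapply(ks, function(k) strrep(u, k), character(1)))
  }
  sort(unique(out))
}

#' Simplify a probability matrix to its consensus string
#'
#' Takes the maximal-probability base at each position; ties are broken
#' alphabetically (A < C < G < T). Hard matrices map back to their
#' consensus exactly.
#'
#' @param matrix a [MotifMatrix-class] or a 4 x L probability matrix with
#'   rows A, C, G, T.
#' @return consensus string.
#' @export
simplifyMotif <- function(matrix) {
  p <- if (is(matrix, "MotifMatrix")) motifProbs(matrix) else matrix
  if (is.null(rownames(p))) rownames(p) <- DNA_BASES
  p <- p[DNA_BASES, , drop = FALSE]
  paste(DNA_BASES[apply(p, 2L, which.max)], collapse = "")
}

#' Differential enrichment of candidate motifs in high- vs low-recombining
#' regions
#'
#' For every candidate, counts exact occurrences (both strands, overlaps
#' allowed) whose start position falls in a high- versus a low-labelled bin,
#' together with the number of scannable start positions per class, and
#' tests for excess in the high class with a one-sided hypergeometric
#' (Fisher) test on the 2x2 table of match vs non-match positions by class.
#' E-values are Bonferroni-style: \eqn{E = p \times} number of candidates
#' tested. This enumerative contingency-table search is a deliberately
#' simple, exactly testable procedure for finding repeat motifs enriched in
#' high-recombining chromatin; it is not an EM motif-discovery algorithm.
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param labels a labelled bin GRanges from [splitHighLow()].
#' @param candidates character vector of candidate motif strings (see
#'   [enumerateCandidates()]).
#' @return a data frame (candidate, unit, count_high, count_low,
#'   positions_high, positions_low, p_value, E_value), sorted by E.
#' @export
differentialEnrichment <- function(genome, labels, candidates) {
  genome <- .asDNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  if (length(candidates) == 0L) stop("candidate list is empty")
  lab <- as.character(labels$label)
  if (!any(lab == "high") || !any(lab == "low"))
    stop("degenerate split: need non-empty high and low classes")
  binSize <- max(width(labels))
  labByChrom <- split(lab, factor(as.character(seqnames(labels)),
                                  levels = seqlevels(labels)))
  chroms <- intersect(names(genome), names(labByChrom))
  if (length(chroms) == 0L) stop("labels do not cover the genome")
  nCand <- length(candidates)
  res <- lapply(candidates, function(cand) {
    .assertDNAString(cand, "candidate")
    L <- nchar(cand)
    cH <- cL <- pH <- pL <- 0
    for (chr in chroms) {
      lv <- labByChrom[[chr]]
      len <- width(genome)[match(chr, names(genome))]
      nstart <- len - L + 1L
      if (nstart < 1L) next
      # scannable start positions per bin (both strands => factor 2)
      binEnds <- pmin(seq_along(lv) * binSize, nstart)
      binStarts <- (seq_along(lv) - 1L) * binSize + 1L
      npos <- pmax(0L, binEnds - binStarts + 1L)
      pH <- pH + 2 * sum(npos[lv == "high"])
      pL <- pL + 2 * sum(npos[lv == "low"])
      starts <- c(start(Biostrings::matchPattern(cand, genome[[chr]])),
                  start(Biostrings::matchPattern(revComp(cand),
                                                 genome[[chr]])))
      if (length(starts)) {
        bl <- lv[(starts - 1L) %/% binSize + 1L]
        cH <- cH + sum(bl == "high")
        cL <- cL + sum(bl == "low")
      }
    }
    p <- stats::phyper(cH - 1, cH + cL, (pH + pL) - (cH + cL), pH,
                       lower.tail = FALSE)
    data.frame(candidate = cand, unit = canonicalUnit(cand),
               count_high = cH, count_low = cL,
               positions_high = pH, positions_low = pL,
               p_value = p, E_value = min(p * nCand, Inf))
  })
  out <- do.call(rbind, res)
  out[order(out$E_value, out$candidate), , drop = FALSE]
}

#' Build the cross-species consensus motif set
#'
#' Two-step consensus construction over discovered motif records:
#' records failing the significance filter (E > \code{eThreshold} at every
#' scale) are dropped; the survivors are grouped by canonical repeat unit
#' (up to rotation and reverse complement); per group the consensus length
#' is the longest length representable in every contributing species, i.e.
#' the minimum over species of the per-species maximum record length;
#' groups present in a single species keep that species' maximum length and
#' are flagged single-species. Groups are ordered by their best (smallest)
#' E-value and labelled C1, C2, ...
#'
#' @param records a data frame with columns \code{species}, \code{motif}
#'   (consensus strings; simplify matrices with [simplifyMotif()] first),
#'   \code{E_value}, and optionally \code{scale_kb}.
#' @param eThreshold retention threshold on E (default 0.01).
#' @return a data frame (id, unit, count, length, consensus, species,
#'   single_species, n_records, min_E); zero rows if nothing survives the
#'   filter.
#' @export
buildConsensusSet <- function(records, eThreshold = 0.01) {
  need <- c("species", "motif", "E_value")
  if (!all(need %in% names(records)))
    stop("records must have columns species, motif, E_value")
  if (nrow(records) == 0L) stop("need at least one record")
  keep <- records[records$E_value <= eThreshold, , drop = FALSE]
  empty <- data.frame(id = character(0), unit = character(0),
                      count = integer(0), length = integer(0),
                      consensus = character(0), species = character(0),
                      single_species = logical(0), n_records = integer(0),
                      min_E = numeric(0))
  if (nrow(keep) == 0L) return(empty)
  keep$unit <- vapply(keep$motif, canonicalUnit, character(1))
  groups <- split(keep, keep$unit)
  rows <- lapply(groups, function(g) {
    maxLenBySp <- tapply(nchar(g$motif), g$species, max)
    single <- length(maxLenBySp) < 2L
    len <- if (single) as.integer(maxLenBySp[[1]])
           else as.integer(min(maxLenBySp))
    u <- g$unit[1]
    count <- as.integer(ceiling(len / nchar(u)))
    consensus <- substr(strrep(u, count), 1L, len)
    data.frame(unit = u, count = count, length = len, consensus = consensus,
               species = paste(sort(names(maxLenBySp)), collapse = "+"),
               single_species = single, n_records = nrow(g),
               min_E = min(g$E_value))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$min_E, out$unit), , drop = FALSE]
  out <- cbind(id = paste0("C", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Write a discovery report / consensus set
#'
#' @param x a data frame from [differentialEnrichment()] or
#'   [buildConsensusSet()].
#' @param path output TSV file.
#' @return \code{path}, invisibly.
#' @export
writeDiscoveryReport <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus motif files
#'
#' A consensus set serializes to a small JSON motif file that the scanning
#' stage consumes directly: \code{readConsensusMotifs()} returns the named
#' character vector of consensus strings (names = motif ids) ready for
#' [consensusToMatrix()] / [scanGenome()].
#'
#' @param consensus a data frame from [buildConsensusSet()].
#' @param path JSON file path.
#' @return \code{writeConsensusMotifs}: \code{path}, invisibly;
#'   \code{readConsensusMotifs}: named character vector of motif strings.
#' @export
writeConsensusMotifs <- function(consensus, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(consensus)), function(i)
      list(id = consensus$id[i], unit = consensus$unit[i],
           count = consensus$count[i], consensus = consensus$consensus[i],
           species = consensus$species[i],
           single_species = consensus$single_species[i])),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeConsensusMotifs
#' @export
readConsensusMotifs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x) == 0L) return(character(0))
  setNames(x$consensus, x$id)
}
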