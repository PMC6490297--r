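#' Simulate a single-chromosome recombination landscape
#'
#' Generates one chromosome's binned rate track. Two empirical landscape
#' shapes are provided, mirroring the contrast between the two
#' \emph{Drosophila} sister species the package is built around:
#' \describe{
#'   \item{\code{"mel_like"}}{a plateau with a gradual logistic decay toward
#'     each chromosome end with length constant \code{decayScale}: rate at
#'     distance d from the nearer end is
#'     \code{plateauRate * plogis((d - 2*decayScale)/decayScale)}; the
#'     noise-free expectation is non-increasing from mid-arm toward each
#'     end.}
#'   \item{\code{"sim_like"}}{a flat plateau that drops sharply
#'     (to plateau/50) within \code{edgeDropWidth} bp of each chromosome
#'     end; with \code{edgeDropWidth = 0} this is exactly flat.}
#' }
#' \code{"flat"} is a constant track and \code{"custom"} takes
#' \code{customRates} verbatim. Multiplicative lognormal noise with
#' coefficient of variation \code{noiseCV} (mean 1) is applied per bin,
#' emulating the bin-to-bin noise of raw linkage-disequilibrium based rate
#' estimates; rates are never negative.
#'
#' @param shape one of \code{"sim_like"}, \code{"mel_like"}, \code{"flat"},
#'   \code{"custom"}.
#' @param chromLength chromosome length in bp (at least 10 bins).
#' @param binSize bin width in bp (default 1000).
#' @param plateauRate plateau rate in cM/Mb, > 0 (default 3).
#' @param edgeDropWidth width of the terminal suppression zone in bp,
#'   >= 0 (sim_like; default 1e6).
#' @param decayScale logistic decay length constant in bp, > 0 (mel_like;
#'   default 1e6).
#' @param noiseCV coefficient of variation of the multiplicative lognormal
#'   per-bin noise, >= 0 (default 0.3).
#' @param seed optional integer seed; when given the track is a
#'   deterministic function of the parameters.
#' @param chromName chromosome name (default "chr1").
#' @param customRates per-bin rates for \code{shape = "custom"}.
#' @return a [RecombinationMap-class] in cM/Mb with one chromosome.
#' @examples
#' simulateLandscape("flat", 1e5, plateauRate = 3, noiseCV = 0)
#' @export
simulateLandscape <- function(shape = c("sim_like", "mel_like", "flat",
                                        "custom"),
                              chromLength, binSize = 1000L, plateauRate = 3,
                              edgeDropWidth = 1e6, decayScale = 1e6,
                              noiseCV = 0.3, seed = NULL,
                              chromName = "chr1", customRates = NULL) {
  shape <- match.arg(shape)
  if (plateauRate <= 0) stop("plateauRate must be > 0")
  if (binSize <= 0) stop("binSize must be > 0")
  if (chromLength <= 0) stop("chromLength must be > 0")
  if (chromLength < 10 * binSize)
    stop("chromLength must cover at least 10 bins")
  if (edgeDropWidth < 0) stop("edgeDropWidth must be >= 0")
  if (decayScale <= 0) stop("decayScale must be > 0")
  if (noiseCV < 0) stop("noiseCV must be >= 0")
  nb <- as.integer(ceiling(chromLength / binSize))
  st <- seq.int(0, by = binSize, length.out = nb)
  mid <- pmin(st + binSize / 2, chromLength)
  d <- pmin(mid, chromLength - mid)       # distance to the nearer end
  base <- switch(shape,
    flat = rep(plateauRate, nb),
    sim_like = ifelse(d < edgeDropWidth, plateauRate / 50, plateauRate),
    mel_like = plateauRate * stats::plogis((d - 2 * decayScale) / decayScale),
    custom = {
      if (is.null(customRates) || length(customRates) != nb)
        stop("customRates must supply one rate per bin")
      as.numeric(customRates)
    })
  if (!is.null(seed)) set.seed(.componentSeed(seed, 0L))
  rate <- if (noiseCV > 0) {
    sigma2 <- log(1 + noiseCV^2)
    base * exp(stats::rnorm(nb, mean = -sigma2 / 2, sd = sqrt(sigma2)))
  } else base
  RecombinationMap(setNames(list(pmax(rate, 0)), chromName),
                   binSize = binSize,
                   chromLengths = setNames(chromLength, chromName),
                   units = "cM_per_Mb")
}

#' Plant motif copies into a background genome coupled to a landscape
#'
#' Draws a genome i.i.d. from a 0-order base-frequency background over the
#' coordinates of \code{map}, then writes copies of \code{motif} at
#' positions drawn from a per-bin Poisson with mean
#' \code{(baseIntensity + coupling * rate_bin) * bin_kb}, placed uniformly
#' within the bin. Planted copies never overlap each other (rejection
#' sampling); overlaps with chance background matches are allowed and
#' expected. With \code{strandPolicy = "both"} each copy lands on a random
#' strand (the reverse complement is written for minus-strand copies). The
#' returned truth list records every planted interval; the plus-strand
#' genome substring at a plus-strand truth interval equals the motif
#' exactly.
#'
#' @param map a [RecombinationMap-class] defining the chromosomes, bins and
#'   per-bin rates the plant intensity couples to.
#' @param motif consensus string over A, C, G, T (bracket shorthand
#'   accepted).
#' @param background named A/C/G/T frequencies of the genome background
#'   (default uniform).
#' @param baseIntensity expected occurrences per kb at rate 0 (>= 0).
#' @param coupling expected extra occurrences per kb per (cM/Mb); may be
#'   negative as long as the intensity stays non-negative everywhere.
#' @param strandPolicy \code{"both"} (default) or \code{"plus_only"}.
#' @param seed optional integer seed.
#' @param maxTries rejection-sampling attempts per copy before it is
#'   skipped (default 100).
#' @return a [FixtureBundle-class].
#' @export
plantMotifs <- function(map, motif,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                        baseIntensity = 0.2, coupling = 0.5,
                        strandPolicy = c("both", "plus_only"), seed = NULL,
                        maxTries = 100L) {
  strandPolicy <- match.arg(strandPolicy)
  motif <- parseMotifNotation(motif)
  .assertDNAString(motif, "motif")
  bg <- .checkBackground(background)
  if (baseIntensity < 0) stop("baseIntensity must be >= 0")
  rl <- rateValues(map)
  rmax <- suppressWarnings(max(unlist(rl), na.rm = TRUE))
  if (baseIntensity + coupling * rmax < 0 ||
      baseIntensity + coupling * 0 < 0)
    stop("plant intensity must be non-negative over the whole rate range")
  binKb <- binSize(map) / 1000
  L <- nchar(motif)
  lens <- chromLengths(map)
  lambdaAll <- lapply(rl, function(r)
    pmax(0, baseIntensity + coupling * ifelse(is.na(r), 0, r)) * binKb)
  expectedBases <- sum(unlist(lambdaAll)) * L
  if (expectedBases > 0.2 * sum(as.numeric(lens)))
    stop("saturation: expected planted bases exceed 20% of genome length")

  if (!is.null(seed)) set.seed(.componentSeed(seed, 0L))
  motifCodes <- .dnaCodes(motif)
  rcCodes <- .dnaCodes(revComp(motif))
  genome <- character(length(lens))
  names(genome) <- names(lens)
  truth <- list()
  for (chr in names(lens)) {
    len <- as.integer(lens[[chr]])
    codes <- sample.int(4L, len, replace = TRUE, prob = bg)
    occupied <- logical(len)
    lambda <- lambdaAll[[chr]]
    counts <- stats::rpois(length(lambda), lambda)
    starts <- integer(0); strands <- character(0)
    bs <- binSize(map)
    for (b in which(counts > 0L)) {
      lo <- (b - 1L) * bs + 1L
      hi <- min(b * bs, len - L + 1L)
      if (hi < lo) next
      for (k in seq_len(counts[b])) {
        for (tr in seq_len(maxTries)) {
          pos <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
          span <- pos:(pos + L - 1L)
          if (!any(occupied[span])) {
            occupied[span] <- TRUE
            strnd <- if (strandPolicy == "both" &&
                         sample.int(2L, 1L) == 2L) "-" else "+"
            codes[span] <- if (strnd == "+") motifCodes else rcCodes
            starts <- c(starts, pos); strands <- c(strands, strnd)
            break
          }
        }
      }
    }
    genome[[chr]] <- .codesToString(codes)
    if (length(starts))
      truth[[chr]] <- GRanges(chr, IRanges(starts, width = L),
                              strand = strands, motif = motif)
  }
  genomeSet <- Biostrings::DNAStringSet(genome)
  truthGR <- if (length(truth)) sort(suppressWarnings(do.call(c, unname(truth))))
             else GRanges()
  if (length(truthGR) == 0L) mcols(truthGR)$motif <- character(0)
  seqlevels(truthGR) <- names(lens)
  seqlengths(truthGR) <- as.integer(lens)
  manifest <- list(motif = motif, background = as.list(bg),
                   baseIntensity = baseIntensity, coupling = coupling,
                   strandPolicy = strandPolicy, seed = seed,
                   binSize = binSize(map),
                   chromLengths = as.list(lens))
  new("FixtureBundle", genome = genomeSet, map = map, truth = truthGR,
      manifest = manifest)
}

setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(
    "FixtureBundle: %d chromosome(s), %s bp total, %d planted occurrence(s)\n",
    length(object@genome), format(sum(width(object@genome)), big.mark = ","),
    length(object@truth)))
  if (length(object@truth))
    cat("  motif(s):", paste(unique(object@truth$motif), collapse = ", "),
        "\n")
})

#' Generate a complete fixture bundle from a manifest
#'
#' Deterministically expands a manifest (all landscape, background and
#' planting parameters plus one global seed) into a
#' [FixtureBundle-class]. The global seed expands into per-component seeds
#' by fixed offsets (landscape: seed + 1, genome/planting: seed + 2),
#' recorded back into the manifest, so regeneration from the manifest is
#' bit-identical.
#'
#' @param manifest a named list with elements \code{seed},
#'   \code{chromLengths} (named), and optional \code{binSize} (default
#'   1000), \code{background} (named A/C/G/T frequencies, default
#'   uniform), \code{landscape} (arguments for [simulateLandscape()]:
#'   shape, plateauRate, edgeDropWidth, decayScale, noiseCV), and
#'   \code{plant} (arguments for [plantMotifs()]: motif, baseIntensity,
#'   coupling, strandPolicy). Omit \code{plant} for a pure background
#'   genome.
#' @return a [FixtureBundle-class] whose manifest records every parameter
#'   and derived seed.
#' @seealso [makeFixture()] to write the bundle to disk.
#' @export
generateFixture <- function(manifest) {
  if (is.null(manifest$seed)) stop("manifest must contain a seed")
  if (is.null(manifest$chromLengths) ||
      is.null(names(manifest$chromLengths)))
    stop("manifest must contain named chromLengths")
  seed <- as.integer(manifest$seed)
  binSize <- as.integer(manifest$binSize %||% 1000L)
  bg <- .checkBackground(unlist(manifest$background %||%
                                  list(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)))
  land <- manifest$landscape %||% list()
  lens <- unlist(manifest$chromLengths)

  set.seed(.componentSeed(seed, 1L))
  maps <- lapply(names(lens), function(chr)
    simulateLandscape(shape = land$shape %||% "sim_like",
                      chromLength = lens[[chr]], binSize = binSize,
                      plateauRate = land$plateauRate %||% 3,
                      edgeDropWidth = land$edgeDropWidth %||% 1e6,
                      decayScale = land$decayScale %||% 1e6,
                      noiseCV = land$noiseCV %||% 0.3,
                      seed = NULL, chromName = chr))
  rates <- lapply(maps, function(m) rateValues(m)[[1]])
  names(rates) <- names(lens)
  map <- RecombinationMap(rates, binSize = binSize, chromLengths = lens,
                          units = "cM_per_Mb")

  plant <- manifest$plant
  set.seed(.componentSeed(seed, 2L))
  bundle <- if (is.null(plant)) {
    plantMotifs(map, "ACGTACGTACGT", background = bg, baseIntensity = 0,
                coupling = 0, seed = NULL)
  } else {
    plantMotifs(map, plant$motif, background = bg,
                baseIntensity = plant$baseIntensity %||% 0.2,
                coupling = plant$coupling %||% 0.5,
                strandPolicy = plant$strandPolicy %||% "both", seed = NULL)
  }
  full <- manifest
  full$binSize <- binSize
  full$background <- as.list(bg)
  full$seeds <- list(global = seed,
                     landscape = .componentSeed(seed, 1L),
                     plant = .componentSeed(seed, 2L))
  bundle@manifest <- full
  bundle
}

#' Write a fixture bundle to disk
#'
#' Writes \code{genome.fasta} (60-column wrap, one record per chromosome),
#' \code{map.csv} (\code{chrom,start,end,rate}, 0-based half-open),
#' \code{truth.bed} (BED6, strand in column 6, motif in the name column)
#' and \code{manifest.json}. The same manifest always produces
#' byte-identical files, and the files round-trip losslessly through
#' [readFixture()].
#'
#' @param manifest a manifest list (see [generateFixture()]) or a
#'   [FixtureBundle-class].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory
#'   (default FALSE).
#' @return the generated [FixtureBundle-class], invisibly.
#' @export
makeFixture <- function(manifest, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- if (is(manifest, "FixtureBundle")) manifest
            else generateFixture(manifest)
  Biostrings::writeXStringSet(bundle@genome,
                              file.path(dir, "genome.fasta"), width = 60L)
  writeRecombinationMap(bundle@map, file.path(dir, "map.csv"))
  tr <- bundle@truth
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(seqnames(tr)), start(tr) - 1L, end(tr),
                     tr$motif, as.character(strand(tr))),
             file.path(dir, "truth.bed"))
  jsonlite::write_json(bundle@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(bundle)
}

#' Read a fixture bundle back from disk
#'
#' @param dir a directory written by [makeFixture()].
#' @return a [FixtureBundle-class].
#' @export
readFixture <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  map <- readRecombinationMap(file.path(dir, "map.csv"))
  bedPath <- file.path(dir, "truth.bed")
  truth <- GRanges()
  mcols(truth)$motif <- character(0)
  if (file.size(bedPath) > 0) {
    bed <- utils::read.table(bedPath, sep = "\t",
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand"))
    truth <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end),
                     strand = bed$strand, motif = bed$name)
  }
  seqlevels(truth) <- names(genome)
  seqlengths(truth) <- width(genome)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  new("FixtureBundle", genome = genome, map = map, truth = sort(truth),
      manifest = as.list(manifest))
}
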