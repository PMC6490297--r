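#' Bracketed repeat-motif notation
#'
#' \code{parseMotifNotation("[CA]6")} expands the field's compact repeat
#' notation to the full string \code{"CACACACACACA"}; plain A/C/G/T strings
#' pass through unchanged. \code{formatMotifNotation()} does the reverse,
#' writing a string as \code{[unit]count} over its canonical
#' (smallest-rotation) minimal repeat unit; strings whose length is not a
#' multiple of their unit are returned verbatim.
#'
#' @param x character vector of motif strings or bracket shorthand.
#' @return character vector of the same length.
#' @examples
#' parseMotifNotation("[GCA]4")          # "GCAGCAGCAGCA"
#' formatMotifNotation("GCAGCAGCAGCA")   # "[AGC]4"
#' @export
parseMotifNotation <- function(x) {
  vapply(x, function(s) {
    m <- regmatches(s, regexec("^\\[([ACGT]+)\\]([0-9]+)$", s))[[1]]
    if (length(m) == 3L) return(strrep(m[2], as.integer(m[3])))
    s
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname parseMotifNotation
#' @export
formatMotifNotation <- function(x) {
  vapply(x, function(s) {
    u <- minimalRepeatUnit(s)
    if (nchar(s) %% nchar(u) != 0L) return(s)
    sprintf("[%s]%d", u, nchar(s) %/% nchar(u))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML (or JSON) configuration file and merges it over the
#' pipeline defaults; see [runPipeline()] for the recognized fields.
#'
#' @param path YAML config file.
#' @return a config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .mergeConfig(cfg)
}

.pipelineDefaults <- list(
  scalesKb = c(1, 5, 25, 101, 501, 2501),
  pThreshold = 1e-4,
  dialect = "hard",
  densityBinKb = 1,
  mapUnits = "cM_per_Mb",
  pseudocount = 0.1,
  granularity = 1e-3,
  discover = FALSE,
  species = "speciesA",
  eThreshold = 0.01,
  unitLengths = 1:3,
  lengthRange = c(8, 12),
  overwrite = FALSE
)

.mergeConfig <- function(cfg) {
  out <- .pipelineDefaults
  for (nm in names(cfg)) out[[nm]] <- cfg[[nm]]
  out
}

#' Run the full motif-density / recombination-rate pipeline
#'
#' Orchestrates the end-to-end analysis over files: read genome and raw
#' map, optionally normalize rho to cM/Mb against anchors, smooth the map
#' with a moving median at every configured scale, split each smoothed map
#' into high/low-recombining regions, optionally run differential motif
#' discovery per scale and build the cross-species consensus set, scan the
#' genome for each motif, attach q-scores, build q-discounted density
#' tracks, and compute the motif x stratum x scale association grid. Every
#' intermediate is written to the run directory as plain text together
#' with a manifest (configuration, package version, file checksums); the
#' whole run is deterministic, so re-running the same configuration
#' reproduces all outputs bit-identically.
#'
#' @param config a configuration list or the path to a YAML config file.
#'   Recognized fields: \code{genome} (FASTA path), \code{map} (CSV path),
#'   \code{mapUnits} ("cM_per_Mb" or "rho"), \code{anchors} (CSV path,
#'   optional; required to normalize a rho map), \code{motifs} (character
#'   vector, bracket shorthand allowed) or \code{discover = TRUE} (with
#'   \code{unitLengths}, \code{lengthRange}, \code{eThreshold},
#'   \code{species}), \code{scalesKb} (default 1, 5, 25, 101, 501, 2501;
#'   each must be an odd multiple of the map bin size), \code{pThreshold}
#'   (default 1e-4), \code{dialect} ("hard"/"soft"), \code{densityBinKb}
#'   (default 1), \code{outDir}, \code{overwrite}.
#' @return invisibly, a list with the grid, motifs, and the run directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- .mergeConfig(config)
  if (is.null(cfg$genome) || is.null(cfg$map) || is.null(cfg$outDir))
    stop("config must provide genome, map and outDir")

  genome <- .asDNAStringSet(cfg$genome)
  map <- readRecombinationMap(cfg$map, units = cfg$mapUnits)

  # validate the whole configuration before any compute
  binKb <- binSize(map) / 1000
  for (s in cfg$scalesKb) {
    w <- s / binKb
    if (abs(w - round(w)) > 1e-9 || round(w) %% 2 == 0)
      stop("scale ", s, " kb is not an odd multiple of the map bin size")
  }
  if (cfg$pThreshold <= 0 || cfg$pThreshold >= 1)
    stop("pThreshold must be in (0, 1)")
  if (!cfg$dialect %in% c("hard", "soft")) stop("unknown dialect")
  if (!isTRUE(cfg$discover) && is.null(cfg$motifs))
    stop("config must provide motifs or discover = TRUE")
  if (dir.exists(cfg$outDir) && length(list.files(cfg$outDir)) > 0L &&
      !isTRUE(cfg$overwrite))
    stop("outDir exists and is not empty; set overwrite: true")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(fmt, ...) message(sprintf(
    "[%6.1fs] %s", proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))

  stage("inputs: %d chromosome(s), %d map bins of %d bp",
        length(genome), length(trackBins(map)), binSize(map))
  if (!is.null(cfg$anchors)) {
    map <- normalizeToCM(map, readAnchors(cfg$anchors))
    stage("normalized rho map to cM/Mb against %s", cfg$anchors)
  } else if (rateUnits(map) == "rho") {
    stop("map is in rho units but no anchors were provided")
  }

  bg <- estimateBackground(genome)
  stage("background: A=%.3f C=%.3f G=%.3f T=%.3f", bg[1], bg[2], bg[3],
        bg[4])

  maps <- list()
  labels <- list()
  for (s in cfg$scalesKb) {
    sm <- movingMedian(map, s)
    maps[[as.character(s)]] <- sm
    writeRecombinationMap(sm,
      file.path(cfg$outDir, sprintf("map_smoothed_w%gkb.csv", s)),
      windowKb = s)
    labels[[as.character(s)]] <- splitHighLow(sm)
    writeRegionLabels(labels[[as.character(s)]],
      file.path(cfg$outDir, sprintf("labels_w%gkb.bed", s)))
    stage("smoothed + segmented at %g kb", s)
  }

  if (isTRUE(cfg$discover)) {
    candidates <- enumerateCandidates(cfg$unitLengths, cfg$lengthRange)
    records <- do.call(rbind, lapply(names(labels), function(s) {
      de <- differentialEnrichment(genome, labels[[s]], candidates)
      writeDiscoveryReport(de,
        file.path(cfg$outDir, sprintf("discovery_w%skb.tsv", s)))
      data.frame(species = cfg$species, scale_kb = as.numeric(s),
                 motif = de$candidate, E_value = de$E_value)
    }))
    consensus <- buildConsensusSet(records, cfg$eThreshold)
    writeDiscoveryReport(consensus, file.path(cfg$outDir, "consensus.tsv"))
    writeConsensusMotifs(consensus, file.path(cfg$outDir, "consensus.json"))
    motifs <- consensus$consensus
    stage("discovery: %d candidate(s), %d consensus motif(s)",
          length(candidates), length(motifs))
    if (length(motifs) == 0L)
      stop("discovery retained no motifs at E <= ", cfg$eThreshold)
  } else {
    motifs <- parseMotifNotation(cfg$motifs)
  }

  lens <- setNames(width(genome), names(genome))
  tracks <- list()
  for (m in motifs) {
    mm <- consensusToMatrix(m, dialect = cfg$dialect)
    occ <- scanGenome(genome, mm, bg, pThreshold = cfg$pThreshold,
                      pseudocount = cfg$pseudocount,
                      granularity = cfg$granularity)
    occ <- computeQvalues(occ)
    writeOccurrences(occ,
      file.path(cfg$outDir, sprintf("occurrences_%s.tsv",
                                    formatMotifNotation(m))))
    tr <- densityTrack(occ, binSize = cfg$densityBinKb * 1000,
                       chromLengths = lens, motifName = m)
    tracks[[m]] <- tr
    writeDensityTrack(tr,
      file.path(cfg$outDir, sprintf("density_%s_%gkb.csv",
                                    formatMotifNotation(m),
                                    cfg$densityBinKb)))
    stage("scanned %s: %d occurrence(s), total 1-q = %.1f", m,
          length(occ), totalCount(occ))
  }

  grid <- associationGrid(maps, tracks)
  utils::write.csv(format(grid, digits = 15),
                   file.path(cfg$outDir, "association_grid.csv"),
                   row.names = FALSE, quote = FALSE)
  stage("association grid: %d row(s)", nrow(grid))

  files <- setdiff(list.files(cfg$outDir), "manifest.json")
  manifest <- list(package = "recmotifs",
                   version = as.character(utils::packageVersion("recmotifs")),
                   config = cfg[order(names(cfg))],
                   md5 = as.list(tools::md5sum(
                     file.path(cfg$outDir, sort(files)))))
  names(manifest$md5) <- sort(files)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(grid = grid, motifs = motifs, maps = maps,
                 tracks = tracks, outDir = cfg$outDir))
}
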