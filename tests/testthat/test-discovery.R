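test_that("minimal repeat units are canonical smallest rotations", {
  expect_identical(minimalRepeatUnit("CACACA"), "AC")
  expect_identical(minimalRepeatUnit("AAAA"), "A")
  expect_identical(minimalRepeatUnit("GCAGCAGCAGCA"), "AGC")
  expect_identical(minimalRepeatUnit("CACAC"), "AC")   # truncated repeat
  expect_identical(minimalRepeatUnit("ACGT"), "ACGT")  # primitive string
})

test_that("canonical units are invariant to rotation and reverse complement", {
  variants <- c("CACACACACACA", "ACACACACACAC", "GTGTGTGTGTGT",
                "TGTGTGTGTGTG")
  expect_identical(unique(vapply(variants, canonicalUnit, character(1),
                                 USE.NAMES = FALSE)), "AC")
  expect_identical(canonicalUnit("GCAGCAGCA"), canonicalUnit("TGCTGCTGC"))
})

test_that("candidate enumeration dedups by canonical unit", {
  expect_identical(enumerateCandidates(1, c(8, 8)),
                   c("AAAAAAAA", "CCCCCCCC"))
  cands <- enumerateCandidates(2, c(8, 12))
  # unit CA and unit AC yield one candidate per length
  expect_identical(sum(grepl("^(AC)+$|^(CA)+$", cands)), 3L)  # 8, 10, 12
  expect_identical(enumerateCandidates(1:2, c(9, 8)), character(0))
  # primitive units only: no AA "dimer" duplicating the homopolymer
  units <- unique(vapply(enumerateCandidates(), canonicalUnit, character(1)))
  expect_false("AA" %in% units)
})

test_that("matrix simplification keeps the most likely base with alphabetic ties", {
  m <- matrix(c(0.6, 0.2, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25,
                0.1, 0.2, 0.3, 0.4), 4, 3,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_identical(simplifyMotif(m), "AAT")
  expect_identical(simplifyMotif(consensusToMatrix("CACA")), "CACA")
  expect_identical(simplifyMotif(consensusToMatrix("GATTA", "soft")),
                   "GATTA")
})

test_that("differential enrichment finds a motif planted only into high bins", {
  # two-level landscape: high bins at 5x the planting intensity of low bins
  rates <- list(c1 = c(rep(1, 250), rep(5, 250)),
                c2 = c(rep(5, 250), rep(1, 250)))
  map <- RecombinationMap(rates, binSize = 1000)
  b <- plantMotifs(map, "[CA]6", baseIntensity = 0, coupling = 0.4,
                   seed = 17)
  labels <- splitHighLow(b@map)
  cands <- enumerateCandidates()
  de <- differentialEnrichment(b@genome, labels, cands)
  hit <- de[de$candidate == "ACACACACACAC", ]
  expect_identical(hit$unit, "AC")
  expect_gt(hit$count_high, 4 * max(1, hit$count_low))
  expect_lt(hit$E_value, 1e-10)
  # an exact hypergeometric cross-check through fisher.test on the 2x2 table
  ft <- fisher.test(matrix(c(hit$count_high,
                             hit$positions_high - hit$count_high,
                             hit$count_low,
                             hit$positions_low - hit$count_low), 2),
                    alternative = "greater")
  expect_equal(hit$p_value, ft$p.value, tolerance = 1e-9)
  expect_equal(hit$E_value, hit$p_value * length(cands), tolerance = 1e-12)
  # E-sorted output
  expect_false(is.unsorted(de$E_value))
})

test_that("degenerate splits and empty candidate lists are refused", {
  m <- RecombinationMap(list(c1 = rep(2, 20)), binSize = 1000)
  b <- plantMotifs(m, "[CA]6", baseIntensity = 0, coupling = 0, seed = 1)
  labels <- splitHighLow(b@map)   # all rates equal -> high empty
  expect_error(differentialEnrichment(b@genome, labels, "ACACACAC"),
               "degenerate")
  m2 <- RecombinationMap(list(c1 = c(rep(1, 10), rep(2, 10))),
                         binSize = 1000)
  b2 <- plantMotifs(m2, "[CA]6", baseIntensity = 0, coupling = 0, seed = 1)
  expect_error(differentialEnrichment(b2@genome, splitHighLow(b2@map),
                                      character(0)), "empty")
})

test_that("enrichment p-values are uniform-conservative under label shuffling", {
  cands <- enumerateCandidates()
  hits <- 0L
  total <- 0L
  for (s in 1:20) {
    man <- list(seed = 4000 + s, chromLengths = list(c1 = 5e4, c2 = 5e4),
                landscape = list(shape = "flat", noiseCV = 0.3))
    b <- generateFixture(man)
    labels <- splitHighLow(b@map)
    set.seed(9000 + s)
    labels$label <- sample(labels$label)   # break any rate-genome link
    de <- differentialEnrichment(b@genome, labels, cands)
    hits <- hits + sum(de$p_value < 0.05)
    total <- total + nrow(de)
  }
  expect_lte(hits / total, 0.07)
})

test_that("consensus construction filters, groups, sizes and flags correctly", {
  recs <- data.frame(
    species = c("speciesA", "speciesB", "speciesA", "speciesA"),
    motif = c(strrep("CA", 7), strrep("AC", 6), strrep("TA", 5),
              strrep("A", 12)),
    E_value = c(1e-5, 5e-3, 9e-3, 0.02))
  cs <- buildConsensusSet(recs)
  expect_identical(nrow(cs), 2L)
  # [CA]7 + [AC]6 merge to the 12-bp consensus representable in both
  ca <- cs[cs$unit == "AC", ]
  expect_identical(ca$length, 12L)
  expect_identical(ca$count, 6L)
  expect_false(ca$single_species)
  expect_identical(ca$id, "C1")
  # [TA]5 survives in one species and is flagged
  ta <- cs[cs$unit == "AT", ]
  expect_identical(ta$length, 10L)
  expect_true(ta$single_species)
  # the E = 0.02 homopolymer is filtered out entirely
  expect_false("A" %in% cs$unit)

  # all-filtered input gives an empty (not error) set
  none <- buildConsensusSet(data.frame(species = "s", motif = "ACACACAC",
                                       E_value = 0.5))
  expect_identical(nrow(none), 0L)
})

test_that("consensus construction is idempotent and strand/rotation invariant", {
  recs <- data.frame(
    species = c("A", "B", "A", "B"),
    motif = c(strrep("CA", 7), strrep("AC", 6), strrep("GCA", 4),
              strrep("AGC", 3)),
    E_value = c(1e-5, 5e-3, 1e-4, 2e-3))
  cs <- buildConsensusSet(recs)
  # feed its own output back (one record per contributing species, E = 0)
  again <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
    sp <- strsplit(cs$species[i], "+", fixed = TRUE)[[1]]
    data.frame(species = sp, motif = cs$consensus[i], E_value = 0)
  }))
  cs2 <- buildConsensusSet(again)
  expect_identical(cs2$unit, cs$unit)
  expect_identical(cs2$length, cs$length)
  expect_identical(cs2$single_species, cs$single_species)

  # reverse-complementing or rotating the records changes nothing
  recsRC <- recs
  recsRC$motif <- revComp(recs$motif)
  csRC <- buildConsensusSet(recsRC)
  expect_identical(csRC$unit, cs$unit)
  expect_identical(csRC$length, cs$length)
})
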