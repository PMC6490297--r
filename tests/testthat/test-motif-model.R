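test_that("consensus strings become dialect-shaped probability matrices", {
  hardA <- consensusToMatrix("AAA", "hard")
  expect_identical(motifLength(hardA), 3L)
  expect_true(all(motifProbs(hardA)["A", ] == 1))
  expect_true(all(motifProbs(hardA)[c("C", "G", "T"), ] == 0))

  softCA <- consensusToMatrix("CA", "soft")
  p <- motifProbs(softCA)
  expect_equal(p[, 1], c(A = 0.01, C = 0.97, G = 0.01, T = 0.01))
  expect_equal(p[, 2], c(A = 0.97, C = 0.01, G = 0.01, T = 0.01))
  expect_equal(colSums(p), rep(1, 2), tolerance = 1e-12)

  expect_error(consensusToMatrix(""), "non-empty")
  expect_error(consensusToMatrix("ACGN"), "ambiguity|A, C, G, T")
  # bracket shorthand is expanded first
  expect_identical(motifLength(consensusToMatrix("[GCA]4")), 12L)
})

test_that("background estimation symmetrizes strands and regularizes zeros", {
  expect_equal(estimateBackground("ACGTACGT"),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  bgA <- estimateBackground("AAAA")
  expect_equal(unname(bgA["A"]), unname(bgA["T"]))
  expect_true(all(bgA > 0))
  expect_equal(sum(bgA), 1, tolerance = 1e-12)
  expect_lt(abs(bgA[["A"]] - 0.5), 1e-5)
  expect_error(estimateBackground("NNNN"), "no A/C/G/T")
})

test_that("log-odds scores follow the pseudocount closed form", {
  sm <- logOdds(consensusToMatrix("A"), uniformBg, pseudocount = 0.1)
  s <- scoreValues(sm)
  expect_equal(unname(s["A", 1]), log2(((1 + 0.1 * 0.25) / 1.1) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(s["C", 1]), log2(((0.1 * 0.25) / 1.1) / 0.25),
               tolerance = 1e-12)

  # a column equal to the background scores 0 everywhere, any pseudocount
  pp <- (matrix(0.25, 4, 1) + 0.3 * 0.25) / 1.3
  expect_equal(log2(pp / 0.25), matrix(0, 4, 1), tolerance = 1e-12)

  # soft dialect, tiny pseudocount: match score tends to log2(0.97/bg)
  smSoft <- logOdds(consensusToMatrix("A", "soft"), uniformBg,
                    pseudocount = 1e-9)
  expect_equal(unname(scoreValues(smSoft)["A", 1]), log2(0.97 / 0.25),
               tolerance = 1e-6)

  expect_error(logOdds(consensusToMatrix("A"), uniformBg, pseudocount = 0),
               "pseudocount")
})

test_that("exact p-value tables match closed forms and brute enumeration", {
  tbl1 <- scorePvalueTable(logOdds(consensusToMatrix("A"), uniformBg))
  expect_equal(lookupPvalue(tbl1, maxAttainableScore(tbl1)), 0.25)

  tbl11 <- scorePvalueTable(logOdds(consensusToMatrix("[A]11"), uniformBg))
  expect_equal(lookupPvalue(tbl11, maxAttainableScore(tbl11)), 0.25^11,
               tolerance = 1e-15)

  # scores below the attainable range have tail 1
  expect_identical(lookupPvalue(tbl11, -1e6), 1)

  # brute-force enumeration oracle at the shared discretization, L <= 6
  bgAT <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (mot in c("ACACAC", "GCAGC", "TATA")) {
    tbl <- scorePvalueTable(logOdds(consensusToMatrix(mot), bgAT))
    bf <- bruteTail(tbl@intScores, bgAT)
    got <- recmotifs:::.lookupPvalueInt(tbl, bf$score)
    expect_lt(max(abs(got - bf$tail)), 1e-12)
  }
})

test_that("scanning a homopolymer genome reports every window on one strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000)))
  occ <- scanGenome(g, "[A]11", uniformBg)
  expect_identical(sum(strand(occ) == "+"), 990L)
  expect_identical(sum(strand(occ) == "-"), 0L)
  expect_equal(unique(occ$pvalue), 0.25^11, tolerance = 1e-15)
  expect_identical(S4Vectors::metadata(occ)$nScannedPositions, 2L * 990L)

  # genome without A or T cannot contain an A-run on either strand
  g2 <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 500)))
  expect_identical(length(scanGenome(g2, "[A]11", uniformBg)), 0L)
})

test_that("scan hits agree with naive per-window scoring, including N handling", {
  set.seed(5)
  s <- sample(c("A", "C", "G", "T", "N"), 20000, TRUE,
              prob = c(.27, .23, .22, .27, .01))
  g <- Biostrings::DNAStringSet(c(chrX = paste(s, collapse = "")))
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  codes <- recmotifs:::.dnaCodes(g[[1]])
  for (mot in c("[A]11", "[GCA]4")) {
    occ <- scanGenome(g, mot, bg, pThreshold = 1e-3)
    mm <- consensusToMatrix(mot)
    tbl <- scorePvalueTable(logOdds(mm, bg))
    totF <- recmotifs:::.windowIntScores(codes, tbl@intScores)
    pF <- recmotifs:::.lookupPvalueInt(tbl, totF)
    expect_setequal(start(occ[strand(occ) == "+"]),
                    which(!is.na(totF) & pF <= 1e-3))
    rcm <- new("MotifMatrix", name = "rc",
               probs = recmotifs:::.revCompProbs(motifProbs(mm)),
               dialect = "hard")
    tblR <- scorePvalueTable(logOdds(rcm, bg))
    totR <- recmotifs:::.windowIntScores(codes, tblR@intScores)
    pR <- recmotifs:::.lookupPvalueInt(tblR, totR)
    expect_setequal(start(occ[strand(occ) == "-"]),
                    which(!is.na(totR) & pR <= 1e-3))
    expect_identical(S4Vectors::metadata(occ)$nScannedPositions,
                     sum(!is.na(totF)) + sum(!is.na(totR)))
  }
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  set.seed(9)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                  collapse = "")
  g <- Biostrings::DNAStringSet(c(c1 = seqstr))
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- "c1"
  occ <- scanGenome(g, "[TA]5", uniformBg, pThreshold = 1e-3)
  occRC <- scanGenome(grc, "[TA]5", uniformBg, pThreshold = 1e-3)
  n <- 30000L
  mirrored <- data.frame(start = n - end(occ) + 1L,
                         strand = ifelse(strand(occ) == "+", "-", "+"))
  got <- data.frame(start = start(occRC), strand = as.character(strand(occRC)))
  o1 <- order(mirrored$start, mirrored$strand)
  o2 <- order(got$start, got$strand)
  expect_identical(mirrored[o1, ], got[o2, ], ignore_attr = TRUE)

  strict <- scanGenome(g, "[TA]5", uniformBg, pThreshold = 1e-5)
  key <- function(x) paste(start(x), strand(x))
  expect_true(all(key(strict) %in% key(occ)))
  expect_true(all(strict$pvalue <= 1e-5))
})

test_that("every planted copy is recovered by the scanner", {
  b <- makeCoupledBundle(71, chromLengthBp = 2e5, nChrom = 1,
                         baseIntensity = 0.6, coupling = 0, noiseCV = 0)
  occ <- scanGenome(b@genome, "[CA]6", estimateBackground(b@genome))
  key <- paste(as.character(seqnames(occ)), start(occ), strand(occ))
  tkey <- paste(as.character(seqnames(b@truth)), start(b@truth),
                strand(b@truth))
  expect_gt(length(tkey), 50)
  expect_true(all(tkey %in% key))
})

test_that("q-scores follow BH with the scanned-positions denominator", {
  occ1 <- fakeOccurrences("c1", 1, q = 0)
  occ1$pvalue <- 0.01
  expect_equal(computeQvalues(occ1, nTests = 1)$qvalue, 0.01)

  occ3 <- fakeOccurrences("c1", c(1, 40, 90), q = c(0, 0, 0))
  occ3$pvalue <- c(0.01, 0.02, 0.03)
  expect_equal(computeQvalues(occ3, nTests = 3)$qvalue,
               c(0.03, 0.03, 0.03))

  # denominator = scanned positions, not occurrence count
  expect_equal(computeQvalues(occ3, nTests = 300)$qvalue,
               pmin(1, naiveBH(c(0.01, 0.02, 0.03), 300)))

  set.seed(12)
  p <- runif(200)^2
  occN <- fakeOccurrences("c1", seq(1, by = 20, length.out = 200), q = 0)
  occN$pvalue <- p
  q <- computeQvalues(occN, nTests = 5000)$qvalue
  expect_equal(q, pmin(1, naiveBH(p, 5000)))
  expect_false(is.unsorted(q[order(p)]))    # q monotone in p
  expect_error(computeQvalues(occN, nTests = 10), "nTests")
})

test_that("occurrence tables write both TSV and BED layouts", {
  occ <- fakeOccurrences("c1", c(5, 25), q = c(0.1, 0.4))
  occ$score <- c(10, 8)
  p1 <- withr::local_tempfile()
  writeOccurrences(occ, p1)
  tab <- read.delim(p1)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$start, c(5L, 25L))
  p2 <- withr::local_tempfile()
  writeOccurrences(occ, p2, format = "bed")
  bed <- read.delim(p2, header = FALSE)
  expect_identical(bed$V2, c(4L, 24L))
})
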