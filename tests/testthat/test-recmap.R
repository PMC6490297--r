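writeToyMap <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  writeLines(c("chrom,start,end,rate", lines), path)
  path
}

test_that("map CSV reading parses bins, tolerates row order, rejects bad bins", {
  p <- writeToyMap(c("chr1,0,1000,1.5", "chr1,1000,2000,2.5",
                     "chr1,2000,3000,0.5"))
  m <- readRecombinationMap(p)
  expect_s4_class(m, "RecombinationMap")
  expect_identical(binSize(m), 1000L)
  expect_equal(rateValues(m, "chr1"), c(1.5, 2.5, 0.5))

  p2 <- writeToyMap(c("chr1,2000,3000,0.5", "chr1,0,1000,1.5",
                      "chr1,1000,2000,2.5"))
  expect_equal(rateValues(readRecombinationMap(p2), "chr1"),
               c(1.5, 2.5, 0.5))

  # gap -> missing bin
  p3 <- writeToyMap(c("chr1,0,1000,1", "chr1,2000,3000,3"))
  expect_equal(rateValues(readRecombinationMap(p3), "chr1"), c(1, NA, 3))

  # interior bin narrower than binSize
  p4 <- writeToyMap(c("chr1,0,1000,1", "chr1,1000,1500,2",
                      "chr1,2000,3000,3"))
  expect_error(readRecombinationMap(p4), "non-uniform|grid")
  # negative rate
  p5 <- writeToyMap(c("chr1,0,1000,-1"))
  expect_error(readRecombinationMap(p5), "negative")
  # overlap
  p6 <- writeToyMap(c("chr1,0,1000,1", "chr1,500,1500,2"))
  expect_error(readRecombinationMap(p6), "overlap|grid")
})

test_that("map CSV writing round-trips rates at full precision", {
  m <- RecombinationMap(list(chr1 = c(pi, exp(1), 1 / 3)), binSize = 500)
  p <- withr::local_tempfile(fileext = ".csv")
  writeRecombinationMap(m, p)
  expect_identical(rateValues(readRecombinationMap(p), "chr1"),
                   c(pi, exp(1), 1 / 3))
})

test_that("anchor normalization forces the anchored genetic length", {
  # uniform rho map over 1 Mb, one anchor of 2 cM -> every bin exactly 2
  m <- RecombinationMap(list(chr1 = rep(0.007, 1000)), binSize = 1000,
                        units = "rho")
  anchors <- data.frame(chrom = "chr1", start = 0, end = 1e6, cM = 2)
  out <- normalizeToCM(m, anchors)
  expect_identical(rateUnits(out), "cM_per_Mb")
  expect_equal(rateValues(out, "chr1"), rep(2, 1000), tolerance = 1e-12)

  # scale invariance of the input rho
  m2 <- RecombinationMap(list(chr1 = rep(0.014, 1000)), binSize = 1000,
                         units = "rho")
  expect_equal(rateValues(normalizeToCM(m2, anchors), "chr1"),
               rateValues(out, "chr1"), tolerance = 1e-12)

  # two anchors: re-summing the output over the anchors gives the cM total
  set.seed(8)
  r <- runif(2000, 0.001, 0.02)
  m3 <- RecombinationMap(list(chrA = r), binSize = 1000, units = "rho")
  a2 <- data.frame(chrom = "chrA", start = c(0, 1e6), end = c(5e5, 1.8e6),
                   cM = c(1, 3))
  out3 <- normalizeToCM(m3, a2)
  rr <- rateValues(out3, "chrA")
  got <- sum(rr[1:500]) / 1000 + sum(rr[1001:1800]) / 1000  # cM/Mb * 1 kb
  expect_equal(got, 4, tolerance = 1e-9)

  expect_error(normalizeToCM(out, anchors), "rho units")
  z <- RecombinationMap(list(chr1 = rep(0, 1000)), binSize = 1000,
                        units = "rho")
  expect_error(normalizeToCM(z, anchors), "zero rho")
})

test_that("moving median matches the sort oracle and keeps map membership", {
  m <- RecombinationMap(list(chr1 = c(1, 5, 2, 8, 3)), binSize = 1000)
  out <- rateValues(movingMedian(m, 3), "chr1")
  expect_identical(out[2:4], c(2, 5, 3))
  expect_identical(out, naiveMovingMedian(c(1, 5, 2, 8, 3), 3))

  set.seed(33)
  x <- rgamma(2000, 2, 1)
  mm <- RecombinationMap(list(chr1 = x), binSize = 1000)
  for (w in c(5, 25, 101)) {
    sm <- rateValues(movingMedian(mm, w), "chr1")
    expect_identical(sm, naiveMovingMedian(x, w))
    h <- (w - 1) / 2
    interior <- (h + 1):(2000 - h)
    member <- vapply(interior, function(i) sm[i] %in% x[(i - h):(i + h)],
                     logical(1))
    expect_true(all(member))
  }
})

test_that("moving median handles constants, monotone tracks, w = 1 and missing bins", {
  const <- RecombinationMap(list(chr1 = rep(4, 50)), binSize = 1000)
  expect_identical(rateValues(movingMedian(const, 7), "chr1"), rep(4, 50))

  mono <- sort(rgamma(60, 2))
  mm <- RecombinationMap(list(chr1 = mono), binSize = 1000)
  expect_false(is.unsorted(rateValues(movingMedian(mm, 9), "chr1")))

  x <- c(2, 9, 4, 7, 1, 6)
  m1 <- RecombinationMap(list(chr1 = x), binSize = 1000)
  expect_identical(rateValues(movingMedian(m1, 1), "chr1"), x)

  withNA <- c(1, NA, 3, NA, NA, 6, 7)
  mna <- RecombinationMap(list(chr1 = withNA), binSize = 1000)
  sm <- rateValues(movingMedian(mna, 3), "chr1")
  expect_identical(sm, naiveMovingMedian(withNA, 3))
  expect_false(anyNA(sm))  # every window here has at least one value

  expect_error(movingMedian(m1, 4), "odd")
  expect_error(movingMedian(m1, 101), "exceeds")
})

test_that("tricube local regression reproduces lines and matches the lm oracle", {
  lin <- 0.5 + 0.02 * seq_len(120)
  m <- RecombinationMap(list(chr1 = lin), binSize = 1000)
  for (span in c(0.2, 0.5, 1))
    expect_equal(rateValues(loessSmooth(m, span), "chr1"), lin,
                 tolerance = 1e-9)

  const <- RecombinationMap(list(chr1 = rep(2, 40)), binSize = 1000)
  expect_equal(rateValues(loessSmooth(const, 0.4), "chr1"), rep(2, 40),
               tolerance = 1e-12)

  step <- c(rep(1, 40), rep(5, 40))
  ms <- RecombinationMap(list(chr1 = step), binSize = 1000)
  expect_equal(rateValues(loessSmooth(ms, 0.3), "chr1"),
               naiveTricube(step, 0.3), tolerance = 1e-9)

  expect_error(loessSmooth(ms, 0), "span")
  tiny <- RecombinationMap(list(chr1 = c(1:5, rep(NA, 15))), binSize = 1000)
  expect_error(loessSmooth(tiny, 0.5), "10 non-missing")
})

test_that("median split labels bins by the strict-majority rule", {
  m <- RecombinationMap(list(chr1 = c(1, 2, 3, 4)), binSize = 1000)
  expect_identical(as.character(splitHighLow(m)$label),
                   c("low", "low", "high", "high"))

  # tie at the median goes low (strictly greater than median -> high)
  m2 <- RecombinationMap(list(chr1 = c(1, 2, 2, 3)), binSize = 1000)
  expect_identical(as.character(splitHighLow(m2)$label),
                   c("low", "low", "low", "high"))

  # all equal: high empty, low = all
  m3 <- RecombinationMap(list(chr1 = rep(2, 5)), binSize = 1000)
  expect_identical(unique(as.character(splitHighLow(m3)$label)), "low")

  # missing bins are excluded; non-missing bins partition exactly
  set.seed(4)
  r <- c(rgamma(50, 2), NA, NA)
  m4 <- RecombinationMap(list(chr1 = r), binSize = 1000)
  lab <- as.character(splitHighLow(m4)$label)
  expect_identical(lab[is.na(r)], rep("excluded", 2))
  expect_identical(sum(lab != "excluded"), 50L)
  med <- median(r, na.rm = TRUE)
  expect_identical(lab[!is.na(r)],
                   ifelse(r[!is.na(r)] > med, "high", "low"))

  mAllNA <- RecombinationMap(list(chr1 = rep(NA_real_, 10)), binSize = 1000)
  expect_error(splitHighLow(mAllNA), "missing")
})
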