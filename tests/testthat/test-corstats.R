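# COR length nulls, exponential fit, matched-control sampling, feature
# enrichment, GC statistics.

test_that("expected COR length is twice the mean gap (inspection paradox)", {
  m <- MarkerSet(rep("s", 3), c(0L, 7L, 14L), rep("A", 3), rep("C", 3))
  nul <- expectedCORLength(m)
  expect_equal(nul$meanGap, 7)
  expect_equal(nul$expectedCORLength, 14)
  m1 <- MarkerSet(rep("s", 11), 0:10, rep("A", 11), rep("C", 11))
  expect_equal(expectedCORLength(m1)$expectedCORLength, 2)
  expect_error(expectedCORLength(m[1]), "at least 2")

  mc <- containingGapMean(nGaps = 100000L, nPoints = 50000L, meanGap = 7,
                          seed = 5L)
  expect_lt(abs(mc$mean - 14), 3 * mc$se)
  expect_lt(abs(mc$ratio - 2), 3 * mc$se / 7)
})

test_that("exponential KS fit is calibrated, rejects degenerate data, and matches the direct statistic", {
  hits <- sum(vapply(1:100, function(s) {
    set.seed(s)
    fitExponentialKS(rexp(500, 1 / 50))$p.value > 0.05
  }, logical(1)))
  expect_gte(hits, 90L)

  expect_lt(fitExponentialKS(rep(30, 100))$p.value, 1e-6)

  set.seed(99)
  x <- rexp(10, 1 / 20)
  fit <- fitExponentialKS(x)
  expect_equal(fit$statistic, ksStatOracle(x, fit$rate), tolerance = 1e-12)
  expect_error(fitExponentialKS(c(1, -2, 3, 4, 5)), "positive")
})

test_that("matched-region sampling preserves lengths, avoids CORs, honours forced choices", {
  # forced choice: exactly one other gap of the COR's length
  m <- MarkerSet(rep("s1", 4), c(0L, 10L, 15L, 25L), rep("A", 4), rep("C", 4))
  cor1 <- CORSet(data.frame(offspring = "o", scaffold = "s1", left = 0L,
                            right = 10L, length = 10L, orientation = "A->B",
                            left_run = 10L, right_run = 10L, class = "simple",
                            stringsAsFactors = FALSE))
  sets <- sampleMatchedRegions(cor1, m, nSets = 20L, seed = 2L)
  for (s in sets) {
    expect_identical(s$left, 15L)
    expect_identical(s$right, 25L)
  }

  cfg <- testConfig(genomeLength = 60000L, nScaffolds = 1L, seed = 61L,
                    coPerOffspring = 4, nOffspring = 8L)
  sim <- simulateCross(cfg)
  mk <- callMarkers(sim$parentA, sim$parentB)
  cors <- CORSet(do.call(rbind, lapply(names(sim$offspring), function(id)
    corTable(detectCrossovers(assignOrigin(sim$offspring[[id]], mk, id),
                              k = 10)))))
  expect_gt(length(cors), 5L)
  sets <- sampleMatchedRegions(cors, mk, nSets = 200L, seed = 3L)
  rec <- corTable(cors)
  lengthsOK <- vapply(sets, function(s)
    identical(sort(s$length), sort(rec$length)), logical(1))
  expect_true(all(lengthsOK))                           # multiset preserved
  overlaps <- vapply(sets, function(s)
    sum(vapply(seq_len(nrow(s)), function(i)
      any(s$left[i] < rec$right & rec$left < s$right[i]), logical(1))),
    integer(1))
  expect_identical(sum(overlaps), 0L)                   # never touch a COR
})

test_that("control exon content tracks the gap pool when divergence is exon-neutral", {
  cfg <- testConfig(genomeLength = 60000L, nScaffolds = 1L, seed = 67L,
                    exonDivergenceFactor = 1, coPerOffspring = 4,
                    nOffspring = 8L)
  sim <- simulateCross(cfg)
  mk <- callMarkers(sim$parentA, sim$parentB)
  cors <- CORSet(do.call(rbind, lapply(names(sim$offspring), function(id)
    corTable(detectCrossovers(assignOrigin(sim$offspring[[id]], mk, id),
                              k = 10)))))
  sets <- sampleMatchedRegions(cors, mk, nSets = 300L, seed = 5L)
  ctlFrac <- mean(vapply(sets, function(s)
    mean(meioscan:::.withinFeature(s, sim$annotation, "exon")), numeric(1)))
  gaps <- markerGaps(mk)
  poolFrac <- mean(meioscan:::.withinFeature(gaps, sim$annotation, "exon"))
  expect_lt(abs(ctlFrac - poolFrac), 0.05)
})

test_that("feature enrichment handles saturated and empty annotations and detects exon-biased COs", {
  m <- MarkerSet(rep("s1", 40), seq(0L, 390L, 10L), rep("A", 40), rep("C", 40))
  rec <- data.frame(offspring = "o", scaffold = "s1",
                    left = c(100L, 200L), right = c(110L, 210L), length = 10L,
                    orientation = "A->B", left_run = 10L, right_run = 10L,
                    class = "simple", stringsAsFactors = FALSE)
  cors <- CORSet(rec)
  allEx <- annotationAll("exon", 400L, "s1")
  resAll <- permutationEnrichment(cors, m, allEx, nPerm = 99L, seed = 1L)
  expect_identical(resAll$observed, 2L)
  expect_equal(resAll$pEnrich, 1)
  noEx <- annotationAll("intergenic", 400L, "s1")
  expect_identical(
    permutationEnrichment(cors, m, noEx, nPerm = 19L, seed = 1L)$observed, 0L)

  # power: 5x exon-weighted CO placement is detected as enrichment
  hits <- vapply(1:20, function(s) {
    cfg <- testConfig(genomeLength = 80000L, nScaffolds = 1L,
                      coModel = "exon_biased", coExonWeight = 5,
                      coPerOffspring = 4.2, nOffspring = 17L,
                      seed = 700L + s)
    sim <- simulateCross(cfg)
    mk <- callMarkers(sim$parentA, sim$parentB)
    cors <- CORSet(do.call(rbind, lapply(names(sim$offspring), function(id)
      corTable(detectCrossovers(assignOrigin(sim$offspring[[id]], mk, id),
                                k = 10)))))
    permutationEnrichment(cors, mk, sim$annotation, nPerm = 199L,
                          seed = s)$pEnrich < 0.05
  }, logical(1))
  expect_gte(sum(hits), 16L)
})

test_that("GC windows and the 2x2 chi-square match hand arithmetic", {
  allG <- c(s1 = strrep("G", 1000))
  ctr <- data.frame(scaffold = "s1", pos = c(200, 600))
  gw <- gcWindows(allG, ctr, widths = c(20L, 100L))
  expect_true(all(gw$windows$gc == 1))
  repAT <- c(s1 = strrep("ATGC", 250))
  expect_equal(gcWindows(repAT, ctr, widths = 100L)$windows$gc, 0.5,
               tolerance = 0.02)

  res <- gcChi2(62, 38, 58, 42)
  O <- matrix(c(62, 38, 58, 42), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(gcChi2(58, 42, 62, 38)$chi2, res$chi2)
  ident <- gcChi2(50, 50, 500, 500)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p.value, 1)
  expect_error(gcChi2(0, 0, 5, 5), "margin")

  # generator truth: exon-elevated GC declines toward background
  cfg <- testConfig(genomeLength = 100000L, nScaffolds = 1L, seed = 71L,
                    exonGC = 0.62, backgroundGC = 0.58)
  par <- simulateParents(cfg)
  ex <- par$annotation[par$annotation$type == "exon"]
  wide <- GenomicRanges::width(ex) >= 200
  mid <- floor((GenomicRanges::start(ex)[wide] + GenomicRanges::end(ex)[wide]) / 2)
  ctr2 <- data.frame(scaffold = "scaffold_1", pos = mid - 1L)
  gw2 <- gcWindows(par$parentA, ctr2, widths = c(100L, 20000L),
                   annotation = par$annotation)
  expect_equal(gw2$windows$gc[1], 0.62, tolerance = 0.015)
  expect_lt(gw2$windows$gc[2], 0.61)
  expect_equal(gw2$genomeGC, 0.60, tolerance = 0.01)
})

test_that("minimum expected crossover bookkeeping multiplies chromosomes by offspring", {
  expect_identical(expectedMinimumCOs(11, 17), 187L)
  expect_identical(expectedMinimumCOs(3, 2), 6L)
})
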