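# Population statistics: joint site filter, pi, MAF bootstrap, site
# classification, Tajima's D.

test_that("joint site filter keeps fully callable sites and drops thin ones", {
  full <- matrix(rep(c("A", "C"), each = 5), nrow = 10, ncol = 20)
  pa <- HaplotypePanel(list(s1 = apply(full, 1, paste, collapse = "")),
                       panelID = "A")
  pb <- HaplotypePanel(list(s1 = apply(full, 1, paste, collapse = "")),
                       panelID = "B")
  sp <- sampleSites(pa, pb, minN = 10L, sampleN = 10L, seed = 1L)
  expect_identical(sampledSites(sp[[1]], "s1"), 0:19)
  expect_identical(sort(as.integer(sp[[1]]@chosen[["s1"]][, 1])), 1:10)

  thin <- full
  thin[1:2, 5] <- "-"               # only 8 callable at site 5 in panel A
  pa2 <- HaplotypePanel(list(s1 = apply(thin, 1, paste, collapse = "")))
  sp2 <- sampleSites(pa2, pb, minN = 9L, sampleN = 9L, seed = 1L)
  expect_false(4L %in% sampledSites(sp2[[1]], "s1"))
  expect_false(4L %in% sampledSites(sp2[[2]], "s1"))   # joint rule

  expect_error(sampleSites(pa, pb, minN = 9L, sampleN = 10L), "sampleN")

  # determinism
  spA <- sampleSites(pa2, pb, minN = 9L, sampleN = 9L, seed = 7L)
  spB <- sampleSites(pa2, pb, minN = 9L, sampleN = 9L, seed = 7L)
  expect_identical(spA[[1]]@chosen, spB[[1]]@chosen)
})

test_that("window pi equals hand and brute-force values", {
  idc <- matrix("A", nrow = 10, ncol = 50)
  spi <- spFromMatrix(idc)
  ctr <- data.frame(scaffold = "scaffold_1", pos = 25)
  expect_equal(piWindows(spi, ctr, widths = 100L)$pi, 0)

  two <- matrix("A", nrow = 2, ncol = 100)
  two[2, 13] <- "G"
  sp2 <- spFromMatrix(two)
  expect_equal(piWindows(sp2, data.frame(scaffold = "scaffold_1", pos = 50),
                         widths = 300L)$pi, 0.01)

  set.seed(11)
  rnd <- matrix(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                nrow = 10, ncol = 20)
  spr <- spFromMatrix(rnd)
  got <- piWindows(spr, data.frame(scaffold = "scaffold_1", pos = 10),
                   widths = 100L)$pi
  expect_equal(got, bruteForcePi(rnd), tolerance = 1e-12)
  expect_equal(piGenomeWide(spr), bruteForcePi(rnd), tolerance = 1e-12)

  # empty window flagged missing
  empty <- piWindows(spr, data.frame(scaffold = "scaffold_1", pos = 1e6),
                     widths = 10L)
  expect_identical(empty$nSites, 0L)
  expect_true(is.na(empty$pi))
})

test_that("sampled-panel pi matches the panel's realized diversity", {
  cfg <- testConfig(genomeLength = 120000L, nScaffolds = 1L, seed = 83L)
  par <- simulateParents(cfg)
  pan1 <- simulatePopulation(par$parentA, par$annotation, cfg, 1L)
  pan2 <- simulatePopulation(par$parentA, par$annotation, cfg, 2L)
  sp <- sampleSites(pan1, pan2, seed = 5L)
  expect_lt(abs(piGenomeWide(sp[[1]]) - panelPi(pan1)) / panelPi(pan1), 0.05)
})

test_that("pi contrast: self-controls coincide; exon-placed CORs show a local dip", {
  cfg <- testConfig(genomeLength = 120000L, nScaffolds = 1L, seed = 89L,
                    coModel = "exon_biased", coExonWeight = 8,
                    coPerOffspring = 5, nOffspring = 17L,
                    popExonFactor = 0.35)
  sim <- simulateCross(cfg)
  mk <- callMarkers(sim$parentA, sim$parentB)
  cors <- CORSet(do.call(rbind, lapply(names(sim$offspring), function(id)
    corTable(detectCrossovers(assignOrigin(sim$offspring[[id]], mk, id),
                              k = 10)))))
  pan <- simulatePopulation(sim$parentA, sim$annotation, cfg, 1L)
  pan2 <- simulatePopulation(sim$parentA, sim$annotation, cfg, 2L)
  sp <- sampleSites(pan, pan2, seed = 7L)[[1]]

  rec <- corTable(cors)
  self <- list(rec[, c("scaffold", "left", "right", "length")])
  pcSelf <- piContrast(sp, cors, self, widths = c(200L, 1000L))
  expect_equal(pcSelf$obsMean, pcSelf$nullMean, tolerance = 1e-12)

  ctl <- sampleMatchedRegions(cors, mk, nSets = 60L, seed = 9L)
  pc <- piContrast(sp, cors, ctl, widths = c(300L, 700L, 20000L))
  expect_lt(pc$obsMean[1], pc$nullMean[1])
  expect_lt(pc$obsMean[2], pc$nullMean[2])
  # at genome scale the curves converge
  expect_lt(abs(pc$obsMean[3] - pc$nullMean[3]) / pc$nullMean[3], 0.1)
})

test_that("MAF profile: degenerate cases and the rare-variant shift in CORs", {
  # every polymorphic site a singleton: MAF constant, CI width zero
  sing <- matrix("A", nrow = 10, ncol = 30)
  for (j in seq(2, 30, 2)) sing[1 + (j %% 9), j] <- "T"
  sps <- spFromMatrix(sing)
  corsAll <- CORSet(data.frame(offspring = "o", scaffold = "scaffold_1",
                               left = 0L, right = 14L, length = 14L,
                               orientation = "A->B", left_run = 10L,
                               right_run = 10L, class = "simple",
                               stringsAsFactors = FALSE))
  mp <- mafProfile(sps, corsAll, window = 60L, nBoot = 50L, seed = 1L)
  expect_equal(mp$corMean, 0.1)
  expect_equal(diff(mp$corCI), 0)

  # identical MAF multisets give p = 1
  expect_equal(suppressWarnings(
    stats::wilcox.test(c(.1, .2, .3), c(.1, .2, .3))$p.value), 1)

  # generator truth: exon-biased CORs + exon-suppressed founder variation
  cfg <- testConfig(genomeLength = 200000L, nScaffolds = 1L, seed = 97L,
                    coModel = "exon_biased", coExonWeight = 10,
                    coPerOffspring = 12, nOffspring = 17L,
                    popExonFactor = 0.2)
  sim <- simulateCross(cfg)
  mk <- callMarkers(sim$parentA, sim$parentB)
  cors <- CORSet(do.call(rbind, lapply(names(sim$offspring), function(id)
    corTable(detectCrossovers(assignOrigin(sim$offspring[[id]], mk, id),
                              k = 10)))))
  pan <- simulatePopulation(sim$parentA, sim$annotation, cfg, 1L)
  pan2 <- simulatePopulation(sim$parentA, sim$annotation, cfg, 2L)
  sp <- sampleSites(pan, pan2, seed = 11L)[[1]]
  mp2 <- mafProfile(sp, cors, window = 10000L, nBoot = 200L, seed = 13L)
  expect_gte(mp2$nCor + mp2$nCtrl, 500L)
  expect_lt(mp2$corMean, mp2$ctrlMean)
  expect_lt(mp2$p.value, 0.05)
  # bootstrap CI covers the observed mean by construction
  expect_gte(mp2$corMean, mp2$corCI[1])
  expect_lte(mp2$corMean, mp2$corCI[2])
})

test_that("site classification follows the genetic code on both strands", {
  # one '+' gene: exon covers positions 1..9 (1-based), CDS frame 0
  base <- "ATGTTTGGCAAAAAAAAAAA"   # ATG TTT GGC then tail
  mat <- matrix(rep(strsplit(base, "")[[1]], 10), nrow = 10, byrow = TRUE)
  mat[1:5, 6] <- "C"    # TTT <-> TTC   (Phe/Phe, 3rd position)
  mat[1:5, 1] <- "T"    # ATG <-> TTG   (Met/Leu, 1st position)
  mat[1:5, 15] <- "G"   # intergenic site
  sp <- spFromMatrix(mat)
  gr <- GenomicRanges::GRanges("scaffold_1", IRanges::IRanges(1L, 9L),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = "exon", gene_id = "g1",
                                               phase = 0L)
  cls <- classifySites(sp, gr)[["scaffold_1"]]
  expect_identical(cls[6], "synonymous")
  expect_identical(cls[1], "nonsynonymous")
  expect_identical(cls[15], "noncoding")
  expect_identical(cls[2], "monomorphic")

  # '-' strand: genomic CCCAAACAT read as ATG TTT GGG; vary third codon pos
  rev <- "CCCAAACATAAAAAAAAAAA"
  matR <- matrix(rep(strsplit(rev, "")[[1]], 10), nrow = 10, byrow = TRUE)
  matR[1:5, 4] <- "G"   # codon TTT -> TTC (reverse strand third position)
  spR <- spFromMatrix(matR)
  grR <- GenomicRanges::GRanges("scaffold_1", IRanges::IRanges(1L, 9L),
                                strand = "-")
  S4Vectors::mcols(grR) <- S4Vectors::DataFrame(type = "exon", gene_id = "g1",
                                                phase = 0L)
  clsR <- classifySites(spR, grR)[["scaffold_1"]]
  expect_identical(clsR[4], "synonymous")

  # a second segregating position inside the codon excludes the site
  mat2 <- mat
  mat2[6:10, 5] <- "C"
  cls2 <- classifySites(spFromMatrix(mat2), gr)[["scaffold_1"]]
  expect_identical(cls2[6], "excluded")
})

test_that("Tajima's D matches the literal-constant oracle and sign conventions", {
  mono <- matrix("A", nrow = 10, ncol = 15)
  expect_true(is.na(tajimasD(mono)$D))

  # 20 singleton sites among 10 haplotypes: strongly negative
  sing <- matrix("A", nrow = 10, ncol = 40)
  for (j in 1:20) sing[1 + (j %% 10), j] <- "G"
  res <- tajimasD(sing)
  expect_identical(res$S, 20L)
  expect_lt(res$D, 0)
  expect_equal(res$D, tajimaOracle(sing), tolerance = 1e-12)

  set.seed(19)
  toy <- matrix(sample(c("A", "G"), 50, replace = TRUE, prob = c(.7, .3)),
                nrow = 5, ncol = 10)
  expect_equal(tajimasD(toy)$D, tajimaOracle(toy), tolerance = 1e-12)

  # SampledPanel route agrees with the matrix route
  sp <- spFromMatrix(sing)
  expect_equal(tajimasD(sp)$D, tajimaOracle(sing), tolerance = 1e-12)
  # region restriction
  reg <- data.frame(scaffold = "scaffold_1", left = 0L, right = 19L)
  expect_identical(tajimasD(sp, regions = reg)$S, 20L)
})
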