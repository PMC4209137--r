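# Crossover detection: run-length rule, double-CO exclusion, complex-tract
# scan, boundary filter, sliding-window genotype, COR context extraction.

test_that("run-length rule emits CORs only with k markers of support on both flanks", {
  o <- originFromString(strrep("A", 10) %.% strrep("B", 10))
  cors <- detectCrossovers(o, k = 10)
  expect_identical(length(cors), 1L)
  expect_identical(corTable(cors)$orientation, "A->B")
  expect_identical(corTable(cors)$left, 9L)
  expect_identical(corTable(cors)$right, 10L)

  expect_identical(length(detectCrossovers(
    originFromString(strrep("A", 9) %.% strrep("B", 10)), k = 10)), 0L)

  # double crossover transferring a short block is excluded entirely
  expect_identical(length(detectCrossovers(
    originFromString(strrep("A", 12) %.% strrep("B", 5) %.% strrep("A", 12)),
    k = 10)), 0L)

  # U calls are dropped, not run-breaking
  s <- strrep("A", 5) %.% "U" %.% strrep("A", 5) %.% strrep("B", 10)
  expect_identical(length(detectCrossovers(originFromString(s), k = 10)), 1L)
})

test_that("detection agrees with the brute-force boundary scanner on random vectors", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 200L
    calls <- sample(c("A", "B", "U"), n, replace = TRUE,
                    prob = c(0.46, 0.46, 0.08))
    pos <- sort(sample.int(5000L, n)) - 1L
    o <- OriginCalls("o", rep("s1", n), pos, calls)
    for (k in c(3L, 10L)) {
      got <- corTable(detectCrossovers(o, k = k))
      exp <- bruteForceCORs(pos, calls, k)
      expect_identical(got$left, exp$left)
      expect_identical(got$right, exp$right)
      expect_identical(got$orientation, exp$orientation)
      expect_identical(as.integer(got$left_run), as.integer(exp$left_run))
    }
  }
})

test_that("clean simulated crosses: sensitivity 1, false positives 0, monotone in k", {
  cfg <- testConfig(genomeLength = 100000L, nScaffolds = 1L,
                   coPerOffspring = 3, nOffspring = 10L, seed = 41L)
  par <- simulateParents(cfg)
  m <- callMarkers(par$parentA, par$parentB)
  pos <- markerPos(m)
  off <- simulateOffspring(par, par$annotation, cfg)
  bp <- truthBreakpoints(off$truth)
  prev <- NULL
  for (k in c(100L, 50L, 10L)) {
    all <- list()
    for (id in names(off$offspring)) {
      o <- assignOrigin(off$offspring[[id]], m, id = id)
      got <- corTable(detectCrossovers(o, k = k))
      all[[id]] <- got
      if (k != 10L) next
      b <- bp$pos[bp$offspring == id]
      gapOf <- findInterval(b - 0.5, pos)
      odd <- table(gapOf) %% 2 == 1
      vis <- as.integer(names(which(odd)))
      # eligibility: >= k retained markers on each side
      elig <- vis[vis >= k & (length(pos) - vis) >= k]
      # every detected COR contains exactly one visible breakpoint
      for (r in seq_len(nrow(got))) {
        inside <- b[b > got$left[r] & b <= got$right[r]]
        expect_identical(length(inside) %% 2L, 1L)
      }
      # every eligible breakpoint is detected
      for (g in elig)
        expect_true(any(got$left == pos[g] & got$right == pos[g + 1L]))
      expect_identical(nrow(got), length(elig))
    }
    cur <- do.call(rbind, all)
    if (!is.null(prev) && nrow(prev))
      expect_true(all(paste(prev$offspring, prev$left) %in%
                      paste(cur$offspring, cur$left)))
    prev <- cur
  }
})

test_that("complex tracts are flagged when three or more switches cluster", {
  single <- originFromString(strrep("A", 12) %.% strrep("B", 12))
  cors <- classifyComplex(detectCrossovers(single, k = 10), single,
                          window = 1000L)
  expect_identical(corTable(cors)$class, "simple")

  # A-B-A-B all within the window: every switch is a complex candidate
  s <- strrep("A", 12) %.% strrep("B", 12) %.% strrep("A", 12) %.% strrep("B", 12)
  o <- originFromString(s)
  cors2 <- classifyComplex(detectCrossovers(o, k = 10), o, window = 1000L)
  expect_true(all(corTable(cors2)$class == "complex_candidate"))

  # two switches far apart stay simple
  far <- OriginCalls("o", rep("s1", 36),
                     c(0:11, 5000:5011, 60000:60011) ,
                     rep(c("A", "B", "A"), each = 12))
  cors3 <- classifyComplex(detectCrossovers(far, k = 10), far, window = 1000L)
  expect_identical(nrow(corTable(cors3)), 2L)
  expect_true(all(corTable(cors3)$class == "simple"))
})

test_that("boundary filter removes CORs near scaffold ends", {
  rec <- data.frame(offspring = "o", scaffold = "s1",
                    left = c(100L, 5000L), right = c(130L, 5030L),
                    length = c(30L, 30L), orientation = "A->B",
                    left_run = 10L, right_run = 10L, class = "simple",
                    stringsAsFactors = FALSE)
  cors <- CORSet(rec)
  lens <- c(s1 = 10000L)
  expect_identical(length(boundaryFilter(cors, lens, margin = 0L)), 2L)
  kept <- corTable(boundaryFilter(cors, lens, margin = 500L))
  expect_identical(kept$left, 5000L)
})

test_that("sliding-window genotype reports majority origin with U ties", {
  allA <- OriginCalls("o", rep("s1", 50), seq(0, 49000, 1000), rep("A", 50))
  tr <- smoothGenotype(allA, c(s1 = 50000L), window = 10000L, step = 5000L)
  expect_true(all(tr$call == "A"))

  tie <- OriginCalls("o", rep("s1", 6), c(0, 10, 20, 30, 40, 50),
                     c("A", "A", "A", "B", "B", "B"))
  tr2 <- smoothGenotype(tie, c(s1 = 100L), window = 100L, step = 100L)
  expect_identical(tr2$call, "U")
  expect_error(smoothGenotype(tie, c(s1 = 100L), window = 10L, step = 20L),
               "window")

  cfg <- testConfig(genomeLength = 400000L, nScaffolds = 1L,
                   coPerOffspring = 1, nOffspring = 1L, seed = 53L)
  par <- simulateParents(cfg)
  m <- callMarkers(par$parentA, par$parentB)
  repeat {  # ensure exactly one mid-scaffold breakpoint
    off <- simulateOffspring(par, par$annotation, cfg)
    bp <- truthBreakpoints(off$truth)
    if (nrow(bp) == 1L && bp$pos > 120000 && bp$pos < 280000) break
    cfg@seed <- cfg@seed + 1L
  }
  o <- assignOrigin(off$offspring[[1]], m)
  tr3 <- smoothGenotype(o, c(scaffold_1 = 400000L))
  calls <- rle(tr3$call[tr3$call != "U"])$values
  expect_identical(length(calls), 2L)
  sw <- tr3$start[match(calls[2], tr3$call)]
  expect_lt(abs(sw - bp$pos), 100000)
})

test_that("COR context extraction clips at scaffold ends and round-trips", {
  genome <- c(s1 = paste(rep("ACGT", 300), collapse = ""))   # 1200 nt
  rec <- data.frame(offspring = "o", scaffold = "s1",
                    left = c(200L, 199L), right = c(230L, 230L),
                    length = c(30L, 31L), orientation = "A->B",
                    left_run = 10L, right_run = 10L, class = "simple",
                    stringsAsFactors = FALSE)
  cors <- CORSet(rec[1, ])
  noFlank <- extractCORContext(cors, genome, flank = 0L)
  expect_identical(Biostrings::width(noFlank), 31L)   # inclusive [left, right]
  clipped <- extractCORContext(cors, genome, flank = 400L)
  expect_identical(Biostrings::width(clipped), 200L + 31L + 400L)  # left-clipped

  tf <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(clipped, tf)
  back <- readGenomeFasta(tf)
  expect_identical(as.character(back[[1]]), as.character(clipped[[1]]))
})
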