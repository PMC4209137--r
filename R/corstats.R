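# COR length statistics and nulls: length-biased exponential expectation,
# exponential goodness of fit, identity-tract-matched permutation controls,
# GC windows.

#' Null expected COR length under random crossover placement
#'
#' If crossovers and interparental differences were placed independently at
#' random, inter-marker gaps are approximately exponential, and a uniformly
#' placed point falls into a gap with probability proportional to its length
#' (length-biased sampling, the inspection paradox).  The containing gap then
#' has expected length twice the overall mean gap.  With mean spacing 7 nt
#' this gives an expected COR of 14 nt.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @return list with \code{meanGap}, \code{expectedCORLength}
#'   (= 2 x meanGap), \code{nGaps}.
#' @export
expectedCORLength <- function(markers) {
  gaps <- markerGaps(markers)
  if (nrow(gaps) == 0L) stop("need at least 2 markers")
  mg <- mean(gaps$length)
  list(meanGap = mg, expectedCORLength = 2 * mg, nGaps = nrow(gaps))
}

#' Monte-Carlo mean of the gap containing a uniform point
#'
#' Independent simulation of the inspection paradox: draws \code{nGaps}
#' exponential gaps of mean \code{meanGap}, concatenates them, places
#' \code{nPoints} uniform points, and returns the mean length of the
#' containing gaps (with its standard error).  Converges to
#' \code{2 * meanGap}.
#'
#' @param nGaps,nPoints simulation sizes.
#' @param meanGap mean gap length, nt.
#' @param seed RNG seed.
#' @return list with \code{mean}, \code{se}, \code{ratio} (mean divided by
#'   \code{meanGap}), \code{n}.
#' @export
containingGapMean <- function(nGaps = 200000L, nPoints = 100000L,
                              meanGap = 7, seed = 1L) {
  set.seed(as.integer(seed))
  gaps <- rexp(nGaps, rate = 1 / meanGap)
  bounds <- cumsum(gaps)
  pts <- runif(nPoints, 0, bounds[nGaps])
  gi <- findInterval(pts, bounds) + 1L
  lens <- gaps[gi]
  list(mean = mean(lens), se = sd(lens) / sqrt(nPoints),
       ratio = mean(lens) / meanGap, n = nPoints)
}

#' Exponential goodness of fit for COR lengths
#'
#' Fits a rate as 1/mean and runs a one-sample Kolmogorov-Smirnov test of
#' the lengths against that exponential.  Because the rate is estimated from
#' the same sample, the plain KS p-value is conservative (inflated); a
#' Lilliefors-style parametric bootstrap is available via
#' \code{bootstrap = TRUE}.
#'
#' @param lengths positive COR lengths, nt (n >= 5).
#' @param bootstrap use a parametric bootstrap p-value.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{rate}, \code{statistic}, \code{p.value} and
#'   (if bootstrapped) \code{p.boot}.
#' @export
fitExponentialKS <- function(lengths, bootstrap = FALSE, nBoot = 999L,
                             seed = 1L) {
  if (any(lengths <= 0)) stop("all lengths must be positive")
  if (length(lengths) < 5L) stop("need at least 5 lengths")
  rate <- 1 / mean(lengths)
  ks <- suppressWarnings(ks.test(lengths, "pexp", rate = rate))
  out <- list(rate = rate, statistic = unname(ks$statistic),
              p.value = ks$p.value)
  if (bootstrap) {
    set.seed(as.integer(seed))
    n <- length(lengths)
    stats <- vapply(seq_len(nBoot), function(b) {
      x <- rexp(n, rate)
      unname(suppressWarnings(
        ks.test(x, "pexp", rate = 1 / mean(x))$statistic))
    }, numeric(1))
    out$p.boot <- (1 + sum(stats >= out$statistic)) / (nBoot + 1)
  }
  out
}

# interval containment of gap/region rows in a feature GRanges ("within");
# rows are 0-based marker coordinates [left, right]
.withinFeature <- function(rows, annotation, feature, midpoint = FALSE) {
  feat <- GenomicRanges::reduce(annotation[annotation$type == feature])
  if (!nrow(rows)) return(logical(0))
  if (midpoint) {
    mid <- floor((rows$left + rows$right) / 2) + 1L
    q <- GenomicRanges::GRanges(rows$scaffold, IRanges::IRanges(mid, mid))
  } else {
    q <- GenomicRanges::GRanges(rows$scaffold,
                                IRanges::IRanges(rows$left + 1L, rows$right + 1L))
  }
  IRanges::overlapsAny(q, feat, type = "within")
}

#' Sample identity-tract-matched control regions
#'
#' Draws, for each observed COR, a random inter-marker gap of the same
#' length elsewhere in the genome (the control has the same interparental
#' identity-tract length as the COR), excluding gaps that overlap any
#' observed COR.  When no gap of exactly matching length exists, the nearest
#' length within \code{tol} (relative) is used with a warning; an orphan COR
#' with no candidate raises an error naming it.  With \code{matchExon} the
#' control must additionally match the COR's exon-containment status.
#'
#' @param cors a \linkS4class{CORSet}.
#' @param markers the \linkS4class{MarkerSet} defining gaps.
#' @param annotation annotation \code{GRanges} (needed for
#'   \code{matchExon}).
#' @param matchExon also match full-exon containment.
#' @param nSets number of independent control sets.
#' @param seed RNG seed.
#' @param tol relative length-match tolerance for the fallback.
#' @return list of \code{nSets} data.frames (scaffold, left, right, length).
#' @export
sampleMatchedRegions <- function(cors, markers, annotation = NULL,
                                 matchExon = FALSE, nSets = 1L, seed = 1L,
                                 tol = 0.1) {
  set.seed(as.integer(seed))
  gaps <- markerGaps(markers)
  rec <- cors@records
  if (!nrow(rec)) return(rep(list(gaps[0, ]), nSets))
  # drop gaps overlapping any COR (strict interval overlap)
  keep <- rep(TRUE, nrow(gaps))
  for (sc in unique(rec$scaffold)) {
    gi <- which(gaps$scaffold == sc)
    ci <- which(rec$scaffold == sc)
    if (!length(gi) || !length(ci)) next
    ov <- outer(gaps$left[gi], rec$right[ci], "<") &
      outer(gaps$right[gi], rec$left[ci], ">")
    keep[gi[rowSums(ov) > 0]] <- FALSE
  }
  gaps <- gaps[keep, , drop = FALSE]
  if (!nrow(gaps)) stop("no candidate gaps outside observed CORs")
  exGap <- exCor <- NULL
  if (matchExon) {
    if (is.null(annotation)) stop("matchExon requires 'annotation'")
    exGap <- .withinFeature(gaps, annotation, "exon")
    exCor <- .withinFeature(rec, annotation, "exon")
  }
  # candidate gap indices per COR
  cand <- vector("list", nrow(rec))
  warned <- FALSE
  for (i in seq_len(nrow(rec))) {
    pool <- if (matchExon) which(exGap == exCor[i]) else seq_len(nrow(gaps))
    exact <- pool[gaps$length[pool] == rec$length[i]]
    if (length(exact)) { cand[[i]] <- exact; next }
    d <- abs(gaps$length[pool] - rec$length[i])
    near <- pool[d <= tol * rec$length[i]]
    if (!length(near))
      stop(sprintf("no control gap within %.0f%% of COR %s:%d-%d (length %d)",
                   100 * tol, rec$scaffold[i], rec$left[i], rec$right[i],
                   rec$length[i]))
    if (!warned) {
      warning("exact length match unavailable for some CORs; using nearest length within tolerance")
      warned <- TRUE
    }
    cand[[i]] <- pool[d == min(d)]
  }
  lapply(seq_len(nSets), function(s) {
    pick <- vapply(cand, function(ix)
      if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
    out <- gaps[pick, c("scaffold", "left", "right", "length"), drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Permutation test of COR enrichment in a genomic feature
#'
#' Counts CORs fully contained in the feature and compares against a null
#' distribution of identity-tract-matched random regions
#' (\code{\link{sampleMatchedRegions}} with \code{matchExon = FALSE}),
#' typically with 1,000 permutations.  Reports add-one permutation p-values
#' for both enrichment, \eqn{(1 + \#\{null \ge obs\})/(n+1)}, and depletion.
#'
#' @param cors a \linkS4class{CORSet}.
#' @param markers the \linkS4class{MarkerSet}.
#' @param annotation annotation \code{GRanges} with a \code{type} column.
#' @param feature feature label to test (\code{"exon"}, \code{"intron"},
#'   ...).
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param containment \code{"full"} (region within feature) or
#'   \code{"midpoint"}.
#' @param tol passed to \code{\link{sampleMatchedRegions}}.
#' @return list with \code{observed}, \code{nullCounts}, \code{pEnrich},
#'   \code{pDeplete}, \code{feature}, \code{nPerm}.
#' @export
permutationEnrichment <- function(cors, markers, annotation,
                                  feature = "exon", nPerm = 1000L, seed = 1L,
                                  containment = c("full", "midpoint"),
                                  tol = 0.1) {
  containment <- match.arg(containment)
  mp <- containment == "midpoint"
  rec <- cors@records
  obs <- sum(.withinFeature(rec, annotation, feature, midpoint = mp))
  sets <- sampleMatchedRegions(cors, markers, annotation = NULL,
                               matchExon = FALSE, nSets = nPerm, seed = seed,
                               tol = tol)
  # score all control sets against the feature in one overlap query
  feat <- GenomicRanges::reduce(annotation[annotation$type == feature])
  big <- do.call(rbind, sets)
  setIdx <- rep(seq_along(sets), vapply(sets, nrow, integer(1)))
  if (mp) {
    mid <- floor((big$left + big$right) / 2) + 1L
    q <- GenomicRanges::GRanges(big$scaffold, IRanges::IRanges(mid, mid))
  } else {
    q <- GenomicRanges::GRanges(big$scaffold,
                                IRanges::IRanges(big$left + 1L, big$right + 1L))
  }
  w <- IRanges::overlapsAny(q, feat, type = "within")
  nulls <- as.integer(vapply(split(w, factor(setIdx, levels = seq_along(sets))),
                             sum, numeric(1)))
  list(observed = obs, nullCounts = nulls,
       pEnrich = (1 + sum(nulls >= obs)) / (nPerm + 1),
       pDeplete = (1 + sum(nulls <= obs)) / (nPerm + 1),
       feature = feature, nPerm = nPerm)
}

#' Pooled GC content in windows around centers
#'
#' For each window width, pools G+C counts over windows centered at the
#' given positions (clipped at scaffold ends) and reports the GC fraction,
#' together with genome-wide and (if annotation is supplied) exon-wide
#' baselines.
#'
#' @param genome \code{DNAStringSet}.
#' @param centers data.frame with scaffold, pos (0-based; e.g.
#'   \code{\link{corMidpoints}}).
#' @param widths window widths, nt.
#' @param annotation optional annotation \code{GRanges} for the exon
#'   baseline.
#' @return list with \code{windows} (data.frame width, gc, nSites),
#'   \code{genomeGC}, \code{exonGC} (NA without annotation).
#' @export
gcWindows <- function(genome, centers, widths, annotation = NULL) {
  stopifnot(all(widths > 0))
  gb <- .genomeBytes(genome)
  gcb <- charToRaw("GC")
  isGC <- function(b) b %in% gcb
  res <- lapply(widths, function(w) {
    gc <- 0; n <- 0
    for (i in seq_len(nrow(centers))) {
      b <- gb[[centers$scaffold[i]]]
      from <- max(1L, as.integer(floor(centers$pos[i] - w / 2)) + 1L)
      to <- min(length(b), as.integer(ceiling(centers$pos[i] + w / 2)) + 1L)
      seg <- b[from:to]
      ok <- .isACGT(seg)
      gc <- gc + sum(isGC(seg[ok])); n <- n + sum(ok)
    }
    data.frame(width = w, gc = gc / n, nSites = n)
  })
  allB <- unlist(gb, use.names = FALSE)
  okAll <- .isACGT(allB)
  genomeGC <- sum(isGC(allB[okAll])) / sum(okAll)
  exonGC <- NA_real_
  if (!is.null(annotation)) {
    ex <- GenomicRanges::reduce(annotation[annotation$type == "exon"])
    if (length(ex)) {
      gcE <- 0; nE <- 0
      for (i in seq_along(ex)) {
        sc <- as.character(GenomicRanges::seqnames(ex))[i]
        seg <- gb[[sc]][GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i]]
        ok <- .isACGT(seg)
        gcE <- gcE + sum(isGC(seg[ok])); nE <- nE + sum(ok)
      }
      exonGC <- gcE / nE
    }
  }
  list(windows = do.call(rbind, res), genomeGC = genomeGC, exonGC = exonGC)
}

#' Chi-square test of two GC proportions
#'
#' 2x2 chi-square test (no continuity correction; counts are nucleotides and
#' large) comparing GC vs AT counts between two sequence sets, e.g. CORs vs
#' the genome average.
#'
#' @param gcA,atA,gcB,atB nucleotide counts of the two groups.
#' @return list with \code{chi2}, \code{p.value}.
#' @export
gcChi2 <- function(gcA, atA, gcB, atB) {
  counts <- c(gcA, atA, gcB, atB)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p.value = ct$p.value)
}

#' Minimum expected crossover count of a cross
#'
#' Bookkeeping expectation if at least one crossover occurred per chromosome
#' per meiosis: chromosomes times offspring.
#'
#' @param nChromosomes haploid chromosome number.
#' @param nOffspring offspring genotyped.
#' @return integer count.
#' @examples
#' expectedMinimumCOs(11, 17)  # 187
#' @export
expectedMinimumCOs <- function(nChromosomes = 11L, nOffspring = 17L) {
  as.integer(nChromosomes) * as.integer(nOffspring)
}
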