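# Synthetic hypervariable haploid cross: parents, annotation, recombinant
# offspring with recorded breakpoints, and population panels.

# Draw bases with a given GC fraction (vectorized over sites).
.drawBases <- function(gcvec) {
  n <- length(gcvec)
  isGC <- runif(n) < gcvec
  pickHigh <- runif(n) < 0.5
  b <- character(n)
  b[isGC] <- ifelse(pickHigh[isGC], "G", "C")
  b[!isGC] <- ifelse(pickHigh[!isGC], "A", "T")
  charToRaw(paste(b, collapse = ""))
}

# Substitute positions idx of byte vector x with a uniformly drawn different
# base.
.mutateBytes <- function(x, idx) {
  if (!length(idx)) return(x)
  cur <- match(x[idx], .BASE_BYTES)          # NA for non-ACGT (left alone)
  ok <- !is.na(cur)
  idx <- idx[ok]; cur <- cur[ok]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  x[idx] <- .BASE_BYTES[((cur - 1L + shift) %% 4L) + 1L]
  x
}

# Random compact gene structures tiling one scaffold.  Returns a data.frame
# of intervals (1-based, inclusive) with type exon/intron/intergenic,
# gene_id, strand, and CDS phase for exons.  Total CDS length per gene is a
# multiple of 3.
.tileAnnotation <- function(L, exonFraction, scPrefix = "g") {
  exonMean <- 250; intronMean <- 75; nExonMean <- 3
  perGeneExon <- nExonMean * exonMean
  perGeneIntron <- (nExonMean - 1) * intronMean
  igMean <- perGeneExon * (1 / max(exonFraction, 1e-6) - 1) - perGeneIntron
  if (exonFraction > 0 && igMean < 20)
    stop("configuration error: 'exonFraction' too high for the gene model")
  rows <- vector("list", 256); nr <- 0L; pos <- 1L; gid <- 0L
  add <- function(start, end, type, gene, strand, phase) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- list(start, end, type, gene, strand, phase)
  }
  while (pos <= L) {
    ig <- if (exonFraction <= 0) L else max(20L, as.integer(round(rexp(1, 1 / igMean))))
    end <- min(L, pos + ig - 1L)
    add(pos, end, "intergenic", NA_character_, "*", NA_integer_)
    pos <- end + 1L
    if (pos > L || exonFraction <= 0) break
    gid <- gid + 1L
    gene <- sprintf("%s%04d", scPrefix, gid)
    strand <- sample(c("+", "-"), 1L)
    nE <- 1L + rpois(1, nExonMean - 1)
    eLens <- pmax(30L, as.integer(round(rexp(nE, 1 / exonMean))))
    rem <- sum(eLens) %% 3L
    if (rem) eLens[nE] <- eLens[nE] + (3L - rem)    # keep CDS in frame
    iLens <- if (nE > 1L) pmax(40L, as.integer(round(rexp(nE - 1L, 1 / intronMean)))) else integer(0)
    cum <- 0L
    exonStarts <- integer(nE); exonEnds <- integer(nE)
    for (e in seq_len(nE)) {
      exonStarts[e] <- pos
      exonEnds[e] <- pos + eLens[e] - 1L
      pos <- exonEnds[e] + 1L
      if (e < nE) pos <- pos + iLens[e]
    }
    if (exonEnds[nE] > L) break                     # drop gene truncated by scaffold end
    cdsBefore <- c(0L, cumsum(eLens))[seq_len(nE)]
    if (strand == "-") cdsBefore <- rev(c(0L, cumsum(rev(eLens)))[seq_len(nE)])
    for (e in seq_len(nE)) {
      add(exonStarts[e], exonEnds[e], "exon", gene, strand,
          (3L - cdsBefore[e] %% 3L) %% 3L)
      cum <- cum + eLens[e]
      if (e < nE)
        add(exonEnds[e] + 1L, exonStarts[e + 1L] - 1L, "intron", gene, strand,
            NA_integer_)
    }
  }
  rows <- rows[seq_len(nr)]
  df <- data.frame(
    start = vapply(rows, `[[`, integer(1), 1L),
    end = vapply(rows, `[[`, integer(1), 2L),
    type = vapply(rows, `[[`, character(1), 3L),
    gene_id = vapply(rows, `[[`, character(1), 4L),
    strand = vapply(rows, `[[`, character(1), 5L),
    phase = vapply(rows, `[[`, integer(1), 6L),
    stringsAsFactors = FALSE)
  df[df$end >= df$start & df$end <= L, , drop = FALSE]
}

# 0/1 exon mask (length L) from annotation for one scaffold
.exonMask <- function(annotation, sc, L) {
  mask <- logical(L)
  ex <- annotation[annotation$type == "exon" &
                   as.character(GenomicRanges::seqnames(annotation)) == sc]
  if (length(ex))
    for (i in seq_along(ex))
      mask[GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i]] <- TRUE
  mask
}

#' Simulate two divergent haploid parents with annotation
#'
#' Generates aligned parental genomes on a shared coordinate system (no
#' indels, so the alignment is exact by construction), a compact exon/intron
#' annotation with in-frame CDS, and hotspot intervals.  Parent B is parent A
#' with independent per-site substitutions.  \code{divergence} is the
#' genome-wide realized difference target; inside exons the substitution rate
#' is multiplied by \code{exonDivergenceFactor} and the non-exon rate is
#' inflated so the mixture still realizes the target.  Exon GC is elevated to
#' \code{exonGC}, background \code{backgroundGC}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{parentA}, \code{parentB}
#'   (\code{DNAStringSet}), \code{annotation} (\code{GRanges} with columns
#'   type/gene_id/phase), and \code{truth} (\linkS4class{SimTruth} carrying
#'   hotspots and realized divergence; no breakpoints yet).
#' @export
simulateParents <- function(config) {
  methods::validObject(config)
  seeds <- .subSeeds(config@seed, 8L)
  set.seed(seeds[1])
  nSc <- config@nScaffolds
  Ls <- rep(config@genomeLength %/% nSc, nSc)
  Ls[nSc] <- Ls[nSc] + config@genomeLength %% nSc
  names(Ls) <- sprintf("scaffold_%d", seq_len(nSc))

  annList <- list(); aBytes <- list(); bBytes <- list()
  wExon <- 0; nSites <- 0
  for (sc in names(Ls)) {
    L <- Ls[[sc]]
    ann <- .tileAnnotation(L, config@exonFraction,
                           scPrefix = paste0(sub("scaffold_", "s", sc), "g"))
    ann$scaffold <- sc
    annList[[sc]] <- ann
    mask <- logical(L)
    ex <- ann[ann$type == "exon", , drop = FALSE]
    for (i in seq_len(nrow(ex))) mask[ex$start[i]:ex$end[i]] <- TRUE
    wExon <- wExon + sum(mask); nSites <- nSites + L
    gc <- ifelse(mask, config@exonGC, config@backgroundGC)
    aBytes[[sc]] <- .drawBases(gc)
    attr(aBytes[[sc]], "exonMask") <- mask
  }
  wReal <- wExon / nSites
  f <- config@exonDivergenceFactor
  dBackground <- config@divergence / (wReal * f + (1 - wReal))
  if (dBackground > 1) dBackground <- 1
  dExon <- f * dBackground

  nDiff <- 0
  for (sc in names(Ls)) {
    mask <- attr(aBytes[[sc]], "exonMask")
    dv <- ifelse(mask, dExon, dBackground)
    idx <- which(runif(Ls[[sc]]) < dv)
    bBytes[[sc]] <- .mutateBytes(aBytes[[sc]], idx)
    nDiff <- nDiff + length(idx)
  }

  # hotspots: uniform non-overlapping intervals, scaffolds weighted by length
  hs <- GenomicRanges::GRanges()
  if (config@hotspotCount > 0L) {
    hsc <- sample(names(Ls), config@hotspotCount, replace = TRUE,
                  prob = Ls / sum(Ls))
    starts <- integer(config@hotspotCount)
    for (i in seq_len(config@hotspotCount)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample.int(Ls[[hsc[i]]] - config@hotspotWidth, 1L)
        clash <- which(hsc[seq_len(i - 1L)] == hsc[i])
        if (!length(clash) ||
            all(abs(starts[clash] - s) >= config@hotspotWidth)) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("configuration error: cannot place non-overlapping hotspots; ",
             "reduce 'hotspotCount' or 'hotspotWidth'")
      starts[i] <- s
    }
    hs <- GenomicRanges::GRanges(hsc, IRanges::IRanges(
      start = starts, width = config@hotspotWidth))
    hs <- sort(hs)
  }

  annDf <- do.call(rbind, annList)
  annotation <- GenomicRanges::GRanges(
    annDf$scaffold, IRanges::IRanges(annDf$start, annDf$end),
    strand = annDf$strand)
  S4Vectors::mcols(annotation) <- S4Vectors::DataFrame(
    type = annDf$type, gene_id = annDf$gene_id, phase = annDf$phase)
  GenomeInfoDb::seqlengths(annotation) <- Ls

  toDSS <- function(lst) Biostrings::DNAStringSet(
    setNames(vapply(lst, rawToChar, character(1)), names(lst)))
  truth <- methods::new("SimTruth",
    breakpoints = data.frame(offspring = character(0), scaffold = character(0),
                             pos = integer(0), stringsAsFactors = FALSE),
    hotspots = hs,
    params = list(seed = config@seed, config = config,
                  realizedDivergence = nDiff / nSites,
                  dExon = dExon, dBackground = dBackground,
                  exonFraction = wReal, scaffoldLengths = Ls))
  list(parentA = toDSS(aBytes), parentB = toDSS(bBytes),
       annotation = annotation, truth = truth)
}

# sample breakpoint positions (0-based inter-base, in 1..L-1) for one
# scaffold under the configured placement model
.placeBreakpoints <- function(n, L, model, config, exonMask, gapLeft, gapLen,
                              hotspotRanges) {
  if (n == 0L) return(integer(0))
  if (model == "uniform") {
    return(sort(sample.int(L - 1L, min(n, L - 1L))))
  }
  if (model == "exon_biased") {
    w <- ifelse(exonMask[seq_len(L - 1L)], config@coExonWeight, 1)
    return(sort(sample.int(L - 1L, min(n, L - 1L), prob = w)))
  }
  if (model == "hotspot") {
    if (is.null(hotspotRanges) || nrow(hotspotRanges) == 0L) return(integer(0))
    sel <- sample.int(nrow(hotspotRanges), n, replace = TRUE,
                      prob = hotspotRanges$width)
    pos <- hotspotRanges$start0[sel] +
      vapply(hotspotRanges$width[sel],
             function(w) sample.int(w, 1L), integer(1))
    return(sort(unique(pmin(pmax(pos, 1L), L - 1L))))
  }
  if (model == "mmr_biased") {
    acc <- integer(0); tries <- 0L
    while (length(acc) < n && tries < 200L) {
      tries <- tries + 1L
      prop <- sample.int(L - 1L, n)
      gi <- findInterval(prop, gapLeft)
      g <- ifelse(gi >= 1L & gi <= length(gapLen), gapLen[pmax(gi, 1L)], Inf)
      keep <- runif(length(prop)) < (1 - exp(-g / config@mmrScale))
      acc <- unique(c(acc, prop[keep]))
    }
    return(sort(acc[seq_len(min(n, length(acc)))]))
  }
  stop(sprintf("unknown coModel '%s'", model))
}

#' Simulate recombinant haploid offspring
#'
#' Each offspring is a mosaic of the two parental sequences switching parent
#' at true breakpoints; breakpoints are 0-based inter-base positions and all
#' are recorded in the returned truth.  Placement models: \code{uniform};
#' \code{mmr_biased} (uniform proposals accepted with probability
#' \eqn{1-\exp(-g/s)} where \eqn{g} is the containing inter-marker gap — a
#' mismatch-repair proxy that favours identity tracts); \code{exon_biased};
#' \code{hotspot} (proposals restricted to hotspot intervals).
#'
#' @param parents result of \code{\link{simulateParents}} (or a list with
#'   \code{parentA}, \code{parentB}, \code{truth}).
#' @param annotation exon annotation \code{GRanges} (used by
#'   \code{exon_biased}).
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{offspring} (named list of \code{DNAStringSet}
#'   genomes) and \code{truth} (\linkS4class{SimTruth} with all true
#'   breakpoints).
#' @export
simulateOffspring <- function(parents, annotation, config) {
  seeds <- .subSeeds(config@seed, 8L)
  set.seed(seeds[2])
  a <- .genomeBytes(parents$parentA)
  b <- .genomeBytes(parents$parentB)
  Ls <- vapply(a, length, integer(1))
  model <- config@coModel
  if (!model %in% c("uniform", "mmr_biased", "exon_biased", "hotspot"))
    stop(sprintf("unknown coModel '%s'", model))

  markers <- if (model == "mmr_biased") callMarkers(parents$parentA, parents$parentB)
             else NULL
  exonMasks <- if (model == "exon_biased")
    lapply(names(Ls), function(sc) .exonMask(annotation, sc, Ls[[sc]]))
  else vector("list", length(Ls))
  names(exonMasks) <- names(Ls)

  hsRanges <- NULL
  if (model == "hotspot") {
    hs <- parents$truth@hotspots
    hsRanges <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(hs)),
      start0 = GenomicRanges::start(hs) - 1L,
      width = GenomicRanges::width(hs), stringsAsFactors = FALSE)
  }

  # scaffold weights for allocating the Poisson CO count
  wts <- Ls / sum(Ls)
  if (model == "hotspot") {
    wts[] <- 0
    for (sc in names(Ls))
      wts[[sc]] <- sum(hsRanges$width[hsRanges$scaffold == sc])
    if (sum(wts) == 0) stop("hotspot model requires at least one hotspot")
    wts <- wts / sum(wts)
  }

  offspring <- list(); bpAll <- list(); startRows <- list()
  for (j in seq_len(config@nOffspring)) {
    id <- sprintf("offspring_%02d", j)
    nCO <- rpois(1, config@coPerOffspring)
    perSc <- if (nCO > 0)
      table(factor(sample(names(Ls), nCO, replace = TRUE, prob = wts),
                   levels = names(Ls)))
    else setNames(rep(0L, length(Ls)), names(Ls))
    segs <- list()
    for (sc in names(Ls)) {
      L <- Ls[[sc]]
      gapLeft <- gapLen <- NULL
      if (!is.null(markers)) {
        p <- markers@pos[markers@scaffold == sc]
        if (length(p) >= 2L) { gapLeft <- p[-length(p)]; gapLen <- diff(p) }
        else { gapLeft <- 0L; gapLen <- Inf }
      }
      bp <- .placeBreakpoints(as.integer(perSc[[sc]]), L, model, config,
                              exonMasks[[sc]], gapLeft, gapLen,
                              if (is.null(hsRanges)) NULL else
                                hsRanges[hsRanges$scaffold == sc, , drop = FALSE])
      start <- sample(0:1, 1L)
      startRows[[length(startRows) + 1L]] <- data.frame(
        offspring = id, scaffold = sc,
        start = c("A", "B")[start + 1L], stringsAsFactors = FALSE)
      cnt <- findInterval(seq.int(0L, L - 1L), bp)
      useB <- ((start + cnt) %% 2L) == 1L
      seq <- a[[sc]]
      seq[useB] <- b[[sc]][useB]
      segs[[sc]] <- rawToChar(seq)
      if (length(bp))
        bpAll[[length(bpAll) + 1L]] <- data.frame(
          offspring = id, scaffold = sc, pos = bp, stringsAsFactors = FALSE)
    }
    offspring[[id]] <- Biostrings::DNAStringSet(unlist(segs))
  }
  bpdf <- if (length(bpAll)) do.call(rbind, bpAll) else
    data.frame(offspring = character(0), scaffold = character(0),
               pos = integer(0), stringsAsFactors = FALSE)
  bpdf <- bpdf[order(bpdf$offspring, bpdf$scaffold, bpdf$pos), , drop = FALSE]
  rownames(bpdf) <- NULL
  truth <- methods::new("SimTruth", breakpoints = bpdf,
                        hotspots = parents$truth@hotspots,
                        params = c(parents$truth@params,
                                   list(coModel = model,
                                        startParent = do.call(rbind, startRows))))
  list(offspring = offspring, truth = truth)
}

#' Mean pairwise dissimilarity of a panel
#'
#' Genome-wide nucleotide diversity \eqn{\pi}: per site, the mean pairwise
#' difference among callable (A/C/G/T) individuals; averaged over sites with
#' at least two callable individuals.  Pairwise deletion throughout.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param scaffold optional scaffold restriction.
#' @return numeric \eqn{\pi} in [0, 1].
#' @export
panelPi <- function(panel, scaffold = NULL) {
  scs <- if (is.null(scaffold)) names(panel@seqs) else scaffold
  tot <- 0; nUsed <- 0
  for (sc in scs) {
    m <- panel@seqs[[sc]]
    counts <- vapply(as.list(.BASE_BYTES),
                     function(bb) .colSumsEq(m, bb), numeric(ncol(m)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
    cal <- rowSums(counts)
    ok <- cal >= 2
    num <- rowSums(counts * (counts - 1))
    piSite <- 1 - num[ok] / (cal[ok] * (cal[ok] - 1))
    tot <- tot + sum(piSite); nUsed <- nUsed + sum(ok)
  }
  if (nUsed == 0) return(NA_real_)
  tot / nUsed
}

.colSumsEq <- function(m, byte) .colSums(m == byte, nrow(m), ncol(m))

#' Simulate a population panel of haploid genomes
#'
#' Forward founder-recombination scheme at stationarity: each haplotype is a
#' mosaic of two founders (the given parent and a mutated copy) with
#' exponential ancestry-segment lengths of mean \code{ldDecayScale} nt plus
#' extra breakpoints concentrated in hotspots, then per-site private
#' mutations.  Founder divergence inside exons is multiplied by
#' \code{popExonFactor} (a purifying-selection proxy), so exonic diversity is
#' reduced and exonic variants are enriched for rare alleles.  The founder
#' divergence is calibrated (and re-calibrated up to \code{maxIter} times)
#' so that realized genome-wide \eqn{\pi} matches \code{popPi[which]}.
#'
#' @param parent parental genome used as founder 1 (\code{DNAStringSet}).
#' @param annotation exon annotation \code{GRanges}.
#' @param config a \linkS4class{SimConfig}.
#' @param which panel index: 1 (US-like) or 2 (Russia-like).
#' @param hotspots optional hotspot \code{GRanges} (default: none).
#' @param missingRate per-site gap probability per individual.
#' @param maxIter,tol calibration iterations and relative tolerance.
#' @return a \linkS4class{HaplotypePanel}; \code{metadata} records the
#'   realized \eqn{\pi} and generator parameters.
#' @export
simulatePopulation <- function(parent, annotation, config, which = 1L,
                               hotspots = NULL, missingRate = 0,
                               maxIter = 3L, tol = 0.1) {
  target <- config@popPi[which]
  if (target < 0 || target >= 0.25)
    stop("configuration error: popPi must lie in [0, 0.25)")
  n <- config@popSizes[which]
  seeds <- .subSeeds(config@seed, 8L)
  set.seed(seeds[2L + which])
  pb <- .genomeBytes(parent)
  Ls <- vapply(pb, length, integer(1))
  masks <- lapply(names(Ls), function(sc) .exonMask(annotation, sc, Ls[[sc]]))
  names(masks) <- names(Ls)
  wReal <- sum(vapply(masks, sum, numeric(1))) / sum(Ls)
  beta <- config@popSingletonShare
  mu <- beta * target / 2
  fb <- 2 * (1 - beta) * target / (wReal * config@popExonFactor + (1 - wReal))

  hsd <- NULL
  if (!is.null(hotspots) && length(hotspots))
    hsd <- data.frame(scaffold = as.character(GenomicRanges::seqnames(hotspots)),
                      start0 = GenomicRanges::start(hotspots) - 1L,
                      width = GenomicRanges::width(hotspots),
                      stringsAsFactors = FALSE)

  build <- function(fb) {
    seqs <- list()
    for (sc in names(Ls)) {
      L <- Ls[[sc]]
      dv <- ifelse(masks[[sc]], fb * config@popExonFactor, fb)
      founder2 <- .mutateBytes(pb[[sc]], which(runif(L) < dv))
      mat <- matrix(as.raw(0), nrow = n, ncol = L)
      hloc <- if (is.null(hsd)) NULL else hsd[hsd$scaffold == sc, , drop = FALSE]
      for (i in seq_len(n)) {
        nbp <- rpois(1, L / config@ldDecayScale)
        bp <- if (nbp > 0) sample.int(L - 1L, min(nbp, L - 1L)) else integer(0)
        if (!is.null(hloc) && nrow(hloc)) {
          extra <- unlist(lapply(seq_len(nrow(hloc)), function(h) {
            k <- rpois(1, config@hotspotIntensity)
            if (k == 0) return(integer(0))
            hloc$start0[h] + sample.int(hloc$width[h], k, replace = TRUE)
          }))
          bp <- c(bp, pmin(pmax(extra, 1L), L - 1L))
        }
        bp <- sort(unique(bp))
        cnt <- findInterval(seq.int(0L, L - 1L), bp)
        useF2 <- ((sample(0:1, 1L) + cnt) %% 2L) == 1L
        hap <- pb[[sc]]
        hap[useF2] <- founder2[useF2]
        hap <- .mutateBytes(hap, which(runif(L) < mu))   # private mutations
        if (missingRate > 0)
          hap[runif(L) < missingRate] <- charToRaw("-")
        mat[i, ] <- hap
      }
      seqs[[sc]] <- mat
    }
    seqs
  }

  panelID <- c("US", "RU")[which]
  for (it in seq_len(max(1L, maxIter))) {
    seqs <- build(fb)
    panel <- methods::new("HaplotypePanel", panelID = panelID,
                          individuals = sprintf("%s_%02d", panelID, seq_len(n)),
                          seqs = seqs, metadata = list())
    realized <- panelPi(panel)
    if (target == 0 || abs(realized - target) / max(target, 1e-12) <= tol) break
    fb <- fb * target / max(realized, 1e-12)
  }
  if (target > 0 && abs(realized - target) / target > 2.5 * tol)
    stop(sprintf("pi target %.4g unreachable after calibration; achieved %.4g",
                 target, realized))
  panel@metadata <- list(seed = config@seed, which = which, targetPi = target,
                         realizedPi = realized, founderDivergence = fb,
                         privateMutationRate = mu)
  panel
}

#' Simulate a complete cross (parents, offspring, panels)
#'
#' Convenience wrapper chaining \code{\link{simulateParents}},
#' \code{\link{simulateOffspring}} and (optionally)
#' \code{\link{simulatePopulation}} for both panels.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param panels logical: also simulate the two population panels.
#' @param ... passed to \code{\link{simulatePopulation}}.
#' @return list with parentA, parentB, annotation, offspring, truth, and
#'   (optionally) panels (list of two \linkS4class{HaplotypePanel}).
#' @export
simulateCross <- function(config, panels = FALSE, ...) {
  par <- simulateParents(config)
  off <- simulateOffspring(par, par$annotation, config)
  res <- list(parentA = par$parentA, parentB = par$parentB,
              annotation = par$annotation, offspring = off$offspring,
              truth = off$truth)
  if (panels)
    res$panels <- list(
      US = simulatePopulation(par$parentA, par$annotation, config, 1L,
                              hotspots = par$truth@hotspots, ...),
      RU = simulatePopulation(par$parentA, par$annotation, config, 2L,
                              hotspots = par$truth@hotspots, ...))
  res
}
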