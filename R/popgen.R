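# Population-panel statistics around CORs: joint site filtering with fixed
# per-site subsampling, pi windows, MAF with bootstrap CIs, site
# classification, Tajima's D.

#' Joint site filter with fixed per-site subsampling
#'
#' Applies the two-panel eligibility rule: a site is retained only if at
#' least \code{minN} individuals carry an unambiguous A/C/G/T there in
#' \emph{both} panels.  At each retained site a uniform random subset of
#' exactly \code{sampleN} callable individuals per panel is drawn once and
#' frozen, so every downstream per-site statistic uses a fixed sample size.
#'
#' @param panelA,panelB two \linkS4class{HaplotypePanel}s on shared
#'   coordinates.
#' @param minN minimum callable individuals per panel.
#' @param sampleN fixed subset size (must be <= \code{minN}).
#' @param seed RNG seed.
#' @return list of two \linkS4class{SampledPanel}s (same retained sites).
#' @export
sampleSites <- function(panelA, panelB, minN = 10L, sampleN = 10L, seed = 1L) {
  if (sampleN > minN)
    stop("configuration error: 'sampleN' must not exceed 'minN'")
  if (panelSize(panelA) < minN || panelSize(panelB) < minN)
    stop("configuration error: 'minN' exceeds a panel size")
  if (!identical(names(panelA@seqs), names(panelB@seqs)))
    stop("panels must share scaffolds")
  set.seed(as.integer(seed))
  out <- list(list(), list())   # per panel: sites/alleles/chosen
  sites <- list()
  res <- lapply(1:2, function(i) list(sites = list(), alleles = list(),
                                      chosen = list()))
  for (sc in names(panelA@seqs)) {
    mats <- list(panelA@seqs[[sc]], panelB@seqs[[sc]])
    call <- lapply(mats, function(m)
      matrix(m %in% .BASE_BYTES, nrow = nrow(m)))
    nCall <- lapply(call, function(cm) .colSums(cm, nrow(cm), ncol(cm)))
    retain <- which(nCall[[1]] >= minN & nCall[[2]] >= minN)
    for (i in 1:2) {
      m <- mats[[i]]; n <- nrow(m); L <- ncol(m)
      K <- matrix(runif(n * L), n, L)
      K[!call[[i]]] <- 2                      # push gaps past all callables
      o <- order(rep.int(seq_len(L), rep.int(n, L)), as.vector(K))
      idx <- o[rep((retain - 1L) * n, each = sampleN) + seq_len(sampleN)]
      rows <- ((idx - 1L) %% n) + 1L
      res[[i]]$sites[[sc]] <- retain - 1L     # 0-based
      res[[i]]$chosen[[sc]] <- matrix(rows, nrow = sampleN)
      res[[i]]$alleles[[sc]] <- matrix(
        m[cbind(rows, rep(retain, each = sampleN))], nrow = sampleN)
    }
  }
  lapply(1:2, function(i) methods::new("SampledPanel",
    panelID = c(panelA@panelID, panelB@panelID)[i],
    sampleN = as.integer(sampleN), sites = res[[i]]$sites,
    alleles = res[[i]]$alleles, chosen = res[[i]]$chosen))
}

# per-site allele counts (4 x nSites) for one scaffold of a SampledPanel
.alleleCounts <- function(sp, sc) {
  al <- sp@alleles[[sc]]
  t(vapply(as.list(.BASE_BYTES),
           function(bb) .colSums(al == bb, nrow(al), ncol(al)),
           numeric(ncol(al))))
}

# per-site mean pairwise difference among the sampleN haplotypes
.piSites <- function(sp, sc) {
  cnt <- .alleleCounts(sp, sc)
  n <- sp@sampleN
  1 - colSums(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Nucleotide diversity in windows
#'
#' Per window: the mean over callable sites of the per-site mean pairwise
#' difference among the fixed \code{sampleN} haplotypes.  A window with no
#' retained site yields \code{NA} with \code{nSites = 0}.
#'
#' @param sp a \linkS4class{SampledPanel}.
#' @param centers data.frame with scaffold, pos (0-based centers, e.g.
#'   \code{\link{corMidpoints}}).
#' @param widths window widths, nt.
#' @return data.frame with scaffold, center, width, pi, nSites.
#' @export
piWindows <- function(sp, centers, widths) {
  stopifnot(all(widths > 0))
  out <- list()
  for (sc in unique(centers$scaffold)) {
    if (!sc %in% names(sp@sites)) next
    pos <- sp@sites[[sc]]
    ps <- .piSites(sp, sc)
    cps <- cumsum(ps)
    ctr <- centers$pos[centers$scaffold == sc]
    for (w in widths) {
      lo <- findInterval(ctr - w / 2 - 1e-9, pos) + 1L
      hi <- findInterval(ctr + w / 2 + 1e-9, pos)
      nS <- pmax(0L, hi - lo + 1L)
      s <- ifelse(nS > 0, cps[pmax(hi, 1L)] - ifelse(lo > 1L, cps[lo - 1L], 0), NA)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, center = ctr, width = w,
        pi = ifelse(nS > 0, s / nS, NA_real_), nSites = nS,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genome-wide nucleotide diversity of a sampled panel
#'
#' @param sp a \linkS4class{SampledPanel}.
#' @return mean per-site pairwise dissimilarity over all retained sites.
#' @export
piGenomeWide <- function(sp) {
  tot <- 0; n <- 0
  for (sc in names(sp@sites)) {
    ps <- .piSites(sp, sc)
    tot <- tot + sum(ps); n <- n + length(ps)
  }
  if (n == 0) return(NA_real_)
  tot / n
}

#' Observed vs matched-control diversity curves
#'
#' Computes \eqn{\pi} in windows of several widths centered at COR midpoints
#' and at each matched-control set's midpoints, and summarizes the null as
#' its mean and a 2.5--97.5 percentile envelope over sets.  Both the mean of
#' per-window values and the site-pooled value are reported.
#'
#' @param sp a \linkS4class{SampledPanel}.
#' @param cors a \linkS4class{CORSet}.
#' @param controls list of control-region data.frames from
#'   \code{\link{sampleMatchedRegions}}.
#' @param widths window widths, nt.
#' @return data.frame with width, obsMean, obsPooled, nullMean, nullLo,
#'   nullHi, nSets.
#' @export
piContrast <- function(sp, cors, controls, widths) {
  mids <- corMidpoints(cors)
  summarize <- function(centers) {
    pw <- piWindows(sp, centers, widths)
    vapply(widths, function(w) {
      r <- pw[pw$width == w, , drop = FALSE]
      c(mean = mean(r$pi, na.rm = TRUE),
        pooled = sum(r$pi * r$nSites, na.rm = TRUE) /
          max(1, sum(r$nSites[!is.na(r$pi)])))
    }, numeric(2))
  }
  obs <- summarize(mids)
  nullMeans <- vapply(controls, function(ctl) {
    ctr <- data.frame(scaffold = ctl$scaffold,
                      pos = (ctl$left + ctl$right) / 2,
                      stringsAsFactors = FALSE)
    summarize(ctr)["mean", ]
  }, numeric(length(widths)))
  if (is.null(dim(nullMeans))) nullMeans <- matrix(nullMeans, nrow = length(widths))
  data.frame(width = widths,
             obsMean = obs["mean", ], obsPooled = obs["pooled", ],
             nullMean = rowMeans(nullMeans),
             nullLo = apply(nullMeans, 1, quantile, 0.025, na.rm = TRUE),
             nullHi = apply(nullMeans, 1, quantile, 0.975, na.rm = TRUE),
             nSets = length(controls))
}

# per-site MAF (NA unless exactly two alleles present) for one scaffold
.mafSites <- function(sp, sc) {
  cnt <- .alleleCounts(sp, sc)
  nAll <- colSums(cnt > 0)
  maf <- rep(NA_real_, ncol(cnt))
  bi <- which(nAll == 2L)
  if (length(bi)) {
    sub <- cnt[, bi, drop = FALSE]
    mx <- apply(sub, 2, max)
    maf[bi] <- (sp@sampleN - mx) / sp@sampleN
  }
  maf
}

#' Minor-allele-frequency profile in CORs vs flanking control windows
#'
#' Records MAF (minor count / \code{sampleN}) at biallelic sampled sites
#' inside CORs and inside windows of \code{window} nt centered at COR
#' midpoints (COR-internal sites excluded from the control), compares the
#' two site sets with a two-sided Mann-Whitney test, and attaches 95\%
#' bootstrap confidence intervals for each mean obtained by resampling sites
#' with replacement from the observed frequency-class distribution
#' (\code{nBoot} replicates).
#'
#' @param sp a \linkS4class{SampledPanel}.
#' @param cors a \linkS4class{CORSet}.
#' @param window control window width, nt.
#' @param nBoot bootstrap replicates for the CIs.
#' @param seed RNG seed.
#' @param siteClasses optional named-by-scaffold list of per-site class
#'   labels (see \code{\link{classifySites}}).
#' @param whichClass restrict to this class label (e.g.
#'   \code{"synonymous"}).
#' @return list with corMean, corCI, ctrlMean, ctrlCI, p.value, nCor,
#'   nCtrl.  Empty site sets are flagged by NA and no test.
#' @export
mafProfile <- function(sp, cors, window = 10000L, nBoot = 1000L, seed = 1L,
                       siteClasses = NULL, whichClass = NULL) {
  set.seed(as.integer(seed))
  rec <- cors@records
  mafCor <- numeric(0); mafCtrl <- numeric(0)
  for (sc in names(sp@sites)) {
    pos <- sp@sites[[sc]]
    maf <- .mafSites(sp, sc)
    ok <- !is.na(maf)
    if (!is.null(siteClasses)) {
      cls <- siteClasses[[sc]]
      ok <- ok & !is.na(cls) & cls == whichClass
    }
    ri <- which(rec$scaffold == sc)
    if (!length(ri)) next
    inCor <- rep(FALSE, length(pos)); inWin <- rep(FALSE, length(pos))
    for (i in ri) {
      inCor <- inCor | (pos >= rec$left[i] & pos <= rec$right[i])
      mid <- (rec$left[i] + rec$right[i]) / 2
      inWin <- inWin | (pos >= mid - window / 2 & pos <= mid + window / 2)
    }
    mafCor <- c(mafCor, maf[ok & inCor])
    mafCtrl <- c(mafCtrl, maf[ok & inWin & !inCor])
  }
  bootCI <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_))
    means <- vapply(seq_len(nBoot), function(b)
      mean(sample(x, length(x), replace = TRUE)), numeric(1))
    unname(quantile(means, c(0.025, 0.975)))
  }
  p <- if (length(mafCor) && length(mafCtrl))
    suppressWarnings(wilcox.test(mafCor, mafCtrl)$p.value)
  else NA_real_
  list(corMean = if (length(mafCor)) mean(mafCor) else NA_real_,
       corCI = bootCI(mafCor),
       ctrlMean = if (length(mafCtrl)) mean(mafCtrl) else NA_real_,
       ctrlCI = bootCI(mafCtrl),
       p.value = p, nCor = length(mafCor), nCtrl = length(mafCtrl))
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

#' Classify sampled sites as synonymous / nonsynonymous / noncoding
#'
#' For each retained site inside an annotated CDS exon, reconstructs the
#' codon using the panel's majority symbol at the other two codon positions
#' and asks whether swapping the site's two alleles changes the encoded
#' amino acid.  Sites outside exons are \code{"noncoding"}; monomorphic
#' sites are \code{"monomorphic"}; sites whose codon context is unavailable
#' or itself segregating are \code{"excluded"}.
#'
#' @param sp a \linkS4class{SampledPanel}.
#' @param annotation \code{GRanges} with type/gene_id/phase columns and
#'   stranded exons forming in-frame CDS per gene.
#' @return named-by-scaffold list of per-site class labels, parallel to
#'   \code{sampledSites}.
#' @export
classifySites <- function(sp, annotation) {
  ex <- annotation[annotation$type == "exon"]
  exd <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene = ex$gene_id, stringsAsFactors = FALSE)
  # per-gene exon tables in transcription order with cumulative CDS offsets
  genes <- split(exd, exd$gene)
  genes <- lapply(genes, function(g) {
    g <- g[order(g$start, decreasing = g$strand[1] == "-"), , drop = FALSE]
    w <- g$end - g$start + 1L
    g$cdsBefore <- c(0L, cumsum(w))[seq_len(nrow(g))]
    if (any(g$strand != g$strand[1])) stop("invalid frame: mixed strand gene")
    g
  })
  cdsToGenomic <- function(g, cds) {   # vectorized over cds coords
    res <- integer(length(cds))
    for (e in seq_len(nrow(g))) {
      off <- cds - g$cdsBefore[e]
      w <- g$end[e] - g$start[e] + 1L
      inE <- off >= 0L & off < w
      res[inE] <- if (g$strand[1] == "+") g$start[e] + off[inE]
                  else g$end[e] - off[inE]
    }
    res
  }
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (sc in names(sp@sites)) {
    pos <- sp@sites[[sc]]               # 0-based
    cnt <- .alleleCounts(sp, sc)
    nAll <- colSums(cnt > 0)
    major <- .BASES[apply(cnt, 2, which.max)]
    cls <- rep("noncoding", length(pos))
    cls[nAll == 1L] <- "monomorphic"
    exSc <- exd[exd$scaffold == sc, , drop = FALSE]
    if (!nrow(exSc)) { out[[sc]] <- cls; next }
    p1 <- pos + 1L
    hit <- rep(NA_integer_, length(pos))
    for (e in seq_len(nrow(exSc)))
      hit[p1 >= exSc$start[e] & p1 <= exSc$end[e]] <- e
    posIndex <- function(gp) match(gp - 1L, pos)   # genomic 1-based -> site idx
    for (i in which(!is.na(hit))) {
      if (nAll[i] != 2L) { if (nAll[i] > 2L) cls[i] <- "excluded"; next }
      e <- exSc[hit[i], ]
      g <- genes[[e$gene]]
      ei <- which(g$start == e$start & g$end == e$end)
      cds <- if (e$strand == "+") g$cdsBefore[ei] + (p1[i] - e$start)
             else g$cdsBefore[ei] + (e$end - p1[i])
      codonStart <- (cds %/% 3L) * 3L
      cdsPos <- codonStart + 0:2
      gpos <- cdsToGenomic(g, cdsPos)
      codon <- character(3)
      bad <- FALSE
      for (j in 1:3) {
        if (cdsPos[j] == cds) next
        si <- posIndex(gpos[j])
        if (is.na(si) || nAll[si] > 1L) { bad <- TRUE; break }
        codon[j] <- major[si]
      }
      if (bad) { cls[i] <- "excluded"; next }
      alle <- .BASES[cnt[, i] > 0]
      slot <- which(cdsPos == cds)
      mk <- function(a) {
        cd <- codon; cd[slot] <- a
        if (e$strand == "-") cd <- .complement(cd)
        paste(cd, collapse = "")
      }
      aa <- code[c(mk(alle[1]), mk(alle[2]))]
      if (any(is.na(aa))) { cls[i] <- "excluded"; next }
      cls[i] <- if (aa[1] == aa[2]) "synonymous" else "nonsynonymous"
    }
    out[[sc]] <- cls
  }
  out
}

#' Tajima's D
#'
#' Standard Tajima (1989) statistic contrasting mean pairwise differences
#' with the normalized segregating-site count, with the usual
#' a1/a2/b1/b2/c1/c2/e1/e2 constants.  Negative values indicate an excess of
#' rare variants.  Undefined (NA) when no site segregates.
#'
#' @param x a \linkS4class{SampledPanel}, or a character matrix of
#'   haplotypes (rows) by sites (columns).
#' @param regions optional data.frame (scaffold, left, right; 0-based
#'   inclusive) restricting the site set (SampledPanel method only).
#' @return list with D, S, pairwiseMean, n.
#' @export
setGeneric("tajimasD", function(x, regions = NULL) standardGeneric("tajimasD"))

.tajima <- function(piSites, segregating, n) {
  S <- sum(segregating)
  if (S < 1) return(list(D = NA_real_, S = 0L, pairwiseMean = 0, n = n))
  khat <- sum(piSites)     # mean pairwise differences, summed over sites
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = as.integer(S), pairwiseMean = khat, n = n)
}

#' @describeIn tajimasD from a sampled panel, optionally within regions.
#' @export
setMethod("tajimasD", "SampledPanel", function(x, regions = NULL) {
  if (x@sampleN < 4L) stop("need sample size >= 4")
  ps <- numeric(0); seg <- logical(0)
  for (sc in names(x@sites)) {
    pos <- x@sites[[sc]]
    keep <- rep(TRUE, length(pos))
    if (!is.null(regions)) {
      keep <- rep(FALSE, length(pos))
      ri <- which(regions$scaffold == sc)
      for (i in ri)
        keep <- keep | (pos >= regions$left[i] & pos <= regions$right[i])
    }
    p <- .piSites(x, sc)[keep]
    cnt <- .alleleCounts(x, sc)[, keep, drop = FALSE]
    ps <- c(ps, p); seg <- c(seg, colSums(cnt > 0) >= 2L)
  }
  .tajima(ps, seg, x@sampleN)
})

#' @describeIn tajimasD from a plain haplotype character matrix.
#' @export
setMethod("tajimasD", "matrix", function(x, regions = NULL) {
  n <- nrow(x)
  if (n < 4L) stop("need sample size >= 4")
  ps <- apply(x, 2, function(col) {
    cc <- table(col[col %in% .BASES])
    m <- sum(cc)
    if (m < 2) return(NA_real_)
    1 - sum(cc * (cc - 1)) / (m * (m - 1))
  })
  seg <- apply(x, 2, function(col) length(unique(col[col %in% .BASES])) >= 2)
  .tajima(ps[!is.na(ps)], seg[!is.na(ps)], n)
})
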