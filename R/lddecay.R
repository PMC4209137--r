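# Linkage disequilibrium: the two-site r2 statistic and the cross-COR vs
# distal-control comparison.

#' Two-site linkage disequilibrium r2
#'
#' For two biallelic sites typed on the same haplotypes, computes
#' \deqn{r^2 = (x_{11} - p_1 q_1)^2 / (p_1 p_2 q_1 q_2)}
#' where \eqn{x_{11}} is the frequency of the haplotype carrying the first
#' allele at both sites and \eqn{p}/\eqn{q} are the allele frequencies at
#' the two sites.  Invariant under allele relabeling and site swapping, and
#' identical to the squared Pearson correlation of 0/1-coded alleles.
#'
#' @param g1,g2 equal-length vectors of allele symbols (no missing values),
#'   each with exactly two distinct values.
#' @return r2 in [0, 1].
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("sites must be typed on the same haplotypes")
  a1 <- unique(g1); a2 <- unique(g2)
  if (length(a1) != 2L || length(a2) != 2L)
    stop("both sites must be biallelic in the sample")
  n <- length(g1)
  p1 <- mean(g1 == a1[1]); p2 <- 1 - p1
  q1 <- mean(g2 == a2[1]); q2 <- 1 - q1
  x11 <- mean(g1 == a1[1] & g2 == a2[1])
  (x11 - p1 * q1)^2 / (p1 * p2 * q1 * q2)
}

#' LD across COR midpoints vs distal control windows
#'
#' For every COR midpoint, samples SNP pairs that straddle the midpoint
#' (class \code{cross_cor}) and SNP pairs lying wholly inside a window of
#' width \code{maxPairDist} centered \code{offset} nt away from the midpoint
#' (class \code{control}; the side alternates per COR).  Each pair uses only
#' individuals carrying A/C/G/T at both sites; if more than \code{sampleN}
#' are callable, \code{sampleN} are drawn at random for that pair, and the
#' pair is kept only if both sites are biallelic among the drawn
#' individuals.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param cors a \linkS4class{CORSet}.
#' @param offset distance from the COR midpoint to the control window
#'   center, nt.
#' @param maxPairDist maximum within-pair distance, nt.
#' @param minN,sampleN callable-individual threshold and per-pair sample
#'   size.
#' @param maxPairsPerCOR cap on sampled pairs per COR and class.
#' @param seed RNG seed.
#' @return data.frame of pairs: scaffold, site1, site2 (0-based), distance,
#'   r2, class, n.  Empty (with a warning) when no pair is eligible.
#' @export
ldAroundCORs <- function(panel, cors, offset = 10000L, maxPairDist = 5000L,
                         minN = 10L, sampleN = 10L, maxPairsPerCOR = 200L,
                         seed = 1L) {
  set.seed(as.integer(seed))
  rec <- cors@records
  out <- list()
  for (sc in unique(rec$scaffold)) {
    if (!sc %in% names(panel@seqs)) next
    m <- panel@seqs[[sc]]
    call <- matrix(m %in% .BASE_BYTES, nrow = nrow(m))
    nCall <- .colSums(call, nrow(call), ncol(call))
    # pre-screen: polymorphic among all callable individuals
    counts <- vapply(as.list(.BASE_BYTES), function(bb)
      .colSums(m == bb & call, nrow(m), ncol(m)), numeric(ncol(m)))
    poly <- which(nCall >= minN & rowSums(counts > 0) >= 2L) # 1-based columns
    if (length(poly) < 2L) next
    ppos <- poly - 1L                                        # 0-based
    ri <- which(rec$scaffold == sc)
    for (ii in seq_along(ri)) {
      i <- ri[ii]
      mid <- (rec$left[i] + rec$right[i]) / 2
      evalPairs <- function(cands, cls) {
        if (is.null(cands) || !nrow(cands)) return(NULL)
        if (nrow(cands) > maxPairsPerCOR)
          cands <- cands[sample.int(nrow(cands), maxPairsPerCOR), , drop = FALSE]
        rows <- lapply(seq_len(nrow(cands)), function(r) {
          s1 <- cands[r, 1]; s2 <- cands[r, 2]   # 1-based columns
          ok <- which(call[, s1] & call[, s2])
          if (length(ok) < minN) return(NULL)
          if (length(ok) > sampleN) ok <- sample(ok, sampleN)
          g1 <- m[ok, s1]; g2 <- m[ok, s2]
          if (length(unique(g1)) != 2L || length(unique(g2)) != 2L) return(NULL)
          data.frame(scaffold = sc, site1 = s1 - 1L, site2 = s2 - 1L,
                     distance = s2 - s1, r2 = ldR2(g1, g2), class = cls,
                     n = length(ok), stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
      }
      # cross pairs straddle the midpoint; bound the candidate grid before
      # enumeration
      capSites <- max(20L, as.integer(ceiling(sqrt(4 * maxPairsPerCOR))))
      leftI <- poly[ppos >= mid - maxPairDist & ppos < mid]
      rightI <- poly[ppos > mid & ppos <= mid + maxPairDist]
      if (length(leftI) > capSites) leftI <- sort(sample(leftI, capSites))
      if (length(rightI) > capSites) rightI <- sort(sample(rightI, capSites))
      cross <- NULL
      if (length(leftI) && length(rightI)) {
        cross <- expand.grid(s1 = leftI, s2 = rightI)
        cross <- cross[cross$s2 - cross$s1 <= maxPairDist, , drop = FALSE]
      }
      # control pairs wholly inside the offset window (side alternates)
      side <- if (ii %% 2L == 1L) 1 else -1
      ctr <- mid + side * offset
      winI <- poly[ppos >= ctr - maxPairDist / 2 & ppos <= ctr + maxPairDist / 2]
      if (length(winI) > capSites) winI <- sort(sample(winI, capSites))
      ctl <- NULL
      if (length(winI) >= 2L) {
        ctl <- t(utils::combn(winI, 2L))
        colnames(ctl) <- c("s1", "s2")
        ctl <- as.data.frame(ctl)
        ctl <- ctl[ctl$s2 - ctl$s1 <= maxPairDist, , drop = FALSE]
      }
      out[[length(out) + 1L]] <- rbind(evalPairs(cross, "cross_cor"),
                                       evalPairs(ctl, "control"))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) {
    warning("no eligible SNP pairs")
    res <- data.frame(scaffold = character(0), site1 = integer(0),
                      site2 = integer(0), distance = integer(0),
                      r2 = numeric(0), class = character(0), n = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Summarize LD pairs by distance bin
#'
#' Mean r2 per class per distance bin.
#'
#' @param pairs data.frame from \code{\link{ldAroundCORs}}.
#' @param binWidth distance bin width, nt.
#' @return data.frame with class, bin (left edge, nt), meanR2, nPairs.
#' @export
ldSummary <- function(pairs, binWidth = 100L) {
  if (!nrow(pairs))
    return(data.frame(class = character(0), bin = numeric(0),
                      meanR2 = numeric(0), nPairs = integer(0)))
  bin <- floor(pairs$distance / binWidth) * binWidth
  agg <- aggregate(pairs$r2, by = list(class = pairs$class, bin = bin), mean)
  cnt <- aggregate(pairs$r2, by = list(class = pairs$class, bin = bin), length)
  data.frame(class = agg$class, bin = agg$bin, meanR2 = agg$x,
             nPairs = cnt$x)
}

# combn without loading utils into the search path explicitly
#' @importFrom utils combn
#' @importFrom stats aggregate
NULL
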