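# Interparental marker calling and parental-origin assignment.

#' Call interparental marker sites between two aligned parents
#'
#' Scans two aligned, equal-length haploid genomes and returns every position
#' where both parents carry an unambiguous A/C/G/T and the two bases differ.
#' Sites with gaps, N or any IUPAC ambiguity in either parent are excluded.
#' Symbols are case-insensitive (soft-masking is ignored).
#'
#' @param parentA,parentB aligned genomes: \code{DNAStringSet} or named
#'   character vectors with identical scaffold names and lengths.
#' @return a \linkS4class{MarkerSet}, sorted by scaffold and position.
#' @examples
#' callMarkers(c(s = "ACGT"), c(s = "AGGT"))
#' @export
callMarkers <- function(parentA, parentB) {
  a <- .genomeBytes(parentA)
  b <- .genomeBytes(parentB)
  if (!identical(names(a), names(b)))
    stop("parents must share scaffold names")
  out <- lapply(names(a), function(sc) {
    x <- a[[sc]]; y <- b[[sc]]
    if (length(x) != length(y))
      stop(sprintf("length mismatch on scaffold '%s'", sc))
    i <- which(x != y & .isACGT(x) & .isACGT(y))
    if (!length(i)) return(NULL)
    data.frame(scaffold = sc, pos = i - 1L,
               allele_a = strsplit(rawToChar(x[i]), "")[[1]],
               allele_b = strsplit(rawToChar(y[i]), "")[[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(MarkerSet(character(0), integer(0), character(0), character(0)))
  MarkerSet(out$scaffold, out$pos, out$allele_a, out$allele_b)
}

#' Assign parental origin along one offspring
#'
#' At every marker site, calls \code{"A"} when the offspring carries the
#' parent-A allele, \code{"B"} for the parent-B allele, and \code{"U"} for
#' any other symbol (gap, N, third allele).  \code{"U"} absorbs all
#' non-matches; no error is raised for messy data.
#'
#' @param offspring aligned offspring genome (same coordinates as parents).
#' @param markers a \linkS4class{MarkerSet}.
#' @param id offspring identifier stored in the result.
#' @return an \linkS4class{OriginCalls}.
#' @export
assignOrigin <- function(offspring, markers, id = "offspring") {
  o <- .genomeBytes(offspring)
  call <- character(length(markers))
  aBytes <- charToRaw(paste(markers@alleleA, collapse = ""))
  bBytes <- charToRaw(paste(markers@alleleB, collapse = ""))
  for (sc in unique(markers@scaffold)) {
    i <- which(markers@scaffold == sc)
    if (!sc %in% names(o))
      stop(sprintf("offspring lacks scaffold '%s'", sc))
    sym <- o[[sc]][markers@pos[i] + 1L]
    call[i] <- ifelse(sym == aBytes[i], "A",
                      ifelse(sym == bBytes[i], "B", "U"))
  }
  OriginCalls(id, markers@scaffold, markers@pos, call)
}

#' Mean spacing between consecutive interparental markers
#'
#' Average positional difference (right minus left) between consecutive
#' markers, pooled over all scaffolds (gaps never span scaffold boundaries).
#' With per-site difference probability \eqn{p} the expectation is
#' \eqn{\approx 1/p}; at 14\% divergence markers are about 7 nt apart.
#'
#' @param markers a \linkS4class{MarkerSet} with at least 2 markers on some
#'   scaffold.
#' @return mean gap length, nt.
#' @export
meanMarkerSpacing <- function(markers) {
  gaps <- markerGaps(markers)
  if (nrow(gaps) == 0L)
    stop("undefined result: need at least 2 markers on one scaffold")
  mean(gaps$length)
}

#' Inter-marker gaps
#'
#' All intervals between consecutive markers on the same scaffold; the
#' candidate pool for identity-tract-matched control regions.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @return data.frame with columns scaffold, left, right, length (0-based
#'   marker positions; length = right - left).
#' @export
markerGaps <- function(markers) {
  res <- lapply(unique(markers@scaffold), function(sc) {
    p <- markers@pos[markers@scaffold == sc]
    if (length(p) < 2L) return(NULL)
    data.frame(scaffold = sc, left = p[-length(p)], right = p[-1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(scaffold = character(0), left = integer(0),
                      right = integer(0), length = integer(0)))
  res$length <- res$right - res$left
  res
}
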