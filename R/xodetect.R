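# Crossover detection from parental-origin vectors: run-length rule,
# complex-tract classification, boundary filters, sliding-window genotype.

#' Detect crossovers with the run-length support rule
#'
#' Scans the origin calls of one offspring and emits one crossover region
#' (COR) per boundary between maximal same-origin runs where \emph{both}
#' flanking runs contain at least \code{k} markers.  Undetermined (\code{U})
#' calls are dropped before run-length analysis, so missing data does not
#' break support runs.  A short transferred block creates an interior run
#' shorter than \code{k}, so neither of its boundaries is emitted — this is
#' exactly the exclusion of double crossovers transferring fewer than
#' \code{k} markers.
#'
#' The COR spans from the last marker of the left run to the first marker of
#' the right run; its length is the positional difference between these two
#' flanking markers (the interparental identity tract in which the exchange
#' occurred).
#'
#' @param origin an \linkS4class{OriginCalls}.
#' @param k minimum markers supporting each flank (typically 10, 50 or 100).
#' @return a \linkS4class{CORSet} (all records classed \code{"simple"};
#'   see \code{\link{classifyComplex}}).
#' @export
detectCrossovers <- function(origin, k = 10L) {
  stopifnot(k >= 1L)
  recs <- list()
  keep <- origin@call != "U"
  scf <- origin@scaffold[keep]; pos <- origin@pos[keep]; cl <- origin@call[keep]
  for (sc in unique(scf)) {
    i <- scf == sc
    p <- pos[i]; v <- cl[i]
    if (length(v) < 2L) next
    r <- rle(v)
    if (length(r$lengths) < 2L) next
    ends <- cumsum(r$lengths)
    bi <- which(r$lengths[-length(r$lengths)] >= k & r$lengths[-1] >= k)
    for (bj in bi) {
      li <- ends[bj]                 # index of last marker of left run
      recs[[length(recs) + 1L]] <- data.frame(
        offspring = origin@offspring, scaffold = sc,
        left = p[li], right = p[li + 1L], length = p[li + 1L] - p[li],
        orientation = paste0(r$values[bj], "->", r$values[bj + 1L]),
        left_run = r$lengths[bj], right_run = r$lengths[bj + 1L],
        class = "simple", stringsAsFactors = FALSE)
    }
  }
  CORSet(if (length(recs)) do.call(rbind, recs) else
    data.frame(offspring = character(0), scaffold = character(0),
               left = integer(0), right = integer(0), length = integer(0),
               orientation = character(0), left_run = integer(0),
               right_run = integer(0), class = character(0),
               stringsAsFactors = FALSE))
}

#' Flag complex conversion-tract candidates
#'
#' A parental-origin pattern alternating more than once over a short span
#' (e.g. A-B-A-B) indicates patchwork repair rather than a single reciprocal
#' exchange.  All origin switches are recomputed at a relaxed support
#' threshold \code{relaxedK}; wherever three or more switches fall within
#' \code{window} nt, the detected CORs at those switches are flagged
#' \code{"complex_candidate"}.
#'
#' @param cors a \linkS4class{CORSet} for the same offspring.
#' @param origin the offspring's \linkS4class{OriginCalls}.
#' @param window span (nt) within which >= 3 switches flag a complex tract.
#' @param relaxedK support threshold for the switch scan (default 1: every
#'   switch counts).
#' @return the \linkS4class{CORSet} with updated \code{class} column.
#' @export
classifyComplex <- function(cors, origin, window = 1000L, relaxedK = 1L) {
  rec <- cors@records
  if (!nrow(rec)) return(cors)
  sw <- detectCrossovers(origin, k = relaxedK)@records
  flagged <- logical(nrow(sw))
  for (sc in unique(sw$scaffold)) {
    i <- which(sw$scaffold == sc)
    s <- (sw$left[i] + sw$right[i]) / 2
    if (length(s) >= 3L)
      for (j in seq_len(length(s) - 2L))
        if (s[j + 2L] - s[j] <= window)
          flagged[i[j:(j + 2L)]] <- TRUE
  }
  key <- function(df) paste(df$scaffold, df$left, df$right)
  hit <- key(rec) %in% key(sw[flagged, , drop = FALSE])
  rec$class <- ifelse(hit, "complex_candidate", "simple")
  CORSet(rec)
}

#' Drop CORs near scaffold boundaries
#'
#' Removes CORs overlapping the first or last \code{margin} nt of their
#' scaffold, guarding against assembly artifacts near contig ends.
#'
#' @param cors a \linkS4class{CORSet}.
#' @param scaffoldLengths named integer vector of scaffold lengths.
#' @param margin exclusion width at each boundary, nt.
#' @return filtered \linkS4class{CORSet}.
#' @export
boundaryFilter <- function(cors, scaffoldLengths, margin = 500L) {
  stopifnot(margin >= 0L)
  rec <- cors@records
  if (!nrow(rec) || margin == 0L) return(cors)
  L <- scaffoldLengths[rec$scaffold]
  keep <- rec$left >= margin & rec$right <= L - margin
  CORSet(rec[keep, , drop = FALSE])
}

#' Sliding-window majority genotype
#'
#' Per-window majority parental origin along a scaffold (windows of
#' \code{window} nt advanced by \code{step} nt), for coarse visualization of
#' offspring mosaics.  A tie or an empty window yields \code{"U"}.
#'
#' @param origin an \linkS4class{OriginCalls}.
#' @param scaffoldLengths named integer vector of scaffold lengths.
#' @param window,step window and step sizes, nt; requires
#'   \code{window >= step}.
#' @return data.frame with scaffold, start, end (0-based half-open), call.
#' @export
smoothGenotype <- function(origin, scaffoldLengths, window = 100000L,
                           step = 25000L) {
  if (window < step) stop("'window' must be >= 'step'")
  out <- list()
  for (sc in names(scaffoldLengths)) {
    L <- scaffoldLengths[[sc]]
    i <- origin@scaffold == sc
    p <- origin@pos[i]; v <- origin@call[i]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    ends <- pmin(starts + window, L)
    call <- vapply(seq_along(starts), function(w) {
      inw <- v[p >= starts[w] & p < ends[w]]
      nA <- sum(inw == "A"); nB <- sum(inw == "B")
      if (nA > nB) "A" else if (nB > nA) "B" else "U"
    }, character(1))
    out[[sc]] <- data.frame(scaffold = sc, start = starts, end = ends,
                            call = call, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extract COR sequences with flanks
#'
#' Returns the genomic sequence of each COR plus \code{flank} nt on each
#' side, clipped at scaffold ends — the input expected by external motif
#' discovery tools.  With \code{flank = 0} the record spans the inclusive
#' interval [left, right], i.e. COR length + 1 bases.
#'
#' @param cors a \linkS4class{CORSet}.
#' @param genome \code{DNAStringSet} to slice (e.g. the offspring or a
#'   parent).
#' @param flank flank width, nt.
#' @return \code{DNAStringSet} named \code{offspring|scaffold|left-right}.
#' @export
extractCORContext <- function(cors, genome, flank = 400L) {
  stopifnot(flank >= 0L)
  rec <- cors@records
  gb <- .genomeBytes(genome)
  seqs <- character(nrow(rec)); nms <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    L <- length(gb[[rec$scaffold[i]]])
    from <- max(0L, rec$left[i] - flank) + 1L          # 1-based
    to <- min(L, rec$right[i] + 1L + flank)
    seqs[i] <- rawToChar(gb[[rec$scaffold[i]]][from:to])
    nms[i] <- sprintf("%s|%s|%d-%d", rec$offspring[i], rec$scaffold[i],
                      rec$left[i], rec$right[i])
  }
  Biostrings::DNAStringSet(setNames(seqs, nms))
}
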