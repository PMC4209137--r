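# Independent oracles and small fixture builders used across tests.
# These re-derive expected values by brute force / literal formulas and must
# stay independent of the package implementation paths they check.

# terse string concatenation for origin-call patterns
`%.%` <- function(a, b) paste0(a, b)

# SimConfig scaled for small test genomes: few, narrow hotspots so that
# placement always succeeds; every other default untouched and overridable.
testConfig <- function(...) {
  args <- list(...)
  if (is.null(args$hotspotCount)) args$hotspotCount <- 2L
  if (is.null(args$hotspotWidth)) args$hotspotWidth <- 500L
  do.call(SimConfig, args)
}

# Brute-force crossover scanner: tests every boundary between adjacent
# retained markers by explicit left/right same-origin counting.
bruteForceCORs <- function(pos, calls, k) {
  keep <- calls != "U"
  pos <- pos[keep]; calls <- calls[keep]
  n <- length(calls)
  out <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    if (calls[i] == calls[i + 1L]) next
    l <- 0L; j <- i
    while (j >= 1L && calls[j] == calls[i]) { l <- l + 1L; j <- j - 1L }
    r <- 0L; j <- i + 1L
    while (j <= n && calls[j] == calls[i + 1L]) { r <- r + 1L; j <- j + 1L }
    if (l >= k && r >= k)
      out[[length(out) + 1L]] <- data.frame(
        left = pos[i], right = pos[i + 1L],
        orientation = paste0(calls[i], "->", calls[i + 1L]),
        left_run = l, right_run = r, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(left = integer(0), right = integer(0),
               orientation = character(0), left_run = integer(0),
               right_run = integer(0))
}

# Mean pairwise dissimilarity over all haplotype pairs (character matrix,
# rows = haplotypes).
bruteForcePi <- function(mat) {
  n <- nrow(mat)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(mat[i, ] != mat[j, ])
    np <- np + 1
  }
  tot / np
}

# Tajima's D from first principles (independent literal evaluation).
tajimaOracle <- function(mat) {
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(mat[i, ] != mat[j, ]); np <- np + 1
  }
  khat <- k / np
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# One-sample KS statistic against Exp(rate) evaluated only at sample points.
ksStatOracle <- function(x, rate) {
  x <- sort(x); n <- length(x)
  Fx <- 1 - exp(-rate * x)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

# Build a SampledPanel from a character matrix (rows = haplotypes) by
# passing it through the joint site filter against itself.
spFromMatrix <- function(mat, sampleN = nrow(mat), seed = 1L) {
  seqs <- list(scaffold_1 = apply(mat, 1, paste, collapse = ""))
  p <- HaplotypePanel(seqs, panelID = "toy")
  sampleSites(p, p, minN = sampleN, sampleN = sampleN, seed = seed)[[1]]
}

# OriginCalls with unit marker spacing from a call string like "AAABBB".
originFromString <- function(s, id = "o1", scaffold = "scaffold_1",
                             pos = NULL) {
  calls <- strsplit(s, "")[[1]]
  if (is.null(pos)) pos <- seq_along(calls) - 1L
  OriginCalls(id, rep(scaffold, length(calls)), pos, calls)
}

# Tiny all-exon / no-exon annotations.
annotationAll <- function(type, L, scaffold = "scaffold_1") {
  gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(1L, L),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = type, gene_id = "g1", phase = 0L)
  gr
}
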