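# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.BASE_BYTES <- charToRaw("ACGT")

# Convert a DNAStringSet / character vector of scaffold sequences into a
# named list of uppercase raw byte vectors.  All per-site arithmetic in the
# package runs on raw bytes; sequences are only materialized as Biostrings
# objects at I/O boundaries.
.genomeBytes <- function(genome) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) && length(genome) == 1L) names(genome) <- "scaffold_1"
  stopifnot(!is.null(names(genome)))
  lapply(genome, function(s) charToRaw(toupper(s)))
}

.bytesToString <- function(b) rawToChar(b)

.isACGT <- function(b) b %in% .BASE_BYTES

# Derive a stream of reproducible sub-seeds from a master seed.  Keeps all
# derived seeds within 32-bit integer range.
.subSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.checkFraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("configuration error: '%s' must lie in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# scaffold lengths from a genome-like object
.scaffoldLengths <- function(genome) {
  if (methods::is(genome, "XStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(.genomeBytes(genome), length, integer(1))
  }
}
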