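# Format suite: FASTA (Biostrings), GFF3/BED (rtracklayer), TSV reports.
# Conventions: GFF3 1-based inclusive; BED 0-based half-open; internal marker
# and COR coordinates 0-based.

#' Read an aligned genome from multi-FASTA
#'
#' @param path FASTA file.
#' @return \code{DNAStringSet} named by the first whitespace-delimited token
#'   of each header.
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a genome to multi-FASTA
#'
#' Headers carry the scaffold name plus \code{role=} and \code{seed=} tags
#' so every simulated output records its provenance.
#'
#' @param genome \code{DNAStringSet}.
#' @param path output file.
#' @param role role tag (parentA, parentB, offspring_01, panel ids, ...).
#' @param seed seed tag (optional).
#' @export
writeGenomeFasta <- function(genome, path, role = NULL, seed = NULL) {
  x <- genome
  tags <- c(if (!is.null(role)) paste0("role=", role),
            if (!is.null(seed)) paste0("seed=", seed))
  if (length(tags))
    names(x) <- paste(names(x), paste(tags, collapse = " "))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read annotation from GFF3
#'
#' 1-based inclusive coordinates as per GFF3; the returned \code{GRanges}
#' keeps \code{type}, \code{gene_id} and \code{phase} columns.
#'
#' @param path GFF3 file.
#' @return annotation \code{GRanges}.
#' @export
readAnnotationGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- intersect(c("type", "gene_id", "phase"), names(S4Vectors::mcols(gr)))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  gr$type <- as.character(gr$type)
  gr
}

#' Write annotation to GFF3
#'
#' @param annotation \code{GRanges} with type/gene_id/phase columns.
#' @param path output file.
#' @export
writeAnnotationGFF3 <- function(annotation, path) {
  gr <- annotation
  gr$source <- "meioscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write / read the marker table (TSV)
#'
#' Columns: scaffold, pos0 (0-based), allele_a, allele_b; '#'-prefixed
#' comment lines allowed.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param path TSV file.
#' @name markerTableIO
#' @export
writeMarkerTable <- function(markers, path) {
  df <- as.data.frame(markers)
  names(df)[names(df) == "pos"] <- "pos0"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname markerTableIO
#' @export
readMarkerTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  MarkerSet(df$scaffold, df$pos0, df$allele_a, df$allele_b)
}

#' Write CORs as BED6 and as a rich TSV
#'
#' BED is 0-based half-open: chromStart = left marker position, chromEnd =
#' right marker position + 1; name = offspring, score = min(left_run,
#' right_run) capped at 1000, strand "+" for A->B and "-" for B->A.
#'
#' @param cors a \linkS4class{CORSet}.
#' @param path output file.
#' @name corIO
#' @export
writeCORBed <- function(cors, path) {
  r <- cors@records
  bed <- data.frame(chrom = r$scaffold, start = r$left, end = r$right + 1L,
                    name = r$offspring,
                    score = pmin(1000L, pmin(r$left_run, r$right_run)),
                    strand = ifelse(r$orientation == "A->B", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname corIO
#' @export
readCORBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             left = GenomicRanges::start(gr) - 1L,
             right = GenomicRanges::end(gr) - 1L,
             offspring = gr$name,
             score = as.integer(gr$score),
             orientation = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                                  "A->B", "B->A"),
             stringsAsFactors = FALSE)
}

#' @rdname corIO
#' @export
writeCORTable <- function(cors, path) {
  write.table(cors@records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the truth breakpoint table (TSV)
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output file.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth@breakpoints, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
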