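#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames
#' @importFrom stats setNames rexp runif rbinom rpois quantile sd ks.test
#'   chisq.test wilcox.test pexp cor median
#' @importFrom utils write.table read.table packageVersion
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration for the synthetic-cross generator
#'
#' Bundles every tunable of the synthetic hypervariable cross: genome layout,
#' interparental divergence, exon structure, crossover placement model,
#' population-panel diversity and LD scale.  Defaults emulate a cross between
#' two haploid fungal individuals at 14\% genome-wide divergence with two
#' population panels at \eqn{\pi \approx 0.06} and \eqn{0.05}, and 17
#' offspring.
#'
#' @slot genomeLength total genome length, nt.
#' @slot nScaffolds number of scaffolds (genome split evenly).
#' @slot divergence genome-wide realized per-site difference fraction between
#'   the two parents.  When \code{exonDivergenceFactor < 1} the non-exon rate
#'   is inflated so that the mixture still realizes this value.
#' @slot exonFraction fraction of the genome inside exons.
#' @slot exonDivergenceFactor multiplier in (0,1] applied to divergence inside
#'   exons (divergence is suppressed in exons by purifying selection).
#' @slot exonGC,backgroundGC GC fractions inside/outside exons.
#' @slot nOffspring number of F1 offspring.
#' @slot coPerOffspring mean number of crossovers per offspring genome
#'   (Poisson).
#' @slot coModel crossover placement model: \code{"uniform"},
#'   \code{"mmr_biased"}, \code{"exon_biased"} or \code{"hotspot"}.
#' @slot mmrScale length scale (nt) of the mismatch-repair acceptance
#'   function \eqn{1 - \exp(-g/s)} applied to the containing inter-marker gap
#'   of length \eqn{g} under \code{coModel = "mmr_biased"}.
#' @slot coExonWeight relative weight of exonic positions under
#'   \code{coModel = "exon_biased"}.
#' @slot hotspotCount,hotspotWidth number and width (nt) of recombination
#'   hotspots.
#' @slot hotspotIntensity expected extra panel-ancestry breakpoints per
#'   hotspot per haplotype (controls how sharply LD breaks across hotspots).
#' @slot popSizes sizes of the two population panels.
#' @slot popPi target genome-wide nucleotide diversity of the two panels.
#' @slot popExonFactor multiplier in (0,1] applied to founder divergence in
#'   exons for the panels (selection proxy; shifts exonic variants toward
#'   rare frequencies).
#' @slot popSingletonShare share of panel diversity contributed by private
#'   (singleton) mutations rather than founder ancestry.
#' @slot ldDecayScale mean panel ancestry-segment length, nt; sets the LD
#'   decay scale.
#' @slot seed master seed; every randomized output records it.
#' @export
setClass("SimConfig", slots = c(
  genomeLength = "integer", nScaffolds = "integer",
  divergence = "numeric", exonFraction = "numeric",
  exonDivergenceFactor = "numeric", exonGC = "numeric", backgroundGC = "numeric",
  nOffspring = "integer", coPerOffspring = "numeric", coModel = "character",
  mmrScale = "numeric", coExonWeight = "numeric",
  hotspotCount = "integer", hotspotWidth = "integer", hotspotIntensity = "numeric",
  popSizes = "integer", popPi = "numeric", popExonFactor = "numeric",
  popSingletonShare = "numeric", ldDecayScale = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  fr <- function(x, nm, lo = 0, hi = 1) {
    if (any(is.na(x)) || any(x < lo) || any(x > hi))
      msgs <<- c(msgs, sprintf("'%s' must lie in [%g, %g]", nm, lo, hi))
  }
  fr(object@divergence, "divergence")
  fr(object@exonFraction, "exonFraction")
  fr(object@exonGC, "exonGC"); fr(object@backgroundGC, "backgroundGC")
  fr(object@popPi, "popPi"); fr(object@popSingletonShare, "popSingletonShare")
  if (object@exonDivergenceFactor <= 0 || object@exonDivergenceFactor > 1)
    msgs <- c(msgs, "'exonDivergenceFactor' must lie in (0, 1]")
  if (object@popExonFactor <= 0 || object@popExonFactor > 1)
    msgs <- c(msgs, "'popExonFactor' must lie in (0, 1]")
  if (!object@coModel %in% c("uniform", "mmr_biased", "exon_biased", "hotspot"))
    msgs <- c(msgs, sprintf("unknown coModel '%s'", object@coModel))
  if (object@hotspotCount > 0L &&
      object@genomeLength < 10L * object@hotspotWidth)
    msgs <- c(msgs, "'genomeLength' must be at least 10 * hotspotWidth")
  if (length(object@popSizes) != 2L || length(object@popPi) != 2L)
    msgs <- c(msgs, "'popSizes' and 'popPi' must have length 2")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn SimConfig-class Constructor with study-condition defaults.
#' @param ... slot overrides, see slots above.
#' @export
SimConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    genomeLength = 1000000L, nScaffolds = 2L,
    divergence = 0.14, exonFraction = 0.5,
    exonDivergenceFactor = 0.7, exonGC = 0.60, backgroundGC = 0.58,
    nOffspring = 17L, coPerOffspring = 4.2, coModel = "uniform",
    mmrScale = 20, coExonWeight = 5,
    hotspotCount = 10L, hotspotWidth = 2000L, hotspotIntensity = 2,
    popSizes = c(13L, 19L), popPi = c(0.06, 0.05), popExonFactor = 0.5,
    popSingletonShare = 0.15, ldDecayScale = 1000,
    seed = 1L)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown field(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(args)] <- args
  ints <- c("genomeLength", "nScaffolds", "nOffspring", "hotspotCount",
            "hotspotWidth", "popSizes", "seed")
  for (nm in ints) defaults[[nm]] <- as.integer(defaults[[nm]])
  do.call(methods::new, c(list("SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@genomeLength, "nt in", object@nScaffolds,
      "scaffold(s); divergence", object@divergence,
      sprintf("(exon factor %.2f)", object@exonDivergenceFactor), "\n")
  cat("  ", object@nOffspring, " offspring, coModel=", object@coModel,
      " (mean ", object@coPerOffspring, " CO/offspring); seed ", object@seed,
      "\n", sep = "")
  cat("  panels n =", paste(object@popSizes, collapse = "/"),
      "targeting pi =", paste(object@popPi, collapse = "/"), "\n")
})

# ---------------------------------------------------------------------------
# SimTruth
# ---------------------------------------------------------------------------

#' Ground truth of a simulated cross
#'
#' Records the true crossover breakpoints of every offspring (0-based
#' inter-base coordinates: breakpoint \code{b} falls between positions
#' \code{b - 1} and \code{b}), the hotspot intervals, and realized generator
#' parameters.
#'
#' @slot breakpoints data.frame with columns \code{offspring},
#'   \code{scaffold}, \code{pos} (sorted within offspring/scaffold).
#' @slot hotspots \linkS4class{GRanges} of hotspot intervals (1-based).
#' @slot params list of realized values (divergence per compartment, seeds,
#'   config echo).
#' @export
setClass("SimTruth", slots = c(
  breakpoints = "data.frame", hotspots = "GRanges", params = "list"))

setValidity("SimTruth", function(object) {
  bp <- object@breakpoints
  need <- c("offspring", "scaffold", "pos")
  if (!all(need %in% names(bp))) return("breakpoints need offspring/scaffold/pos")
  if (nrow(bp)) {
    o <- order(bp$offspring, bp$scaffold, bp$pos)
    if (!identical(o, seq_len(nrow(bp)))) return("breakpoints must be sorted")
    if (any(bp$pos < 0)) return("breakpoints must lie inside the genome")
  }
  TRUE
})

#' @describeIn SimTruth-class true breakpoints as a data.frame.
#' @param x a SimTruth.
#' @export
truthBreakpoints <- function(x) x@breakpoints

#' @describeIn SimTruth-class hotspot intervals as a GRanges.
#' @export
hotspots <- function(x) x@hotspots

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@breakpoints), "true breakpoint(s) in",
      length(unique(object@breakpoints$offspring)), "offspring;",
      length(object@hotspots), "hotspot(s)\n")
})

# ---------------------------------------------------------------------------
# MarkerSet
# ---------------------------------------------------------------------------

#' Interparental marker sites
#'
#' Sorted single-nucleotide difference sites between the two aligned parents.
#' Only sites where both parents carry an unambiguous A/C/G/T are eligible.
#' Positions are 0-based and strictly increasing within each scaffold.
#'
#' @slot scaffold scaffold of each marker.
#' @slot pos 0-based position.
#' @slot alleleA,alleleB parental alleles (differ at every marker).
#' @export
setClass("MarkerSet", slots = c(
  scaffold = "character", pos = "integer",
  alleleA = "character", alleleB = "character"))

setValidity("MarkerSet", function(object) {
  n <- length(object@pos)
  if (length(object@scaffold) != n || length(object@alleleA) != n ||
      length(object@alleleB) != n) return("slot lengths differ")
  if (n == 0L) return(TRUE)
  if (!all(object@alleleA %in% .BASES) || !all(object@alleleB %in% .BASES))
    return("alleles must be A/C/G/T")
  if (any(object@alleleA == object@alleleB)) return("alleles must differ")
  bad <- tapply(object@pos, object@scaffold, function(p) any(diff(p) <= 0))
  if (any(unlist(bad))) return("positions must be strictly increasing per scaffold")
  TRUE
})

#' @describeIn MarkerSet-class construct from parallel vectors.
#' @param scaffold,pos,alleleA,alleleB parallel marker columns.
#' @export
MarkerSet <- function(scaffold, pos, alleleA, alleleB) {
  methods::new("MarkerSet", scaffold = as.character(scaffold),
               pos = as.integer(pos), alleleA = as.character(alleleA),
               alleleB = as.character(alleleB))
}

#' @export
setMethod("length", "MarkerSet", function(x) length(x@pos))

#' @describeIn MarkerSet-class marker positions (0-based).
#' @param x a MarkerSet.
#' @export
markerPos <- function(x) x@pos

#' @describeIn MarkerSet-class scaffold of each marker.
#' @export
markerScaffold <- function(x) x@scaffold

#' @describeIn MarkerSet-class alleles of parent A.
#' @export
alleleA <- function(x) x@alleleA

#' @describeIn MarkerSet-class alleles of parent B.
#' @export
alleleB <- function(x) x@alleleB

#' @export
setMethod("as.data.frame", "MarkerSet", function(x, ...) {
  data.frame(scaffold = x@scaffold, pos = x@pos,
             allele_a = x@alleleA, allele_b = x@alleleB,
             stringsAsFactors = FALSE)
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet:", length(object@pos), "marker(s) on",
      length(unique(object@scaffold)), "scaffold(s)\n")
  if (length(object@pos) >= 2L)
    cat("  mean spacing:", round(meanMarkerSpacing(object), 2), "nt\n")
})

setMethod("[", "MarkerSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("MarkerSet", scaffold = x@scaffold[i], pos = x@pos[i],
               alleleA = x@alleleA[i], alleleB = x@alleleB[i])
})

# ---------------------------------------------------------------------------
# OriginCalls
# ---------------------------------------------------------------------------

#' Parental-origin calls along one offspring
#'
#' One call per interparental marker: \code{"A"} if the offspring carries the
#' parent-A allele, \code{"B"} for parent B, \code{"U"} for gap/ambiguity/
#' third allele.  Carries the marker coordinates so it is self-contained for
#' downstream crossover detection.
#'
#' @slot offspring offspring identifier.
#' @slot scaffold,pos marker coordinates (0-based), parallel to \code{call}.
#' @slot call character vector over \{A, B, U\}.
#' @export
setClass("OriginCalls", slots = c(
  offspring = "character", scaffold = "character",
  pos = "integer", call = "character"))

setValidity("OriginCalls", function(object) {
  if (length(object@scaffold) != length(object@call) ||
      length(object@pos) != length(object@call)) return("slot lengths differ")
  if (!all(object@call %in% c("A", "B", "U"))) return("calls must be A/B/U")
  TRUE
})

#' @describeIn OriginCalls-class construct from parallel vectors.
#' @param offspring,scaffold,pos,call see slots.
#' @export
OriginCalls <- function(offspring, scaffold, pos, call) {
  methods::new("OriginCalls", offspring = as.character(offspring)[1],
               scaffold = as.character(scaffold), pos = as.integer(pos),
               call = as.character(call))
}

#' @export
setMethod("length", "OriginCalls", function(x) length(x@call))

#' @describeIn OriginCalls-class calls as a character vector.
#' @param x an OriginCalls.
#' @export
originCall <- function(x) x@call

#' @export
setMethod("as.data.frame", "OriginCalls", function(x, ...) {
  data.frame(offspring = rep(x@offspring, length(x@call)),
             scaffold = x@scaffold, pos = x@pos, call = x@call,
             stringsAsFactors = FALSE)
})

setMethod("show", "OriginCalls", function(object) {
  tab <- table(factor(object@call, levels = c("A", "B", "U")))
  cat("OriginCalls for", object@offspring, ":", length(object@call),
      "markers (A:", tab[["A"]], "B:", tab[["B"]], "U:", tab[["U"]], ")\n")
})

# ---------------------------------------------------------------------------
# CORSet
# ---------------------------------------------------------------------------

#' A set of crossover regions (CORs)
#'
#' A COR is the interval between the two interparental markers flanking a
#' detected parental-origin switch: the identity tract in which the crossover
#' occurred.  Coordinates are 0-based marker positions; \code{length} is
#' \code{right - left}.
#'
#' @slot records data.frame with columns \code{offspring}, \code{scaffold},
#'   \code{left}, \code{right}, \code{length}, \code{orientation}
#'   (\code{"A->B"}/\code{"B->A"}), \code{left_run}, \code{right_run},
#'   \code{class} (\code{"simple"}/\code{"complex_candidate"}).
#' @export
setClass("CORSet", slots = c(records = "data.frame"))

setValidity("CORSet", function(object) {
  r <- object@records
  need <- c("offspring", "scaffold", "left", "right", "length",
            "orientation", "left_run", "right_run", "class")
  if (!all(need %in% names(r))) return("missing COR columns")
  if (nrow(r)) {
    if (any(r$left >= r$right)) return("need left < right")
    if (any(r$length != r$right - r$left)) return("length must equal right - left")
    if (any(r$left_run < 1L) || any(r$right_run < 1L))
      return("flanking runs must have >= 1 marker")
  }
  TRUE
})

#' @describeIn CORSet-class construct from a records data.frame.
#' @param records data.frame of COR records (see slots).
#' @export
CORSet <- function(records) {
  if (nrow(records) == 0L)
    records <- data.frame(offspring = character(0), scaffold = character(0),
                          left = integer(0), right = integer(0),
                          length = integer(0), orientation = character(0),
                          left_run = integer(0), right_run = integer(0),
                          class = character(0), stringsAsFactors = FALSE)
  methods::new("CORSet", records = records)
}

#' @export
setMethod("length", "CORSet", function(x) nrow(x@records))

#' @describeIn CORSet-class the underlying records data.frame.
#' @param x a CORSet.
#' @export
corTable <- function(x) x@records

#' @describeIn CORSet-class COR lengths, nt.
#' @export
corLengths <- function(x) x@records$length

#' @describeIn CORSet-class COR midpoints as a data.frame (scaffold, pos).
#' @export
corMidpoints <- function(x) {
  data.frame(scaffold = x@records$scaffold,
             pos = (x@records$left + x@records$right) / 2,
             stringsAsFactors = FALSE)
}

#' @export
setMethod("as.data.frame", "CORSet", function(x, ...) x@records)

setMethod("show", "CORSet", function(object) {
  cat("CORSet:", nrow(object@records), "crossover region(s)")
  if (nrow(object@records))
    cat("; mean length", round(mean(object@records$length), 1), "nt;",
        sum(object@records$class == "complex_candidate"), "complex candidate(s)")
  cat("\n")
})

setAs("CORSet", "GRanges", function(from) {
  r <- from@records
  gr <- GenomicRanges::GRanges(r$scaffold,
                               IRanges::IRanges(start = r$left + 1L,
                                                end = r$right + 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    offspring = r$offspring, orientation = r$orientation, class = r$class)
  gr
})

# ---------------------------------------------------------------------------
# HaplotypePanel / SampledPanel
# ---------------------------------------------------------------------------

#' A panel of aligned haploid genomes
#'
#' Population panel stored as one byte matrix per scaffold (individuals in
#' rows, aligned positions in columns).  Gaps/ambiguities may appear as
#' \code{-} or \code{N}.
#'
#' @slot panelID panel label (e.g. "US", "RU").
#' @slot individuals individual identifiers (row names).
#' @slot seqs named list (by scaffold) of raw byte matrices.
#' @slot metadata free-form list (seeds, realized pi, ...).
#' @export
setClass("HaplotypePanel", slots = c(
  panelID = "character", individuals = "character",
  seqs = "list", metadata = "list"))

setValidity("HaplotypePanel", function(object) {
  if (!length(object@seqs)) return("empty panel")
  if (is.null(names(object@seqs))) return("seqs must be named by scaffold")
  nr <- vapply(object@seqs, nrow, integer(1))
  if (any(nr != length(object@individuals)))
    return("every scaffold matrix must have one row per individual")
  TRUE
})

#' @describeIn HaplotypePanel-class construct from aligned sequences.
#' @param seqs named list (by scaffold) of equal-length character vectors
#'   (one aligned sequence per individual), or a single such vector.
#' @param panelID panel label.
#' @param individuals optional individual ids.
#' @param metadata optional list.
#' @export
HaplotypePanel <- function(seqs, panelID = "panel", individuals = NULL,
                           metadata = list()) {
  if (!is.list(seqs)) seqs <- list(scaffold_1 = seqs)
  mats <- lapply(seqs, function(ss) {
    ss <- toupper(as.character(ss))
    L <- unique(nchar(ss))
    if (length(L) != 1L) stop("aligned sequences must have equal length")
    do.call(rbind, lapply(ss, charToRaw))
  })
  if (is.null(individuals))
    individuals <- sprintf("ind_%02d", seq_len(nrow(mats[[1]])))
  methods::new("HaplotypePanel", panelID = panelID,
               individuals = individuals, seqs = mats, metadata = metadata)
}

#' @describeIn HaplotypePanel-class number of individuals.
#' @param x a HaplotypePanel.
#' @export
panelSize <- function(x) length(x@individuals)

#' @describeIn HaplotypePanel-class byte matrix for one scaffold.
#' @param scaffold scaffold name.
#' @export
panelMatrix <- function(x, scaffold = NULL) {
  if (is.null(scaffold)) scaffold <- names(x@seqs)[1]
  x@seqs[[scaffold]]
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel '", object@panelID, "': ", length(object@individuals),
      " individuals, ", length(object@seqs), " scaffold(s), ",
      sum(vapply(object@seqs, ncol, integer(1))), " nt\n", sep = "")
})

#' Per-site fixed-size subsample of one population panel
#'
#' Result of the joint site filter: sites with at least \code{minN} callable
#' (A/C/G/T) individuals in \emph{both} panels are retained and, at each
#' retained site, a fixed random subset of exactly \code{sampleN} callable
#' individuals is drawn and frozen.  All per-site population statistics
#' (\eqn{\pi}, MAF, Tajima's D) are computed on this object.
#'
#' @slot panelID panel label.
#' @slot sampleN subset size per site.
#' @slot sites named list (by scaffold) of 0-based retained positions.
#' @slot alleles named list of raw byte matrices (\code{sampleN} rows, one
#'   column per retained site).
#' @slot chosen named list of integer matrices of the sampled individual
#'   indices, same shape as \code{alleles}.
#' @export
setClass("SampledPanel", slots = c(
  panelID = "character", sampleN = "integer",
  sites = "list", alleles = "list", chosen = "list"))

setValidity("SampledPanel", function(object) {
  if (!identical(names(object@sites), names(object@alleles)))
    return("sites/alleles scaffold names differ")
  for (sc in names(object@sites)) {
    if (ncol(object@alleles[[sc]]) != length(object@sites[[sc]]))
      return("one allele column per retained site required")
    if (nrow(object@alleles[[sc]]) != object@sampleN)
      return("allele matrix must have sampleN rows")
  }
  TRUE
})

#' @describeIn SampledPanel-class retained 0-based positions for a scaffold.
#' @param x a SampledPanel.
#' @param scaffold scaffold name (default: first).
#' @export
sampledSites <- function(x, scaffold = NULL) {
  if (is.null(scaffold)) scaffold <- names(x@sites)[1]
  x@sites[[scaffold]]
}

#' @describeIn SampledPanel-class sampled allele byte matrix for a scaffold.
#' @export
sampledAlleles <- function(x, scaffold = NULL) {
  if (is.null(scaffold)) scaffold <- names(x@alleles)[1]
  x@alleles[[scaffold]]
}

setMethod("show", "SampledPanel", function(object) {
  cat("SampledPanel '", object@panelID, "': ", object@sampleN,
      " haplotypes/site, ", sum(lengths(object@sites)),
      " retained site(s) on ", length(object@sites), " scaffold(s)\n", sep = "")
})
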