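# End-to-end pipeline driver: simulate or load a cross, then run markers ->
# CO detection -> length nulls -> enrichment -> population patterns -> LD,
# writing every report plus a manifest.

#' Run the full crossover-landscape pipeline
#'
#' Orchestrates the analysis in its natural order: marker calling, origin
#' assignment, crossover detection (with boundary filter and complex-tract
#' scan), the length-biased exponential null and exponential fit, the
#' identity-tract-matched exon/intron permutation tests, population-panel
#' statistics (pi contrast, MAF, Tajima's D) and cross-COR LD.  Inputs come
#' either from a \linkS4class{SimConfig} (a synthetic cross is generated and
#' written out) or from files.  Every randomized stage derives its seed from
#' the master seed; rerunning with the same configuration reproduces every
#' output byte for byte.
#'
#' @param outDir output directory (created if needed).
#' @param config a \linkS4class{SimConfig} used to simulate the cross; or
#'   \code{NULL} to read files.
#' @param parentA,parentB,offspring,annotation,panels file paths (FASTA x3
#'   or list of FASTA for offspring/panels, GFF3 for annotation) used when
#'   \code{config} is \code{NULL}.
#' @param k run-length support threshold.
#' @param margin scaffold-boundary exclusion, nt.
#' @param nPerm permutations for feature enrichment.
#' @param nBoot bootstrap replicates for MAF CIs.
#' @param piWidths window widths for the pi contrast, nt.
#' @param runPanels compute the population/LD stages (needs panels).
#' @param ldOffset,ldMaxPairDist LD stage geometry, nt.
#' @return invisibly, a list with the main objects and the manifest.
#' @export
runPipeline <- function(outDir, config = SimConfig(genomeLength = 300000L),
                        parentA = NULL, parentB = NULL, offspring = NULL,
                        annotation = NULL, panels = NULL,
                        k = 10L, margin = 500L, nPerm = 1000L, nBoot = 1000L,
                        piWidths = c(100L, 400L, 1000L, 4000L, 10000L),
                        runPanels = TRUE, ldOffset = 10000L,
                        ldMaxPairDist = 5000L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[meioscan] ", sprintf(...))
  manifest <- list(package = as.character(packageVersion("meioscan")),
                   rversion = as.character(getRversion()),
                   stages = list(), outputs = character(0))
  emit <- function(name, path) manifest$outputs <<- c(manifest$outputs,
                                                      setNames(path, name))

  if (!is.null(config)) {
    log("simulating cross (seed %d)", config@seed)
    sim <- simulateCross(config, panels = runPanels)
    pA <- sim$parentA; pB <- sim$parentB; ann <- sim$annotation
    offs <- sim$offspring; truth <- sim$truth
    panelList <- sim$panels
    seed <- config@seed
    writeGenomeFasta(pA, file.path(outDir, "parentA.fasta"), "parentA", seed)
    writeGenomeFasta(pB, file.path(outDir, "parentB.fasta"), "parentB", seed)
    writeAnnotationGFF3(ann, file.path(outDir, "annotation.gff3"))
    writeTruthTable(truth, file.path(outDir, "truth_breakpoints.tsv"))
    jsonlite::write_json(
      list(seed = seed, coModel = config@coModel,
           genomeLength = config@genomeLength,
           divergence = config@divergence),
      file.path(outDir, "config.json"), auto_unbox = TRUE)
    manifest$seed <- seed
  } else {
    for (nm in c("parentA", "parentB", "offspring")) {
      if (is.null(get(nm)))
        stop(sprintf("input error: missing input '%s'", nm))
    }
    log("reading inputs")
    pA <- readGenomeFasta(parentA); pB <- readGenomeFasta(parentB)
    offs <- lapply(offspring, readGenomeFasta)
    if (is.null(names(offs)))
      names(offs) <- sprintf("offspring_%02d", seq_along(offs))
    ann <- if (!is.null(annotation)) readAnnotationGFF3(annotation) else NULL
    panelList <- if (!is.null(panels)) lapply(panels, function(p)
      HaplotypePanel(lapply(as.list(readGenomeFasta(p)), as.character))) else NULL
    truth <- NULL
    seed <- 1L
  }
  if (is.null(ann) && nPerm > 0L)
    stop("input error: missing input 'annotation' (required for enrichment)")
  scafLens <- .scaffoldLengths(pA)

  log("calling markers")
  markers <- callMarkers(pA, pB)
  writeMarkerTable(markers, file.path(outDir, "markers.tsv"))
  emit("markers", "markers.tsv")
  manifest$stages$markers <- list(n = length(markers),
                                  meanSpacing = meanMarkerSpacing(markers))

  log("detecting crossovers (k = %d)", k)
  corList <- lapply(names(offs), function(id) {
    org <- assignOrigin(offs[[id]], markers, id = id)
    detectCrossovers(org, k = k)@records
  })
  cors <- CORSet(do.call(rbind, corList))
  cors <- boundaryFilter(cors, scafLens, margin = margin)
  writeCORBed(cors, file.path(outDir, "cors.bed"))
  writeCORTable(cors, file.path(outDir, "cors.tsv"))
  emit("cors", "cors.tsv")
  manifest$stages$detection <- list(k = k, margin = margin, n = length(cors))

  log("length null and exponential fit")
  null <- expectedCORLength(markers)
  fit <- if (length(cors) >= 5L) fitExponentialKS(corLengths(cors)) else
    list(rate = NA, statistic = NA, p.value = NA)
  lenRep <- data.frame(meanGap = null$meanGap,
                       expectedCORLength = null$expectedCORLength,
                       observedMean = if (length(cors)) mean(corLengths(cors)) else NA,
                       observedMedian = if (length(cors)) median(corLengths(cors)) else NA,
                       ksStatistic = fit$statistic, ksP = fit$p.value)
  write.table(lenRep, file.path(outDir, "length_null.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit("length_null", "length_null.tsv")
  manifest$stages$lengthNull <- as.list(lenRep)

  if (length(cors)) {
    log("feature enrichment (%d permutations)", nPerm)
    enr <- lapply(c("exon", "intron"), function(ft)
      permutationEnrichment(cors, markers, ann, feature = ft, nPerm = nPerm,
                            seed = seed + 101L))
    enrRep <- do.call(rbind, lapply(enr, function(e)
      data.frame(feature = e$feature, observed = e$observed,
                 nullMean = mean(e$nullCounts), pEnrich = e$pEnrich,
                 pDeplete = e$pDeplete)))
    write.table(enrRep, file.path(outDir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("enrichment", "enrichment.tsv")
    manifest$stages$enrichment <- enrRep

    log("GC windows")
    gcw <- gcWindows(pA, corMidpoints(cors),
                     widths = c(50L, 200L, 1000L, 5000L), annotation = ann)
    gcRep <- gcw$windows
    gcRep$genomeGC <- gcw$genomeGC; gcRep$exonGC <- gcw$exonGC
    write.table(gcRep, file.path(outDir, "gc_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("gc", "gc_windows.tsv")
  }

  if (runPanels && !is.null(panelList) && length(cors)) {
    log("population patterns")
    spd <- sampleSites(panelList[[1]], panelList[[2]], seed = seed + 202L)
    controls <- sampleMatchedRegions(cors, markers, annotation = ann,
                                     matchExon = TRUE,
                                     nSets = min(nPerm, 200L),
                                     seed = seed + 303L)
    piRep <- do.call(rbind, lapply(seq_along(spd), function(i) {
      pc <- piContrast(spd[[i]], cors, controls, widths = piWidths)
      pc$panel <- spd[[i]]@panelID
      pc
    }))
    write.table(piRep, file.path(outDir, "pi_contrast.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("pi", "pi_contrast.tsv")

    mafRep <- do.call(rbind, lapply(seq_along(spd), function(i) {
      mp <- mafProfile(spd[[i]], cors, nBoot = nBoot, seed = seed + 404L)
      data.frame(panel = spd[[i]]@panelID, corMean = mp$corMean,
                 corLo = mp$corCI[1], corHi = mp$corCI[2],
                 ctrlMean = mp$ctrlMean, ctrlLo = mp$ctrlCI[1],
                 ctrlHi = mp$ctrlCI[2], p = mp$p.value,
                 nCor = mp$nCor, nCtrl = mp$nCtrl)
    }))
    write.table(mafRep, file.path(outDir, "maf_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("maf", "maf_profile.tsv")

    tdRep <- do.call(rbind, lapply(seq_along(spd), function(i) {
      r <- cors@records
      inCor <- tajimasD(spd[[i]], regions = data.frame(
        scaffold = r$scaffold, left = r$left, right = r$right))
      all <- tajimasD(spd[[i]])
      data.frame(panel = spd[[i]]@panelID, D_cor = inCor$D, S_cor = inCor$S,
                 D_all = all$D, S_all = all$S)
    }))
    write.table(tdRep, file.path(outDir, "tajimas_d.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("tajima", "tajimas_d.tsv")

    log("LD around CORs")
    ldRep <- do.call(rbind, lapply(panelList, function(pl) {
      lp <- suppressWarnings(
        ldAroundCORs(pl, cors, offset = ldOffset,
                     maxPairDist = ldMaxPairDist, seed = seed + 505L))
      lp$panel <- if (nrow(lp)) pl@panelID else character(0)
      lp
    }))
    write.table(ldRep, file.path(outDir, "ld_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ldSummary(ldRep), file.path(outDir, "ld_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("ld", "ld_pairs.tsv")
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done: %d outputs in %s", length(manifest$outputs), outDir)
  invisible(list(markers = markers, cors = cors, manifest = manifest))
}
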