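#' Run the full synthetic-cohort concordance pipeline
#'
#' Orchestrates simulate, filter, pairwise classification, cohort summary,
#' CN similarity, barcode clustering, clonality, hotspot and enrichment
#' stages from one YAML configuration, writing every artifact under `outDir`
#' together with an md5 checksum manifest. Stages are checksum-gated: when a
#' stage's outputs exist and the configuration (plus seed) is unchanged, the
#' stage is skipped on a rerun, so outputs are reproducible and reruns
#' resume.
#'
#' @param config path to a YAML file or an equivalent named list. Required
#'   keys: `n_patients`, `window`; optional: `seed`, `min_itx_span`, `sim`
#'   (overrides for [SimConfig()], snake_case), `enrichment` (`n_sims`),
#'   `hotspots` (`bandwidth`, `grid_step`, `threshold`).
#' @param outDir output directory (created).
#' @param seed optional integer overriding the config seed.
#' @return invisibly, a list with the cohort counts, summary and key artifact
#'   paths.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validatePipelineConfig(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  simCfg <- simConfigFromYaml(cfg$sim, seed = cfg$seed)
  window <- cfg$window
  minItxSpan <- if (is.null(cfg$min_itx_span)) 7000 else cfg$min_itx_span
  nSims <- if (is.null(cfg$enrichment$n_sims)) 1000L else as.integer(cfg$enrichment$n_sims)
  hs <- cfg$hotspots
  bandwidth <- if (is.null(hs$bandwidth)) 1e4 else hs$bandwidth
  gridStep <- if (is.null(hs$grid_step)) 1e4 else hs$grid_step
  threshold <- if (is.null(hs$threshold)) 3e-6 else hs$threshold

  hash <- .configHash(cfg)
  hashFile <- file.path(outDir, ".pipeline_hash")
  reportPath <- file.path(outDir, "cohort_report.tsv")
  countsPath <- file.path(outDir, "cohort_counts.tsv")
  if (file.exists(hashFile) && file.exists(reportPath) &&
      identical(readLines(hashFile, warn = FALSE)[1], hash)) {
    .log("runPipeline: outputs up to date, resuming from %s", outDir)
    counts <- utils::read.delim(countsPath, stringsAsFactors = FALSE)
    return(invisible(list(counts = counts, summary = cohortSummary(counts),
                          outDir = outDir)))
  }

  .log("runPipeline: simulating %d patient(s)", cfg$n_patients)
  genome <- simulateGenome(simCfg)
  cohort <- simulateCohort(simCfg, nPatients = cfg$n_patients)
  writeSampleMeta(cohort$manifest, file.path(outDir, "manifest.tsv"))
  writeRearrangements(cohort$pool, file.path(outDir, "pool.bedpe"))

  samplesDir <- file.path(outDir, "samples")
  dir.create(samplesDir, showWarnings = FALSE)
  samples <- list()
  for (p in cohort$patients) {
    for (side in c("primary", "met")) {
      r <- p[[side]]
      id <- r$meta$sample_id
      writeRearrangements(r$rawCalls, file.path(samplesDir, paste0(id, ".raw.bedpe")))
      writeEvidence(r$evidence, file.path(samplesDir, paste0(id, ".evidence.tsv")))
      samples[[id]] <- list(render = r, patient = p$patientId)
    }
  }

  .log("runPipeline: filtering %d sample(s)", length(samples))
  filteredDir <- file.path(outDir, "filtered")
  dir.create(filteredDir, showWarnings = FALSE)
  catalogues <- list()
  for (id in names(samples)) {
    r <- samples[[id]]$render
    f <- filterCatalogue(r$rawCalls, r$meta, normalPool = cohort$pool,
                         genome = genome, minItxSpan = minItxSpan,
                         window = window)
    catalogues[[id]] <- f$catalogue
    writeRearrangements(f$catalogue, file.path(filteredDir, paste0(id, ".bedpe")))
    rep <- data.frame(filter = c("input", names(removedCounts(f$report)), "output"),
                      count = c(f$report@inputCount, removedCounts(f$report),
                                f$report@outputCount))
    utils::write.table(rep, file.path(filteredDir, paste0(id, ".report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .log("runPipeline: classifying matched and cross-patient pairs")
  ids <- names(samples)
  pcs <- list()
  cnPct <- list()
  cnProfiles <- list()
  for (p in cohort$patients)
    cnProfiles[[p$patientId]] <- simulateCnProfiles(
      p$truth@config, sampleIds = paste0(p$patientId, c("_P", "_M")))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- ids[i]; b <- ids[j]
    ra <- samples[[a]]$render; rb <- samples[[b]]$render
    pcs[[length(pcs) + 1L]] <- classifyPair(
      catalogues[[a]], catalogues[[b]], rawA = ra$rawCalls, rawB = rb$rawCalls,
      evA = ra$evidence, evB = rb$evidence, window = window)
  }
  counts <- pairComparisonsToCounts(pcs, cohort$manifest)
  # event-based CN similarity, one value per comparison (first direction row)
  profileOf <- list()
  for (p in cohort$patients) {
    prof <- cnProfiles[[p$patientId]]
    profileOf[[p$primary$meta$sample_id]] <- prof$primary
    profileOf[[p$met$meta$sample_id]] <- prof$metastasis
  }
  counts$cn_pct <- NA_real_
  for (k in seq_along(pcs)) {
    pc <- pcs[[k]]
    win <- unionWindows(profileOf[[pc@sampleA]], profileOf[[pc@sampleB]], genome)
    counts$cn_pct[2L * k - 1L] <- .roundHalfUp(suppressWarnings(cnEventSimilarity(win)))
  }
  utils::write.table(counts, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- cohortSummary(counts)
  utils::write.table(summ$stats, reportPath, sep = "\t", quote = FALSE, row.names = FALSE)

  .log("runPipeline: barcode clustering")
  bm <- buildNonredundant(catalogues, window = window)
  utils::write.table(cbind(sample = rownames(barcodeMatrix(bm)), barcodeMatrix(bm)),
                     file.path(outDir, "barcode_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(barcodeMatrix(bm)) >= 2)
    writeDendrogram(wardCluster(binaryDistance(bm)),
                    file.path(outDir, "dendrogram.nwk"))

  .log("runPipeline: clonality tables")
  clonDir <- file.path(outDir, "clonality")
  dir.create(clonDir, showWarnings = FALSE)
  matchedIdx <- which(vapply(pcs, function(pc)
    samples[[pc@sampleA]]$patient == samples[[pc@sampleB]]$patient, logical(1)))
  for (k in matchedIdx) {
    pc <- pcs[[k]]
    ct <- clonalityTable(pc, samples[[pc@sampleA]]$render$meta,
                         samples[[pc@sampleB]]$render$meta)
    utils::write.table(ct, file.path(clonDir, sprintf("%s_vs_%s.tsv",
                                                      pc@sampleA, pc@sampleB)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .log("runPipeline: hotspots")
  roles <- stats::setNames(cohort$manifest$role, cohort$manifest$sample_id)
  hm <- pairHeatmap(catalogues, genome, splitByRole = roles)
  for (nm in names(hm))
    utils::write.table(hm[[nm]], file.path(outDir, sprintf("heatmap_%s.tsv", nm)),
                       sep = "\t", quote = FALSE)
  track <- breakpointDensity(catalogues, genome, bandwidth = bandwidth,
                             gridStep = gridStep)
  writeDensityBedGraph(track, file.path(outDir, "density.bedgraph"))
  hot <- callHotspots(track, threshold = threshold, genome = genome)
  hotGenes <- annotateRegions(hot, genomeGenes(genome), genome)
  hot$genes <- vapply(hotGenes, paste, character(1), collapse = ",")
  utils::write.table(hot, file.path(outDir, "hotspots.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  .log("runPipeline: enrichment (%d sims)", nSims)
  gb <- genicBreakpoints(catalogues, genomeGenes(genome), genome)
  null <- simulateGenicNull(gb$nTotal, genome, genomeGenes(genome),
                            nSims = nSims, seed = cfg$seed + 7L,
                            observed = gb$count)
  universe <- mcols(genomeGenes(genome))$gene
  cge <- cancerGeneEnrichment(gb$affectedGenes, universe, cancerGenes(genome),
                              nSims = nSims, seed = cfg$seed + 8L)
  enr <- data.frame(
    metric = c("genic_breakpoints", "cancer_genes"),
    observed = c(gb$count, cge@observed),
    n_total = c(gb$nTotal, cge@nTotal),
    null_median = c(null@nullMedian, cge@nullMedian),
    fold = c(null@fold, cge@fold),
    p_two_sided = c(null@pTwoSided, cge@pTwoSided),
    p_is_bound = c(null@pIsBound, cge@pIsBound))
  utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  patientOf <- stats::setNames(cohort$manifest$patient_id, cohort$manifest$sample_id)
  agt <- affectedGeneTable(catalogues, genomeGenes(genome),
                           patientOf = patientOf, window = window,
                           genome = genome)
  utils::write.table(agt, file.path(outDir, "affected_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  arts <- setdiff(list.files(outDir, recursive = TRUE, full.names = TRUE),
                  c(hashFile, file.path(outDir, "artifact_checksums.tsv")))
  sums <- tools::md5sum(arts)
  utils::write.table(
    data.frame(artifact = sub(paste0("^", outDir, "/?"), "", names(sums)),
               md5 = unname(sums)),
    file.path(outDir, "artifact_checksums.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(hash, hashFile)
  invisible(list(counts = counts, summary = summ, outDir = outDir,
                 enrichment = enr))
}

.validatePipelineConfig <- function(cfg) {
  if (!is.list(cfg)) stop("pipeline config must be a list or YAML path")
  miss <- setdiff(c("n_patients", "window"), names(cfg))
  if (length(miss))
    stop(sprintf("pipeline config missing key(s): %s", paste(miss, collapse = ", ")))
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1)
    stop("n_patients must be a positive integer")
  if (!is.numeric(cfg$window) || cfg$window < 0)
    stop("window must be a non-negative number")
  extra <- setdiff(names(cfg), c("n_patients", "window", "seed", "min_itx_span",
                                 "sim", "enrichment", "hotspots"))
  if (length(extra))
    stop(sprintf("unknown pipeline config key(s): %s", paste(extra, collapse = ", ")))
  invisible(TRUE)
}

#' Build a generator configuration from a YAML `sim` block
#'
#' Maps the snake_case keys of a pipeline configuration's `sim` section
#' (e.g. `n_primary_events`, `shared_fraction`, `jitter_sd`) onto
#' [SimConfig()] arguments. Unknown keys are an error.
#'
#' @param sim named list, as returned by `yaml::read_yaml()` for the `sim`
#'   block (may be `NULL`).
#' @param seed optional seed to set on the resulting config.
#' @return a [SimConfig-class] object.
#' @export
simConfigFromYaml <- function(sim, seed = NULL) {
  args <- .simArgsFromYaml(sim)
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(SimConfig, args)
}

# snake_case sim YAML block -> SimConfig arguments
.simArgsFromYaml <- function(sim) {
  if (is.null(sim)) return(list())
  map <- c(n_chromosomes = NA, n_primary_events = "nPrimaryEvents",
           shared_fraction = "sharedFraction", n_met_private = "nMetPrivate",
           n_germline = "nGermline", jitter_sd = "jitterSd",
           subclonal_fraction = "subclonalFraction",
           lookup_only_fraction = "lookupOnlyFraction",
           coverage_primary = "physCoveragePrimary",
           coverage_met = "physCoverageMet",
           seq_coverage_primary = "seqCoveragePrimary",
           seq_coverage_met = "seqCoverageMet",
           cn_n_segments = "cnNSegments",
           cn_shared_fraction = "cnSharedFraction",
           cn_aberrant_fraction = "cnAberrantFraction",
           genic_fraction_target = "genicFractionTarget",
           n_cancer_genes = "nCancerGenes", min_span = "minSpan",
           p_ctx = "pCtx", chrom_lengths = NA)
  args <- list()
  for (key in names(sim)) {
    if (key == "chrom_lengths") {
      args$chromLengths <- unlist(sim[[key]])
    } else if (key %in% names(map) && !is.na(map[[key]])) {
      args[[map[[key]]]] <- sim[[key]]
    } else {
      stop(sprintf("unknown sim config key: %s", key))
    }
  }
  args
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}
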