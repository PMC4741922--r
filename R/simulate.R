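#' Create a generator configuration
#'
#' All arguments override the prototype defaults of [SimConfig-class]; see
#' that class for the meaning and default of every parameter.
#'
#' @param ... named slot values, e.g. `seed`, `nPrimaryEvents`,
#'   `sharedFraction`, `jitterSd`.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 7, nPrimaryEvents = 50L, sharedFraction = 0.8)
#' @export
SimConfig <- function(...) {
  args <- list(...)
  for (nm in c("seed", "nPrimaryEvents", "nMetPrivate", "nGermline",
               "cnNSegments", "nCancerGenes"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimConfig"), args))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: seed %d, %d chromosome(s) (%.0f Mb), ",
                     "%d primary events, shared fraction %.2f, ",
                     "%d met-private, %d germline\n"),
              object@seed, length(object@chromLengths),
              sum(object@chromLengths) / 1e6, object@nPrimaryEvents,
              object@sharedFraction, object@nMetPrivate, object@nGermline))
})

# place n events on the genome: breakpoints uniform over the unmasked genome,
# duplicate positions rejected and redrawn; intrachromosomal spans >= minSpan
.placeEvents <- function(n, config, masks = list()) {
  lens <- config@chromLengths
  chroms <- names(lens)
  if (n == 0L)
    return(data.frame(chrom1 = character(), pos1 = integer(),
                      chrom2 = character(), pos2 = integer(),
                      svType = character(), stringsAsFactors = FALSE))
  if (2 * n > sum(lens) / 1e3)
    stop("event count exceeds genome capacity for non-duplicate breakpoints")
  inMask <- function(chrom, pos) {
    if (length(masks) == 0L) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    for (m in masks) {
      ov <- suppressWarnings(
        GenomicRanges::countOverlaps(.grFromPoints0(chrom, pos), m))
      hit <- hit | ov > 0
    }
    hit
  }
  drawPos <- function(k, chrom) as.integer(floor(stats::runif(k, 0, lens[chrom])))
  seen <- character()
  out <- vector("list", n)
  intraTypes <- c("ITX", "DEL", "INV")
  i <- 1L
  while (i <= n) {
    isCtx <- stats::runif(1) < config@pCtx && length(chroms) > 1
    if (isCtx) {
      cs <- sample(chroms, 2, prob = lens)
      p1 <- drawPos(1, cs[1]); p2 <- drawPos(1, cs[2])
      type <- "CTX"
    } else {
      cs <- rep(sample(chroms, 1, prob = pmax(lens - config@minSpan, 0)), 2)
      span <- config@minSpan + round(stats::rexp(1, 1 / 5e5))
      if (span >= lens[cs[1]]) next
      p1 <- as.integer(floor(stats::runif(1, 0, lens[cs[1]] - span)))
      p2 <- as.integer(p1 + span)
      type <- sample(intraTypes, 1)
    }
    key <- c(paste(cs[1], p1), paste(cs[2], p2))
    if (any(key %in% seen)) next
    if (any(inMask(cs[1], p1)) || any(inMask(cs[2], p2))) next
    seen <- c(seen, key)
    out[[i]] <- data.frame(chrom1 = cs[1], pos1 = p1, chrom2 = cs[2],
                           pos2 = p2, svType = type, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  .canonicalizeEvents(do.call(rbind, out), chroms)
}

#' Simulate the ground truth of one clonally related tumor pair
#'
#' Places somatic and germline events uniformly on the genome, selects the
#' shared subset (`round(sharedFraction * nPrimaryEvents)` events retained by
#' the metastasis), draws per-event clonal fractions from
#' `Beta(clonalShape1, clonalShape2)` and assigns each shared event a
#' metastasis observation mode (`normal`, `subclonal` or `lookup_only`).
#' Germline events are fully clonal in every sample. Deterministic given
#' `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a [PatientTruth-class] object.
#' @export
simulatePatient <- function(config) {
  stopifnot(validObject(config))
  set.seed(config@seed)
  nP <- config@nPrimaryEvents
  nShared <- as.integer(round(config@sharedFraction * nP))
  nTot <- nP + config@nMetPrivate + config@nGermline
  ev <- .placeEvents(nTot, config)
  cls <- c(rep("primary_only", nP), rep("met_only", config@nMetPrivate),
           rep("germline", config@nGermline))
  if (nShared > 0) cls[sample(nP, nShared)] <- "shared"
  ev$eventId <- seq_len(nTot)
  ev$class <- cls
  inP <- cls %in% c("shared", "primary_only", "germline")
  inM <- cls %in% c("shared", "met_only", "germline")
  ev$cfPrimary <- ifelse(cls == "germline", 1,
                         ifelse(inP, stats::rbeta(nTot, config@clonalShape1,
                                                  config@clonalShape2), 0))
  ev$cfMet <- ifelse(cls == "germline", 1,
                     ifelse(inM, stats::rbeta(nTot, config@clonalShape1,
                                              config@clonalShape2), 0))
  ev$metMode <- "normal"
  sharedIdx <- which(cls == "shared")
  if (length(sharedIdx)) {
    u <- stats::runif(length(sharedIdx))
    mode <- rep("normal", length(sharedIdx))
    mode[u < config@lookupOnlyFraction] <- "lookup_only"
    mode[u >= config@lookupOnlyFraction &
         u < config@lookupOnlyFraction + config@subclonalFraction] <- "subclonal"
    ev$metMode[sharedIdx] <- mode
  }
  new("PatientTruth", events = ev, chromOrder = names(config@chromLengths),
      config = config)
}

#' @describeIn simulatePatient true event table of a [PatientTruth-class].
#' @param x a `PatientTruth`.
#' @export
truthEvents <- function(x) x@events

setMethod("show", "PatientTruth", function(object) {
  tab <- table(object@events$class)
  cat("PatientTruth:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Render the observed call set of one sample
#'
#' Converts the ground truth into what a read-pair SV caller would report for
#' one sample: per-event support is Poisson with mean physical coverage x
#' clonal fraction; somatic breakpoint coordinates receive independent
#' Gaussian jitter (`jitterSd`), truncated to chromosome bounds, while
#' germline breakpoints (fully clonal, maximal support) are reported at their
#' true positions. Events at or above the support threshold
#' ([supportThreshold()] of the sequence coverage) enter the catalogue;
#' events with `1 <= support < threshold` appear only in the raw call list;
#' shared events in `lookup_only` mode leave at least one read pair in the
#' evidence index but no call. Every supporting read pair is recorded in the
#' evidence index with additional per-pair coordinate noise
#' (`evidenceJitterSd`).
#'
#' @param truth a [PatientTruth-class] from [simulatePatient()].
#' @param role `"primary"`, `"metastasis"` or `"normal_pool"`.
#' @param sampleId sample id for the emitted calls (default the role).
#' @param patientId patient id recorded in the manifest row.
#' @param seed RNG seed; defaults to `config@seed` plus a role-specific
#'   offset so the three samples of a patient are independent but
#'   reproducible.
#' @return list with elements `catalogue` and `rawCalls`
#'   ([Rearrangements-class]), `evidence` ([EvidenceIndex-class]) and `meta`
#'   (one manifest row).
#' @export
renderObserved <- function(truth, role = c("primary", "metastasis", "normal_pool"),
                           sampleId = NULL, patientId = "patient1", seed = NULL) {
  role <- match.arg(role)
  config <- truth@config
  if (is.null(sampleId)) sampleId <- role
  if (is.null(seed))
    seed <- config@seed + switch(role, primary = 1L, metastasis = 2L,
                                 normal_pool = 3L)
  set.seed(seed)
  ev <- truth@events
  lens <- config@chromLengths
  present <- switch(role,
    primary = ev$class %in% c("shared", "primary_only", "germline"),
    metastasis = ev$class %in% c("shared", "met_only", "germline"),
    normal_pool = ev$class == "germline")
  ev <- ev[present, , drop = FALSE]
  cf <- switch(role, primary = ev$cfPrimary, metastasis = ev$cfMet,
               normal_pool = rep(1, nrow(ev)))
  physCov <- switch(role, primary = config@physCoveragePrimary,
                    metastasis = config@physCoverageMet,
                    normal_pool = config@physCoveragePrimary)
  seqCov <- switch(role, primary = config@seqCoveragePrimary,
                   metastasis = config@seqCoverageMet,
                   normal_pool = config@seqCoveragePrimary)
  thr <- supportThreshold(seqCov)
  n <- nrow(ev)
  meta <- data.frame(sample_id = sampleId, patient_id = patientId, role = role,
                     physical_coverage = physCov, sequence_coverage = seqCov,
                     stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(catalogue = Rearrangements(genome = names(lens)),
                rawCalls = Rearrangements(genome = names(lens)),
                evidence = EvidenceIndex(genome = names(lens)), meta = meta))
  }
  support <- stats::rpois(n, physCov * cf)
  mode <- if (role == "metastasis") ev$metMode else rep("normal", n)
  mode[ev$class != "shared"] <- "normal"
  sub <- mode == "subclonal"
  if (any(sub))
    support[sub] <- sample(seq_len(thr - 1), sum(sub), replace = TRUE)
  jitter <- function(chrom, pos, sd, germ) {
    j <- pos + round(stats::rnorm(length(pos), 0, sd))
    j[germ] <- pos[germ]
    pmin(pmax(j, 0L), as.integer(lens[chrom]) - 1L)
  }
  germ <- ev$class == "germline"
  obs1 <- jitter(ev$chrom1, ev$pos1, config@jitterSd, germ)
  obs2 <- jitter(ev$chrom2, ev$pos2, config@jitterSd, germ)
  lookupOnly <- mode == "lookup_only"
  evSupport <- ifelse(lookupOnly, pmax(1L, support), support)
  callable <- support >= 1L & !lookupOnly
  obsEv <- data.frame(chrom1 = ev$chrom1, pos1 = obs1, chrom2 = ev$chrom2,
                      pos2 = obs2, svType = ev$svType, support = support,
                      sampleId = sampleId, origin = "called",
                      eventId = ev$eventId, stringsAsFactors = FALSE)
  raw <- Rearrangements(obsEv[callable, , drop = FALSE], names(lens))
  catalogue <- Rearrangements(obsEv[callable & support >= thr, , drop = FALSE],
                              names(lens))
  withEv <- which(evSupport >= 1L)
  if (length(withEv)) {
    reps <- evSupport[withEv]
    idx <- rep(withEv, reps)
    pairs <- data.frame(
      readname = sprintf("%s_e%05d_rp%03d", sampleId, ev$eventId[idx],
                         sequence(reps)),
      chrom1 = ev$chrom1[idx],
      pos1 = jitter(ev$chrom1[idx], obs1[idx], config@evidenceJitterSd,
                    germ[idx]),
      chrom2 = ev$chrom2[idx],
      pos2 = jitter(ev$chrom2[idx], obs2[idx], config@evidenceJitterSd,
                    germ[idx]),
      stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(readname = character(), chrom1 = character(),
                        pos1 = integer(), chrom2 = character(),
                        pos2 = integer(), stringsAsFactors = FALSE)
  }
  evidence <- EvidenceIndex(pairs, names(lens))
  list(catalogue = catalogue, rawCalls = raw, evidence = evidence, meta = meta)
}

#' Simulate a pair of piecewise-constant copy-number profiles
#'
#' Partitions each chromosome into random segments (total `cnNSegments`,
#' allocated proportionally to length), marks a fraction
#' `cnAberrantFraction` of them aberrant, and shares `cnSharedFraction` of
#' the aberrant segments between primary and metastasis (same state in both);
#' the remaining aberrant segments alternate between primary-only and
#' metastasis-only, so the event-based CN similarity of the pair equals the
#' configured sharing up to rounding. Deterministic given the seed.
#'
#' @param config a [SimConfig-class].
#' @param sampleIds ids for the two profiles.
#' @param seed RNG seed (default `config@seed + 4`).
#' @return list of two [CnProfile-class] objects, `primary` and `metastasis`.
#' @export
simulateCnProfiles <- function(config, sampleIds = c("primary", "metastasis"),
                               seed = NULL) {
  if (is.null(seed)) seed <- config@seed + 4L
  set.seed(seed)
  lens <- config@chromLengths
  total <- sum(lens)
  segs <- list()
  for (ch in names(lens)) {
    k <- max(1L, as.integer(round(config@cnNSegments * lens[ch] / total)))
    cuts <- if (k > 1) sort(sample.int(lens[ch] - 1L, k - 1L)) else integer()
    b <- c(0L, cuts, as.integer(lens[ch]))
    segs[[ch]] <- data.frame(chrom = ch, start = b[-length(b)], end = b[-1],
                             stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, segs)
  rownames(seg) <- NULL
  S <- nrow(seg)
  nAb <- as.integer(round(config@cnAberrantFraction * S))
  cnP <- rep(2, S); cnM <- rep(2, S)
  if (nAb > 0) {
    ab <- sample.int(S, nAb)
    nSh <- as.integer(round(config@cnSharedFraction * nAb))
    states <- sample(config@cnStates, nAb, replace = TRUE)
    shared <- seq_len(nAb) <= nSh
    rest <- which(!shared)
    pOnly <- rest[seq_along(rest) %% 2 == 1L]
    mOnly <- setdiff(rest, pOnly)
    cnP[ab[shared]] <- states[shared]; cnM[ab[shared]] <- states[shared]
    cnP[ab[pOnly]] <- states[pOnly]
    cnM[ab[mOnly]] <- states[mOnly]
  }
  list(primary = CnProfile(sampleIds[1], transform(seg, cn = cnP)),
       metastasis = CnProfile(sampleIds[2], transform(seg, cn = cnM)))
}

#' Simulate a gene annotation with a cancer-gene subset
#'
#' Lays non-overlapping genes along each chromosome so that the extended
#' footprints (2 kb promoter through gene end) cover exactly
#' `genicFractionTarget` of the genome (up to per-chromosome rounding), with
#' log-normal gene lengths and random strands separated by random gaps.
#' A subset of `nCancerGenes` names is flagged cancer-associated.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed (default `config@seed + 5`).
#' @return list with elements `genes` (`GRanges` with `gene` metadata) and
#'   `cancerGenes` (character).
#' @export
simulateAnnotation <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config@seed + 5L
  set.seed(seed)
  promoter <- 2000L
  lens <- config@chromLengths
  total <- sum(lens)
  F <- round(config@genicFractionTarget * total)
  if (F <= 0)
    return(list(genes = GenomicRanges::GRanges(gene = character()),
                cancerGenes = character()))
  rows <- list()
  gi <- 0L
  for (ch in names(lens)) {
    Fc <- round(F * lens[ch] / total)
    if (Fc < promoter + 1000) next
    extLens <- integer()
    while (sum(extLens) < Fc) {
      gl <- max(1000L, as.integer(round(stats::rlnorm(1, log(2e4), 0.6))))
      extLens <- c(extLens, gl + promoter)
    }
    over <- sum(extLens) - Fc
    last <- length(extLens)
    if (extLens[last] - over >= promoter + 1000) {
      extLens[last] <- extLens[last] - over
    } else {
      leftover <- extLens[last] - over
      extLens <- extLens[-last]
      extLens[length(extLens)] <- extLens[length(extLens)] + leftover
    }
    nG <- length(extLens)
    gapTotal <- lens[ch] - sum(extLens)
    w <- stats::runif(nG + 1)
    gaps <- floor(gapTotal * cumsum(w) / sum(w))
    gaps <- diff(c(0, gaps))
    cursor <- 0
    for (j in seq_len(nG)) {
      cursor <- cursor + gaps[j]
      a <- cursor
      b <- cursor + extLens[j]
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") { gs <- a + promoter; ge <- b } else { gs <- a; ge <- b - promoter }
      rows[[gi]] <- data.frame(chrom = ch, start = gs, end = ge,
                               name = sprintf("gene%05d", gi), strand = strand,
                               stringsAsFactors = FALSE)
      cursor <- b
    }
  }
  df <- do.call(rbind, rows)
  gr <- .grFromBed0(df$chrom, df$start, df$end, strand = df$strand)
  mcols(gr)$gene <- df$name
  k <- min(config@nCancerGenes, length(gr))
  cg <- if (k > 0) sample(df$name, k) else character()
  list(genes = gr, cancerGenes = cg)
}

#' Build a full synthetic genome model
#'
#' @param config a [SimConfig-class].
#' @param masks optional named list of mask `GRanges`.
#' @return a [GenomeModel-class] with the simulated annotation.
#' @export
simulateGenome <- function(config, masks = list()) {
  ann <- simulateAnnotation(config)
  GenomeModel(config@chromLengths, masks = masks, genes = ann$genes,
              cancerGenes = ann$cancerGenes)
}

#' Simulate a cohort of clonally related tumor pairs
#'
#' One patient = one [simulatePatient()] truth plus rendered primary and
#' metastasis samples (and a shared normal pool accumulating every patient's
#' germline events). Patient seeds are `config@seed + 1000 * i`.
#'
#' @param config base [SimConfig-class].
#' @param nPatients number of patients.
#' @return list with `patients` (per patient: `truth`, `primary`, `met`),
#'   `pool` (a [Rearrangements-class] normal-pool call list) and `manifest`
#'   (sample metadata data.frame).
#' @export
simulateCohort <- function(config, nPatients = 6L) {
  patients <- vector("list", nPatients)
  poolCalls <- list()
  metaRows <- list()
  for (i in seq_len(nPatients)) {
    cfg <- config
    cfg@seed <- config@seed + 1000L * i
    pid <- sprintf("P%02d", i)
    truth <- simulatePatient(cfg)
    pri <- renderObserved(truth, "primary", sampleId = paste0(pid, "_P"),
                          patientId = pid)
    met <- renderObserved(truth, "metastasis", sampleId = paste0(pid, "_M"),
                          patientId = pid)
    pool <- renderObserved(truth, "normal_pool", sampleId = "pool",
                           patientId = pid)
    patients[[i]] <- list(patientId = pid, truth = truth, primary = pri,
                          met = met)
    poolCalls[[i]] <- eventTable(pool$rawCalls)
    metaRows[[i]] <- rbind(pri$meta, met$meta)
  }
  pool <- Rearrangements(do.call(rbind, poolCalls), names(config@chromLengths))
  manifest <- do.call(rbind, metaRows)
  list(patients = patients, pool = pool, manifest = asSampleMeta(manifest))
}
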