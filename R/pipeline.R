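#' Write / read a continuous recording in the columnar CSV dialect
#'
#' One file per recording: a small key-value header (\code{# key: value}
#' lines carrying the sampling rate and labels) followed by one column per
#' channel and one row per sample. The round trip is lossless to the printed
#' precision (15 significant digits).
#'
#' @param x numeric matrix, channels x samples, rownames = channel labels.
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param subjectId,condition labels stored in the header.
#' @return \code{writeRecording} returns \code{path} invisibly;
#'   \code{readRecording} returns a list with \code{data} (channels x
#'   samples matrix), \code{fs}, \code{subjectId}, \code{condition}.
#' @export
writeRecording <- function(x, path, fs, subjectId = "s01",
                           condition = "session1") {
  x <- rbind(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("ch%02d", seq_len(nrow(x)))
  hdr <- c("# eeg-recording v1",
           sprintf("# fs: %s", format(fs, digits = 15)),
           sprintf("# subject: %s", subjectId),
           sprintf("# condition: %s", condition))
  writeLines(hdr, path)
  dt <- data.table::as.data.table(t(x))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeRecording
#' @param dialect \code{"csv"} (the native dialect). \code{"edf"} is part of
#'   the reader interface but no EDF backend is bundled; requesting it
#'   raises an informative error.
#' @export
readRecording <- function(path, dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  if (dialect == "edf")
    stop("no EDF backend is bundled; convert to the CSV dialect first")
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10L)
  if (length(hdr) == 0L) stop("empty file: ", path)
  if (!startsWith(hdr[1L], "# eeg-recording"))
    stop("unrecognized header in ", path, " (line 1: ",
         substr(hdr[1L], 1, 40), ")")
  meta <- grep("^# [a-z]+: ", hdr, value = TRUE)
  kv <- sub("^# ([a-z]+): (.*)$", "\\1\r\\2", meta)
  kv <- strsplit(kv, "\r", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  fs <- suppressWarnings(as.numeric(vals[match("fs", keys)]))
  if (is.na(fs)) stop("missing or unparseable 'fs' header field in ", path)
  dt <- data.table::fread(path, skip = length(meta) + 1L, header = TRUE)
  if (nrow(dt) == 0L) stop("no samples in ", path)
  data <- t(as.matrix(dt))
  list(data = data, fs = fs,
       subjectId = vals[match("subject", keys)],
       condition = vals[match("condition", keys)])
}

#' Write a synthetic cohort to disk
#'
#' One CSV file per recording (\code{<subject>_<condition>.csv}) in the
#' dialect of [writeRecording()], plus a \code{ground_truth.json} sidecar
#' with the drawn variance components and theoretical ICCs.
#'
#' @param cohort a [generateCohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$recordings))
    for (cond in cohort$conditions)
      writeRecording(cohort$recordings[[s]][[cond]],
                     file.path(dir, paste0(s, "_", cond, ".csv")),
                     fs = cohort$fs, subjectId = s, condition = cond)
  gt <- cohort$groundTruth
  gt$coupling <- as.data.frame(gt$coupling)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the arguments of [cohortConfig()] (under a \code{cohort}
#' block) and [runStudy()] (top level), e.g. \code{measures},
#' \code{iccType}, \code{categoryBasis}, \code{seed}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a named list.
#' @export
readStudyConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

studyMeasures <- c("PLI", "AECc", "AECc_concat", "PE", "JPE_INV")
mstMetricNames <- c("kmax", "leaf_fraction", "diameter", "bc_max",
                    "eccentricity", "tree_hierarchy")

#' Run the full reliability study on a synthetic cohort
#'
#' End-to-end orchestration: for every subject, condition and band the
#' continuous recording is band-filtered (zero-phase FIR), segmented into
#' epochs, and summarised into one scalar per measure (whole-brain mean for
#' PLI/AECc/JPE_INV, channel mean for PE, metric value for the spanning-tree
#' measures). Temporal reliability compares \code{session1} with
#' \code{session2}; state reliability compares \code{session1} with
#' \code{semirest} (both fixed by the study design, not configurable). For
#' every measure and band a two-way mixed-effects ICC with 95\% CI, its
#' reliability category, and the combined state/temporal biomarker class are
#' reported; for the spanning-tree backbone the per-subject edge overlap is
#' summarised as mean percent, SD and mean edge count per band, measure and
#' comparison.
#'
#' @param cohort a [generateCohort()] result, a [cohortConfig()] (the cohort
#'   is then generated here), or a directory written by [writeCohort()].
#' @param measures subset of \code{PLI, AECc, AECc_concat, PE, JPE_INV}.
#' @param mstMeasures connectivity measures whose maximum spanning tree is
#'   characterised (subset of \code{PLI}, \code{AECc}; each must also be in
#'   \code{measures}).
#' @param bands list of [BandDefinition-class]; defaults to the cohort
#'   configuration's bands.
#' @param m,tau ordinal-pattern parameters.
#' @param edgeTrimFrac edge trim fraction for phase/envelope statistics.
#' @param iccType \code{"consistency"} or \code{"agreement"}.
#' @param categoryBasis \code{"point"} or \code{"ci_low"} for the category.
#' @param bootstrap also compute bootstrap percentile CIs.
#' @param nBootstrap bootstrap resamples (default 1000).
#' @param concatTargetS segment length for \code{AECc_concat} (default 60 s;
#'   reduced automatically if the recording is shorter).
#' @param seed seed for the bootstrap stage (signal generation uses the
#'   cohort's own seed).
#' @return a [StudyReport-class].
#' @export
runStudy <- function(cohort, measures = c("PLI", "AECc", "PE", "JPE_INV"),
                     mstMeasures = intersect(measures, c("PLI", "AECc")),
                     bands = NULL, m = 3L, tau = 1L, edgeTrimFrac = 0.1,
                     iccType = c("consistency", "agreement"),
                     categoryBasis = c("point", "ci_low"),
                     bootstrap = FALSE, nBootstrap = 1000L,
                     concatTargetS = 60, seed = 1L) {
  iccType <- match.arg(iccType)
  categoryBasis <- match.arg(categoryBasis)
  measures <- match.arg(measures, studyMeasures, several.ok = TRUE)
  if (!all(mstMeasures %in% c("PLI", "AECc")))
    stop("mstMeasures must be a subset of PLI, AECc")
  if (!all(mstMeasures %in% measures))
    stop("every spanning-tree measure needs its parent connectivity measure")
  t0 <- proc.time()[["elapsed"]]
  if (inherits(cohort, "cohortConfig")) cohort <- generateCohort(cohort)
  if (is.character(cohort)) cohort <- readCohortDir(cohort)
  stopifnot(inherits(cohort, "syntheticCohort"))
  cfg <- cohort$config
  if (is.null(bands)) bands <- cfg$bands
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b) b@name, "")

  subjects <- names(cohort$recordings)
  conditions <- cohort$conditions
  rows <- list()
  trees <- list()
  for (s in subjects) {
    for (cond in conditions) {
      cont <- cohort$recordings[[s]][[cond]]
      for (bn in names(bands)) {
        bd <- bands[[bn]]
        filt <- bandpass(cont, bd, fs = cohort$fs)
        rownames(filt) <- cohort$channelLabels
        rec <- segmentEpochs(filt, fs = cohort$fs, epochLenS = cfg$epochLenS,
                             nEpochs = cfg$nEpochs, band = bd,
                             subjectId = s, condition = cond)
        vals <- c()
        mats <- list()
        if ("PLI" %in% measures) {
          mats$PLI <- connectivityMatrix(rec, "PLI",
                                         edgeTrimFrac = edgeTrimFrac)
          vals["PLI"] <- wholeBrainMean(mats$PLI)
        }
        if ("AECc" %in% measures) {
          mats$AECc <- connectivityMatrix(rec, "AECc",
                                          edgeTrimFrac = edgeTrimFrac)
          vals["AECc"] <- wholeBrainMean(mats$AECc)
        }
        if ("AECc_concat" %in% measures) {
          tgt <- min(concatTargetS, cfg$nEpochs * cfg$epochLenS)
          recC <- suppressMessages(concatenateEpochs(rec, tgt))
          vals["AECc_concat"] <- wholeBrainMean(
            connectivityMatrix(recC, "AECc", edgeTrimFrac = edgeTrimFrac))
        }
        if ("JPE_INV" %in% measures) {
          cmJ <- connectivityMatrix(rec, "JPE_INV", m = m, tau = tau)
          vals["JPE_INV"] <- wholeBrainMean(cmJ)
        }
        if ("PE" %in% measures)
          vals["PE"] <- channelEntropy(rec, m = m, tau = tau)$mean
        for (mm in mstMeasures) {
          tr <- maxSpanningTree(mats[[mm]])
          trees[[paste(s, cond, bn, mm, sep = "|")]] <- tr
          met <- mstMetrics(tr)
          vals[paste0(mm, "_MST")] <- mstEdgeMean(tr, mats[[mm]])
          for (mn in mstMetricNames)
            vals[paste("MST", mm, mn, sep = "_")] <- met[[mn]]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond, band = bn,
          measure = names(vals), value = unname(vals))
      }
    }
  }
  measureTable <- do.call(rbind, rows)
  rownames(measureTable) <- NULL

  comparisons <- list(temporal = c("session1", "session2"),
                      state = c("session1", "semirest"))
  rel <- reliabilityFromTable(measureTable, comparisons, iccType,
                              categoryBasis, bootstrap, nBootstrap, seed)

  ov <- list()
  for (s in subjects)
    for (bn in names(bands))
      for (mm in mstMeasures)
        for (cn in names(comparisons)) {
          pr <- comparisons[[cn]]
          tA <- trees[[paste(s, pr[1L], bn, mm, sep = "|")]]
          tB <- trees[[paste(s, pr[2L], bn, mm, sep = "|")]]
          ov[[length(ov) + 1L]] <- data.frame(
            subject = s, band = bn, measure = mm, comparison = cn,
            overlap = mstOverlap(tA, tB))
        }
  overlapTable <- if (length(ov)) summarizeOverlap(do.call(rbind, ov),
                                                   nNodes = cfg$nChannels)
                  else data.frame()

  manifest <- list(seed = seed, iccType = iccType,
                   categoryBasis = categoryBasis, measures = measures,
                   mstMeasures = mstMeasures, m = m, tau = tau,
                   edgeTrimFrac = edgeTrimFrac,
                   nSubjects = length(subjects),
                   bands = lapply(bands, function(b)
                     list(name = b@name, low = b@low, high = b@high)),
                   cohortSeed = cfg$seed,
                   package = as.character(utils::packageVersion("eegReliability")),
                   elapsedS = proc.time()[["elapsed"]] - t0)
  new("StudyReport", measureTable = measureTable, reliability = rel,
      overlap = overlapTable, groundTruth = cohort$groundTruth,
      manifest = manifest)
}

reliabilityFromTable <- function(measureTable, comparisons, iccType,
                                 categoryBasis, bootstrap, nBootstrap, seed) {
  out <- list()
  cells <- unique(measureTable[, c("measure", "band")])
  for (i in seq_len(nrow(cells))) {
    mm <- cells$measure[i]; bn <- cells$band[i]
    sub <- measureTable[measureTable$measure == mm & measureTable$band == bn, ]
    cats <- list()
    for (cn in names(comparisons)) {
      pr <- comparisons[[cn]]
      w <- stats::reshape(
        sub[sub$condition %in% pr, c("subject", "condition", "value")],
        idvar = "subject", timevar = "condition", direction = "wide")
      y <- as.matrix(w[, -1L, drop = FALSE])
      fit <- icc2way(y, type = iccType)
      ciMethod <- "F"
      if (bootstrap) {
        bs <- iccBootstrapCI(y, type = iccType, nResamples = nBootstrap,
                             seed = childSeed(seed, "boot", mm, bn, cn))
        fit$ci_low <- bs$ci_low
        fit$ci_high <- bs$ci_high
        ciMethod <- sprintf("bootstrap(%d)", nBootstrap)
      }
      cat_ <- categorizeICC(fit, basis = categoryBasis)
      cats[[cn]] <- cat_
      out[[length(out) + 1L]] <- data.frame(
        measure = mm, band = bn, comparison = cn, n = fit$n,
        n_dropped = fit$n_dropped, icc = fit$icc, ci_low = fit$ci_low,
        ci_high = fit$ci_high, ci_method = ciMethod,
        degenerate = fit$degenerate, category = as.character(cat_))
    }
    cls <- classifyBiomarker(cats$temporal, cats$state)
    idx <- (length(out) - 1L):length(out)
    for (j in idx) out[[j]]$biomarker_class <- cls
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise per-subject spanning-tree overlaps
#'
#' Aggregates per-subject overlap percentages into the band x (measure,
#' comparison) layout: arithmetic mean, sample SD across subjects, and the
#' equivalent mean shared-edge count \code{mean/100 * (nNodes - 1)}.
#'
#' @param perSubject data.frame with columns \code{subject}, \code{band},
#'   \code{measure}, \code{comparison}, \code{overlap} (percent).
#' @param nNodes number of channels (tree has \code{nNodes - 1} edges).
#' @return data.frame: band, measure, comparison, n, mean_overlap_pct,
#'   sd_overlap_pct, mean_edges.
#' @export
summarizeOverlap <- function(perSubject, nNodes) {
  stopifnot(all(c("subject", "band", "measure", "comparison", "overlap") %in%
                names(perSubject)))
  if (length(unique(perSubject$subject)) < 2L)
    stop("need at least 2 subjects to summarise overlap")
  agg <- stats::aggregate(overlap ~ band + measure + comparison,
                          data = perSubject,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(band = agg$band, measure = agg$measure,
                    comparison = agg$comparison,
                    n = agg$overlap[, "n"],
                    mean_overlap_pct = agg$overlap[, "mean"],
                    sd_overlap_pct = agg$overlap[, "sd"])
  out$mean_edges <- overlapEdgeCount(out$mean_overlap_pct, nNodes)
  out[order(out$band, out$measure, out$comparison), , drop = FALSE]
}

readCohortDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("no recordings found in ", dir)
  recs <- list()
  fs <- NULL
  for (f in files) {
    r <- readRecording(f)
    fs <- fs %||% r$fs
    if (r$fs != fs) stop("inconsistent sampling rates in ", dir)
    recs[[r$subjectId]][[r$condition]] <- r$data
  }
  conds <- unique(unlist(lapply(recs, names)))
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtPath)) jsonlite::read_json(gtPath,
                                                     simplifyVector = TRUE)
        else list()
  nSamples <- ncol(recs[[1L]][[1L]])
  ## minimal config reconstructed from the files; epoching defaults apply
  nEp <- max(1L, nSamples %/% (4 * fs))
  cfg <- cohortConfig(nSubjects = max(2L, length(recs)),
                      nChannels = nrow(recs[[1L]][[1L]]), fs = fs,
                      nEpochs = nEp, epochLenS = nSamples / fs / nEp)
  structure(list(recordings = recs, fs = fs,
                 channelLabels = rownames(recs[[1L]][[1L]]),
                 conditions = conds, config = cfg, groundTruth = gt),
            class = "syntheticCohort")
}

#' Write the tidy study report to disk
#'
#' Writes \code{measures.csv}, \code{reliability.csv}, \code{overlap.csv}
#' and \code{manifest.json} into \code{dir}.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report@measureTable, file.path(dir, "measures.csv"))
  data.table::fwrite(report@reliability, file.path(dir, "reliability.csv"))
  if (nrow(report@overlap))
    data.table::fwrite(report@overlap, file.path(dir, "overlap.csv"))
  jsonlite::write_json(report@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
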