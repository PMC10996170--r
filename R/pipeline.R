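# Experiment orchestration: simulate -> trim -> segment -> landmarks ->
# featurize -> split -> cross-validate -> tune -> evaluate, as one seeded,
# logged run.

#' Build an experiment configuration
#'
#' The defaults describe the desk-scale study conditions: 60 recordings
#' from 20 participants (three recordings each, emulating repeat visits),
#' four contraction cycles per recording, the four classes in equal
#' proportion, bladder size varied +-25% across recordings (different
#' urine volumes), 0.5 s clip padding, stride-10 landmark sampling, a
#' stratified 70/30 split and a 5-fold cross-validated comparison of the
#' three-model roster.
#'
#' @param n_recordings Number of recordings to simulate.
#' @param n_participants Number of participants the recordings are spread
#'   over (round robin).
#' @param class_mix Named proportions over [pfmClasses()]; must sum to 1.
#' @param sim Base [SimulationConfig-class]; per-recording seeds and
#'   semi-axes are derived from it.
#' @param size_jitter Relative half-range of the per-recording bladder
#'   semi-axis scaling (0.25 scales both axes by U(0.75, 1.25)).
#' @param padding_s Clip window padding, seconds.
#' @param seg_params Segmentation parameters, see [segmentBladder()].
#' @param stride Landmark sampling stride in frames.
#' @param split A [splitSpec()] (its seed is overridden by the global
#'   seed).
#' @param model_specs List of [modelSpec()] objects to compare.
#' @param k Cross-validation folds.
#' @param out_dir Output directory for persisted artifacts (NULL: keep
#'   everything in memory).
#' @param save_recordings Also persist every recording as multi-page
#'   TIFF plus event-log/label CSVs (large; default FALSE).
#' @param seed Global experiment seed; all stage seeds derive from it.
#' @return A list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(n_recordings = 60L, n_participants = 20L,
                             class_mix = c(UNDETERMINABLE = 0.25,
                                           CORRECT = 0.25,
                                           FAILURE = 0.25, NONE = 0.25),
                             sim = simulationConfig(),
                             size_jitter = 0.25, padding_s = 0.5,
                             seg_params = list(), stride = 10L,
                             split = splitSpec(),
                             model_specs = defaultModelSpecs(), k = 5L,
                             out_dir = NULL, save_recordings = FALSE,
                             seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")
  if (!all(names(class_mix) %in% pfmClasses()))
    stop("class_mix names must be drawn from pfmClasses()")
  structure(list(n_recordings = as.integer(n_recordings),
                 n_participants = as.integer(n_participants),
                 class_mix = class_mix, sim = sim,
                 size_jitter = size_jitter, padding_s = padding_s,
                 seg_params = seg_params, stride = as.integer(stride),
                 split = split, model_specs = model_specs,
                 k = as.integer(k), out_dir = out_dir,
                 save_recordings = isTRUE(save_recordings),
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

# exact label allocation matching class_mix over n slots, shuffled
.allocateLabels <- function(n, class_mix) {
  counts <- floor(class_mix * n)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(class_mix * n - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(class_mix), counts))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run a full seeded experiment
#'
#' Executes simulate, trim, segment/landmark, featurize, split,
#' cross-validated comparison, grid-search tuning and held-out evaluation
#' in order, logging per-stage counts. Deterministic given the global
#' seed. When \code{config$out_dir} is set, the clip manifest, landmark
#' series, feature table (+ sidecar), report JSON and confusion CSV are
#' persisted there (recordings too when \code{save_recordings}).
#'
#' @param config An [experimentConfig()].
#' @param simulate_only Stop after featurization and return the feature
#'   table instead of a report.
#' @param feature_table Optional precomputed feature table (e.g. from an
#'   earlier \code{simulate_only} run or a persisted CSV); skips the
#'   simulation and featurization stages.
#' @return A [ModelReport-class] (or a feature table when
#'   \code{simulate_only}).
#' @export
runExperiment <- function(config = experimentConfig(),
                          simulate_only = FALSE, feature_table = NULL) {
  stopifnot(inherits(config, "ExperimentConfig"))
  nrec <- config$n_recordings
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       nrec + 4L))
  cycle_labels <- withr::with_seed(seeds[nrec + 1L],
    .allocateLabels(nrec * config$sim@n_contractions, config$class_mix))
  size_scales <- withr::with_seed(seeds[nrec + 2L],
    runif(nrec, 1 - config$size_jitter, 1 + config$size_jitter))

  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  manifest <- NULL
  series <- list()
  if (is.null(feature_table)) .stage("simulate+landmarks", {
    for (r in seq_len(nrec)) {
      cfg <- config$sim
      cfg@semi_axis_x <- cfg@semi_axis_x * size_scales[r]
      cfg@semi_axis_y <- cfg@semi_axis_y * size_scales[r]
      cfg@seed <- seeds[r]
      rid <- sprintf("rec%03d", r)
      pid <- sprintf("p%03d", ((r - 1L) %% config$n_participants) + 1L)
      lab <- cycle_labels[((r - 1L) * cfg@n_contractions + 1L):
                            (r * cfg@n_contractions)]
      rec <- simulateRecording(cfg, lab, recordingId = rid,
                               participantId = pid)
      if (!is.null(out_dir) && config$save_recordings) {
        writeFrameStack(rec@stack, file.path(out_dir,
                                             paste0(rid, ".tif")))
        writeEventLog(rec@events,
                      file.path(out_dir, paste0(rid, "_events.csv")))
        writeLabels(rec@labels,
                    file.path(out_dir, paste0(rid, "_labels.csv")))
      }
      cl <- trimClips(rec, padding_s = config$padding_s)
      ls <- lapply(cl, extractSeries, stride = config$stride,
                   seg_params = config$seg_params)
      # keep only manifest rows and landmark series; frame data of this
      # recording is released here
      manifest <- rbind(manifest,
                        do.call(rbind, lapply(cl, clipManifestRow)))
      series <- c(series, ls)
    }
  })
  if (is.null(feature_table)) {
    message("simulated ", nrec, " recordings -> ", nrow(manifest),
            " clips")
    if (!is.null(out_dir)) {
      writeClipManifest(manifest, file.path(out_dir, "clip_manifest.csv"))
      writeLandmarkSeries(series,
                          file.path(out_dir, "landmark_series.csv"))
    }
    tab <- .stage("featurize", buildFeatureTable(series))
    if (!is.null(out_dir))
      writeFeatureTable(tab, file.path(out_dir, "feature_table.csv"))
    if (simulate_only) return(tab)
  } else {
    tab <- feature_table
    tab$label <- .asLabelFactor(tab$label)
  }

  split <- config$split
  split$seed <- seeds[nrec + 3L]
  parts <- .stage("split", splitTrainTest(tab, split))
  message("split: ", nrow(parts$train), " train / ", nrow(parts$test),
          " test clips")

  cv <- .stage("cross_validate",
               crossValidateModels(parts$train, config$model_specs,
                                   k = config$k,
                                   seed = seeds[nrec + 4L]))
  chosen <- cv$model[1]
  spec <- config$model_specs[[match(chosen, vapply(config$model_specs,
    function(s) s$algorithm, character(1)))]]
  message("chosen model: ", chosen)

  model <- .stage("tune", gridSearchTune(parts$train, spec, k = config$k,
                                         seed = seeds[nrec + 4L]))
  ev <- .stage("evaluate", evaluateModel(model, parts$test))
  imp <- tryCatch(topFeatureImportances(model, 10L),
                  error = function(e) data.frame(feature = character(),
                                                 importance = numeric()))

  report <- new("ModelReport",
    cvTable = cv, chosenModel = chosen,
    tunedParams = model$params, metrics = ev$metrics,
    confusion = ev$confusion, importances = imp, model = model,
    log = list(n_recordings = nrec,
               n_clips = if (is.null(feature_table)) nrow(manifest)
                         else nrow(tab),
               n_rows = nrow(tab),
               n_features_before = attr(tab, "n_features_before"),
               n_features_after = attr(tab, "n_features_after"),
               n_dropped_columns = length(attr(tab, "dropped_columns")),
               n_train = nrow(parts$train), n_test = nrow(parts$test),
               seed = config$seed))
  if (!is.null(out_dir))
    writeModelReport(report, file.path(out_dir, "report.json"))
  report
}
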