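# External interfaces: multi-page TIFF for frame stacks, CSV for event
# logs, labels, contours, landmark series and feature tables, YAML for
# configurations, JSON for reports.

#' Write / read a FrameStack as multi-page TIFF
#'
#' Intensities are stored as 8-bit grayscale pages. The frame rate is not
#' part of the TIFF and must be supplied on reading.
#'
#' @param stack A [FrameStack-class].
#' @param path Output .tif path.
#' @export
writeFrameStack <- function(stack, path) {
  pages <- lapply(seq_len(nFrames(stack)),
                  function(i) getFrame(stack, i) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeFrameStack
#' @param fps Frame rate to attach to the read stack.
#' @return \code{readFrameStack}: a [FrameStack-class].
#' @export
readFrameStack <- function(path, fps = 24) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    frames[, , i] <- p * 255
  }
  frameStack(frames, fps)
}

#' Write an event log as CSV (`kind,time_s`)
#' @param events Event log data frame.
#' @param path Output path.
#' @export
writeEventLog <- function(events, path) {
  write.csv(events[, c("kind", "time_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  v <- validateEventLog(ev)
  if (!isTRUE(v)) stop(v)
  ev
}

#' Write ground-truth cycle labels as CSV (`cycle_index,label`)
#' @param labels Factor or character vector of per-cycle labels.
#' @param path Output path.
#' @export
writeLabels <- function(labels, path) {
  write.csv(data.frame(cycle_index = seq_along(labels) - 1L,
                       label = as.character(labels)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame contours as CSV (`frame_index,vertex_index,x,y`)
#' @param contours List of contour matrices (columns x, y), one per
#'   frame; NULL entries (failed frames) are skipped.
#' @param path Output path.
#' @export
writeContours <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    if (is.null(ct)) return(NULL)
    data.frame(frame_index = i - 1L,
               vertex_index = seq_len(nrow(ct)) - 1L,
               x = ct[, 1], y = ct[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a clip manifest as CSV
#' @param clips List of [Clip-class] objects, or an already-built
#'   manifest data frame.
#' @param path Output path.
#' @export
writeClipManifest <- function(clips, path) {
  man <- if (is.data.frame(clips)) clips
  else do.call(rbind, lapply(clips, clipManifestRow))
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClipManifest
#' @param clip A single [Clip-class].
#' @export
clipManifestRow <- function(clip) {
  data.frame(clip_id = clip@clipId, recording_id = clip@recordingId,
             participant_id = clip@participantId,
             label = as.character(clip@label),
             start_s = clip@startS, end_s = clip@endS)
}

#' Write landmark series as CSV
#'
#' One row per sample with columns \code{clip_id, sample_index,
#' frame_index, missing} and the ten coordinate channels.
#'
#' @param series_list List of [LandmarkSeries-class] objects.
#' @param path Output path.
#' @export
writeLandmarkSeries <- function(series_list, path) {
  ord <- as.vector(t(outer(c("Center", "Left", "Right", "Top", "Bottom"),
                           c("x", "y"), paste, sep = "_")))
  rows <- lapply(series_list, function(s) data.frame(
    clip_id = s@clipId, sample_index = seq_along(s@sampleTimes) - 1L,
    frame_index = s@frameIndex, missing = s@missing,
    as.data.frame(s@coords[, ord, drop = FALSE]), check.names = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the feature table as CSV plus a sidecar JSON
#'
#' The sidecar records the catalogue version, sample rate and the names
#' of the feature columns excluded for missing values.
#'
#' @param table Feature table from [buildFeatureTable()].
#' @param path Output CSV path (the sidecar gets extension .json).
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  side <- list(catalogue_version = attr(table, "catalogue_version"),
               sample_rate_hz = attr(table, "sample_rate_hz"),
               n_features_before = attr(table, "n_features_before"),
               n_features_after = attr(table, "n_features_after"),
               dropped_columns = attr(table, "dropped_columns"))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a simulation or experiment configuration as YAML
#' @param config A [SimulationConfig-class] or a plain list.
#' @param path Output path.
#' @export
writeConfig <- function(config, path) {
  if (is(config, "SimulationConfig")) {
    nm <- slotNames(config)
    config <- setNames(lapply(nm, function(s) slot(config, s)), nm)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Serialize a ModelReport as JSON (plus the confusion matrix as CSV)
#' @param report A [ModelReport-class].
#' @param path Output JSON path.
#' @export
writeModelReport <- function(report, path) {
  out <- list(
    chosen_model = report@chosenModel,
    tuned_params = report@tunedParams,
    cv_table = report@cvTable,
    metrics = report@metrics,
    confusion = list(classes = rownames(report@confusion),
                     matrix = unname(apply(report@confusion, 1L,
                                           as.integer, simplify = FALSE))),
    importances = report@importances,
    log = report@log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  cm_path <- sub("\\.json$", "_confusion.csv", path)
  write.csv(as.data.frame(report@confusion), cm_path, row.names = TRUE)
  invisible(path)
}
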