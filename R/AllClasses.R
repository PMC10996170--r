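#' @import methods
#' @importFrom stats fft median rnorm rgamma runif sd var dist setNames predict
#' @importFrom utils head modifyList write.csv read.csv
NULL

#' The four pelvic floor muscle contraction classes
#'
#' Expert readers classify each contraction clip as one of four outcomes:
#' \code{UNDETERMINABLE} (the video cannot be read), \code{CORRECT}
#' (the bladder base elevates, indicating a proper PFM contraction),
#' \code{FAILURE} (an attempted contraction without base elevation,
#' typically whole-bladder displacement from abdominal breathing or probe
#' motion) and \code{NONE} (no contraction). All label factors in the
#' package use this level order.
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
#' @examples
#' pfmClasses()
pfmClasses <- function() c("UNDETERMINABLE", "CORRECT", "FAILURE", "NONE")

.asLabelFactor <- function(x) factor(as.character(x), levels = pfmClasses())

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic ultrasound generator
#'
#' Holds the geometry, timing, motion and noise parameters of one synthetic
#' transverse-bladder recording. Image coordinates follow the raster
#' convention: origin at the top-left pixel, x rightward, y downward,
#' 0-based; "elevation" of the bladder base is therefore a decrease of the
#' Bottom landmark's y coordinate.
#'
#' @slot frame_width,frame_height Frame size in pixels.
#' @slot fps Frame rate in frames per second (recordings are made at 24).
#' @slot n_contractions Number of contraction/rest cycles (study protocol:
#'   4--10 per recording).
#' @slot contraction_s,rest_s Duration in seconds of the contraction and
#'   rest phase of each cycle.
#' @slot semi_axis_x,semi_axis_y Resting bladder semi-axes in pixels;
#'   varying these emulates different urine volumes.
#' @slot base_amplitude_px Peak upward displacement of the inferior bladder
#'   wall during a CORRECT contraction, pixels.
#' @slot translation_amplitude_px Peak rigid whole-bladder displacement
#'   during a FAILURE (breathing / probe motion), pixels.
#' @slot breathing_freq_hz Frequency of the horizontal breathing
#'   oscillation applied to FAILURE clips, Hz.
#' @slot jitter_px Standard deviation of isotropic per-vertex boundary
#'   jitter, pixels (frame-to-frame segmentation noise).
#' @slot speckle_var Variance of the unit-mean multiplicative speckle
#'   field applied to the rendered image.
#' @slot dropout_prob Per-frame probability, within UNDETERMINABLE cycles
#'   only, of corrupting the frame with an occluding band so that
#'   segmentation fails.
#' @slot seed Integer seed making the recording fully reproducible.
#' @export
setClass("SimulationConfig",
  representation(
    frame_width = "integer", frame_height = "integer",
    fps = "numeric", n_contractions = "integer",
    contraction_s = "numeric", rest_s = "numeric",
    semi_axis_x = "numeric", semi_axis_y = "numeric",
    base_amplitude_px = "numeric", translation_amplitude_px = "numeric",
    breathing_freq_hz = "numeric", jitter_px = "numeric",
    speckle_var = "numeric", dropout_prob = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@frame_width < 8L || object@frame_height < 8L)
    msg <- c(msg, "frame_width and frame_height must be at least 8 px")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@n_contractions < 1L) msg <- c(msg, "n_contractions must be >= 1")
  if (object@contraction_s <= 0 || object@rest_s <= 0)
    msg <- c(msg, "contraction_s and rest_s must be positive")
  if (object@semi_axis_x <= 0 || object@semi_axis_y <= 0)
    msg <- c(msg, "semi-axes must be positive")
  if (object@base_amplitude_px < 0 || object@translation_amplitude_px < 0 ||
      object@jitter_px < 0 || object@speckle_var < 0)
    msg <- c(msg, "amplitudes, jitter and speckle_var must be non-negative")
  if (object@dropout_prob < 0 || object@dropout_prob > 1)
    msg <- c(msg, "dropout_prob must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-recording configuration
#'
#' Defaults describe the desk-scale study conditions: 128x128 frames at
#' 24 fps, four 3 s contraction / 3 s rest cycles, a resting bladder of
#' semi-axes (32, 20) px, a 10 px bladder-base elevation for CORRECT
#' contractions, an 8 px rigid displacement with a 0.25 Hz breathing
#' oscillation for FAILUREs, 0.5 px boundary jitter, speckle variance 0.02
#' and a 0.6 per-frame corruption probability inside UNDETERMINABLE
#' cycles.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Frames per second.
#' @param n_contractions Number of contraction/rest cycles.
#' @param contraction_s,rest_s Phase durations, seconds.
#' @param semi_axis_x,semi_axis_y Resting bladder semi-axes, pixels.
#' @param base_amplitude_px CORRECT base-elevation amplitude, pixels.
#' @param translation_amplitude_px FAILURE rigid-motion amplitude, pixels.
#' @param breathing_freq_hz FAILURE breathing-oscillation frequency, Hz.
#' @param jitter_px Per-vertex boundary jitter SD, pixels.
#' @param speckle_var Multiplicative speckle variance.
#' @param dropout_prob Frame-corruption probability in UNDETERMINABLE
#'   cycles.
#' @param seed Integer seed.
#' @return A validated [SimulationConfig-class] object.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1L)
#' cfg
simulationConfig <- function(frame_width = 128L, frame_height = 128L,
                             fps = 24, n_contractions = 4L,
                             contraction_s = 3, rest_s = 3,
                             semi_axis_x = 32, semi_axis_y = 20,
                             base_amplitude_px = 10,
                             translation_amplitude_px = 8,
                             breathing_freq_hz = 0.25,
                             jitter_px = 0.5, speckle_var = 0.02,
                             dropout_prob = 0.6, seed = 1L) {
  new("SimulationConfig",
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    fps = as.numeric(fps), n_contractions = as.integer(n_contractions),
    contraction_s = as.numeric(contraction_s), rest_s = as.numeric(rest_s),
    semi_axis_x = as.numeric(semi_axis_x),
    semi_axis_y = as.numeric(semi_axis_y),
    base_amplitude_px = as.numeric(base_amplitude_px),
    translation_amplitude_px = as.numeric(translation_amplitude_px),
    breathing_freq_hz = as.numeric(breathing_freq_hz),
    jitter_px = as.numeric(jitter_px), speckle_var = as.numeric(speckle_var),
    dropout_prob = as.numeric(dropout_prob), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@frame_width, "x", object@frame_height,
      "px @", object@fps, "fps\n")
  cat("  cycles:", object@n_contractions, "x (", object@contraction_s,
      "s contract +", object@rest_s, "s rest )\n")
  cat("  bladder semi-axes: (", object@semi_axis_x, ",",
      object@semi_axis_y, ") px\n")
  cat("  amplitudes: base", object@base_amplitude_px, "px, translation",
      object@translation_amplitude_px, "px @", object@breathing_freq_hz,
      "Hz\n")
  cat("  noise: jitter", object@jitter_px, "px, speckle_var",
      object@speckle_var, ", dropout_prob", object@dropout_prob,
      ", seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# FrameStack
# ---------------------------------------------------------------------------

#' Time-ordered grayscale frames
#'
#' The unit of recording: an H x W x T array of intensities in [0, 255]
#' plus the frame rate. Frames are stored `[y + 1, x + 1, t]` under the
#' raster convention (0-based x/y used throughout the geometry code).
#'
#' @slot frames Numeric array, height x width x n_frames, values in
#'   [0, 255].
#' @slot fps Frames per second.
#' @export
setClass("FrameStack",
  representation(frames = "array", fps = "numeric"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array (H x W x T)")
  if (d[3] < 1L) return("a FrameStack needs at least one frame")
  if (object@fps <= 0) return("fps must be positive")
  rng <- range(object@frames)
  if (rng[1] < 0 || rng[2] > 255)
    return("intensities must lie in [0, 255]")
  TRUE
})

#' Construct a FrameStack
#' @param frames Numeric H x W x T array with values in [0, 255]; a single
#'   matrix is promoted to a one-frame stack.
#' @param fps Frames per second.
#' @return A [FrameStack-class].
#' @export
frameStack <- function(frames, fps = 24) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("FrameStack", frames = frames, fps = as.numeric(fps))
}

#' @describeIn frameStack Number of frames.
#' @param x A FrameStack.
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @describeIn frameStack Frame rate in frames per second.
#' @export
fps <- function(x) x@fps

#' @describeIn frameStack Extract frame \code{i} (1-based) as a matrix.
#' @param i Frame index, 1-based.
#' @export
getFrame <- function(x, i) x@frames[, , i]

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[3], "frames of", d[1], "x", d[2], "px @",
      object@fps, "fps (", round(d[3] / object@fps, 2), "s )\n")
})

# ---------------------------------------------------------------------------
# USRecording
# ---------------------------------------------------------------------------

#' A synthetic ultrasound recording with ground truth
#'
#' Bundles the rendered [FrameStack-class], the event log of
#' contraction/rest call times, and the generator's ground truth:
#' per-cycle labels, the jitter-free true contour of every frame and the
#' true landmark trajectory.
#'
#' @slot stack The rendered frames.
#' @slot events Data frame with columns \code{kind} ("contract"/"rest")
#'   and \code{time_s}; times strictly increasing, kinds alternating and
#'   starting with "contract".
#' @slot labels Factor of per-cycle classes (see [pfmClasses()]).
#' @slot contours List of true (noise-free) contours, one per frame.
#' @slot landmarks Data frame of true landmark coordinates per frame
#'   (columns \code{frame_index}, \code{time_s} and the ten channels
#'   \code{Center_x} ... \code{Bottom_y}).
#' @slot corrupted Logical per-frame flag: TRUE where the rendered frame
#'   was occluded (UNDETERMINABLE dropout).
#' @slot config The [SimulationConfig-class] used.
#' @slot recordingId,participantId Identifiers for provenance.
#' @export
setClass("USRecording",
  representation(stack = "FrameStack", events = "data.frame",
                 labels = "factor", contours = "list",
                 landmarks = "data.frame", corrupted = "logical",
                 config = "SimulationConfig",
                 recordingId = "character", participantId = "character"))

setValidity("USRecording", function(object) {
  msg <- character()
  if (length(object@labels) != object@config@n_contractions)
    msg <- c(msg, "one label per contraction cycle is required")
  if (!all(levels(object@labels) == pfmClasses()))
    msg <- c(msg, "labels must use the canonical class levels")
  if (length(object@contours) != nFrames(object@stack))
    msg <- c(msg, "one true contour per frame is required")
  v <- validateEventLog(object@events)
  if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

setMethod("show", "USRecording", function(object) {
  cat("USRecording", object@recordingId, "( participant",
      object@participantId, ")\n")
  show(object@stack)
  cat("  cycles:", paste(as.character(object@labels), collapse = ", "), "\n")
  cat("  events:", nrow(object@events), "| corrupted frames:",
      sum(object@corrupted), "\n")
})

#' Validate an event log
#'
#' An event log is a data frame with columns \code{kind} and
#' \code{time_s}: call times must be strictly increasing and kinds must
#' alternate contract, rest, contract, ... starting with "contract".
#'
#' @param events Data frame to check.
#' @return TRUE if valid, otherwise a character description of the defect.
#' @export
validateEventLog <- function(events) {
  if (!all(c("kind", "time_s") %in% names(events)))
    return("event log needs columns 'kind' and 'time_s'")
  if (nrow(events) == 0L) return("event log is empty")
  if (!all(events$kind %in% c("contract", "rest")))
    return("event kinds must be 'contract' or 'rest'")
  if (any(diff(events$time_s) <= 0))
    return("event times must be strictly increasing")
  expected <- rep(c("contract", "rest"), length.out = nrow(events))
  if (!all(events$kind == expected))
    return("event kinds must alternate starting with 'contract'")
  TRUE
}

# ---------------------------------------------------------------------------
# Clip
# ---------------------------------------------------------------------------

#' A per-contraction clip
#'
#' The analysis unit: the slice of a recording covering one contraction
#' call-to-rest-call window (plus padding), together with its expert (here:
#' generator) label and provenance.
#'
#' @slot clipId,recordingId,participantId Identifiers.
#' @slot stack [FrameStack-class] slice.
#' @slot label One of [pfmClasses()].
#' @slot startS,endS Clip window in recording time, seconds.
#' @slot frameOffset 0-based index of the clip's first frame within the
#'   source recording (aligns the clip with recording-level ground truth).
#' @export
setClass("Clip",
  representation(clipId = "character", recordingId = "character",
                 participantId = "character", stack = "FrameStack",
                 label = "factor", startS = "numeric", endS = "numeric",
                 frameOffset = "integer"))

setValidity("Clip", function(object) {
  if (nFrames(object@stack) < 1L) return("clip has no frames")
  if (object@endS <= object@startS) return("empty clip window")
  TRUE
})

setMethod("show", "Clip", function(object) {
  cat("Clip", object@clipId, "[", as.character(object@label), "]",
      nFrames(object@stack), "frames,",
      sprintf("%.2f-%.2f s", object@startS, object@endS), "\n")
})

# ---------------------------------------------------------------------------
# LandmarkSeries
# ---------------------------------------------------------------------------

#' Stride-sampled landmark coordinate time series
#'
#' Ten coordinate channels (Center/Left/Right/Top/Bottom x and y) sampled
#' every \code{stride} frames of a clip, with a per-sample missing flag set
#' where segmentation or landmark extraction failed.
#'
#' @slot clipId,recordingId,participantId Provenance.
#' @slot label Clip label.
#' @slot sampleTimes Sample times in seconds from the clip start.
#' @slot frameIndex 0-based clip frame index of each sample.
#' @slot coords Numeric matrix, samples x 10 channels, NA where missing.
#' @slot missing Logical per-sample flag.
#' @slot sampleRateHz Effective sampling rate (fps / stride).
#' @export
setClass("LandmarkSeries",
  representation(clipId = "character", recordingId = "character",
                 participantId = "character", label = "factor",
                 sampleTimes = "numeric", frameIndex = "integer",
                 coords = "matrix", missing = "logical",
                 sampleRateHz = "numeric"))

landmarkChannels <- function() {
  as.vector(outer(c("Center", "Left", "Right", "Top", "Bottom"),
                  c("x", "y"), function(p, a) paste(p, a, sep = "_")))
}

setValidity("LandmarkSeries", function(object) {
  n <- length(object@sampleTimes)
  if (nrow(object@coords) != n || length(object@missing) != n ||
      length(object@frameIndex) != n)
    return("sampleTimes, frameIndex, coords rows and missing must align")
  if (!identical(colnames(object@coords), landmarkChannels()))
    return("coords must have the ten canonical channel columns")
  bad <- !object@missing & apply(object@coords, 1L, anyNA)
  if (any(bad)) return("non-missing samples must have complete coordinates")
  TRUE
})

setMethod("show", "LandmarkSeries", function(object) {
  cat("LandmarkSeries", object@clipId, "[", as.character(object@label),
      "]:", length(object@sampleTimes), "samples @",
      object@sampleRateHz, "Hz,", sum(object@missing), "missing\n")
})

# ---------------------------------------------------------------------------
# ModelReport
# ---------------------------------------------------------------------------

#' Result of the classification protocol
#'
#' @slot cvTable Cross-validation comparison table (one row per model,
#'   fold-mean accuracy/AUC/recall/precision/F1, ranked by accuracy).
#' @slot chosenModel Name of the selected algorithm.
#' @slot tunedParams Named list of the grid-search winning hyperparameters.
#' @slot metrics Named list of held-out metrics (accuracy, auc, recall,
#'   precision, f1 -- macro averaged).
#' @slot confusion 4 x 4 integer matrix, rows = true class, columns =
#'   predicted class.
#' @slot importances Data frame of ranked feature importances (columns
#'   \code{feature}, \code{importance}), descending.
#' @slot model The fitted model object.
#' @slot log Named list of per-stage counts recorded by the pipeline.
#' @export
setClass("ModelReport",
  representation(cvTable = "data.frame", chosenModel = "character",
                 tunedParams = "list", metrics = "list",
                 confusion = "matrix", importances = "data.frame",
                 model = "ANY", log = "list"))

setValidity("ModelReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (any(cm < 0)) return("confusion matrix must be non-negative")
  TRUE
})

setMethod("show", "ModelReport", function(object) {
  cat("ModelReport --", object@chosenModel, "\n")
  if (nrow(object@cvTable)) {
    cat("Cross-validation ranking:\n")
    print(object@cvTable, row.names = FALSE, digits = 3)
  }
  m <- object@metrics
  cat(sprintf(
    "Held-out: accuracy %.3f | AUC %.3f | recall %.3f | precision %.3f | F1 %.3f\n",
    m$accuracy, ifelse(is.na(m$auc), NA, m$auc), m$recall, m$precision,
    m$f1))
  cat("Confusion matrix (rows = truth):\n")
  print(object@confusion)
  if (nrow(object@importances)) {
    cat("Top feature importances:\n")
    print(head(object@importances, 10L), row.names = FALSE, digits = 3)
  }
})
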