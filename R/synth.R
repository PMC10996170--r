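# Synthetic transverse-bladder B-mode generator.
#
# The bladder lumen (urine) is anechoic, so it is rendered as a dark
# ellipse-derived region on a bright multiplicative-speckle background.
# Class-specific motion encodes the clinical reading: a CORRECT pelvic
# floor muscle contraction elevates the bladder base (the inferior wall
# moves cranially, i.e. to smaller y), a contraction FAILURE displaces the
# whole bladder rigidly (abdominal breathing / probe motion) without any
# differential base motion, NONE is static, and UNDETERMINABLE clips are
# static but their frames are randomly occluded so that segmentation
# fails.

.N_VERTICES <- 120L

.ellipseCenter <- function(config) {
  c(x = (config@frame_width - 1) / 2, y = (config@frame_height - 1) / 2)
}

# raised-cosine activation: 0 outside [t0, t1], smooth bump peaking at 1
# at the interval midpoint
.bump <- function(t, t0, t1) {
  if (t1 <= t0) return(0)
  if (t < t0 || t > t1) return(0)
  0.5 - 0.5 * cos(2 * pi * (t - t0) / (t1 - t0))
}

# Jitter-free contour under the class motion model; also the source of
# ground-truth geometry.
.motionContour <- function(time_s, label, event_window, config,
                           n_vertices = .N_VERTICES) {
  ctr <- .ellipseCenter(config)
  a <- config@semi_axis_x
  b <- config@semi_axis_y
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  x <- ctr["x"] + a * cos(theta)
  y <- ctr["y"] + b * sin(theta)   # sin > 0 is the inferior (lower) half
  s <- .bump(time_s, event_window[1], event_window[2])
  if (label == "CORRECT") {
    # inferior wall elevated (y decreases), superior wall static
    y <- y - config@base_amplitude_px * s * pmax(0, sin(theta))
  } else if (label == "FAILURE") {
    # rigid whole-bladder motion: vertical bump + horizontal breathing
    y <- y - config@translation_amplitude_px * s
    x <- x + 0.5 * config@translation_amplitude_px *
      sin(2 * pi * config@breathing_freq_hz * time_s)
  } else if (!label %in% c("NONE", "UNDETERMINABLE")) {
    stop("unknown contraction label: ", label)
  }
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  rownames(m) <- NULL
  m
}

# True landmark positions under the same (jitter-free) motion model.
.trueLandmarks <- function(time_s, label, event_window, config) {
  ctr <- .ellipseCenter(config)
  a <- config@semi_axis_x
  b <- config@semi_axis_y
  s <- .bump(time_s, event_window[1], event_window[2])
  dx <- 0
  dy <- 0
  bottom_y <- ctr["y"] + b
  if (label == "CORRECT") {
    bottom_y <- bottom_y - config@base_amplitude_px * s
  } else if (label == "FAILURE") {
    dy <- -config@translation_amplitude_px * s
    dx <- 0.5 * config@translation_amplitude_px *
      sin(2 * pi * config@breathing_freq_hz * time_s)
  } else if (!label %in% c("NONE", "UNDETERMINABLE")) {
    stop("unknown contraction label: ", label)
  }
  c(Center_x = ctr[["x"]] + dx, Center_y = ctr[["y"]] + dy,
    Left_x = ctr[["x"]] - a + dx, Left_y = ctr[["y"]] + dy,
    Right_x = ctr[["x"]] + a + dx, Right_y = ctr[["y"]] + dy,
    Top_x = ctr[["x"]] + dx, Top_y = ctr[["y"]] - b + dy,
    Bottom_x = ctr[["x"]] + dx, Bottom_y = bottom_y[[1]] + dy)
}

#' True bladder contour at a time point
#'
#' Evaluates the class-specific motion model at \code{time_s} and returns
#' the (possibly jittered) closed bladder contour. A CORRECT contraction
#' displaces the inferior half of the wall upward by
#' \code{base_amplitude_px} times a raised-cosine activation supported on
#' the contraction interval (the superior wall stays put); a FAILURE
#' translates the whole contour rigidly by \code{translation_amplitude_px}
#' times the same activation plus a horizontal sinusoid at
#' \code{breathing_freq_hz}; NONE and UNDETERMINABLE are static. Isotropic
#' Gaussian vertex jitter with SD \code{jitter_px} is then added (drawn
#' from the current RNG stream).
#'
#' @param time_s Time in seconds within the recording.
#' @param label One of [pfmClasses()].
#' @param event_window Numeric length-2: the contraction interval
#'   (contract call, rest call) containing or nearest to \code{time_s},
#'   seconds.
#' @param config A [SimulationConfig-class].
#' @param n_vertices Number of contour vertices.
#' @return Numeric matrix with columns \code{x}, \code{y}: a closed
#'   polygon (last vertex connects back to the first), 0-based pixel
#'   coordinates.
#' @export
#' @examples
#' cfg <- simulationConfig(jitter_px = 0)
#' head(contourAt(1.5, "CORRECT", c(0, 3), cfg))
contourAt <- function(time_s, label, event_window, config,
                      n_vertices = .N_VERTICES) {
  poly <- .motionContour(time_s, label, event_window, config, n_vertices)
  # jitter is always drawn so that RNG consumption does not depend on the
  # class or the amplitudes (zero-amplitude runs stay seed-comparable)
  poly + matrix(rnorm(2L * nrow(poly), 0, config@jitter_px), ncol = 2L)
}

# Even-odd scanline rasterization of a closed polygon onto pixel centres.
.polygonMask <- function(poly, height, width) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1L), 1]; y2 <- poly[c(2:n, 1L), 2]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  r0 <- pmax(ceiling(lo), 0)
  r1 <- pmin(ceiling(hi) - 1, height - 1L)   # half-open [lo, hi)
  cnt <- pmax(r1 - r0 + 1L, 0L)
  idx <- rep.int(seq_along(x1), cnt)
  rows <- sequence(cnt, from = r0)
  mask <- matrix(FALSE, height, width)
  if (!length(rows)) return(mask)
  xc <- x1[idx] + (rows - y1[idx]) / (y2[idx] - y1[idx]) *
    (x2[idx] - x1[idx])
  byrow <- split(xc, rows)
  for (rn in names(byrow)) {
    xs <- byrow[[rn]]
    if (length(xs) == 2L) {
      if (xs[1L] > xs[2L]) xs <- xs[c(2L, 1L)]
    } else {
      xs <- xs[order(xs)]
      if (length(xs) %% 2L == 1L) xs <- xs[-length(xs)]  # tangency guard
    }
    if (!length(xs)) next
    r <- as.integer(rn) + 1L
    for (p in seq(1L, length(xs), by = 2L)) {
      c0 <- max(ceiling(xs[p]), 0) + 1L
      c1 <- min(floor(xs[p + 1L]), width - 1L) + 1L
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

.INSIDE_LEVEL <- 20
.OUTSIDE_LEVEL <- 180
.BAND_LEVEL <- 215

#' Render one B-mode frame from a contour
#'
#' Pixels inside the contour are near-dark (anechoic lumen), pixels
#' outside are bright; both are multiplied by a unit-mean gamma speckle
#' field of variance \code{speckle_var}. When \code{allowDropout} is TRUE
#' (the caller is rendering an UNDETERMINABLE cycle), the frame is, with
#' probability \code{dropout_prob}, corrupted by a bright occluding band
#' covering the inferior bladder boundary and everything below it, so that
#' downstream segmentation fails.
#'
#' @param contour Closed polygon matrix (columns x, y), 0-based pixel
#'   coordinates; must fit inside the frame.
#' @param config A [SimulationConfig-class].
#' @param allowDropout Whether the dropout coin may be tossed for this
#'   frame.
#' @return Numeric height x width matrix in [0, 255] with attribute
#'   \code{corrupted} (logical).
#' @export
#' @examples
#' cfg <- simulationConfig(speckle_var = 0)
#' fr <- renderFrame(contourAt(0, "NONE", c(0, 3), cfg), cfg)
#' range(fr)
renderFrame <- function(contour, config, allowDropout = FALSE) {
  h <- config@frame_height
  w <- config@frame_width
  if (any(contour[, 1] < 0) || any(contour[, 1] > w - 1) ||
      any(contour[, 2] < 0) || any(contour[, 2] > h - 1))
    stop("contour exceeds frame bounds")
  mask <- .polygonMask(contour, h, w)
  img <- matrix(.OUTSIDE_LEVEL, h, w)
  img[mask] <- .INSIDE_LEVEL
  if (config@speckle_var > 0) {
    shape <- 1 / config@speckle_var
    g <- matrix(rgamma(h * w, shape = shape, scale = 1 / shape), h, w)
    img <- img * g
  }
  corrupted <- FALSE
  if (allowDropout && config@dropout_prob > 0 &&
      runif(1) < config@dropout_prob) {
    corrupted <- TRUE
    band_top <- floor(mean(contour[, 2]) - 0.9 * config@semi_axis_y)
    band_top <- min(max(band_top, 0), h - 1)
    img[(band_top + 1L):h, ] <- .BAND_LEVEL
  }
  img <- pmin(pmax(img, 0), 255)
  attr(img, "corrupted") <- corrupted
  img
}

#' Simulate a full contraction/rest recording
#'
#' Renders \code{n_contractions} cycles of (contraction_s + rest_s)
#' seconds each at \code{fps} frames per second, with one contract call and
#' one rest call per cycle in the event log, the per-cycle class labels
#' given in \code{label_sequence}, and ground-truth contours and landmark
#' trajectories from the jitter-free motion model. The whole recording is
#' reproducible from \code{config@seed}.
#'
#' @param config A [SimulationConfig-class].
#' @param label_sequence Character or factor of length
#'   \code{n_contractions}, values in [pfmClasses()].
#' @param recordingId,participantId Identifiers stored for provenance.
#' @return A [USRecording-class].
#' @export
#' @examples
#' cfg <- simulationConfig(frame_width = 64L, frame_height = 64L,
#'                         semi_axis_x = 16, semi_axis_y = 10,
#'                         n_contractions = 2L, seed = 7L)
#' rec <- simulateRecording(cfg, c("CORRECT", "NONE"))
#' rec
simulateRecording <- function(config, label_sequence,
                              recordingId = "rec01",
                              participantId = "p01") {
  labels <- .asLabelFactor(label_sequence)
  if (anyNA(labels))
    stop("unknown contraction label in label_sequence")
  if (length(labels) != config@n_contractions)
    stop("label_sequence must have one label per contraction (",
         config@n_contractions, ")")
  cyc <- config@contraction_s + config@rest_s
  n_frames <- as.integer(round(config@n_contractions * cyc * config@fps))
  t_frames <- (seq_len(n_frames) - 1L) / config@fps
  k <- pmin(floor(t_frames / cyc), config@n_contractions - 1L)
  win0 <- k * cyc
  win1 <- win0 + config@contraction_s
  frame_label <- as.character(labels)[k + 1L]
  # dropout may strike any frame a clip window (call-to-call +- 0.5 s
  # padding) can reach
  in_dropout_zone <- frame_label == "UNDETERMINABLE" &
    t_frames >= win0 - 0.5 & t_frames <= win1 + 0.5

  events <- data.frame(
    kind = rep(c("contract", "rest"), config@n_contractions),
    time_s = as.vector(rbind(cyc * (seq_len(config@n_contractions) - 1L),
                             cyc * (seq_len(config@n_contractions) - 1L) +
                               config@contraction_s)))

  frames <- array(0, c(config@frame_height, config@frame_width, n_frames))
  contours <- vector("list", n_frames)
  corrupted <- logical(n_frames)
  lmk <- matrix(NA_real_, n_frames, 10L,
                dimnames = list(NULL, landmarkChannels()))
  withr::local_seed(config@seed)
  for (i in seq_len(n_frames)) {
    win <- c(win0[i], win1[i])
    contours[[i]] <- .motionContour(t_frames[i], frame_label[i], win,
                                    config)
    lmk[i, ] <- .trueLandmarks(t_frames[i], frame_label[i], win,
                               config)[landmarkChannels()]
    poly <- contourAt(t_frames[i], frame_label[i], win, config)
    fr <- renderFrame(poly, config, allowDropout = in_dropout_zone[i])
    corrupted[i] <- attr(fr, "corrupted")
    frames[, , i] <- fr
  }
  landmarks <- data.frame(frame_index = seq_len(n_frames) - 1L,
                          time_s = t_frames, lmk, check.names = FALSE)
  new("USRecording",
      stack = frameStack(frames, config@fps), events = events,
      labels = labels, contours = contours, landmarks = landmarks,
      corrupted = corrupted, config = config,
      recordingId = recordingId, participantId = participantId)
}
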