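# Five-landmark extraction.
#
# Per frame, the bladder contour yields five landmarks: the endpoints of
# the maximum bladder diameter (Left, Right: the longest chord between
# contour vertices), its midpoint (Center), and the points where the
# vertical line through Center crosses the superior and inferior bladder
# wall (Top, Bottom). Landmarks are assembled into stride-sampled time
# series per clip; frames whose segmentation or geometry fails become
# missing samples, never aborted clips.

#' Maximum bladder diameter chord
#'
#' Exhaustive search over all vertex pairs for the pair at maximal
#' Euclidean distance. Left is the endpoint with smaller x (tie: smaller
#' y), Right the other, Center the arithmetic midpoint. Ties between
#' equally long chords are broken by the lexicographically smallest
#' (left, right) coordinate tuple.
#'
#' @param contour Polygon matrix (columns x, y) with at least 3 vertices.
#' @return List with numeric length-2 elements \code{left}, \code{right},
#'   \code{center} (named x, y).
#' @export
#' @examples
#' sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' maxDiameterChord(sq)
maxDiameterChord <- function(contour) {
  n <- nrow(contour)
  if (is.null(n) || n < 3L) stop("contour needs at least 3 vertices")
  d <- as.matrix(stats::dist(contour))
  hits <- which(d == max(d), arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  ends <- lapply(seq_len(nrow(hits)), function(r) {
    a <- contour[hits[r, 1], 1:2]
    b <- contour[hits[r, 2], 1:2]
    swap <- b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])
    if (swap) list(left = b, right = a) else list(left = a, right = b)
  })
  key <- vapply(ends, function(e) c(e$left, e$right), numeric(4))
  best <- do.call(order, as.data.frame(t(key)))[1]
  left <- unname(ends[[best]]$left)
  right <- unname(ends[[best]]$right)
  list(left = c(x = left[1], y = left[2]),
       right = c(x = right[1], y = right[2]),
       center = c(x = (left[1] + right[1]) / 2,
                  y = (left[2] + right[2]) / 2))
}

#' Vertical bladder-wall extents through a column
#'
#' Intersects the vertical line x = \code{center_x} with every contour
#' edge (linear interpolation along edges; vertices lying exactly on the
#' line count as crossings). Top is the intersection with minimum y,
#' Bottom the one with maximum y; concave contours may cross more than
#' twice, in which case the global extremes are taken.
#'
#' @param contour Polygon matrix (columns x, y).
#' @param center_x Column (x coordinate) of the vertical line.
#' @return List with numeric length-2 elements \code{top}, \code{bottom}.
#' @export
#' @examples
#' sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' verticalExtents(sq, 5)
verticalExtents <- function(contour, center_x) {
  n <- nrow(contour)
  if (is.null(n) || n < 3L) stop("contour needs at least 3 vertices")
  x <- contour[, 1]; y <- contour[, 2]
  xn <- x[c(2:n, 1L)]; yn <- y[c(2:n, 1L)]
  ys <- y[x == center_x]                       # vertices on the line
  cross <- (x - center_x) * (xn - center_x) < 0
  if (any(cross)) {
    t <- (center_x - x[cross]) / (xn[cross] - x[cross])
    ys <- c(ys, y[cross] + t * (yn[cross] - y[cross]))
  }
  if (!length(ys))
    stop("vertical line x = ", center_x, " does not intersect the contour")
  list(top = c(x = center_x, y = min(ys)),
       bottom = c(x = center_x, y = max(ys)))
}

# All five landmarks of one contour, or NULL on geometric failure.
.landmarksFromContour <- function(contour) {
  chord <- maxDiameterChord(contour)
  ext <- tryCatch(verticalExtents(contour, chord$center[["x"]]),
                  error = function(e) NULL)
  if (is.null(ext)) return(NULL)
  c(Center_x = chord$center[["x"]], Center_y = chord$center[["y"]],
    Left_x = chord$left[["x"]], Left_y = chord$left[["y"]],
    Right_x = chord$right[["x"]], Right_y = chord$right[["y"]],
    Top_x = ext$top[["x"]], Top_y = ext$top[["y"]],
    Bottom_x = ext$bottom[["x"]], Bottom_y = ext$bottom[["y"]])
}

#' Extract a stride-sampled landmark series from a clip
#'
#' Landmarks are computed at clip frames 0, stride, 2*stride, ...
#' (sampling starts at the clip's first frame), giving an effective
#' sample rate of fps / stride (2.4 Hz at the 24 fps / stride-10
#' defaults). Frames whose segmentation failed, or where the vertical
#' line through Center misses the contour, yield missing samples; the
#' series is emitted even if every sample is missing.
#'
#' @param clip A [Clip-class].
#' @param segmentation_results Optional list covering the clip's frames
#'   (entries as returned by [segmentBladder()]; only the sampled
#'   positions are consulted). When NULL, the sampled frames are
#'   segmented on the fly.
#' @param stride Frame stride (default 10).
#' @param seg_params Parameters passed to [segmentBladder()] when
#'   segmenting internally.
#' @return A [LandmarkSeries-class] with the ten coordinate channels.
#' @export
extractSeries <- function(clip, segmentation_results = NULL, stride = 10L,
                          seg_params = list()) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  nf <- nFrames(clip@stack)
  idx <- seq.int(0L, nf - 1L, by = stride)
  if (!is.null(segmentation_results) &&
      length(segmentation_results) < nf)
    stop("segmentation_results must cover the clip's frames")
  coords <- matrix(NA_real_, length(idx), 10L,
                   dimnames = list(NULL, landmarkChannels()))
  miss <- logical(length(idx))
  for (s in seq_along(idx)) {
    i <- idx[s]
    seg <- if (is.null(segmentation_results))
      segmentBladder(getFrame(clip@stack, i + 1L), seg_params)
    else segmentation_results[[i + 1L]]
    lm <- NULL
    if (!is.null(seg) && identical(seg$status, "ok"))
      lm <- .landmarksFromContour(seg$contour)
    if (is.null(lm)) miss[s] <- TRUE
    else coords[s, ] <- lm[landmarkChannels()]
  }
  new("LandmarkSeries",
      clipId = clip@clipId, recordingId = clip@recordingId,
      participantId = clip@participantId, label = clip@label,
      sampleTimes = idx / fps(clip@stack), frameIndex = idx,
      coords = coords, missing = miss,
      sampleRateHz = fps(clip@stack) / stride)
}
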