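# Clip trimming and bladder segmentation.
#
# Recordings are trimmed into per-contraction clips using the logged call
# times. Segmentation is a deliberately simple stand-in for the external
# bladder-extraction system used on real recordings: automatic bimodal
# (Otsu) thresholding of the dark anechoic region, morphological closing,
# largest connected component, traced outer boundary. It is adequate for
# synthetic frames; real-image robustness is out of scope.

#' Trim a recording into per-contraction clips
#'
#' One clip per contraction cycle; the clip window is the
#' call-to-call interval [contract call, rest call] extended by
#' \code{padding_s} on each side (clamped to the recording bounds), so
#' that contraction onset and offset motion are captured.
#'
#' @param x A [USRecording-class] (labels and events taken from the
#'   object) or a [FrameStack-class].
#' @param events Event log data frame (ignored for USRecording input).
#' @param labels Per-cycle labels, one per contract call (ignored for
#'   USRecording input).
#' @param padding_s Symmetric window padding, seconds (default 0.5).
#' @param recordingId,participantId Provenance for FrameStack input.
#' @param ... Passed between methods.
#' @return List of [Clip-class] objects, in cycle order.
#' @export
setGeneric("trimClips", function(x, ...) standardGeneric("trimClips"))

#' @rdname trimClips
#' @export
setMethod("trimClips", "USRecording", function(x, padding_s = 0.5, ...) {
  trimClips(x@stack, events = x@events, labels = x@labels,
            padding_s = padding_s, recordingId = x@recordingId,
            participantId = x@participantId)
})

#' @rdname trimClips
#' @export
setMethod("trimClips", "FrameStack", function(x, events, labels,
                                              padding_s = 0.5,
                                              recordingId = "rec01",
                                              participantId = "p01", ...) {
  v <- validateEventLog(events)
  if (!isTRUE(v)) stop(v)
  contracts <- events$time_s[events$kind == "contract"]
  rests <- events$time_s[events$kind == "rest"]
  if (length(contracts) != length(rests))
    stop("event log must pair every contract call with a rest call")
  labels <- .asLabelFactor(labels)
  if (length(labels) != length(contracts))
    stop("need exactly one label per contract call (",
         length(contracts), " calls, ", length(labels), " labels)")
  n_total <- nFrames(x)
  out <- vector("list", length(contracts))
  for (k in seq_along(contracts)) {
    i0 <- max(0L, as.integer(round((contracts[k] - padding_s) * fps(x))))
    i1 <- min(n_total - 1L,
              as.integer(round((rests[k] + padding_s) * fps(x))) - 1L)
    if (i1 < i0) stop("empty clip window for cycle ", k)
    out[[k]] <- new("Clip",
      clipId = sprintf("%s_c%02d", recordingId, k),
      recordingId = recordingId, participantId = participantId,
      stack = frameStack(x@frames[, , (i0 + 1L):(i1 + 1L), drop = FALSE],
                         fps(x)),
      label = labels[k], startS = i0 / fps(x), endS = (i1 + 1L) / fps(x),
      frameOffset = i0)
  }
  out
})

# Outward half-pixel offset of a traced boundary: boundary pixel centres
# sit on average half a pixel inside the true edge, so the raw trace
# under-estimates the enclosed region by ~ perimeter / 2 px^2.
.outsetContour <- function(poly, d = 0.5) {
  n <- nrow(poly)
  if (n < 3L) return(poly)
  nxt <- poly[c(2:n, 1L), , drop = FALSE]
  prv <- poly[c(n, 1:(n - 1L)), , drop = FALSE]
  tg <- nxt - prv
  len <- sqrt(rowSums(tg^2))
  len[len == 0] <- 1
  nrm <- cbind(tg[, 2], -tg[, 1]) / len
  ctr <- colMeans(poly)
  outward <- rowSums(nrm * sweep(poly, 2L, ctr)) >= 0
  nrm[!outward, ] <- -nrm[!outward, , drop = FALSE]
  poly + d * nrm
}

.shoelaceArea <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Segment the bladder in one frame
#'
#' Automatic bimodal (Otsu) threshold, dark-region mask, morphological
#' closing, largest connected component, traced outer boundary with a
#' half-pixel outward offset. Segmentation fails (status \code{"failed"},
#' no contour) when no dark component reaches \code{min_area_frac} of the
#' frame or the traced boundary degenerates; failure is an explicit state,
#' never a zero-area contour.
#'
#' @param frame Numeric grayscale matrix, intensities in [0, 255].
#' @param params List of tuning parameters: \code{min_area_frac} (minimum
#'   component area as a fraction of the frame, default 0.01),
#'   \code{brush_size} (closing structuring-element diameter, default 5)
#'   and \code{max_contrast} (the accepted component must be anechoic:
#'   its mean intensity must be below this fraction of the mean intensity
#'   of the rest of the frame, default 0.5).
#' @return A list with elements \code{status} ("ok" or "failed") and,
#'   when ok, \code{contour}: a closed polygon matrix (columns x, y,
#'   0-based pixel coordinates).
#' @export
#' @examples
#' cfg <- simulationConfig(speckle_var = 0, jitter_px = 0)
#' fr <- renderFrame(contourAt(0, "NONE", c(0, 3), cfg), cfg)
#' res <- segmentBladder(fr)
#' res$status
segmentBladder <- function(frame, params = list()) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("segmentBladder expects a single grayscale frame matrix")
  p <- modifyList(list(min_area_frac = 0.01, brush_size = 5L,
                       max_contrast = 0.5), params)
  failed <- list(status = "failed", contour = NULL)
  img <- frame / 255
  thr <- EBImage::otsu(EBImage::Image(img))
  mask <- (img < thr) * 1
  if (!any(mask > 0)) return(failed)
  mask <- EBImage::closing(mask,
                           EBImage::makeBrush(p$brush_size, shape = "disc"))
  lbl <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lbl))
  if (!length(sizes)) return(failed)
  biggest <- which.max(sizes)
  if (sizes[biggest] < p$min_area_frac * length(frame)) return(failed)
  comp <- (lbl == biggest) * 1
  # anechoic check: the bladder lumen must be dark relative to the
  # surrounding tissue, otherwise the threshold split something else
  # (e.g. an occluded, bladder-free frame)
  inside_mean <- mean(frame[comp > 0])
  outside_mean <- mean(frame[comp == 0])
  if (!is.finite(outside_mean) ||
      inside_mean >= p$max_contrast * outside_mean) return(failed)
  oc <- EBImage::ocontour(comp)
  if (!length(oc)) return(failed)
  b <- oc[[1]]                       # 0-based (dim1, dim2) = (y, x)
  if (nrow(b) < 3L) return(failed)
  contour <- .outsetContour(cbind(x = b[, 2], y = b[, 1]))
  if (.shoelaceArea(contour) <= 0) return(failed)
  list(status = "ok", contour = contour)
}
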