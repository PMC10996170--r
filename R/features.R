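# Time-series featurization.
#
# A fixed, versioned catalogue of per-channel features (moments, peak
# counts, FFT coefficient magnitudes, spectral summaries) is applied to
# the ten landmark coordinate channels plus the bladder-area surrogate,
# and combined with the bespoke bladder-base elevation feature. Missing
# samples are excluded from moment-type features; spectral features are
# computed only on gap-free series (a discrete Fourier transform of
# gapped data is ill-defined). Features that come out missing anywhere in
# the dataset are excluded column-wise when the table is assembled.

.CATALOGUE_VERSION <- "pfmus-catalogue-1"

#' The fixed per-channel feature catalogue
#'
#' Twenty named features computed for every coordinate channel and for
#' the bladder-area surrogate: moments (mean, minimum, maximum, median,
#' standard_deviation, variance, range), dynamics (mean_abs_change,
#' count_above_mean, autocorrelation_lag1, linear_trend_slope,
#' number_of_peaks with support 1 and 3), and spectral summaries on the
#' mean-removed series (|FFT| coefficients k = 1..4,
#' dominant_frequency_hz, spectral_energy).
#'
#' @return Character vector of feature names; attribute \code{version}
#'   identifies the catalogue revision recorded in outputs.
#' @export
#' @examples
#' featureCatalogue()
featureCatalogue <- function() {
  feats <- c("mean", "minimum", "maximum", "median",
             "standard_deviation", "variance", "range",
             "mean_abs_change", "count_above_mean",
             "autocorrelation_lag1", "linear_trend_slope",
             "number_of_peaks_1", "number_of_peaks_3",
             paste0("abs_fft_coefficient_", 1:4),
             "dominant_frequency_hz", "spectral_energy")
  attr(feats, "version") <- .CATALOGUE_VERSION
  feats
}

# strict local maxima with support n: greater than every neighbour within
# n positions on both sides
.numberOfPeaks <- function(x, n) {
  len <- length(x)
  if (len < 2L * n + 1L) return(NA_real_)
  count <- 0L
  for (i in (n + 1L):(len - n)) {
    lo <- x[(i - n):(i - 1L)]
    hi <- x[(i + 1L):(i + n)]
    if (all(x[i] > lo) && all(x[i] > hi)) count <- count + 1L
  }
  as.numeric(count)
}

#' Compute the feature catalogue on one channel
#'
#' Moment-type features are computed on the non-missing samples; spectral
#' features (FFT magnitudes, dominant frequency, spectral energy) require
#' a gap-free series of at least 4 samples and come out NA otherwise, as
#' do features whose minimum sample count is not met (e.g. peak counts of
#' support n need 2n + 1 samples).
#'
#' @param x Numeric series, NA marking missing samples.
#' @param sample_rate_hz Sampling rate in Hz (fps / stride).
#' @param catalogue Feature name vector from [featureCatalogue()].
#' @return Named numeric vector, one entry per catalogue feature.
#' @export
#' @examples
#' computeChannelFeatures(c(0, 1, 0, 2, 0), sample_rate_hz = 2.4)
computeChannelFeatures <- function(x, sample_rate_hz,
                                   catalogue = featureCatalogue()) {
  ok <- !is.na(x)
  xo <- x[ok]
  n <- length(xo)
  N <- length(x)
  t_ok <- ((seq_len(N) - 1L) / sample_rate_hz)[ok]
  out <- setNames(rep(NA_real_, length(catalogue)), catalogue)

  if (n >= 1L) {
    out["mean"] <- mean(xo)
    out["minimum"] <- min(xo)
    out["maximum"] <- max(xo)
    out["median"] <- median(xo)
    out["range"] <- max(xo) - min(xo)
    out["count_above_mean"] <- sum(xo > mean(xo))
  }
  if (n >= 2L) {
    out["standard_deviation"] <- sd(xo)
    out["variance"] <- var(xo)
    out["mean_abs_change"] <- mean(abs(diff(xo)))
    tc <- t_ok - mean(t_ok)
    denom <- sum(tc^2)
    out["linear_trend_slope"] <-
      if (denom > 0) sum(tc * (xo - mean(xo))) / denom else 0
  }
  if (n >= 3L) {
    m <- mean(xo)
    denom <- sum((xo - m)^2)
    out["autocorrelation_lag1"] <-
      if (denom > 0) sum((xo[-n] - m) * (xo[-1] - m)) / denom else 0
  }
  out["number_of_peaks_1"] <- .numberOfPeaks(xo, 1L)
  out["number_of_peaks_3"] <- .numberOfPeaks(xo, 3L)

  if (all(ok) && N >= 4L) {
    z <- x - mean(x)
    absF <- Mod(fft(z))
    for (k in 1:4)
      if (k <= N - 1L)
        out[paste0("abs_fft_coefficient_", k)] <- absF[k + 1L]
    half <- 2:(floor(N / 2) + 1L)
    kmax <- which.max(absF[half])          # ties: smallest k wins
    out["dominant_frequency_hz"] <- kmax * sample_rate_hz / N
    out["spectral_energy"] <- sum(absF^2) / N
  }
  out
}

#' Bladder-area surrogate series
#'
#' Per sample, the product of the horizontal landmark span and the
#' vertical landmark span, |Right_x - Left_x| * |Bottom_y - Top_y| in
#' squared pixels: a surrogate for urine volume. Missing samples
#' propagate as NA.
#'
#' @param series A [LandmarkSeries-class], or a numeric matrix with the
#'   ten canonical channel columns.
#' @return Numeric vector, one value per sample.
#' @export
areaSeries <- function(series) {
  m <- if (is(series, "LandmarkSeries")) series@coords else series
  abs(m[, "Right_x"] - m[, "Left_x"]) * abs(m[, "Bottom_y"] - m[, "Top_y"])
}

#' Bladder base elevation
#'
#' The difference between the maximum and minimum of the Bottom landmark's
#' y coordinate over the non-missing samples: the total vertical excursion
#' of the bladder base during the clip. Requires at least two non-missing
#' samples (NA otherwise); always non-negative.
#'
#' @param series A [LandmarkSeries-class] or a numeric Bottom_y vector
#'   (NA marking missing samples).
#' @return Scalar elevation in pixels, or NA.
#' @export
#' @examples
#' baseElevation(c(60, 58, 55, 58, 60))
baseElevation <- function(series) {
  y <- if (is(series, "LandmarkSeries")) series@coords[, "Bottom_y"]
       else series
  y <- y[!is.na(y)]
  if (length(y) < 2L) return(NA_real_)
  max(y) - min(y)
}

#' Assemble the labeled feature table
#'
#' Computes the catalogue features for the ten coordinate channels plus
#' the Area channel of every landmark series, adds the bladder-base
#' elevation, and attaches labels and provenance. Clips with zero
#' non-missing samples are dropped as rows (with a message); afterwards
#' every feature column still containing at least one missing value is
#' excluded, so that the returned table is complete. Counts before and
#' after exclusion are reported and stored as attributes.
#'
#' @param landmark_series_list List of [LandmarkSeries-class] objects.
#' @param labels Optional label vector (one per series); defaults to the
#'   labels carried by the series.
#' @param catalogue Feature catalogue, see [featureCatalogue()].
#' @return A data.frame with provenance columns (\code{clip_id},
#'   \code{recording_id}, \code{participant_id}), the surviving feature
#'   columns, and a \code{label} factor column. Attributes:
#'   \code{dropped_columns}, \code{n_features_before},
#'   \code{n_features_after}, \code{catalogue_version},
#'   \code{sample_rate_hz}.
#' @export
buildFeatureTable <- function(landmark_series_list, labels = NULL,
                              catalogue = featureCatalogue()) {
  if (!length(landmark_series_list)) stop("no landmark series supplied")
  if (is.null(labels))
    labels <- vapply(landmark_series_list,
                     function(s) as.character(s@label), character(1))
  labels <- .asLabelFactor(labels)
  if (length(labels) != length(landmark_series_list))
    stop("need exactly one label per landmark series")

  keep <- vapply(landmark_series_list, function(s) any(!s@missing),
                 logical(1))
  if (!any(keep))
    stop("every clip has zero usable samples; nothing to featurize")
  if (any(!keep))
    message(sum(!keep), " clip(s) dropped: zero non-missing samples (",
            paste(vapply(landmark_series_list[!keep],
                         function(s) s@clipId, character(1)),
                  collapse = ", "), ")")
  series <- landmark_series_list[keep]
  labels <- labels[keep]

  channels <- c(landmarkChannels(), "Area")
  featNames <- as.vector(vapply(channels, function(ch)
    paste0(ch, "__", catalogue), character(length(catalogue))))
  rows <- lapply(series, function(s) {
    chans <- cbind(s@coords, Area = areaSeries(s))
    vals <- unlist(lapply(channels, function(ch)
      computeChannelFeatures(chans[, ch], s@sampleRateHz, catalogue)),
      use.names = FALSE)
    c(setNames(vals, featNames), base_elevation = baseElevation(s))
  })
  feat <- as.data.frame(do.call(rbind, rows))

  n_before <- ncol(feat)
  dropped <- names(feat)[vapply(feat, anyNA, logical(1))]
  feat <- feat[, setdiff(names(feat), dropped), drop = FALSE]
  if (!ncol(feat))
    stop("all feature columns contain missing values; nothing survives")
  message("feature columns: ", n_before, " computed, ", length(dropped),
          " excluded for missing values, ", ncol(feat), " retained")

  tab <- data.frame(
    clip_id = vapply(series, function(s) s@clipId, character(1)),
    recording_id = vapply(series, function(s) s@recordingId, character(1)),
    participant_id = vapply(series, function(s) s@participantId,
                            character(1)),
    feat, label = labels, check.names = FALSE)
  attr(tab, "dropped_columns") <- dropped
  attr(tab, "n_features_before") <- n_before
  attr(tab, "n_features_after") <- ncol(feat)
  attr(tab, "catalogue_version") <- attr(catalogue, "version")
  attr(tab, "sample_rate_hz") <- series[[1]]@sampleRateHz
  tab
}

# feature-matrix / label helpers shared by the classification code
.featureColumns <- function(table) {
  setdiff(names(table),
          c("clip_id", "recording_id", "participant_id", "label"))
}

.featureMatrix <- function(table) {
  as.matrix(table[, .featureColumns(table), drop = FALSE])
}
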