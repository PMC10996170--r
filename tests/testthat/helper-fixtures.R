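# Shared fixtures and independent oracles. Everything is generated in
# code; expensive simulations are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# closed ellipse contour, 0-based raster coordinates (y down)
ellipseContour <- function(n = 360L, a = 20, b = 10, cx = 50, cy = 50) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = cx + a * cos(th), y = cy + b * sin(th))
}

# random star-shaped polygon: simple by construction
starPolygon <- function(n, r_min = 5, r_max = 40, cx = 50, cy = 50) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_min, r_max)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# O(n^2) nested-loop chord oracle, independent of the dist()-based
# implementation: collect all maximal pairs, then apply the stated
# tie-break (lexicographically smallest (left, right) tuple)
chordOracle <- function(poly) {
  n <- nrow(poly)
  best <- -1
  tuples <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- (poly[i, 1] - poly[j, 1])^2 + (poly[i, 2] - poly[j, 2])^2
    if (d < best) next
    a <- poly[i, 1:2]; b <- poly[j, 1:2]
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) {
      tmp <- a; a <- b; b <- tmp
    }
    if (d > best) {
      best <- d
      tuples <- list(c(a, b))
    } else {
      tuples <- c(tuples, list(c(a, b)))
    }
  }
  key <- do.call(rbind, tuples)
  win <- tuples[[do.call(order, as.data.frame(key))[1]]]
  list(left = unname(win[1:2]), right = unname(win[3:4]), d2 = best)
}

# dense vertical-scan oracle for the extents: sub-pixel sampling of
# in-polygon points along the column x = cx (pracma::inpolygon)
extentsOracle <- function(poly, cx, step = 0.125) {
  ys <- seq(min(poly[, 2]) - 1, max(poly[, 2]) + 1, by = step)
  inside <- pracma::inpolygon(rep(cx, length(ys)), ys, poly[, 1], poly[, 2])
  if (!any(inside)) return(NULL)
  list(top = min(ys[inside]), bottom = max(ys[inside]))
}

# exhaustive pair-counting AUC (ties count one half)
aucOracle <- function(truth, score) {
  pos <- score[truth]
  neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# polygon simplicity check: no two non-adjacent edges intersect
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

isSimplePolygon <- function(poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]   # skip adjacent (wrap) edges
    for (j in js)
      if (segmentsIntersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                            poly[idx[j, 1], ], poly[idx[j, 2], ]))
        return(FALSE)
  }
  TRUE
}

# hand-built LandmarkSeries around a resting ellipse geometry
makeSeries <- function(bottom_y, clip_id = "fix01", label = "NONE",
                       missing = rep(FALSE, length(bottom_y)),
                       left_x = 30, right_x = 70, top_y = 40,
                       rate = 2.4, participant = "p01",
                       recording = "rec01") {
  n <- length(bottom_y)
  coords <- cbind(
    Center_x = rep(50, n), Left_x = rep(left_x, n),
    Right_x = rep(right_x, n), Top_x = rep(50, n), Bottom_x = rep(50, n),
    Center_y = (top_y + bottom_y) / 2, Left_y = (top_y + bottom_y) / 2,
    Right_y = (top_y + bottom_y) / 2, Top_y = rep(top_y, n),
    Bottom_y = bottom_y)
  coords <- coords[, pfmus:::landmarkChannels(), drop = FALSE]
  coords[missing, ] <- NA_real_
  new("LandmarkSeries", clipId = clip_id, recordingId = recording,
      participantId = participant,
      label = factor(label, levels = pfmClasses()),
      sampleTimes = (seq_len(n) - 1L) / rate,
      frameIndex = as.integer((seq_len(n) - 1L) * 10L),
      coords = coords, missing = missing, sampleRateHz = rate)
}

# jittered but non-missing series pool for feature-table tests
makeCleanSeriesSet <- function(n_series = 10L, n_samples = 10L,
                               seed = 42L) {
  withr::with_seed(seed, lapply(seq_len(n_series), function(i)
    makeSeries(60 + rnorm(n_samples, 0, 0.5),
               clip_id = sprintf("fix%02d", i),
               label = pfmClasses()[(i %% 4L) + 1L],
               participant = sprintf("p%02d", (i %% 3L) + 1L))))
}

# small labelled feature table where base_elevation alone separates the
# four classes
separableTable <- function(n_per_class = 12L, seed = 7L, noise_cols = 4L) {
  withr::with_seed(seed, {
    lab <- rep(pfmClasses(), each = n_per_class)
    elev <- rep(c(0, 10, 20, 30), each = n_per_class) + rnorm(length(lab), 0, 0.5)
    noise <- matrix(rnorm(length(lab) * noise_cols), ncol = noise_cols,
                    dimnames = list(NULL, paste0("noise_", seq_len(noise_cols))))
    data.frame(clip_id = sprintf("c%03d", seq_along(lab)),
               recording_id = sprintf("r%03d", seq_along(lab)),
               participant_id = sprintf("p%02d", rep(1:8, length.out = length(lab))),
               base_elevation = elev, noise,
               label = factor(lab, levels = pfmClasses()))
  })
}

# one small simulated recording per label, defaults, cached
smallRecording <- function(label, seed = 11L, jitter = NULL,
                           speckle = NULL) {
  key <- paste("rec", label, seed, jitter, speckle, sep = "_")
  cached(key, {
    cfg <- simulationConfig(n_contractions = 1L, seed = seed)
    if (!is.null(jitter)) cfg@jitter_px <- jitter
    if (!is.null(speckle)) cfg@speckle_var <- speckle
    simulateRecording(cfg, label)
  })
}
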