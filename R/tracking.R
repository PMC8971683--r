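# Red-cell detection and tracking along vessel centerlines.
#
# The analysis is one-dimensional by design: each frame is reduced to an
# intensity profile over the arclength of a manually traced centerline, cells
# are detected as prominent profile peaks, nearby peaks are coalesced into
# one cell at their centroid, and velocities come from nearest-neighbour
# links between consecutive frames with a hard distance cutoff.

#' Vessel centerline trace
#'
#' @param vessel_id label.
#' @param x,y polyline vertex coordinates in micrometres.
#' @return object of class `vessel_trace`: vertices, cumulative arclength
#'   table, total length.
#' @export
vessel_trace <- function(vessel_id, x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("a trace needs at least two vertices", call. = FALSE)
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg <= 0)) {
    stop("degenerate trace: repeated vertices give zero-length segments",
         call. = FALSE)
  }
  cumlen <- c(0, cumsum(seg))
  structure(list(vessel_id = vessel_id, x = x, y = y, cumlen = cumlen,
                 length = cumlen[length(cumlen)]), class = "vessel_trace")
}

#' Tracking parameters
#'
#' Defaults follow the published procedure: peaks closer than the ~3 um cell
#' radius are coalesced, and links longer than 30 um are discarded.
#'
#' @param coalesce_radius peak coalescence radius, um. Default 3.
#' @param max_link_distance frame-to-frame link cutoff, um. Default 30.
#' @param tube_halfwidth halfwidth of the intensity sampling band normal to
#'   the centerline, um. Default 3.
#' @param peak_prominence minimum peak prominence as a fraction of the
#'   profile dynamic range. Default 0.2 (not stated in the source procedure;
#'   exposed as a knob).
#' @param profile_smooth_sigma matched-filter width, um: the profile is
#'   smoothed with a Gaussian of this sigma before peak finding (set to the
#'   point-spread width; 0 disables). Default 1.
#' @param mutual_nearest if `TRUE`, keep only mutual nearest-neighbour links;
#'   default `FALSE` (per-source nearest neighbour, many-to-one allowed).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(coalesce_radius = 3, max_link_distance = 30,
                            tube_halfwidth = 3, peak_prominence = 0.2,
                            profile_smooth_sigma = 1,
                            mutual_nearest = FALSE) {
  if (any(c(coalesce_radius, max_link_distance, tube_halfwidth,
            peak_prominence) <= 0) || profile_smooth_sigma < 0) {
    stop("tracking parameters must be positive", call. = FALSE)
  }
  if (max_link_distance <= coalesce_radius) {
    stop("`max_link_distance` must exceed `coalesce_radius`", call. = FALSE)
  }
  structure(list(coalesce_radius = coalesce_radius,
                 max_link_distance = max_link_distance,
                 tube_halfwidth = tube_halfwidth,
                 peak_prominence = peak_prominence,
                 profile_smooth_sigma = profile_smooth_sigma,
                 mutual_nearest = mutual_nearest), class = "tracking_params")
}

# Gaussian smoothing with replicate padding (sigma in samples)
gaussian_smooth <- function(y, sigma_samples) {
  if (sigma_samples <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(seq(-half, half), sd = sigma_samples)
  k <- k / sum(k)
  padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
  stats::filter(padded, k, sides = 2)[(half + 1):(half + length(y))]
}

#' Intensity profile along a centerline
#'
#' Samples the frame every `0.25 * pixel_size` along the trace; at each
#' arclength the intensity is the mean of bilinear samples taken across the
#' band normal to the centerline (halfwidth `tube_halfwidth`, spaced half a
#' pixel apart). Samples falling outside the frame are clamped to the border
#' with a warning.
#'
#' @param frame intensity matrix (rows = y, cols = x).
#' @param trace a [vessel_trace()].
#' @param params a [tracking_params()].
#' @param pixel_size pixel edge length, um.
#' @return list: `arclength` (um), `intensity`, `step` (um).
#' @export
sample_centerline_profile <- function(frame, trace, params = tracking_params(),
                                      pixel_size = 1.136) {
  stopifnot(inherits(trace, "vessel_trace"))
  if (trace$length <= 0) stop("invalid trace: zero length", call. = FALSE)
  step <- 0.25 * pixel_size
  s <- seq(0, trace$length, by = step)
  pts <- polyline_point(trace$x, trace$y, trace$cumlen, s)
  # unit tangents by central differences on the sampled path
  tx <- c(diff(pts[, 1])[1], diff(pts[, 1]))
  ty <- c(diff(pts[, 2])[1], diff(pts[, 2]))
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  nx <- -ty / nrm    # unit normal
  ny <- tx / nrm
  offsets <- seq(-params$tube_halfwidth, params$tube_halfwidth,
                 by = pixel_size / 2)
  xs <- outer(pts[, 1], rep(1, length(offsets))) + outer(nx, offsets)
  ys <- outer(pts[, 2], rep(1, length(offsets))) + outer(ny, offsets)
  w_um <- ncol(frame) * pixel_size
  h_um <- nrow(frame) * pixel_size
  if (any(xs < 0 | xs > w_um | ys < 0 | ys > h_um)) {
    warning("centerline band leaves the frame; samples clamped to the border",
            call. = FALSE)
  }
  vals <- bilinear_sample(frame, as.vector(xs), as.vector(ys), pixel_size)
  prof <- rowMeans(matrix(vals, nrow = length(s)))
  list(arclength = s, intensity = prof, step = step)
}

# prominence of each local maximum, scipy-style: walk out on both sides to
# the nearest higher sample (or the boundary); the base on each side is the
# minimum over that stretch and the prominence is height - max(bases)
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    i <- p
    left_min <- h
    while (i > 1L) {
      i <- i - 1L
      if (y[i] > h) break
      if (y[i] < left_min) left_min <- y[i]
    }
    i <- p
    right_min <- h
    n <- length(y)
    while (i < n) {
      i <- i + 1L
      if (y[i] > h) break
      if (y[i] < right_min) right_min <- y[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect cells as prominent profile peaks
#'
#' The profile is matched-filtered (Gaussian smoothing at the point-spread
#' width), local maxima whose prominence is at least
#' `peak_prominence * (max - min)` of the smoothed profile are kept, and
#' each surviving peak is refined to sub-pixel accuracy by a
#' baseline-subtracted intensity centroid over a local window. Plateau
#' maxima are reported at their centre.
#'
#' @param profile a [sample_centerline_profile()] result.
#' @param params a [tracking_params()].
#' @return numeric vector of peak arclengths (um), increasing.
#' @export
detect_cells <- function(profile, params = tracking_params()) {
  y <- profile$intensity
  n <- length(y)
  if (n == 0L) stop("empty profile", call. = FALSE)
  step <- profile$step %||% (if (n > 1) diff(profile$arclength[1:2]) else 1)
  y <- as.numeric(gaussian_smooth(y, params$profile_smooth_sigma / step))
  rng <- max(y) - min(y)
  if (rng == 0) return(numeric(0))
  # local maxima with plateau handling: run-length encode, a run is a peak
  # when both neighbouring runs are lower (boundary runs never qualify)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 2L) return(numeric(0))
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    lower_left <- i > 1L && r$values[i - 1L] < r$values[i]
    lower_right <- i < k && r$values[i + 1L] < r$values[i]
    is_peak[i] <- (i > 1L) && (i < k) && lower_left && lower_right
  }
  peak_idx <- as.integer(round((starts[is_peak] + ends[is_peak]) / 2))
  if (!length(peak_idx)) return(numeric(0))
  prom <- peak_prominences(y, peak_idx)
  keep <- peak_idx[prom >= params$peak_prominence * rng]
  if (!length(keep)) return(numeric(0))
  # sub-pixel refinement: baseline-subtracted centroid over a local window
  half <- max(2L, ceiling(2 * params$profile_smooth_sigma / step))
  refined <- vapply(keep, function(p) {
    w <- max(1L, p - half):min(n, p + half)
    wt <- y[w] - min(y[w])
    if (sum(wt) == 0) return(profile$arclength[p])
    sum(wt * profile$arclength[w]) / sum(wt)
  }, numeric(1))
  sort(refined)
}

#' Coalesce nearby peaks into cells
#'
#' Single-linkage clustering on the arclength axis: peaks closer than
#' `coalesce_radius` to any member of a cluster join it; each cluster becomes
#' one detection at the unweighted mean of its peaks.
#'
#' @param peaks sorted numeric vector of peak arclengths, um.
#' @param coalesce_radius merge radius, um. Default 3.
#' @return numeric vector of detection arclengths.
#' @export
coalesce_peaks <- function(peaks, coalesce_radius = 3) {
  if (length(peaks) <= 1L) return(as.numeric(peaks))
  p <- sort(peaks)
  grp <- cumsum(c(TRUE, diff(p) >= coalesce_radius))
  as.numeric(tapply(p, grp, mean))
}

#' Red-cell number density of one frame
#'
#' Count divided by vessel length, reported per centimetre.
#'
#' @param n number of detected cells in the frame.
#' @param vessel_length vessel length, um.
#' @return density in 1/cm.
#' @export
number_density <- function(n, vessel_length) {
  if (vessel_length <= 0) stop("`vessel_length` must be > 0", call. = FALSE)
  if (any(n < 0)) stop("`n` must be >= 0", call. = FALSE)
  n / (vessel_length * 1e-4)
}

#' Link detections across consecutive frames
#'
#' For each detection in frame t the nearest detection in frame t+1 (by
#' arclength distance) becomes its match; matches farther than
#' `max_link_distance` are dropped. Many-to-one links are allowed unless
#' `mutual_nearest` is set in the parameters. Speeds are signed (positive =
#' increasing arclength) and reported in cm/s.
#'
#' @param s_t,s_t1 detection arclengths (um) in frames t and t+1.
#' @param params a [tracking_params()].
#' @param frame_rate frames per second.
#' @return data frame: `from_um`, `to_um`, `displacement_um`, `speed_cms`.
#' @export
link_frames <- function(s_t, s_t1, params = tracking_params(),
                        frame_rate = 20) {
  empty <- data.frame(from_um = numeric(0), to_um = numeric(0),
                      displacement_um = numeric(0), speed_cms = numeric(0))
  if (!length(s_t) || !length(s_t1)) return(empty)
  nearest <- vapply(s_t, function(s) which.min(abs(s_t1 - s)), integer(1))
  disp <- s_t1[nearest] - s_t
  keep <- abs(disp) <= params$max_link_distance
  if (isTRUE(params$mutual_nearest)) {
    back <- vapply(s_t1, function(s) which.min(abs(s_t - s)), integer(1))
    keep <- keep & (back[nearest] == seq_along(s_t))
  }
  data.frame(
    from_um = s_t[keep],
    to_um = s_t1[nearest[keep]],
    displacement_um = disp[keep],
    speed_cms = disp[keep] * frame_rate * 1e-4
  )
}

#' Majority-rule flow direction and counter-flow filtering
#'
#' A segmental vessel carries flow in one direction, so the sign of the
#' majority of velocity samples defines the vessel direction and samples of
#' the opposite sign are discarded as artifacts. An exact tie leaves the
#' direction undetermined and keeps every sample, flagged.
#'
#' @param speeds signed speeds, cm/s.
#' @return list: `direction` (+1, -1 or 0 = undetermined), `speeds` (kept
#'   samples), `tie` (logical), `n_removed`.
#' @export
infer_direction_and_filter <- function(speeds) {
  if (!length(speeds)) stop("no velocity samples", call. = FALSE)
  n_pos <- sum(speeds > 0)
  n_neg <- sum(speeds < 0)
  if (n_pos == n_neg) {
    return(list(direction = 0L, speeds = speeds, tie = TRUE, n_removed = 0L))
  }
  dir <- if (n_pos > n_neg) 1L else -1L
  keep <- if (dir > 0) speeds >= 0 else speeds <= 0
  list(direction = dir, speeds = speeds[keep], tie = FALSE,
       n_removed = sum(!keep))
}

#' Per-vessel flow statistics
#'
#' Time-averaged number density, majority direction, and the median of the
#' direction-filtered absolute speeds.
#'
#' @param detections list of per-frame detection arclength vectors (um).
#' @param speeds signed velocity samples, cm/s (pooled over frame pairs).
#' @param trace a [vessel_trace()].
#' @return one-row data frame: `vessel_id`, `number_density_cm`,
#'   `median_speed_cms`, `direction`, `n_samples`, `tie`.
#' @export
summarize_vessel <- function(detections, speeds, trace) {
  stopifnot(inherits(trace, "vessel_trace"))
  if (!length(detections)) stop("need at least one frame", call. = FALSE)
  dens <- mean(vapply(detections, length, integer(1))) /
    (trace$length * 1e-4)
  if (length(speeds)) {
    flt <- infer_direction_and_filter(speeds)
    med <- stats::median(abs(flt$speeds))
    dir <- flt$direction
    tie <- flt$tie
    n <- length(flt$speeds)
  } else {
    med <- NA_real_
    dir <- 0L
    tie <- FALSE
    n <- 0L
  }
  data.frame(vessel_id = trace$vessel_id, number_density_cm = dens,
             median_speed_cms = med, direction = dir, n_samples = n,
             tie = tie)
}

#' Track one vessel through a movie
#'
#' Convenience pipeline: profile sampling, peak detection, coalescence and
#' consecutive-frame linking over a whole stack for one centerline.
#'
#' @param stack 3D array (rows x cols x frames).
#' @param trace a [vessel_trace()].
#' @param params a [tracking_params()].
#' @param pixel_size um per pixel.
#' @param frame_rate frames per second.
#' @return list: `detections` (per-frame arclength vectors), `links` (data
#'   frame with a `frame` column), `stats` ([summarize_vessel()] row).
#' @export
track_vessel <- function(stack, trace, params = tracking_params(),
                         pixel_size = 1.136, frame_rate = 20) {
  n_frames <- dim(stack)[3]
  detections <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    prof <- sample_centerline_profile(stack[, , f], trace, params, pixel_size)
    detections[[f]] <- coalesce_peaks(detect_cells(prof, params),
                                      params$coalesce_radius)
  }
  links <- NULL
  if (n_frames >= 2L) {
    pieces <- vector("list", n_frames - 1L)
    for (f in seq_len(n_frames - 1L)) {
      lk <- link_frames(detections[[f]], detections[[f + 1L]], params,
                        frame_rate)
      if (nrow(lk)) lk$frame <- f
      pieces[[f]] <- lk
    }
    pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0L]
    links <- if (length(pieces)) do.call(rbind, pieces) else NULL
  }
  speeds <- if (is.null(links)) numeric(0) else links$speed_cms
  list(detections = detections, links = links,
       stats = summarize_vessel(detections, speeds, trace))
}
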