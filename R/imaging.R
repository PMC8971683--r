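# Ground-truthed synthetic fluorescence imaging.
#
# Movies emulate single-plane time-lapse imaging of fluorescent blood cells:
# each cell is rendered as an isotropic Gaussian blob (a point-spread-function
# surrogate) at its projected 2D position, on a constant background, with
# optional Gaussian or Poisson noise and bit-depth clipping. The generator
# returns exact per-frame truth so every downstream stage can be tested
# without real data. Deliberately not modelled: depth attenuation,
# photobleaching, motion blur within a frame, and z-structure.

#' Imaging configuration
#'
#' @param pixel_size um per pixel. Default 1.136 (a 1.29 um^2 pixel).
#' @param frame_rate frames per second, typically 20-40. Default 20.
#' @param psf_sigma Gaussian blob sigma in um. Default 1.0, so a ~3 um cell
#'   spans about 3 pixels.
#' @param cell_peak_intensity blob peak amplitude, arbitrary units.
#' @param background_level constant background, arbitrary units.
#' @param noise a [noise_model()]. Default none.
#' @param bit_depth 8 or 16; intensities are clipped to the representable
#'   range after noise.
#' @param field_size c(rows, cols) of the rendered frames, pixels.
#' @return object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 1.136, frame_rate = 20,
                           psf_sigma = 1.0, cell_peak_intensity = 150,
                           background_level = 10,
                           noise = noise_model("none"),
                           bit_depth = 16, field_size = c(128L, 128L)) {
  if (pixel_size <= 0 || frame_rate <= 0 || psf_sigma <= 0) {
    stop("pixel_size, frame_rate and psf_sigma must be positive",
         call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16",
                                     call. = FALSE)
  structure(list(pixel_size = pixel_size, frame_rate = frame_rate,
                 psf_sigma = psf_sigma,
                 cell_peak_intensity = cell_peak_intensity,
                 background_level = background_level, noise = noise,
                 bit_depth = bit_depth,
                 field_size = as.integer(field_size)),
            class = "imaging_config")
}

#' Noise model
#'
#' @param type one of `"none"`, `"gaussian"` (additive, standard deviation
#'   `sd`) or `"poisson"` (photon shot noise: intensities are scaled by
#'   `scale`, Poisson-sampled, and scaled back).
#' @param sd,scale model parameters.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(type = c("none", "gaussian", "poisson"), sd = 10,
                        scale = 1) {
  type <- match.arg(type)
  structure(list(type = type, sd = sd, scale = scale), class = "noise_model")
}

apply_noise <- function(img, noise) {
  switch(noise$type,
         none = img,
         gaussian = img + stats::rnorm(length(img), 0, noise$sd),
         poisson = stats::rpois(length(img), pmax(img, 0) * noise$scale) /
           noise$scale)
}

# add one Gaussian blob (peak amplitude `amp`, sigma um) at (x, y) um into a
# frame, only touching the +-4 sigma window for speed
add_blob <- function(frame, x, y, amp, sigma, pixel_size) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  half <- ceiling(4 * sigma / pixel_size)
  c_ctr <- x / pixel_size + 0.5
  r_ctr <- y / pixel_size + 0.5
  c_lo <- max(1L, floor(c_ctr - half))
  c_hi <- min(nc, ceiling(c_ctr + half))
  r_lo <- max(1L, floor(r_ctr - half))
  r_hi <- min(nr, ceiling(r_ctr + half))
  if (c_lo > c_hi || r_lo > r_hi) return(frame)  # blob entirely off-field
  cs <- c_lo:c_hi
  rs <- r_lo:r_hi
  px <- (cs - 0.5) * pixel_size
  py <- (rs - 0.5) * pixel_size
  gx <- exp(-(px - x)^2 / (2 * sigma^2))
  gy <- exp(-(py - y)^2 / (2 * sigma^2))
  frame[rs, cs] <- frame[rs, cs] + amp * outer(gy, gx)
  frame
}

#' Render a synthetic time-lapse movie
#'
#' Projects cell trajectories (per-edge arclengths) onto 2D image positions
#' via the vessel centerlines and renders each frame. Frames are taken at
#' `config$frame_rate`; for each frame and cell, the trajectory sample whose
#' time is closest to the frame time (within half a frame interval) supplies
#' the position. Cells outside the field of view are clipped in the rendering
#' but retained in the truth table with `in_field = FALSE`.
#'
#' @param trajectories data frame with `time_s`, `cell_id`, `edge_id`,
#'   `arclength_um` (e.g. from [simulate_rbc_transport()]).
#' @param centerlines named list of [vessel_trace()] objects; names must
#'   cover every `edge_id` present.
#' @param config an [imaging_config()].
#' @param seed integer seed for the noise draws.
#' @return object of class `movie_stack`: `stack` (rows x cols x frames
#'   array), `truth` (data frame: frame, cell_id, edge_id, arclength_um,
#'   x_um, y_um, in_field), `config`, `seed`.
#' @export
render_movie <- function(trajectories, centerlines, config = imaging_config(),
                         seed = 1L) {
  set.seed(seed)
  missing_ids <- setdiff(unique(trajectories$edge_id), names(centerlines))
  if (length(missing_ids)) {
    stop("no centerline for edge(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  nr <- config$field_size[1]
  nc <- config$field_size[2]
  t_max <- if (nrow(trajectories)) max(trajectories$time_s) else 0
  n_frames <- max(1L, floor(t_max * config$frame_rate) + 1L)
  half_frame <- 0.5 / config$frame_rate
  maxval <- 2^config$bit_depth - 1

  stack <- array(0, dim = c(nr, nc, n_frames))
  truth <- vector("list", n_frames)
  w_um <- nc * config$pixel_size
  h_um <- nr * config$pixel_size

  for (f in seq_len(n_frames)) {
    t_f <- (f - 1L) / config$frame_rate
    frame <- matrix(config$background_level, nr, nc)
    rows <- NULL
    if (nrow(trajectories)) {
      dtime <- abs(trajectories$time_s - t_f)
      cand <- trajectories[dtime <= half_frame + 1e-12, , drop = FALSE]
      if (nrow(cand)) {
        # nearest sample per cell
        cand <- cand[order(abs(cand$time_s - t_f)), , drop = FALSE]
        cand <- cand[!duplicated(cand$cell_id), , drop = FALSE]
        tr_list <- centerlines[cand$edge_id]
        xy <- t(mapply(function(tr, s) {
          polyline_point(tr$x, tr$y, tr$cumlen, s)[1, ]
        }, tr_list, cand$arclength_um))
        in_field <- xy[, 1] >= 0 & xy[, 1] <= w_um &
          xy[, 2] >= 0 & xy[, 2] <= h_um
        for (i in seq_len(nrow(cand))) {
          frame <- add_blob(frame, xy[i, 1], xy[i, 2],
                            config$cell_peak_intensity, config$psf_sigma,
                            config$pixel_size)
        }
        rows <- data.frame(frame = f, cell_id = cand$cell_id,
                           edge_id = cand$edge_id,
                           arclength_um = cand$arclength_um,
                           x_um = xy[, 1], y_um = xy[, 2],
                           in_field = in_field)
      }
    }
    frame <- apply_noise(frame, config$noise)
    frame <- pmin(pmax(round(frame), 0), maxval)
    stack[, , f] <- frame
    truth[[f]] <- rows
  }
  truth <- truth[!vapply(truth, is.null, logical(1))]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(0), cell_id = integer(0),
               edge_id = character(0), arclength_um = numeric(0),
               x_um = numeric(0), y_um = numeric(0), in_field = logical(0))
  structure(list(stack = stack, truth = truth, config = config, seed = seed),
            class = "movie_stack")
}

#' Render a two-channel colocalization fixture with known truth
#'
#' Places `n_components` rectangular foreground components per channel on a
#' regular grid (guaranteeing separation), with channel B's component shifted
#' vertically against channel A's so that a known number of pixels overlap:
#' `round(overlap_fraction * height)` rows of the rectangle. Exact truth
#' masks and per-component areas are returned.
#'
#' @param n_components number of component pairs.
#' @param overlap_fraction requested pairwise overlap in \\[0, 1\\].
#' @param component_px_range c(min, max) component area in pixels.
#' @param field c(rows, cols) image size in pixels.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param intensities named list: `background`, `a`, `b` foreground levels.
#' @return object of class `coloc_pair`: `channel_a`, `channel_b` (intensity
#'   matrices), `mask_a`, `mask_b`, `overlap_mask` (logical truth),
#'   `components` (data frame: id, area_px, overlap_px), `overlap_px_total`.
#' @export
render_coloc_pair <- function(n_components = 5, overlap_fraction = 0.5,
                              component_px_range = c(60, 120),
                              field = c(128L, 128L),
                              noise = noise_model("none"), seed = 1L,
                              intensities = list(background = 8, a = 160,
                                                 b = 220)) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  nr <- field[1]
  nc <- field[2]
  areas <- round(stats::runif(n_components, component_px_range[1],
                              component_px_range[2]))
  hs <- pmax(2L, round(sqrt(areas)))
  ws <- pmax(2L, round(areas / hs))
  dys <- hs - round(overlap_fraction * hs)   # B shifted down by dy rows

  # grid placement: cell big enough for the A rect plus B's shift plus a gap
  cell_h <- max(hs + dys) + 4L
  cell_w <- max(ws) + 4L
  per_row <- max(1L, nc %/% cell_w)
  n_rows_grid <- ceiling(n_components / per_row)
  if (n_rows_grid * cell_h > nr) {
    stop("packing error: field too small for the requested components",
         call. = FALSE)
  }
  a_mask <- matrix(FALSE, nr, nc)
  b_mask <- matrix(FALSE, nr, nc)
  comp <- vector("list", n_components)
  for (i in seq_len(n_components)) {
    gr <- (i - 1L) %/% per_row
    gc <- (i - 1L) %% per_row
    r0 <- gr * cell_h + 2L
    c0 <- gc * cell_w + 2L
    ra <- r0:(r0 + hs[i] - 1L)
    ca <- c0:(c0 + ws[i] - 1L)
    rb <- ra + dys[i]
    a_mask[ra, ca] <- TRUE
    b_mask[rb, ca] <- TRUE
    ov <- max(0L, hs[i] - dys[i]) * ws[i]
    comp[[i]] <- data.frame(id = i, area_px = hs[i] * ws[i],
                            overlap_px = ov)
  }
  comp <- do.call(rbind, comp)
  overlap <- a_mask & b_mask
  mk_channel <- function(mask, fg) {
    img <- matrix(intensities$background, nr, nc)
    img[mask] <- fg
    apply_noise(img, noise)
  }
  structure(list(
    channel_a = mk_channel(a_mask, intensities$a),
    channel_b = mk_channel(b_mask, intensities$b),
    mask_a = a_mask, mask_b = b_mask, overlap_mask = overlap,
    components = comp, overlap_px_total = sum(overlap),
    seed = seed
  ), class = "coloc_pair")
}
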