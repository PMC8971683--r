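# Two-regime wall shear stress model.
#
# The endothelium of a segmental vessel is split into the part adjacent to a
# red cell and the plasma-only remainder. Plasma WSS follows Poiseuille flow,
# sigma_p = 4 mu v / r. Next to a red cell, the force balance between the
# pressure drop and wall shear adds the cell's occlusive resistance
# contribution, sigma_cell = 4 mu v / r + pi r^3 v alpha_c / (2 l_cell).
# Stresses are computed in SI and reported in dyne/cm^2 (1 Pa = 10 dyne/cm^2).

#' Wall-shear-stress parameters
#'
#' @param mu plasma viscosity, Pa·s. Default 1e-3.
#' @param radius vessel radius in micrometres; default 3 (uniform across
#'   segmental vessels).
#' @param cell_length red-cell length in micrometres; default 6.
#' @param alpha_c occlusive strength, Pa·s·m^-3 per cell. Default 1e15
#'   (mid-trunk order of magnitude; see the trunk builder's gradient).
#' @return object of class `wss_params`.
#' @export
wss_params <- function(mu = 1e-3, radius = 3, cell_length = 6,
                       alpha_c = 1e15) {
  vals <- c(mu = mu, radius = radius, cell_length = cell_length)
  if (any(vals <= 0) || alpha_c < 0) {
    stop("wss parameters must be positive (alpha_c >= 0)", call. = FALSE)
  }
  structure(list(mu = mu, radius = radius, cell_length = cell_length,
                 alpha_c = alpha_c), class = "wss_params")
}

#' Plasma wall shear stress
#'
#' `sigma_p = 4 mu v / r` for Poiseuille flow at median cell speed `v`.
#'
#' @param params a [wss_params()] object.
#' @param v speed in cm/s (non-negative).
#' @return stress in dyne/cm^2.
#' @export
plasma_wss <- function(params, v) {
  if (any(v < 0)) stop("`v` must be >= 0", call. = FALSE)
  v_si <- v * 1e-2
  r_si <- params$radius * 1e-6
  sigma_pa <- 4 * params$mu * v_si / r_si
  10 * sigma_pa
}

#' Cell-adjacent wall shear stress
#'
#' Adds the occlusive contribution of a red cell to the plasma stress:
#' `sigma_cell = 4 mu v / r + pi r^3 v alpha_c / (2 l_cell)` (SI), reported
#' in dyne/cm^2. With `alpha_c = 0` this reduces to [plasma_wss()].
#'
#' @inheritParams plasma_wss
#' @return stress in dyne/cm^2.
#' @export
cell_wss <- function(params, v) {
  if (any(v < 0)) stop("`v` must be >= 0", call. = FALSE)
  v_si <- v * 1e-2
  r_si <- params$radius * 1e-6
  l_si <- params$cell_length * 1e-6
  sigma_pa <- 4 * params$mu * v_si / r_si +
    pi * r_si^3 * v_si * params$alpha_c / (2 * l_si)
  10 * sigma_pa
}

#' Per-frame WSS decomposition of one vessel
#'
#' Splits the endothelium of each frame into the fraction adjacent to red
#' cells and the plasma-only remainder. When per-cell arclengths are given,
#' each cell occupies a window of `cell_length` centred on it and overlapping
#' windows are merged (interval union); when only counts are given, the
#' occupied fraction is `min(1, n * cell_length / L)`.
#'
#' @param cells either an integer vector (cells per frame) or a list of
#'   numeric vectors of per-frame cell arclengths in micrometres.
#' @param v median cell speed of the vessel, cm/s.
#' @param vessel_length vessel length in micrometres.
#' @param params a [wss_params()] object.
#' @param vessel_id optional label carried into the output.
#' @return data frame of class `wss_decomposition`: `vessel_id`, `frame`,
#'   `sigma_p_dyncm2`, `sigma_cell_dyncm2`, `occupied_fraction`.
#' @export
build_wss_decomposition <- function(cells, v, vessel_length,
                                    params = wss_params(),
                                    vessel_id = "vessel") {
  if (vessel_length <= 0) stop("`vessel_length` must be > 0", call. = FALSE)
  if (is.list(cells)) {
    occ <- vapply(cells, function(s) {
      if (!length(s)) return(0)
      half <- params$cell_length / 2
      covered <- interval_union_length(pmax(s - half, 0),
                                       pmin(s + half, vessel_length))
      covered / vessel_length
    }, numeric(1))
  } else {
    occ <- pmin(1, as.numeric(cells) * params$cell_length / vessel_length)
  }
  n_frames <- length(occ)
  structure(data.frame(
    vessel_id = rep(vessel_id, n_frames),
    frame = seq_len(n_frames),
    sigma_p_dyncm2 = rep(plasma_wss(params, v), n_frames),
    sigma_cell_dyncm2 = rep(cell_wss(params, v), n_frames),
    occupied_fraction = occ
  ), class = c("wss_decomposition", "data.frame"))
}

#' Activation threshold from pooled plasma stresses
#'
#' The 0.975 quantile (linear-interpolation convention, R type 7) of plasma
#' wall shear stress samples pooled across all intersegmental vessels and
#' frames.
#'
#' @param sigma_p numeric vector of plasma stresses, dyne/cm^2.
#' @return the threshold, dyne/cm^2.
#' @export
plasma_threshold <- function(sigma_p) {
  sigma_p <- sigma_p[!is.na(sigma_p)]
  if (!length(sigma_p)) stop("no plasma stress samples", call. = FALSE)
  unname(stats::quantile(sigma_p, 0.975, type = 7))
}

#' Peak shear stress portion
#'
#' Fraction of endothelium-time during which the local WSS exceeds the
#' activation threshold: the mean over frames of
#' `occupied * 1(sigma_cell > thr) + (1 - occupied) * 1(sigma_p > thr)`.
#'
#' @param decomp a [build_wss_decomposition()] result.
#' @param threshold activation threshold, dyne/cm^2 (>= 0).
#' @return a fraction in \\[0, 1\\].
#' @export
peak_stress_portion <- function(decomp, threshold) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  occ <- decomp$occupied_fraction
  mean(occ * (decomp$sigma_cell_dyncm2 > threshold) +
         (1 - occ) * (decomp$sigma_p_dyncm2 > threshold))
}
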