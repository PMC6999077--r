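#' Compute the phase retardation volume
#'
#' Per voxel, `delta = arctan(A_cross / A_co)` in degrees on the
#' repeat-averaged channel amplitudes. Polarization-preserving tissue
#' keeps the signal in the co-polarized channel and yields low values;
#' melanin scrambles the polarization state and yields values spread over
#' the full `[0, 90]` degree range. Voxels whose combined amplitude does
#' not exceed `snr_factor` times the noise floor are masked.
#'
#' The ratio convention is configurable (`swap_channels = TRUE` computes
#' `arctan(A_co / A_cross)`); the default assigns low retardation to
#' polarization-preserving tissue.
#'
#' @param volume an [oct_volume()].
#' @param config a [pipeline_config()] (section `polarization`).
#' @param noise_floor amplitude of the noise floor; estimated from the
#'   anterior (vitreous) depths when `NULL`.
#' @param swap_channels use the inverted amplitude ratio.
#' @return an object of class `retardation_volume`: `delta_deg`
#'   (`[y, x, z]`, `NA` where masked), `snr_mask`, `noise_floor`.
#' @export
compute_retardation <- function(volume, config = pipeline_config(),
                                noise_floor = NULL, swap_channels = FALSE) {
  pcfg <- config$polarization
  if (isTRUE(pcfg$per_repeat)) {
    a_co <- abs(volume$co[1L, , , , drop = TRUE])
    a_cr <- abs(volume$cross[1L, , , , drop = TRUE])
  } else {
    a_co <- channel_amplitude(volume, "co")
    a_cr <- channel_amplitude(volume, "cross")
  }
  if (swap_channels) { tmp <- a_co; a_co <- a_cr; a_cr <- tmp }
  comb <- sqrt(a_co^2 + a_cr^2)
  if (is.null(noise_floor)) {
    # anterior (vitreous) planes, ignoring zero padding from flattening
    nz <- dim(comb)[3L]
    n_noise <- max(4L, nz %/% 4L)
    nv <- comb[, , seq_len(n_noise)]
    nv <- nv[nv > 0]
    noise_floor <- if (length(nv)) stats::median(nv) else 0
  }
  snr <- comb > pcfg$snr_factor * max(noise_floor, .Machine$double.eps)
  delta <- atan2(a_cr, a_co) * 180 / pi
  delta[comb == 0] <- NA_real_
  delta[!snr] <- NA_real_
  structure(list(delta_deg = delta, snr_mask = snr,
                 noise_floor = noise_floor),
            class = "retardation_volume")
}

#' Build the expected-depolarization voxel mask
#'
#' High retardation is anatomically expected only in the melanin-bearing
#' RPE/choroid complex and around the ONH (hyaloid-artery remnant). The
#' mask is the union of the slab from `rpe_band_um + rpe_margin_um` above
#' the detected posterior RPE edge downwards (the complex plus a safety
#' margin) and a cylinder around the ONH centre.
#'
#' @param layer_map a [segment_layers()] result.
#' @param nz axial extent of the volume, pixels.
#' @param pitch_um named `c(x = , y = )` en-face pitches.
#' @param onh_center_um ONH centre `c(x, y)` in um.
#' @param onh_radius_um ONH radius in um.
#' @param config a [pipeline_config()] (`polarization$rpe_margin_um`,
#'   `polarization$onh_margin_um`).
#' @return logical array `[y, x, z]`.
#' @export
build_expected_mask <- function(layer_map, nz, pitch_um,
                                onh_center_um = NULL, onh_radius_um = 0,
                                config = pipeline_config()) {
  pcfg <- config$polarization
  p <- layer_map$axial_pitch_um
  d <- dim(layer_map$rpe_px)
  ny <- d[1L]; nx <- d[2L]
  # the melanin-bearing complex extends rpe_band_um anterior of the detected
  # posterior RPE edge; rpe_margin_um adds slack above it
  zlo <- layer_map$rpe_px - (pcfg$rpe_band_um + pcfg$rpe_margin_um) / p
  zidx <- array(rep(seq_len(nz), each = ny * nx), c(ny, nx, nz))
  mask <- zidx >= array(rep(zlo, nz), c(ny, nx, nz))
  if (!is.null(onh_center_um) && onh_radius_um + pcfg$onh_margin_um > 0) {
    cc <- pixel_centers_um(ny, nx, pitch_um[["y"]], pitch_um[["x"]])
    X <- matrix(cc$x, ny, nx, byrow = TRUE)
    Y <- matrix(cc$y, ny, nx)
    r <- sqrt((X - onh_center_um[["x"]])^2 + (Y - onh_center_um[["y"]])^2)
    cyl <- r < onh_radius_um + pcfg$onh_margin_um
    mask <- mask | array(rep(cyl, nz), c(ny, nx, nz))
  }
  mask
}

#' Screen for ectopic depolarizing deposits
#'
#' Candidate voxels are SNR-valid, exceed the retardation threshold, and
#' lie outside the expected-depolarization mask. 26-connected components
#' of at least the minimum voxel count are reported with centroid, size,
#' mean retardation and the retinal compartment of the centroid.
#'
#' @param retardation a [compute_retardation()] result.
#' @param expected_mask logical `[y, x, z]` from [build_expected_mask()].
#' @param layer_map a [segment_layers()] result (for compartment labels).
#' @param pitch_um named `c(x = , y = )` en-face pitches, um.
#' @param config a [pipeline_config()].
#' @return data.frame with one row per deposit: centroid (um and px),
#'   `n_voxels`, `mean_delta_deg`, `layer`; zero rows when nothing is
#'   found.
#' @export
screen_deposits <- function(retardation, expected_mask, layer_map, pitch_um,
                            config = pipeline_config()) {
  pcfg <- config$polarization
  delta <- retardation$delta_deg
  cand <- !is.na(delta) & delta > pcfg$retardation_threshold_deg &
    !expected_mask
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0), z_px = numeric(0),
                      n_voxels = integer(0), mean_delta_deg = numeric(0),
                      layer = character(0), stringsAsFactors = FALSE)
  if (!any(cand)) return(empty)
  comps <- label_components_26(cand)
  comps <- comps[vapply(comps, nrow, integer(1L)) >= pcfg$min_deposit_voxels]
  if (!length(comps)) return(empty)
  p <- layer_map$axial_pitch_um
  rows <- lapply(comps, function(mb) {
    cy <- mean(mb[, "y"]); cx <- mean(mb[, "x"]); cz <- mean(mb[, "z"])
    iy <- round(cy); ix <- round(cx)
    layer <- if (cz < layer_map$ilm_px[iy, ix]) "vitreous"
    else if (cz < layer_map$opl_px[iy, ix]) "inner retina"
    else if (cz < layer_map$rpe_px[iy, ix]) "outer retina"
    else "RPE/choroid"
    data.frame(x_um = (cx - 0.5) * pitch_um[["x"]],
               y_um = (cy - 0.5) * pitch_um[["y"]],
               z_um = (cz - 0.5) * p,
               x_px = cx, y_px = cy, z_px = cz,
               n_voxels = nrow(mb),
               mean_delta_deg = mean(delta[mb]),
               layer = layer, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
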