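#' Estimate per-B-scan axial motion offsets
#'
#' Axial bulk motion between B-scan locations is estimated by maximising
#' the 1-D cross-correlation of the depth-wise mean intensity profiles of
#' adjacent B-scans and accumulating the pairwise lags, yielding the
#' integer-pixel offset of every B-scan relative to the first.
#'
#' @param volume an [oct_volume()] with at least 2 B-scan locations.
#' @param max_lag largest pairwise lag searched, pixels.
#' @return integer vector of per-B-scan offsets (pixels, relative to the
#'   first B-scan; positive = shifted posteriorly).
#' @export
estimate_axial_offsets <- function(volume, max_lag = dim(volume$co)[4L] %/% 4L) {
  d <- dim(volume$co)
  ny <- d[2L]; nz <- d[4L]
  if (ny < 2L)
    stop_retoct("at least 2 B-scans are required", "retoct_validation_error")
  prof <- matrix(0, ny, nz)
  for (y in seq_len(ny)) {
    a <- abs(volume$co[, y, , , drop = FALSE]) +
      abs(volume$cross[, y, , , drop = FALSE])
    prof[y, ] <- apply(a, 4L, mean)
    if (all(prof[y, ] == 0))
      stop_retoct(sprintf("no signal in B-scan %d", y),
                  "retoct_no_signal_error")
  }
  lags <- integer(ny)
  for (y in 2:ny) {
    best <- -Inf; bl <- 0L
    for (l in -max_lag:max_lag) {
      s <- sum(shift_fill(prof[y, ], -l) * prof[y - 1L, ])
      if (s > best) { best <- s; bl <- l }
    }
    lags[y] <- bl
  }
  as.integer(cumsum(lags))
}

#' Detect the RPE/choroid surface from the cross-polarized channel
#'
#' The melanin-rich RPE/choroidal complex depolarizes and so dominates the
#' cross-polarized channel. Per A-scan, the depth of the maximum of the
#' axially boxcar-smoothed, repeat-averaged cross-channel amplitude is
#' taken; A-scans whose peak does not exceed the noise floor are marked
#' invalid and filled by lateral interpolation; the map is then
#' median-filtered laterally.
#'
#' @param volume an [oct_volume()].
#' @param config a [pipeline_config()] (section `preprocess`).
#' @return integer matrix `[y, x]` of RPE peak depths (pixels), with
#'   attributes `valid` (logical matrix) and `noise_floor` (estimated
#'   amplitude).
#' @export
detect_rpe_crosspol <- function(volume, config = pipeline_config()) {
  detect_rpe_from_amp(channel_amplitude(volume, "cross"), config)
}

# Core of the RPE detection, operating on a repeat-averaged cross-channel
# amplitude array [y, x, z] (lets callers motion-correct amplitudes
# without materialising a corrected complex volume).
detect_rpe_from_amp <- function(amp, config = pipeline_config()) {
  pc <- config$preprocess
  d <- dim(amp)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  # lateral box smoothing (the focal spot spans neighbouring A-scans);
  # stabilises the peak of the broad melanin band against speckle
  amp <- lateral_box_smooth(amp, pc$rpe_lateral_px)
  m <- matrix(amp, ny * nx, nz)
  ms <- smooth_rows_boxcar(m, pc$rpe_boxcar_px)
  # the RPE/choroid complex is the deepest depolarizing structure; exclude
  # anterior depths (e.g. the hyaloid remnant at the ONH) from the search
  z_from <- max(1L, floor(pc$rpe_search_fraction * nz))
  zwin <- z_from:nz
  peak_z <- zwin[max.col(ms[, zwin, drop = FALSE], ties.method = "first")]
  peak_v <- ms[cbind(seq_len(ny * nx), peak_z)]
  # sub-pixel refinement: intensity-weighted centroid of the band above
  # half maximum, within a window around the peak
  hw <- pc$rpe_centroid_halfwidth_px %||% 10L
  npx <- ny * nx
  num <- numeric(npx); den <- numeric(npx)
  for (k in -hw:hw) {
    zk <- peak_z + k
    ok <- zk >= 1L & zk <= nz
    w <- pmax(ms[cbind(which(ok), zk[ok])] - 0.5 * peak_v[ok], 0)
    num[ok] <- num[ok] + w * zk[ok]
    den[ok] <- den[ok] + w
  }
  peak_c <- ifelse(den > 0, num / den, peak_z)
  noise <- stats::median(m)
  valid <- peak_v > pc$rpe_snr_factor * max(noise, .Machine$double.eps)
  if (!any(valid))
    stop_retoct("no depolarizing RPE signal found in the cross channel",
                "retoct_no_signal_error")
  frac_invalid <- mean(!valid)
  if (frac_invalid > pc$max_invalid_fraction)
    stop_retoct(sprintf("RPE detection failed for %.0f%% of A-scans",
                        100 * frac_invalid), "retoct_exclusion_error")
  zmap <- matrix(peak_c, ny, nx)
  vmat <- matrix(valid, ny, nx)
  zmap <- fill_invalid_lateral(zmap, !vmat)
  zmap <- median_filter2(zmap, pc$rpe_median_px)
  structure(zmap, valid = vmat, noise_floor = noise)
}

#' Flatten a volume to the detected RPE surface
#'
#' Every A-scan is rolled axially (integer pixels, zero fill) so that the
#' detected RPE depth sits at a common target depth. Complex values are
#' moved, never modified, so repeat-to-repeat complex differences are
#' unaffected outside the padded margins. When `rpe_map`/`offsets` are not
#' supplied they are computed from the volume ([estimate_axial_offsets()]
#' is applied first, and the RPE is detected on the motion-corrected
#' volume).
#'
#' @param volume an [oct_volume()].
#' @param rpe_map optional RPE depth map from [detect_rpe_crosspol()]
#'   (in the motion-corrected frame).
#' @param offsets optional per-B-scan offsets from
#'   [estimate_axial_offsets()].
#' @param config a [pipeline_config()].
#' @return an object of class `flatten_result`: `volume` (flattened),
#'   `shift_px` (`[y, x]` flattening shift in the motion-corrected frame;
#'   the total roll applied to the raw input is `shift_px - offsets`),
#'   `rpe_map` (detected, motion-corrected frame), `offsets` (per B-scan),
#'   `target_z` and `quality` (per-B-scan fraction of valid RPE pixels).
#' @export
flatten_volume <- function(volume, rpe_map = NULL, offsets = NULL,
                           config = pipeline_config()) {
  d <- dim(volume$co)
  nr <- d[1L]; ny <- d[2L]; nx <- d[3L]; nz <- d[4L]
  if (is.null(offsets)) offsets <- estimate_axial_offsets(volume)
  if (length(offsets) != ny)
    stop_retoct("offsets length must equal the number of B-scan locations",
                "retoct_validation_error")
  offsets <- as.integer(offsets)
  if (is.null(rpe_map)) {
    # detect on motion-corrected amplitudes; rolling commutes with the
    # modulus, so no corrected complex volume needs to be materialised
    amp <- channel_amplitude(volume, "cross")
    for (y in seq_len(ny)) {
      s <- -offsets[y]
      if (s == 0L) next
      plane <- amp[y, , ]
      rolled <- matrix(0, nx, nz)
      if (s > 0 && s < nz) rolled[, (s + 1L):nz] <- plane[, 1L:(nz - s)]
      else if (s < 0 && -s < nz) rolled[, 1L:(nz + s)] <- plane[, (1L - s):nz]
      amp[y, , ] <- rolled
    }
    rpe_map <- detect_rpe_from_amp(amp, config)
    rm(amp)
  }
  target_z <- round(config$preprocess$flatten_target_fraction * nz)
  shift <- round(target_z - unclass(rpe_map))   # motion-corrected frame
  attributes(shift) <- list(dim = dim(rpe_map))
  total <- sweep(shift, 1L, offsets, "-")       # applied to the raw input
  if (any(abs(total) >= nz))
    stop_retoct("required flattening shift exceeds the axial extent",
                "retoct_exclusion_error")
  out <- volume
  zs <- seq_len(nz)
  for (y in seq_len(ny)) {
    srow <- total[y, ]
    if (all(srow == 0L)) next
    zsrc <- outer(-srow, zs, "+")          # [x, z] source depth
    ok <- zsrc >= 1L & zsrc <= nz
    xi <- row(zsrc)[ok]; zi <- col(zsrc)[ok]; zf <- zsrc[ok]
    for (r in seq_len(nr)) {
      mco <- out$co[r, y, , ]; mcr <- out$cross[r, y, , ]
      nco <- matrix(complex(real = 0), nx, nz)
      ncr <- nco
      nco[cbind(xi, zi)] <- mco[cbind(xi, zf)]
      ncr[cbind(xi, zi)] <- mcr[cbind(xi, zf)]
      out$co[r, y, , ] <- nco
      out$cross[r, y, , ] <- ncr
    }
  }
  valid <- attr(rpe_map, "valid") %||% matrix(TRUE, ny, nx)
  structure(list(volume = out,
                 shift_px = shift,
                 rpe_map = rpe_map,
                 offsets = offsets,
                 target_z = target_z,
                 quality = rowMeans(valid)),
            class = "flatten_result")
}
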