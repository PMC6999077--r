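#' Segment the ILM, posterior OPL and posterior RPE boundaries
#'
#' Operates on the repeat-averaged co-channel amplitude of a flattened
#' volume. Each boundary is returned as the 1-based depth index of the
#' first voxel of the posterior side, so that boundary differences count
#' voxels exactly and inner + outer thickness equals total thickness by
#' construction:
#' \itemize{
#'   \item ILM: first depth whose repeat-averaged amplitude exceeds a
#'     noise-adaptive threshold (noise mean + k x noise sd, estimated from
#'     the anterior noise-floor region);
#'   \item posterior RPE: last depth, at or after the reflectivity peak of
#'     the RPE band, whose amplitude stays above a configured fraction of
#'     the peak, plus one (the falling edge of the band);
#'   \item posterior OPL: the strongest, most posterior falling edge of the
#'     hyper-reflective OPL band inside the inner-retina search window.
#' }
#' Boundary maps are median-filtered laterally; pixels violating the
#' monotonicity ILM < posterior OPL < posterior RPE (e.g. inside the ONH)
#' are flagged invalid and filled by lateral interpolation.
#'
#' @param volume a flattened [oct_volume()] (see [flatten_volume()]).
#' @param config a [pipeline_config()] (section `layers`).
#' @param rpe_map optional RPE peak depth map ([detect_rpe_crosspol()]);
#'   detected from the cross channel when `NULL`. The posterior RPE edge
#'   is searched posterior to this peak on the combined
#'   (polarization-independent) intensity, because inside the
#'   depolarizing melanin band the co-channel amplitude alone is
#'   randomized by the polarization scrambling.
#' @return an object of class `layer_map`: matrices `ilm_px`, `opl_px`,
#'   `rpe_px` (`[y, x]`, pixels), `valid` mask, and the axial pitch.
#' @export
segment_layers <- function(volume, config = pipeline_config(),
                           rpe_map = NULL) {
  lc <- config$layers
  amp <- channel_amplitude(volume, "co")
  d <- dim(amp)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  m <- matrix(amp, ny * nx, nz)
  amp_cr <- channel_amplitude(volume, "cross")
  mc <- matrix(sqrt(amp^2 + amp_cr^2), ny * nx, nz)
  rm(amp_cr)
  if (is.null(rpe_map)) rpe_map <- detect_rpe_crosspol(volume, config)

  # noise statistics from the anterior (vitreous) noise-floor region,
  # excluding zero-padded voxels introduced by flattening; capped at half
  # the typical column peak so noise-free volumes (no vitreous signal at
  # all) still threshold sensibly
  n_noise <- max(4L, nz %/% 4L)
  nvals <- m[, seq_len(n_noise)]
  nvals <- nvals[nvals > 0]
  peaks <- m[cbind(seq_len(ny * nx), max.col(m, ties.method = "first"))]
  cap <- 0.5 * stats::median(peaks)
  thr <- if (length(nvals) < 2L) 0
         else min(mean(nvals) + lc$ilm_snr_factor * stats::sd(nvals), cap)

  above <- m > thr
  ilm <- apply(above, 1L, function(v) {
    w <- which(v)
    if (length(w)) w[1L] else NA_integer_
  })

  # posterior RPE: falling edge of the combined-intensity profile,
  # searched posterior to the cross-channel-detected RPE peak on the
  # axially boxcar-smoothed profile (suppresses speckle maxima)
  mcs <- smooth_rows_boxcar(mc, 5L)
  npx <- ny * nx
  pk_z <- pmin(pmax(as.integer(round(c(unclass(rpe_map)))), 1L), nz)
  pk_v <- mcs[cbind(seq_len(npx), pk_z)]
  rpe <- rep(NA_real_, npx)
  remaining <- !is.na(ilm) & pk_v > thr
  k <- 1L
  while (any(remaining) && k <= nz) {
    zk <- pk_z + k
    hit <- remaining & zk <= nz
    hit[hit] <- mcs[cbind(which(hit), zk[hit])] <
      lc$rpe_falling_fraction * pk_v[hit]
    rpe[hit] <- zk[hit]
    remaining <- remaining & !hit & zk < nz
    k <- k + 1L
  }

  # posterior OPL: strongest posterior falling edge in the inner window.
  # The profile is smoothed laterally (the boundary is laterally smooth;
  # speckle in bright foci or vessels is not) and lightly along depth (the
  # boxcar is symmetric, so the edge position is unbiased).
  opl <- rep(NA_real_, ny * nx)
  m_lat <- matrix(lateral_box_smooth(amp, lc$opl_lateral_px %||% 5L),
                  ny * nx, nz)
  m3 <- smooth_rows_boxcar(m_lat, lc$opl_smooth_px %||% 3L)
  dm <- m3[, -1L, drop = FALSE] - m3[, -nz, drop = FALSE] # d[z] = a[z+1]-a[z]
  for (i in seq_len(ny * nx)) {
    if (is.na(ilm[i]) || is.na(rpe[i]) || rpe[i] <= ilm[i] + 4) next
    span <- rpe[i] - ilm[i]
    w0 <- floor(ilm[i] + lc$opl_window[1L] * span)
    w1 <- ceiling(ilm[i] + lc$opl_window[2L] * span)
    w0 <- max(w0, 1L); w1 <- min(w1, nz - 1L)
    if (w1 <= w0) next
    g <- dm[i, w0:w1]
    gmin <- min(g)
    if (gmin >= 0) next
    cand <- which(g <= lc$opl_gradient_fraction * gmin)
    # most posterior contiguous run of strong candidates; its middle is
    # the unbiased edge position under the symmetric smoothing kernel
    brk <- which(diff(cand) > 1L)
    run <- if (length(brk)) cand[(brk[length(brk)] + 1L):length(cand)] else cand
    opl[i] <- w0 + run[ceiling(length(run) / 2)]  # first voxel of the ONL
  }

  ilm_m <- matrix(as.numeric(ilm), ny, nx)
  opl_m <- matrix(opl, ny, nx)
  rpe_m <- matrix(rpe, ny, nx)
  invalid <- is.na(ilm_m) | is.na(opl_m) | is.na(rpe_m)
  frac <- mean(invalid)
  if (frac > lc$max_invalid_fraction)
    stop_retoct(sprintf("layer segmentation failed for %.0f%% of A-scans",
                        100 * frac), "retoct_exclusion_error")
  ilm_m <- fill_invalid_lateral(ilm_m, invalid)
  opl_m <- fill_invalid_lateral(opl_m, invalid)
  rpe_m <- fill_invalid_lateral(rpe_m, invalid)
  k <- lc$boundary_median_px
  ilm_m <- round(median_filter2(ilm_m, k))
  opl_m <- round(median_filter2(opl_m, k))
  rpe_m <- round(median_filter2(rpe_m, k))
  mono_bad <- !(ilm_m < opl_m & opl_m < rpe_m)
  # plausibility: inside the ONH the layered structure is absent and the
  # detectors latch onto whatever bright structure exists (e.g. the
  # hyaloid remnant); flag thickness outliers as invalid
  tot <- rpe_m - ilm_m
  usable <- !mono_bad & !invalid
  med_tot <- stats::median(tot[usable])
  med_ilm <- stats::median(ilm_m[usable])
  f <- lc$thickness_outlier_fraction %||% 0.3
  # on a flattened volume the ILM depth is laterally smooth as well, so a
  # grossly deviating ILM is as implausible as a deviating thickness
  outlier <- abs(tot - med_tot) > f * med_tot |
    abs(ilm_m - med_ilm) > f * med_tot
  bad <- mono_bad | outlier
  invalid <- invalid | bad
  if (mean(invalid) > lc$max_invalid_fraction)
    stop_retoct("layer ordering violated for too many A-scans",
                "retoct_exclusion_error")
  if (any(bad)) {
    ilm_m <- fill_invalid_lateral(ilm_m, bad)
    opl_m <- fill_invalid_lateral(opl_m, bad)
    rpe_m <- fill_invalid_lateral(rpe_m, bad)
  }
  structure(list(ilm_px = ilm_m, opl_px = opl_m, rpe_px = rpe_m,
                 valid = !invalid,
                 axial_pitch_um = volume$metadata$axial_pitch_um),
            class = "layer_map")
}

#' Build the peripapillary measurement annulus
#'
#' A ring around the ONH centre, specified in physical (micrometre)
#' coordinates so anisotropic en-face pixels are handled, cut transversely
#' through the centre into a superior and an inferior half. Pixel centres
#' at `(i - 0.5) * pitch`; a pixel belongs to the annulus when
#' `inner_radius <= r < outer_radius`.
#'
#' @param dims `c(ny, nx)` of the en-face grid.
#' @param pitch_um named `c(x = , y = )` en-face pitches, um.
#' @param center_um ONH centre `c(x, y)` in um.
#' @param config a [pipeline_config()] (section `annulus`), or explicit
#'   `inner_diameter_um`/`outer_diameter_um`/`split_orientation_deg`.
#' @return an object of class `annulus_mask`: logical matrices `annulus`,
#'   `superior`, `inferior` and the geometry used.
#' @export
build_annulus <- function(dims, pitch_um, center_um,
                          config = pipeline_config()) {
  ac <- config$annulus
  ny <- dims[1L]; nx <- dims[2L]
  cc <- pixel_centers_um(ny, nx, pitch_um[["y"]], pitch_um[["x"]])
  X <- matrix(cc$x, ny, nx, byrow = TRUE)
  Y <- matrix(cc$y, ny, nx)
  r_in <- ac$inner_diameter_um / 2
  r_out <- ac$outer_diameter_um / 2
  if (r_out < r_in)
    stop_retoct("outer diameter must not be smaller than inner diameter",
                "retoct_validation_error")
  fx <- nx * pitch_um[["x"]]; fy <- ny * pitch_um[["y"]]
  if (center_um[["x"]] < 0 || center_um[["x"]] > fx ||
      center_um[["y"]] < 0 || center_um[["y"]] > fy)
    stop_retoct("annulus centre lies outside the field of view",
                "retoct_validation_error")
  if (center_um[["x"]] - r_out < 0 || center_um[["x"]] + r_out > fx ||
      center_um[["y"]] - r_out < 0 || center_um[["y"]] + r_out > fy) {
    area_fov <- fx * fy
    clip <- 1 - min(1, area_fov / (pi * r_out^2))
    stop_retoct(sprintf(
      "annulus (outer radius %.0f um) exceeds the field of view (>= %.0f%% clipped)",
      r_out, 100 * clip), "retoct_validation_error")
  }
  r <- sqrt((X - center_um[["x"]])^2 + (Y - center_um[["y"]])^2)
  ann <- r >= r_in & r < r_out
  th <- ac$split_orientation_deg * pi / 180
  # signed distance to the transverse split line through the centre;
  # negative side (image top at 0 deg) = superior
  sgn <- -(Y - center_um[["y"]]) * cos(th) + (X - center_um[["x"]]) * sin(th)
  sup <- ann & sgn >= 0
  inf <- ann & sgn < 0
  structure(list(annulus = ann, superior = sup, inferior = inf,
                 center_um = center_um,
                 inner_diameter_um = ac$inner_diameter_um,
                 outer_diameter_um = ac$outer_diameter_um,
                 split_orientation_deg = ac$split_orientation_deg,
                 pitch_um = pitch_um),
            class = "annulus_mask")
}

#' Compute the nine annulus thickness metrics
#'
#' Mean total, inner, and outer retinal thickness (boundary differences
#' times the axial pitch) over the valid pixels of the whole annulus and
#' its superior and inferior halves. Total = inner + outer holds exactly
#' in every region.
#'
#' @param layer_map a [segment_layers()] result.
#' @param annulus a [build_annulus()] result.
#' @param eye_id,group,age_weeks record labels.
#' @return a one-row data.frame of class `thickness_record` with columns
#'   `total`, `inner`, `outer` crossed with `_whole`, `_superior`,
#'   `_inferior` (um).
#' @export
compute_thickness <- function(layer_map, annulus, eye_id = "eye",
                              group = "wildtype", age_weeks = NA_real_) {
  p <- layer_map$axial_pitch_um
  tot <- (layer_map$rpe_px - layer_map$ilm_px) * p
  inn <- (layer_map$opl_px - layer_map$ilm_px) * p
  out <- (layer_map$rpe_px - layer_map$opl_px) * p
  regions <- list(whole = annulus$annulus, superior = annulus$superior,
                  inferior = annulus$inferior)
  rec <- list(eye_id = eye_id, group = group, age_weeks = age_weeks)
  for (rn in names(regions)) {
    sel <- regions[[rn]] & layer_map$valid
    if (!any(sel))
      stop_retoct(sprintf("no valid pixels in region '%s'", rn),
                  "retoct_validation_error")
    rec[[paste0("total_", rn)]] <- mean(tot[sel])
    rec[[paste0("inner_", rn)]] <- mean(inn[sel])
    rec[[paste0("outer_", rn)]] <- mean(out[sel])
  }
  df <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(df) <- c("thickness_record", class(df))
  df
}
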