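#' Configure the synthetic PS-OCT retina phantom
#'
#' Describes a layered, speckled, dual-polarization mouse-retina phantom:
#' smoothly undulating layer boundaries (ILM, posterior OPL, posterior RPE)
#' with per-layer reflectivity including a hyper-reflective OPL band and a
#' melanin (RPE/choroid) band; a layerless optic nerve head (ONH)
#' depression with a depolarizing hyaloid-remnant column; flow-decorrelated
#' vessels in a superficial (SVP) and a deep (DCP) plexus; optional
#' hyper-reflective foci (HRF) and ectopic melanin deposits; per-B-scan
#' axial motion and per-repeat global phase jitter; and an additive complex
#' noise floor.
#'
#' Depth geometry uses 1-based voxel indices with the voxel `z` centred at
#' `(z - 0.5) * axial_pitch_um` micrometres; a boundary at depth `b` um has
#' the continuous voxel coordinate `b / pitch + 0.5`.
#'
#' @param n_repeats,n_y,n_x,n_z volume shape (repeats, slow axis, fast
#'   axis, depth). The desk-scale default is `5 x 100 x 128 x 256`; the
#'   full acquisition scale `5 x 400 x 512 x 1024` is supported.
#' @param fov_x_mm,fov_y_mm,axial_pitch_um physical sampling.
#' @param ilm_um,inner_um,outer_um ILM depth and inner/outer retinal
#'   thicknesses in um (posterior OPL = `ilm + inner`, posterior RPE =
#'   `ilm + inner + outer`).
#' @param reflectivity named list of linear speckle amplitudes per band:
#'   `rnfl`, `inl`, `opl`, `onl`, `rpe_peak`, `rpe_edge`, `sclera`, `onh`,
#'   `remnant`, plus band geometry `rnfl_um`, `opl_band_um`,
#'   `melanin_band_um`.
#' @param undulation_um amplitude of the smooth common boundary undulation.
#' @param onh list with `center_um` (x, y), `radius_um`, `remnant_radius_um`.
#' @param vessels data.frame with columns `plexus` ("SVP"/"DCP"),
#'   `x0_um, y0_um, x1_um, y1_um` (centerline segment), `radius_um`,
#'   `decorrelation` in `[0, 1]`; `default_vessels()` builds the default
#'   plexus layout.
#' @param svp_slab_um,dcp_slab_um plexus slab extents (SVP below the ILM,
#'   DCP above the posterior OPL).
#' @param hrf data.frame with columns `x_um, y_um, depth_frac` (normalized
#'   outer-retina depth of the centre), `radius_um`, `amplitude_factor`;
#'   `NULL` for the default three foci, `data.frame()` for none.
#' @param melanin_deposits data.frame with columns `x_um, y_um, z_um`
#'   (anatomical depth), `radius_um`; default none.
#' @param motion_sigma_px per-B-scan axial random-walk step, pixels.
#' @param phase_jitter apply a random global phase per repeated B-scan.
#' @param noise_floor additive complex noise amplitude (linear).
#' @param eye_id,group_label,age_weeks metadata carried into the volume.
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return a validated `phantom_config` list.
#' @export
phantom_config <- function(n_repeats = 5L, n_y = 100L, n_x = 128L, n_z = 256L,
                           fov_x_mm = 1, fov_y_mm = 1, axial_pitch_um = 2,
                           ilm_um = 100, inner_um = 130, outer_um = 90,
                           reflectivity = list(),
                           undulation_um = 8,
                           onh = list(),
                           vessels = NULL,
                           svp_slab_um = 20, dcp_slab_um = 15,
                           hrf = NULL,
                           melanin_deposits = data.frame(),
                           motion_sigma_px = 1,
                           phase_jitter = TRUE,
                           noise_floor = 0.04,
                           eye_id = "phantom-001",
                           group_label = "wildtype",
                           age_weeks = 60,
                           seed = 1L) {
  refl <- list(rnfl = 1.6, inl = 0.55, opl = 1.0, onl = 0.30,
               rpe_peak = 2.2, rpe_edge = 1.2, sclera = 0.12,
               onh = 0.15, remnant = 1.0,
               rnfl_um = 40, opl_band_um = 20, melanin_band_um = 32)
  bad <- setdiff(names(reflectivity), names(refl))
  if (length(bad)) stop_retoct(paste("unknown reflectivity field(s):",
                                     paste(bad, collapse = ", ")),
                               "retoct_validation_error")
  refl[names(reflectivity)] <- reflectivity
  onh_def <- list(center_um = c(x = 500 * fov_x_mm, y = 500 * fov_y_mm),
                  radius_um = 100, remnant_radius_um = 30)
  bad <- setdiff(names(onh), names(onh_def))
  if (length(bad)) stop_retoct(paste("unknown onh field(s):",
                                     paste(bad, collapse = ", ")),
                               "retoct_validation_error")
  onh_def[names(onh)] <- onh
  if (is.null(vessels))
    vessels <- default_vessels(fov_x_mm * 1e3, fov_y_mm * 1e3,
                               onh_def$center_um)
  if (is.null(hrf)) hrf <- default_hrf(fov_x_mm * 1e3, fov_y_mm * 1e3)
  cfg <- list(n_repeats = as.integer(n_repeats), n_y = as.integer(n_y),
              n_x = as.integer(n_x), n_z = as.integer(n_z),
              fov_x_mm = fov_x_mm, fov_y_mm = fov_y_mm,
              axial_pitch_um = axial_pitch_um,
              ilm_um = ilm_um, inner_um = inner_um, outer_um = outer_um,
              reflectivity = refl, undulation_um = undulation_um,
              onh = onh_def, vessels = vessels,
              svp_slab_um = svp_slab_um, dcp_slab_um = dcp_slab_um,
              hrf = hrf, melanin_deposits = melanin_deposits,
              motion_sigma_px = motion_sigma_px, phase_jitter = phase_jitter,
              noise_floor = noise_floor,
              eye_id = eye_id, group_label = group_label,
              age_weeks = age_weeks, seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  for (f in c("n_repeats", "n_y", "n_x", "n_z"))
    if (!is_count(cfg[[f]]))
      stop_retoct(sprintf("'%s' must be a positive integer", f),
                  "retoct_validation_error")
  if (!(cfg$ilm_um > 0 && cfg$inner_um > 0 && cfg$outer_um > 0))
    stop_retoct("layer depths/thicknesses must be positive and increasing",
                "retoct_validation_error")
  zmax <- cfg$n_z * cfg$axial_pitch_um
  if (cfg$ilm_um + cfg$inner_um + cfg$outer_um >= zmax)
    stop_retoct("layer stack exceeds the axial extent of the volume",
                "retoct_validation_error")
  v <- cfg$vessels
  if (nrow(v)) {
    if (any(v$decorrelation < 0 | v$decorrelation > 1))
      stop_retoct("vessel decorrelation fractions must lie in [0, 1]",
                  "retoct_validation_error")
    if (any(v$radius_um <= 0))
      stop_retoct("vessel radii must be positive", "retoct_validation_error")
  }
  if (nrow(cfg$hrf) && any(cfg$hrf$radius_um <= 0))
    stop_retoct("HRF radii must be positive", "retoct_validation_error")
  if (!is_nonneg_scalar(cfg$noise_floor))
    stop_retoct("noise floor must be non-negative", "retoct_validation_error")
  invisible(TRUE)
}

#' @rdname phantom_config
#' @param fov_x_um,fov_y_um field of view in um.
#' @param onh_center_um ONH centre `c(x, y)` in um.
#' @export
default_vessels <- function(fov_x_um = 1000, fov_y_um = 1000,
                            onh_center_um = c(x = 500, y = 500)) {
  ang <- seq(15, 335, by = 60) * pi / 180
  len <- 0.75 * max(fov_x_um, fov_y_um)
  svp <- data.frame(
    plexus = "SVP",
    x0_um = onh_center_um[["x"]], y0_um = onh_center_um[["y"]],
    x1_um = onh_center_um[["x"]] + len * cos(ang),
    y1_um = onh_center_um[["y"]] + len * sin(ang),
    radius_um = 16, decorrelation = 1.0)
  gx <- fov_x_um * c(0.17, 0.39, 0.61, 0.83)
  gy <- fov_y_um * c(0.17, 0.39, 0.61, 0.83)
  dcp <- rbind(
    data.frame(plexus = "DCP", x0_um = gx, y0_um = 0, x1_um = gx,
               y1_um = fov_y_um, radius_um = 15, decorrelation = 0.5),
    data.frame(plexus = "DCP", x0_um = 0, y0_um = gy, x1_um = fov_x_um,
               y1_um = gy, radius_um = 15, decorrelation = 0.5))
  rbind(svp, dcp)
}

#' @rdname phantom_config
#' @export
default_hrf <- function(fov_x_um = 1000, fov_y_um = 1000) {
  data.frame(
    x_um = fov_x_um * c(0.25, 0.68, 0.80),
    y_um = fov_y_um * c(0.30, 0.22, 0.72),
    depth_frac = c(0.33, 0.38, 0.36),
    radius_um = c(20, 16, 18),
    amplitude_factor = 8)
}

# Distance from points (px, py) to the segment (x0,y0)-(x1,y1), vectorised
# over points.
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

#' Generate a synthetic dual-polarization OCT volume with ground truth
#'
#' Realises fully developed speckle as an independent circular complex
#' Gaussian per voxel scaled by the layer reflectivity. Static voxels are
#' identical across repeats up to the applied global phase and axial
#' shifts; vessel voxels are redrawn independently in each repeat with
#' probability equal to the vessel's decorrelation fraction.
#' Polarization-preserving voxels put all signal amplitude in the co
#' channel; melanin voxels draw a per-voxel retardation angle uniform on
#' `[0, 90]` degrees and split the amplitude as `cos`/`sin` of it.
#'
#' @param config a [phantom_config()].
#' @return a list with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`): boundary maps in continuous voxel
#'   coordinates (`ilm_px`, `opl_px`, `rpe_px`, `rpe_peak_px`, motion-free
#'   frame), `valid` en-face mask (outside the ONH), per-plexus en-face
#'   vessel masks and 1-pixel centerline rasters, HRF records with voxel
#'   index lists and volumes,
#'   the expected-depolarization voxel mask and ectopic deposit voxel
#'   lists, per-B-scan axial shifts, per-repeat phase offsets, and the
#'   generating config.
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  nr <- config$n_repeats; ny <- config$n_y; nx <- config$n_x; nz <- config$n_z
  p <- config$axial_pitch_um
  px_um <- 1e3 * config$fov_x_mm / nx
  py_um <- 1e3 * config$fov_y_mm / ny
  cc <- pixel_centers_um(ny, nx, py_um, px_um)
  X <- matrix(cc$x, ny, nx, byrow = TRUE)   # [y, x] en-face centres, um
  Y <- matrix(cc$y, ny, nx)
  zc <- (seq_len(nz) - 0.5) * p             # voxel centre depths, um

  # common smooth undulation of all boundaries (thickness is unchanged)
  S <- config$undulation_um *
    sin(2 * pi * 1.5 * X / (1e3 * config$fov_x_mm)) *
    cos(2 * pi * Y / (1e3 * config$fov_y_mm))

  ilm_um <- config$ilm_um + S
  opl_um <- ilm_um + config$inner_um
  rpe_um <- opl_um + config$outer_um
  refl <- config$reflectivity
  band <- refl$melanin_band_um
  rpe_mid_um <- rpe_um - band / 2

  # anatomical depth of each voxel (depth relative to the undulating stack)
  Q <- array(rep(zc, each = ny * nx), c(ny, nx, nz)) -
    array(rep(S, nz), c(ny, nx, nz))
  q0 <- config$ilm_um

  A <- array(refl$sclera, c(ny, nx, nz))
  A[Q < q0] <- 0
  A[Q >= q0 & Q < q0 + refl$rnfl_um] <- refl$rnfl
  A[Q >= q0 + refl$rnfl_um & Q < q0 + config$inner_um - refl$opl_band_um] <- refl$inl
  A[Q >= q0 + config$inner_um - refl$opl_band_um & Q < q0 + config$inner_um] <- refl$opl
  onl_hi <- q0 + config$inner_um + config$outer_um - band
  A[Q >= q0 + config$inner_um & Q < onl_hi] <- refl$onl
  in_band <- Q >= onl_hi & Q < q0 + config$inner_um + config$outer_um
  mid <- q0 + config$inner_um + config$outer_um - band / 2
  A[in_band] <- refl$rpe_edge + (refl$rpe_peak - refl$rpe_edge) *
    (1 - abs(Q[in_band] - mid) / (band / 2))
  melanin <- in_band

  # ONH: layerless depression plus depolarizing remnant column
  onh <- config$onh
  R2 <- sqrt((X - onh$center_um[["x"]])^2 + (Y - onh$center_um[["y"]])^2)
  onh_disc <- R2 <= onh$radius_um
  if (any(onh_disc)) {
    disc3 <- array(rep(onh_disc, nz), c(ny, nx, nz))
    A[disc3] <- refl$onh
    melanin[disc3] <- FALSE
    rem <- R2 <= onh$remnant_radius_um
    rem3 <- array(rep(rem, nz), c(ny, nx, nz)) &
      Q >= q0 - 40 & Q < q0 + 60
    A[rem3] <- refl$remnant
    melanin[rem3] <- TRUE
  }

  # ectopic melanin deposits (anatomical coordinates)
  deposit_voxels <- list()
  md <- config$melanin_deposits
  if (nrow(md)) {
    X3 <- array(rep(X, nz), c(ny, nx, nz))
    Y3 <- array(rep(Y, nz), c(ny, nx, nz))
    for (i in seq_len(nrow(md))) {
      d2 <- (X3 - md$x_um[i])^2 + (Y3 - md$y_um[i])^2 +
        (Q - (q0 + md$z_um[i]))^2
      vox <- d2 <= md$radius_um[i]^2
      if (!any(vox))
        stop_retoct("melanin deposit smaller than one voxel; increase radius",
                    "retoct_validation_error")
      melanin[vox] <- TRUE
      A[vox] <- pmax(A[vox], refl$remnant)
      deposit_voxels[[i]] <- which(vox)
    }
  }

  # HRF: reflectivity multiplied inside spheres in the outer retina
  hrf_records <- list()
  if (nrow(config$hrf)) {
    X3 <- array(rep(X, nz), c(ny, nx, nz))
    Y3 <- array(rep(Y, nz), c(ny, nx, nz))
    for (i in seq_len(nrow(config$hrf))) {
      h <- config$hrf[i, ]
      cz <- q0 + config$inner_um + h$depth_frac * config$outer_um
      d2 <- (X3 - h$x_um)^2 + (Y3 - h$y_um)^2 + (Q - cz)^2
      vox <- d2 <= h$radius_um^2 & !melanin
      A[vox] <- A[vox] * h$amplitude_factor
      hrf_records[[i]] <- list(
        x_um = h$x_um, y_um = h$y_um, depth_frac = h$depth_frac,
        radius_um = h$radius_um,
        voxels = which(vox),
        volume_um3 = sum(vox) * px_um * py_um * p)
    }
  }

  # vessel decorrelation field and en-face truth masks
  D <- array(0, c(ny, nx, nz))
  vmask <- list(SVP = matrix(FALSE, ny, nx), DCP = matrix(FALSE, ny, nx))
  vline <- list(SVP = matrix(FALSE, ny, nx), DCP = matrix(FALSE, ny, nx))
  v <- config$vessels
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      dd <- point_segment_distance(c(X), c(Y), v$x0_um[i], v$y0_um[i],
                                   v$x1_um[i], v$y1_um[i])
      ef <- matrix(dd <= v$radius_um[i], ny, nx)
      pl <- v$plexus[i]
      vmask[[pl]] <- vmask[[pl]] | ef
      # 1-px centerline raster: threshold is half the pixel extent
      # projected onto the segment normal
      seg <- c(v$x1_um[i] - v$x0_um[i], v$y1_um[i] - v$y0_um[i])
      L <- sqrt(sum(seg^2))
      nrm <- if (L > 0) c(-seg[2L], seg[1L]) / L else c(1, 0)
      w_half <- 0.5 * (abs(nrm[1L]) * px_um + abs(nrm[2L]) * py_um)
      vline[[pl]] <- vline[[pl]] | matrix(dd <= w_half, ny, nx)
      slab <- if (pl == "SVP") c(q0, q0 + config$svp_slab_um)
              else c(q0 + config$inner_um - config$dcp_slab_um,
                     q0 + config$inner_um)
      vox <- array(rep(ef, nz), c(ny, nx, nz)) & Q >= slab[1] & Q < slab[2]
      D[vox] <- pmax(D[vox], v$decorrelation[i])
    }
  }

  # speckle, polarization split, repeats
  delta <- array(0, c(ny, nx, nz))
  nmel <- sum(melanin)
  if (nmel) delta[melanin] <- stats::runif(nmel, 0, pi / 2)
  psi <- array(0, c(ny, nx, nz))
  if (nmel) psi[melanin] <- stats::runif(nmel, 0, 2 * pi)
  cosd <- cos(delta); sind_e <- sin(delta) * exp(1i * psi)
  rm(delta, psi)

  nvox <- ny * nx * nz
  b <- complex(real = stats::rnorm(nvox), imaginary = stats::rnorm(nvox)) /
    sqrt(2) * c(A)
  dim(b) <- c(ny, nx, nz)
  ves_idx <- which(D > 0)

  # axial motion: integer random-walk shift per B-scan location (common to
  # all repeats and both channels)
  shifts <- integer(ny)
  if (config$motion_sigma_px > 0 && ny > 1)
    shifts <- as.integer(round(cumsum(c(0, stats::rnorm(ny - 1, 0,
                                                        config$motion_sigma_px)))))
  # per-repeat global phase per B-scan
  phases <- matrix(0, nr, ny)
  if (config$phase_jitter)
    phases <- matrix(stats::runif(nr * ny, 0, 2 * pi), nr, ny)

  shift_groups <- split(seq_len(ny), shifts)
  apply_motion <- function(a) {   # a: [ny, nx, nz]
    if (all(shifts == 0L)) return(a)
    out <- array(complex(real = 0), dim(a))
    for (sg in names(shift_groups)) {
      s <- as.integer(sg); ys <- shift_groups[[sg]]
      if (s == 0L) out[ys, , ] <- a[ys, , , drop = FALSE]
      else if (s > 0 && s < nz)
        out[ys, , (s + 1L):nz] <- a[ys, , 1L:(nz - s), drop = FALSE]
      else if (s < 0 && -s < nz)
        out[ys, , 1L:(nz + s)] <- a[ys, , (1L - s):nz, drop = FALSE]
    }
    out
  }

  co <- array(complex(real = 0), c(ny, nx, nz, nr))
  cross <- co
  for (r in seq_len(nr)) {
    cr <- b
    if (length(ves_idx)) {
      redraw <- ves_idx[stats::runif(length(ves_idx)) < D[ves_idx]]
      if (length(redraw))
        cr[redraw] <- complex(real = stats::rnorm(length(redraw)),
                              imaginary = stats::rnorm(length(redraw))) /
          sqrt(2) * A[redraw]
    }
    # polarization split happens in the tissue frame; motion then shifts
    # both detection channels identically
    ph_r <- if (config$phase_jitter) exp(1i * phases[r, ]) else 1
    co_r <- apply_motion(cr * cosd) * ph_r   # phase recycles along y
    cross_r <- apply_motion(cr * sind_e) * ph_r
    if (config$noise_floor > 0) {
      co_r <- co_r +
        complex(real = stats::rnorm(nvox), imaginary = stats::rnorm(nvox)) /
        sqrt(2) * config$noise_floor
      cross_r <- cross_r +
        complex(real = stats::rnorm(nvox), imaginary = stats::rnorm(nvox)) /
        sqrt(2) * config$noise_floor
    }
    co[, , , r] <- co_r
    cross[, , , r] <- cross_r
  }
  co <- aperm(co, c(4L, 1L, 2L, 3L))
  cross <- aperm(cross, c(4L, 1L, 2L, 3L))

  md_obj <- acquisition_metadata(
    n_ascans_per_bscan = nx, n_bscan_locations = ny, n_repeats = nr,
    fov_x_mm = config$fov_x_mm, fov_y_mm = config$fov_y_mm,
    axial_pitch_um = p, eye_id = config$eye_id,
    group_label = config$group_label, age_weeks = config$age_weeks)
  vol <- oct_volume(co, cross, md_obj)

  truth <- structure(list(
    ilm_px = ilm_um / p + 0.5,
    opl_px = opl_um / p + 0.5,
    rpe_px = rpe_um / p + 0.5,
    rpe_peak_px = rpe_mid_um / p + 0.5,
    valid = !onh_disc,
    vessel_enface = vmask,
    vessel_centerline = vline,
    hrf = hrf_records,
    melanin_mask = melanin,
    deposit_voxels = deposit_voxels,
    axial_shift_px = shifts,
    phase_offsets = phases,
    onh_center_um = onh$center_um,
    onh_radius_um = onh$radius_um,
    pitch_um = c(x = px_um, y = py_um, z = p),
    config = config,
    seed = config$seed), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

# Shift one repeated B-scan block [r, 1, x, z] along z by s pixels
# (positive = posterior), zero filling.
shift_bscan_z <- function(block, s) {
  d <- dim(block)
  nz <- d[4L]
  out <- array(complex(real = 0), d)
  if (s > 0) {
    if (s < nz) out[, , , (s + 1L):nz] <- block[, , , 1L:(nz - s)]
  } else {
    s <- -s
    if (s < nz) out[, , , 1L:(nz - s)] <- block[, , , (s + 1L):nz]
  }
  out
}
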