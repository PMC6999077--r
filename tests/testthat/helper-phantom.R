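# Shared fixtures. The default-scale phantom pipeline is expensive, so it
# is computed once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Full default-scale phantom (5 x 100 x 128 x 256, seed 42) with the whole
# reflectivity pipeline applied: flattened volume, layer map, annulus.
default_pipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    ph <- generate_phantom(phantom_config(seed = 42L))
    fl <- flatten_volume(ph$volume)
    ph$volume <- NULL               # keep memory bounded: flat volume only
    lm <- segment_layers(fl$volume)
    pp <- c(x = 1000 / 128, y = 1000 / 100)
    ann <- build_annulus(dim(lm$ilm_px), pp, ph$truth$onh_center_um)
    .fixtures$pipe <- list(truth = ph$truth, flat = fl,
                           layers = lm, pitch = pp, annulus = ann)
    gc(FALSE)
  }
  .fixtures$pipe
}

# Medium phantom (standard geometry, reduced lateral sampling) for
# HRF-scale tests; memoised together with its flattening and layer map.
medium_hrf_pipeline <- function() {
  if (is.null(.fixtures$hrfpipe)) {
    foci <- data.frame(x_um = c(250, 700), y_um = c(300, 650),
                       depth_frac = c(0.35, 0.42), radius_um = c(16, 13),
                       amplitude_factor = 8)
    ph <- generate_phantom(phantom_config(n_y = 60L, n_x = 64L, n_z = 256L,
                                          hrf = foci, motion_sigma_px = 0,
                                          seed = 26L))
    fl <- flatten_volume(ph$volume)
    ph$volume <- NULL
    lm <- segment_layers(fl$volume)
    .fixtures$hrfpipe <- list(truth = ph$truth, flat = fl, layers = lm)
    gc(FALSE)
  }
  .fixtures$hrfpipe
}

# Small, fast phantom for I/O and structural tests. Named overrides in
# `...` replace the scaled-down defaults (reflectivity/onh are merged).
small_phantom <- function(seed = 3L, ...) {
  args <- list(n_y = 24L, n_x = 32L, n_z = 128L,
               ilm_um = 50, inner_um = 65, outer_um = 45,
               reflectivity = list(rnfl_um = 20, opl_band_um = 10,
                                   melanin_band_um = 16),
               undulation_um = 4,
               onh = list(radius_um = 60, remnant_radius_um = 20),
               hrf = data.frame(),
               seed = seed)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("reflectivity", "onh"))
      args[[nm]] <- utils::modifyList(args[[nm]], ov[[nm]])
    else args[[nm]] <- ov[[nm]]
  }
  generate_phantom(do.call(phantom_config, args))
}

# Noise-free, motion-free 3-layer step B-scan stack with a triangular
# melanin band, for exact-recovery segmentation tests. Boundaries are the
# first voxel of the posterior side.
step_volume <- function(ilm = 50L, opl = 120L, rpe = 180L,
                        ny = 8L, nx = 16L, nz = 256L, band = 16L,
                        amps = c(inner = 1, opl_band = 1.6, onl = 0.3,
                                 peak = 2.2, edge = 1.2)) {
  prof_co <- numeric(nz)
  prof_cross <- numeric(nz)
  opl_band <- max(ilm + 1L, opl - 10L)
  prof_co[ilm:(opl_band - 1L)] <- amps[["inner"]]
  prof_co[opl_band:(opl - 1L)] <- amps[["opl_band"]]
  prof_co[opl:(rpe - band - 1L)] <- amps[["onl"]]
  tri <- rpe - band:1L        # band voxels, peak in the middle
  mid <- rpe - band / 2
  prof_cross[tri] <- amps[["edge"]] + (amps[["peak"]] - amps[["edge"]]) *
    (1 - abs(tri - mid) / (band / 2))
  co <- array(complex(real = rep(prof_co, each = 2L * ny * nx)),
              c(2L, ny, nx, nz))
  cross <- array(complex(real = rep(prof_cross, each = 2L * ny * nx)),
                 c(2L, ny, nx, nz))
  md <- acquisition_metadata(n_ascans_per_bscan = nx, n_bscan_locations = ny,
                             n_repeats = 2L, axial_pitch_um = 2)
  oct_volume(co, cross, md)
}

# Brute-force reference: dilate a logical matrix by a k x k square, by
# explicit looping (independent of the morphology library).
brute_square_dilate <- function(mask, k = 5L) {
  r <- (k - 1L) %/% 2L
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!mask[y, x]) next
    ys <- max(1L, y - r):min(ny, y + r)
    xs <- max(1L, x - r):min(nx, x + r)
    out[ys, xs] <- TRUE
  }
  out
}
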