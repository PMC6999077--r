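#' Read and write OCT volume containers
#'
#' A volume is stored as a directory holding one NIfTI file per detection
#' channel (`co.nii`, `cross.nii`; float64, dimensions
#' `[repeat, y, x, z, 2]` with the real and imaginary parts stacked on the
#' fifth dimension) and a JSON metadata sidecar (`metadata.json`). Double
#' precision storage makes the read/write round trip bit-exact, and the
#' byte layout is deterministic for identical input.
#'
#' @param volume an [oct_volume()].
#' @param path directory to write to (created if absent) or read from.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   validated [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  validate_volume(volume)
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop_retoct(sprintf("cannot create directory '%s'", path),
                  "retoct_io_error")
  for (ch in c("co", "cross")) {
    a <- volume[[ch]]
    d <- dim(a)
    ri <- array(0, c(d, 2L))
    ri[, , , , 1L] <- Re(a)
    ri[, , , , 2L] <- Im(a)
    f <- file.path(path, paste0(ch, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(ri), f, datatype = "double")
  }
  md <- unclass(volume$metadata)
  jsonlite::write_json(md, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  mdf <- file.path(path, "metadata.json")
  if (!file.exists(mdf))
    stop_retoct(sprintf("missing metadata sidecar '%s'", mdf),
                "retoct_io_error")
  md <- jsonlite::read_json(mdf, simplifyVector = TRUE)
  md <- do.call(acquisition_metadata, md)
  ch <- lapply(c(co = "co", cross = "cross"), function(nm) {
    f <- file.path(path, paste0(nm, ".nii"))
    if (!file.exists(f))
      stop_retoct(sprintf("missing channel file '%s'", f), "retoct_io_error")
    a <- as.array(RNifti::readNifti(f))
    attributes(a) <- list(dim = dim(a))
    if (length(dim(a)) != 5L || dim(a)[5L] != 2L)
      stop_retoct(sprintf("channel file '%s' is not a [r,y,x,z,2] stack", f),
                  "retoct_validation_error")
    cmplx <- complex(real = a[, , , , 1L], imaginary = a[, , , , 2L])
    dim(cmplx) <- dim(a)[1:4]
    cmplx
  })
  oct_volume(ch$co, ch$cross, md)
}

#' Pipeline configuration
#'
#' One nested list holding every tunable of every stage, with validated
#' defaults. `pipeline_config()` builds the default configuration and
#' applies overrides given as nested named lists; unknown keys (at any
#' level) are rejected. The configuration serializes to/from JSON.
#'
#' @param ... named overrides, e.g. `pipeline_config(angio = list(clahe_limit = 4))`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    preprocess = list(
      rpe_boxcar_px = 5L,          # axial smoothing before the RPE peak search
      rpe_lateral_px = 3L,         # lateral box smoothing before the peak search
      rpe_search_fraction = 0.35,  # search only below this fraction of z extent
      rpe_centroid_halfwidth_px = 10L, # centroid refinement window half-width
      rpe_median_px = 5L,          # lateral median filter on the RPE map
      rpe_snr_factor = 3,          # peak must exceed factor x noise floor
      max_invalid_fraction = 0.2,  # beyond this, detection raises an error
      flatten_target_fraction = 0.75 # RPE target depth as fraction of z extent
    ),
    layers = list(
      ilm_snr_factor = 4,          # threshold = noise mean + k * noise sd
      boundary_median_px = 5L,
      rpe_falling_fraction = 0.35, # posterior RPE = last sample above this x peak
      opl_window = c(0.30, 0.70),  # inner-retina search window, fraction of span
      opl_smooth_px = 3L,          # axial boxcar before the gradient search
      opl_lateral_px = 5L,         # lateral box smoothing for the OPL search
      opl_gradient_fraction = 0.7, # candidate edges within this factor of min grad
      thickness_outlier_fraction = 0.3, # invalidate implausible total thickness
      max_invalid_fraction = 0.3
    ),
    annulus = list(
      inner_diameter_um = 500,
      outer_diameter_um = 900,
      split_orientation_deg = 0
    ),
    stats = list(
      pretest_alpha = 0.05,
      bonferroni = FALSE
    ),
    angio = list(
      repeat_exclusion_threshold = 0.6,
      clahe_tiles = 8L,
      clahe_limit = 2,
      open_close_brush = "diamond",  # radius-1 disc structuring element
      svp_slab_um = 20,              # [ILM, ILM + 20 um]
      dcp_slab_um = 15               # [posterior OPL - 15 um, posterior OPL]
    ),
    polarization = list(
      snr_factor = 6,              # static speckle: dim-tail voxels carry
                                   # large noise-driven retardation errors
      retardation_threshold_deg = 30,
      min_deposit_voxels = 27L,
      onh_margin_um = 75,          # cylinder margin; segmentation is least
                                   # reliable in the ring around the ONH
      rpe_band_um = 32,            # thickness of the RPE/choroid complex
      rpe_margin_um = 10,          # anterior margin above the complex; must
                                   # exceed the boundary-detection uncertainty
      per_repeat = FALSE
    ),
    hrf = list(
      threshold_db = 6,
      smooth_z_px = 5L,            # depth-wise speckle smoothing before threshold
      min_voxels = 8L,
      max_voxels = 4000L,
      rpe_band_um = 32,
      opl_margin_um = 8            # guard band below the posterior OPL;
                                   # boundary speckle otherwise floods in
    ),
    histology = list(
      hue_deg = c(10, 40),
      min_saturation = 0.2,
      max_value = 0.9,
      min_area_um2 = 20
    )
  )
  merge_config(cfg, list(...), "config")
}

merge_config <- function(base, ov, where) {
  bad <- setdiff(names(ov), names(base))
  if (length(bad))
    stop_retoct(sprintf("unknown %s key(s): %s", where,
                        paste(bad, collapse = ", ")),
                "retoct_validation_error")
  for (nm in names(ov)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(ov[[nm]]))
        stop_retoct(sprintf("%s key '%s' must be a list", where, nm),
                    "retoct_validation_error")
      base[[nm]] <- merge_config(base[[nm]], ov[[nm]],
                                 paste0(where, "$", nm))
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  class(base) <- unique(c("pipeline_config", class(base)))
  base
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  ov <- rapply(ov, function(x) x, how = "replace")
  do.call(pipeline_config, ov)
}
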