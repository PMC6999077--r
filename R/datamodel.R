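#' Acquisition metadata
#'
#' Describes one acquired volume: scan geometry, timing, and the animal
#' labels carried through to the cohort statistics. All numeric fields are
#' validated strictly; en-face pixel pitches are derived as field of view /
#' sample count.
#'
#' @param ascan_rate_hz A-scan rate in Hz.
#' @param n_ascans_per_bscan A-scans per B-scan (fast axis, x).
#' @param n_bscan_locations unique B-scan locations (slow axis, y).
#' @param n_repeats repeated B-scans per location.
#' @param flyback_time_s scanner flyback time, s.
#' @param fov_x_mm,fov_y_mm field of view, mm.
#' @param axial_pitch_um depth sampling pitch, um per pixel.
#' @param center_wavelength_nm source center wavelength, nm.
#' @param beam_power_mw power on the cornea, mW.
#' @param eye_id free-form eye identifier.
#' @param group_label `"transgenic"` or `"wildtype"`.
#' @param age_weeks age at acquisition, weeks.
#' @return an object of class `acquisition_metadata` (a validated list).
#' @export
acquisition_metadata <- function(ascan_rate_hz = 83e3,
                                 n_ascans_per_bscan = 512L,
                                 n_bscan_locations = 400L,
                                 n_repeats = 5L,
                                 flyback_time_s = 1.5e-3,
                                 fov_x_mm = 1,
                                 fov_y_mm = 1,
                                 axial_pitch_um = 2,
                                 center_wavelength_nm = 840,
                                 beam_power_mw = 2.85,
                                 eye_id = "eye-001",
                                 group_label = "wildtype",
                                 age_weeks = 60) {
  md <- list(ascan_rate_hz = ascan_rate_hz,
             n_ascans_per_bscan = n_ascans_per_bscan,
             n_bscan_locations = n_bscan_locations,
             n_repeats = n_repeats,
             flyback_time_s = flyback_time_s,
             fov_x_mm = fov_x_mm, fov_y_mm = fov_y_mm,
             axial_pitch_um = axial_pitch_um,
             center_wavelength_nm = center_wavelength_nm,
             beam_power_mw = beam_power_mw,
             eye_id = eye_id, group_label = group_label,
             age_weeks = age_weeks)
  validate_metadata(md)   # before coercion, so 2.5 repeats is an error
  for (f in c("n_ascans_per_bscan", "n_bscan_locations", "n_repeats"))
    md[[f]] <- as.integer(md[[f]])
  for (f in c("ascan_rate_hz", "flyback_time_s", "fov_x_mm", "fov_y_mm",
              "axial_pitch_um", "center_wavelength_nm", "beam_power_mw",
              "age_weeks"))
    md[[f]] <- as.numeric(md[[f]])
  class(md) <- "acquisition_metadata"
  md
}

validate_metadata <- function(md) {
  req_pos <- c("ascan_rate_hz", "fov_x_mm", "fov_y_mm", "axial_pitch_um",
               "center_wavelength_nm", "age_weeks")
  for (f in req_pos)
    if (!is_positive_scalar(md[[f]]))
      stop_retoct(sprintf("metadata field '%s' must be a positive number", f),
                  "retoct_validation_error")
  for (f in c("n_ascans_per_bscan", "n_bscan_locations", "n_repeats"))
    if (!is_count(md[[f]]))
      stop_retoct(sprintf("metadata field '%s' must be a positive integer", f),
                  "retoct_validation_error")
  for (f in c("flyback_time_s", "beam_power_mw"))
    if (!is_nonneg_scalar(md[[f]]))
      stop_retoct(sprintf("metadata field '%s' must be non-negative", f),
                  "retoct_validation_error")
  if (!is.character(md$eye_id) || length(md$eye_id) != 1L)
    stop_retoct("metadata field 'eye_id' must be a string",
                "retoct_validation_error")
  if (!md$group_label %in% c("transgenic", "wildtype"))
    stop_retoct("metadata field 'group_label' must be 'transgenic' or 'wildtype'",
                "retoct_validation_error")
  invisible(TRUE)
}

#' Dual-polarization complex OCT volume
#'
#' A pair of complex 4-D arrays (co- and cross-polarized detection channel)
#' indexed `[repeat, y, x, z]` with y the slow scan axis, x the fast axis
#' and z depth increasing posteriorly, plus acquisition metadata. Channel
#' shapes must agree with each other and with the metadata, and all
#' amplitudes must be finite.
#'
#' @param co,cross complex arrays `[repeat, y, x, z]`.
#' @param metadata an [acquisition_metadata()] object.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(co, cross, metadata) {
  v <- structure(list(co = co, cross = cross, metadata = metadata),
                 class = "oct_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  validate_metadata(v$metadata)
  dco <- dim(v$co); dcr <- dim(v$cross)
  if (length(dco) != 4L)
    stop_retoct("channel arrays must be 4-D [repeat, y, x, z]",
                "retoct_validation_error")
  if (!identical(dco, dcr))
    stop_retoct("co and cross channels must have identical shape",
                "retoct_validation_error")
  md <- v$metadata
  if (dco[1L] != md$n_repeats)
    stop_retoct("repeat dimension does not match metadata field 'n_repeats'",
                "retoct_validation_error")
  if (dco[2L] != md$n_bscan_locations)
    stop_retoct("slow-axis dimension does not match metadata field 'n_bscan_locations'",
                "retoct_validation_error")
  if (dco[3L] != md$n_ascans_per_bscan)
    stop_retoct("fast-axis dimension does not match metadata field 'n_ascans_per_bscan'",
                "retoct_validation_error")
  if (!is.complex(v$co) || !is.complex(v$cross))
    stop_retoct("channels must be complex arrays", "retoct_validation_error")
  if (!all(is.finite(v$co)) || !all(is.finite(v$cross)))
    stop_retoct("channel amplitudes must all be finite",
                "retoct_validation_error")
  invisible(TRUE)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$co)
  cat(sprintf("<oct_volume> %d repeats x %d y x %d x x %d z | eye %s (%s, %.0f wk)\n",
              d[1], d[2], d[3], d[4], x$metadata$eye_id,
              x$metadata$group_label, x$metadata$age_weeks))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$co)

# Repeat-averaged channel amplitude, [y, x, z].
channel_amplitude <- function(v, channel = c("co", "cross")) {
  channel <- match.arg(channel)
  a <- abs(v[[channel]])
  d <- dim(a)
  out <- array(0, d[2:4])
  for (r in seq_len(d[1L])) out <- out + a[r, , , , drop = TRUE]
  out / d[1L]
}
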