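#' Acquisition-protocol and optics derivations
#'
#' Closed-form quantities of the raster-scan protocol and the delivery
#' optics: the B-scan period, the beam diameter after the refocusing
#' telescope, the theoretical (diffraction-limited) lateral resolution at
#' the retina, and the en-face pixel pitches. All are pure functions of a
#' protocol or telescope description.
#'
#' @param protocol a list with fields `n_ascans_per_bscan`, `ascan_rate_hz`,
#'   `flyback_time_s` (and for [theoretical_lateral_resolution_um()] also
#'   `center_wavelength_nm` and `eye_focal_length_mm`); see [scan_protocol()].
#' @return `bscan_period_ms`: the time from the start of one B-scan to the
#'   start of the next, in milliseconds.
#' @examples
#' p <- scan_protocol()
#' bscan_period_ms(p)                      # ~7.7 ms
#' reduced_beam_diameter_mm(telescope_spec())  # 0.5 mm
#' @name optics
NULL

#' Default scan protocol
#'
#' The raster protocol of the reference small-animal system: 83 kHz A-scan
#' rate, 512 A-scans per B-scan, 400 B-scan locations with 5 repeats,
#' 1.5 ms scanner flyback, a 1 mm x 1 mm field of view, 840 nm center
#' wavelength, and a 2.6 mm mouse-eye focal length.
#'
#' @param ... named overrides of any field.
#' @return a list of protocol constants.
#' @export
scan_protocol <- function(...) {
  p <- list(
    ascan_rate_hz        = 83e3,
    n_ascans_per_bscan   = 512L,
    n_bscan_locations    = 400L,
    n_repeats            = 5L,
    flyback_time_s       = 1.5e-3,
    fov_x_mm             = 1,
    fov_y_mm             = 1,
    center_wavelength_nm = 840,
    beam_power_mw        = 2.85,
    eye_focal_length_mm  = 2.6
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop_retoct(paste("unknown protocol field(s):",
                                     paste(bad, collapse = ", ")),
                               "retoct_validation_error")
  p[names(ov)] <- ov
  p
}

#' Refocusing telescope description
#'
#' Two achromatic doublet pairs (focal lengths 80 mm and 50 mm) that
#' demagnify the 0.8 mm collimated beam before the eye.
#'
#' @param input_beam_diameter_mm collimated beam diameter entering the
#'   telescope, mm.
#' @param focal_length_1_mm,focal_length_2_mm focal lengths of the first
#'   and second doublet pair, mm.
#' @return a list with the three fields.
#' @export
telescope_spec <- function(input_beam_diameter_mm = 0.8,
                           focal_length_1_mm = 80,
                           focal_length_2_mm = 50) {
  if (!is_positive_scalar(input_beam_diameter_mm) ||
      !is_positive_scalar(focal_length_1_mm) ||
      !is_positive_scalar(focal_length_2_mm))
    stop_retoct("telescope parameters must be positive numbers",
                "retoct_domain_error")
  list(input_beam_diameter_mm = input_beam_diameter_mm,
       focal_length_1_mm = focal_length_1_mm,
       focal_length_2_mm = focal_length_2_mm)
}

#' @rdname optics
#' @export
bscan_period_ms <- function(protocol) {
  if (!is_positive_scalar(protocol$ascan_rate_hz))
    stop_retoct("A-scan rate must be positive", "retoct_domain_error")
  if (!is_count(protocol$n_ascans_per_bscan))
    stop_retoct("number of A-scans must be a positive integer",
                "retoct_domain_error")
  if (!is_nonneg_scalar(protocol$flyback_time_s))
    stop_retoct("flyback time must be non-negative", "retoct_domain_error")
  1e3 * (protocol$n_ascans_per_bscan / protocol$ascan_rate_hz +
           protocol$flyback_time_s)
}

#' @rdname optics
#' @param telescope a telescope description, see [telescope_spec()].
#' @return `reduced_beam_diameter_mm`: the demagnified beam diameter on the
#'   pupil, `input * f2 / f1`, in mm.
#' @export
reduced_beam_diameter_mm <- function(telescope) {
  if (!is_positive_scalar(telescope$input_beam_diameter_mm) ||
      !is_positive_scalar(telescope$focal_length_1_mm) ||
      !is_positive_scalar(telescope$focal_length_2_mm))
    stop_retoct("telescope parameters must be positive", "retoct_domain_error")
  telescope$input_beam_diameter_mm *
    telescope$focal_length_2_mm / telescope$focal_length_1_mm
}

#' @rdname optics
#' @param beam_diameter_mm beam diameter incident on the pupil, mm. Defaults
#'   to the output of [reduced_beam_diameter_mm()] on the default telescope.
#' @details The lateral resolution is the Gaussian 1/e^2 focal-spot diameter
#'   `4 * lambda * f_eye / (pi * d)`. With the default telescope and protocol
#'   this evaluates to 5.6 um (to one decimal).
#' @return `theoretical_lateral_resolution_um`: focal-spot diameter in um.
#' @export
theoretical_lateral_resolution_um <- function(protocol,
                                              beam_diameter_mm =
                                                reduced_beam_diameter_mm(telescope_spec())) {
  if (!is_positive_scalar(beam_diameter_mm))
    stop_retoct("beam diameter must be positive", "retoct_domain_error")
  if (!is_positive_scalar(protocol$center_wavelength_nm) ||
      !is_positive_scalar(protocol$eye_focal_length_mm))
    stop_retoct("wavelength and eye focal length must be positive",
                "retoct_domain_error")
  lambda_um <- protocol$center_wavelength_nm * 1e-3
  f_um <- protocol$eye_focal_length_mm * 1e3
  d_um <- beam_diameter_mm * 1e3
  4 * lambda_um * f_um / (pi * d_um)
}

#' @rdname optics
#' @param metadata an acquisition metadata object or protocol list carrying
#'   `fov_x_mm`, `fov_y_mm`, `n_ascans_per_bscan`, `n_bscan_locations`.
#' @return `pixel_pitch_um`: named numeric `c(x = , y = )` en-face pitches
#'   in um (fast axis x, slow axis y).
#' @export
pixel_pitch_um <- function(metadata) {
  if (!is_count(metadata$n_ascans_per_bscan) ||
      !is_count(metadata$n_bscan_locations))
    stop_retoct("sample counts must be positive integers",
                "retoct_domain_error")
  if (!is_positive_scalar(metadata$fov_x_mm) ||
      !is_positive_scalar(metadata$fov_y_mm))
    stop_retoct("field of view must be positive", "retoct_domain_error")
  c(x = 1e3 * metadata$fov_x_mm / metadata$n_ascans_per_bscan,
    y = 1e3 * metadata$fov_y_mm / metadata$n_bscan_locations)
}

#' Print all derived protocol quantities
#'
#' @param protocol see [scan_protocol()].
#' @param telescope see [telescope_spec()].
#' @return invisibly, a data.frame of quantity/value/unit rows.
#' @export
protocol_report <- function(protocol = scan_protocol(),
                            telescope = telescope_spec()) {
  d <- reduced_beam_diameter_mm(telescope)
  pp <- pixel_pitch_um(protocol)
  out <- data.frame(
    quantity = c("bscan_period_ms", "reduced_beam_diameter_mm",
                 "theoretical_lateral_resolution_um",
                 "pixel_pitch_x_um", "pixel_pitch_y_um"),
    value = c(bscan_period_ms(protocol), d,
              theoretical_lateral_resolution_um(protocol, d),
              pp[["x"]], pp[["y"]]),
    unit = c("ms", "mm", "um", "um", "um"),
    stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE)
  invisible(out)
}
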