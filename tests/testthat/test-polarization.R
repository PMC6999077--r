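# Phase retardation mapping and depolarizing-deposit screening.

test_that("retardation limits and homogeneity hold", {
  nr <- 2L; ny <- 2L; nx <- 2L; nz <- 4L
  mk <- function(aco, acr) {
    co <- array(complex(real = aco), c(nr, ny, nx, nz))
    cross <- array(complex(real = acr), c(nr, ny, nx, nz))
    md <- acquisition_metadata(n_ascans_per_bscan = nx,
                               n_bscan_locations = ny, n_repeats = nr)
    oct_volume(co, cross, md)
  }
  r45 <- compute_retardation(mk(1, 1), noise_floor = 0.01)
  expect_true(all(abs(r45$delta_deg - 45) < 1e-9))
  expect_true(all(compute_retardation(mk(1, 0), noise_floor = 0.01)$delta_deg == 0))
  expect_true(all(compute_retardation(mk(0, 1), noise_floor = 0.01)$delta_deg == 90))
  # invariance under simultaneous scaling of both channels
  r2 <- compute_retardation(mk(3, 3), noise_floor = 0.01)
  expect_equal(r2$delta_deg, r45$delta_deg)
  # literal channel-swap convention
  r_sw <- compute_retardation(mk(1, 0), noise_floor = 0.01,
                              swap_channels = TRUE)
  expect_true(all(r_sw$delta_deg == 90))
})

test_that("melanin voxels are uniform on [0, 90] and preserving tissue is low", {
  # noise-free phantom isolates the polarization split: the amplitude
  # ratio then recovers the drawn retardation angle exactly
  ph0 <- small_phantom(seed = 19L, motion_sigma_px = 0, noise_floor = 0,
                       n_y = 40L, n_x = 48L)
  ret0 <- compute_retardation(ph0$volume, noise_floor = 0)
  mel <- ph0$truth$melanin_mask & ret0$snr_mask
  d_mel <- ret0$delta_deg[mel]
  d_mel <- d_mel[!is.na(d_mel)]
  expect_gt(length(d_mel), 5000)
  ks <- suppressWarnings(stats::ks.test(d_mel, "punif", 0, 90))
  expect_gt(ks$p.value, 0.01)
  # with the noise floor present, SNR gating keeps preserving-tissue
  # retardation low: 95th percentile below 10 degrees
  ph <- small_phantom(seed = 19L, motion_sigma_px = 0, n_y = 40L, n_x = 48L)
  ret <- compute_retardation(ph$volume)
  pres <- !ph$truth$melanin_mask & ret$snr_mask
  d_p <- ret$delta_deg[pres]
  expect_lt(stats::quantile(d_p, 0.95, na.rm = TRUE), 10)
})

test_that("expected mask geometry: RPE slab and ONH cylinder", {
  ny <- 10L; nx <- 12L; nz <- 100L
  lm <- structure(list(ilm_px = matrix(20, ny, nx),
                       opl_px = matrix(50, ny, nx),
                       rpe_px = matrix(80, ny, nx),
                       valid = matrix(TRUE, ny, nx),
                       axial_pitch_um = 2), class = "layer_map")
  # no band, no margin, no ONH: pure half-space below the posterior RPE
  cfg0 <- pipeline_config(polarization = list(rpe_band_um = 0,
                                              rpe_margin_um = 0,
                                              onh_margin_um = 0))
  m0 <- build_expected_mask(lm, nz, c(x = 2, y = 2), config = cfg0)
  expect_true(all(m0[, , 80:100]))
  expect_false(any(m0[, , 1:79]))
  # band + margin move the ceiling up by (32 + 10) / 2 = 21 px
  m1 <- build_expected_mask(lm, nz, c(x = 2, y = 2))
  expect_true(all(m1[, , 59:100]))
  expect_false(any(m1[, , 1:58]))
  # ONH cylinder extends through all depths (margin 0 to probe the edge)
  cfg_onh <- pipeline_config(polarization = list(onh_margin_um = 0))
  m2 <- build_expected_mask(lm, nz, c(x = 2, y = 2),
                            onh_center_um = c(x = 12, y = 10),
                            onh_radius_um = 4, config = cfg_onh)
  expect_true(all(m2[5, 6, ]))     # pixel centre at (11, 9) um, r < 4
  expect_false(m2[1, 12, 10])      # pixel centre (23, 1) um, far outside
})

test_that("expected mask covers the phantom melanin and screening is clean", {
  ph <- small_phantom(seed = 20L, motion_sigma_px = 0)
  fl <- flatten_volume(ph$volume)
  lm <- segment_layers(fl$volume)
  ret <- compute_retardation(fl$volume)
  pp <- pixel_pitch_um(fl$volume$metadata)
  em <- build_expected_mask(lm, dim(ret$delta_deg)[3L], pp,
                            ph$truth$onh_center_um, ph$truth$onh_radius_um)
  # motion-free: flattening is a per-column roll by shift_px
  mel <- which(ph$truth$melanin_mask, arr.ind = TRUE)
  zf <- mel[, 3L] + fl$shift_px[mel[, 1:2, drop = FALSE]]
  ok <- zf >= 1 & zf <= dim(em)[3L]
  covered <- em[cbind(mel[ok, 1L], mel[ok, 2L], zf[ok])]
  expect_gte(mean(covered), 0.99)
  # no ectopic deposits configured: empty result
  dep <- screen_deposits(ret, em, lm, pp)
  expect_equal(nrow(dep), 0L)
})

test_that("an ectopic inner-retina deposit is found; undersized ones are not", {
  dep_cfg <- data.frame(x_um = c(300, 700), y_um = c(650, 300),
                        z_um = c(85, 85), radius_um = c(18, 10))
  ph <- generate_phantom(phantom_config(n_y = 60L, n_x = 64L, n_z = 256L,
                                        hrf = data.frame(),
                                        melanin_deposits = dep_cfg,
                                        motion_sigma_px = 0, seed = 21L))
  fl <- flatten_volume(ph$volume)
  lm <- segment_layers(fl$volume)
  ret <- compute_retardation(fl$volume)
  pp <- pixel_pitch_um(fl$volume$metadata)
  em <- build_expected_mask(lm, dim(ret$delta_deg)[3L], pp,
                            ph$truth$onh_center_um, ph$truth$onh_radius_um)
  found <- screen_deposits(ret, em, lm, pp)
  expect_equal(nrow(found), 1L)
  expect_lt(abs(found$x_um - 300), 8)
  expect_lt(abs(found$y_um - 650), 8)
  expect_equal(found$layer, "inner retina")
  # deposit count never increases with a stricter threshold or size floor
  n_prev <- Inf
  for (thr in c(20, 30, 45, 60)) {
    cfg <- pipeline_config(polarization = list(retardation_threshold_deg = thr))
    n <- nrow(screen_deposits(ret, em, lm, pp, cfg))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
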