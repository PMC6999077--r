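# Synthetic phantom generator: determinism, speckle statistics, the
# polarization split, flow decorrelation, and the cohort/histology
# generators.

test_that("identical seeds give bit-identical phantoms", {
  a <- small_phantom(seed = 9L)
  b <- small_phantom(seed = 9L)
  expect_identical(a$volume$co, b$volume$co)
  expect_identical(a$volume$cross, b$volume$cross)
  expect_identical(a$truth$axial_shift_px, b$truth$axial_shift_px)
  c <- small_phantom(seed = 10L)
  expect_false(identical(a$volume$co, c$volume$co))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(small_phantom(seed = 4L))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("speckle amplitude in a homogeneous slab is Rayleigh", {
  # noise-free, melanin-free, vessel-free slab: |c| ~ Rayleigh with
  # E|c|^2 = reflectivity^2
  ph <- generate_phantom(phantom_config(
    n_y = 50L, n_x = 64L, n_z = 128L,
    ilm_um = 30, inner_um = 120, outer_um = 60,
    reflectivity = list(rnfl = 1, inl = 1, opl = 1, onl = 1,
                        rpe_peak = 1, rpe_edge = 1, sclera = 0,
                        rnfl_um = 120, opl_band_um = 0.01,
                        melanin_band_um = 0.01),
    undulation_um = 0, onh = list(radius_um = 1e-6,
                                  remnant_radius_um = 1e-7),
    vessels = data.frame(plexus = character(0), x0_um = numeric(0),
                         y0_um = numeric(0), x1_um = numeric(0),
                         y1_um = numeric(0), radius_um = numeric(0),
                         decorrelation = numeric(0)),
    hrf = data.frame(), motion_sigma_px = 0, phase_jitter = FALSE,
    noise_floor = 0, seed = 77L))
  a <- abs(ph$volume$co[1L, , , ])
  zin <- 20:70                      # well inside the unit-reflectivity slab
  x <- c(a[, , zin])
  x <- x[x > 0]
  expect_gt(length(x), 1e5)
  x <- x[seq_len(1e5)]
  # Rayleigh CDF with E|c|^2 = 1: F(x) = 1 - exp(-x^2)
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - exp(-q^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("preserving tissue puts all signal in the co channel", {
  ph <- small_phantom(seed = 5L,
                      reflectivity = list(melanin_band_um = 0.01),
                      onh = list(remnant_radius_um = 1e-7),
                      noise_floor = 0)
  co_e <- sum(abs(ph$volume$co)^2)
  cross_e <- sum(abs(ph$volume$cross)^2)
  expect_lt(cross_e / (co_e + cross_e), 0.01)
})

test_that("flow decorrelation shows up only inside the vessel mask", {
  ves <- data.frame(plexus = "SVP", x0_um = 0, y0_um = 375, x1_um = 1000,
                    y1_um = 375, radius_um = 40, decorrelation = 1.0)
  ph <- generate_phantom(phantom_config(
    n_y = 24L, n_x = 32L, n_z = 128L,
    ilm_um = 50, inner_um = 65, outer_um = 45,
    reflectivity = list(rnfl_um = 20, opl_band_um = 10,
                        melanin_band_um = 16),
    vessels = ves, hrf = data.frame(),
    motion_sigma_px = 0, phase_jitter = FALSE, noise_floor = 0,
    seed = 21L))
  v <- ph$volume
  dif <- abs(v$co[2L, , , ] - v$co[1L, , , ])
  slab <- 26:31                     # SVP depths (ILM 50 um + 20 um slab)
  vm <- ph$truth$vessel_enface$SVP
  inside <- mean(dif[, , slab][array(vm, c(24, 32, length(slab)))])
  outside <- mean(dif[, , slab][array(!vm, c(24, 32, length(slab)))])
  expect_equal(outside, 0)
  expect_gt(inside, 0.5)
})

test_that("phantom truth is self-consistent", {
  ph <- small_phantom(seed = 2L)
  tr <- ph$truth
  # boundaries strictly ordered everywhere
  expect_true(all(tr$ilm_px < tr$opl_px))
  expect_true(all(tr$opl_px < tr$rpe_px))
  # HRF volumes equal voxel count x voxel volume
  for (r in tr$hrf)
    expect_equal(r$volume_um3,
                 length(r$voxels) * prod(tr$pitch_um))
  # invalid config rejected
  expect_error(phantom_config(ilm_um = 400, inner_um = 130, outer_um = 90,
                              n_z = 256L),
               class = "retoct_validation_error")
  expect_error(phantom_config(vessels = data.frame(
    plexus = "SVP", x0_um = 0, y0_um = 0, x1_um = 1, y1_um = 1,
    radius_um = 5, decorrelation = 1.5)),
    class = "retoct_validation_error")
})

test_that("cohort generator recovers configured slopes exactly at sigma 0", {
  cfg <- cohort_config(groups = list(
    transgenic = list(n_eyes = 20L, age_range_weeks = c(45, 104),
                      baseline_um = 240, slope_um_per_week = 0.37,
                      sigma_um = 0),
    wildtype = list(n_eyes = 20L, age_range_weeks = c(45, 104),
                    baseline_um = 240, slope_um_per_week = 0.26,
                    sigma_um = 0)), seed = 8L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 40L)
  tg <- coh[coh$group == "transgenic", ]
  fit <- fit_age_pretest(tg, "total_whole")
  expect_equal(fit$slope, -0.37, tolerance = 1e-10)
  # total = inner + outer in every region by construction
  for (rg in c("whole", "superior", "inferior"))
    expect_equal(coh[[paste0("total_", rg)]],
                 coh[[paste0("inner_", rg)]] + coh[[paste0("outer_", rg)]])
  expect_error(cohort_config(groups = list(
    a = list(n_eyes = 1L, age_range_weeks = c(1, 2), baseline_um = 1,
             slope_um_per_week = 0, sigma_um = 0))),
    class = "retoct_validation_error")
})

test_that("histology image generator honours the truth count", {
  g <- generate_histology_image(0, seed = 3L)
  q0 <- segment_plaques(g$image, px_size_um = g$px_size_um)
  expect_equal(q0$plaque_count, 0L)
  g1 <- generate_histology_image(12, seed = 3L)
  g2 <- generate_histology_image(12, seed = 3L)
  expect_identical(g1$image, g2$image)
  expect_equal(nrow(g1$truth), 12L)
  # crowding beyond geometric capacity raises
  expect_error(generate_histology_image(500, field_area_mm2 = 0.04,
                                        seed = 1L, max_tries = 300L),
               class = "retoct_validation_error")
})
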