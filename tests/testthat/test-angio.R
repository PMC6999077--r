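# Angiography: bulk phase correction, complex-difference computation,
# en-face projection, the binarization pipeline, and vessel metrics.

make_repeats <- function(seed = 1L, nr = 4L, nx = 16L, nz = 32L) {
  set.seed(seed)
  base <- matrix(complex(real = rnorm(nx * nz), imaginary = rnorm(nx * nz)),
                 nx, nz)
  reps <- array(complex(real = 0), c(nr, nx, nz))
  for (r in seq_len(nr)) reps[r, , ] <- base
  list(base = base, reps = reps)
}

test_that("a pure global phase is removed and leaves zero decorrelation", {
  mk <- make_repeats()
  reps <- mk$reps
  phases <- c(0, 1.1, -2.3, 0.7)
  for (r in 1:4) reps[r, , ] <- reps[r, , ] * exp(1i * phases[r])
  bc <- bulk_phase_correct(reps)
  expect_length(bc$excluded, 0L)
  octa <- compute_octa(bc$repeats)
  expect_lt(max(octa), 1e-10)
})

test_that("a noise-replaced repeat is screened out", {
  mk <- make_repeats(seed = 2L)
  reps <- mk$reps
  set.seed(99)
  reps[3L, , ] <- matrix(complex(real = rnorm(16 * 32),
                                 imaginary = rnorm(16 * 32)), 16, 32)
  bc <- bulk_phase_correct(reps)
  expect_equal(bc$excluded, 3L)
  expect_equal(dim(bc$repeats)[1L], 3L)
  # static repeats, no corruption: nothing excluded
  bc0 <- bulk_phase_correct(mk$reps)
  expect_length(bc0$excluded, 0L)
})

test_that("the decorrelation image is the mean magnitude of differences", {
  reps <- array(complex(real = 0), c(2L, 1L, 1L))
  reps[1L, 1L, 1L] <- 3 + 4i
  reps[2L, 1L, 1L] <- 0
  expect_equal(as.numeric(compute_octa(reps)), 5)
  # identical repeats give the zero image
  mk <- make_repeats(seed = 3L)
  expect_equal(max(compute_octa(mk$reps)), 0)
  expect_error(compute_octa(mk$reps[1L, , , drop = FALSE]),
               class = "retoct_validation_error")
})

test_that("octa is invariant to a global phase on all repeats", {
  mk <- make_repeats(seed = 4L, nr = 3L)
  reps <- mk$reps
  reps[2L, , ] <- reps[2L, , ] * 1.0001   # slight difference to see signal
  o1 <- compute_octa(bulk_phase_correct(reps)$repeats)
  reps2 <- reps * exp(1i * 0.83)
  o2 <- compute_octa(bulk_phase_correct(reps2)$repeats)
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("en-face projection takes the slab maximum per A-scan", {
  ny <- 6L; nx <- 8L; nz <- 64L
  octa <- array(0, c(ny, nx, nz))
  lm <- structure(list(ilm_px = matrix(20, ny, nx),
                       opl_px = matrix(40, ny, nx),
                       rpe_px = matrix(55, ny, nx),
                       valid = matrix(TRUE, ny, nx),
                       axial_pitch_um = 2), class = "layer_map")
  expect_equal(enface_projection(octa, lm, "SVP"), matrix(0, ny, nx))
  octa[3L, 4L, 25L] <- 7          # inside the SVP slab [20, 30]
  ef <- enface_projection(octa, lm, "SVP")
  expect_equal(ef[3L, 4L], 7)
  expect_equal(sum(ef), 7)
  # DCP slab [opl - 15 um, opl] does not see it
  ef_d <- enface_projection(octa, lm, "DCP")
  expect_equal(sum(ef_d), 0)
})

test_that("binarization of a bright bar gives the 5-px dilated skeleton", {
  ny <- 48L; nx <- 48L
  img <- matrix(0, ny, nx)
  img[23:25, 5:44] <- 1                      # horizontal 3-px-thick bar
  img <- img + 0.02 * matrix(runif(ny * nx, 0, 1), ny, nx)
  bv <- binarize_vessels(img)
  # oracle: skeleton of the bar is its centreline; the final map is the
  # centreline dilated by a 5 x 5 square (computed by brute force)
  expect_true(all(bv$skeleton[24, 7:42]))
  oracle <- brute_square_dilate(bv$skeleton, 5L)
  expect_identical(bv$final, oracle)
  expect_error(binarize_vessels(matrix(0.3, 8, 8)),
               class = "retoct_no_contrast_error")
})

test_that("vessel density equals brute-force pixel counting", {
  cfg <- pipeline_config(annulus = list(inner_diameter_um = 20,
                                        outer_diameter_um = 60))
  ann <- build_annulus(c(40L, 40L), c(x = 2, y = 2), c(x = 40, y = 40), cfg)
  set.seed(6)
  final <- matrix(runif(1600) < 0.3, 40L, 40L)
  vd <- vessel_density(final, ann)
  brute <- function(mask) {
    hit <- 0L; tot <- 0L
    for (y in 1:40) for (x in 1:40)
      if (mask[y, x]) { tot <- tot + 1L; if (final[y, x]) hit <- hit + 1L }
    100 * hit / tot
  }
  expect_equal(vd[["whole"]], brute(ann$annulus))
  expect_equal(vd[["superior"]], brute(ann$superior))
  expect_equal(vd[["inferior"]], brute(ann$inferior))
  # exact identity: whole density is the count-weighted mean of the halves
  expect_equal(vd[["whole"]],
               (vd[["superior"]] * sum(ann$superior) +
                  vd[["inferior"]] * sum(ann$inferior)) / sum(ann$annulus))
})

test_that("degenerate vessel maps give 0 or 100 percent", {
  cfg <- pipeline_config(annulus = list(inner_diameter_um = 20,
                                        outer_diameter_um = 60))
  ann <- build_annulus(c(40L, 40L), c(x = 2, y = 2), c(x = 40, y = 40), cfg)
  all_v <- matrix(TRUE, 40L, 40L)
  expect_equal(unname(vessel_density(all_v, ann)), c(100, 100, 100))
  none <- matrix(FALSE, 40L, 40L)
  expect_equal(unname(vessel_density(none, ann)), c(0, 0, 0))
  # vessels filling exactly the superior half
  sup_only <- ann$superior
  vd <- vessel_density(sup_only, ann)
  expect_equal(vd[["superior"]], 100)
  expect_equal(vd[["inferior"]], 0)
  expect_equal(vd[["whole"]], 100 * sum(ann$superior) / sum(ann$annulus))
})

test_that("Weber contrast is the background-normalised vessel excess", {
  cfg <- pipeline_config(annulus = list(inner_diameter_um = 0,
                                        outer_diameter_um = 60))
  ann <- build_annulus(c(40L, 40L), c(x = 2, y = 2), c(x = 40, y = 40), cfg)
  raw <- matrix(1, 40L, 40L)
  final <- matrix(FALSE, 40L, 40L)
  final[18:22, ] <- TRUE
  raw[final] <- 2
  expect_equal(weber_contrast(raw, final, ann), 1.0)
  raw[] <- 1
  expect_equal(weber_contrast(raw, final, ann), 0)
  expect_error(weber_contrast(raw, matrix(TRUE, 40L, 40L), ann),
               class = "retoct_validation_error")
})
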