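# Layer segmentation, annulus construction, and thickness metrics.

test_that("noise-free step retina is recovered exactly", {
  v <- step_volume(ilm = 50L, opl = 120L, rpe = 180L, band = 16L)
  cfg <- pipeline_config(preprocess = list(flatten_target_fraction = 172 / 256))
  lm <- segment_layers(v, cfg)
  expect_true(all(lm$ilm_px == 50))
  expect_true(all(lm$opl_px == 120))
  expect_true(all(lm$rpe_px == 180))
  expect_true(all(lm$valid))
  # inner + outer = total everywhere, by construction
  tot <- (lm$rpe_px - lm$ilm_px)
  expect_equal((lm$opl_px - lm$ilm_px) + (lm$rpe_px - lm$opl_px), tot)
})

test_that("annulus mask equals the brute-force physical-distance oracle", {
  cfg <- pipeline_config()
  dims <- c(60L, 50L)
  for (pitch in list(c(x = 2, y = 2), c(x = 1.6, y = 2.4))) {
    center <- c(x = 25 * pitch[["x"]], y = 30 * pitch[["y"]])
    fits <- center[["x"]] - 450 >= 0 &&
      center[["x"]] + 450 <= dims[2L] * pitch[["x"]]
    cfgs <- pipeline_config(annulus = list(inner_diameter_um = 30,
                                           outer_diameter_um = 70))
    ann <- build_annulus(dims, pitch, center, cfgs)
    # brute force: explicit loop over every pixel centre
    oracle <- matrix(FALSE, dims[1L], dims[2L])
    for (y in seq_len(dims[1L])) for (x in seq_len(dims[2L])) {
      dx <- (x - 0.5) * pitch[["x"]] - center[["x"]]
      dy <- (y - 0.5) * pitch[["y"]] - center[["y"]]
      r <- sqrt(dx^2 + dy^2)
      oracle[y, x] <- r >= 15 && r < 35
    }
    expect_identical(ann$annulus, oracle)
    # halves partition the annulus
    expect_identical(ann$superior | ann$inferior, ann$annulus)
    expect_false(any(ann$superior & ann$inferior))
    expect_equal(sum(ann$superior) + sum(ann$inferior), sum(ann$annulus))
  }
})

test_that("degenerate annuli are handled", {
  pitch <- c(x = 2, y = 2)
  cfg0 <- pipeline_config(annulus = list(inner_diameter_um = 40,
                                         outer_diameter_um = 40))
  ann <- build_annulus(c(50L, 50L), pitch, c(x = 50, y = 50), cfg0)
  expect_equal(sum(ann$annulus), 0L)
  # annulus clipped by the field of view is refused with the clipped share
  cfg_big <- pipeline_config(annulus = list(inner_diameter_um = 50,
                                            outer_diameter_um = 300))
  expect_error(build_annulus(c(50L, 50L), pitch, c(x = 50, y = 50), cfg_big),
               regexp = "clipped", class = "retoct_validation_error")
})

test_that("annulus split orientation rotates the halves", {
  pitch <- c(x = 2, y = 2)
  center <- c(x = 50, y = 50)
  cfg90 <- pipeline_config(annulus = list(inner_diameter_um = 20,
                                          outer_diameter_um = 60,
                                          split_orientation_deg = 90))
  ann90 <- build_annulus(c(50L, 50L), pitch, center, cfg90)
  # at 90 deg the split line is vertical: superior = nasal/temporal half
  sup_px <- which(ann90$superior, arr.ind = TRUE)
  expect_true(all((sup_px[, 2L] - 0.5) * 2 - 50 >= 0 |
                    abs((sup_px[, 2L] - 0.5) * 2 - 50) < 2))
})

test_that("thickness metrics are exact on a constant-thickness phantom", {
  v <- step_volume(ilm = 50L, opl = 115L, rpe = 160L, band = 16L)
  # the coarse 8 x 16 grid has 125 x 62.5 um pixels; the ring must span
  # several pixel centres in both halves
  cfg <- pipeline_config(annulus = list(inner_diameter_um = 0,
                                        outer_diameter_um = 400))
  lm <- segment_layers(v, cfg)
  pitch <- pixel_pitch_um(v$metadata)
  ann <- build_annulus(dim(lm$ilm_px), pitch,
                       c(x = 8 * pitch[["x"]], y = 4 * pitch[["y"]]), cfg)
  th <- compute_thickness(lm, ann, eye_id = "e1", group = "wildtype",
                          age_weeks = 70)
  # 110 px x 2 um = 220 um total; 65 px inner = 130 um; 45 px outer = 90 um
  for (rg in c("whole", "superior", "inferior")) {
    expect_equal(th[[paste0("total_", rg)]], 220)
    expect_equal(th[[paste0("inner_", rg)]], 130)
    expect_equal(th[[paste0("outer_", rg)]], 90)
  }
})

test_that("regional thinning shows up in the superior half only", {
  # construct a layer map directly: superior rows 10 um thinner
  ny <- 40L; nx <- 40L
  lm <- structure(list(
    ilm_px = matrix(50, ny, nx),
    opl_px = matrix(115, ny, nx),
    rpe_px = matrix(160, ny, nx),
    valid = matrix(TRUE, ny, nx),
    axial_pitch_um = 2), class = "layer_map")
  lm$rpe_px[1:20, ] <- 155           # superior = low y rows
  cfg <- pipeline_config(annulus = list(inner_diameter_um = 20,
                                        outer_diameter_um = 60))
  ann <- build_annulus(c(ny, nx), c(x = 2, y = 2), c(x = 40, y = 40), cfg)
  th <- compute_thickness(lm, ann)
  expect_equal(th$total_superior, 210)
  expect_equal(th$total_inferior, 220)
  expect_equal(th$total_whole,
               (210 * sum(ann$superior) + 220 * sum(ann$inferior)) /
                 sum(ann$annulus))
  # empty valid region raises
  lm$valid[] <- FALSE
  expect_error(compute_thickness(lm, ann), class = "retoct_validation_error")
})
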