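#' Generate a synthetic immunostained brightfield image
#'
#' A tissue-pink background with `n_plaques` non-overlapping brown disks
#' of randomized radii, emulating DAB-stained amyloid plaques in a
#' paraffin cortex section. Pixel colours carry mild Gaussian noise; the
#' truth count equals `n_plaques` by construction.
#'
#' @param n_plaques number of plaques (>= 0).
#' @param field_area_mm2 imaged field area; the image is square.
#' @param px_size_um pixel size, um.
#' @param radius_range_um plaque radius range (uniform), um.
#' @param noise_sd channel noise SD.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget for non-overlapping
#'   placement; exceeded -> validation error (field too crowded).
#' @return list: `image` (array `[y, x, 3]`, RGB in `[0, 1]`), `truth`
#'   (data.frame of centres/radii), `n_plaques`, `px_size_um`,
#'   `field_area_mm2`.
#' @export
generate_histology_image <- function(n_plaques, field_area_mm2 = 1,
                                     px_size_um = 2,
                                     radius_range_um = c(12, 40),
                                     noise_sd = 0.015, seed = 1L,
                                     max_tries = 2000L) {
  if (!is.numeric(n_plaques) || n_plaques < 0 || n_plaques != round(n_plaques))
    stop_retoct("n_plaques must be a non-negative integer",
                "retoct_validation_error")
  force(seed)     # before the RNG state snapshot: the argument may draw
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  side_um <- sqrt(field_area_mm2) * 1e3
  n <- max(8L, round(side_um / px_size_um))
  bg <- c(0.93, 0.76, 0.82)    # eosin-pink tissue
  brown <- c(0.48, 0.30, 0.12) # DAB reaction product
  img <- array(rep(bg, each = n * n), c(n, n, 3L))
  cx <- cy <- r <- numeric(0)
  if (n_plaques > 0) {
    tries <- 0L
    while (length(r) < n_plaques) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_retoct("field too small to place non-overlapping plaques",
                    "retoct_validation_error")
      rr <- stats::runif(1, radius_range_um[1L], radius_range_um[2L])
      px <- stats::runif(1, rr, side_um - rr)
      py <- stats::runif(1, rr, side_um - rr)
      if (length(r) &&
          any(sqrt((cx - px)^2 + (cy - py)^2) < (r + rr) + 2 * px_size_um))
        next
      cx <- c(cx, px); cy <- c(cy, py); r <- c(r, rr)
    }
    cc <- pixel_centers_um(n, n, px_size_um, px_size_um)
    X <- matrix(cc$x, n, n, byrow = TRUE)
    Y <- matrix(cc$y, n, n)
    for (i in seq_len(n_plaques)) {
      disk <- (X - cx[i])^2 + (Y - cy[i])^2 <= r[i]^2
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[disk] <- brown[ch]
        img[, , ch] <- pl
      }
    }
  }
  if (noise_sd > 0)
    img <- pmin(1, pmax(0, img + stats::rnorm(length(img), 0, noise_sd)))
  dim(img) <- c(n, n, 3L)
  list(image = img,
       truth = data.frame(x_um = cx, y_um = cy, radius_um = r),
       n_plaques = as.integer(n_plaques),
       px_size_um = px_size_um, field_area_mm2 = field_area_mm2)
}

#' Segment brown plaques and compute the plaque load
#'
#' Re-implementation of colour-window segmentation plus particle counting:
#' pixels are converted to HSV and selected by a brown window (hue inside
#' `hue_deg`, saturation above `min_saturation`, value below `max_value`);
#' connected components inside the region mask with at least the minimum
#' equivalent area are counted, and the load is count per mm^2 of region
#' area.
#'
#' @param image RGB array `[y, x, 3]` in `[0, 1]`.
#' @param region_mask logical `[y, x]` analysis region (e.g. the cortex);
#'   `NULL` selects the full field.
#' @param px_size_um pixel size in um (required).
#' @param config a [pipeline_config()] (section `histology`).
#' @param image_id,age_weeks record labels.
#' @return a one-row data.frame of class `plaque_quantification`:
#'   `plaque_count`, `region_area_mm2`, `plaque_load_per_mm2`, labels; the
#'   label matrix is attached as attribute `labels`.
#' @export
segment_plaques <- function(image, region_mask = NULL, px_size_um,
                            config = pipeline_config(),
                            image_id = "img", age_weeks = NA_real_) {
  if (missing(px_size_um) || !is_positive_scalar(px_size_um))
    stop_retoct("pixel size (um) is required", "retoct_validation_error")
  hc <- config$histology
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop_retoct("image must be an RGB array [y, x, 3]",
                "retoct_validation_error")
  if (is.null(region_mask)) region_mask <- matrix(TRUE, d[1L], d[2L])
  if (!any(region_mask))
    stop_retoct("region mask is empty", "retoct_validation_error")
  rgb <- rbind(c(image[, , 1L]), c(image[, , 2L]), c(image[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1L, ] * 360
  sel <- hue >= hc$hue_deg[1L] & hue <= hc$hue_deg[2L] &
    hsv[2L, ] > hc$min_saturation & hsv[3L, ] < hc$max_value
  selm <- matrix(sel, d[1L], d[2L]) & region_mask
  lab <- EBImage::bwlabel(EBImage::Image(selm * 1))
  labm <- EBImage::imageData(lab)
  min_px <- hc$min_area_um2 / (px_size_um^2)
  if (max(labm) > 0) {
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= min_px)
    count <- length(keep)
    labm[!(labm %in% keep)] <- 0L
  } else count <- 0L
  area_mm2 <- sum(region_mask) * (px_size_um^2) / 1e6
  out <- data.frame(image_id = image_id, age_weeks = age_weeks,
                    plaque_count = as.integer(count),
                    region_area_mm2 = area_mm2,
                    plaque_load_per_mm2 = count / area_mm2,
                    stringsAsFactors = FALSE)
  structure(out, labels = labm,
            class = c("plaque_quantification", "data.frame"))
}

#' Fit the plaque-load-versus-age trend
#'
#' Ordinary least squares of plaque load (plaques/mm^2) on age (weeks).
#'
#' @param quantifications data.frame with columns `age_weeks` and
#'   `plaque_load_per_mm2` (rows from [segment_plaques()]).
#' @return list of class `plaque_age_trend`: `slope` (plaques/mm^2/week),
#'   `intercept`, `r_squared`, `p_value` (slope t-test), `n`.
#' @export
fit_plaque_trend <- function(quantifications) {
  y <- quantifications$plaque_load_per_mm2
  x <- quantifications$age_weeks
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3L || length(unique(x)) < 2L)
    stop_retoct("trend fit needs >= 3 images with >= 2 distinct ages",
                "retoct_validation_error")
  if (stats::sd(y) < 1e-12)  # constant load: no trend, no evidence
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, n = length(y)),
                     class = "plaque_age_trend"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- unname(sm$coefficients["x", "Pr(>|t|)"])
  if (!is.finite(p))  # degenerate zero-residual fit
    p <- if (abs(slope) < 1e-12) 1 else 0
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 n = length(y)),
            class = "plaque_age_trend")
}
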