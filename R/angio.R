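#' Bulk-motion phase correction of repeated B-scans
#'
#' For each adjacent pair of repeats the global (bulk) phase offset is the
#' argument of the inner product `sum(C[i+1] * Conj(C[i]))`; repeat `i+1`
#' is rotated by its conjugate so all repeats share the phase of the
#' first. A repeat whose post-correction mean complex difference against
#' the pixel-wise median repeat, normalised by the median repeat's mean
#' amplitude, exceeds the configured threshold is excluded (the analogue
#' of screening out frames with uncorrectable motion).
#'
#' @param repeats complex array `[repeat, x, z]` of one B-scan location.
#' @param config a [pipeline_config()] (section `angio`).
#' @return list with `repeats` (corrected, retained, `[repeat, x, z]`),
#'   `excluded` (indices of dropped repeats), `phases` (applied
#'   corrections, radians).
#' @export
bulk_phase_correct <- function(repeats, config = pipeline_config()) {
  d <- dim(repeats)
  if (length(d) != 3L || d[1L] < 2L)
    stop_retoct("need a [repeat, x, z] array with >= 2 repeats",
                "retoct_validation_error")
  nr <- d[1L]
  corr <- repeats
  phases <- numeric(nr)
  for (i in 2:nr) {
    ip <- sum(corr[i, , ] * Conj(corr[i - 1L, , ]))
    phases[i] <- Arg(ip)
    corr[i, , ] <- corr[i, , ] * exp(-1i * phases[i])
  }
  med <- apply_pixel_median(corr)
  denom <- mean(abs(med))
  score <- vapply(seq_len(nr), function(r)
    mean(abs(corr[r, , ] - med)) / max(denom, .Machine$double.eps),
    numeric(1L))
  keep <- score <= config$angio$repeat_exclusion_threshold
  if (sum(keep) < 2L)
    stop_retoct("fewer than 2 repeats retained after motion screening",
                "retoct_exclusion_error")
  list(repeats = corr[keep, , , drop = FALSE],
       excluded = which(!keep), phases = phases, score = score)
}

# Pixel-wise median repeat (median of real and imaginary parts), via a
# pmin/pmax sorting network over the (small) repeat dimension.
apply_pixel_median <- function(corr) {
  d <- dim(corr)
  nr <- d[1L]
  med_of_rows <- function(x) {   # x: [nr, npix] numeric
    v <- lapply(seq_len(nr), function(r) x[r, ])
    for (i in seq_len(nr - 1L)) for (j in seq_len(nr - i)) {
      lo <- pmin(v[[j]], v[[j + 1L]])
      v[[j + 1L]] <- pmax(v[[j]], v[[j + 1L]])
      v[[j]] <- lo
    }
    if (nr %% 2L) v[[(nr + 1L) %/% 2L]]
    else (v[[nr %/% 2L]] + v[[nr %/% 2L + 1L]]) / 2
  }
  flat <- matrix(corr, nr, d[2L] * d[3L])
  matrix(complex(real = med_of_rows(Re(flat)),
                 imaginary = med_of_rows(Im(flat))), d[2L], d[3L])
}

#' Compute the decorrelation (angiography) B-scan
#'
#' The motion-contrast image is the averaged magnitude of the complex
#' differences between consecutive retained repeats:
#' `OCTA(x, z) = mean_i |C[i+1](x, z) - C[i](x, z)|`.
#'
#' @param repeats corrected complex array `[repeat, x, z]` (>= 2 repeats),
#'   e.g. the `repeats` element of [bulk_phase_correct()].
#' @return numeric matrix `[x, z]` with attribute `n_pairs`.
#' @export
compute_octa <- function(repeats) {
  d <- dim(repeats)
  if (length(d) != 3L || d[1L] < 2L)
    stop_retoct("need >= 2 retained repeats", "retoct_validation_error")
  nr <- d[1L]
  acc <- matrix(0, d[2L], d[3L])
  for (i in seq_len(nr - 1L))
    acc <- acc + abs(repeats[i + 1L, , ] - repeats[i, , ])
  structure(acc / (nr - 1L), n_pairs = nr - 1L)
}

#' Compute the full angiography volume
#'
#' Applies [bulk_phase_correct()] and [compute_octa()] to the co channel
#' of every B-scan location.
#'
#' @param volume an [oct_volume()] (typically flattened).
#' @param config a [pipeline_config()].
#' @return list: `octa` array `[y, x, z]`, `excluded` list of per-location
#'   dropped repeat indices.
#' @export
compute_octa_volume <- function(volume, config = pipeline_config()) {
  d <- dim(volume$co)
  ny <- d[2L]
  octa <- array(0, d[2:4])
  excl <- vector("list", ny)
  for (y in seq_len(ny)) {
    reps <- volume$co[, y, , ]
    bc <- bulk_phase_correct(reps, config)
    octa[y, , ] <- compute_octa(bc$repeats)
    excl[[y]] <- bc$excluded
  }
  list(octa = octa, excluded = excl)
}

#' Maximum-intensity en-face projection over a plexus slab
#'
#' SVP: `[ILM, ILM + svp_slab_um]`; DCP: `[posterior OPL - dcp_slab_um,
#' posterior OPL]`, per A-scan, following the segmented boundaries.
#'
#' @param octa `[y, x, z]` decorrelation volume (see
#'   [compute_octa_volume()]).
#' @param layer_map a [segment_layers()] result.
#' @param plexus `"SVP"` or `"DCP"`.
#' @param config a [pipeline_config()].
#' @return numeric matrix `[y, x]`.
#' @export
enface_projection <- function(octa, layer_map, plexus = c("SVP", "DCP"),
                              config = pipeline_config()) {
  plexus <- match.arg(plexus)
  d <- dim(octa)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  p <- layer_map$axial_pitch_um
  if (plexus == "SVP") {
    z0 <- layer_map$ilm_px
    z1 <- layer_map$ilm_px + round(config$angio$svp_slab_um / p)
  } else {
    z0 <- layer_map$opl_px - round(config$angio$dcp_slab_um / p)
    z1 <- layer_map$opl_px
  }
  z0 <- matrix(pmax(1L, pmin(nz, round(z0))), ny, nx)
  z1 <- matrix(pmax(1L, pmin(nz, round(z1))), ny, nx)
  if (any(z1 < z0))
    stop_retoct("empty projection slab", "retoct_validation_error")
  n_off <- max(z1 - z0) + 1L
  out <- matrix(-Inf, ny, nx)
  yi <- row(z0); xi <- col(z0)
  for (k in 0:(n_off - 1L)) {
    zk <- z0 + k
    sel <- zk <= z1
    idx <- cbind(yi[sel], xi[sel], zk[sel])
    vals <- octa[idx]
    cur <- out[cbind(yi[sel], xi[sel])]
    out[cbind(yi[sel], xi[sel])] <- pmax(cur, vals)
  }
  out
}

#' Binarize an en-face angiogram into a vessel map
#'
#' The pipeline: contrast-limited adaptive histogram equalization, global
#' Otsu threshold, morphological opening then closing with a radius-1 disc
#' element, skeletonization (Zhang-Suen thinning), and a 5-pixel square
#' averaging filter whose positive support defines the final binary
#' vessel map (equivalently, dilation of the skeleton by a 5 x 5 square).
#'
#' @param raw numeric `[y, x]` en-face image.
#' @param config a [pipeline_config()] (section `angio`).
#' @return an object of class `angio_enface`: `raw`, `equalized`,
#'   `binary`, `skeleton`, `final` (all `[y, x]`, the last three logical).
#' @export
binarize_vessels <- function(raw, config = pipeline_config()) {
  if (!length(raw) || diff(range(raw)) == 0)
    stop_retoct("no contrast in en-face image", "retoct_no_contrast_error")
  ac <- config$angio
  norm <- (raw - min(raw)) / diff(range(raw))
  eq <- clahe_pad(norm, ac$clahe_tiles, ac$clahe_limit)
  thr <- EBImage::otsu(EBImage::Image(eq), range = c(0, 1))
  bin <- eq > thr
  brush <- EBImage::makeBrush(3L, shape = ac$open_close_brush)
  opened <- EBImage::opening(EBImage::Image(bin * 1), brush)
  closed <- EBImage::closing(opened, brush)
  binm <- EBImage::imageData(closed) > 0.5
  skel <- skeletonize_zs(binm)
  fin <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(skel * 1),
                    EBImage::makeBrush(5L, shape = "box"))) > 0.5
  structure(list(raw = raw, equalized = eq, binary = binm,
                 skeleton = skel, final = fin),
            class = "angio_enface")
}

# CLAHE with edge-replicated padding to a tile-divisible size.
clahe_pad <- function(img, tiles, limit) {
  ny <- nrow(img); nx <- ncol(img)
  py <- ceiling(ny / tiles) * tiles
  px <- ceiling(nx / tiles) * tiles
  ri <- c(seq_len(ny), rep(ny, py - ny))
  ci <- c(seq_len(nx), rep(nx, px - nx))
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::clahe(EBImage::Image(padded), nx = tiles, ny = tiles,
                        limit = limit)
  EBImage::imageData(out)[seq_len(ny), seq_len(nx)]
}

#' Vessel density inside the annulus
#'
#' Percentage of pixels marked vessel in the whole annulus and in its
#' superior and inferior halves.
#'
#' @param final logical `[y, x]` vessel map (`final` element of
#'   [binarize_vessels()]).
#' @param annulus a [build_annulus()] result.
#' @return named numeric `c(whole = , superior = , inferior = )` in percent.
#' @export
vessel_density <- function(final, annulus) {
  regions <- list(whole = annulus$annulus, superior = annulus$superior,
                  inferior = annulus$inferior)
  vapply(regions, function(m) {
    n <- sum(m)
    if (n == 0L)
      stop_retoct("empty annulus region", "retoct_validation_error")
    100 * sum(final & m) / n
  }, numeric(1L))
}

#' Modified Weber contrast of an angiogram
#'
#' `C_W = (Iv - Ib) / Ib` with `Iv` (`Ib`) the mean raw en-face intensity
#' over vessel (non-vessel) pixels inside the annulus. Computed on the raw
#' (pre-equalization) image so the metric audits the true angiogram
#' signal-to-background ratio.
#'
#' @param raw numeric `[y, x]` raw en-face image.
#' @param final logical `[y, x]` vessel map.
#' @param annulus a [build_annulus()] result.
#' @return scalar Weber contrast.
#' @export
weber_contrast <- function(raw, final, annulus) {
  sel_v <- annulus$annulus & final
  sel_b <- annulus$annulus & !final
  if (!any(sel_v) || !any(sel_b))
    stop_retoct("annulus must contain both vessel and background pixels",
                "retoct_validation_error")
  iv <- mean(raw[sel_v]); ib <- mean(raw[sel_b])
  if (ib == 0)
    stop_retoct("background intensity is zero", "retoct_validation_error")
  (iv - ib) / ib
}
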