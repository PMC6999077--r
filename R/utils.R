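# Internal numeric helpers shared across the pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_retoct <- function(msg, class) {
  stop(structure(class = c(class, "retoct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)

is_positive_scalar <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x > 0

is_nonneg_scalar <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 0

# Shift a vector along its only dimension by s, filling with `fill`.
shift_fill <- function(v, s, fill = 0) {
  n <- length(v)
  if (s == 0L) return(v)
  out <- rep(fill, n)
  if (s > 0) {
    if (s < n) out[(s + 1L):n] <- v[1L:(n - s)]
  } else {
    s <- -s
    if (s < n) out[1L:(n - s)] <- v[(s + 1L):n]
  }
  out
}

# Shift a matrix by (dy, dx) with edge replication (used by median filters).
mshift_replicate <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  ci <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  m[ri, ci, drop = FALSE]
}

# k x k moving median of a matrix, edges replicated. Used to regularise
# boundary depth maps laterally; k is odd.
median_filter2 <- function(m, k = 5L) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) mshift_replicate(m, offs$dy[i], offs$dx[i]),
                  m)
  apply(stack, c(1L, 2L), stats::median)
}

# Boxcar smoothing of each row of a matrix (rows = pixels, cols = depth),
# window w (odd), edges renormalised by the in-window count.
smooth_rows_boxcar <- function(m, w = 5L) {
  stopifnot(w %% 2L == 1L)
  r <- (w - 1L) %/% 2L
  nz <- ncol(m)
  acc <- matrix(0, nrow(m), nz)
  cnt <- numeric(nz)
  for (d in -r:r) {
    ci <- seq_len(nz) + d
    ok <- ci >= 1L & ci <= nz
    acc[, ok] <- acc[, ok] + m[, ci[ok], drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  sweep(acc, 2L, cnt, "/")
}

# Fill NA entries of a map with the median of valid values inside a window
# that grows until at least one valid neighbour is found.
fill_invalid_lateral <- function(m, invalid) {
  if (!any(invalid)) return(m)
  if (all(invalid)) stop_retoct("no valid pixels available for interpolation",
                                "retoct_no_signal_error")
  out <- m
  out[invalid] <- NA_real_
  k <- 3L
  while (anyNA(out)) {
    med <- median_filter2_na(out, k)
    nas <- is.na(out)
    out[nas] <- med[nas]
    k <- k + 2L
    if (k > 2L * max(dim(m))) {
      gm <- stats::median(m[!invalid])
      out[is.na(out)] <- gm
    }
  }
  out
}

# Median filter ignoring NAs (returns NA where no valid neighbour exists).
median_filter2_na <- function(m, k = 3L) {
  r <- (k - 1L) %/% 2L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) mshift_replicate(m, offs$dy[i], offs$dx[i]),
                  m)
  apply(stack, c(1L, 2L), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  })
}

# 26-connected components of a logical [ny, nx, nz] array.
# Returns a list of integer matrices (one per component) with columns y, x, z.
label_components_26 <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  idx <- which(mask)
  if (!length(idx)) return(list())
  ny <- dims[1L]; nx <- dims[2L]; nz <- dims[3L]
  lab <- array(0L, dims)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  comps <- list()
  nextlab <- 0L
  unvisited <- array(FALSE, dims)
  unvisited[idx] <- TRUE
  for (seed in idx) {
    if (!unvisited[seed]) next
    nextlab <- nextlab + 1L
    frontier <- arrayInd(seed, dims)
    unvisited[seed] <- FALSE
    members <- frontier
    while (nrow(frontier)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(frontier, 2L, offs[i, ], "+")))
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= ny &
            cand[, 2L] >= 1L & cand[, 2L] <= nx &
            cand[, 3L] >= 1L & cand[, 3L] <= nz
      cand <- cand[ok, , drop = FALSE]
      lin <- (cand[, 3L] - 1L) * (ny * nx) + (cand[, 2L] - 1L) * ny + cand[, 1L]
      keep <- !duplicated(lin)
      cand <- cand[keep, , drop = FALSE]; lin <- lin[keep]
      new <- unvisited[lin]
      cand <- cand[new, , drop = FALSE]; lin <- lin[new]
      unvisited[lin] <- FALSE
      members <- rbind(members, cand)
      frontier <- cand
    }
    colnames(members) <- c("y", "x", "z")
    comps[[nextlab]] <- members
  }
  comps
}

# Zhang-Suen thinning of a logical matrix down to a 1-px skeleton.
skeletonize_zs <- function(img) {
  img <- img * 1L
  pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
  unpad <- function(m) m[2:(nrow(m) - 1L), 2:(ncol(m) - 1L), drop = FALSE]
  m <- pad(img)
  sh <- function(m, dy, dx) {
    ny <- nrow(m); nx <- ncol(m)
    out <- matrix(0L, ny, nx)
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    xs <- max(1L, 1L + dx):min(nx, nx + dx)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(m, -1L, 0L); p3 <- sh(m, -1L, 1L); p4 <- sh(m, 0L, 1L)
      p5 <- sh(m, 1L, 1L);  p6 <- sh(m, 1L, 0L);  p7 <- sh(m, 1L, -1L)
      p8 <- sh(m, 0L, -1L); p9 <- sh(m, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- p2 * p4 * p6
        c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8
        c2 <- p2 * p6 * p8
      }
      del <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unpad(m) > 0L
}

# Lateral (y, x) k x k box smoothing of a [ny, nx, nz] array with edge
# replication; depth profiles keep their axial sharpness.
lateral_box_smooth <- function(a, k = 3L) {
  if (k <= 1L) return(a)
  r <- (k - 1L) %/% 2L
  d <- dim(a)
  acc <- array(0, d)
  for (dy in -r:r) for (dx in -r:r) {
    ri <- pmin(pmax(seq_len(d[1L]) + dy, 1L), d[1L])
    ci <- pmin(pmax(seq_len(d[2L]) + dx, 1L), d[2L])
    acc <- acc + a[ri, ci, , drop = FALSE]
  }
  acc / ((2 * r + 1)^2)
}

# Separable k x k x k box smoothing of a [ny, nx, nz] array, edges
# renormalised. Used for speckle suppression before intensity thresholds.
box_smooth_3d <- function(a, k = 3L) {
  if (k <= 1L) return(a)
  r <- (k - 1L) %/% 2L
  d <- dim(a)
  sm_dim <- function(a, dimi) {
    n <- d[dimi]
    acc <- array(0, d); cnt <- numeric(n)
    for (s in -r:r) {
      ii <- seq_len(n) + s
      ok <- ii >= 1L & ii <= n
      src <- switch(dimi,
                    a[ii[ok], , , drop = FALSE],
                    a[, ii[ok], , drop = FALSE],
                    a[, , ii[ok], drop = FALSE])
      if (dimi == 1L) acc[which(ok), , ] <- acc[which(ok), , , drop = FALSE] + src
      if (dimi == 2L) acc[, which(ok), ] <- acc[, which(ok), , drop = FALSE] + src
      if (dimi == 3L) acc[, , which(ok)] <- acc[, , which(ok), drop = FALSE] + src
      cnt[ok] <- cnt[ok] + 1
    }
    sweep(acc, dimi, cnt, "/")
  }
  sm_dim(sm_dim(sm_dim(a, 3L), 2L), 1L)
}

# En-face pixel centre coordinates in micrometres for a [ny, nx] grid.
pixel_centers_um <- function(ny, nx, pitch_y_um, pitch_x_um) {
  list(y = (seq_len(ny) - 0.5) * pitch_y_um,
       x = (seq_len(nx) - 0.5) * pitch_x_um)
}
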