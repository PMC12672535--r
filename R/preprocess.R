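#' Parameters for CT-stack and micrograph conditioning
#'
#' @param bg_sigma_px Gaussian sigma for background estimation (default 400,
#'   sensible range 300-500).
#' @param unsharp_radius_px unsharp-mask Gaussian radius (default 1.5).
#' @param unsharp_weight unsharp-mask weight in (0, 1) (default 0.5,
#'   sensible range 0.4-0.6).
#' @param clip_lo,clip_hi intensity clipping bounds (absolute values).
#' @param flatfield_sigma_px Gaussian sigma applied to the feature-empty
#'   reference tile before division (default 50).
#' @param epsilon small positive constant guarding divisions.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(bg_sigma_px = 400, unsharp_radius_px = 1.5,
                              unsharp_weight = 0.5, clip_lo = 0, clip_hi = 1,
                              flatfield_sigma_px = 50, epsilon = 1e-6) {
  stopifnot(bg_sigma_px > 0, unsharp_radius_px > 0,
            unsharp_weight > 0, unsharp_weight < 1,
            clip_lo < clip_hi, epsilon > 0)
  structure(list(bg_sigma_px = bg_sigma_px,
                 unsharp_radius_px = unsharp_radius_px,
                 unsharp_weight = unsharp_weight,
                 clip_lo = clip_lo, clip_hi = clip_hi,
                 flatfield_sigma_px = flatfield_sigma_px,
                 epsilon = epsilon),
            class = "preprocess_params")
}

#' Gaussian-blur background subtraction
#'
#' Removes smooth contrast gradients (e.g. air-resin edge artifacts) by
#' subtracting a heavily blurred copy of the image. The image mean is added
#' back so the result stays in the original intensity range.
#'
#' @param img numeric matrix.
#' @param sigma_px blur sigma in pixels (> 0; 300-500 typical for cropped
#'   CT slices).
#' @return matrix of the same shape.
#' @export
background_subtract <- function(img, sigma_px = 400) {
  stopifnot(is.matrix(img), sigma_px > 0)
  if (!all(is.finite(img))) stop("background_subtract: non-finite input")
  img - gauss_blur(img, sigma_px) + mean(img)
}

#' Unsharp-mask sharpening
#'
#' The renormalized subtractive form used by common imaging software:
#' `(img - weight * blur(img)) / (1 - weight)`, which leaves constants (and
#' the image mean under symmetric boundaries) unchanged.
#'
#' @param img numeric matrix.
#' @param radius_px Gaussian radius in pixels.
#' @param weight sharpening weight in (0, 1).
#' @return sharpened matrix.
#' @export
unsharp_mask <- function(img, radius_px = 1.5, weight = 0.5) {
  stopifnot(is.matrix(img), radius_px > 0)
  if (weight >= 1 || weight <= 0)
    stop("unsharp_mask: weight must lie strictly between 0 and 1")
  (img - weight * gauss_blur(img, radius_px)) / (1 - weight)
}

#' Clip and normalize a volume to the unit interval
#'
#' Clips intensities to `[lo, hi]`, maps them affinely onto `[0, 1]` and
#' stores the result at 32-bit float precision (the precision the
#' segmentation stage consumes; R computes in double, the values are
#' rounded to float32 representables).
#'
#' @param vol a [volume3d()] (or bare numeric array/matrix).
#' @param lo,hi clipping bounds, `lo < hi`.
#' @return object of the same type, values in `[0, 1]`.
#' @export
clip_normalize <- function(vol, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi))
    stop("clip_normalize: need lo < hi")
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  arr <- (pmin(pmax(arr, lo), hi) - lo) / (hi - lo)
  # round through float32 representation
  con <- rawConnection(raw(0), "r+")
  writeBin(as.vector(arr), con, size = 4L)
  seek(con, 0)
  out <- readBin(con, "numeric", n = length(arr), size = 4L)
  close(con)
  if (is.null(dim(arr))) dim(out) <- NULL else dim(out) <- dim(arr)
  if (inherits(vol, "volume3d")) volume3d(out, voxel_um = vol$voxel_um)
  else out
}

#' Flat-field (shading) correction of a micrograph tile
#'
#' Divides the tile by a Gaussian-filtered feature-empty reference tile and
#' rescales the result to unit mean, removing the detector/beam vignette.
#'
#' @param tile numeric matrix.
#' @param reference feature-empty tile of the same shape.
#' @param params a [preprocess_params()] (uses `flatfield_sigma_px`,
#'   `epsilon`).
#' @return corrected tile with mean 1.
#' @export
flatfield_correct <- function(tile, reference,
                              params = preprocess_params()) {
  if (!identical(dim(tile), dim(reference)))
    stop("flatfield_correct: tile and reference shapes differ")
  gain <- gauss_blur(reference, params$flatfield_sigma_px)
  out <- tile / pmax(gain, params$epsilon)
  out / mean(out)
}

#' Invert image contrast
#'
#' Maps intensity v to `(max + min) - v`, matching inverted-contrast
#' micrographs to CT contrast. Involution: `invert(invert(x)) == x`.
#'
#' @param img numeric matrix.
#' @return inverted matrix.
#' @export
invert_contrast <- function(img) {
  stopifnot(is.matrix(img))
  if (!all(is.finite(img))) stop("invert_contrast: non-finite input")
  (max(img) + min(img)) - img
}

# phase-correlation offset of b relative to a, searched within +/- max_shift
# of (0, 0); ties broken by the smallest displacement
phase_correlate <- function(a, b, max_shift = 8L) {
  stopifnot(identical(dim(a), dim(b)))
  # Hann window against wrap-around edges; regularized whitening so that
  # numerically-dead high frequencies of smooth images do not drown the
  # correlation peak
  hann <- function(n) if (n == 1L) 1 else 0.5 - 0.5 * cos(2 * pi *
                                                          (seq_len(n) - 1) /
                                                          (n - 1))
  w <- outer(hann(nrow(a)), hann(ncol(a)))
  A <- fft((a - mean(a)) * w)
  B <- fft((b - mean(b)) * w)
  R <- A * Conj(B)
  mag <- Mod(R)
  R <- R / pmax(mag, 0.01 * max(mag))
  cc <- Re(fft(R, inverse = TRUE))
  d <- dim(cc)
  sh <- as.matrix(expand.grid(dr = -max_shift:max_shift,
                              dc = -max_shift:max_shift))
  rows <- ((sh[, 1]) %% d[1]) + 1L
  cols <- ((sh[, 2]) %% d[2]) + 1L
  vals <- cc[cbind(rows, cols)]
  best <- which(vals == max(vals))
  if (length(best) > 1L) {
    disp <- sh[best, 1]^2 + sh[best, 2]^2
    best <- best[which.min(disp)]
  }
  c(dr = sh[best, 1], dc = sh[best, 2])
}

#' Stitch a tile mosaic into one image
#'
#' Tiles are placed at their nominal grid offsets; with `refine = TRUE`,
#' each tile's offset is re-estimated by phase correlation of its overlap
#' with the already-anchored neighbour (search bounded to `max_shift`
#' pixels around nominal, ties broken by smallest displacement). Tiles are
#' composited with linear feathered blending whose weights sum to one at
#' every covered output pixel.
#'
#' @param tiles a [tile_set()].
#' @param refine logical; re-estimate offsets by phase correlation.
#' @param max_shift refinement search bound in pixels.
#' @return list with `image` (the composite) and `offsets` (the integer
#'   per-tile offsets actually used).
#' @export
stitch_tiles <- function(tiles, refine = TRUE, max_shift = 8L) {
  stopifnot(inherits(tiles, "tile_set"))
  n <- length(tiles$tiles)
  noms <- tiles$nominal_offsets
  dims <- t(vapply(tiles$tiles, dim, integer(2)))
  offs <- noms
  if (refine && n > 1L) {
    # anchor tile 1; refine the others against overlap with any anchored tile
    done <- c(TRUE, rep(FALSE, n - 1L))
    offs[1, ] <- noms[1, ]
    overlap_area <- function(i, j, oi, oj) {
      r0 <- max(oi[1], oj[1]); r1 <- min(oi[1] + dims[i, 1], oj[1] + dims[j, 1])
      c0 <- max(oi[2], oj[2]); c1 <- min(oi[2] + dims[i, 2], oj[2] + dims[j, 2])
      max(0L, r1 - r0) * max(0L, c1 - c0)
    }
    while (!all(done)) {
      pend <- which(!done)
      # pick the pending tile with the largest nominal overlap to an anchor
      best <- NULL
      for (i in pend) for (j in which(done)) {
        a <- overlap_area(i, j, noms[i, ], offs[j, ])
        if (is.null(best) || a > best$a) best <- list(i = i, j = j, a = a)
      }
      if (best$a <= 0) stop("stitch_tiles: disconnected mosaic")
      i <- best$i; j <- best$j
      # crop the nominal overlap window from both tiles and phase-correlate
      r0 <- max(noms[i, 1], offs[j, 1])
      r1 <- min(noms[i, 1] + dims[i, 1], offs[j, 1] + dims[j, 1])
      c0 <- max(noms[i, 2], offs[j, 2])
      c1 <- min(noms[i, 2] + dims[i, 2], offs[j, 2] + dims[j, 2])
      ai <- tiles$tiles[[i]][(r0 - noms[i, 1] + 1L):(r1 - noms[i, 1]),
                             (c0 - noms[i, 2] + 1L):(c1 - noms[i, 2]),
                             drop = FALSE]
      aj <- tiles$tiles[[j]][(r0 - offs[j, 1] + 1L):(r1 - offs[j, 1]),
                             (c0 - offs[j, 2] + 1L):(c1 - offs[j, 2]),
                             drop = FALSE]
      ms <- min(max_shift, dim(ai) - 1L)
      sh <- if (all(dim(ai) > 2L)) phase_correlate(aj, ai, ms) else c(0L, 0L)
      offs[i, ] <- noms[i, ] + sh
      done[i] <- TRUE
    }
  } else if (n > 1L) {
    # connectivity check still applies without refinement
    reach <- c(TRUE, rep(FALSE, n - 1L))
    repeat {
      grew <- FALSE
      for (i in which(!reach)) for (j in which(reach)) {
        r_ov <- min(offs[i, 1] + dims[i, 1], offs[j, 1] + dims[j, 1]) -
                max(offs[i, 1], offs[j, 1])
        c_ov <- min(offs[i, 2] + dims[i, 2], offs[j, 2] + dims[j, 2]) -
                max(offs[i, 2], offs[j, 2])
        if (r_ov > 0 && c_ov > 0) { reach[i] <- TRUE; grew <- TRUE }
      }
      if (all(reach)) break
      if (!grew) stop("stitch_tiles: disconnected mosaic")
    }
  }
  offs <- offs - rep(apply(offs, 2, min), each = n)
  out_dim <- c(max(offs[, 1] + dims[, 1]), max(offs[, 2] + dims[, 2]))
  acc <- matrix(0, out_dim[1], out_dim[2])
  wacc <- matrix(0, out_dim[1], out_dim[2])
  for (i in seq_len(n)) {
    h <- dims[i, 1]; w <- dims[i, 2]
    # feathered weight: linear ramp from each tile edge
    wr <- pmin(seq_len(h), h:1); wc <- pmin(seq_len(w), w:1)
    wt <- outer(pmin(wr, max(1, min(h, w) %/% 4)),
                pmin(wc, max(1, min(h, w) %/% 4)), pmin)
    rows <- offs[i, 1] + seq_len(h); cols <- offs[i, 2] + seq_len(w)
    acc[rows, cols] <- acc[rows, cols] + tiles$tiles[[i]] * wt
    wacc[rows, cols] <- wacc[rows, cols] + wt
  }
  covered <- wacc > 0
  acc[covered] <- acc[covered] / wacc[covered]
  list(image = acc, offsets = offs)
}
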