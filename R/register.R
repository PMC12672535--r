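#' Rigid pose of a virtual slice plane
#'
#' Rotations in degrees about the volume axes, applied in z.y.x order
#' (R = Rz Ry Rx); translations in voxels of the slice-plane origin relative
#' to the volume centre voxel (`floor(dim/2) + 1`). The identity pose
#' selects the central z-slice. The coordinate frame is right-handed with
#' axis order (z, y, x).
#'
#' @param rx,ry,rz rotations in degrees, normalized to (-180, 180].
#' @param tx,ty,tz translations in voxels.
#' @return an object of class `slice_pose`.
#' @export
slice_pose <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0) {
  norm180 <- function(a) {
    a <- a %% 360
    ifelse(a > 180, a - 360, a)
  }
  structure(list(rx = norm180(rx), ry = norm180(ry), rz = norm180(rz),
                 tx = tx, ty = ty, tz = tz),
            class = "slice_pose")
}

#' In-plane affine correction of a micrograph
#'
#' Anisotropic scale, shear (`x' = x + k * y`) and in-plane rotation
#' applied about the image centre; models the irregular scaling and local
#' shear of section-based micrographs relative to the tomographic frame.
#'
#' @param sx,sy anisotropic scale factors (> 0).
#' @param k shear coefficient.
#' @param theta2d in-plane rotation in degrees.
#' @return an object of class `inplane_affine`.
#' @export
inplane_affine <- function(sx = 1, sy = 1, k = 0, theta2d = 0) {
  if (sx <= 0 || sy <= 0)
    stop("inplane_affine: scale factors must be positive (degenerate affine)")
  structure(list(sx = sx, sy = sy, k = k, theta2d = theta2d),
            class = "inplane_affine")
}

#' Coarse-to-fine optimization schedule
#'
#' @param pyramid_factors strictly decreasing integer downsampling factors
#'   ending at 1.
#' @param step_init named initial step per parameter (degrees, voxels, or
#'   unitless for scale/shear).
#' @param step_min convergence threshold per parameter.
#' @param shrink_factor step multiplier applied after a sweep without
#'   improvement (default 0.5).
#' @param max_sweeps sweep budget per pyramid level.
#' @param bins joint-histogram bin count for the MI metric.
#' @param binarize optimize MI of median-thresholded (binary) images.
#' @param min_overlap minimum unmasked pixel fraction for a candidate view.
#' @return an object of class `reg_schedule`.
#' @export
reg_schedule <- function(pyramid_factors = c(8L, 4L, 2L, 1L),
                         step_init = c(tz = 4, rx = 4, ry = 4, tx = 4,
                                       ty = 4, theta2d = 2, sx = 0.04,
                                       sy = 0.04, k = 0.04),
                         step_min = c(tz = 0.25, rx = 0.1, ry = 0.1,
                                      tx = 0.25, ty = 0.25, theta2d = 0.1,
                                      sx = 0.004, sy = 0.004, k = 0.002),
                         shrink_factor = 0.5, max_sweeps = 50L,
                         bins = 64L, binarize = FALSE, min_overlap = 0.5) {
  stopifnot(all(diff(pyramid_factors) < 0),
            pyramid_factors[length(pyramid_factors)] == 1L,
            all(step_init > 0), all(step_min > 0),
            shrink_factor > 0, shrink_factor < 1, bins >= 2L)
  structure(list(pyramid_factors = as.integer(pyramid_factors),
                 step_init = step_init, step_min = step_min,
                 shrink_factor = shrink_factor,
                 max_sweeps = as.integer(max_sweeps), bins = as.integer(bins),
                 binarize = binarize, min_overlap = min_overlap),
            class = "reg_schedule")
}

# block-mean downsampling (one axis at a time via colMeans)
downsample_block <- function(arr, f) {
  if (f == 1L) return(arr)
  nd <- length(dim(arr))
  for (ax in seq_len(nd)) {
    d <- dim(arr)
    n <- d[1] %/% f
    idx <- seq_len(n * f)
    arr <- if (nd == 3L) arr[idx, , , drop = FALSE] else arr[idx, , drop = FALSE]
    dim(arr) <- c(f, n, prod(dim(arr)) / (f * n))
    arr <- colMeans(arr)
    dim(arr) <- if (nd == 3L) c(n, d[2], d[3]) else c(n, d[2])
    arr <- aperm(arr, c(seq_len(nd)[-1], 1L))
  }
  arr
}

# Sample the virtual view defined by (pose, affine) on an out_shape pixel
# grid with the given pixel spacing (in voxels of `arr`). Returns the view
# matrix and the validity mask.
sample_view <- function(arr, pose, affine, out_shape, spacing = 1,
                        fill = 0) {
  d <- dim(arr)
  ctr <- floor(d / 2) + 1
  h <- out_shape[1]; w <- out_shape[2]
  oc <- floor(c(h, w) / 2) + 1
  g <- as.matrix(expand.grid(i = seq_len(h), j = seq_len(w)))
  y <- (g[, 1] - oc[1]) * spacing
  x <- (g[, 2] - oc[2]) * spacing
  # in-plane affine: shear, scale, rotate
  x1 <- affine$sx * (x + affine$k * y)
  y1 <- affine$sy * y
  th <- affine$theta2d * pi / 180
  x2 <- cos(th) * x1 - sin(th) * y1
  y2 <- sin(th) * x1 + cos(th) * y1
  R <- rot3("z", pose$rz) %*% rot3("y", pose$ry) %*% rot3("x", pose$rx)
  loc <- cbind(0, y2, x2) %*% t(R)
  coords <- cbind(loc[, 1] + ctr[1] + pose$tz,
                  loc[, 2] + ctr[2] + pose$ty,
                  loc[, 3] + ctr[3] + pose$tx)
  r <- cpp_sample_trilinear(arr, d, coords, fill)
  view <- matrix(r$values, h, w)
  mask <- matrix(r$inside, h, w)
  attr(view, "mask") <- mask
  view
}

#' Extract a virtual tomographic slice
#'
#' Resamples the volume on the oblique plane defined by `pose` with
#' trilinear interpolation at unit voxel spacing. Samples outside the
#' volume are filled with 0 and flagged in the `mask` attribute; a plane
#' entirely outside the volume is flagged with a warning.
#'
#' @param vol a [volume3d()].
#' @param pose a [slice_pose()].
#' @param out_shape (rows, cols) of the output slice; defaults to the
#'   (y, x) dimensions of the volume.
#' @return numeric matrix with logical attribute `mask` (TRUE = valid).
#' @export
extract_virtual_slice <- function(vol, pose, out_shape = NULL) {
  stopifnot(inherits(vol, "volume3d"), inherits(pose, "slice_pose"))
  if (is.null(out_shape)) out_shape <- dim(vol$data)[2:3]
  stopifnot(all(out_shape >= 1))
  v <- sample_view(vol$data, pose, inplane_affine(), out_shape)
  if (!any(attr(v, "mask")))
    warning("extract_virtual_slice: plane lies entirely outside the volume")
  v
}

#' Histogram mutual information between two images (bits)
#'
#' Joint histogram of `bins x bins` cells with per-image min-max binning;
#' masked (invalid) pixels are excluded. MI = sum p(i,j) log2 p(i,j) /
#' (p(i) p(j)).
#'
#' @param a,b numeric matrices of equal shape.
#' @param bins number of histogram bins per image (>= 2).
#' @param mask optional logical matrix; FALSE pixels are excluded. The
#'   `mask` attributes of `a`/`b` (as set by [extract_virtual_slice()]) are
#'   honoured automatically.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(a, b, bins = 64L, mask = NULL) {
  stopifnot(identical(dim(a), dim(b)), bins >= 2L)
  m <- !logical(length(a))
  if (!is.null(attr(a, "mask"))) m <- m & as.vector(attr(a, "mask"))
  if (!is.null(attr(b, "mask"))) m <- m & as.vector(attr(b, "mask"))
  if (!is.null(mask)) m <- m & as.vector(mask)
  av <- as.vector(a)[m]; bv <- as.vector(b)[m]
  if (!length(av)) stop("mutual_information: empty overlap after masking")
  bin_idx <- function(x) {
    mn <- min(x); mx <- max(x)
    if (mx == mn) return(rep(1L, length(x)))
    pmin(bins, as.integer(floor((x - mn) / (mx - mn) * bins)) + 1L)
  }
  ia <- bin_idx(av); ib <- bin_idx(bv)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  mi <- sum(pm[nz] * log2(pm[nz] / outer(pa, pb)[nz]))
  max(mi, 0)
}

# objective for the hill-climb: MI between img and the candidate view
# (optionally median-binarized), -Inf when the overlap is too small
view_objective <- function(arr, img, p, sched, spacing) {
  pose <- slice_pose(p[["rx"]], p[["ry"]], p[["rz"]],
                     p[["tx"]], p[["ty"]], p[["tz"]])
  if (p[["sx"]] <= 0.05 || p[["sy"]] <= 0.05) return(-Inf)
  aff <- inplane_affine(p[["sx"]], p[["sy"]], p[["k"]], p[["theta2d"]])
  v <- sample_view(arr, pose, aff, dim(img), spacing)
  msk <- attr(v, "mask")
  if (mean(msk) < sched$min_overlap) return(-Inf)
  if (sched$binarize) {
    av <- as.vector(img)[msk]; bv <- as.vector(v)[msk]
    a2 <- matrix(as.numeric(as.vector(img) >= median(av)), nrow(img))
    b2 <- v
    b2[] <- as.numeric(as.vector(v) >= median(bv))
    attr(b2, "mask") <- msk
    mutual_information(a2, b2, bins = 2L)
  } else {
    mutual_information(img, v, bins = sched$bins, mask = msk)
  }
}

#' Register a 2D image to a virtual slice plane of a 3D volume
#'
#' Coarse-to-fine mutual-information maximization: at each pyramid level a
#' deterministic coordinate-descent hill-climb visits the parameters in the
#' fixed order (tz, rx, ry, tx, ty, theta2d, sx, sy, k), trying +/- one
#' step each; after a sweep without improvement all steps shrink by
#' `shrink_factor` until they fall below `step_min`. The image is assumed
#' to be preprocessed to CT contrast (flat-field corrected, stitched,
#' inverted).
#'
#' @param vol a [volume3d()].
#' @param img numeric matrix (the micrograph, at CT contrast).
#' @param init list with elements `pose` ([slice_pose()]) and `affine`
#'   ([inplane_affine()]); must lie within the capture range.
#' @param sched a [reg_schedule()].
#' @param optimize character vector of parameter names to optimize
#'   (default: all nine).
#' @return an object of class `registration_result`: `pose`, `affine`,
#'   `mi_bits`, `trace` (level, sweep, mi_bits), `converged` (final MI not
#'   below the initial MI), `img_shape`.
#' @export
register_slice <- function(vol, img, init = list(pose = slice_pose(),
                                                 affine = inplane_affine()),
                           sched = reg_schedule(),
                           optimize = c("tz", "rx", "ry", "tx", "ty",
                                        "theta2d", "sx", "sy", "k")) {
  stopifnot(inherits(vol, "volume3d"), is.matrix(img))
  p <- c(tz = init$pose$tz, rx = init$pose$rx, ry = init$pose$ry,
         tx = init$pose$tx, ty = init$pose$ty, rz = init$pose$rz,
         theta2d = init$affine$theta2d, sx = init$affine$sx,
         sy = init$affine$sy, k = init$affine$k)
  order_all <- c("tz", "rx", "ry", "tx", "ty", "theta2d", "sx", "sy", "k")
  pars <- order_all[order_all %in% optimize]
  trace <- data.frame()
  mi_init <- NA_real_
  for (f in sched$pyramid_factors) {
    arr_f <- downsample_block(vol$data, f)
    img_f <- downsample_block(img, f)
    pf <- p
    pf[c("tz", "tx", "ty")] <- pf[c("tz", "tx", "ty")] / f
    steps <- sched$step_init
    steps[c("tz", "tx", "ty")] <- steps[c("tz", "tx", "ty")] / f
    smin <- sched$step_min
    smin[c("tz", "tx", "ty")] <- pmax(smin[c("tz", "tx", "ty")] / f, 0.05)
    cur <- view_objective(arr_f, img_f, pf, sched, spacing = 1)
    if (f == sched$pyramid_factors[1]) mi_init <- cur
    for (sweep in seq_len(sched$max_sweeps)) {
      improved <- FALSE
      for (par in pars) {
        for (dir in c(1, -1)) {
          trial <- pf
          trial[par] <- trial[par] + dir * steps[par]
          val <- view_objective(arr_f, img_f, trial, sched, spacing = 1)
          if (val > cur + 1e-12) {
            pf <- trial
            cur <- val
            improved <- TRUE
          }
        }
      }
      trace <- rbind(trace,
                     data.frame(level = f, sweep = sweep, mi_bits = cur))
      if (!improved) {
        steps <- steps * sched$shrink_factor
        if (all(steps[pars] < smin[pars])) break
      }
    }
    p <- pf
    p[c("tz", "tx", "ty")] <- p[c("tz", "tx", "ty")] * f
  }
  mi_final <- view_objective(vol$data, img, p, sched, spacing = 1)
  res <- list(pose = slice_pose(p[["rx"]], p[["ry"]], p[["rz"]],
                                p[["tx"]], p[["ty"]], p[["tz"]]),
              affine = inplane_affine(p[["sx"]], p[["sy"]], p[["k"]],
                                      p[["theta2d"]]),
              mi_bits = mi_final, trace = trace,
              converged = is.finite(mi_final) &&
                (!is.finite(mi_init) || mi_final >= mi_init),
              img_shape = dim(img))
  class(res) <- "registration_result"
  if (!res$converged)
    warning("register_slice: final MI below initial MI (capture failure)")
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: MI = %.4f bits, converged = %s\n",
              x$mi_bits, x$converged))
  cat(sprintf("  pose: rx=%.2f ry=%.2f rz=%.2f deg, t=(%.2f, %.2f, %.2f) vox\n",
              x$pose$rx, x$pose$ry, x$pose$rz, x$pose$tz, x$pose$ty,
              x$pose$tx))
  cat(sprintf("  affine: sx=%.3f sy=%.3f k=%.3f theta2d=%.2f deg\n",
              x$affine$sx, x$affine$sy, x$affine$k, x$affine$theta2d))
  invisible(x)
}

#' Re-apply registration parameters at full micrograph resolution
#'
#' Warps the original-resolution micrograph into the slice coordinate frame
#' (undoing scale/shear/rotation) and bilinearly upscales the registered CT
#' slice to the micrograph resolution, so both share one coordinate system.
#'
#' @param result a `registration_result`.
#' @param img_hi the original-resolution micrograph; its dimensions must be
#'   an integer multiple of the registered image's.
#' @param vol the volume registered against.
#' @return list with `micrograph_corrected` and `ct_slice_upscaled`.
#' @export
reapply_full_res <- function(result, img_hi, vol) {
  stopifnot(inherits(result, "registration_result"), is.matrix(img_hi),
            inherits(vol, "volume3d"))
  ratio <- dim(img_hi) / result$img_shape
  if (any(abs(ratio - round(ratio)) > 1e-9) || ratio[1] != ratio[2])
    stop("reapply_full_res: micrograph is not an integer upscale of the registered image")
  ratio <- round(ratio[1])
  aff <- result$affine
  h <- nrow(img_hi); w <- ncol(img_hi)
  oc <- floor(c(h, w) / 2) + 1
  g <- as.matrix(expand.grid(i = seq_len(h), j = seq_len(w)))
  y <- g[, 1] - oc[1]
  x <- g[, 2] - oc[2]
  # forward affine (slice frame -> micrograph frame): shear, scale, rotate
  x1 <- aff$sx * (x + aff$k * y)
  y1 <- aff$sy * y
  th <- aff$theta2d * pi / 180
  xs <- cos(th) * x1 - sin(th) * y1
  ys <- sin(th) * x1 + cos(th) * y1
  r <- cpp_sample_bilinear(img_hi, cbind(ys + oc[1], xs + oc[2]), 0)
  corrected <- matrix(r$values, h, w)
  attr(corrected, "mask") <- matrix(r$inside, h, w)
  slice_lo <- extract_virtual_slice(vol, result$pose, result$img_shape)
  # node-aligned integer upscale: hi pixel 1 maps to lo pixel 1
  gi <- (g[, 1] - 1) / ratio + 1
  gj <- (g[, 2] - 1) / ratio + 1
  gi <- pmin(gi, nrow(slice_lo)); gj <- pmin(gj, ncol(slice_lo))
  r2 <- cpp_sample_bilinear(slice_lo, cbind(gi, gj), 0)
  upscaled <- matrix(r2$values, h, w)
  list(micrograph_corrected = corrected, ct_slice_upscaled = upscaled)
}

#' Refine registration for a high-magnification region
#'
#' Keeps the slice-plane orientation of a prior registration fixed
#' (rx, ry and the out-of-plane offset tz) and re-optimizes only the
#' in-plane parameters (tx, ty, theta2d, sx, sy, k) for a zoomed image.
#'
#' @param vol a [volume3d()].
#' @param img_zoom zoomed micrograph at CT contrast, same pixel spacing as
#'   the registered overview (crop-level refinement).
#' @param prior a `registration_result` from the overview registration.
#' @param sched a [reg_schedule()].
#' @return a `registration_result`.
#' @export
refine_region <- function(vol, img_zoom, prior, sched = reg_schedule()) {
  stopifnot(inherits(prior, "registration_result"))
  register_slice(vol, img_zoom,
                 init = list(pose = prior$pose, affine = prior$affine),
                 sched = sched,
                 optimize = c("tx", "ty", "theta2d", "sx", "sy", "k"))
}
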