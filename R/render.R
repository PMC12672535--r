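#' Render an SEM-like tile mosaic from a virtual slice
#'
#' Produces the registration test input: the virtual slice at `pose` is
#' sampled at `1/upscale` voxel spacing (emulating the higher micrograph
#' resolution), warped by the in-plane affine, contrast-inverted (secondary
#' electron convention), cut into overlapping tiles with optional offset
#' jitter, multiplied by a radial vignette and degraded with Gaussian
#' noise. Ground-truth pose, affine, per-tile true offsets and the vignette
#' gain are recorded in the tile-set metadata.
#'
#' @param vol a [volume3d()].
#' @param pose a [slice_pose()].
#' @param affine an [inplane_affine()]; non-positive scales (determinant
#'   <= 0) are rejected by the constructor.
#' @param tiling list of options: `upscale` (integer magnification, default
#'   2), `tile_shape` (default c(128, 128)), `overlap_fraction` (default
#'   0.1), `jitter_px` (default 0), `vignette_strength` in `[0, 1)`
#'   (default 0), `noise_sd` (default 0), `base_shape` (slice pixel grid
#'   before upscaling; default volume (y, x) dims), `seed` (default 1).
#' @return a [tile_set()]; `meta` holds `pose`, `affine`, `true_offsets`,
#'   `vignette` (per-tile gain matrix), `reference_tile` (feature-empty
#'   tile carrying the same vignette) and `full_image`.
#' @export
render_sem_view <- function(vol, pose, affine = inplane_affine(),
                            tiling = list()) {
  stopifnot(inherits(vol, "volume3d"), inherits(pose, "slice_pose"),
            inherits(affine, "inplane_affine"))
  tl <- modifyList(list(upscale = 2L, tile_shape = c(128L, 128L),
                        overlap_fraction = 0.1, jitter_px = 0L,
                        vignette_strength = 0, noise_sd = 0,
                        base_shape = dim(vol$data)[2:3], seed = 1L),
                   tiling)
  with_seed(tl$seed, {
    hi <- tl$base_shape * tl$upscale
    view <- sample_view(vol$data, pose, affine, hi, spacing = 1 / tl$upscale)
    if (!any(attr(view, "mask")))
      stop("render_sem_view: slice plane does not intersect the volume")
    img <- (max(view) + min(view)) - view   # SEM contrast
    th <- min(tl$tile_shape[1], hi[1]); tw <- min(tl$tile_shape[2], hi[2])
    stride_r <- max(1L, round(th * (1 - tl$overlap_fraction)))
    stride_c <- max(1L, round(tw * (1 - tl$overlap_fraction)))
    starts <- function(n, t, s) {
      st <- seq(0L, max(0L, n - t), by = s)
      if (st[length(st)] < n - t) st <- c(st, n - t)
      st
    }
    rs <- starts(hi[1], th, stride_r)
    cs <- starts(hi[2], tw, stride_c)
    grid <- expand.grid(r = rs, c = cs)
    # radial vignette gain shared by all tiles
    vr <- (seq_len(th) - (th + 1) / 2) / (th / 2)
    vc <- (seq_len(tw) - (tw + 1) / 2) / (tw / 2)
    gain <- 1 - tl$vignette_strength * outer(vr^2, vc^2, "+") / 2
    tiles <- vector("list", nrow(grid))
    true_off <- as.matrix(grid)
    for (i in seq_len(nrow(grid))) {
      jr <- if (tl$jitter_px > 0)
        as.integer(round(runif(1, -tl$jitter_px, tl$jitter_px))) else 0L
      jc <- if (tl$jitter_px > 0)
        as.integer(round(runif(1, -tl$jitter_px, tl$jitter_px))) else 0L
      r0 <- min(max(grid$r[i] + jr, 0L), hi[1] - th)
      c0 <- min(max(grid$c[i] + jc, 0L), hi[2] - tw)
      true_off[i, ] <- c(r0, c0)
      cut <- img[r0 + seq_len(th), c0 + seq_len(tw)]
      tiles[[i]] <- cut * gain +
        if (tl$noise_sd > 0) matrix(rnorm(th * tw, 0, tl$noise_sd), th) else 0
    }
    reference <- gain * stats::median(img) +
      if (tl$noise_sd > 0) matrix(rnorm(th * tw, 0, tl$noise_sd), th) else 0
    tile_set(tiles, as.matrix(grid),
             overlap_fraction = tl$overlap_fraction,
             pixel_um = vol$voxel_um / tl$upscale,
             meta = list(pose = pose, affine = affine,
                         true_offsets = true_off, vignette = gain,
                         reference_tile = reference, full_image = img,
                         upscale = tl$upscale))
  })
}
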