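#' Parameterization of a synthetic lymph-node phantom
#'
#' Defines the geometry and statistical structure of a synthetic LN volume:
#' an ellipsoidal node with capsule and subcapsular sinus shells, a deep
#' cortical unit (DCU) displaced towards one pole, a medulla at the opposite
#' pole permeated by a sinus network, cortical B-cell follicles, medullary
#' nodules (spherical-to-ovoid ellipsoids encapsulated by a sinus rind),
#' adipocytes at the cortico-medullary border, venules, outer vasculature,
#' and per-compartment capillary networks.
#'
#' Size laws are stated at the unshrunk ("true") tissue scale; the default
#' nodule law is the corrected-scale nodule size distribution (mean
#' 128.57 um, sd 38.57 um, i.e. 90/0.7 and 27/0.7), truncated at
#' `diam_trunc_sd` standard deviations. `generate_phantom(..., scale =
#' "embedded")` renders all object sizes multiplied by `(1 - shrinkage_s)`,
#' emulating the resin-embedded specimen the scanner sees.
#'
#' @param shape_voxels integer triple (z, y, x) array dimensions.
#' @param voxel_um isotropic voxel size in micrometres (default 1.8).
#' @param ln_radii_um ellipsoid semi-axes (z, y, x) in micrometres.
#' @param compartment_params list with `capsule_frac`, `scs_frac`
#'   (shell thicknesses as fractions of the normalized radius), `dcu_center`
#'   and `dcu_radii` (normalized), `medulla_u_max` (normalized z below which
#'   the medulla lies), `sinus_spacing_um`, `sinus_radius_um`,
#'   `follicle_u_min`, `shell_frac` (adjacent-tissue rim).
#' @param follicle_count,follicle_diam_um count and (mean, sd) diameter law.
#' @param nodule_count,nodule_diam_true_um count and (mean, sd) Feret
#'   diameter law at unshrunk scale.
#' @param nodule_axis_ratio_range minor/major axis ratio range encoding the
#'   spherical-to-ovoid shape (default c(0.7, 1)).
#' @param capillary_fraction named fractions in `[0, 1]`: target capillary
#'   voxel fraction per compartment.
#' @param adipocyte_count,adipocyte_diam_um count and (min, max) diameter.
#' @param venule_count,outer_vessel_count vessel counts for realism classes.
#' @param noise_sd additive Gaussian intensity noise.
#' @param shrinkage_s linear tissue shrinkage factor (default 0.30).
#' @param diam_trunc_sd symmetric truncation of normal size laws, in sd.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(224L, 200L, 184L),
                         voxel_um = 1.8,
                         ln_radii_um = c(190, 168, 152),
                         compartment_params = list(),
                         follicle_count = 6L,
                         follicle_diam_um = c(120, 18),
                         nodule_count = 5L,
                         nodule_diam_true_um = c(90 / 0.7, 27 / 0.7),
                         nodule_axis_ratio_range = c(0.7, 1.0),
                         capillary_fraction = c(parenchyma = 0.015,
                                                DCU = 0.02,
                                                follicle = 0.044,
                                                nodule = 0.0436),
                         adipocyte_count = 0L,
                         adipocyte_diam_um = c(40, 90),
                         venule_count = 8L,
                         outer_vessel_count = 10L,
                         noise_sd = 0.04,
                         shrinkage_s = 0.30,
                         diam_trunc_sd = 2,
                         seed = 1L) {
  cp <- modifyList(list(capsule_frac = 0.035, scs_frac = 0.035,
                        dcu_center = 0.30, dcu_radii = c(0.42, 0.45, 0.45),
                        medulla_u_max = -0.05, sinus_spacing_um = 54,
                        sinus_radius_um = 7, follicle_u_min = 0.20,
                        shell_frac = 0.10),
                   compartment_params)
  spec <- list(shape_voxels = as.integer(shape_voxels), voxel_um = voxel_um,
               ln_radii_um = ln_radii_um, compartment_params = cp,
               follicle_count = as.integer(follicle_count),
               follicle_diam_um = follicle_diam_um,
               nodule_count = as.integer(nodule_count),
               nodule_diam_true_um = nodule_diam_true_um,
               nodule_axis_ratio_range = nodule_axis_ratio_range,
               capillary_fraction = capillary_fraction,
               adipocyte_count = as.integer(adipocyte_count),
               adipocyte_diam_um = adipocyte_diam_um,
               venule_count = as.integer(venule_count),
               outer_vessel_count = as.integer(outer_vessel_count),
               noise_sd = noise_sd, shrinkage_s = shrinkage_s,
               diam_trunc_sd = diam_trunc_sd, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$shape_voxels) == 3L, all(spec$shape_voxels >= 8L),
            spec$voxel_um > 0, length(spec$ln_radii_um) == 3L,
            all(spec$ln_radii_um > 0),
            spec$follicle_count >= 0L, spec$nodule_count >= 0L,
            spec$adipocyte_count >= 0L,
            all(spec$follicle_diam_um > 0), all(spec$nodule_diam_true_um > 0),
            all(spec$adipocyte_diam_um > 0),
            spec$adipocyte_diam_um[1] <= spec$adipocyte_diam_um[2],
            all(spec$capillary_fraction >= 0),
            all(spec$capillary_fraction <= 1),
            spec$nodule_axis_ratio_range[1] > 0,
            spec$nodule_axis_ratio_range[2] <= 1,
            spec$noise_sd >= 0, spec$shrinkage_s >= 0, spec$shrinkage_s < 1)
  invisible(spec)
}

# voxel-offset neighbourhood within Euclidean radius r (voxels)
ball_offsets <- function(r) {
  h <- as.integer(ceiling(r))
  g <- expand.grid(dz = -h:h, dy = -h:h, dx = -h:h)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# linear indices for coordinate matrix (z,y,x), NA when out of bounds
lin_index <- function(coords, d) {
  z <- coords[, 1]; y <- coords[, 2]; x <- coords[, 3]
  bad <- z < 1L | z > d[1] | y < 1L | y > d[2] | x < 1L | x > d[3]
  idx <- z + d[1] * (y - 1L) + d[1] * d[2] * (x - 1L)
  idx[bad] <- NA_integer_
  idx
}

#' Generate a synthetic lymph-node phantom
#'
#' Produces a grayscale volume and a matching eleven-class label volume.
#' Object placement uses rejection sampling (cap 10000 attempts per object)
#' with a two-voxel exclusion margin, so distinct objects never touch under
#' 26-connectivity; nodules are wrapped in a one-voxel medullary-sinus rind,
#' mirroring the sinus encapsulation of medullary B-cell aggregates.
#' Capillaries are laid down as ~3-voxel-thick tube segments per compartment
#' until each compartment's capillary voxel fraction reaches its target.
#'
#' @param spec a [phantom_spec()].
#' @param scale `"true"` renders size laws as stated (unshrunk tissue);
#'   `"embedded"` multiplies all object sizes by `(1 - shrinkage_s)`,
#'   emulating the embedded specimen directly.
#' @return list with `volume` ([volume3d()]), `labels` ([label_volume()])
#'   and `truth` (placed-object tables and realized capillary counts).
#' @export
generate_phantom <- function(spec, scale = c("embedded", "true")) {
  validate_phantom_spec(spec)
  scale <- match.arg(scale)
  with_seed(spec$seed, generate_phantom_impl(spec, scale))
}

generate_phantom_impl <- function(spec, scale) {
  d <- spec$shape_voxels
  vx <- spec$voxel_um
  cm <- ln_class_map()
  cp <- spec$compartment_params
  size_mult <- if (scale == "embedded") 1 - spec$shrinkage_s else 1
  ctr <- (d + 1) / 2

  # normalized ellipsoid coordinate rho (per-axis vectors broadcast)
  az <- (((seq_len(d[1]) - ctr[1]) * vx) / spec$ln_radii_um[1])
  ay <- (((seq_len(d[2]) - ctr[2]) * vx) / spec$ln_radii_um[2])
  ax <- (((seq_len(d[3]) - ctr[3]) * vx) / spec$ln_radii_um[3])
  rho2 <- outer(outer(az^2, ay^2, "+"), ax^2, "+")

  ri <- 1 - cp$capsule_frac - cp$scs_frac   # interior boundary
  labels <- array(cm[["background"]], d)
  labels[rho2 <= (1 + cp$shell_frac)^2] <- cm[["adjacent_tissue"]]
  labels[rho2 <= 1] <- cm[["parenchyma"]]
  labels[rho2 <= (1 - cp$capsule_frac)^2 & rho2 > ri^2] <-
    cm[["subcapsular_sinus"]]

  # DCU: ellipsoidal core displaced towards the +z pole
  q <- outer(outer(((az - cp$dcu_center) / cp$dcu_radii[1])^2,
                   (ay / cp$dcu_radii[2])^2, "+"),
             (ax / cp$dcu_radii[3])^2, "+")
  dcu <- q <= 1 & rho2 <= ri^2
  labels[dcu] <- cm[["DCU"]]

  # medulla: interior cap opposite the DCU pole
  medulla <- rho2 <= ri^2 & !dcu
  medulla[az >= cp$medulla_u_max, , ] <- FALSE
  rm(q)

  # medullary sinus network: jittered tube lattice along x and y,
  # spacing chosen so every medullary point lies close to a sinus
  g_vox <- max(2L, round(cp$sinus_spacing_um / vx))
  r_sin <- max(1, cp$sinus_radius_um / vx)
  sin_off2 <- {
    h <- as.integer(ceiling(r_sin))
    g2 <- expand.grid(da = -h:h, db = -h:h)
    as.matrix(g2[g2$da^2 + g2$db^2 <= r_sin^2, , drop = FALSE])
  }
  sinus_code <- cm[["medullary_sinus"]]
  lay_tubes <- function(axis) {
    # axis = 3: tubes along x over a (z, y) grid; axis = 2: along y
    med_z <- which(az < cp$medulla_u_max)
    if (!length(med_z)) return(invisible())
    zs <- seq(min(med_z), max(med_z), by = g_vox)
    os <- seq(1L, if (axis == 3L) d[2] else d[3], by = g_vox)
    span <- seq_len(if (axis == 3L) d[3] else d[2])
    for (z0 in zs) for (o0 in os) {
      zj <- as.integer(round(z0 + runif(1, -g_vox / 4, g_vox / 4)))
      oj <- as.integer(round(o0 + runif(1, -g_vox / 4, g_vox / 4)))
      for (k in seq_len(nrow(sin_off2))) {
        zz <- zj + sin_off2[k, 1]; oo <- oj + sin_off2[k, 2]
        if (zz < 1L || zz > d[1]) next
        if (oo < 1L || oo > (if (axis == 3L) d[2] else d[3])) next
        if (axis == 3L) {
          sel <- medulla[zz, oo, ] & labels[zz, oo, ] == cm[["parenchyma"]]
          if (any(sel)) labels[zz, oo, span[sel]] <<- sinus_code
        } else {
          sel <- medulla[zz, , oo] & labels[zz, , oo] == cm[["parenchyma"]]
          if (any(sel)) labels[zz, span[sel], oo] <<- sinus_code
        }
      }
    }
  }
  lay_tubes(3L)
  lay_tubes(2L)

  place_err <- function(what, compartment)
    stop(sprintf("phantom placement failed: could not place %s inside '%s' after 10000 attempts",
                 what, compartment), call. = FALSE)

  # ---- follicles: spheres in the cortical rim --------------------------
  fol_zone <- which(rho2 <= ri^2 & !dcu & !medulla &
                    labels == cm[["parenchyma"]] &
                    outer(outer(az >= cp$follicle_u_min, rep(TRUE, d[2]), "&"),
                          rep(TRUE, d[3]), "&"))
  follicles <- data.frame()
  for (i in seq_len(spec$follicle_count)) {
    D <- rnorm_trunc(1, spec$follicle_diam_um[1], spec$follicle_diam_um[2],
                     spec$diam_trunc_sd, lower = 2 * vx) * size_mult
    r_vox <- D / 2 / vx
    core_off <- ball_offsets(r_vox)
    chk_off <- ball_offsets(r_vox + 2)
    placed <- FALSE
    for (att in seq_len(10000L)) {
      cidx <- fol_zone[sample.int(length(fol_zone), 1L)]
      cz <- ((cidx - 1L) %% d[1]) + 1L
      cy <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
      cx <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
      chk <- cbind(cz + chk_off[, 1], cy + chk_off[, 2], cx + chk_off[, 3])
      li <- lin_index(chk, d)
      if (anyNA(li)) next
      if (any(rho2[li] > ri^2) || any(medulla[li]) || any(dcu[li])) next
      if (!all(labels[li] == cm[["parenchyma"]])) next
      core <- lin_index(cbind(cz + core_off[, 1], cy + core_off[, 2],
                              cx + core_off[, 3]), d)
      labels[core] <- cm[["follicle"]]
      follicles <- rbind(follicles,
                         data.frame(id = i, z = cz, y = cy, x = cx,
                                    diam_um = D))
      placed <- TRUE
      break
    }
    if (!placed) place_err("follicle", "cortex")
  }

  # ---- nodules: ellipsoids in the medulla, sinus-encapsulated ----------
  med_zone <- which(medulla & (labels == cm[["parenchyma"]] |
                               labels == sinus_code))
  if (spec$nodule_count > 0L && !length(med_zone))
    place_err("nodule", "medulla")
  nodules <- data.frame()
  for (i in seq_len(spec$nodule_count)) {
    D <- rnorm_trunc(1, spec$nodule_diam_true_um[1],
                     spec$nodule_diam_true_um[2],
                     spec$diam_trunc_sd, lower = 3 * vx) * size_mult
    rr <- runif(2, spec$nodule_axis_ratio_range[1],
                spec$nodule_axis_ratio_range[2])
    R <- random_rotation()
    semi <- c(D / 2, rr[1] * D / 2, rr[2] * D / 2)   # um
    hb <- as.integer(ceiling(D / 2 / vx)) + 3L
    offs <- as.matrix(expand.grid(dz = -hb:hb, dy = -hb:hb, dx = -hb:hb))
    P <- offs * vx
    qf <- function(s) {
      M <- R %*% diag(1 / s^2) %*% t(R)
      rowSums((P %*% M) * P)
    }
    v_core <- qf(semi)
    v_shell <- qf(semi + vx)
    v_chk <- qf(semi + 2 * vx)
    core_off <- offs[v_core <= 1, , drop = FALSE]
    shell_off <- offs[v_shell <= 1 & v_core > 1, , drop = FALSE]
    chk_off <- offs[v_chk <= 1, , drop = FALSE]
    placed <- FALSE
    for (att in seq_len(10000L)) {
      cidx <- med_zone[sample.int(length(med_zone), 1L)]
      cz <- ((cidx - 1L) %% d[1]) + 1L
      cy <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
      cx <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
      li <- lin_index(cbind(cz + chk_off[, 1], cy + chk_off[, 2],
                            cx + chk_off[, 3]), d)
      if (anyNA(li)) next
      if (!all(medulla[li])) next
      lv <- labels[li]
      if (!all(lv == cm[["parenchyma"]] | lv == sinus_code)) next
      core <- lin_index(cbind(cz + core_off[, 1], cy + core_off[, 2],
                              cx + core_off[, 3]), d)
      shell <- lin_index(cbind(cz + shell_off[, 1], cy + shell_off[, 2],
                               cx + shell_off[, 3]), d)
      labels[core] <- cm[["nodule"]]
      labels[shell] <- sinus_code
      nodules <- rbind(nodules,
                       data.frame(id = i, z = cz, y = cy, x = cx,
                                  feret_um = D, ratio1 = rr[1],
                                  ratio2 = rr[2],
                                  voxels = nrow(core_off)))
      placed <- TRUE
      break
    }
    if (!placed) place_err("nodule", "medulla")
  }

  # ---- adipocytes: spheres near the cortico-medullary border -----------
  adipocytes <- data.frame()
  if (spec$adipocyte_count > 0L) {
    band <- az >= cp$medulla_u_max - 0.35 & az <= cp$medulla_u_max + 0.30
    ad_zone <- which(rho2 <= ri^2 & !dcu &
                     (labels == cm[["parenchyma"]] | labels == sinus_code) &
                     outer(outer(band, rep(TRUE, d[2]), "&"),
                           rep(TRUE, d[3]), "&"))
    if (!length(ad_zone)) place_err("adipocyte", "cortico-medullary border")
    for (i in seq_len(spec$adipocyte_count)) {
      D <- runif(1, spec$adipocyte_diam_um[1],
                 spec$adipocyte_diam_um[2]) * size_mult
      r_vox <- D / 2 / vx
      core_off <- ball_offsets(r_vox)
      chk_off <- ball_offsets(r_vox + 2)
      placed <- FALSE
      for (att in seq_len(10000L)) {
        cidx <- ad_zone[sample.int(length(ad_zone), 1L)]
        cz <- ((cidx - 1L) %% d[1]) + 1L
        cy <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
        cx <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
        li <- lin_index(cbind(cz + chk_off[, 1], cy + chk_off[, 2],
                              cx + chk_off[, 3]), d)
        if (anyNA(li)) next
        if (any(rho2[li] > ri^2) || any(dcu[li])) next
        lv <- labels[li]
        if (!all(lv == cm[["parenchyma"]] | lv == sinus_code)) next
        core <- lin_index(cbind(cz + core_off[, 1], cy + core_off[, 2],
                                cx + core_off[, 3]), d)
        labels[core] <- cm[["fat_pad"]]
        adipocytes <- rbind(adipocytes,
                            data.frame(id = i, z = cz, y = cy, x = cx,
                                       diam_um = D))
        placed <- TRUE
        break
      }
      if (!placed) place_err("adipocyte", "cortico-medullary border")
    }
  }

  # ---- venules and outer vasculature: straight tube segments -----------
  tube_voxels <- function(start, dir, len_vox, radius_vox) {
    ts <- seq(-len_vox / 2, len_vox / 2, by = 0.5)
    pts <- cbind(start[1] + ts * dir[1], start[2] + ts * dir[2],
                 start[3] + ts * dir[3])
    off <- ball_offsets(radius_vox)
    ctr_vox <- unique(round(pts))
    all_vox <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
      cbind(ctr_vox[, 1] + off[k, 1], ctr_vox[, 2] + off[k, 2],
            ctr_vox[, 3] + off[k, 3])))
    unique(stats::na.omit(lin_index(all_vox, d)))
  }
  interior_idx <- which(rho2 <= ri^2 & labels == cm[["parenchyma"]])
  for (i in seq_len(spec$venule_count)) {
    if (!length(interior_idx)) break
    cidx <- interior_idx[sample.int(length(interior_idx), 1L)]
    st <- c(((cidx - 1L) %% d[1]) + 1L,
            (((cidx - 1L) %/% d[1]) %% d[2]) + 1L,
            ((cidx - 1L) %/% (d[1] * d[2])) + 1L)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    li <- tube_voxels(st, dir, runif(1, 60, 120) / vx, max(1, 9 / vx))
    li <- li[labels[li] == cm[["parenchyma"]] & rho2[li] <= ri^2]
    labels[li] <- cm[["venule"]]
  }
  shell_idx <- which(rho2 > 1 & rho2 <= (1 + cp$shell_frac)^2)
  for (i in seq_len(spec$outer_vessel_count)) {
    if (!length(shell_idx)) break
    cidx <- shell_idx[sample.int(length(shell_idx), 1L)]
    st <- c(((cidx - 1L) %% d[1]) + 1L,
            (((cidx - 1L) %/% d[1]) %% d[2]) + 1L,
            ((cidx - 1L) %/% (d[1] * d[2])) + 1L)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    li <- tube_voxels(st, dir, runif(1, 80, 150) / vx, max(1, 7 / vx))
    li <- li[rho2[li] > (ri + cp$scs_frac)^2 &
             rho2[li] <= (1 + cp$shell_frac)^2]
    labels[li] <- cm[["outer_vasculature"]]
  }

  # ---- capillaries: 3-voxel-thick tubes per compartment ----------------
  cap_truth <- list()
  cap_r <- 1.5
  cap_off <- ball_offsets(cap_r)
  for (comp in names(spec$capillary_fraction)) {
    f <- spec$capillary_fraction[[comp]]
    if (f <= 0) next
    code <- cm[[comp]]
    comp_idx <- which(labels == code)
    n0 <- length(comp_idx)
    if (n0 == 0L) next
    target <- as.integer(ceiling(f * n0))
    placed <- 0L
    tubes <- 0L
    max_tubes <- max(2000L, 100L * as.integer(ceiling(target / 50)))
    while (placed < target) {
      tubes <- tubes + 1L
      if (tubes > max_tubes)
        stop(sprintf("phantom placement failed: capillary fraction %.3f unreachable in compartment '%s'",
                     f, comp), call. = FALSE)
      # sample a start voxel still carrying the compartment label
      cidx <- comp_idx[sample.int(n0, 1L)]
      if (labels[cidx] != code) next
      st <- c(((cidx - 1L) %% d[1]) + 1L,
              (((cidx - 1L) %/% d[1]) %% d[2]) + 1L,
              ((cidx - 1L) %/% (d[1] * d[2])) + 1L)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len_vox <- runif(1, 40, 80) / vx
      ts <- seq(-len_vox / 2, len_vox / 2, by = 0.5)
      pts <- unique(round(cbind(st[1] + ts * dir[1], st[2] + ts * dir[2],
                                st[3] + ts * dir[3])))
      vox <- do.call(rbind, lapply(seq_len(nrow(cap_off)), function(k)
        cbind(pts[, 1] + cap_off[k, 1], pts[, 2] + cap_off[k, 2],
              pts[, 3] + cap_off[k, 3])))
      li <- unique(stats::na.omit(lin_index(vox, d)))
      li <- li[labels[li] == code]
      if (!length(li)) next
      # keep tube voxels strictly interior to the compartment (no face
      # contact with other classes), so capillaries attribute unambiguously
      lz <- ((li - 1L) %% d[1]) + 1L
      ly <- (((li - 1L) %/% d[1]) %% d[2]) + 1L
      lx <- (li - 1L) %/% (d[1] * d[2]) + 1L
      okv <- rep(TRUE, length(li))
      for (sft in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                       c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        ni <- lin_index(cbind(lz + sft[1], ly + sft[2], lx + sft[3]), d)
        nv <- labels[ifelse(is.na(ni), 1L, ni)]
        okv <- okv & !is.na(ni) &
          (nv == code | nv == cm[["capillary"]])
      }
      li <- li[okv]
      if (!length(li)) next
      # truncate the final tube so the realized fraction lands on target
      if (placed + length(li) > target) li <- li[seq_len(target - placed)]
      labels[li] <- cm[["capillary"]]
      placed <- placed + length(li)
    }
    cap_truth[[comp]] <- list(fraction_target = f, voxels_initial = n0,
                              voxels_capillary = placed,
                              fraction_realized = placed / n0)
  }

  rm(rho2, medulla, dcu)

  # ---- intensity: class base level plus Gaussian noise -----------------
  levels <- c(background = 0.05, parenchyma = 0.55, medullary_sinus = 0.25,
              DCU = 0.50, follicle = 0.80, subcapsular_sinus = 0.20,
              nodule = 0.85, fat_pad = 0.12, outer_vasculature = 0.30,
              venule = 0.20, capillary = 0.30, adjacent_tissue = 0.35)
  base <- levels[match(names(cm), names(levels))]
  lut <- numeric(max(cm) + 1L)
  lut[cm + 1L] <- base
  intensity <- array(lut[as.integer(labels) + 1L] +
                     rnorm(length(labels), 0, spec$noise_sd), d)

  list(volume = volume3d(intensity, voxel_um = vx),
       labels = label_volume(labels, class_map = cm, voxel_um = vx),
       truth = list(spec = spec, scale = scale, follicles = follicles,
                    nodules = nodules, adipocytes = adipocytes,
                    capillaries = cap_truth))
}

#' Apply isotropic tissue shrinkage to a volume
#'
#' Scales all linear dimensions by `(1 - s)` by resampling onto a grid of
#' `round(dim * (1 - s))` voxels about the volume centre: trilinear
#' interpolation for intensity volumes, nearest-neighbour for label volumes.
#' The voxel size is unchanged (the tissue shrinks, the scanner does not).
#'
#' @param vol a `volume3d` or `label_volume`.
#' @param s linear shrinkage factor in `[0, 1)` (default 0.30).
#' @return object of the same class as `vol`.
#' @export
simulate_shrinkage <- function(vol, s = 0.30) {
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s >= 1)
    stop("simulate_shrinkage: s must lie in [0, 1)")
  if (s == 0) return(vol)
  is_lab <- inherits(vol, "label_volume")
  arr <- if (is_lab) vol$labels else vol$data
  d_in <- dim(arr)
  d_out <- pmax(1L, as.integer(round(d_in * (1 - s))))
  c_in <- (d_in + 1) / 2
  c_out <- (d_out + 1) / 2
  out <- array(if (is_lab) 0L else 0, d_out)
  # chunk over x-planes to bound the coordinate matrix size
  zy <- as.matrix(expand.grid(z = seq_len(d_out[1]), y = seq_len(d_out[2])))
  zc <- c_in[1] + (zy[, 1] - c_out[1]) / (1 - s)
  yc <- c_in[2] + (zy[, 2] - c_out[2]) / (1 - s)
  for (x in seq_len(d_out[3])) {
    xc <- c_in[3] + (x - c_out[3]) / (1 - s)
    coords <- cbind(zc, yc, rep(xc, length(zc)))
    if (is_lab) {
      r <- cpp_sample_nearest(arr, d_in, coords, 0L)
      out[, , x] <- r$values
    } else {
      r <- cpp_sample_trilinear(arr, d_in, coords, 0)
      out[, , x] <- r$values
    }
  }
  if (is_lab) label_volume(out, class_map = vol$class_map,
                           voxel_um = vol$voxel_um)
  else volume3d(out, voxel_um = vol$voxel_um)
}

#' Rasterize a single ellipsoidal object into its own label volume
#'
#' Used to simulate isolated nodules for size-distribution studies: the
#' ellipsoid with major axis `feret_um` and minor/major ratios `ratios` is
#' voxelized at `voxel_um` under a random (or given) orientation.
#'
#' @param feret_um major-axis length in micrometres.
#' @param ratios length-2 minor/major axis ratios.
#' @param voxel_um voxel size.
#' @param rotation optional 3x3 rotation matrix; random when `NULL`.
#' @param class_name label class for the object voxels.
#' @return a [label_volume()] containing the single object.
#' @export
rasterize_ellipsoid <- function(feret_um, ratios = c(1, 1), voxel_um = 1.8,
                                rotation = NULL, class_name = "nodule") {
  stopifnot(feret_um > 0, length(ratios) == 2L, all(ratios > 0))
  if (is.null(rotation)) rotation <- random_rotation()
  cm <- ln_class_map()
  semi <- c(feret_um / 2, ratios[1] * feret_um / 2, ratios[2] * feret_um / 2)
  hb <- as.integer(ceiling(feret_um / 2 / voxel_um)) + 2L
  n <- 2L * hb + 1L
  M <- rotation %*% diag(1 / semi^2) %*% t(rotation)
  inside <- cpp_ellipsoid_mask(hb, voxel_um, M)
  arr <- array(0L, c(n, n, n))
  arr[inside] <- cm[[class_name]]
  label_volume(arr, class_map = cm, voxel_um = voxel_um)
}
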