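#' Packaged phantom configurations
#'
#' Named parameter sets reproducing the study conditions of the reference
#' morphometry: nodule size law 128.57 +/- 38.57 um at native scale (90 +/-
#' 27 um embedded), ~30% linear shrinkage, per-compartment capillary
#' fractions in the ratios follicle:DCU = 2.2 and nodule:DCU = 2.18 over a
#' 2% DCU baseline, and LN volumes sized so the expected nodule volume
#' fractions equal 1.9% (young) and 4.7% (old) and the expected adipocyte
#' fraction equals 0.26% (young popliteal, 15 adipocytes of 40-90 um).
#' Fixture phantoms are rendered at 4.5 um voxels (a desk-scale sampling of
#' the same geometry; the default spec keeps the native 1.8 um).
#'
#' @param name one of `"mandibular_young_1"`, `"mandibular_young_2"`,
#'   `"mandibular_old_1"`, `"mandibular_old_2"`, `"popliteal_young"`,
#'   `"capillary_ratio"`, `"registration"`.
#' @param base_seed base RNG seed; each configuration derives its own seed
#'   as `base_seed + offset` (offsets in [fixture_table()]).
#' @return a [phantom_spec()].
#' @export
phantom_config <- function(name, base_seed = 42L) {
  ft <- fixture_table()
  if (!name %in% ft$name)
    stop("phantom_config: unknown configuration '", name, "'")
  row <- ft[ft$name == name, ]
  common <- list(voxel_um = 4.5,
                 nodule_diam_true_um = c(90 / 0.7, 27 / 0.7),
                 follicle_diam_um = c(120 / 0.7, 18 / 0.7),
                 adipocyte_diam_um = c(40, 90),
                 seed = base_seed + row$seed_offset)
  extra <- switch(name,
    registration = list(follicle_diam_um = c(86, 14),
                        nodule_diam_true_um = c(79, 11),
                        follicle_count = 10L),
    list())
  # counting fixtures carry no intra-nodular capillaries, so the placed
  # objects are guaranteed to satisfy their own acceptance criteria; the
  # vasculature phantom (capillary_ratio) keeps the full fraction map
  if (!name %in% c("capillary_ratio", "registration"))
    common$capillary_fraction <- c(parenchyma = 0.015, DCU = 0.02,
                                   follicle = 0.044)
  args <- modifyList(c(list(
    shape_voxels = c(row$dim_z, row$dim_y, row$dim_x),
    ln_radii_um = c(row$radius_z_um, row$radius_y_um, row$radius_x_um),
    nodule_count = row$nodule_count,
    follicle_count = row$follicle_count,
    adipocyte_count = row$adipocyte_count), common), extra)
  do.call(phantom_spec, args)
}

#' Committed fixture table
#'
#' The canonical per-phantom parameters behind [phantom_config()] and
#' [make_fixtures()]: two "young" LNs with 28 and 29 nodules (mean 28.5)
#' and two "old" LNs with 59 and 60 (mean 59.5), a mildly lipomatous young
#' popliteal LN (15 adipocytes), the capillary-ratio phantom and the
#' registration phantom.
#'
#' @return data.frame of fixture parameters.
#' @export
fixture_table <- function() {
  data.frame(
    name = c("mandibular_young_1", "mandibular_young_2",
             "mandibular_old_1", "mandibular_old_2",
             "popliteal_young", "capillary_ratio", "registration"),
    age = c("young", "young", "old", "old", "young", NA, NA),
    nodule_count = c(28L, 29L, 59L, 60L, 0L, 30L, 8L),
    follicle_count = c(10L, 10L, 10L, 10L, 8L, 12L, 10L),
    adipocyte_count = c(0L, 0L, 0L, 0L, 15L, 0L, 0L),
    dim_z = c(254L, 254L, 240L, 240L, 232L, 256L, 128L),
    dim_y = c(226L, 226L, 214L, 214L, 198L, 256L, 128L),
    dim_x = c(210L, 210L, 200L, 200L, 172L, 256L, 128L),
    radius_z_um = c(548, 548, 515, 515, 500, 560, 260),
    radius_y_um = c(485, 485, 458, 458, 425, 505, 240),
    radius_x_um = c(449, 449, 427, 427, 367, 470, 225),
    seed_offset = 1:7)
}

#' Generate the canonical test fixtures
#'
#' Builds the fixture phantoms of [fixture_table()] plus a registration
#' image pair (ground-truth pose/affine recorded) and a toy abundance
#' matrix. Optionally writes everything to `dir` (TIFF stacks with YAML
#' sidecars, tile TIFFs with an offset CSV, abundance/design CSVs).
#'
#' @param seed base seed (default 42).
#' @param dir optional output directory.
#' @param which subset of fixture names to build (default: all).
#' @return named list of fixtures; phantom entries are
#'   [generate_phantom()] results.
#' @export
make_fixtures <- function(seed = 42L, dir = NULL,
                          which = c("mandibular_young_1",
                                    "mandibular_young_2",
                                    "mandibular_old_1", "mandibular_old_2",
                                    "popliteal_young", "capillary_ratio",
                                    "registration", "proteomics")) {
  out <- list()
  for (nm in setdiff(which, "proteomics")) {
    out[[nm]] <- generate_phantom(phantom_config(nm, base_seed = seed))
  }
  if ("registration" %in% which) {
    ph <- out[["registration"]]
    tiles <- render_sem_view(ph$volume,
                             slice_pose(rx = 4, ry = -3, tx = 5, ty = -4,
                                        tz = 6),
                             inplane_affine(sx = 1.02, sy = 0.98, k = 0.06),
                             tiling = list(upscale = 2L,
                                           tile_shape = c(96L, 96L),
                                           overlap_fraction = 0.15,
                                           jitter_px = 2L,
                                           vignette_strength = 0.25,
                                           noise_sd = 0.01,
                                           seed = seed + 100L))
    out[["registration_tiles"]] <- tiles
  }
  if ("proteomics" %in% which) {
    out[["proteomics"]] <- simulate_abundances(
      n_proteins = 400L, n_per_group = 10L,
      effects = list(n_site = 20L, site_effect = 1.79,
                     n_age_both = 15L, age_effect = 1.2,
                     n_age_site = 10L),
      seed = seed + 8L)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      x <- out[[nm]]
      if (is.list(x) && inherits(x$labels, "label_volume")) {
        write_volume(x$labels, file.path(dir, paste0(nm, "_labels.tif")))
        write_volume(x$volume, file.path(dir, paste0(nm, "_intensity.tif")))
      } else if (inherits(x, "tile_set")) {
        for (i in seq_along(x$tiles))
          tiff::writeTIFF(x$tiles[[i]] / max(abs(x$tiles[[i]])),
                          file.path(dir, sprintf("%s_tile%02d.tif", nm, i)),
                          bits.per.sample = 32L)
        write.csv(data.frame(tile = seq_along(x$tiles),
                             row = x$nominal_offsets[, 1],
                             col = x$nominal_offsets[, 2]),
                  file.path(dir, paste0(nm, "_offsets.csv")),
                  row.names = FALSE)
      } else if (nm == "proteomics") {
        write.csv(as.data.frame(unclass(x$mat)),
                  file.path(dir, "proteomics_log2.csv"))
        write.csv(x$design, file.path(dir, "proteomics_design.csv"),
                  row.names = FALSE)
        write.csv(x$truth, file.path(dir, "proteomics_truth.csv"),
                  row.names = FALSE)
      }
    }
  }
  out
}

#' Simulate and measure isolated nodules
#'
#' Draws `n` ellipsoidal nodules from the corrected-scale size law of
#' `spec` (truncated normal Feret diameters, axis ratios uniform on the
#' spherical-to-ovoid range, random orientations), rasterizes each at the
#' spec's voxel size, applies [simulate_shrinkage()] at the spec's
#' shrinkage factor, and measures the embedded-scale Feret diameter of
#' each object.
#'
#' @param n number of nodules.
#' @param spec a [phantom_spec()] supplying the size law, voxel size and
#'   shrinkage factor (defaults to the package default spec).
#' @param seed integer seed.
#' @param voxel_um raster voxel size for the isolated-object measurement;
#'   defaults to half the spec's acquisition voxel, which halves the
#'   (positive, about one voxel) discretization bias of the maximum-caliper
#'   convention on smooth digital objects.
#' @return data.frame (`true_feret_um`, `embedded_feret_um`,
#'   `measured_feret_um`).
#' @export
simulate_nodule_feret_sample <- function(n = 200L, spec = phantom_spec(),
                                         seed = 7L,
                                         voxel_um = spec$voxel_um / 2) {
  with_seed(seed, {
    D <- rnorm_trunc(n, spec$nodule_diam_true_um[1],
                     spec$nodule_diam_true_um[2], spec$diam_trunc_sd,
                     lower = 3 * voxel_um)
    ratios <- matrix(runif(2 * n, spec$nodule_axis_ratio_range[1],
                           spec$nodule_axis_ratio_range[2]), n)
    rots <- lapply(seq_len(n), function(i) random_rotation())
    measured <- vapply(seq_len(n), function(i) {
      lv <- rasterize_ellipsoid(D[i], ratios[i, ], voxel_um,
                                rotation = rots[[i]])
      sh <- simulate_shrinkage(lv, spec$shrinkage_s)
      if (!any(sh$labels > 0L)) return(NA_real_)
      feret_of_mask(sh$labels > 0L, sh$voxel_um)
    }, numeric(1))
    data.frame(true_feret_um = D,
               embedded_feret_um = D * (1 - spec$shrinkage_s),
               measured_feret_um = measured)
  })
}
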