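#' Run the phantom-to-morphometry pipeline from a configuration
#'
#' Executes the configured stages in order -- phantom generation, volume
#' preprocessing, slice rendering + registration, morphometry -- plus an
#' independent proteomics stage, writing stage outputs and a JSON manifest
#' (parameters, seeds, timings, output checksums) to the output directory.
#' Identical configurations produce identical manifests.
#'
#' @param config configuration list, or path to a YAML file. Required
#'   blocks: `seed`, `out_dir`, `phantom` (either `name` referencing
#'   [phantom_config()] or explicit [phantom_spec()] arguments). Optional
#'   blocks: `preprocess` (`clip_lo`, `clip_hi`), `register` (logical or a
#'   list with `pose`/`affine` values), `morphometry` ([nodule_criteria()]
#'   arguments), `proteomics` ([simulate_abundances()] arguments).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (block in c("seed", "out_dir", "phantom")) {
    if (is.null(config[[block]]))
      stop("run_pipeline: configuration is missing required block '",
           block, "'")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("lymphomorph")),
                   seed = config$seed, stages = list())
  t_stage <- function(expr) {
    t0 <- Sys.time()
    val <- expr
    list(value = val, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }

  # ---- phantom ---------------------------------------------------------
  st <- t_stage({
    spec <- if (!is.null(config$phantom$name)) {
      phantom_config(config$phantom$name, base_seed = config$seed)
    } else {
      args <- config$phantom
      args$seed <- args$seed %||% config$seed
      do.call(phantom_spec, args)
    }
    generate_phantom(spec)
  })
  ph <- st$value
  manifest$stages$phantom <- list(seconds = st$seconds,
                                  nodule_count = nrow(ph$truth$nodules),
                                  voxel_um = ph$labels$voxel_um,
                                  dim = dim(ph$labels$labels))

  # ---- preprocess ------------------------------------------------------
  vol <- ph$volume
  if (!is.null(config$preprocess)) {
    st <- t_stage({
      lo <- config$preprocess$clip_lo %||%
        unname(quantile(vol$data, 0.005))
      hi <- config$preprocess$clip_hi %||%
        unname(quantile(vol$data, 0.995))
      clip_normalize(vol, lo, hi)
    })
    vol <- st$value
    manifest$stages$preprocess <- list(seconds = st$seconds,
                                       range = range(vol$data))
  }

  # ---- registration demo ----------------------------------------------
  if (isTRUE(config$register) || is.list(config$register)) {
    st <- t_stage({
      rc <- if (is.list(config$register)) config$register else list()
      pose <- do.call(slice_pose, rc$pose %||% list(rx = 3, tz = 5))
      aff <- do.call(inplane_affine, rc$affine %||% list(k = 0.05))
      tiles <- render_sem_view(vol, pose, aff,
                               tiling = list(upscale = 1L,
                                             tile_shape = dim(vol$data)[2:3],
                                             noise_sd = 0.01,
                                             seed = config$seed))
      img <- invert_contrast(stitch_tiles(tiles, refine = FALSE)$image)
      res <- register_slice(vol, img,
                            sched = reg_schedule(pyramid_factors = c(4, 2, 1)))
      list(true_pose = pose, true_affine = aff, result = res)
    })
    r <- st$value$result
    manifest$stages$register <- list(
      seconds = st$seconds, mi_bits = r$mi_bits, converged = r$converged,
      pose_error = c(rx = r$pose$rx - st$value$true_pose$rx,
                     tz = r$pose$tz - st$value$true_pose$tz),
      shear_error = r$affine$k - st$value$true_affine$k)
  }

  # ---- morphometry -----------------------------------------------------
  st <- t_stage({
    crit <- do.call(nodule_criteria, config$morphometry %||% list())
    objs <- connected_components(ph$labels, "nodule",
                                 min_voxels = crit$min_voxels)
    nod <- classify_nodules(objs, ph$labels, crit)
    attribution <- attribute_capillaries(ph$labels)
    comp <- c("follicle", "DCU", "nodule")
    comp <- comp[vapply(comp, function(cc)
      sum(ph$labels$labels == ph$labels$class_map[[cc]]) > 0, logical(1))]
    stats <- lapply(comp, function(cc)
      compartment_stats(ph$labels, cc, attribution))
    names(stats) <- comp
    list(objects = nod, stats = stats)
  })
  nod_df <- as.data.frame(st$value$objects)
  nod_df$feret_corrected_um <- vapply(st$value$objects, `[[`, numeric(1),
                                      "feret_corrected_um")
  obj_csv <- file.path(config$out_dir, "nodules.csv")
  write.csv(nod_df, obj_csv, row.names = FALSE)
  comp_df <- do.call(rbind, lapply(st$value$stats, function(s)
    data.frame(compartment = s$compartment, total_voxels = s$total_voxels,
               capillary_voxels = s$capillary_voxels,
               capillary_density = s$capillary_density,
               volume_fraction_pct = s$volume_fraction_pct)))
  comp_csv <- file.path(config$out_dir, "compartments.csv")
  write.csv(comp_df, comp_csv, row.names = FALSE)
  summ <- list(nodule_count = nrow(nod_df),
               mean_feret_um = mean(nod_df$feret_um),
               mean_feret_corrected_um = mean(nod_df$feret_corrected_um),
               nodule_volume_fraction_pct =
                 volume_fraction(ph$labels, "nodule"),
               density_ratios = if (all(c("follicle", "DCU", "nodule")
                                        %in% names(st$value$stats))) {
                 list(follicle_dcu = density_ratio(st$value$stats$follicle,
                                                   st$value$stats$DCU),
                      nodule_dcu = density_ratio(st$value$stats$nodule,
                                                 st$value$stats$DCU))
               })
  summ_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summ, summ_json, auto_unbox = TRUE, digits = NA)
  manifest$stages$morphometry <- list(seconds = st$seconds,
                                      accepted_nodules = nrow(nod_df))

  # ---- proteomics (independent) ----------------------------------------
  if (!is.null(config$proteomics)) {
    st <- t_stage({
      args <- config$proteomics
      args$seed <- args$seed %||% config$seed
      sim <- do.call(simulate_abundances, args)
      rows <- adaptive_test(sim$mat, sim$design, "mand_vs_sub_mean")
      write.csv(rows, file.path(config$out_dir, "differential.csv"),
                row.names = FALSE)
      write.csv(volcano_table(rows),
                file.path(config$out_dir, "volcano.csv"), row.names = FALSE)
      nrow(rows)
    })
    manifest$stages$proteomics <- list(seconds = st$seconds,
                                       proteins = st$value)
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest[.]json$", outputs)]
  manifest$outputs <- lapply(setNames(outputs, basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
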