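#' The canonical eleven-class lymph-node label map
#'
#' Integer codes for the anatomical classes segmented in whole-LN volumes:
#' parenchyma, medullary sinuses, deep cortical unit (DCU), B-cell follicles,
#' subcapsular sinuses, medullary nodules, fat pad (adipocytes), outer
#' vasculature, venules, capillaries and adjacent (non-LN) tissue, plus
#' 0 for background.
#'
#' @return named integer vector mapping class name to label code.
#' @export
ln_class_map <- function() {
  c(background = 0L, parenchyma = 1L, medullary_sinus = 2L, DCU = 3L,
    follicle = 4L, subcapsular_sinus = 5L, nodule = 6L, fat_pad = 7L,
    outer_vasculature = 8L, venule = 9L, capillary = 10L,
    adjacent_tissue = 11L)
}

#' 3D intensity volume
#'
#' A lightweight container for an isotropic scalar volume. Axis order is
#' fixed to (z, y, x): the first array dimension is the slice axis.
#'
#' @param data numeric 3D array.
#' @param voxel_um voxel edge length in micrometres (> 0).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_um = 1.8) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(voxel_um), length(voxel_um) == 1L, voxel_um > 0)
  if (!all(is.finite(data))) stop("volume3d: data contains non-finite values")
  structure(list(data = data, voxel_um = as.numeric(voxel_um)),
            class = "volume3d")
}

#' Integer label volume with class map
#'
#' @param labels integer 3D array; every voxel carries exactly one label.
#' @param class_map named integer vector mapping class name to code; must
#'   cover every label present.
#' @param voxel_um voxel edge length in micrometres.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, class_map = ln_class_map(), voxel_um = 1.8) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            is.numeric(voxel_um), voxel_um > 0)
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.integer(labels)))
  if (!all(present %in% class_map))
    stop("label_volume: labels present without class_map entry: ",
         paste(setdiff(present, class_map), collapse = ", "))
  structure(list(labels = labels, class_map = class_map,
                 voxel_um = as.numeric(voxel_um)),
            class = "label_volume")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels (z,y,x), %.3g um/voxel, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(as.integer(x$labels) + 1L, nbins = max(x$class_map) + 1L)
  present <- names(x$class_map)[x$class_map %in% (which(tab > 0) - 1L)]
  cat(sprintf("label_volume: %d x %d x %d voxels (z,y,x), %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_um))
  cat("  classes present:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

class_mask <- function(lab, class_name) {
  if (!class_name %in% names(lab$class_map))
    stop("unknown class: ", class_name)
  lab$labels == lab$class_map[[class_name]]
}

#' Micrograph tile mosaic
#'
#' @param tiles list of numeric matrices (>= 1).
#' @param nominal_offsets integer matrix (n x 2) of per-tile (row, col) pixel
#'   offsets of each tile's top-left corner in mosaic coordinates.
#' @param overlap_fraction nominal fractional overlap between neighbours.
#' @param pixel_um pixel pitch in micrometres.
#' @param meta optional list of generation metadata (ground-truth pose,
#'   affine, vignette model) recorded by the renderer for tests.
#' @return an object of class `tile_set`.
#' @export
tile_set <- function(tiles, nominal_offsets, overlap_fraction = 0.1,
                     pixel_um = 1.8, meta = list()) {
  stopifnot(is.list(tiles), length(tiles) >= 1L,
            all(vapply(tiles, is.matrix, logical(1))),
            is.matrix(nominal_offsets), nrow(nominal_offsets) == length(tiles),
            ncol(nominal_offsets) == 2L)
  structure(list(tiles = tiles, nominal_offsets = nominal_offsets,
                 overlap_fraction = overlap_fraction, pixel_um = pixel_um,
                 meta = meta),
            class = "tile_set")
}

#' Write / read a volume as a multi-page TIFF with a YAML sidecar
#'
#' One TIFF page per z-slice; the sidecar records `voxel_um` (and the class
#' map for label volumes). Intensities are stored as 32-bit float; labels as
#' integer-valued floats (TIFF container limitation, restored on read).
#'
#' @param vol a `volume3d` or `label_volume`.
#' @param path output TIFF path; the sidecar is written at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_lab <- inherits(vol, "label_volume")
  arr <- if (is_lab) vol$labels else vol$data
  d <- dim(arr)
  # the TIFF writer stores values on [0, 1]: map integer labels through a
  # recorded scale and clip intensities to their recorded range
  if (is_lab) {
    scale <- max(1L, max(arr))
    rng <- c(0, scale)
  } else {
    rng <- range(arr)
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  }
  pages <- lapply(seq_len(d[1]), function(z)
    matrix((as.numeric(arr[z, , ]) - rng[1]) / (rng[2] - rng[1]),
           d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = if (is_lab) 16L else 32L,
                  reduce = FALSE)
  side <- list(voxel_um = vol$voxel_um,
               kind = if (is_lab) "labels" else "intensity",
               value_range = rng)
  if (is_lab) side$class_map <- as.list(vol$class_map)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, d)
  rng <- unlist(side$value_range)
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * (rng[2] - rng[1]) +
    rng[1]
  if (identical(side$kind, "labels")) {
    arr <- round(arr)
    storage.mode(arr) <- "integer"
    cm <- unlist(side$class_map)
    storage.mode(cm) <- "integer"
    label_volume(arr, class_map = cm, voxel_um = side$voxel_um)
  } else {
    volume3d(arr, voxel_um = side$voxel_um)
  }
}
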