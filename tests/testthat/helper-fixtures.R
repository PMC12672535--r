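# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small, fast phantom for unit tests
small_phantom_spec <- function(nodule_count = 10L, seed = 42L, ...) {
  phantom_spec(shape_voxels = c(120L, 110L, 100L), voxel_um = 4.5,
               ln_radii_um = c(250, 230, 210),
               follicle_count = 5L, follicle_diam_um = c(60, 8),
               nodule_count = nodule_count,
               nodule_diam_true_um = c(60, 8),
               seed = seed, ...)
}

small_phantom <- function() {
  cached("small_phantom", function() generate_phantom(small_phantom_spec()))
}

registration_phantom <- function() {
  cached("registration_phantom", function()
    generate_phantom(phantom_config("registration")))
}

# independent flood-fill oracle: 26-connected component count by repeated
# seed growth over a coordinate set (pure R, no shared code path)
flood_fill_count <- function(mask) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  if (!nrow(coords)) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  remaining <- new.env(parent = emptyenv())
  for (k in key(coords)) assign(k, TRUE, envir = remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n <- 0L
  all_keys <- key(coords)
  coord_of <- setNames(split(coords, row(coords)), all_keys)
  while (length(ls(remaining))) {
    n <- n + 1L
    seed_key <- ls(remaining)[1]
    queue <- list(coord_of[[seed_key]])
    rm(list = seed_key, envir = remaining)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(p), "+")
      nk <- key(nb)
      hit <- nk[vapply(nk, exists, logical(1), envir = remaining)]
      for (k in hit) {
        rm(list = k, envir = remaining)
        queue <- c(queue, list(coord_of[[k]]))
      }
    }
  }
  n
}

# brute-force Feret oracle: max pairwise distance over all voxel centres
# of the mask plus one voxel
feret_brute_force <- function(mask, voxel_um) {
  coords <- which(mask, arr.ind = TRUE) * voxel_um
  max(dist(coords)) + voxel_um
}
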