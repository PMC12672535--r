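#' Connected components of a label class
#'
#' Extracts 26-connected components of one class of a label volume,
#' discards components below `min_voxels`, and computes per-object
#' morphometrics: voxel count, volume, centroid, bounding box, maximum
#' Feret diameter and sphericity. Objects are ordered deterministically by
#' the (z, y, x) coordinates of their first voxel.
#'
#' @param labels a [label_volume()].
#' @param class_name class to analyse (must be present in the class map).
#' @param min_voxels minimum component size retained (default 1).
#' @return an object of class `segmented_objects`: a list of per-object
#'   lists (`object_id`, `class_name`, `voxel_count`, `volume_um3`,
#'   `centroid_um`, `bounding_box`, `feret_um`, `sphericity`, `voxels`,
#'   `surface_voxels`); convert with [as.data.frame()].
#' @export
connected_components <- function(labels, class_name, min_voxels = 1L) {
  stopifnot(inherits(labels, "label_volume"))
  if (!class_name %in% names(labels$class_map))
    stop("connected_components: unknown class '", class_name, "'")
  d <- dim(labels$labels)
  vx <- labels$voxel_um
  mask <- labels$labels == labels$class_map[[class_name]]
  if (!any(mask)) {
    return(structure(list(), class = "segmented_objects"))
  }
  lab <- cpp_label_components(as.vector(mask), d)
  ncomp <- attr(lab, "n_components")
  surf <- cpp_component_surfaces(lab, d, ncomp)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  zz <- ((idx - 1L) %% d[1]) + 1L
  yy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  xx <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  ord <- order(comp)
  comp <- comp[ord]; zz <- zz[ord]; yy <- yy[ord]; xx <- xx[ord]
  is_surf <- surf$surface[idx][ord]
  bounds <- c(0L, cumsum(tabulate(comp, ncomp)))
  objs <- vector("list", ncomp)
  keep <- logical(ncomp)
  for (i in seq_len(ncomp)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    n <- length(sel)
    if (n < min_voxels) next
    vz <- zz[sel]; vy <- yy[sel]; vxx <- xx[sel]
    vox <- cbind(z = vz, y = vy, x = vxx)
    sv <- vox[is_surf[sel], , drop = FALSE]
    objs[[i]] <- structure(list(
      object_id = NA_integer_,
      class_name = class_name,
      voxel_count = n,
      volume_um3 = n * vx^3,
      centroid_um = c(mean(vz), mean(vy), mean(vxx)) * vx,
      bounding_box = rbind(min = c(min(vz), min(vy), min(vxx)),
                           max = c(max(vz), max(vy), max(vxx))),
      feret_um = feret_from_voxels(sv, vx),
      sphericity = if (n >= 8L)
        sphericity_value(n, surf$faces[i], vx) else NA_real_,
      voxels = vox,
      surface_voxels = sv), class = "segmented_object")
    keep[i] <- TRUE
  }
  objs <- objs[keep]
  # deterministic ordering by (z, y, x) of each object's first voxel
  first <- t(vapply(objs, function(o) o$voxels[
    order(o$voxels[, 1], o$voxels[, 2], o$voxels[, 3])[1], ], numeric(3)))
  if (length(objs)) {
    ord2 <- order(first[, 1], first[, 2], first[, 3])
    objs <- objs[ord2]
    for (i in seq_along(objs)) objs[[i]]$object_id <- i
  }
  structure(objs, class = "segmented_objects")
}

#' @export
as.data.frame.segmented_objects <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(object_id = integer(), class_name = character(),
                      voxel_count = integer(), volume_um3 = numeric(),
                      feret_um = numeric(), sphericity = numeric(),
                      centroid_z_um = numeric(), centroid_y_um = numeric(),
                      centroid_x_um = numeric()))
  }
  data.frame(
    object_id = vapply(x, `[[`, integer(1), "object_id"),
    class_name = vapply(x, `[[`, character(1), "class_name"),
    voxel_count = vapply(x, `[[`, integer(1), "voxel_count"),
    volume_um3 = vapply(x, `[[`, numeric(1), "volume_um3"),
    feret_um = vapply(x, `[[`, numeric(1), "feret_um"),
    sphericity = vapply(x, function(o) o$sphericity %||% NA_real_,
                        numeric(1)),
    centroid_z_um = vapply(x, function(o) o$centroid_um[1], numeric(1)),
    centroid_y_um = vapply(x, function(o) o$centroid_um[2], numeric(1)),
    centroid_x_um = vapply(x, function(o) o$centroid_um[3], numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximum pairwise distance between surface-voxel centres plus one voxel.
# Small sets are solved exactly; larger sets are first reduced to their
# support points (extrema along a fixed set of sphere directions), a subset
# of the convex-hull vertices that carries the diameter to high accuracy.
feret_from_voxels <- function(sv, voxel_um, exact_limit = 400L) {
  n <- nrow(sv)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(voxel_um)
  P <- sv * voxel_um
  if (n > exact_limit) {
    dirs <- fibonacci_directions(256L)
    proj <- P %*% t(dirs)
    cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    P <- P[cand, , drop = FALSE]
  }
  # max pairwise distance among (reduced) points
  G <- P %*% t(P)
  sq <- diag(G)
  d2 <- outer(sq, sq, "+") - 2 * G
  sqrt(max(d2)) + voxel_um
}

# Feret diameter of a single binary mask (fast path for isolated objects):
# surface voxels found by 6-neighbour comparison, then the usual
# support-point reduction.
feret_of_mask <- function(mask, voxel_um) {
  sv <- cpp_surface_coords(as.vector(mask), dim(mask))
  feret_from_voxels(sv, voxel_um)
}

# quasi-uniform unit directions (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * sin(theta), sin(phi) * cos(theta))
}

#' Maximum 3D Feret diameter of a segmented object
#'
#' Convention: the maximum Euclidean distance between surface-voxel centres
#' plus one voxel size (accounting for voxel extent), so a single voxel has
#' Feret diameter equal to the voxel size.
#'
#' @param obj a `segmented_object` (from [connected_components()]).
#' @param voxel_um voxel size; defaults to the value implied by the object.
#' @return Feret diameter in micrometres.
#' @export
feret_diameter <- function(obj, voxel_um = NULL) {
  stopifnot(inherits(obj, "segmented_object"))
  if (is.null(voxel_um)) return(obj$feret_um)
  feret_from_voxels(obj$surface_voxels, voxel_um)
}

sphericity_value <- function(voxel_count, faces, voxel_um,
                             lattice_correction = 0.735) {
  V <- voxel_count * voxel_um^3
  A <- faces * voxel_um^2 * lattice_correction
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Sphericity of a segmented object
#'
#' psi = pi^(1/3) (6V)^(2/3) / A with V the voxel volume and A a surface
#' area estimated from exposed boundary-face counting with a 0.735 lattice
#' correction (the expected overcount of axis-aligned faces relative to the
#' true area of a randomly oriented smooth surface).
#'
#' @param obj a `segmented_object` with at least 8 voxels.
#' @return sphericity in (0, 1.05] (slight overshoot possible from
#'   discretization).
#' @export
sphericity <- function(obj) {
  stopifnot(inherits(obj, "segmented_object"))
  if (obj$voxel_count < 8L)
    stop("sphericity: object too small (< 8 voxels)")
  obj$sphericity
}

#' Morphological nodule acceptance criteria
#'
#' Operationalizes the nodule definition: (i) localization within the
#' medulla (near medullary sinuses), (ii) spherical-to-ovoid shape via a
#' sphericity floor, (iii) Feret diameter window at the embedded scale.
#' The fourth published criterion (a LYVE-1+ lymphatic cell boundary) is a
#' molecular-imaging property and is not computable from label geometry;
#' it is intentionally excluded here.
#'
#' @param require_medulla enforce criterion (i).
#' @param sphericity_min sphericity floor (default 0.6).
#' @param feret_um_range accepted Feret window at embedded scale, um
#'   (default c(30, 180)).
#' @param min_voxels minimum object size (default 50).
#' @param shrinkage_s shrinkage factor used when reporting corrected
#'   diameters (default 0.30).
#' @param medulla_radius_um maximum distance from the object surface to the
#'   nearest medullary-sinus voxel for criterion (i) (default 45).
#' @return an object of class `nodule_criteria`.
#' @export
nodule_criteria <- function(require_medulla = TRUE, sphericity_min = 0.6,
                            feret_um_range = c(30, 180), min_voxels = 50L,
                            shrinkage_s = 0.30, medulla_radius_um = 45) {
  stopifnot(feret_um_range[1] < feret_um_range[2],
            shrinkage_s >= 0, shrinkage_s < 1, sphericity_min > 0)
  structure(list(require_medulla = require_medulla,
                 sphericity_min = sphericity_min,
                 feret_um_range = feret_um_range,
                 min_voxels = as.integer(min_voxels),
                 shrinkage_s = shrinkage_s,
                 medulla_radius_um = medulla_radius_um),
            class = "nodule_criteria")
}

# is any medullary-sinus voxel within `radius_um` of the object surface?
near_medullary_sinus <- function(obj, labels, radius_um) {
  cm <- labels$class_map
  if (!"medullary_sinus" %in% names(cm))
    stop("classify_nodules: class map lacks 'medullary_sinus'")
  d <- dim(labels$labels)
  vx <- labels$voxel_um
  r_vox <- radius_um / vx
  bb <- obj$bounding_box
  lo <- pmax(bb["min", ] - ceiling(r_vox), 1)
  hi <- pmin(bb["max", ] + ceiling(r_vox), d)
  sub <- labels$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sidx <- which(sub == cm[["medullary_sinus"]])
  if (!length(sidx)) return(FALSE)
  # fast path: sinus voxel directly adjacent to the bounding box
  dsub <- dim(sub)
  sz <- ((sidx - 1L) %% dsub[1]) + lo[1] - 1L
  sy <- (((sidx - 1L) %/% dsub[1]) %% dsub[2]) + lo[2] - 1L
  sx <- ((sidx - 1L) %/% (dsub[1] * dsub[2])) + lo[3] - 1L
  S <- cbind(sz + 1L, sy + 1L, sx + 1L)
  inb <- S[, 1] >= bb["min", 1] - 2 & S[, 1] <= bb["max", 1] + 2 &
         S[, 2] >= bb["min", 2] - 2 & S[, 2] <= bb["max", 2] + 2 &
         S[, 3] >= bb["min", 3] - 2 & S[, 3] <= bb["max", 3] + 2
  if (any(inb)) return(TRUE)
  # general path: minimum surface-to-sinus distance (deterministic
  # thinning of both point sets bounds the cost)
  thin <- function(M, cap = 800L) {
    if (nrow(M) <= cap) return(M)
    M[seq(1L, nrow(M), length.out = cap), , drop = FALSE]
  }
  A <- thin(obj$surface_voxels) * vx
  B <- thin(S) * vx
  G <- A %*% t(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
  sqrt(max(0, min(d2))) <= radius_um
}

#' Classify medullary nodules among segmented objects
#'
#' Applies the geometric criteria of [nodule_criteria()] to a set of
#' segmented objects: medullary localization, sphericity floor, Feret
#' window, minimum size. The returned objects gain a
#' `feret_corrected_um` field (`feret_um / (1 - shrinkage_s)`).
#'
#' @param objects a `segmented_objects` list.
#' @param labels the [label_volume()] the objects came from (for the
#'   medulla test).
#' @param crit a [nodule_criteria()].
#' @return accepted objects as a `segmented_objects` list (a subset of the
#'   input), with attribute `rejected` recording per-object reasons.
#' @export
classify_nodules <- function(objects, labels,
                             crit = nodule_criteria()) {
  stopifnot(inherits(objects, "segmented_objects"),
            inherits(labels, "label_volume"),
            inherits(crit, "nodule_criteria"))
  if (crit$require_medulla &&
      !"medullary_sinus" %in% names(labels$class_map))
    stop("classify_nodules: class map lacks 'medullary_sinus'")
  keep <- logical(length(objects))
  why <- character(length(objects))
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    if (o$voxel_count < crit$min_voxels) { why[i] <- "too_small"; next }
    if (o$feret_um < crit$feret_um_range[1] ||
        o$feret_um > crit$feret_um_range[2]) { why[i] <- "feret"; next }
    if (!is.na(o$sphericity) && o$sphericity < crit$sphericity_min) {
      why[i] <- "sphericity"; next
    }
    if (crit$require_medulla &&
        !near_medullary_sinus(o, labels, crit$medulla_radius_um)) {
      why[i] <- "not_medullary"; next
    }
    keep[i] <- TRUE
  }
  out <- objects[keep]
  for (i in seq_along(out))
    out[[i]]$feret_corrected_um <- shrinkage_correct(out[[i]]$feret_um,
                                                     crit$shrinkage_s)
  structure(out, class = "segmented_objects",
            rejected = data.frame(
              object_id = vapply(objects[!keep], `[[`, integer(1),
                                 "object_id"),
              reason = why[!keep]))
}

#' Attribute capillary voxels to their surrounding compartments
#'
#' Each capillary voxel takes the majority class among its 6-neighbours'
#' non-capillary labels; interior tube voxels inherit iteratively from
#' attributed neighbours (the nearest non-capillary label). Ties break to
#' the smaller class code. The result can be passed to
#' [capillary_density()] / [compartment_stats()] to avoid repeating the
#' global pass when querying several compartments.
#'
#' @param labels a [label_volume()] containing a `capillary` class.
#' @return integer vector of attributed class codes, named by the linear
#'   voxel index of each capillary voxel (NA when unattributable).
#' @export
attribute_capillaries <- function(labels) {
  cm <- labels$class_map
  if (!"capillary" %in% names(cm)) stop("class map lacks 'capillary'")
  cap_code <- cm[["capillary"]]
  d <- dim(labels$labels)
  idx <- which(labels$labels == cap_code)
  if (!length(idx)) return(integer(0))
  zz <- ((idx - 1L) %% d[1]) + 1L
  yy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  xx <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  shifts <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  neigh <- matrix(NA_integer_, length(idx), 6L)
  pos <- integer(length(labels$labels))
  pos[idx] <- seq_along(idx)   # map linear index -> capillary row
  for (s in seq_len(6L)) {
    li <- lin_index(cbind(zz + shifts[s, 1], yy + shifts[s, 2],
                          xx + shifts[s, 3]), d)
    v <- rep(NA_integer_, length(idx))
    okn <- !is.na(li)
    v[okn] <- labels$labels[li[okn]]
    neigh[, s] <- v
    attr(neigh, paste0("li", s)) <- li
  }
  assigned <- rep(NA_integer_, length(idx))
  codes <- sort(setdiff(unique(as.vector(neigh)), c(NA, cap_code)))
  majority <- function(M) {
    best <- rep(NA_integer_, nrow(M))
    bestn <- integer(nrow(M))
    for (cc in codes) {
      ncc <- rowSums(M == cc, na.rm = TRUE)
      upd <- ncc > bestn
      best[upd] <- cc
      bestn[upd] <- ncc[upd]
    }
    best[bestn == 0L] <- NA_integer_
    best
  }
  assigned <- majority(neigh)
  # propagate attribution into tube interiors
  for (iter in seq_len(10L)) {
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    M <- matrix(NA_integer_, length(todo), 6L)
    for (s in seq_len(6L)) {
      li <- attr(neigh, paste0("li", s))[todo]
      v <- rep(NA_integer_, length(todo))
      okn <- !is.na(li)
      vlab <- labels$labels[li[okn]]
      v[okn] <- ifelse(vlab == cap_code,
                       assigned[pos[li[okn]]], vlab)
      M[, s] <- v
    }
    newv <- majority(M)
    if (all(is.na(newv))) break
    assigned[todo] <- newv
  }
  setNames(assigned, idx)
}

#' Capillary density of a compartment
#'
#' Capillary voxels are attributed to the compartment whose label dominates
#' their immediate non-capillary neighbourhood (nearest non-capillary
#' label, propagated into tube interiors). Density is the attributed
#' capillary voxel fraction: attributed / (compartment voxels +
#' attributed).
#'
#' @param labels a [label_volume()] containing `capillary` and the
#'   compartment class.
#' @param compartment compartment class name.
#' @param attribution optional precomputed attribution (from
#'   `attribute_capillaries`), to avoid repeating the global pass when
#'   querying several compartments.
#' @return density in `[0, 1]`.
#' @export
capillary_density <- function(labels, compartment, attribution = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (!compartment %in% names(labels$class_map))
    stop("capillary_density: unknown compartment '", compartment, "'")
  n_comp <- sum(labels$labels == labels$class_map[[compartment]])
  if (n_comp == 0L)
    stop("capillary_density: compartment '", compartment, "' is empty")
  if (is.null(attribution)) attribution <- attribute_capillaries(labels)
  n_cap <- sum(attribution == labels$class_map[[compartment]], na.rm = TRUE)
  n_cap / (n_comp + n_cap)
}

#' Per-compartment statistics
#'
#' @param labels a [label_volume()].
#' @param compartment compartment class name.
#' @param attribution optional precomputed capillary attribution.
#' @return an object of class `compartment_stats` with `compartment`,
#'   `total_voxels`, `capillary_voxels`, `capillary_density`,
#'   `volume_fraction_pct`.
#' @export
compartment_stats <- function(labels, compartment, attribution = NULL) {
  if (is.null(attribution)) attribution <- attribute_capillaries(labels)
  n_comp <- sum(labels$labels == labels$class_map[[compartment]])
  n_cap <- sum(attribution == labels$class_map[[compartment]], na.rm = TRUE)
  structure(list(compartment = compartment, total_voxels = n_comp,
                 capillary_voxels = n_cap,
                 capillary_density = n_cap / (n_comp + n_cap),
                 volume_fraction_pct = volume_fraction(labels, compartment)),
            class = "compartment_stats")
}

#' Ratio of capillary densities between two compartments
#'
#' @param stats_a,stats_b `compartment_stats` objects (numerator,
#'   denominator).
#' @return `stats_a$capillary_density / stats_b$capillary_density`.
#' @export
density_ratio <- function(stats_a, stats_b) {
  stopifnot(inherits(stats_a, "compartment_stats"),
            inherits(stats_b, "compartment_stats"))
  if (stats_b$capillary_density <= 0)
    stop("density_ratio: denominator compartment has zero capillary density")
  stats_a$capillary_density / stats_b$capillary_density
}

#' Volume fraction of a class within the lymph node
#'
#' Percentage of the LN mask (all classes except background and adjacent
#' tissue) occupied by `class_name`.
#'
#' @param labels a [label_volume()].
#' @param class_name class of interest.
#' @return percentage in `[0, 100]`.
#' @export
volume_fraction <- function(labels, class_name) {
  stopifnot(inherits(labels, "label_volume"))
  cm <- labels$class_map
  if (!class_name %in% names(cm))
    stop("volume_fraction: unknown class '", class_name, "'")
  excl <- cm[names(cm) %in% c("background", "adjacent_tissue")]
  ln_mask_n <- sum(!(labels$labels %in% excl))
  if (ln_mask_n == 0L) stop("volume_fraction: empty LN mask")
  100 * sum(labels$labels == cm[[class_name]]) / ln_mask_n
}

#' Correct a diameter for linear tissue shrinkage
#'
#' Converts an embedded-specimen dimension to its estimated native value:
#' `d / (1 - s)`.
#'
#' @param d_um measured diameter(s) in micrometres (> 0).
#' @param s linear shrinkage factor in `[0, 1)` (default 0.30).
#' @return corrected diameter(s).
#' @export
shrinkage_correct <- function(d_um, s = 0.30) {
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s >= 1)
    stop("shrinkage_correct: s must lie in [0, 1)")
  if (any(d_um <= 0)) stop("shrinkage_correct: diameters must be positive")
  d_um / (1 - s)
}

#' Two-group comparison (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when both groups
#' have n <= 8 and there are no ties, normal approximation with continuity
#' correction otherwise. Significance stars follow the convention
#' `**` for p <= 0.01 and `*` for p <= 0.05.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list with `statistic`, `p`, `stars`.
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop("compare_groups: empty group")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1   # degenerate case: complete ties carry no evidence
  stars <- if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
  list(statistic = unname(wt$statistic), p = p, stars = stars)
}
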