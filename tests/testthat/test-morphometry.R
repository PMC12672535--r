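test_that("Feret diameter follows the voxel-caliper convention", {
  cm <- ln_class_map()
  # single voxel: Feret equals the voxel size
  a1 <- array(0L, c(3, 3, 3)); a1[2, 2, 2] <- cm[["nodule"]]
  o1 <- connected_components(label_volume(a1, voxel_um = 1.8), "nodule")
  expect_equal(o1[[1]]$feret_um, 1.8)
  # 1x1x20 rod at 1.8 um: 19 * 1.8 + 1.8 = 36
  a2 <- array(0L, c(5, 5, 24)); a2[3, 3, 3:22] <- cm[["nodule"]]
  o2 <- connected_components(label_volume(a2, voxel_um = 1.8), "nodule")
  expect_equal(o2[[1]]$feret_um, 36)
  # digital ball radius 10 voxels: 36 +/- one voxel, against brute force
  ball <- rasterize_ellipsoid(36, c(1, 1), 1.8, rotation = diag(3))
  ob <- connected_components(ball, "nodule")[[1]]
  expect_equal(ob$feret_um, feret_brute_force(ball$labels > 0L, 1.8))
  expect_lt(abs(ob$feret_um - 36), 1.8 + 1e-9)
})

test_that("support-point Feret equals brute force on random ellipsoids", {
  set.seed(31)
  for (i in 1:4) {
    D <- runif(1, 30, 70)
    lv <- rasterize_ellipsoid(D, runif(2, 0.7, 1), 2.5)
    obj <- connected_components(lv, "nodule")[[1]]
    expect_equal(obj$feret_um, feret_brute_force(lv$labels > 0L, 2.5),
                 tolerance = 1e-9)
  }
})

test_that("Feret is invariant to translation and stable under rotation", {
  cm <- ln_class_map()
  ball <- rasterize_ellipsoid(40, c(1, 1), 2, rotation = diag(3))
  f0 <- connected_components(ball, "nodule")[[1]]$feret_um
  # translated copy inside a larger array
  big <- array(0L, dim(ball$labels) + 10L)
  big[5 + seq_len(dim(ball$labels)[1]), 3 + seq_len(dim(ball$labels)[2]),
      7 + seq_len(dim(ball$labels)[3])] <- ball$labels
  f1 <- connected_components(label_volume(big, voxel_um = 2),
                             "nodule")[[1]]$feret_um
  expect_equal(f0, f1)
  set.seed(32)
  for (i in 1:3) {
    rot <- rasterize_ellipsoid(40, c(1, 1), 2)   # random orientation
    fr <- connected_components(rot, "nodule")[[1]]$feret_um
    expect_lt(abs(fr - f0), 2 + 1e-9)            # within one voxel
  }
})

test_that("sphericity separates balls from rods and stays bounded", {
  # large digital ball approaches the lattice-corrected sphere limit
  ball <- rasterize_ellipsoid(120, c(1, 1), 1.8, rotation = diag(3))
  ob <- connected_components(ball, "nodule")[[1]]
  expect_gte(ob$sphericity, 0.9)
  expect_lte(ob$sphericity, 1.05)
  # elongated rod scores far lower than the nodule threshold
  cm <- ln_class_map()
  rod <- array(0L, c(5, 5, 24)); rod[3, 3, 3:22] <- cm[["nodule"]]
  orod <- connected_components(label_volume(rod, voxel_um = 1.8), "nodule")
  expect_lt(orod[[1]]$sphericity, 0.6)
  expect_gt(orod[[1]]$sphericity, 0)
  # too-small objects are rejected
  a1 <- array(0L, c(3, 3, 3)); a1[2, 2, 2] <- cm[["nodule"]]
  o1 <- connected_components(label_volume(a1, voxel_um = 1.8), "nodule")
  expect_error(sphericity(o1[[1]]), "too small")
})

test_that("connected components: empty class, counts, sizes, ordering", {
  cm <- ln_class_map()
  arr <- array(0L, c(20, 20, 20))
  lv <- label_volume(arr, voxel_um = 2)
  expect_length(connected_components(lv, "nodule"), 0L)
  expect_error(connected_components(lv, "nonexistent"), "unknown class")
  # two disjoint balls with known voxel counts (flood-fill oracle)
  arr[3:7, 3:7, 3:7] <- cm[["nodule"]]       # 125-voxel cube
  arr[12:18, 12:18, 12:18] <- cm[["nodule"]] # 343-voxel cube
  lv <- label_volume(arr, voxel_um = 2)
  objs <- connected_components(lv, "nodule")
  expect_length(objs, 2L)
  expect_equal(flood_fill_count(arr == cm[["nodule"]]), 2L)
  expect_equal(sort(vapply(objs, `[[`, integer(1), "voxel_count")),
               c(125L, 343L))
  expect_equal(objs[[1]]$volume_um3, objs[[1]]$voxel_count * 8)
  # deterministic ordering by first voxel and min_voxels filtering
  expect_equal(objs[[1]]$voxel_count, 125L)
  expect_length(connected_components(lv, "nodule", min_voxels = 200L), 1L)
})

test_that("phantom ground truth is recovered end to end", {
  ph <- small_phantom()
  objs <- connected_components(ph$labels, "nodule", min_voxels = 20L)
  expect_length(objs, nrow(ph$truth$nodules))
  # diameters come back near the generated sizes (truth records the
  # rendered, embedded-scale Feret diameters)
  df <- as.data.frame(objs)
  gen <- ph$truth$nodules$feret_um
  expect_lt(abs(mean(df$feret_um) - mean(gen)), 3 * ph$labels$voxel_um)
})

test_that("nodule classification applies the localization and size criteria", {
  ph <- small_phantom()
  crit <- nodule_criteria(feret_um_range = c(25, 180), min_voxels = 20L)
  objs <- connected_components(ph$labels, "nodule",
                               min_voxels = crit$min_voxels)
  acc <- classify_nodules(objs, ph$labels, crit)
  expect_length(acc, nrow(ph$truth$nodules))
  expect_true(all(vapply(acc, `[[`, numeric(1), "feret_corrected_um") >
                  vapply(acc, `[[`, numeric(1), "feret_um")))
  # a cortical sphere meeting shape+size criteria is rejected (criterion i):
  # plant a synthetic follicle-like ball far from any medullary sinus and
  # relabel it as nodule class
  lab2 <- ph$labels
  fol <- ph$truth$follicles[1, ]
  r <- 4L
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  off <- off[rowSums(off^2) <= r^2, ]
  idx <- cbind(fol$z + off[, 1], fol$y + off[, 2], fol$x + off[, 3])
  lab2$labels[idx] <- lab2$class_map[["nodule"]]
  objs2 <- connected_components(lab2, "nodule", min_voxels = 20L)
  acc2 <- classify_nodules(objs2, lab2, crit)
  expect_length(acc2, length(acc))        # the cortical impostor is rejected
  expect_true("not_medullary" %in% attr(acc2, "rejected")$reason)
  # a medullary object below the Feret window is rejected
  crit_hi <- nodule_criteria(feret_um_range = c(60, 180), min_voxels = 20L)
  acc3 <- classify_nodules(objs, ph$labels, crit_hi)
  expect_true(all(vapply(acc3, `[[`, numeric(1), "feret_um") >= 60))
  expect_true(length(acc3) < length(objs))
})

test_that("capillary density uses nearest-compartment attribution", {
  cm <- ln_class_map()
  # hand-built block: a DCU cube containing a 100-voxel capillary slab
  # strictly interior to it, so attribution is exact by construction
  arr <- array(0L, c(16, 16, 16))
  arr[3:14, 3:14, 3:14] <- cm[["DCU"]]
  arr[6:7, 6:10, 4:13] <- cm[["capillary"]]  # 2 x 5 x 10 = 100 voxels
  lv <- label_volume(arr, voxel_um = 2)
  n_cap <- sum(arr == cm[["capillary"]])
  expect_equal(n_cap, 100L)
  dens <- capillary_density(lv, "DCU")
  expect_equal(dens, 100 / (sum(arr == cm[["DCU"]]) + 100))
  # compartment with no capillaries scores zero
  arr2 <- array(0L, c(6, 6, 6)); arr2[2:5, 2:5, 2:5] <- cm[["follicle"]]
  expect_equal(capillary_density(label_volume(arr2, voxel_um = 2),
                                 "follicle"), 0)
  expect_error(capillary_density(lv, "follicle"), "empty")
})

test_that("density ratios behave arithmetically", {
  mk <- function(comp, dens) structure(
    list(compartment = comp, total_voxels = 1000L,
         capillary_voxels = round(1000 * dens / (1 - dens)),
         capillary_density = dens, volume_fraction_pct = 10),
    class = "compartment_stats")
  expect_equal(density_ratio(mk("a", 0.1), mk("b", 0.1)), 1.0)
  expect_equal(density_ratio(mk("a", 0.22), mk("b", 0.10)), 2.2)
  expect_error(density_ratio(mk("a", 0.2), mk("b", 0)), "zero")
})

test_that("volume fractions partition the LN mask", {
  cm <- ln_class_map()
  arr <- array(cm[["parenchyma"]], c(10, 10, 10))
  arr[seq_len(47)] <- cm[["nodule"]]               # 47 of 1000 LN voxels
  lv <- label_volume(arr, voxel_um = 2)
  expect_equal(volume_fraction(lv, "nodule"), 4.7)
  expect_equal(volume_fraction(lv, "fat_pad"), 0)  # absent class
  ph <- small_phantom()
  ln_classes <- setdiff(names(ph$labels$class_map),
                        c("background", "adjacent_tissue"))
  total <- sum(vapply(ln_classes, function(cc)
    volume_fraction(ph$labels, cc), numeric(1)))
  expect_equal(total, 100, tolerance = 1e-9)
  empty <- label_volume(array(0L, c(4, 4, 4)), voxel_um = 2)
  expect_error(volume_fraction(empty, "nodule"), "empty LN mask")
})

test_that("shrinkage correction is the exact linear inverse", {
  expect_equal(shrinkage_correct(90, 0), 90)
  expect_equal(shrinkage_correct(90, 0.30), 128.5714, tolerance = 1e-4)
  d <- c(17.3, 90, 240)
  expect_equal(shrinkage_correct(d * (1 - 0.3), 0.3), d, tolerance = 1e-12)
  expect_error(shrinkage_correct(90, 1))
  expect_error(shrinkage_correct(-5, 0.3))
})

test_that("group comparison: exact Wilcoxon enumeration and stars", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)         # 2 / choose(6, 3)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(compare_groups(1:20, 1:20 + 100)$stars, "**")
  expect_equal(r$stars, "ns")
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})
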