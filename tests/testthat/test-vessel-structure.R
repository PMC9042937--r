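test_that("per-plane IsoData threshold separates bimodal planes", {
  arr <- array(10, c(8, 8, 2))
  arr[3:5, 3:5, 1] <- 200
  arr[2:3, 6:7, 2] <- 200
  bin <- binarize_stack(fluor_volume(arr, voxel_size = c(1, 1, 1)))
  expect_true(all(bin$thresholds$threshold > 10 & bin$thresholds$threshold < 200))
  expect_equal(sum(bin$mask[, , 1]), 9)
  expect_equal(which(bin$mask[, , 1]), which(arr[, , 1] == 200))
  # constant plane: empty foreground with a warning flag
  arr2 <- array(7, c(4, 4, 1))
  expect_warning(bin2 <- binarize_stack(fluor_volume(arr2, voxel_size = c(1, 1, 1))),
                 "constant")
  expect_equal(sum(bin2$mask), 0)
  expect_true(bin2$thresholds$degenerate[1])
})

test_that("IsoData threshold matches the enumeration fixed-point oracle", {
  set.seed(21)
  for (rep in 1:10) {
    vals <- c(rnorm(150, 20, 4), rnorm(60, 120, 15))
    arr <- array(sample(vals), c(14, 15, 1))
    bin <- binarize_stack(fluor_volume(arr, voxel_size = c(1, 1, 1)))
    expect_equal(bin$thresholds$threshold[1], intermeans_oracle(as.vector(arr)),
                 tolerance = 1e-5)
  }
})

test_that("Otsu alternative also separates the bimodal phantom", {
  arr <- array(10, c(10, 10, 1)); arr[2:6, 2:6, 1] <- 200
  bin <- binarize_stack(fluor_volume(arr, voxel_size = c(1, 1, 1)), method = "otsu")
  expect_equal(which(bin$mask), which(arr == 200))
})

test_that("3-d labeling matches flood fill and honors anisotropic volumes", {
  # one tube: single component whose voxel count matches the phantom's
  tt <- vessel_tree_truth(list(straight_tube(c(2, 5, 5), c(18, 5, 5), 2)),
                          voxel_size = c(1, 1, 1))
  vol <- gen_vessel_volume(tt, c(20, 10, 10))
  comp <- label_vessels(vol$intensity > 100, voxel_size = c(1, 1, 1))
  expect_equal(nrow(comp), 1)
  expect_equal(comp$voxel_count, attr(vol, "truth")$tube_voxels[1])
  # two well-separated tubes: two components under both connectivities
  t2 <- vessel_tree_truth(list(straight_tube(c(2, 3, 5), c(18, 3, 5), 1),
                               straight_tube(c(2, 8, 5), c(18, 8, 5), 1)),
                          voxel_size = c(1, 1, 1))
  v2 <- gen_vessel_volume(t2, c(20, 12, 10))
  for (conn in c(6, 26))
    expect_equal(nrow(label_vessels(v2$intensity > 100, connectivity = conn,
                                    voxel_size = c(1, 1, 1))), 2)
  # anisotropic voxel volume in um3
  comp2 <- label_vessels(v2$intensity > 100, voxel_size = c(0.5, 0.5, 5))
  expect_equal(comp2$volume_um3, comp2$voxel_count * 0.5 * 0.5 * 5)
  # random volumes against the BFS oracle
  set.seed(22)
  for (rep in 1:20) {
    mask <- array(runif(16 * 16 * 8) < 0.2, c(16, 16, 8))
    for (conn in c(6, 26)) {
      got <- attr(label_vessels(mask, connectivity = conn,
                                voxel_size = c(1, 1, 1)), "label_array")
      expect_identical(got, flood_fill_labels(mask, conn))
    }
  }
})

test_that("component bookkeeping conserves foreground voxels", {
  set.seed(23)
  mask <- array(runif(20 * 20 * 6) < 0.25, c(20, 20, 6))
  comp <- label_vessels(mask, voxel_size = c(2, 2, 5))
  expect_equal(sum(comp$voxel_count), sum(mask))
  expect_equal(sum(comp$volume_um3), sum(mask) * 20)
  # min_voxels filter only drops small components
  comp2 <- label_vessels(mask, voxel_size = c(2, 2, 5), min_voxels = 3)
  expect_true(all(comp2$voxel_count >= 3))
})

test_that("VVF follows the x1000 volume-fraction definition", {
  geom <- hippocampus_geometry(surface_um2 = 4e6, section_height_um = 50)
  expect_equal(geom$volume_um3, 2e8)
  comp <- tibble::tibble(id = 1:3, voxel_count = c(1, 1, 1),
                         volume_um3 = c(2e8, 0, 1e5))
  out <- compute_vvf(comp, geom)
  expect_equal(out$vvf, c(1000, 0, 0.5))
  expect_error(hippocampus_geometry(surface_um2 = 0, section_height_um = 50),
               "positive")
  # ROI-derived surface
  roi <- matrix(TRUE, 10, 10)
  g2 <- hippocampus_geometry(roi = roi, voxel_size = c(2, 3, 1),
                             section_height_um = 10)
  expect_equal(g2$surface_um2, 600)
})

test_that("range partition assigns each vessel to exactly one caliber range", {
  comp <- tibble::tibble(id = 1:4, voxel_count = 1, volume_um3 = 1,
                         vvf = c(1e-4, 1e-3, 0.5, 2))
  part <- partition_ranges(comp)
  expect_equal(part$n_vessels, rep(1L, 4))
  expect_equal(as.character(part$range),
               c("0-0.0003", "0.0003-0.003", "0.003-1", ">1"))
  # boundary values: 0.003 and 1 belong to the third range, above 1 to the fourth
  b <- partition_ranges(tibble::tibble(id = 1:3, voxel_count = 1, volume_um3 = 1,
                                       vvf = c(3e-3, 1, 1 + 1e-9)))
  expect_equal(b$n_vessels, c(0L, 0L, 2L, 1L))
  # empty input: all ranges empty, means reported missing
  e <- partition_ranges(tibble::tibble(id = integer(), voxel_count = integer(),
                                       volume_um3 = numeric(), vvf = numeric()))
  expect_equal(e$n_vessels, rep(0L, 4))
  expect_true(all(is.na(e$mean_vvf)))
  expect_error(partition_ranges(tibble::tibble(id = 1, voxel_count = 1,
                                               volume_um3 = 1, vvf = -1)),
               "negative")
})

test_that("per-range totals conserve the grand total and means respect ordering", {
  set.seed(24)
  vvf <- 10^runif(100, -5, 1)
  part <- partition_ranges(tibble::tibble(id = 1:100, voxel_count = 1,
                                          volume_um3 = 1, vvf = vvf))
  expect_equal(sum(part$total_vvf), sum(vvf), tolerance = 1e-9)
  expect_equal(sum(part$n_vessels), 100L)
  means <- part$mean_vvf[!is.na(part$mean_vvf)]
  expect_true(all(diff(means) > 0))
})

test_that("two-slice averaging matches a per-range loop oracle", {
  set.seed(25)
  mk <- function() partition_ranges(tibble::tibble(id = 1:30, voxel_count = 1,
                                                   volume_um3 = 1,
                                                   vvf = 10^runif(30, -5, 1)))
  a <- mk(); b <- mk()
  avg <- average_slices(a, b)
  for (i in 1:4) {
    for (col in c("n_vessels", "mean_vvf", "total_vvf", "vvf_per_vessel"))
      expect_equal(avg[[col]][i], (a[[col]][i] + b[[col]][i]) / 2)
  }
  same <- average_slices(a, a)
  expect_equal(same$mean_vvf, a$mean_vvf)
  bad <- partition_ranges(tibble::tibble(id = 1, voxel_count = 1, volume_um3 = 1,
                                         vvf = 0.5), boundaries = c(1e-4, 1e-2, 2))
  expect_error(average_slices(a, bad), "boundaries differ")
})
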