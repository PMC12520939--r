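# build chemical_maps directly from an abundance cube
maps_from_cube <- function(cube) {
  srspheno:::new_chemical_maps(cube, 0, matrix(0, dim(cube)[1],
                                               dim(cube)[2]))
}

disk_mask <- function(H, W, cr, cc, r) {
  rr <- matrix(seq_len(H), H, W)
  cc_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - cr)^2 + (cc_ - cc)^2 <= r^2
}

test_that("blank maps segment to zero cells", {
  cube <- array(0, c(40, 40, 4))
  expect_equal(max(segment_cells(maps_from_cube(cube))), 0L)
})

test_that("a rendered disk is recovered with its exact pixel footprint", {
  lib <- small_library()
  fld <- tiny_field(lib, n_cells = 1, noise_sigma = 0, background = 0)
  maps <- unmix_image(fld$image, lib, unmix_config(lambda = 0))
  mask <- segment_cells(maps, min_area = 20)
  expect_equal(max(mask), 1L)
  expect_equal(sum(mask == 1), fld$cells$true_area_px[1])
})

test_that("small specks fall below min_area; disjoint disks are counted", {
  H <- 64; W <- 64
  cube <- array(0, c(H, W, 4))
  plane <- matrix(0, H, W)
  plane[disk_mask(H, W, 16, 16, 6)] <- 1
  plane[disk_mask(H, W, 48, 48, 7)] <- 1
  plane[30, 10:14] <- 1                  # 5-pixel speck
  cube[, , 1] <- plane
  mask <- segment_cells(maps_from_cube(cube), min_area = 20,
                        threshold = 0.5)
  expect_equal(max(mask), 2L)
  # raster order of centroids: top-left disk is label 1
  expect_true(mask[16, 16] == 1L && mask[48, 48] == 2L)
})

test_that("labeling uses 8-connectivity", {
  H <- 16; W <- 16
  cube <- array(0, c(H, W, 4))
  plane <- matrix(0, H, W)
  plane[3:6, 3:6] <- 1
  plane[7:10, 7:10] <- 1                 # touches only diagonally
  cube[, , 2] <- plane
  mask <- segment_cells(maps_from_cube(cube), min_area = 5,
                        threshold = 0.5)
  expect_equal(max(mask), 1L)
})

test_that("feature extraction is exact sums over the mask", {
  H <- 20; W <- 20
  cube <- array(0, c(H, W, 4))
  cube[, , 1] <- 0.5                      # constant protein map
  mask <- matrix(0L, H, W)
  mask[1:10, 1:10] <- 1L                  # one cell, exactly 100 px
  ft <- extract_features(mask, maps_from_cube(cube))
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$area, 100)
  expect_equal(ft$protein, 50)
  expect_equal(ft$nucleic_acid, 0)
  # documented 5-feature order in the table
  expect_equal(names(ft)[4:8],
               c("area", "protein", "nucleic_acid", "saturated_lipid",
                 "unsaturated_lipid"))
  # micrometer scaling and per-pixel mean variant
  ft_um <- extract_features(mask, maps_from_cube(cube), pixel_size = 0.3)
  expect_equal(ft_um$area, 100 * 0.09)
  ft_mean <- extract_features(mask, maps_from_cube(cube),
                              content = "mean")
  expect_equal(ft_mean$protein, 0.5)

  empty <- extract_features(matrix(0L, H, W), maps_from_cube(cube))
  expect_equal(nrow(empty), 0L)
  expect_error(extract_features(matrix(0L, 5, 5), maps_from_cube(cube)),
               "dimensions")
})

test_that("contents are additive over disjoint mask splits", {
  lib <- small_library()
  fld <- tiny_field(lib, n_cells = 1, noise_sigma = 0.01)
  maps <- unmix_image(fld$image, lib, unmix_config())
  whole <- fld$truth_mask
  top <- whole; top[31:nrow(whole), ] <- 0L
  bottom <- whole; bottom[1:30, ] <- 0L
  f_whole <- extract_features(whole, maps)
  f_top <- extract_features(top, maps)
  f_bot <- extract_features(bottom, maps)
  for (cmp in c("protein", "nucleic_acid", "saturated_lipid",
                "unsaturated_lipid")) {
    parts <- sum(f_top[[cmp]], f_bot[[cmp]])
    expect_equal(parts, f_whole[[cmp]], tolerance = 1e-9)
  }
})

test_that("raising a fixed threshold never grows the foreground", {
  lib <- small_library()
  fld <- tiny_field(lib, n_cells = 2, noise_sigma = 0.02,
                    background = 0.02, seed = 8)
  maps <- unmix_image(fld$image, lib, unmix_config())
  areas <- sapply(c(0.2, 0.5, 1, 1.5), function(th)
    sum(segment_cells(maps, min_area = 1, threshold = th) > 0))
  expect_true(all(diff(areas) <= 0))
})

test_that("IoU matching identifies identical and merged masks", {
  m <- matrix(0L, 30, 30)
  m[disk_mask(30, 30, 8, 8, 4)] <- 1L
  m[disk_mask(30, 30, 22, 22, 5)] <- 2L
  res <- match_cells_to_truth(m, m)
  expect_equal(res$matches$iou, c(1, 1))
  expect_equal(res$matches$cell_id, res$matches$truth_id)

  merged <- matrix(0L, 30, 30)
  merged[m > 0] <- 1L                     # one blob over two truth cells
  res2 <- match_cells_to_truth(merged, m)
  expect_equal(nrow(res2$matches), 1L)
  expect_lt(res2$matches$iou, 1)
  expect_equal(length(res2$unmatched_truth), 1L)
})

test_that("segmentation matches ground truth with high IoU on a cohort field", {
  lib <- small_library()
  prof <- default_class_profiles()
  prof <- prof[prof$class_label %in% c("AML-M5", "ALL-Ph-"), ]
  cfg <- cohort_config(classes = prof, cells_per_class = 4,
                       image_size = c(128, 128), noise_sigma = 0.02,
                       background_level = 0.02, seed = 31)
  cells <- rbind(sample_cells(prof[1, ], 4, seed = 31),
                 sample_cells(prof[2, ], 4, seed = 32))
  cells$cell_id <- seq_len(8)
  fld <- render_field(cells, lib, cfg, seed = 33)
  maps <- unmix_image(fld$image, lib, unmix_config())
  mask <- segment_cells(maps)
  res <- match_cells_to_truth(mask, fld$truth_mask)
  expect_equal(nrow(res$matches), 8L)
  expect_gt(mean(res$matches$iou), 0.9)
})
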