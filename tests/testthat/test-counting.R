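test_that("final relabelling uses 6-connectivity across all slices", {
  # two blobs touching only via an edge-diagonal: distinct under 6-conn
  v <- array(0L, dim = c(6, 6, 6))
  v[1:2, 1:2, 1:2] <- 1L
  v[3:4, 3:4, 1:2] <- 1L
  out <- relabel_components(label_grid(v), 6)
  expect_equal(max(out$data), 2L)
  expect_equal(max(relabel_components(label_grid(v), 18)$data), 1L)

  solid <- array(1L, dim = c(3, 4, 4))
  expect_equal(max(relabel_components(label_grid(solid), 6)$data), 1L)
  empty <- array(0L, dim = c(3, 4, 4))
  expect_equal(max(relabel_components(label_grid(empty), 6)$data), 0L)

  # watershed regions meeting at a face stay distinct (same-label tracking)
  two <- array(0L, dim = c(2, 4, 8))
  two[, , 1:4] <- 1L
  two[, , 5:8] <- 2L
  expect_equal(max(relabel_components(label_grid(two), 6)$data), 2L)

  # binary input is labelled plainly
  m <- array(FALSE, dim = c(2, 6, 6)); m[1, 1:2, 1:2] <- TRUE; m[2, 5:6, 5:6] <- TRUE
  expect_equal(max(relabel_components(binary_grid(m), 6)$data), 2L)
})

test_that("relabelling matches the connected-components oracle", {
  set.seed(51)
  for (conn in c(6, 18, 26)) {
    v <- array(as.integer(runif(5 * 9 * 9) < 0.5), dim = c(5, 9, 9))
    got <- relabel_components(label_grid(v), conn)$data
    expect_identical(got, oracle_label(v, conn, same_value_only = TRUE))
  }
})

test_that("volume filter rejects objects below the micron cutoff", {
  # voxel (0.2, 0.2, 0.5) um = 0.02 um^3: cutoff 3.172/0.02 = 158.6 voxels
  v <- array(0L, dim = c(10, 24, 24))
  v[1:6, 1:5, 1:5] <- 1L           # 150 voxels: rejected
  v[1:8, 10:14, 10:14] <- 2L       # 200 voxels: kept
  res <- volume_filter(label_grid(v, voxel_size = c(0.2, 0.2, 0.5)),
                       pipeline_params())
  expect_equal(res$n_cells, 1L)
  expect_equal(res$cells$voxels, 200L)
  expect_equal(res$cells$volume_um3, 4, tolerance = 1e-9)
  expect_equal(res$cells$label, 1L)
  expect_true(all(res$labels$data %in% c(0L, 1L)))
  expect_gte(min(res$cells$volume_um3), res$params$min_volume_um3)

  # vacuous filter keeps everything
  res2 <- volume_filter(label_grid(v), pipeline_params(min_volume_um3 = 1e-9))
  expect_equal(res2$n_cells, 2L)
  # centroid of the kept block
  expect_equal(res2$cells$centroid_z[2], 4.5)
  expect_equal(res2$cells$centroid_y[2], 12)

  res3 <- volume_filter(label_grid(array(0L, dim = c(2, 4, 4))), pipeline_params())
  expect_equal(res3$n_cells, 0L)
})

test_that("the pipeline counts well-separated nuclei exactly", {
  ph <- generate_phantom(synthetic_spec(shape = c(20L, 128L, 128L),
                                        n_cells = 20L, nucleus_mode = "regular",
                                        radius_range = c(1.0, 1.8),
                                        rng_seed = 7L))
  expect_equal(ph$n_cells, 20L)
  run <- run_pipeline(ph$image)
  expect_equal(run$result$n_cells, 20L)
  rep <- match_objects(run$labels, ph$truth)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$fp, 0L)
})

test_that("a zero-nucleus stack yields zero cells; an unstainable one errors", {
  ph0 <- generate_phantom(synthetic_spec(shape = c(8L, 64L, 64L), n_cells = 0L,
                                         rng_seed = 3L))
  run0 <- run_pipeline(ph0$image)
  expect_equal(run0$result$n_cells, 0L)

  zero <- voxel_grid(array(0, dim = c(4, 32, 32)))
  expect_error(suppressWarnings(run_pipeline(zero)),
               class = "unusable_sample")
})

test_that("nuclei separated by a single background slice stay two cells", {
  # two ellipsoids one voxel apart in z; per-slice thresholds must keep the
  # thin gap open so the objects remain distinct in 3D
  centers <- rbind(c(3.0, 6.4, 6.4), c(7.75, 6.4, 6.4))
  radii <- rbind(c(2, 1.5, 1.5), c(2, 1.5, 1.5))
  ph <- generate_phantom(synthetic_spec(shape = c(24L, 64L, 64L), n_cells = 2L,
                                        centers = centers, radii = radii,
                                        blur_sigma = 0.5, rng_seed = 9L))
  expect_equal(ph$n_cells, 2L)
  gap_z <- 11L   # the one slice between the two nuclei
  expect_true(all(ph$truth$data[gap_z, , ] == 0L))
  run <- run_pipeline(ph$image)
  expect_equal(run$result$n_cells, 2L)
  rep <- match_objects(run$labels, ph$truth)
  expect_equal(rep$tp, 2L)
})

test_that("the pipeline is deterministic and monotone in its parameters", {
  ph <- generate_phantom(small_phantom_spec())
  a <- run_pipeline(ph$image)
  b <- run_pipeline(ph$image)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$result$cells, b$result$cells)

  counts_v <- vapply(c(0.5, 3.172, 20, 60), function(v)
    run_pipeline(ph$image, pipeline_params(min_volume_um3 = v))$result$n_cells,
    integer(1))
  expect_true(all(diff(counts_v) <= 0))

  # below k ~ 2 the threshold admits enough noise to merge objects, so the
  # count claim applies from the outlier-cut regime upward
  counts_k <- vapply(c(2, 3, 6, 12), function(k)
    run_pipeline(ph$image, pipeline_params(k_sigma = k))$result$n_cells,
    integer(1))
  expect_true(all(diff(counts_k) <= 0))
})

test_that("output objects are 6-connected and lie in the thresholded foreground", {
  ph <- generate_phantom(small_phantom_spec())
  run <- run_pipeline(ph$image)
  lab <- run$labels$data
  mask <- fill_holes(binarise_stack(median_filter(ph$image, 1),
                                    pipeline_params()))$data
  expect_true(all(mask[lab > 0L]))
  for (L in seq_len(max(lab))) {
    comp <- array(as.integer(lab == L), dim = dim(lab))
    expect_equal(max(oracle_label(comp, 6)), 1L)
  }
})
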