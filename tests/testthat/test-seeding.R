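test_that("distance transform handles canonical shapes exactly", {
  # single foreground voxel: nearest background is one step away
  m <- array(FALSE, dim = c(3, 3, 3)); m[2, 2, 2] <- TRUE
  d <- distance_transform(binary_grid(m))
  expect_equal(d$data[2, 2, 2], 1.0)
  expect_true(all(d$data[!m] == 0))

  # 5x5x5 solid cube embedded in a 9^3 grid: centre is 3 voxels from background
  cube <- array(FALSE, dim = c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  dc <- distance_transform(binary_grid(cube))
  expect_equal(dc$data[5, 5, 5], 3.0)
  expect_equal(dc$data, oracle_edt(cube))

  # all-background mask is identically zero
  expect_true(all(distance_transform(binary_grid(array(FALSE, dim = c(2, 4, 4))))$data == 0))
})

test_that("distance transform matches the all-pairs oracle on random masks", {
  set.seed(31)
  for (i in 1:8) {
    dm <- sample(4:10, 3, replace = TRUE)
    m <- array(runif(prod(dm)) < 0.6, dim = dm)
    m[1, 1, 1] <- FALSE                         # keep at least one background voxel
    got <- distance_transform(binary_grid(m))$data
    expect_equal(got, oracle_edt(m), tolerance = 1e-12)
  }
  # anisotropic variant weights z by dz/dx
  m <- array(TRUE, dim = c(5, 5, 5)); m[1, , ] <- FALSE
  g <- binary_grid(m, voxel_size = c(0.2, 0.2, 0.5))
  got <- distance_transform(g, anisotropic = TRUE)$data
  expect_equal(got, oracle_edt(m, w = c(2.5, 1, 1)), tolerance = 1e-12)
})

test_that("grayscale reconstruction reaches the unique fixed point", {
  # marker == mask: identity
  set.seed(32)
  mask <- array(runif(4 * 5 * 5), dim = c(4, 5, 5))
  expect_equal(grayscale_reconstruct(mask, mask), mask)

  # isolated peak of height v over 0: reconstruction of (mask - h)
  # plateaus at v - h over the peak's support
  pk <- array(0, dim = c(5, 7, 7)); pk[3, 4, 4] <- 10
  marker <- pmax(pk - 7, 0); dim(marker) <- dim(pk)
  rec <- grayscale_reconstruct(marker, pk)
  expect_equal(rec[3, 4, 4], 3)
  expect_true(all(rec[pk == 0] == 0))

  # zero marker is absorbing
  expect_true(all(grayscale_reconstruct(array(0, dim = dim(mask)), mask) == 0))

  # marker above mask is rejected
  expect_error(grayscale_reconstruct(mask + 1, mask), "marker exceeds mask")
})

test_that("reconstruction matches the iterative-dilation oracle and is idempotent", {
  set.seed(33)
  for (i in 1:6) {
    dm <- sample(3:8, 3, replace = TRUE)
    mask <- array(sample(0:10, prod(dm), replace = TRUE), dim = dm)
    marker <- pmax(mask - sample(1:4, 1), 0); dim(marker) <- dm
    rec <- grayscale_reconstruct(marker, mask)
    expect_equal(rec, oracle_reconstruct(marker, mask))
    expect_equal(grayscale_reconstruct(rec, mask), rec)   # idempotent
    expect_true(all(rec <= mask) && all(rec >= marker))   # bracketed
  }
})

test_that("h-dome extracts domes of bounded height", {
  # constant grid: no regional maxima, no domes
  expect_true(all(hdome(array(5, dim = c(3, 4, 4)), 7) == 0))

  # single peak of height 10 over flat 0, h = 7: dome of exactly 7
  pk <- array(0, dim = c(5, 7, 7)); pk[3, 4, 4] <- 10
  dh <- hdome(pk, 7)
  expect_equal(dh[3, 4, 4], 7)
  expect_true(all(dh[pk == 0] == 0))

  # two peaks (9 and 4) on a shared plateau of 2: domes 7 and 2
  two <- array(0, dim = c(3, 5, 9))
  two[2, 2:4, 2:8] <- 2
  two[2, 3, 3] <- 9
  two[2, 3, 7] <- 4
  d2 <- hdome(two, 7)
  expect_equal(d2[2, 3, 3], 7)
  expect_equal(d2[2, 3, 7], 2)

  expect_error(hdome(pk, 0), "positive")
})

test_that("h-dome is bounded by min(dist, h) and vanishes on constants", {
  set.seed(34)
  for (i in 1:10) {
    dm <- sample(3:9, 3, replace = TRUE)
    q <- array(sample(0:12, prod(dm), replace = TRUE), dim = dm)
    h <- runif(1, 0.5, 8)
    dh <- hdome(q, h)
    expect_true(all(dh >= -1e-12))
    expect_true(all(dh <= h + 1e-12))
    expect_true(all(dh <= q + 1e-12))
  }
})

test_that("seed extraction rejects small components and honours connectivity", {
  p <- pipeline_params()
  # a 10-voxel bump is spurious, a 100-voxel dome is a true seed
  d <- array(0, dim = c(4, 12, 12))
  d[2, 1:2, 1:5] <- 1          # 10 voxels
  d[2:3, 5:9, 5:9] <- 2        # 50 voxels... grow to 100
  d[1:4, 8:12, 8:12] <- 2      # overlapping block, union >= 100 voxels
  s <- extract_seeds(d, p)
  expect_equal(length(s$sizes), 1L)
  expect_equal(s$n_rejected, 1L)
  expect_true(all(s$sizes >= p$seed_min_voxels))

  # everything below the cutoff: empty seed set
  d2 <- array(0, dim = c(3, 6, 6))
  d2[1, 1:2, 1:2] <- 1
  d2[3, 5:6, 5:6] <- 1
  s2 <- extract_seeds(d2, p)
  expect_equal(length(s2$sizes), 0L)
  expect_true(all(s2$labels$data == 0L))

  # two blocks joined only by an edge-diagonal pair: one seed under
  # 18-connectivity, two under 6-connectivity
  d3 <- array(0, dim = c(8, 8, 8))
  d3[1:3, 1:3, 1:3] <- 1                       # 27 voxels
  d3[4:6, 4:6, 1:3] <- 1                       # touches only diagonally in (z,y)
  s18 <- extract_seeds(d3, pipeline_params(seed_min_voxels = 5))
  s6 <- extract_seeds(d3, pipeline_params(seed_min_voxels = 5,
                                          seed_connectivity = 6))
  expect_equal(length(s18$sizes), 1L)
  expect_equal(length(s6$sizes), 2L)
})

test_that("seed count is non-increasing in the minimum seed size", {
  set.seed(35)
  d <- array(sample(0:3, 6 * 14 * 14, replace = TRUE), dim = c(6, 14, 14))
  ns <- vapply(c(1, 5, 20, 60), function(mn)
    length(extract_seeds(d, pipeline_params(seed_min_voxels = mn))$sizes),
    numeric(1))
  expect_true(all(diff(ns) <= 0))
})
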