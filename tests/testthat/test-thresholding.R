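test_that("slice histograms count every pixel exactly", {
  h <- slice_histogram(matrix(5, 10, 10))
  expect_equal(h$counts[6], 100)
  expect_equal(sum(h$counts), 100)

  set.seed(3)
  sl <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  h2 <- slice_histogram(sl)
  expect_equal(sum(h2$counts), h2$n_pixels)
  expect_equal(h2$counts[100], sum(sl == 99))

  expect_error(slice_histogram(matrix(numeric(0), 0, 0)), "no pixels")
})

test_that("background fit recovers a clean and a contaminated Gaussian mode", {
  m <- fit_background(gaussian_histogram(1000, 30, 5))
  expect_lt(abs(m$mu - 30), 0.5)
  expect_lt(abs(m$sigma - 5), 0.5)

  # a far mode holding 1% of pixels must not move the background estimate
  m2 <- fit_background(gaussian_histogram(1000, 30, 5, contaminant_at = 200))
  expect_lt(abs(m2$mu - 30), 0.5)
  expect_lt(abs(m2$sigma - 5), 0.5)

  # all pixels in one bin: sigma is undefined
  one <- structure(list(counts = c(rep(0L, 40), 500L, rep(0L, 215)),
                        n_pixels = 500L), class = "intensity_histogram")
  expect_error(fit_background(one), "degenerate background")
  empty <- structure(list(counts = rep(0L, 256), n_pixels = 0L),
                     class = "intensity_histogram")
  expect_error(fit_background(empty), "degenerate background")
})

test_that("threshold combines mu + k*sigma with a floor and 8-bit clamp", {
  m <- structure(list(mu = 10, sigma = 2), class = "background_model")
  expect_equal(threshold_value(m, k_sigma = 3, t_min = 0), 16)
  expect_equal(threshold_value(m, k_sigma = 3, t_min = 25), 25)
  m2 <- structure(list(mu = 250, sigma = 10), class = "background_model")
  expect_equal(threshold_value(m2, k_sigma = 3, t_min = 0), 255)
})

test_that("binarisation separates discs from a Gaussian background per slice", {
  set.seed(21)
  nz <- 4L; ny <- 64L; nx <- 64L
  arr <- array(pmin(pmax(round(rnorm(nz * ny * nx, 30, 5)), 0), 255),
               dim = c(nz, ny, nx))
  truth <- array(FALSE, dim = dim(arr))
  for (z in seq_len(nz)) {
    cy <- 10 * z; cx <- 32
    for (y in seq_len(ny)) for (x in seq_len(nx))
      if ((y - cy)^2 + (x - cx)^2 <= 36) truth[z, y, x] <- TRUE
  }
  # deeper slices attenuated x0.6: per-slice fitting must still find discs
  arr[truth] <- 200
  deep <- arr[3:4, , , drop = FALSE] * 0.6
  arr[3:4, , ] <- round(deep)
  mask <- binarise_stack(voxel_grid(arr), pipeline_params())
  for (z in seq_len(nz)) {
    fg <- mask$data[z, , ]; tr <- truth[z, , ]
    expect_true(all(fg[tr]))                      # discs detected, shallow & deep
    expect_gte(mean(!fg[!tr]), 0.99)              # >=99% of background correct
  }
  expect_true(all(attr(mask, "diagnostics")$ok))
})

test_that("raising k_sigma never adds foreground pixels", {
  set.seed(22)
  arr <- array(pmin(pmax(round(rnorm(3 * 48 * 48, 30, 5)), 0), 255),
               dim = c(3, 48, 48))
  arr[, 20:28, 20:28] <- 200
  g <- voxel_grid(arr)
  counts <- vapply(c(1, 2, 3, 5, 8), function(k)
    sum(binarise_stack(g, pipeline_params(k_sigma = k))$data), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a degenerate slice degrades to all-background without touching others", {
  set.seed(23)
  arr <- array(pmin(pmax(round(rnorm(2 * 48 * 48, 30, 5)), 0), 255),
               dim = c(2, 48, 48))
  arr[, 20:28, 20:28] <- 200
  base <- binarise_stack(voxel_grid(arr), pipeline_params())
  with_const <- array(0, dim = c(3, 48, 48))
  with_const[1:2, , ] <- arr                    # slice 3 is constant zero
  expect_warning(mask <- binarise_stack(voxel_grid(with_const), pipeline_params()),
                 "all-background")
  expect_identical(mask$data[1:2, , ], base$data)
  expect_false(any(mask$data[3, , ]))
  expect_false(attr(mask, "diagnostics")$ok[3])

  zero <- voxel_grid(array(0, dim = c(2, 16, 16)))
  w <- capture_warnings(m0 <- binarise_stack(zero, pipeline_params()))
  expect_length(w, 2)                          # one warning per failed slice
  expect_false(any(m0$data))
})

test_that("fit recovery holds across a parameter sweep", {
  for (mu in c(20, 40, 60))
    for (sigma in c(3, 9, 15)) {
      m <- fit_background(gaussian_histogram(2000, mu, sigma))
      expect_lt(abs(m$mu - mu), 0.5)
      expect_lt(abs(m$sigma - sigma), 0.5)
    }
})
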