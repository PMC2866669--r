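#' Specification of a synthetic phantom stack
#'
#' Describes a 3D phantom emulating a confocal stack of sparsely
#' distributed, brightly labelled embryonic nuclei: high signal over low
#' non-specific background, Poisson photon noise, intensity decaying with
#' focus depth, and occasional abrupt background shifts between slices.
#' Two nucleus shapes are offered: `"regular"` axis-aligned ellipsoids
#' (Repo-like glial nuclei) and `"irregular"` unions of 2-4 jittered
#' overlapping ellipsoids (pH3-like mitotic chromatin).
#'
#' @param shape `(depth, height, width)` in voxels.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param n_cells nuclei to place; default 78 for regular mode, 65 for
#'   irregular.
#' @param nucleus_mode `"regular"` or `"irregular"`.
#' @param radius_range semi-axis range in um, sampled per axis.
#' @param min_separation minimum gap (um) between the bounding spheres of
#'   two nuclei; near 0 creates touching pairs.
#' @param signal_mean,background_mean expected 8-bit intensities of nucleus
#'   interior and background at the top slice.
#' @param attenuation_per_slice multiplicative intensity decay per slice
#'   (0.991 gives ~30% total loss over 40 slices).
#' @param background_jump_prob,background_jump_mag per-slice probability of
#'   an abrupt additive background shift, and its maximum magnitude.
#' @param blur_sigma isotropic optics proxy: Gaussian sigma in xy pixels
#'   (the z sigma is scaled by `dx/dz`); 0 disables.
#' @param poisson_noise draw each voxel from a Poisson with the noiseless
#'   expectation as mean.
#' @param rng_seed integer seed; phantoms are byte-reproducible from it.
#' @param centers optional matrix (n x 3) of fixed nucleus centres in um
#'   `(z, y, x)` (bypasses random placement; requires `radii`).
#' @param radii optional matrix (n x 3) of fixed semi-axes in um
#'   `(rz, ry, rx)`.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(40L, 256L, 256L),
                           voxel_size = c(0.2, 0.2, 0.5),
                           n_cells = NULL,
                           nucleus_mode = c("regular", "irregular"),
                           radius_range = c(1.5, 3),
                           min_separation = 1,
                           signal_mean = 200,
                           background_mean = 20,
                           attenuation_per_slice = 0.991,
                           background_jump_prob = 0.1,
                           background_jump_mag = 8,
                           blur_sigma = 1,
                           poisson_noise = TRUE,
                           rng_seed = 1L,
                           centers = NULL,
                           radii = NULL) {
  nucleus_mode <- match.arg(nucleus_mode)
  if (is.null(n_cells))
    n_cells <- if (nucleus_mode == "regular") 78L else 65L
  spec <- structure(list(
    shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
    n_cells = as.integer(n_cells), nucleus_mode = nucleus_mode,
    radius_range = as.numeric(radius_range),
    min_separation = as.numeric(min_separation),
    signal_mean = as.numeric(signal_mean),
    background_mean = as.numeric(background_mean),
    attenuation_per_slice = as.numeric(attenuation_per_slice),
    background_jump_prob = as.numeric(background_jump_prob),
    background_jump_mag = as.numeric(background_jump_mag),
    blur_sigma = as.numeric(blur_sigma),
    poisson_noise = isTRUE(poisson_noise),
    rng_seed = as.integer(rng_seed),
    centers = centers, radii = radii), class = "synthetic_spec")
  with(spec, {
    stopifnot(length(shape) == 3L, all(shape >= 1L),
              length(voxel_size) == 3L, all(voxel_size > 0),
              n_cells >= 0L,
              length(radius_range) == 2L, all(radius_range > 0),
              radius_range[1] <= radius_range[2],
              min_separation >= 0,
              signal_mean > background_mean, background_mean >= 0,
              attenuation_per_slice > 0, attenuation_per_slice <= 1,
              background_jump_prob >= 0, background_jump_prob <= 1,
              background_jump_mag >= 0, blur_sigma >= 0)
  })
  if (!is.null(spec$centers) && is.null(spec$radii))
    stop("fixed centers require fixed radii")
  spec
}

# run `expr` under the spec's RNG without disturbing the caller's stream
with_phantom_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a phantom stack with voxel-accurate ground truth
#'
#' Places `n_cells` nuclei by rejection sampling (bounding spheres at least
#' `min_separation` apart, fully inside the stack), renders the noiseless
#' expected image (background plus nuclei, depth attenuation, per-slice
#' background jumps, optional Gaussian blur), then draws independent
#' Poisson noise per voxel and clips to \[0, 255\]. Truth labels record
#' exactly the voxels of each nucleus before blur and noise.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `phantom` with `image` (a [voxel_grid]), `truth`
#'   (a [label_grid]), `n_cells` (the truth count) and `cells` (data.frame
#'   of centres and bounding radii in um).
#' @export
generate_phantom <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_phantom_rng(spec$rng_seed, {
    dz <- spec$voxel_size[3]; dy <- spec$voxel_size[2]; dx <- spec$voxel_size[1]
    nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
    extent <- c(nz * dz, ny * dy, nx * dx)   # um, (z, y, x)

    nuclei <- place_nuclei(spec, extent)

    truth <- array(0L, dim = spec$shape)
    signal <- array(FALSE, dim = spec$shape)
    zc <- (seq_len(nz) - 0.5) * dz
    yc <- (seq_len(ny) - 0.5) * dy
    xc <- (seq_len(nx) - 0.5) * dx
    for (i in seq_along(nuclei)) {
      for (comp in nuclei[[i]]$components) {
        vox <- ellipsoid_voxels(comp$center, comp$radius, zc, yc, xc)
        if (length(vox)) {
          truth[vox] <- i
          signal[vox] <- TRUE
        }
      }
    }

    atten <- spec$attenuation_per_slice ^ (seq_len(nz) - 1)
    jumps <- ifelse(runif(nz) < spec$background_jump_prob,
                    runif(nz, -spec$background_jump_mag, spec$background_jump_mag),
                    0)
    expected <- array(spec$background_mean, dim = spec$shape)
    expected[signal] <- spec$signal_mean
    expected <- expected * atten                 # recycles over first dim (z)
    expected <- expected + jumps
    expected[expected < 0] <- 0
    if (spec$blur_sigma > 0) {
      sig <- c(spec$blur_sigma * dx / dz, spec$blur_sigma, spec$blur_sigma)
      expected <- cpp_blur_sep(as.numeric(expected), spec$shape, sig)
    }
    img <- if (spec$poisson_noise) {
      array(rpois(length(expected), lambda = pmax(expected, 0)),
            dim = spec$shape)
    } else {
      round(expected)
    }
    img[img > 255] <- 255
    img[img < 0] <- 0

    cells <- if (length(nuclei)) {
      do.call(rbind, lapply(seq_along(nuclei), function(i) {
        n <- nuclei[[i]]
        data.frame(label = i, z_um = n$center[1], y_um = n$center[2],
                   x_um = n$center[3], bound_um = n$bound)
      }))
    } else {
      data.frame(label = integer(0), z_um = numeric(0), y_um = numeric(0),
                 x_um = numeric(0), bound_um = numeric(0))
    }
    structure(list(
      image = voxel_grid(img, spec$voxel_size,
                         name = sprintf("phantom_%s_seed%d", spec$nucleus_mode,
                                        spec$rng_seed)),
      truth = label_grid(truth, spec$voxel_size, name = "truth"),
      n_cells = length(nuclei),
      cells = cells,
      spec = spec), class = "phantom")
  })
}

# voxel linear indices inside an axis-aligned ellipsoid, restricted to its
# bounding box; center/radius in um, (z, y, x)
ellipsoid_voxels <- function(center, radius, zc, yc, xc) {
  zi <- which(abs(zc - center[1]) <= radius[1])
  yi <- which(abs(yc - center[2]) <= radius[2])
  xi <- which(abs(xc - center[3]) <= radius[3])
  if (!length(zi) || !length(yi) || !length(xi)) return(integer(0))
  g <- expand.grid(z = zi, y = yi, x = xi)
  d2 <- ((zc[g$z] - center[1]) / radius[1])^2 +
        ((yc[g$y] - center[2]) / radius[2])^2 +
        ((xc[g$x] - center[3]) / radius[3])^2
  inside <- d2 <= 1
  nz <- length(zc); ny <- length(yc)
  (g$z[inside]) + nz * (g$y[inside] - 1L) + nz * ny * (g$x[inside] - 1L)
}

# rejection-sample nucleus positions and shapes
place_nuclei <- function(spec, extent) {
  n <- spec$n_cells
  if (n == 0L) return(list())
  fixed <- !is.null(spec$centers)
  nuclei <- list()
  placed_centers <- matrix(numeric(0), ncol = 3)
  placed_bounds <- numeric(0)
  attempts <- 0L
  max_attempts <- 200L * n
  i <- 1L
  while (i <= n) {
    if (fixed) {
      center <- as.numeric(spec$centers[i, ])
      base_r <- as.numeric(spec$radii[i, ])
    } else {
      base_r <- runif(3, spec$radius_range[1], spec$radius_range[2])
      center <- NULL
    }
    comps <- if (spec$nucleus_mode == "regular") {
      list(list(offset = c(0, 0, 0), radius = base_r))
    } else {
      k <- sample(2:4, 1)
      lapply(seq_len(k), function(j) {
        list(offset = runif(3, -0.8, 0.8),
             radius = base_r * runif(3, 0.6, 0.9))
      })
    }
    bound <- max(vapply(comps, function(c_) sqrt(sum(c_$offset^2)) + max(c_$radius),
                        numeric(1)))
    if (!fixed) {
      lo <- bound + 0.1
      hi <- extent - bound - 0.1
      if (any(hi <= lo))
        stop("nuclei too large for the requested stack extent")
      center <- c(runif(1, lo, hi[1]), runif(1, lo, hi[2]), runif(1, lo, hi[3]))
      ok <- TRUE
      if (nrow(placed_centers)) {
        dsep <- sqrt(colSums((t(placed_centers) - center)^2))
        ok <- all(dsep >= placed_bounds + bound + spec$min_separation)
      }
      attempts <- attempts + 1L
      if (!ok) {
        if (attempts >= max_attempts)
          stop(sprintf("cannot place %d nuclei at separation %.2f um in %d attempts",
                       n, spec$min_separation, attempts))
        next
      }
    }
    nuclei[[i]] <- list(
      center = center, bound = bound,
      components = lapply(comps, function(c_)
        list(center = center + c_$offset, radius = c_$radius)))
    placed_centers <- rbind(placed_centers, center)
    placed_bounds <- c(placed_bounds, bound)
    i <- i + 1L
  }
  nuclei
}

#' Fade a stack towards its background to emulate faint staining
#'
#' Scales every voxel towards the stack's median intensity:
#' `new = med + factor * (old - med)`. Factors near 1 leave the stack
#' unchanged; small factors emulate badly stained samples whose background
#' fit degenerates, exercising the discard path of [run_pipeline()].
#'
#' @param grid a [voxel_grid].
#' @param factor in `[0, 1]`.
#' @return a faded [voxel_grid].
#' @export
degrade_to_faint <- function(grid, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0 || factor > 1)
    stop("factor must lie in [0, 1]")
  data <- grid_data(grid)
  med <- median(data)
  out <- round(med + factor * (data - med))
  out[out < 0] <- 0
  out[out > 255] <- 255
  grid_like(out, grid, "voxel_grid")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s: %d nuclei (%s), %d x %d x %d voxels\n",
              x$image$name, x$n_cells, x$spec$nucleus_mode,
              dim(x$image$data)[1], dim(x$image$data)[2], dim(x$image$data)[3]))
  invisible(x)
}
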