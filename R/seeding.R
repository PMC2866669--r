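#' 3D Euclidean distance transform
#'
#' Assigns every foreground voxel its exact Euclidean distance (in voxel
#' units) to the nearest in-image background voxel; background voxels are 0.
#' Inside a nucleus the map rises towards the centre, so the nuclei become
#' "mountains" whose peaks the h-dome stage marks as seeds. By default the
#' three axes are weighted equally so that the dome height `h` stays a pure
#' voxel-geometry parameter; `anisotropic = TRUE` weights z by `dz/dx`.
#'
#' @param mask a [binary_grid].
#' @param anisotropic scale the z axis by the physical aspect ratio.
#' @return a [distance_grid].
#' @export
distance_transform <- function(mask, anisotropic = FALSE) {
  data <- grid_data(mask)
  storage.mode(data) <- "logical"
  vs <- grid_voxel_size(mask)
  w <- if (isTRUE(anisotropic)) c(vs[3] / vs[1], vs[2] / vs[1], 1) else c(1, 1, 1)
  out <- cpp_edt(data, dim(data), w)
  if (any(is.infinite(out)))
    stop("mask has no background voxels; distances are undefined")
  grid_like(out, mask, "distance_grid")
}

#' Grayscale reconstruction by dilation
#'
#' Computes `rho_mask(marker)`: the limit of iterated geodesic dilation
#' (26-neighbourhood) of `marker` under `mask` -- the largest image that is
#' `<= mask` everywhere and reachable from `marker` by dilations. This is
#' the engine of the h-dome/h-maxima transforms. The implementation uses
#' hybrid raster/anti-raster sweeps plus a propagation queue and returns the
#' unique fixed point (idempotent, anti-extensive with respect to the mask).
#'
#' @param marker,mask [distance_grid]s or bare 3D arrays with
#'   `marker <= mask` everywhere.
#' @return the reconstruction, same container kind as `mask`.
#' @export
grayscale_reconstruct <- function(marker, mask) {
  m <- grid_data(marker)
  k <- grid_data(mask)
  if (!identical(dim(m), dim(k))) stop("marker and mask dimensions differ")
  out <- cpp_reconstruct(as.numeric(m), as.numeric(k), dim(k))
  if (inherits(mask, "grid3d")) grid_like(out, mask, class(mask)[1]) else out
}

#' h-dome transform
#'
#' `D_h = q - rho_q(q - h)`, with `(q - h)` floored at the image minimum
#' (0 for any distance map that touches background): subtracting the
#' reconstruction of the image lowered by `h` from the image itself leaves
#' only the local "domes" of height at most `h`. Applied to the distance
#' map, each nucleus contributes a dome around its centre; everywhere
#' `0 <= D_h <= min(q, h)`, and an image without relief has no domes.
#'
#' @param dist a [distance_grid] (or 3D array).
#' @param h dome height, > 0, in the units of `dist`.
#' @return same container kind as `dist`.
#' @export
hdome <- function(dist, h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a positive scalar")
  q <- grid_data(dist)
  marker <- pmax(q - h, min(q))
  dim(marker) <- dim(q)
  rec <- cpp_reconstruct(as.numeric(marker), as.numeric(q), dim(q))
  out <- q - rec
  if (inherits(dist, "grid3d")) grid_like(out, dist, class(dist)[1]) else out
}

#' Extract watershed seeds from the h-dome image
#'
#' Voxels whose dome value exceeds `dome_threshold` form the seed mask;
#' its components are labelled with `seed_connectivity` (default 18) and
#' components smaller than `seed_min_voxels` are discarded as spurious
#' (irregular nuclei can carry several shallow secondary peaks, which yield
#' only small domes -- typically at most ~10 voxels, against >= 100 for a
#' true seed). Remaining seeds are relabelled 1..n in raster order.
#'
#' @param domes output of [hdome()].
#' @param params a [pipeline_params].
#' @return a `seed_set`: list with `labels` (a [label_grid]) and `sizes`
#'   (voxel count per retained seed).
#' @export
extract_seeds <- function(domes, params = pipeline_params()) {
  d <- grid_data(domes)
  seed_mask <- array(as.integer(d > params$dome_threshold), dim = dim(d))
  lab <- cpp_label(seed_mask, dim(d), params$seed_connectivity, FALSE)
  sizes <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab)) else integer(0)
  keep <- which(sizes >= params$seed_min_voxels)
  lab[!(lab %in% keep)] <- 0L
  lab <- relabel_consecutive(lab)
  n_rejected <- length(sizes) - length(keep)
  out_sizes <- if (length(keep)) sizes[keep] else integer(0)
  structure(list(labels = grid_like(lab, domes, "label_grid", name = "seeds"),
                 sizes = out_sizes, n_rejected = n_rejected),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds (%d rejected as too small)\n",
              length(x$sizes), x$n_rejected))
  if (length(x$sizes))
    cat(sprintf("  sizes: %d..%d voxels\n", min(x$sizes), max(x$sizes)))
  invisible(x)
}
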