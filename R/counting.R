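#' Relabel connected components
#'
#' Final 3D labelling step: positive voxels are relabelled by connected
#' components (default 6-connectivity) through all slices of the stack.
#' When the input carries watershed labels, components are tracked *within*
#' each label, so two watershed regions meeting at a 6-adjacent boundary
#' stay distinct instead of fusing back. A binary mask is labelled plainly.
#'
#' @param labels a [label_grid] or [binary_grid].
#' @param connectivity 6, 18 or 26.
#' @return a [label_grid] with consecutive labels.
#' @export
relabel_components <- function(labels, connectivity = 6L) {
  data <- grid_data(labels)
  vals <- array(as.integer(data), dim = dim(data))
  out <- cpp_label(vals, dim(vals), as.integer(connectivity), TRUE)
  grid_like(out, labels, "label_grid")
}

#' Classify labelled objects by volume
#'
#' Objects whose volume `voxels * dx * dy * dz` falls below
#' `min_volume_um3` are rejected (background spots and debris); survivors
#' become cell records and their number is the count. Volume is the plain
#' voxel-count estimate -- the natural partner of a hard volume cutoff.
#'
#' @param labels a [label_grid] with a meaningful voxel size.
#' @param params a [pipeline_params]; `params$voxel_size`, when set,
#'   overrides the grid's.
#' @return a `count_result`: list with `cells` (data.frame: `label`,
#'   `voxels`, `volume_um3`, `centroid_z/y/x` in voxel coordinates),
#'   `n_cells`, `params`, `diagnostics`, and `labels`, the filtered
#'   [label_grid] relabelled 1..n_cells to match `cells$label`.
#' @export
volume_filter <- function(labels, params = pipeline_params()) {
  data <- grid_data(labels)
  vs <- params$voxel_size %||% grid_voxel_size(labels)
  if (any(vs <= 0)) stop("voxel size must be positive")
  vox_um3 <- prod(vs)
  nmax <- max(data)
  if (nmax == 0L) {
    cells <- data.frame(label = integer(0), voxels = integer(0),
                        volume_um3 = numeric(0), centroid_z = numeric(0),
                        centroid_y = numeric(0), centroid_x = numeric(0))
    return(structure(list(cells = cells, n_cells = 0L, params = params,
                          diagnostics = NULL,
                          labels = grid_like(data, labels, "label_grid")),
                     class = "count_result"))
  }
  sizes <- tabulate(data[data > 0L], nbins = nmax)
  volumes <- sizes * vox_um3
  keep <- which(sizes > 0L & volumes >= params$min_volume_um3)
  filtered <- data
  filtered[!(filtered %in% keep)] <- 0L
  filtered <- relabel_consecutive(filtered)
  idx <- which(filtered > 0L)
  cells <- data.frame(label = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0))
  if (length(idx)) {
    lab <- filtered[idx]
    co <- arrayInd(idx, dim(filtered))
    n <- length(keep)
    cnt <- tabulate(lab, nbins = n)
    cells <- data.frame(
      label = seq_len(n),
      voxels = cnt,
      volume_um3 = cnt * vox_um3,
      centroid_z = as.vector(rowsum(co[, 1], lab)) / cnt,
      centroid_y = as.vector(rowsum(co[, 2], lab)) / cnt,
      centroid_x = as.vector(rowsum(co[, 3], lab)) / cnt)
  }
  structure(list(cells = cells, n_cells = nrow(cells), params = params,
                 diagnostics = NULL,
                 labels = grid_like(filtered, labels, "label_grid")),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d cells\n", x$n_cells))
  if (x$n_cells > 0) {
    cat(sprintf("  volumes: %.2f .. %.2f um^3 (median %.2f)\n",
                min(x$cells$volume_um3), max(x$cells$volume_um3),
                stats::median(x$cells$volume_um3)))
  }
  if (!is.null(x$diagnostics))
    cat(sprintf("  seeds: %d kept, %d rejected; %d/%d slices thresholded\n",
                x$diagnostics$n_seeds, x$diagnostics$n_seeds_rejected,
                sum(x$diagnostics$slices$ok), nrow(x$diagnostics$slices)))
  invisible(x)
}

#' Run the full counting pipeline on one stack
#'
#' Executes median filtering, per-slice binarisation, hole filling, the 3D
#' distance transform, h-dome seed extraction, the IFT watershed, the
#' optional adjacent-slice merge, 6-connected relabelling and the volume
#' filter. The pipeline is fully deterministic: the same stack and
#' parameters always yield the same count and label stack.
#'
#' @param grid a [voxel_grid].
#' @param params a [pipeline_params].
#' @param region optional [roi] cropped before processing.
#' @return list with `result` (a `count_result`) and `labels` (the output
#'   [label_grid], aligned voxel-for-voxel with the processed stack).
#' @export
run_pipeline <- function(grid, params = pipeline_params(), region = NULL) {
  validate_params(params)
  if (!is.null(region)) grid <- crop_roi(grid, region)
  if (!is.null(params$voxel_size))
    grid <- new_grid(grid_data(grid), params$voxel_size, grid_name(grid),
                     "voxel_grid")
  filtered <- median_filter(grid, params$median_radius)
  mask <- binarise_stack(filtered, params)
  slice_diag <- attr(mask, "diagnostics")
  if (!any(slice_diag$ok))
    stop(errorCondition(
      paste0("sample unusable: background fit failed on every slice ",
             "(badly stained samples must be discarded)"),
      class = c("unusable_sample", "error", "condition")))
  mask <- fill_holes(mask)
  dist <- distance_transform(mask, params$anisotropic_distance)
  domes <- hdome(dist, params$h)
  seeds <- extract_seeds(domes, params)
  lab <- ift_watershed(dist, seeds, mask)
  lab <- merge_by_intersection(lab, params$intersection_pct)
  lab <- relabel_components(lab, params$label_connectivity)
  res <- volume_filter(lab, params)
  res$diagnostics <- list(slices = slice_diag,
                          n_seeds = length(seeds$sizes),
                          n_seeds_rejected = seeds$n_rejected,
                          n_foreground = sum(grid_data(mask)))
  list(result = res, labels = res$labels)
}

#' Write per-stack counts or per-cell tables as CSV
#'
#' @param results named list of `count_result`s (names = stack names), or a
#'   single `count_result` for `write_cells_csv`.
#' @param path output CSV.
#' @export
write_count_csv <- function(results, path) {
  df <- data.frame(stack = names(results),
                   n_cells = vapply(results, function(r) r$n_cells, integer(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_count_csv
#' @export
write_cells_csv <- function(results, path) {
  write.csv(results$cells, path, row.names = FALSE)
  invisible(results$cells)
}
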