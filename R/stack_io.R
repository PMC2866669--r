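#' Read a multi-page TIFF stack
#'
#' Reads a single-channel, 8- or 16-bit multi-page TIFF into a
#' [voxel_grid]. 16-bit data are rescaled linearly by the full range
#' (`x * 255 / 65535`) so thresholds stay comparable across a batch. The
#' voxel size is taken from `voxel_size` if given, else from TIFF x/y
#' resolution metadata (z step defaulting to 0.5 um), else the default
#' `(0.2, 0.2, 0.5)` um with a warning.
#'
#' @param path TIFF file.
#' @param voxel_size optional `(dx, dy, dz)` um override.
#' @return a [voxel_grid].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(slices) == 0L) stop("stack has zero slices: ", path)
  if (any(vapply(slices, function(s) length(dim(s)) != 2L, logical(1))))
    stop("multi-channel unsupported: ", path)
  bits <- attr(slices[[1]], "bits.per.sample")
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  arr <- array(0, dim = c(length(slices), ny, nx))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
  if (!is.null(bits) && bits == 16L) {
    arr <- arr * (255 / 65535)
  } else if (max(arr) > 255) {
    arr <- arr * (255 / max(arr))
  }
  vs <- voxel_size
  if (is.null(vs)) {
    vs <- voxel_size_from_info(slices[[1]])
    if (is.null(vs)) {
      vs <- c(0.2, 0.2, 0.5)
      warning("no voxel size in TIFF metadata for '", basename(path),
              "'; assuming (0.2, 0.2, 0.5) um -- pass voxel_size to override",
              call. = FALSE)
    }
  }
  voxel_grid(arr, voxel_size = vs,
             name = tools::file_path_sans_ext(basename(path)))
}

# xy pixel size from TIFF resolution tags (pixels per unit); z defaults to
# 0.5 um since TIFF carries no z spacing
voxel_size_from_info <- function(slice) {
  xres <- attr(slice, "x.resolution")
  unit <- attr(slice, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  um_per_unit <- switch(as.character(unit %||% "none"),
                        "cm" = 1e4, "inch" = 25400, NULL)
  if (is.null(um_per_unit)) return(NULL)
  dx <- um_per_unit / xres
  yres <- attr(slice, "y.resolution")
  dy <- if (is.null(yres) || !is.numeric(yres) || yres <= 0) dx else um_per_unit / yres
  c(dx, dy, 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rectangular region of interest
#'
#' Pixel bounds applied to every slice; 0-based, half-open intervals
#' `[y0, y1) x [x0, x1)`.
#'
#' @param y0,y1,x0,x1 integer pixel bounds.
#' @return an object of class `roi`.
#' @export
roi <- function(y0, y1, x0, x1) {
  b <- as.integer(c(y0, y1, x0, x1))
  if (anyNA(b)) stop("roi bounds must be integers")
  if (b[1] < 0L || b[1] >= b[2] || b[3] < 0L || b[3] >= b[4])
    stop("roi requires 0 <= y0 < y1 and 0 <= x0 < x1")
  structure(list(y0 = b[1], y1 = b[2], x0 = b[3], x1 = b[4]), class = "roi")
}

#' Crop a stack to a region of interest
#'
#' @param grid a [voxel_grid] (or any grid container).
#' @param region an [roi].
#' @return a grid of the same class with shape `(depth, y1-y0, x1-x0)`;
#'   voxel size unchanged.
#' @export
crop_roi <- function(grid, region) {
  stopifnot(inherits(region, "roi"))
  d <- dim(grid_data(grid))
  if (region$y1 > d[2] || region$x1 > d[3])
    stop(sprintf("roi (%d,%d,%d,%d) out of bounds for %dx%d slices",
                 region$y0, region$y1, region$x0, region$x1, d[2], d[3]))
  out <- grid_data(grid)[, (region$y0 + 1L):region$y1,
                         (region$x0 + 1L):region$x1, drop = FALSE]
  grid_like(out, grid, class(grid)[1])
}

#' Write a label stack as 16-bit multi-page TIFF
#'
#' Background is 0 and every object keeps its distinct label value, so the
#' written stack aligns voxel-for-voxel with the input stack.
#'
#' @param labels a [label_grid].
#' @param path output file.
#' @export
write_label_stack <- function(labels, path) {
  data <- grid_data(labels)
  m <- max(data)
  if (m > 65535) stop("more than 65535 labels cannot be written as 16-bit: ", m)
  pages <- lapply(seq_len(dim(data)[1]),
                  function(z) data[z, , , drop = TRUE] / 65535)
  invisible(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "none"))
}

#' Read a label stack written by [write_label_stack()]
#'
#' @param path TIFF file.
#' @param voxel_size `(dx, dy, dz)` um to attach.
#' @return a [label_grid].
#' @export
read_label_stack <- function(path, voxel_size = c(0.2, 0.2, 0.5)) {
  if (!file.exists(path)) stop("file not found: ", path)
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(slices) == 0L) stop("stack has zero slices: ", path)
  arr <- array(0L, dim = c(length(slices), nrow(slices[[1]]), ncol(slices[[1]])))
  for (z in seq_along(slices)) arr[z, , ] <- as.integer(slices[[z]])
  label_grid(arr, voxel_size = voxel_size,
             name = tools::file_path_sans_ext(basename(path)))
}

#' Write an intensity stack as 8-bit multi-page TIFF
#'
#' @param grid a [voxel_grid].
#' @param path output file.
#' @export
write_image_stack <- function(grid, path) {
  data <- round(grid_data(grid))
  pages <- lapply(seq_len(dim(data)[1]),
                  function(z) data[z, , , drop = TRUE] / 255)
  invisible(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                            compression = "none"))
}
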