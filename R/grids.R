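#' @title Grid containers
#' @description
#' All stages of the pipeline operate on 3D arrays with dimension order
#' `(z, y, x)` carried in a light container that also records the voxel size
#' `(dx, dy, dz)` in micrometres and a sample name. Four flavours exist:
#' `voxel_grid` (intensities in \[0, 255\]), `binary_grid` (logical
#' foreground mask), `distance_grid` (non-negative distances, zero exactly on
#' background) and `label_grid` (non-negative integers, 0 = background).
#' @param data 3D array, dimension order `(z, y, x)`.
#' @param voxel_size numeric length 3, `(dx, dy, dz)` in micrometres.
#' @param name sample identifier.
#' @return an object of the corresponding class: a list with elements
#'   `data`, `voxel_size`, `name`.
#' @name grids
NULL

new_grid <- function(data, voxel_size, name, class) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  if (dim(data)[1] < 1L) stop("stack must have at least one slice")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (dx, dy, dz) in um")
  structure(list(data = data, voxel_size = voxel_size, name = name),
            class = c(class, "grid3d"))
}

#' @rdname grids
#' @export
voxel_grid <- function(data, voxel_size = c(0.2, 0.2, 0.5), name = "stack") {
  rng <- range(data)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  new_grid(data, voxel_size, name, "voxel_grid")
}

#' @rdname grids
#' @export
binary_grid <- function(data, voxel_size = c(0.2, 0.2, 0.5), name = "mask") {
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  new_grid(data, voxel_size, name, "binary_grid")
}

#' @rdname grids
#' @export
label_grid <- function(data, voxel_size = c(0.2, 0.2, 0.5), name = "labels") {
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L)) stop("labels must be non-negative integers")
  new_grid(data, voxel_size, name, "label_grid")
}

#' @rdname grids
#' @export
distance_grid <- function(data, voxel_size = c(0.2, 0.2, 0.5), name = "distance") {
  if (any(data < 0)) stop("distances must be non-negative")
  new_grid(data, voxel_size, name, "distance_grid")
}

# accept either a grid container or a bare array; return the array
grid_data <- function(x) {
  if (inherits(x, "grid3d")) x$data else x
}

grid_voxel_size <- function(x, default = c(0.2, 0.2, 0.5)) {
  if (inherits(x, "grid3d")) x$voxel_size else default
}

grid_name <- function(x, default = "stack") {
  if (inherits(x, "grid3d")) x$name else default
}

# rebuild a container of class `class` shaped like template `like`
grid_like <- function(data, like, class, name = NULL) {
  new_grid(data, grid_voxel_size(like), if (is.null(name)) grid_name(like) else name,
           class)
}

#' @export
print.grid3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> '%s'  %d slices x %d x %d  voxel (%.3g, %.3g, %.3g) um\n",
              class(x)[1], x$name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (inherits(x, "label_grid"))
    cat(sprintf("  %d labelled objects\n", length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' @export
dim.grid3d <- function(x) dim(x$data)

# number of distinct positive labels
n_labels <- function(labels) {
  data <- grid_data(labels)
  m <- max(data)
  if (m == 0L) 0L else sum(tabulate(data[data > 0L], nbins = m) > 0L)
}

# map labels to consecutive 1..n preserving ascending order of old labels
relabel_consecutive <- function(data) {
  old <- sort(unique(data[data > 0L]))
  if (length(old) == 0L) return(data)
  map <- integer(max(old))
  map[old] <- seq_along(old)
  out <- data
  pos <- data > 0L
  out[pos] <- map[data[pos]]
  out
}
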