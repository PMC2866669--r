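#' Seeded 3D watershed via the Image Foresting Transform
#'
#' Partitions the foreground among the seeds as an optimum-path forest on
#' the 6-connected foreground graph: the cost of a path is the maximum of
#' `dmax - dist(v)` over its voxels (the watershed of the inverted distance
#' map), so every foreground voxel joins the seed it can reach over the
#' highest "ridge-free" route. Seed voxels always keep their own labels;
#' foreground components containing no seed stay 0. Ties are deterministic:
#' the lower seed label wins, FIFO within equal cost, so repeated runs give
#' identical partitions.
#'
#' @param dist a [distance_grid] over `mask`.
#' @param seeds a `seed_set` (or a [label_grid] of seed voxels).
#' @param mask the foreground [binary_grid].
#' @return a [label_grid].
#' @export
ift_watershed <- function(dist, seeds, mask) {
  seed_lab <- if (inherits(seeds, "seed_set")) seeds$labels else seeds
  d <- grid_data(dist)
  s <- grid_data(seed_lab)
  m <- grid_data(mask)
  storage.mode(m) <- "logical"
  if (!identical(dim(d), dim(s)) || !identical(dim(d), dim(m)))
    stop("dist, seeds and mask dimensions differ")
  out <- cpp_ift_watershed(as.numeric(d), s, m, dim(d))
  grid_like(out, mask, "label_grid", name = grid_name(mask))
}

#' Merge labels overlapping across adjacent slices
#'
#' Optional post-watershed stage controlled by `intersection_pct`: for every
#' pair of labels present in adjacent slices, the xy-overlap area of their
#' footprints is compared with the smaller footprint; pairs at or above the
#' percentage are merged (transitively), then labels are renumbered
#' consecutively. Disabled (`NA`, the default) it is the identity.
#'
#' @param labels a [label_grid].
#' @param intersection_pct percent in (0, 100\], or `NA` to disable.
#' @return a [label_grid].
#' @export
merge_by_intersection <- function(labels, intersection_pct = NA) {
  if (is.null(intersection_pct) || is.na(intersection_pct)) return(labels)
  if (intersection_pct <= 0 || intersection_pct > 100)
    stop("intersection_pct must be in (0, 100]")
  data <- grid_data(labels)
  nz <- dim(data)[1]
  nmax <- max(data)
  if (nmax < 2L || nz < 2L) return(labels)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_len(nz - 1L)) {
    a <- data[z, , , drop = TRUE]
    b <- data[z + 1L, , , drop = TRUE]
    # per-slice footprint areas
    fa <- tabulate(a[a > 0L], nbins = nmax)
    fb <- tabulate(b[b > 0L], nbins = nmax)
    both <- a > 0L & b > 0L & a != b
    if (!any(both)) next
    pair_code <- (as.numeric(a[both]) - 1) * nmax + as.numeric(b[both])
    tab <- table(pair_code)
    codes <- as.numeric(names(tab))
    la <- as.integer(floor((codes - 1) / nmax) + 1)
    lb <- as.integer(codes - (as.numeric(la) - 1) * nmax)
    overlap <- as.numeric(tab)
    smaller <- pmin(fa[la], fb[lb])
    hit <- overlap >= (intersection_pct / 100) * smaller
    for (i in which(hit)) {
      ra <- find(la[i]); rb <- find(lb[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  out <- data
  pos <- data > 0L
  out[pos] <- roots[data[pos]]
  out <- relabel_consecutive(out)
  grid_like(out, labels, "label_grid")
}
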