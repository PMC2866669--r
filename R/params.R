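#' Pipeline parameters
#'
#' Collects the tunable parameters of the counting pipeline. Defaults match
#' the validated embryo setting: dome height `h = 7` (voxel units of the
#' distance map), seeds below 20 voxels rejected, objects below 3.172 um^3
#' rejected, seeds labelled with 18-connectivity and final objects with
#' 6-connectivity.
#'
#' @param k_sigma multiplier of the background standard deviation; the
#'   per-slice threshold is `max(t_min, mu + k_sigma * sigma)`. Raising it
#'   removes foreground pixels.
#' @param t_min minimum threshold (8-bit intensity), a floor preventing
#'   noise take-over in dark slices.
#' @param median_radius half-width of the per-slice median window
#'   (`2r+1 x 2r+1`).
#' @param h dome height of the h-dome transform of the distance map, in
#'   voxel units.
#' @param dome_threshold seeds are voxels whose dome value exceeds this
#'   (default 0: any strictly positive dome voxel).
#' @param seed_min_voxels seeds with fewer voxels are discarded as spurious.
#' @param min_volume_um3 objects below this volume (um^3) are rejected.
#' @param intersection_pct optional merge stage: minimum percent xy-overlap
#'   between footprints of two labels in adjacent slices for the labels to
#'   be merged; `NA` (default) disables the stage.
#' @param seed_connectivity connectivity used to label seed components
#'   (6, 18 or 26).
#' @param label_connectivity connectivity used for the final object
#'   labelling (6, 18 or 26).
#' @param voxel_size optional `(dx, dy, dz)` um override applied to input
#'   stacks.
#' @param anisotropic_distance if `TRUE`, the distance transform weights the
#'   z-axis by `dz/dx`; default `FALSE` (pure voxel-unit distance, so `h`
#'   stays a voxel-geometry parameter).
#' @return an object of class `pipeline_params`.
#' @export
pipeline_params <- function(k_sigma = 3.0,
                            t_min = 10,
                            median_radius = 1L,
                            h = 7,
                            dome_threshold = 0,
                            seed_min_voxels = 20L,
                            min_volume_um3 = 3.172,
                            intersection_pct = NA_real_,
                            seed_connectivity = 18L,
                            label_connectivity = 6L,
                            voxel_size = NULL,
                            anisotropic_distance = FALSE) {
  p <- structure(list(
    k_sigma = as.numeric(k_sigma),
    t_min = as.numeric(t_min),
    median_radius = as.integer(median_radius),
    h = as.numeric(h),
    dome_threshold = as.numeric(dome_threshold),
    seed_min_voxels = as.integer(seed_min_voxels),
    min_volume_um3 = as.numeric(min_volume_um3),
    intersection_pct = as.numeric(intersection_pct),
    seed_connectivity = as.integer(seed_connectivity),
    label_connectivity = as.integer(label_connectivity),
    voxel_size = if (is.null(voxel_size)) NULL else as.numeric(voxel_size),
    anisotropic_distance = isTRUE(anisotropic_distance)
  ), class = "pipeline_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot_msg <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  stopifnot_msg(is.finite(p$k_sigma) && p$k_sigma >= 0, "k_sigma must be >= 0")
  stopifnot_msg(is.finite(p$t_min), "t_min must be finite")
  stopifnot_msg(p$median_radius >= 1L, "median_radius must be >= 1")
  stopifnot_msg(is.finite(p$h) && p$h > 0, "h must be > 0")
  stopifnot_msg(is.finite(p$dome_threshold) && p$dome_threshold >= 0,
                "dome_threshold must be >= 0")
  stopifnot_msg(p$seed_min_voxels >= 1L, "seed_min_voxels must be >= 1")
  stopifnot_msg(is.finite(p$min_volume_um3) && p$min_volume_um3 > 0,
                "min_volume_um3 must be > 0")
  stopifnot_msg(is.na(p$intersection_pct) ||
                  (p$intersection_pct > 0 && p$intersection_pct <= 100),
                "intersection_pct must be in (0, 100] or NA")
  stopifnot_msg(p$seed_connectivity %in% c(6L, 18L, 26L),
                "seed_connectivity must be 6, 18 or 26")
  stopifnot_msg(p$label_connectivity %in% c(6L, 18L, 26L),
                "label_connectivity must be 6, 18 or 26")
  if (!is.null(p$voxel_size))
    stopifnot_msg(length(p$voxel_size) == 3L && all(p$voxel_size > 0),
                  "voxel_size must be 3 positive numbers")
  invisible(p)
}

#' Load pipeline parameters from a flat key-value file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Keys are the argument names of
#' [pipeline_params()]; `voxel_size` takes three comma-separated numbers.
#' File entries override the defaults; unknown keys are an error.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return a `pipeline_params` object.
#' @export
load_params <- function(path = NULL) {
  if (is.null(path)) return(pipeline_params())
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("unparsable config line: '", ln, "'")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    known <- names(formals(pipeline_params))
    if (!key %in% known)
      stop("unknown config key: '", key, "'")
    parsed <- if (key == "voxel_size") {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "anisotropic_distance") {
      as.logical(val)
    } else if (key == "intersection_pct" && tolower(val) %in% c("na", "none", "disabled")) {
      NA_real_
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) stop("non-numeric value for '", key, "': '", val, "'")
      v
    }
    if (anyNA(parsed) && key != "intersection_pct")
      stop("unparsable value for '", key, "': '", val, "'")
    overrides[[key]] <- parsed
  }
  do.call(pipeline_params, overrides)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "(from stack)" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
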