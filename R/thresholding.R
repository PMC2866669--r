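#' Exact 256-bin histogram of one slice
#'
#' @param slice 2D matrix of 8-bit intensities.
#' @return an `intensity_histogram`: list with `counts` (256 integers, bin
#'   `q+1` counts pixels of value `q`) and `n_pixels`.
#' @export
slice_histogram <- function(slice) {
  if (length(slice) == 0L) stop("slice has no pixels")
  v <- as.integer(round(slice))
  if (any(v < 0L) || any(v > 255L)) stop("intensities must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, n_pixels = length(v)),
            class = "intensity_histogram")
}

#' Fit a Gaussian to the background mode of a histogram
#'
#' Confocal slices of sparse bright nuclei have a unimodal histogram: the
#' large background mode dominates and cell pixels form a thin high tail.
#' A Gaussian `G(q) = A exp(-(q - mu)^2 / (2 sigma^2))` is fitted by least
#' squares to the bins around the mode; the fitting interval is the
#' contiguous run of bins whose count is at least `mode_frac` of the peak
#' count, which excludes the cell tail (those pixels are treated as
#' outliers).
#'
#' @param hist an `intensity_histogram` from [slice_histogram()].
#' @param mode_frac fraction of the peak count bounding the fitting
#'   interval; default 0.1.
#' @return a `background_model`: list with `mu`, `sigma`, `amplitude`,
#'   `fit_error` (residual sum of squares).
#' @export
fit_background <- function(hist, mode_frac = 0.1) {
  counts <- as.numeric(hist$counts)
  if (all(counts == 0)) stop("degenerate background: empty histogram")
  peak_bin <- which.max(counts)            # bin index, value = peak_bin - 1
  peak <- counts[peak_bin]
  lim <- mode_frac * peak
  lo <- peak_bin
  while (lo > 1L && counts[lo - 1L] >= lim) lo <- lo - 1L
  hi <- peak_bin
  while (hi < 256L && counts[hi + 1L] >= lim) hi <- hi + 1L
  if (hi - lo + 1L < 3L)
    stop("degenerate background: mode too narrow to fit")
  q <- (lo:hi) - 1
  y <- counts[lo:hi]
  # init: mu at mode, sigma from half width at half maximum
  half <- peak / 2
  left <- q[which(y >= half)[1]]
  right <- q[rev(which(y >= half))[1]]
  sigma0 <- max((right - left) / 2 / 1.177, 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(q - mu)^2 / (2 * sigma^2)),
                      start = list(A = peak, mu = peak_bin - 1, sigma = sigma0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("background fit failed to converge")
  co <- stats::coef(fit)
  mu <- unname(co["mu"]); sigma <- abs(unname(co["sigma"]))
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0 || mu < 0 || mu > 255)
    stop("background fit produced an invalid model")
  structure(list(mu = mu, sigma = sigma, amplitude = unname(co["A"]),
                 fit_error = sum(stats::resid(fit)^2)),
            class = "background_model")
}

#' Per-slice threshold from a background model
#'
#' `t = max(t_min, mu + k_sigma * sigma)`, clamped to \[0, 255\]. Pixels
#' strictly above `t` are foreground: cell pixels are outliers of the
#' background Gaussian, `k_sigma` standard deviations above its mean. The
#' floor `t_min` prevents noise take-over in dark slices.
#'
#' @param model a `background_model`.
#' @param k_sigma standard-deviation multiplier.
#' @param t_min minimum threshold.
#' @return threshold intensity (numeric scalar).
#' @export
threshold_value <- function(model, k_sigma = 3, t_min = 10) {
  t <- max(t_min, model$mu + k_sigma * model$sigma)
  min(255, max(0, t))
}

#' Binarise a stack slice by slice
#'
#' Each slice is thresholded at its own `t` from [fit_background()] and
#' [threshold_value()]; this per-slice adaptation is what absorbs the decay
#' of intensity with depth and abrupt background changes between slices,
#' without any explicit attenuation correction. A slice whose background
#' fit fails yields an all-background slice and a warning.
#'
#' @param grid a (median-filtered) [voxel_grid].
#' @param params a [pipeline_params].
#' @return a [binary_grid]; attribute `"diagnostics"` holds a data.frame
#'   with per-slice `mu`, `sigma`, `threshold` and `ok`.
#' @export
binarise_stack <- function(grid, params = pipeline_params()) {
  data <- grid_data(grid)
  nz <- dim(data)[1]
  out <- array(FALSE, dim = dim(data))
  diag <- data.frame(z = seq_len(nz), mu = NA_real_, sigma = NA_real_,
                     threshold = NA_real_, ok = FALSE)
  for (z in seq_len(nz)) {
    slice <- data[z, , , drop = TRUE]
    model <- tryCatch(fit_background(slice_histogram(slice)),
                      error = function(e) e)
    if (inherits(model, "error")) {
      warning(sprintf("slice %d: %s; marked all-background", z,
                      conditionMessage(model)), call. = FALSE)
      next
    }
    t <- threshold_value(model, params$k_sigma, params$t_min)
    out[z, , ] <- slice > t
    diag$mu[z] <- model$mu
    diag$sigma[z] <- model$sigma
    diag$threshold[z] <- t
    diag$ok[z] <- TRUE
  }
  res <- grid_like(out, grid, "binary_grid")
  attr(res, "diagnostics") <- diag
  res
}
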