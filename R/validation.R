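#' Object-level comparison of detected cells against ground truth
#'
#' Matches detected and true objects one-to-one in 3D by greatest voxel
#' overlap (greedy: largest overlap first; ties broken towards the lower
#' detected, then truth, label). Matched pairs are true positives;
#' unmatched detections are false positives; unmatched truth objects are
#' false negatives. Under the one-to-one constraint, a true cell split into
#' two detections counts once as a match and once as a false positive, and
#' two cells merged into one detection count as a match plus a false
#' negative -- the error taxonomy of manual validation.
#'
#' @param detected,truth [label_grid]s of identical geometry.
#' @return a `validation_report`: list with `n_true`, `n_detected`, `tp`,
#'   `fp`, `fn`, `fp_pct` (percent of detections that are false),
#'   `fn_pct` (percent of true cells missed) and `sensitivity`
#'   (`tp / n_true`).
#' @export
match_objects <- function(detected, truth) {
  d <- grid_data(detected)
  t_ <- grid_data(truth)
  if (!identical(dim(d), dim(t_)))
    stop("detected and truth geometry mismatch")
  nd <- n_labels(detected)
  nt <- n_labels(truth)
  both <- d > 0L & t_ > 0L
  tp <- 0L
  if (any(both)) {
    tmax <- max(t_)
    code <- (as.numeric(d[both]) - 1) * tmax + as.numeric(t_[both])
    tab <- table(code)
    codes <- as.numeric(names(tab))
    ov <- data.frame(det = floor((codes - 1) / tmax) + 1,
                     tru = codes - floor((codes - 1) / tmax) * tmax,
                     overlap = as.numeric(tab))
    ov <- ov[order(-ov$overlap, ov$det, ov$tru), , drop = FALSE]
    used_d <- logical(max(d)); used_t <- logical(tmax)
    for (i in seq_len(nrow(ov))) {
      a <- ov$det[i]; b <- ov$tru[i]
      if (!used_d[a] && !used_t[b]) {
        used_d[a] <- TRUE; used_t[b] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  structure(list(
    n_true = nt, n_detected = nd, tp = tp, fp = fp, fn = fn,
    fp_pct = if (nd > 0) 100 * fp / nd else 0,
    fn_pct = if (nt > 0) 100 * fn / nt else 0,
    sensitivity = if (nt > 0) tp / nt else NA_real_),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("cells  detected  TP  FP(%)  FN(%)  sensitivity\n")
  cat(sprintf("%5d  %8d  %2d  %5.2f  %5.2f  %.3f\n",
              x$n_true, x$n_detected, x$tp, x$fp_pct, x$fn_pct,
              x$sensitivity))
  invisible(x)
}

#' Write a validation report as a one-row CSV
#'
#' @param report a `validation_report`.
#' @param path output CSV.
#' @export
write_validation_csv <- function(report, path) {
  df <- data.frame(cells = report$n_true, detected = report$n_detected,
                   tp = report$tp, fp_pct = report$fp_pct,
                   fn_pct = report$fn_pct, sensitivity = report$sensitivity)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
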