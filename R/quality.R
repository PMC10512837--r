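# Displacement-quality metrics (SNR, DCCCC), displacement compensation and
# the overlap-sweep optimization used to pick the matching-window overlap.

#' Displacement signal-to-noise ratio over a region of interest
#'
#' `SNR = mean(D_ROI) / sd(D_ROI)` with the sample (N-1) standard
#' deviation. The signed mean is used, so a field of mean zero has SNR 0
#' and a sign flip of the whole map flips the SNR sign. A perfectly uniform
#' field (sd 0) returns `Inf`.
#'
#' @param cda_map A `cda_map` or a numeric matrix of displacement values.
#' @param roi_mask Logical matrix of the same shape with at least 2 pixels.
#' @return The SNR (dimensionless).
#' @export
cda_snr <- function(cda_map, roi_mask) {
  M <- if (inherits(cda_map, "cda_map")) cda_map$values else cda_map
  if (!is.logical(roi_mask) || !all(dim(M) == dim(roi_mask)))
    stop_invalid("roi_mask must be a logical matrix matching the map")
  v <- M[roi_mask]
  if (length(v) < 2)
    stop_invalid("ROI must contain at least 2 pixels")
  s <- sd(v)
  if (s == 0) return(Inf)
  mean(v) / s
}

#' Motion-compensate the post-frame with a dense displacement field
#'
#' Realizes the displacement compensation `F_postC(x - D_A, y - D_L) =
#' F_post(x, y)` by inverse mapping: the output at (x, y) samples the
#' post-frame at `(x + D_A(x, y), y + D_L(x, y))` with bilinear
#' interpolation (a first-order realization, exact for uniform fields).
#' Lookups leaving the frame are marked invalid.
#'
#' @param f_post `rf_frame` or matrix.
#' @param dense_d_axial,dense_d_lateral Dense displacement fields in
#'   samples / lines, same shape as the frame.
#' @return List with `samples` (compensated frame, `NA` where invalid) and
#'   `valid` (logical matrix).
#' @export
compensate_frame <- function(f_post, dense_d_axial, dense_d_lateral) {
  M <- as_rf_samples(f_post)
  if (!all(dim(M) == dim(dense_d_axial)) ||
      !all(dim(M) == dim(dense_d_lateral)))
    stop_invalid("displacement fields must match the frame shape")
  nr <- nrow(M); nc <- ncol(M)
  ri <- row(M) + dense_d_axial
  ci <- col(M) + dense_d_lateral
  valid <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- matrix(NA_real_, nr, nc)
  out[valid] <- bilinear_lookup(M, ri[valid], ci[valid])
  list(samples = out, valid = valid)
}

#' Displacement-compensated cross-correlation coefficient
#'
#' Zero-normalized correlation between the pre-frame and the
#' motion-compensated post-frame over the region of interest:
#' `sum((f - fbar)(g - gbar)) / sqrt(sum((f - fbar)^2) sum((g - gbar)^2))`.
#' The higher the value, the more accurate the displacement estimate; it is
#' a ground-truth-free accuracy proxy. Pixels whose compensated lookup left
#' the frame are excluded via `valid_mask`.
#'
#' @param f_pre `rf_frame` or matrix.
#' @param f_post_c Compensated frame: the list returned by
#'   [compensate_frame()], or a matrix.
#' @param roi_mask Logical ROI matrix.
#' @param valid_mask Optional logical matrix of valid compensated pixels
#'   (taken from `f_post_c` when it is a [compensate_frame()] result).
#' @return DCCCC in `[-1, 1]`.
#' @export
dcccc <- function(f_pre, f_post_c, roi_mask, valid_mask = NULL) {
  pre <- as_rf_samples(f_pre)
  if (is.list(f_post_c) && !is.null(f_post_c$samples)) {
    if (is.null(valid_mask)) valid_mask <- f_post_c$valid
    f_post_c <- f_post_c$samples
  }
  if (!all(dim(pre) == dim(f_post_c)))
    stop_invalid("frames must have identical shape")
  m <- roi_mask
  if (!is.null(valid_mask)) m <- m & valid_mask
  m <- m & !is.na(f_post_c)
  f <- pre[m]; g <- f_post_c[m]
  if (length(f) < 2)
    stop_invalid("ROI with valid compensated pixels is too small")
  fd <- f - mean(f); gd <- g - mean(g)
  den <- sqrt(sum(fd^2) * sum(gd^2))
  if (den == 0)
    stop_invalid("zero variance over the ROI; DCCCC undefined")
  if (all(f == g)) return(1)  # perfect compensation, exactly 1 by definition
  sum(fd * gd) / den
}

#' Sweep the matching-window overlap and score each setting
#'
#' For every overlap value the displacement field between the frame pair is
#' estimated, densified, and scored: SNR of the single-pair axial
#' displacement map over the ROI (Eq.-1-style mean/sd) and DCCCC between
#' the pre-frame and the compensated post-frame. Per-overlap failures are
#' recorded as flagged rows, never aborting the sweep.
#'
#' @param f_pre,f_post The frame pair.
#' @param overlaps Numeric vector (>= 2 values) of overlap percentages in
#'   `[10, 99.9]`; duplicates are not allowed.
#' @param roi_mask Logical ROI matrix (myocardium region).
#' @param config Base [tracking_config()]; its overlap is replaced by each
#'   sweep value.
#' @return A `quality_report`: data frame `records` (one row per overlap,
#'   ascending) and `selected_overlap` per [select_optimal_overlap()].
#' @export
overlap_sweep <- function(f_pre, f_post, overlaps, roi_mask,
                          config = tracking_config()) {
  overlaps <- as.numeric(overlaps)
  if (length(overlaps) < 2 || anyDuplicated(overlaps) ||
      any(overlaps < 10 | overlaps > 99.9))
    stop_invalid("overlaps must be >= 2 distinct values in [10, 99.9]")
  overlaps <- sort(overlaps)
  rows <- lapply(overlaps, function(ov) {
    cfg <- config; cfg$overlap_percent <- ov
    tryCatch({
      fld <- vncc_displacement(f_pre, f_post, cfg)
      da_smp <- densify_field(fld, "axial", "samples")
      dl_smp <- densify_field(fld, "lateral", "samples")
      da_mm <- da_smp * fld$metadata$sound_speed /
        (2 * fld$metadata$sampling_frequency) * 1000
      comp <- compensate_frame(f_post, da_smp, dl_smp)
      pre <- as_rf_samples(f_pre)
      roi_valid <- roi_mask & comp$valid
      data.frame(overlap_percent = ov,
                 snr = cda_snr(da_mm, roi_mask),
                 dcccc = dcccc(f_pre, comp, roi_mask),
                 roi_mean_displacement = mean(da_mm[roi_mask]),
                 roi_sd_displacement = sd(da_mm[roi_mask]),
                 roi_mean_pre = mean(pre[roi_valid]),
                 roi_mean_comp = mean(comp$samples[roi_valid]),
                 flagged = FALSE, message = "")
    }, error = function(e) {
      data.frame(overlap_percent = ov, snr = NA_real_, dcccc = NA_real_,
                 roi_mean_displacement = NA_real_,
                 roi_sd_displacement = NA_real_,
                 roi_mean_pre = NA_real_, roi_mean_comp = NA_real_,
                 flagged = TRUE, message = conditionMessage(e))
    })
  })
  records <- do.call(rbind, rows)
  selected <- tryCatch(select_optimal_overlap(records),
                       error = function(e) NA_real_)
  structure(list(records = records, selected_overlap = selected),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(x$records[, c("overlap_percent", "snr", "dcccc", "flagged")],
        row.names = FALSE)
  cat("selected overlap:", x$selected_overlap, "%\n")
  invisible(x)
}

#' Select the optimal overlap from a sweep
#'
#' The DCCCC curve is median-filtered (width `outlier_filter_width`,
#' endpoints kept) to suppress single-point spikes, then the smallest
#' overlap whose filtered DCCCC reaches `(1 - plateau_tolerance)` times the
#' filtered maximum is returned: the plateau start, i.e. the accuracy /
#' computational-cost compromise.
#'
#' @param report A `quality_report` or its `records` data frame.
#' @param plateau_tolerance Relative tolerance defining the plateau
#'   (default 0.005).
#' @param outlier_filter_width Odd median-filter width (default 3).
#' @return The selected overlap percentage.
#' @export
select_optimal_overlap <- function(report, plateau_tolerance = 0.005,
                                   outlier_filter_width = 3) {
  rec <- if (inherits(report, "quality_report")) report$records else report
  if (!is.data.frame(rec) || !nrow(rec))
    stop_invalid("report is empty")
  if (outlier_filter_width %% 2 != 1 || outlier_filter_width < 1)
    stop_invalid("outlier_filter_width must be odd and >= 1")
  ok <- !rec$flagged & is.finite(rec$dcccc)
  if (!any(ok)) stop_invalid("all sweep records are flagged invalid")
  rec <- rec[ok, , drop = FALSE]
  rec <- rec[order(rec$overlap_percent), , drop = FALSE]
  d <- rec$dcccc
  filt <- if (length(d) >= outlier_filter_width && outlier_filter_width > 1)
    as.numeric(runmed(d, outlier_filter_width, endrule = "keep"))
  else d
  thr <- (1 - plateau_tolerance) * max(filt)
  rec$overlap_percent[which(filt >= thr)[1]]
}
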