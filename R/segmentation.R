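# Semiautomatic regional (6-segment) and layer-specific (3/10-layer)
# left-ventricle myocardium segmentation from manually picked border key
# points. Coordinates are mm, axial depth increasing downward; masks are
# logical matrices over a rectilinear pixel grid (rows = axial).

#' Define a rectilinear pixel grid
#'
#' @param axial_mm,lateral_mm Strictly increasing pixel-center coordinate
#'   vectors (mm).
#' @return A `pixel_grid`.
#' @export
pixel_grid <- function(axial_mm, lateral_mm) {
  if (length(axial_mm) < 2 || length(lateral_mm) < 2 ||
      any(diff(axial_mm) <= 0) || any(diff(lateral_mm) <= 0))
    stop_invalid("grid coordinates must be strictly increasing")
  structure(list(axial_mm = axial_mm, lateral_mm = lateral_mm,
                 pixel_geometry = c(axial = mean(diff(axial_mm)),
                                    lateral = mean(diff(lateral_mm)))),
            class = "pixel_grid")
}

#' Pixel grid of an RF frame
#'
#' @param frame An `rf_frame`.
#' @return The [pixel_grid()] whose pixel centers are the RF samples.
#' @export
pixel_grid_from_frame <- function(frame) {
  if (!inherits(frame, "rf_frame")) stop_invalid("frame must be an rf_frame")
  dz <- mm_per_sample(frame)
  pixel_grid(frame$axial_origin_mm + (seq_len(nrow(frame$samples)) - 1) * dz,
             frame$lateral_origin_mm +
               (seq_len(ncol(frame$samples)) - 1) * frame$pitch)
}

#' Interpolate border key points to a dense trace
#'
#' Cubic-spline interpolation through the manually picked key points
#' (chord-length parameterized), resampled at `n_points` equally spaced
#' arc-length positions. The spline passes through every key point and the
#' endpoints are preserved exactly.
#'
#' @param key_points Data frame (`axial_mm`, `lateral_mm`) or 2-column
#'   matrix, ordered base -> apex -> base; at least 4 points, no
#'   consecutive duplicates.
#' @param n_points Number of resampled points (>= number of key points).
#' @param role Optional `"endo"` or `"epi"` tag.
#' @return A `border_trace` data frame with attribute `role`.
#' @export
interpolate_border <- function(key_points, n_points = 400, role = NULL) {
  kp <- as_points_df(key_points, "key_points")
  n_kp <- nrow(kp)
  if (n_kp < 4) stop_invalid("need at least 4 key points")
  seg <- sqrt(diff(kp$axial_mm)^2 + diff(kp$lateral_mm)^2)
  if (any(seg == 0)) stop_invalid("duplicate consecutive key points")
  if (n_points < n_kp)
    stop_invalid("n_points must be >= the number of key points")
  t_kp <- c(0, cumsum(seg))
  fz <- splinefun(t_kp, kp$axial_mm, method = "natural")
  fx <- splinefun(t_kp, kp$lateral_mm, method = "natural")
  td <- seq(0, max(t_kp), length.out = max(50 * n_kp, 2000))
  zd <- fz(td); xd <- fx(td)
  arc <- c(0, cumsum(sqrt(diff(zd)^2 + diff(xd)^2)))
  s_out <- seq(0, max(arc), length.out = n_points)
  t_out <- approx(arc, td, xout = s_out, ties = "ordered")$y
  out <- data.frame(axial_mm = fz(t_out), lateral_mm = fx(t_out))
  out[1, ] <- kp[1, ]
  out[n_points, ] <- kp[n_kp, ]
  attr(out, "role") <- role
  class(out) <- c("border_trace", "data.frame")
  out
}

#' Basal middle point of a border
#'
#' Arithmetic midpoint of the first and last trace points (the two basal
#' endpoints of the open border).
#'
#' @param border A `border_trace` (or any ordered point data frame).
#' @return Named numeric `c(axial_mm, lateral_mm)`.
#' @export
basal_middle_point <- function(border) {
  b <- as_points_df(border, "border")
  c(axial_mm = (b$axial_mm[1] + b$axial_mm[nrow(b)]) / 2,
    lateral_mm = (b$lateral_mm[1] + b$lateral_mm[nrow(b)]) / 2)
}

#' Apical point of a border
#'
#' The border point farthest (Euclidean) from the basal middle point. Exact
#' distance ties are broken by the smallest index and flagged.
#'
#' @param border A `border_trace`.
#' @param bmp The basal middle point, `c(axial_mm, lateral_mm)`.
#' @return List with `point`, `index`, `tie`.
#' @export
apical_point <- function(border, bmp = basal_middle_point(border)) {
  b <- as_points_df(border, "border")
  d <- sqrt((b$axial_mm - bmp[1])^2 + (b$lateral_mm - bmp[2])^2)
  idx <- which.max(d)
  list(point = c(axial_mm = b$axial_mm[idx], lateral_mm = b$lateral_mm[idx]),
       index = idx,
       tie = sum(d == d[idx]) > 1)
}

# Split an ordered polyline into 3 sections of equal arc length; cut points
# are linearly interpolated and inserted into the adjacent sections.
split_equal_arclength <- function(pts, k = 3) {
  s <- c(0, cumsum(sqrt(diff(pts$axial_mm)^2 + diff(pts$lateral_mm)^2)))
  L <- s[length(s)]
  cuts <- L * seq_len(k - 1) / k
  point_at <- function(st) {
    i <- findInterval(st, s, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(pts) - 1)
    w <- if (s[i + 1] > s[i]) (st - s[i]) / (s[i + 1] - s[i]) else 0
    data.frame(axial_mm = (1 - w) * pts$axial_mm[i] + w * pts$axial_mm[i + 1],
               lateral_mm = (1 - w) * pts$lateral_mm[i] + w * pts$lateral_mm[i + 1])
  }
  bounds <- c(0, cuts, L)
  lapply(seq_len(k), function(j) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    inner <- pts[s > lo & s < hi, , drop = FALSE]
    sec <- rbind(if (j == 1) pts[1, ] else point_at(lo),
                 inner,
                 if (j == k) pts[nrow(pts), ] else point_at(hi))
    rownames(sec) <- NULL
    sec
  })
}

#' Divide a border into six equal-arc-length sections
#'
#' The border is split at the apical point into two sub-borders; each is
#' divided into three sections of equal arc length (cut points linearly
#' interpolated). Sections are returned ordered anterior-base -> apex ->
#' posterior-base.
#'
#' @param border A `border_trace`.
#' @param apex_index Index of the apical point (strictly interior).
#' @return List of 6 point data frames, with attribute `arc_lengths`.
#' @export
divide_border <- function(border, apex_index) {
  b <- as_points_df(border, "border")
  n <- nrow(b)
  if (apex_index <= 1 || apex_index >= n)
    stop_invalid("apex must be strictly interior to the border")
  sub1 <- b[1:apex_index, , drop = FALSE]
  sub2 <- b[apex_index:n, , drop = FALSE]
  secs <- c(split_equal_arclength(sub1, 3), split_equal_arclength(sub2, 3))
  arc_len <- vapply(secs, function(p)
    sum(sqrt(diff(p$axial_mm)^2 + diff(p$lateral_mm)^2)), numeric(1))
  attr(secs, "arc_lengths") <- arc_len
  secs
}

#' Default segment names, anterior base to posterior base
#'
#' Six-segment naming of the long-axis view: the anteroseptal sub-border
#' carries B-ANT-SEP, M-ANT-SEP, A-SEP (base to apex) and the inferolateral
#' sub-border A-LAT, M-INF-LAT, B-INF-LAT (apex to base). The mapping of
#' image sides to walls depends on probe orientation and may be overridden.
#'
#' @return Character vector of 6 segment names.
#' @export
default_segment_names <- function() {
  c("B-ANT-SEP", "M-ANT-SEP", "A-SEP", "A-LAT", "M-INF-LAT", "B-INF-LAT")
}

#' Build the six segment masks from border sections
#'
#' For each of the six positions a closed contour is formed from the
#' endocardial section, the reversed epicardial section and the two
#' connecting cross-wall cuts; pixels (by their centers) are assigned to
#' exactly one segment by point-in-polygon, in a fixed order so boundary
#' pixels are deterministic.
#'
#' @param endo_sections,epi_sections Lists of 6 sections from
#'   [divide_border()], same ordering.
#' @param pixel_grid A [pixel_grid()].
#' @param segment_names Names for the 6 positions
#'   (anterior-base -> apex -> posterior-base).
#' @return An `lv_segmentation`: `segment_masks` (named list of logical
#'   matrices), `myocardium_mask`, `pixel_grid`, `contours`.
#' @export
build_segments <- function(endo_sections, epi_sections, pixel_grid,
                           segment_names = default_segment_names()) {
  if (length(endo_sections) != 6 || length(epi_sections) != 6)
    stop_invalid("expected 6 endocardial and 6 epicardial sections")
  if (length(segment_names) != 6 || anyDuplicated(segment_names))
    stop_invalid("segment_names must be 6 distinct names")
  for (k in 1:6) {
    en <- endo_sections[[k]]; ep <- epi_sections[[k]]
    a1 <- as.numeric(en[1, ]); a2 <- as.numeric(ep[1, ])
    b1 <- as.numeric(en[nrow(en), ]); b2 <- as.numeric(ep[nrow(ep), ])
    if (segments_cross(a1, a2, b1, b2))
      stop_invalid("cross-wall cuts of segment ", k, " intersect")
  }
  ax <- pixel_grid$axial_mm; lat <- pixel_grid$lateral_mm
  nr <- length(ax); nc <- length(lat)
  assigned <- matrix(0L, nr, nc)
  contours <- vector("list", 6)
  for (k in 1:6) {
    en <- endo_sections[[k]]; ep <- epi_sections[[k]]
    poly <- rbind(en, ep[rev(seq_len(nrow(ep))), ])
    contours[[k]] <- poly
    i_rng <- which(ax >= min(poly$axial_mm) - 1e-9 &
                   ax <= max(poly$axial_mm) + 1e-9)
    j_rng <- which(lat >= min(poly$lateral_mm) - 1e-9 &
                   lat <= max(poly$lateral_mm) + 1e-9)
    if (!length(i_rng) || !length(j_rng)) next
    cand <- expand.grid(i = i_rng, j = j_rng)
    cand <- cand[assigned[cbind(cand$i, cand$j)] == 0L, , drop = FALSE]
    if (!nrow(cand)) next
    inside <- pracma::inpolygon(lat[cand$j], ax[cand$i],
                                poly$lateral_mm, poly$axial_mm,
                                boundary = TRUE)
    hit <- cand[inside, , drop = FALSE]
    assigned[cbind(hit$i, hit$j)] <- k
  }
  masks <- lapply(1:6, function(k) assigned == k)
  names(masks) <- segment_names
  names(contours) <- segment_names
  structure(list(segment_masks = masks,
                 myocardium_mask = assigned > 0L,
                 pixel_grid = pixel_grid,
                 contours = contours,
                 layer_masks = list()),
            class = "lv_segmentation")
}

#' Stratify the myocardium into transmural layers
#'
#' Every myocardial pixel gets a normalized transmural coordinate
#' `t = d_epi / (d_epi + d_endo)` from its distances to the epicardial and
#' endocardial border polylines (t = 0 at the epicardium) and is assigned
#' to layer `floor(t * n_layers) + 1`, clamped. Within each segment the
#' layer masks are ordered epicardium -> endocardium and exactly partition
#' the segment mask.
#'
#' @param segmentation An `lv_segmentation` from [build_segments()].
#' @param endo_border,epi_border The full interpolated `border_trace`s.
#' @param n_layers 3 or 10.
#' @return The segmentation with `layer_masks[[as.character(n_layers)]]`
#'   filled: per segment, a list of `n_layers` logical matrices.
#' @export
stratify_layers <- function(segmentation, endo_border, epi_border,
                            n_layers) {
  if (!inherits(segmentation, "lv_segmentation"))
    stop_invalid("segmentation must be an lv_segmentation")
  if (!n_layers %in% c(3, 10)) stop_invalid("n_layers must be 3 or 10")
  en <- as_points_df(endo_border, "endo_border")
  ep <- as_points_df(epi_border, "epi_border")
  myo <- which(segmentation$myocardium_mask)
  ax <- segmentation$pixel_grid$axial_mm
  lat <- segmentation$pixel_grid$lateral_mm
  nr <- length(ax)
  pi_ <- (myo - 1) %% nr + 1
  pj_ <- (myo - 1) %/% nr + 1
  px <- lat[pj_]; pz <- ax[pi_]
  d_endo <- .polyline_mindist_cpp(px, pz, en$lateral_mm, en$axial_mm)
  d_epi <- .polyline_mindist_cpp(px, pz, ep$lateral_mm, ep$axial_mm)
  t <- d_epi / (d_epi + d_endo)
  layer <- pmin(floor(t * n_layers) + 1L, n_layers)
  layer_mat <- matrix(0L, nr, length(lat))
  layer_mat[myo] <- layer
  per_segment <- lapply(segmentation$segment_masks, function(seg_mask) {
    lapply(seq_len(n_layers), function(k) seg_mask & layer_mat == k)
  })
  segmentation$layer_masks[[as.character(n_layers)]] <- per_segment
  segmentation$transmural_coordinate <- {
    tm <- matrix(NA_real_, nr, length(lat)); tm[myo] <- t; tm
  }
  segmentation
}

#' Full semiautomatic segmentation from key points
#'
#' Runs the five segmentation steps: border interpolation, basal-middle and
#' apical point detection, equal-arc-length division, six-segment mask
#' construction, and transmural layer stratification.
#'
#' @param endo_keypoints,epi_keypoints Key-point data frames
#'   (`axial_mm`, `lateral_mm`), ordered base -> apex -> base.
#' @param pixel_grid A [pixel_grid()].
#' @param n_points Border resampling density.
#' @param layer_counts Layer stratifications to compute (subset of
#'   `c(3, 10)`).
#' @param segment_names See [build_segments()].
#' @return An `lv_segmentation` with landmarks attached.
#' @export
segment_myocardium <- function(endo_keypoints, epi_keypoints, pixel_grid,
                               n_points = 400, layer_counts = c(3, 10),
                               segment_names = default_segment_names()) {
  endo <- interpolate_border(endo_keypoints, n_points, role = "endo")
  epi <- interpolate_border(epi_keypoints, n_points, role = "epi")
  endo_bmp <- basal_middle_point(endo)
  epi_bmp <- basal_middle_point(epi)
  endo_ap <- apical_point(endo, endo_bmp)
  epi_ap <- apical_point(epi, epi_bmp)
  endo_secs <- divide_border(endo, endo_ap$index)
  epi_secs <- divide_border(epi, epi_ap$index)
  seg <- build_segments(endo_secs, epi_secs, pixel_grid, segment_names)
  for (nl in layer_counts) seg <- stratify_layers(seg, endo, epi, nl)
  seg$landmarks <- list(endo_bmp = endo_bmp, epi_bmp = epi_bmp,
                        endo_apex = endo_ap, epi_apex = epi_ap)
  seg$borders <- list(endo = endo, epi = epi)
  seg
}

#' @export
print.lv_segmentation <- function(x, ...) {
  counts <- vapply(x$segment_masks, sum, numeric(1))
  cat("<lv_segmentation> segment pixel counts:\n")
  print(counts)
  if (length(x$layer_masks))
    cat("layer stratifications:", paste(names(x$layer_masks), collapse = ", "),
        "\n")
  invisible(x)
}
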