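# NCC/VNCC block-matching displacement estimation between successive RF
# frames and accumulation into the cumulative axial displacement map (CDA).

#' Block-matching configuration
#'
#' The matching block spans `block_axial_wavelengths` wavelengths axially
#' (one wavelength = `sampling_frequency / center_frequency` RF samples) and
#' `block_lateral_pitches` beam lines laterally. The overlap between
#' successive matching windows sets the node-grid stride: window shift =
#' `max(1, round(block * (1 - overlap/100)))` per axis, so 99.9% overlap
#' gives a 1-sample shift.
#'
#' @param block_axial_wavelengths Axial block size in wavelengths
#'   (default 4).
#' @param block_lateral_pitches Lateral block size in beam lines
#'   (default 7).
#' @param overlap_percent Overlap between successive windows, in
#'   `[10, 99.9]`.
#' @param search_margin_axial,search_margin_lateral Search half-widths in
#'   samples / lines; must exceed the per-frame motion.
#' @param subsample_refinement Refine the correlation peak to sub-sample
#'   precision by parabolic interpolation.
#' @return A `tracking_config`.
#' @export
tracking_config <- function(block_axial_wavelengths = 4,
                            block_lateral_pitches = 7,
                            overlap_percent = 80,
                            search_margin_axial = 8,
                            search_margin_lateral = 2,
                            subsample_refinement = TRUE) {
  if (!is_number(overlap_percent) || overlap_percent < 10 ||
      overlap_percent > 99.9)
    stop_invalid("overlap_percent must lie in [10, 99.9]")
  if (!is_number(block_axial_wavelengths) || block_axial_wavelengths <= 0)
    stop_invalid("block_axial_wavelengths must be > 0")
  if (!is_number(block_lateral_pitches) || block_lateral_pitches < 1)
    stop_invalid("block_lateral_pitches must be >= 1")
  if (!is_number(search_margin_axial) || search_margin_axial < 1 ||
      !is_number(search_margin_lateral) || search_margin_lateral < 1)
    stop_invalid("search margins must be >= 1")
  structure(list(block_axial_wavelengths = block_axial_wavelengths,
                 block_lateral_pitches = as.integer(block_lateral_pitches),
                 overlap_percent = overlap_percent,
                 search_margin_axial = as.integer(search_margin_axial),
                 search_margin_lateral = as.integer(search_margin_lateral),
                 subsample_refinement = isTRUE(subsample_refinement)),
            class = "tracking_config")
}

# Resolve block/shift sizes in samples for a given acquisition.
block_geometry <- function(config, frame) {
  lambda <- frame$sampling_frequency / frame$center_frequency
  block_ax <- round(config$block_axial_wavelengths * lambda)
  if (block_ax < 3)
    stop_invalid("axial block of ", block_ax,
                 " samples is too small (need >= 3)")
  ov <- config$overlap_percent / 100
  list(block_ax = as.integer(block_ax),
       block_lat = config$block_lateral_pitches,
       shift_ax = max(1L, as.integer(round(block_ax * (1 - ov)))),
       shift_lat = max(1L, as.integer(round(config$block_lateral_pitches *
                                            (1 - ov)))))
}

#' Zero-normalized cross-correlation surface
#'
#' Correlates a matching block against every equally sized candidate inside
#' a larger search region. The value at lag (0, 0) corresponds to the
#' centered alignment of the block in the region. A zero-variance block or
#' candidate makes the correlation undefined; that lag is set to 0 and
#' flagged in the `degenerate` attribute.
#'
#' @param matching_block,search_region Numeric matrices; the region must be
#'   strictly larger than the block in both dimensions.
#' @return Correlation surface matrix with attributes `axial_lags`,
#'   `lateral_lags` (integer lag coordinates) and `degenerate` (logical
#'   matrix).
#' @export
ncc_surface <- function(matching_block, search_region) {
  b <- as_rf_samples(matching_block); r <- as_rf_samples(search_region)
  if (nrow(r) <= nrow(b) || ncol(r) <= ncol(b))
    stop_invalid("search_region must be strictly larger than matching_block")
  res <- .ncc_surface_cpp(b, r)
  surf <- res$surface
  attr(surf, "axial_lags") <- seq_len(nrow(surf)) - 1L -
    floor((nrow(r) - nrow(b)) / 2)
  attr(surf, "lateral_lags") <- seq_len(ncol(surf)) - 1L -
    floor((ncol(r) - ncol(b)) / 2)
  attr(surf, "degenerate") <- res$degenerate
  surf
}

#' Sub-sample refinement of a correlation peak
#'
#' One-dimensional parabolic fits through the integer peak and its two
#' axial (respectively lateral) neighbours. The fractional offset is
#' `(s[-1] - s[+1]) / (2 (s[-1] - 2 s[0] + s[+1]))`, guaranteed in
#' (-0.5, 0.5); equal neighbours give 0. A peak on the surface border is
#' left unrefined and flagged.
#'
#' @param surface Correlation surface matrix.
#' @param integer_peak Length-2 integer index `c(row, col)` of the peak in
#'   the surface.
#' @return List with `d_axial_frac`, `d_lateral_frac`, `flagged`.
#' @export
refine_subsample <- function(surface, integer_peak) {
  i <- integer_peak[1]; j <- integer_peak[2]
  if (i < 1 || i > nrow(surface) || j < 1 || j > ncol(surface))
    stop_invalid("integer_peak outside the surface")
  if (i == 1 || i == nrow(surface) || j == 1 || j == ncol(surface))
    return(list(d_axial_frac = 0, d_lateral_frac = 0, flagged = TRUE))
  vertex <- function(sm, s0, sp) {
    denom <- sm - 2 * s0 + sp
    if (denom == 0) return(0)
    off <- (sm - sp) / (2 * denom)
    if (!is.finite(off) || abs(off) >= 0.5) 0 else off
  }
  list(d_axial_frac = vertex(surface[i - 1, j], surface[i, j], surface[i + 1, j]),
       d_lateral_frac = vertex(surface[i, j - 1], surface[i, j], surface[i, j + 1]),
       flagged = FALSE)
}

#' Block-matching displacement field between two RF frames
#'
#' For every node of the overlap-defined grid, the block from the pre-frame
#' is correlated against all candidates within the search margins in the
#' post-frame; the displacement is the lag of the correlation maximum,
#' optionally refined to sub-sample precision. Ties between equal maxima go
#' to the smallest lag magnitude (then smallest axial, then lateral lag).
#' Nodes whose search window would leave the frame are dropped from the
#' grid; positive axial displacement means motion toward greater depth.
#'
#' @param f_pre,f_post `rf_frame`s (or plain matrices) of identical shape.
#' @param config A [tracking_config()].
#' @return A `displacement_field`: node positions (block-center sample/line
#'   indices), matrices `d_axial` (samples), `d_lateral` (lines),
#'   `peak_ncc`, and `flag` (0 ok, 1 zero-variance, 2 border peak
#'   unrefined).
#' @export
vncc_displacement <- function(f_pre, f_post, config = tracking_config()) {
  pre <- as_rf_samples(f_pre); post <- as_rf_samples(f_post)
  if (!all(dim(pre) == dim(post)))
    stop_invalid("frames must have identical shape")
  meta <- if (inherits(f_pre, "rf_frame")) f_pre else
    rf_frame(pre)
  if (inherits(f_post, "rf_frame") &&
      (f_post$sampling_frequency != meta$sampling_frequency ||
       f_post$center_frequency != meta$center_frequency))
    stop_invalid("frames must share acquisition metadata")
  g <- block_geometry(config, meta)
  ma <- config$search_margin_axial; ml <- config$search_margin_lateral
  if (nrow(pre) < g$block_ax + 2 * ma || ncol(pre) < g$block_lat + 2 * ml)
    stop_invalid("frame too small for block size plus search margins")
  res <- .block_match_cpp(pre, post, g$block_ax, g$block_lat,
                          g$shift_ax, g$shift_lat, ma, ml,
                          config$subsample_refinement)
  structure(list(node_axial_positions = res$i0 + 1 + (g$block_ax - 1) / 2,
                 node_lateral_positions = res$j0 + 1 + (g$block_lat - 1) / 2,
                 d_axial = res$d_axial,
                 d_lateral = res$d_lateral,
                 peak_ncc = res$peak_ncc,
                 flag = res$flag,
                 frame_shape = dim(pre),
                 geometry = g,
                 config = config,
                 metadata = meta[c("center_frequency", "sampling_frequency",
                                   "sound_speed", "pitch")]),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d nodes (overlap %.1f%%), mean peak NCC %.3f\n",
              length(x$node_axial_positions), length(x$node_lateral_positions),
              x$config$overlap_percent, mean(x$peak_ncc)))
  invisible(x)
}

#' Interpolate a node-grid displacement field to the dense pixel grid
#'
#' Separable (bilinear) interpolation of the node values to every RF
#' sample, with edge values extended outward beyond the node hull.
#'
#' @param field A `displacement_field`.
#' @param component `"axial"` or `"lateral"`.
#' @param units `"samples"` (native) or `"mm"`.
#' @return Dense numeric matrix of the frame shape.
#' @export
densify_field <- function(field, component = c("axial", "lateral"),
                          units = c("samples", "mm")) {
  component <- match.arg(component); units <- match.arg(units)
  vals <- if (component == "axial") field$d_axial else field$d_lateral
  nr <- field$frame_shape[1]; nc <- field$frame_shape[2]
  interp_axis <- function(pos, V, nout) {
    if (length(pos) == 1) return(matrix(rep(as.numeric(V), each = nout),
                                        nrow = nout))
    vapply(seq_len(ncol(V)),
           function(j) approx(pos, V[, j], xout = seq_len(nout), rule = 2)$y,
           numeric(nout))
  }
  M <- interp_axis(field$node_axial_positions, vals, nr)        # nr x nlat
  M <- t(interp_axis(field$node_lateral_positions, t(M), nc))   # nr x nc
  if (units == "mm") {
    scale <- if (component == "axial")
      field$metadata$sound_speed / (2 * field$metadata$sampling_frequency) * 1000
    else field$metadata$pitch
    M <- M * scale
  }
  M
}

#' Accumulate incremental fields into the cumulative axial displacement map
#'
#' Each incremental field is interpolated to the dense pixel grid,
#' converted from samples to mm via `c / (2 fs)`, and summed at fixed pixel
#' coordinates (Eulerian accumulation). Positive values are downward
#' (away-from-probe) motion.
#'
#' @param fields Ordered list of `displacement_field`s (successive frame
#'   pairs).
#' @param frame_shape Optional shape check.
#' @return A `cda_map` with dense `values` in mm.
#' @export
accumulate_displacement <- function(fields, frame_shape = NULL) {
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  if (!length(fields)) stop_invalid("need at least one displacement field")
  shp <- fields[[1]]$frame_shape
  if (!is.null(frame_shape) && !all(shp == frame_shape))
    stop_invalid("frame_shape does not match the fields")
  for (f in fields)
    if (!all(f$frame_shape == shp))
      stop_invalid("all fields must share one frame shape")
  values <- matrix(0, shp[1], shp[2])
  for (f in fields) values <- values + densify_field(f, "axial", "mm")
  structure(list(values = values, frame_shape = shp,
                 n_pairs = length(fields),
                 metadata = fields[[1]]$metadata),
            class = "cda_map")
}

#' @export
print.cda_map <- function(x, ...) {
  cat(sprintf("<cda_map> %d x %d px over %d frame pair(s), range [%.4f, %.4f] mm\n",
              x$frame_shape[1], x$frame_shape[2], x$n_pairs,
              min(x$values), max(x$values)))
  invisible(x)
}
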