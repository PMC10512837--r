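# Layer-averaged cumulative displacement profiles and the transmural
# motion index (TMI): the slope of the straight-line fit of mean CDA
# across the 10 transmural layers (epicardium -> endocardium).

#' Layer-averaged cumulative axial displacement profile
#'
#' Mean of the cumulative axial displacement map over each layer mask of
#' one segment, ordered epicardium -> endocardium.
#'
#' @param cda_map A `cda_map` or numeric matrix (mm).
#' @param layer_masks List of logical layer masks for one segment
#'   (epi -> endo), e.g.
#'   `segmentation$layer_masks[["10"]][["M-ANT-SEP"]]`.
#' @param segment_name Optional segment label carried through.
#' @return A `layer_profile` with `values` (mm), `n_layers`,
#'   `pixel_counts`.
#' @export
layer_profile <- function(cda_map, layer_masks, segment_name = NULL) {
  M <- if (inherits(cda_map, "cda_map")) cda_map$values else cda_map
  n <- length(layer_masks)
  counts <- vapply(layer_masks, sum, numeric(1))
  if (any(counts == 0))
    stop_invalid("empty layer mask (segment ",
                 if (is.null(segment_name)) "?" else segment_name,
                 ", layer ", which(counts == 0)[1], ")")
  vals <- vapply(layer_masks, function(m) mean(M[m]), numeric(1))
  if (!all(is.finite(vals)))
    stop_invalid("non-finite layer mean encountered")
  structure(list(segment_name = segment_name, n_layers = n,
                 values = unname(vals), pixel_counts = unname(counts)),
            class = "layer_profile")
}

#' Transmural motion index
#'
#' Ordinary least-squares straight-line fit of the 10 layer-mean CDA
#' values against the layer index n = 1..10; the TMI is the fitted slope
#' (mm per layer index), the first derivative of the first-order
#' polynomial. Signed CDA is used by default; `absolute = TRUE` fits the
#' absolute layer means instead (clearly labelled in the result).
#'
#' @param profile A `layer_profile` with `n_layers = 10`.
#' @param absolute Fit `|CDA|` instead of signed CDA.
#' @return A `tmi_result`: `tmi` (slope), `intercept`, `segment_name`,
#'   `n_layers`, `absolute`.
#' @export
tmi <- function(profile, absolute = FALSE) {
  if (!inherits(profile, "layer_profile"))
    stop_invalid("profile must be a layer_profile")
  if (profile$n_layers != 10)
    stop_invalid("TMI is defined on the 10-layer profile")
  y <- profile$values
  if (!all(is.finite(y))) stop_invalid("profile contains non-finite values")
  if (absolute) y <- abs(y)
  n <- seq_len(10)
  fit <- lm(y ~ n)
  structure(list(segment_name = profile$segment_name,
                 tmi = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_layers = 10L,
                 absolute = absolute),
            class = "tmi_result")
}

#' @export
print.tmi_result <- function(x, ...) {
  cat(sprintf("<tmi_result> %s: TMI = %.4f mm/layer (intercept %.4f)%s\n",
              if (is.null(x$segment_name)) "?" else x$segment_name,
              x$tmi, x$intercept,
              if (x$absolute) " [absolute CDA]" else ""))
  invisible(x)
}

#' Mean cumulative axial displacement of a segment
#'
#' Signed mean of the CDA map over the segment mask (positive = downward,
#' away-from-probe motion).
#'
#' @param cda_map A `cda_map` or numeric matrix (mm).
#' @param segment_mask Logical mask.
#' @return Mean CDA in mm.
#' @export
segment_mean_cda <- function(cda_map, segment_mask) {
  M <- if (inherits(cda_map, "cda_map")) cda_map$values else cda_map
  if (!any(segment_mask)) stop_invalid("segment mask is empty")
  mean(M[segment_mask])
}

#' Per-segment motion summary table
#'
#' Combines segment mean CDA, the 10-layer profile and the fitted TMI for
#' every segment of a segmentation.
#'
#' @param cda_map A `cda_map`.
#' @param segmentation An `lv_segmentation` with a 10-layer
#'   stratification.
#' @param absolute Passed to [tmi()].
#' @return Data frame: `segment`, `mean_cda_mm`, `tmi_mm_per_layer`,
#'   `intercept_mm`, `layer_1` .. `layer_10`.
#' @export
transmural_table <- function(cda_map, segmentation, absolute = FALSE) {
  if (is.null(segmentation$layer_masks[["10"]]))
    stop_invalid("segmentation lacks the 10-layer stratification")
  segs <- names(segmentation$segment_masks)
  rows <- lapply(segs, function(s) {
    prof <- layer_profile(cda_map, segmentation$layer_masks[["10"]][[s]], s)
    fit <- tmi(prof, absolute = absolute)
    out <- data.frame(segment = s,
                      mean_cda_mm = segment_mean_cda(
                        cda_map, segmentation$segment_masks[[s]]),
                      tmi_mm_per_layer = fit$tmi,
                      intercept_mm = fit$intercept)
    layer_cols <- as.data.frame(as.list(prof$values))
    names(layer_cols) <- paste0("layer_", seq_len(10))
    cbind(out, layer_cols)
  })
  do.call(rbind, rows)
}
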