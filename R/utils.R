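# Internal helpers shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Vectorized bilinear lookup into matrix M at fractional (row, col)
# coordinates. Coordinates are clamped to the valid interpolation range;
# callers that need out-of-range detection must mask beforehand.
bilinear_lookup <- function(M, ri, ci) {
  nr <- nrow(M); nc <- ncol(M)
  i0 <- pmin(pmax(floor(ri), 1), max(nr - 1, 1))
  j0 <- pmin(pmax(floor(ci), 1), max(nc - 1, 1))
  fr <- pmin(pmax(ri - i0, 0), 1)
  fc <- pmin(pmax(ci - j0, 0), 1)
  i1 <- pmin(i0 + 1, nr); j1 <- pmin(j0 + 1, nc)
  (1 - fr) * (1 - fc) * M[cbind(i0, j0)] +
    fr * (1 - fc) * M[cbind(i1, j0)] +
    (1 - fr) * fc * M[cbind(i0, j1)] +
    fr * fc * M[cbind(i1, j1)]
}

# Proper segment intersection test (shared endpoints do not count).
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

as_points_df <- function(x, what = "points") {
  if (is.matrix(x)) x <- data.frame(axial_mm = x[, 1], lateral_mm = x[, 2])
  if (!is.data.frame(x) || !all(c("axial_mm", "lateral_mm") %in% names(x)))
    stop_invalid(what, " must be a data frame with columns axial_mm, lateral_mm")
  if (!all(is.finite(x$axial_mm)) || !all(is.finite(x$lateral_mm)))
    stop_invalid(what, " contains non-finite coordinates")
  x[, c("axial_mm", "lateral_mm")]
}
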