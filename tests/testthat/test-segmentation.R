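# Regional and layer-specific segmentation: border interpolation accuracy,
# landmark detection, equal-arc division, pixel-exact partitions, and
# transmural layer geometry.

half_ellipse_points <- function(a, b, center = c(1, 0), n = 13) {
  phi <- seq(0, pi, length.out = n)
  data.frame(axial_mm = center[1] + b * sin(phi),
             lateral_mm = center[2] - a * cos(phi))
}

test_that("border interpolation reproduces an analytic half-ellipse", {
  kp <- half_ellipse_points(4, 8, n = 13)
  tr <- interpolate_border(kp, 400)
  expect_equal(nrow(tr), 400)
  expect_equal(as.numeric(tr[1, ]), as.numeric(kp[1, ]))
  expect_equal(as.numeric(tr[400, ]), as.numeric(kp[13, ]))
  # distance to the analytic curve below 0.5% of the semi-minor axis
  phi_d <- seq(0, pi, length.out = 20000)
  ez <- 1 + 8 * sin(phi_d); ex <- -4 * cos(phi_d)
  dmin <- vapply(seq_len(400), function(i)
    min(sqrt((tr$axial_mm[i] - ez)^2 + (tr$lateral_mm[i] - ex)^2)),
    numeric(1))
  expect_lt(max(dmin), 0.005 * 4)

  expect_error(interpolate_border(kp[1:3, ], 100), "4 key points")
  expect_error(interpolate_border(kp, 3), "n_points")
  dup <- kp; dup[2, ] <- dup[1, ]
  expect_error(interpolate_border(dup, 100), "duplicate")
})

test_that("basal middle point and apical point follow their definitions", {
  b <- data.frame(axial_mm = c(0, 5, 8, 5, 0), lateral_mm = c(0, 1, 2, 3, 4))
  expect_equal(basal_middle_point(b), c(axial_mm = 0, lateral_mm = 2))
  deg <- data.frame(axial_mm = c(1, 5, 1), lateral_mm = c(2, 3, 2))
  expect_equal(basal_middle_point(deg), c(axial_mm = 1, lateral_mm = 2))

  # half-ellipse with depth semi-axis 8: apex 8 mm below the BMp
  kp <- half_ellipse_points(4, 8, n = 13)
  tr <- interpolate_border(kp, 401)
  bmp <- basal_middle_point(tr)
  expect_equal(unname(bmp), c(1, 0), tolerance = 1e-8)
  ap <- apical_point(tr, bmp)
  expect_equal(unname(ap$point), c(9, 0), tolerance = 1e-3)
  expect_gt(ap$index, 1)
  expect_lt(ap$index, 401)
  expect_false(ap$tie)

  # exact equidistant points (3-4-5 construction): tie flagged, first wins
  circ <- data.frame(axial_mm = c(0, 4, 5, 4, 0),
                     lateral_mm = c(-5, -3, 0, 3, 5))
  apc <- apical_point(circ, c(0, 0))
  expect_true(apc$tie)
  expect_equal(apc$index, 1)
})

test_that("equal-arc-length division cuts where it should", {
  # straight-line sub-border of length 9: cuts at 3 and 6
  border <- data.frame(axial_mm = c(seq(0, 9, by = 1), seq(8, 0, by = -1)),
                       lateral_mm = c(rep(0, 10), rep(2, 9)))
  segs <- divide_border(border, apex_index = 10)
  arc <- attr(segs, "arc_lengths")
  expect_equal(arc[1:3], rep(3, 3), tolerance = 1e-12)
  expect_equal(segs[[1]]$axial_mm[nrow(segs[[1]])], 3)
  expect_equal(segs[[2]]$axial_mm[nrow(segs[[2]])], 6)

  # quarter-arc sub-borders of a half circle: each section (pi R / 2) / 3
  R <- 5
  kp <- half_ellipse_points(R, R, center = c(0, 0), n = 21)
  tr <- interpolate_border(kp, 399)
  segs2 <- divide_border(tr, apex_index = 200)
  arcs <- attr(segs2, "arc_lengths")
  expect_lt(max(abs(arcs - (pi * R / 2) / 3)) / ((pi * R / 2) / 3), 0.005)

  # concatenation preserves the original point set
  joined <- do.call(rbind, segs2)
  expect_true(all(round(tr$axial_mm, 9) %in% round(joined$axial_mm, 9)))

  expect_error(divide_border(tr, 1), "interior")
  expect_error(divide_border(tr, 399), "interior")
})

test_that("six segments tile the myocardium pixel-exactly and symmetrically", {
  ph <- make_lv_phantom(c(4, 6), c(6, 8), center = c(1, 0), seed = 2)
  grid <- pixel_grid(seq(0, 9.5, by = 0.05), seq(-7, 7, by = 0.09))
  seg <- segment_myocardium(ph$endo_keypoints, ph$epi_keypoints, grid,
                            layer_counts = 3)
  counts <- vapply(seg$segment_masks, sum, numeric(1))
  expect_true(all(counts > 0))
  # pairwise disjoint and conserving
  total <- Reduce(`+`, seg$segment_masks)
  expect_true(all(total <= 1))
  expect_equal(sum(counts), sum(seg$myocardium_mask))
  # mirror symmetry of the phantom: apical segments agree within 2%
  expect_lt(abs(counts[["A-SEP"]] - counts[["A-LAT"]]) /
              max(counts[["A-SEP"]], counts[["A-LAT"]]), 0.02)

  # layers partition each segment exactly
  for (s in names(seg$segment_masks)) {
    lm <- seg$layer_masks[["3"]][[s]]
    expect_length(lm, 3)
    expect_equal(Reduce(`+`, lm), seg$segment_masks[[s]] + 0L,
                 ignore_attr = TRUE)
  }
})

test_that("segment areas are stable under border resampling", {
  ph <- make_lv_phantom(c(4, 6), c(6, 8), center = c(1, 0), seed = 2)
  grid <- pixel_grid(seq(0, 9.5, by = 0.05), seq(-7, 7, by = 0.09))
  s1 <- segment_myocardium(ph$endo_keypoints, ph$epi_keypoints, grid,
                           n_points = 300, layer_counts = integer(0))
  s2 <- segment_myocardium(ph$endo_keypoints, ph$epi_keypoints, grid,
                           n_points = 600, layer_counts = integer(0))
  a1 <- vapply(s1$segment_masks, sum, numeric(1))
  a2 <- vapply(s2$segment_masks, sum, numeric(1))
  expect_true(all(abs(a1 - a2) / a1 < 0.02))
})

test_that("layer stratification recovers concentric-annulus radii", {
  # half circular annulus, r = 10, R = 16: 3-layer boundaries at 12 and 14.
  # Borders are picked densely (41 key points) so that the spline border is
  # well below a pixel from the true circle and the check isolates the
  # stratification geometry.
  ph <- make_lv_phantom(c(10, 10), c(16, 16), center = c(0, 0),
                        seed = 3, density_per_mm2 = 5, n_border_points = 41)
  grid <- pixel_grid(seq(0, 17, by = 0.05), seq(-17, 17, by = 0.05))
  endo <- interpolate_border(ph$endo_keypoints, 800)
  epi <- interpolate_border(ph$epi_keypoints, 800)
  # the circle has no unique farthest point; pin the apex at the geometric
  # bottom so the six-segment division is well defined
  apex_idx <- function(b) which.max(b$axial_mm)
  seg <- build_segments(divide_border(endo, apex_idx(endo)),
                        divide_border(epi, apex_idx(epi)), grid)
  seg <- stratify_layers(seg, endo, epi, 3)
  seg <- stratify_layers(seg, endo, epi, 10)

  zz <- matrix(grid$axial_mm, length(grid$axial_mm), length(grid$lateral_mm))
  xx <- matrix(grid$lateral_mm, length(grid$axial_mm),
               length(grid$lateral_mm), byrow = TRUE)
  rho <- sqrt(zz^2 + xx^2)
  half_px <- 0.05 / 2

  all3 <- lapply(1:3, function(k)
    Reduce(`|`, lapply(seg$layer_masks[["3"]], `[[`, k)))
  # epicardial layer: rho in (14, 16); middle (12, 14); endocardial (10, 12)
  expect_gt(min(rho[all3[[1]]]), 14 - half_px)
  expect_lt(max(rho[all3[[2]]]), 14 + half_px)
  expect_gt(min(rho[all3[[2]]]), 12 - half_px)
  expect_lt(max(rho[all3[[3]]]), 12 + half_px)

  # 10 layers: each 0.6 mm wide within half a pixel
  all10 <- lapply(1:10, function(k)
    Reduce(`|`, lapply(seg$layer_masks[["10"]], `[[`, k)))
  for (k in 1:10) {
    lo <- 16 - 0.6 * k; hi <- 16 - 0.6 * (k - 1)
    expect_gt(min(rho[all10[[k]]]), lo - half_px)
    expect_lt(max(rho[all10[[k]]]), hi + half_px)
  }
})
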