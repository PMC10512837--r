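# Block-matching displacement estimation: oracle equivalence, shift
# recovery, invariances, grid contract, sub-sample refinement, and
# cumulative-displacement accumulation.

test_that("correlation surface matches a brute-force oracle and its symmetries", {
  set.seed(10)
  block <- matrix(sample(0:9, 9, replace = TRUE), 3, 3)
  region <- matrix(sample(0:9, 25, replace = TRUE), 5, 5)
  surf <- ncc_surface(block, region)
  expect_equal(unclass(surf), naive_ncc_surface(block, region),
               tolerance = 1e-12, ignore_attr = TRUE)

  # block embedded at the center: max exactly 1 at lag (0, 0)
  big <- matrix(rnorm(11 * 11), 11, 11)
  blk <- big[5:7, 5:7]
  s2 <- ncc_surface(blk, big[3:9, 3:9])
  peak <- which(s2 == max(s2), arr.ind = TRUE)
  expect_equal(max(s2), 1)
  expect_equal(attr(s2, "axial_lags")[peak[1]], 0)
  expect_equal(attr(s2, "lateral_lags")[peak[2]], 0)

  # ZNCC gain/offset invariance of the candidate frame
  s3 <- ncc_surface(blk, 2.5 * big[3:9, 3:9] + 7)
  expect_equal(unclass(s3), unclass(s2), tolerance = 1e-12)

  expect_error(ncc_surface(blk, blk), "strictly larger")
})

test_that("zero-variance blocks are flagged and scored 0", {
  blk <- matrix(rnorm(9), 3, 3)
  region <- matrix(1, 5, 5)          # constant: every candidate degenerate
  s <- ncc_surface(blk, region)
  expect_true(all(s == 0))
  expect_true(all(attr(s, "degenerate")))
})

test_that("fast matcher equals the naive triple-loop matcher node-for-node", {
  cfg <- tracking_config(overlap_percent = 80, search_margin_axial = 4,
                         search_margin_lateral = 2,
                         subsample_refinement = FALSE)
  for (seed in 1:3) {
    set.seed(seed)
    pre <- matrix(rnorm(64 * 32), 64, 32)
    post <- matrix(rnorm(64 * 32), 64, 32)
    fast <- vncc_displacement(pre, post, cfg)
    ref <- naive_block_match(pre, post, block_ax = 16, block_lat = 7,
                             shift_ax = 3, shift_lat = 1, ma = 4, ml = 2)
    expect_identical(fast$d_axial, ref$d_axial)
    expect_identical(fast$d_lateral, ref$d_lateral)
    expect_equal(fast$peak_ncc, ref$peak_ncc, tolerance = 1e-12)
  }
})

test_that("integer circular shifts are recovered exactly everywhere", {
  set.seed(42)
  pre <- matrix(rnorm(100 * 30), 100, 30)
  for (k in c(-3, 3)) {
    post <- circular_shift_rows(pre, k)
    f <- vncc_displacement(pre, post, tracking_config())
    expect_true(all(f$d_axial == k))
    expect_true(all(f$d_lateral == 0))
    expect_true(all(abs(f$peak_ncc - 1) < 1e-12))
  }
})

test_that("identity, gain invariance, and reversal symmetry hold", {
  set.seed(7)
  pre <- matrix(rnorm(80 * 25), 80, 25)
  f0 <- vncc_displacement(pre, pre, tracking_config())
  expect_true(all(f0$d_axial == 0) && all(f0$d_lateral == 0))

  post <- shift_rows(pre, 4)
  f1 <- vncc_displacement(pre, post, tracking_config())
  f1g <- vncc_displacement(pre, 3.7 * post, tracking_config())
  expect_identical(f1$d_axial, f1g$d_axial)
  expect_identical(f1$d_lateral, f1g$d_lateral)

  f2 <- vncc_displacement(post, pre, tracking_config())
  expect_true(all(f1$d_axial == 4))
  expect_true(all(f2$d_axial == -4))
})

test_that("node grid follows the overlap-defined window shift", {
  pre <- matrix(rnorm(200 * 40), 200, 40)
  meta <- rf_frame(pre)  # lambda = 4 samples, block 16 x 7
  for (ov in c(10, 50, 80, 99.9)) {
    cfg <- tracking_config(overlap_percent = ov)
    f <- vncc_displacement(pre, pre, cfg)
    shift_ax <- max(1, round(16 * (1 - ov / 100)))
    shift_lat <- max(1, round(7 * (1 - ov / 100)))
    expect_length(f$node_axial_positions,
                  floor((200 - 16 - 2 * 8) / shift_ax) + 1)
    expect_length(f$node_lateral_positions,
                  floor((40 - 7 - 2 * 2) / shift_lat) + 1)
    if (length(f$node_axial_positions) > 1)
      expect_equal(unique(diff(f$node_axial_positions)), shift_ax)
  }
  # 99.9% overlap means a one-sample window shift
  f999 <- vncc_displacement(pre, pre, tracking_config(overlap_percent = 99.9))
  expect_equal(unique(diff(f999$node_axial_positions)), 1)
})

test_that("sub-sample refinement is the closed-form parabola vertex", {
  s <- matrix(0.1, 3, 3)
  s[1, 2] <- 0.6; s[2, 2] <- 1.0; s[3, 2] <- 0.9
  s[2, 1] <- 0.5; s[2, 3] <- 0.5
  r <- refine_subsample(s, c(2, 2))
  expect_equal(r$d_axial_frac, (0.6 - 0.9) / (2 * (0.6 - 2 + 0.9)))
  expect_equal(r$d_axial_frac, 0.3)
  expect_equal(r$d_lateral_frac, 0)        # symmetric neighbours
  expect_false(r$flagged)

  r2 <- refine_subsample(s, c(1, 1))       # corner peak: no refinement
  expect_true(r2$flagged)
  expect_equal(r2$d_axial_frac, 0)

  # scatterer-level half-sample shift recovered to sub-sample accuracy
  pair <- make_speckle_pair(0.5, seed = 3)
  f <- vncc_displacement(pair$f_pre, pair$f_post,
                         tracking_config(overlap_percent = 80))
  ok <- f$flag == 0
  expect_gt(mean(ok), 0.9)
  expect_lt(mean(abs(f$d_axial[ok] - 0.5)), 0.25)
})

test_that("accumulation densifies, converts to mm, and sums Eulerian", {
  fs <- 1540 / (2 * 0.018e-3)   # 1 RF sample = 0.018 mm
  mk_field <- function(val) {
    structure(list(node_axial_positions = c(10, 20, 30),
                   node_lateral_positions = c(4, 8),
                   d_axial = matrix(val, 3, 2),
                   d_lateral = matrix(0, 3, 2),
                   peak_ncc = matrix(1, 3, 2),
                   flag = matrix(0L, 3, 2),
                   frame_shape = c(40L, 12L),
                   metadata = list(center_frequency = fs / 4,
                                   sampling_frequency = fs,
                                   sound_speed = 1540, pitch = 0.09)),
              class = "displacement_field")
  }
  m <- accumulate_displacement(list(mk_field(1), mk_field(1)))
  expect_equal(dim(m$values), c(40L, 12L))
  expect_true(all(abs(m$values - 0.036) < 1e-12))

  one <- accumulate_displacement(list(mk_field(2.5)))
  expect_equal(one$values,
               densify_field(mk_field(2.5), "axial", "mm"))
  expect_error(accumulate_displacement(list()), "at least one")
})

test_that("cumulative displacement matches ground truth on a uniform sequence", {
  psf <- psf_params()
  dz <- mm_per_sample(psf)
  scene <- make_scatterer_field(c(0, 6, 0, 5), 200, seed = 6)
  m <- motion_model("uniform", n_frames = 5, axial_mm_per_frame = 2 * dz)
  seq <- generate_sequence(scene, psf, m)
  cfg <- tracking_config(overlap_percent = 80)
  fields <- lapply(1:4, function(k)
    vncc_displacement(seq$frames[[k]], seq$frames[[k + 1]], cfg))
  cda <- accumulate_displacement(fields)
  truth_mm <- 8 * dz
  interior <- cda$values[100:500, 10:45]
  expect_lt(max(abs(interior - truth_mm)), 0.1 * dz)
})
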