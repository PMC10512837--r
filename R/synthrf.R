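# Synthetic RF simulator: point-scatterer scenes convolved with a separable
# Gaussian-envelope cosine PSF, warped by analytic motion models so that the
# ground-truth displacement field is known exactly at every position.
#
# Coordinates are mm; axial depth increases downward (away from the probe).

#' Point-spread-function and acquisition parameters
#'
#' Parameters of the band-limited PSF and the sampling grid used to render
#' synthetic RF frames. Defaults mimic a high-frequency small-animal probe
#' with a 21 MHz center frequency.
#'
#' @param center_frequency Transmit center frequency in Hz.
#' @param sampling_frequency RF sampling frequency in Hz; must be at least
#'   four times the center frequency.
#' @param sound_speed Speed of sound in m/s (soft-tissue value by default).
#' @param axial_pulse_sigma Gaussian envelope standard deviation of the
#'   two-way pulse, in seconds. The default (half a carrier period) gives a
#'   short broadband pulse whose RF autocorrelation side lobe one carrier
#'   period away is well below the main lobe, keeping correlation-based
#'   block matching well-posed; long narrowband pulses reintroduce
#'   phase-wrapping ambiguity.
#' @param lateral_beam_sigma Lateral Gaussian beam standard deviation, mm.
#' @param pitch Element pitch (lateral line spacing), mm.
#'
#' @return An object of class `psf_params`.
#' @export
psf_params <- function(center_frequency = 21e6,
                       sampling_frequency = 4 * center_frequency,
                       sound_speed = 1540,
                       axial_pulse_sigma = 0.5 / center_frequency,
                       lateral_beam_sigma = 0.10,
                       pitch = 0.09) {
  vals <- c(center_frequency, sampling_frequency, sound_speed,
            axial_pulse_sigma, lateral_beam_sigma, pitch)
  if (!all(vapply(vals, is_number, logical(1))) || any(vals <= 0))
    stop_invalid("all psf_params fields must be positive finite numbers")
  if (sampling_frequency < 4 * center_frequency)
    stop_invalid("sampling_frequency must be >= 4 * center_frequency")
  structure(list(center_frequency = center_frequency,
                 sampling_frequency = sampling_frequency,
                 sound_speed = sound_speed,
                 axial_pulse_sigma = axial_pulse_sigma,
                 lateral_beam_sigma = lateral_beam_sigma,
                 pitch = pitch),
            class = "psf_params")
}

#' Axial sample spacing in mm for a given acquisition
#'
#' One RF sample spans `sound_speed / (2 * sampling_frequency)` metres of
#' depth (two-way travel).
#'
#' @param x A `psf_params` or `rf_frame` object.
#' @return Millimetres per axial RF sample.
#' @export
mm_per_sample <- function(x) {
  x$sound_speed / (2 * x$sampling_frequency) * 1000
}

#' Draw a random point-scatterer scene
#'
#' Scatterer count is Poisson with mean `density_per_mm2 * area`; positions
#' are uniform in the region and reflectivities zero-mean Gaussian. The same
#' seed always reproduces the identical scene.
#'
#' @param region Numeric length-4: `c(axial_min, axial_max, lateral_min,
#'   lateral_max)` in mm.
#' @param density_per_mm2 Expected scatterers per square millimetre (> 0).
#' @param amplitude_sd Standard deviation of scatterer reflectivity.
#' @param seed Integer seed; the scene is a pure function of the arguments.
#'
#' @return A `scatterer_scene`: fields `axial_mm`, `lateral_mm`,
#'   `amplitude`, `region`, `seed`.
#' @export
make_scatterer_field <- function(region, density_per_mm2, amplitude_sd = 1,
                                 seed = 1L) {
  region <- as.numeric(region)
  if (length(region) != 4 || !all(is.finite(region)))
    stop_invalid("region must be c(axial_min, axial_max, lateral_min, lateral_max)")
  area <- (region[2] - region[1]) * (region[4] - region[3])
  if (area <= 0) stop_invalid("region is empty (non-positive area)")
  if (!is_number(density_per_mm2) || density_per_mm2 <= 0)
    stop_invalid("density_per_mm2 must be > 0")
  if (!is_number(amplitude_sd) || amplitude_sd <= 0)
    stop_invalid("amplitude_sd must be > 0")
  withr::with_seed(as.integer(seed), {
    n <- rpois(1, density_per_mm2 * area)
    z <- runif(n, region[1], region[2])
    x <- runif(n, region[3], region[4])
    a <- rnorm(n, 0, amplitude_sd)
  })
  structure(list(axial_mm = z, lateral_mm = x, amplitude = a,
                 region = region, seed = as.integer(seed)),
            class = "scatterer_scene")
}

#' Construct an RF frame object
#'
#' Wraps a numeric matrix of RF samples (rows = axial samples, columns =
#' lateral lines) with the acquisition metadata needed for sample/mm
#' conversion.
#'
#' @param samples Numeric matrix of RF echo samples.
#' @param center_frequency,sampling_frequency Hz.
#' @param sound_speed m/s.
#' @param pitch Lateral line spacing, mm.
#' @param axial_origin_mm,lateral_origin_mm Physical coordinate of sample
#'   (1, 1).
#' @return An `rf_frame` object.
#' @export
rf_frame <- function(samples, center_frequency = 21e6,
                     sampling_frequency = 4 * center_frequency,
                     sound_speed = 1540, pitch = 0.09,
                     axial_origin_mm = 0, lateral_origin_mm = 0) {
  if (!is.matrix(samples) || !is.numeric(samples) || !all(is.finite(samples)))
    stop_invalid("samples must be a finite numeric matrix")
  structure(list(samples = samples,
                 center_frequency = center_frequency,
                 sampling_frequency = sampling_frequency,
                 sound_speed = sound_speed,
                 pitch = pitch,
                 axial_origin_mm = axial_origin_mm,
                 lateral_origin_mm = lateral_origin_mm),
            class = "rf_frame")
}

as_rf_samples <- function(x) {
  if (inherits(x, "rf_frame")) x$samples
  else if (is.matrix(x)) x
  else stop_invalid("expected an rf_frame or a numeric matrix")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d axial samples x %d lines, f0 = %.1f MHz, fs = %.1f MHz\n",
              nrow(x$samples), ncol(x$samples),
              x$center_frequency / 1e6, x$sampling_frequency / 1e6))
  invisible(x)
}

#' Render an RF frame from a scatterer scene
#'
#' Each scatterer contributes `amplitude * exp(-tau^2 / (2 sigma_t^2)) *
#' cos(2 pi f0 tau) * exp(-(x - x_s)^2 / (2 sigma_x^2))` with two-way delay
#' `tau = 2 (z - z_s) / c`, summed on the sampling grid. The model is linear
#' in the amplitudes. Scatterers outside the rendered extent are silently
#' truncated (only PSF tails falling on the grid contribute).
#'
#' @param scene A `scatterer_scene`.
#' @param psf A `psf_params`.
#' @param n_axial,n_lines Grid size; defaults cover the scene region.
#' @return An `rf_frame`.
#' @export
render_rf_frame <- function(scene, psf, n_axial = NULL, n_lines = NULL) {
  if (!inherits(scene, "scatterer_scene")) stop_invalid("scene must be a scatterer_scene")
  if (!inherits(psf, "psf_params")) stop_invalid("psf must be psf_params")
  dz <- mm_per_sample(psf)
  r <- scene$region
  if (is.null(n_axial)) n_axial <- floor((r[2] - r[1]) / dz) + 1
  if (is.null(n_lines)) n_lines <- floor((r[4] - r[3]) / psf$pitch) + 1
  F <- .render_frame_cpp(scene$axial_mm, scene$lateral_mm, scene$amplitude,
                         r[1], dz, as.integer(n_axial),
                         r[3], psf$pitch, as.integer(n_lines),
                         psf$center_frequency, psf$sound_speed,
                         psf$axial_pulse_sigma, psf$lateral_beam_sigma)
  rf_frame(F, psf$center_frequency, psf$sampling_frequency, psf$sound_speed,
           psf$pitch, axial_origin_mm = r[1], lateral_origin_mm = r[3])
}

#' Move every scatterer by a displacement field
#'
#' Each scatterer is moved by the field evaluated at its own current
#' position; amplitudes are unchanged. Sub-sample motion is therefore exact
#' at the scatterer level (no frame resampling is ever involved).
#'
#' @param scene A `scatterer_scene`.
#' @param displacement_fn Function `(axial_mm, lateral_mm)` returning a list
#'   with components `d_axial_mm` and `d_lateral_mm` (vectorized).
#' @return The warped `scatterer_scene`.
#' @export
warp_scene <- function(scene, displacement_fn) {
  if (!inherits(scene, "scatterer_scene")) stop_invalid("scene must be a scatterer_scene")
  d <- displacement_fn(scene$axial_mm, scene$lateral_mm)
  scene$axial_mm <- scene$axial_mm + d$d_axial_mm
  scene$lateral_mm <- scene$lateral_mm + d$d_lateral_mm
  scene
}

#' Specify an inter-frame motion model
#'
#' Supported kinds:
#' \describe{
#'   \item{`uniform`}{rigid per-frame shift: `axial_mm_per_frame`,
#'     `lateral_mm_per_frame`.}
#'   \item{`linear_axial_gradient`}{axial shift growing linearly with depth:
#'     `base_mm_per_frame + slope_per_mm * (z - z_ref_mm)` per frame.}
#'   \item{`transmural_gradient`}{axial shift rising linearly across the
#'     wall from `epi_total_mm` (total over the whole sequence) at the
#'     epicardium to `endo_total_mm` at the endocardium. The transmural
#'     coordinate is either circular -- give `center = c(axial, lateral)`
#'     and radii `r_inner < r_outer`, `t = (r_outer - rho)/(r_outer -
#'     r_inner)` clamped to `[0, 1]` -- or border-based -- give
#'     `endo_points` / `epi_points` polylines, `t = d_epi/(d_epi +
#'     d_endo)` from the distances to the two borders, the same coordinate
#'     the layer stratification uses. Surrounding tissue follows the
#'     continuous field.}
#' }
#'
#' @param kind One of `"uniform"`, `"linear_axial_gradient"`,
#'   `"transmural_gradient"`.
#' @param n_frames Number of frames in the sequence (>= 2).
#' @param ... Kind-specific parameters, see Details.
#' @return A `motion_model`.
#' @export
motion_model <- function(kind = c("uniform", "linear_axial_gradient",
                                  "transmural_gradient"),
                         n_frames, ...) {
  kind <- match.arg(kind)
  if (!is_number(n_frames) || n_frames < 2)
    stop_invalid("n_frames must be >= 2")
  p <- list(...)
  defaults <- switch(kind,
    uniform = list(axial_mm_per_frame = NULL, lateral_mm_per_frame = 0),
    linear_axial_gradient = list(base_mm_per_frame = 0, slope_per_mm = NULL,
                                 z_ref_mm = 0),
    transmural_gradient = list(center = NULL, r_inner = NULL, r_outer = NULL,
                               endo_points = NULL, epi_points = NULL,
                               epi_total_mm = NULL, endo_total_mm = NULL))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop_invalid("unknown parameters for kind '", kind, "': ",
                 paste(unknown, collapse = ", "))
  prm <- utils::modifyList(defaults, p)
  if (kind == "transmural_gradient") {
    circular <- !is.null(prm$r_inner)
    if (circular) {
      if (is.null(prm$center) || is.null(prm$r_outer) ||
          !(prm$r_inner > 0 && prm$r_outer > prm$r_inner))
        stop_invalid("circular transmural_gradient requires center and 0 < r_inner < r_outer")
    } else {
      if (is.null(prm$endo_points) || is.null(prm$epi_points))
        stop_invalid("transmural_gradient requires either (center, r_inner, r_outer) or (endo_points, epi_points)")
      prm$endo_points <- as_points_df(prm$endo_points, "endo_points")
      prm$epi_points <- as_points_df(prm$epi_points, "epi_points")
    }
    if (is.null(prm$epi_total_mm) || is.null(prm$endo_total_mm))
      stop_invalid("transmural_gradient requires epi_total_mm and endo_total_mm")
    prm <- prm[!vapply(prm, is.null, logical(1))]
  } else {
    missing <- names(prm)[vapply(prm, is.null, logical(1))]
    if (length(missing))
      stop_invalid("missing parameters for kind '", kind, "': ",
                   paste(missing, collapse = ", "))
  }
  structure(list(kind = kind, n_frames = as.integer(n_frames),
                 parameters = prm),
            class = "motion_model")
}

# Per-frame-pair displacement field of a motion model, as a function of
# position. The same analytic field applies to every pair.
motion_field_fn <- function(model) {
  prm <- model$parameters
  switch(model$kind,
    uniform = function(z, x) {
      list(d_axial_mm = rep(prm$axial_mm_per_frame, length(z)),
           d_lateral_mm = rep(prm$lateral_mm_per_frame, length(z)))
    },
    linear_axial_gradient = function(z, x) {
      list(d_axial_mm = prm$base_mm_per_frame +
             prm$slope_per_mm * (z - prm$z_ref_mm),
           d_lateral_mm = rep(0, length(z)))
    },
    transmural_gradient = {
      n_pairs <- model$n_frames - 1L
      if (!is.null(prm$r_inner)) {
        function(z, x) {
          rho <- sqrt((z - prm$center[1])^2 + (x - prm$center[2])^2)
          t <- pmin(pmax((prm$r_outer - rho) / (prm$r_outer - prm$r_inner), 0), 1)
          total <- prm$epi_total_mm + (prm$endo_total_mm - prm$epi_total_mm) * t
          list(d_axial_mm = total / n_pairs, d_lateral_mm = rep(0, length(z)))
        }
      } else {
        function(z, x) {
          d_en <- .polyline_mindist_cpp(x, z, prm$endo_points$lateral_mm,
                                        prm$endo_points$axial_mm)
          d_ep <- .polyline_mindist_cpp(x, z, prm$epi_points$lateral_mm,
                                        prm$epi_points$axial_mm)
          t <- d_ep / (d_ep + d_en)
          total <- prm$epi_total_mm + (prm$endo_total_mm - prm$epi_total_mm) * t
          list(d_axial_mm = total / n_pairs, d_lateral_mm = rep(0, length(z)))
        }
      }
    })
}

#' Generate an RF frame sequence with exact ground truth
#'
#' Renders `n_frames` frames from successively warped copies of the scene.
#' The returned ground truth exposes the analytic inter-frame displacement
#' field for every successive pair and the cumulative field (sum of the
#' incremental fields), both evaluable at any (axial, lateral) position.
#'
#' @param scene A `scatterer_scene`.
#' @param psf A `psf_params`.
#' @param model A `motion_model`.
#' @param n_axial,n_lines Optional fixed grid size passed to
#'   [render_rf_frame()].
#' @return A list with `frames` (list of `rf_frame`) and `truth`
#'   (`ground_truth` with functions `incremental(pair)` and
#'   `cumulative(n_pairs)`).
#' @export
generate_sequence <- function(scene, psf, model, n_axial = NULL,
                              n_lines = NULL) {
  if (!inherits(model, "motion_model")) stop_invalid("model must be a motion_model")
  fld <- motion_field_fn(model)
  n_pairs <- model$n_frames - 1L
  d0 <- fld(scene$axial_mm, scene$lateral_mm)
  r <- scene$region
  max_total_ax <- max(abs(d0$d_axial_mm)) * n_pairs
  max_total_lat <- max(abs(d0$d_lateral_mm)) * n_pairs
  if (max_total_ax > (r[2] - r[1]) || max_total_lat > (r[4] - r[3]))
    stop_invalid("cumulative displacement exceeds the scene region")
  frames <- vector("list", model$n_frames)
  frames[[1]] <- render_rf_frame(scene, psf, n_axial, n_lines)
  cur <- scene
  for (k in seq_len(n_pairs)) {
    cur <- warp_scene(cur, fld)
    frames[[k + 1]] <- render_rf_frame(cur, psf,
                                       nrow(frames[[1]]$samples),
                                       ncol(frames[[1]]$samples))
  }
  truth <- structure(
    list(model = model,
         n_frames = model$n_frames,
         incremental = function(pair = 1L) {
           if (pair < 1 || pair > n_pairs) stop_invalid("pair out of range")
           fld
         },
         cumulative = function(n = n_pairs) {
           if (n < 1 || n > n_pairs) stop_invalid("pair count out of range")
           function(z, x) {
             d <- fld(z, x)
             list(d_axial_mm = d$d_axial_mm * n,
                  d_lateral_mm = d$d_lateral_mm * n)
           }
         }),
    class = "ground_truth")
  list(frames = frames, truth = truth)
}

#' Build a half-annulus left-ventricle phantom (long-axis topology)
#'
#' Two concentric half-ellipses open at the base, apex at maximal depth:
#' border key points run basal-anterior end -> apex -> basal-posterior end,
#' with the first and last point of each border on the basal line. The
#' myocardial annulus between them is filled with random scatterers;
#' optionally the whole region is filled so that the wall is embedded in
#' speckle-generating tissue.
#'
#' @param inner_axes,outer_axes Numeric length-2 semi-axes
#'   `c(lateral, axial)` in mm of the endocardial and epicardial
#'   half-ellipses; inner must be strictly smaller componentwise.
#' @param center `c(axial_mm, lateral_mm)` of the basal mid-point (the
#'   common ellipse center on the basal line).
#' @param n_border_points Key points per border.
#' @param density_per_mm2 Scatterer density.
#' @param amplitude_sd Scatterer reflectivity standard deviation.
#' @param seed Integer seed.
#' @param background Fill the full rectangular region with scatterers
#'   (`TRUE`) or only the myocardial annulus (`FALSE`, default).
#' @param region_pad Margin in mm added around the outer ellipse.
#' @return A list: `endo_keypoints`, `epi_keypoints` (data frames with
#'   `axial_mm`, `lateral_mm`), `scene`, dense analytic `endo_border` /
#'   `epi_border` polylines, plus the phantom geometry.
#' @export
make_lv_phantom <- function(inner_axes, outer_axes, center = c(1, 0),
                            n_border_points = 13, density_per_mm2 = 200,
                            amplitude_sd = 1, seed = 1L,
                            background = FALSE, region_pad = 1) {
  inner_axes <- as.numeric(inner_axes); outer_axes <- as.numeric(outer_axes)
  if (length(inner_axes) != 2 || length(outer_axes) != 2 ||
      any(!is.finite(c(inner_axes, outer_axes))) ||
      any(inner_axes <= 0) || any(inner_axes >= outer_axes))
    stop_invalid("require 0 < inner_axes < outer_axes componentwise")
  z0 <- center[1]; x0 <- center[2]
  phi <- seq(0, pi, length.out = n_border_points)
  kp <- function(a, b) data.frame(axial_mm = z0 + b * sin(phi),
                                  lateral_mm = x0 - a * cos(phi))
  endo <- kp(inner_axes[1], inner_axes[2])
  epi <- kp(outer_axes[1], outer_axes[2])
  region <- c(z0 - region_pad, z0 + outer_axes[2] + region_pad,
              x0 - outer_axes[1] - region_pad, x0 + outer_axes[1] + region_pad)
  in_half_ellipse <- function(z, x, a, b)
    z >= z0 & ((x - x0) / a)^2 + ((z - z0) / b)^2 <= 1
  if (background) {
    scene <- make_scatterer_field(region, density_per_mm2, amplitude_sd, seed)
  } else {
    area <- (pi / 2) * (outer_axes[1] * outer_axes[2] -
                        inner_axes[1] * inner_axes[2])
    withr::with_seed(as.integer(seed), {
      n <- rpois(1, density_per_mm2 * area)
      z <- numeric(0); x <- numeric(0)
      while (length(z) < n) {
        m <- max(4 * (n - length(z)), 100)
        zc <- runif(m, z0, z0 + outer_axes[2])
        xc <- runif(m, x0 - outer_axes[1], x0 + outer_axes[1])
        keep <- in_half_ellipse(zc, xc, outer_axes[1], outer_axes[2]) &
          !in_half_ellipse(zc, xc, inner_axes[1], inner_axes[2])
        z <- c(z, zc[keep]); x <- c(x, xc[keep])
      }
      z <- z[seq_len(n)]; x <- x[seq_len(n)]
      a <- rnorm(n, 0, amplitude_sd)
    })
    scene <- structure(list(axial_mm = z, lateral_mm = x, amplitude = a,
                            region = region, seed = as.integer(seed)),
                       class = "scatterer_scene")
  }
  phi_dense <- seq(0, pi, length.out = 361)
  dense <- function(a, b) data.frame(axial_mm = z0 + b * sin(phi_dense),
                                     lateral_mm = x0 - a * cos(phi_dense))
  list(endo_keypoints = endo, epi_keypoints = epi, scene = scene,
       endo_border = dense(inner_axes[1], inner_axes[2]),
       epi_border = dense(outer_axes[1], outer_axes[2]),
       center = center, inner_axes = inner_axes, outer_axes = outer_axes,
       region = region)
}
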