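# Synthetic OCT cohort generation.
#
# Class-conditional texture is modelled as a stationary Gaussian random
# field: white noise smoothed with a separable anisotropic Gaussian kernel,
# renormalised to unit marginal variance, then scaled by noise_sd and a
# per-class contrast gain and shifted by a base intensity. Anisotropy
# (correlation_length_x vs _y) drives the directional wavelet subbands and
# the direction-supremum GLCM features; contrast_gain drives amplitude
# metrics. Layer surfaces are smooth parallel sheets with a radial foveal
# depression shared between layers.

#' Class-conditional texture parameters
#'
#' Describes the texture of the six inner retinal layers for one diagnostic
#' class. Each field is recycled across layers when given as a scalar.
#'
#' @param class_label One of `"HC"`, `"AD"`, `"PD"`.
#' @param base_intensity Mean grey value per layer (arbitrary grey units).
#' @param noise_sd Marginal standard deviation of the fluctuation field
#'   (grey units); must be >= 0.
#' @param correlation_length_x,correlation_length_y Gaussian correlation
#'   lengths of the field along the temporal-nasal (x) and
#'   superior-inferior (y) axes, in en-face pixels; must be > 0.
#' @param contrast_gain Dimensionless multiplier on the fluctuation
#'   amplitude.
#' @return An object of class `class_texture_params`.
#' @export
class_texture_params <- function(class_label,
                                 base_intensity = 120,
                                 noise_sd = 12,
                                 correlation_length_x = 3,
                                 correlation_length_y = 3,
                                 contrast_gain = 1) {
  class_label <- match.arg(class_label, diagnostic_classes())
  layers <- retinal_layers()
  rec <- function(v, what) {
    if (!length(v) %in% c(1L, length(layers)))
      stop(what, " must have length 1 or ", length(layers))
    setNames(rep_len(as.numeric(v), length(layers)), layers)
  }
  p <- list(
    class_label = class_label,
    base_intensity = rec(base_intensity, "base_intensity"),
    noise_sd = rec(noise_sd, "noise_sd"),
    correlation_length_x = rec(correlation_length_x, "correlation_length_x"),
    correlation_length_y = rec(correlation_length_y, "correlation_length_y"),
    contrast_gain = rec(contrast_gain, "contrast_gain")
  )
  if (any(p$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(p$correlation_length_x <= 0) || any(p$correlation_length_y <= 0))
    stop("correlation lengths must be > 0")
  structure(p, class = "class_texture_params")
}

#' Default class texture parameter sets
#'
#' `default_class_params()` returns the standard three-class study
#' conditions: HC is isotropic at unit contrast; AD is horizontally
#' elongated (longer x-correlation) with raised contrast; PD is vertically
#' elongated with reduced contrast. `null_class_params()` gives all three
#' classes identical (HC) texture, for null-calibration experiments.
#'
#' @return A named list of three [class_texture_params()] objects.
#' @export
default_class_params <- function() {
  list(
    HC = class_texture_params("HC", base_intensity = 120, noise_sd = 12,
                              correlation_length_x = 3, correlation_length_y = 3,
                              contrast_gain = 1.0),
    AD = class_texture_params("AD", base_intensity = 125, noise_sd = 12,
                              correlation_length_x = 6, correlation_length_y = 2,
                              contrast_gain = 1.6),
    PD = class_texture_params("PD", base_intensity = 115, noise_sd = 12,
                              correlation_length_x = 2, correlation_length_y = 6,
                              contrast_gain = 0.7)
  )
}

#' @rdname default_class_params
#' @export
null_class_params <- function() {
  base <- default_class_params()$HC
  out <- lapply(diagnostic_classes(), function(cl) {
    p <- base
    p$class_label <- cl
    p
  })
  setNames(out, diagnostic_classes())
}

#' Synthetic cohort configuration
#'
#' @param n_subjects_per_class Number of subjects per diagnostic class
#'   (each contributes two eyes).
#' @param grid Integer vector `(n_ascans_x, n_bscans_y, n_depth)` voxels.
#'   The default mirrors a 512x128 macular cube with 128 depth samples.
#' @param voxel_scale Micrometres per voxel along x, y, z. The default
#'   approximates a 6x6 mm macular cube.
#' @param foveal_pit_depth Depth of the central foveal depression, µm.
#' @param within_subject_correlation Fraction in \[0,1\] of each layer's
#'   texture field shared between a subject's two eyes.
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_class = 20,
                          grid = c(512L, 128L, 128L),
                          voxel_scale = c(11.72, 46.88, 3.9),
                          foveal_pit_depth = 100,
                          within_subject_correlation = 0.5,
                          seed = 1L) {
  stopifnot(n_subjects_per_class >= 1,
            length(grid) == 3, all(grid >= 1),
            length(voxel_scale) == 3, all(voxel_scale > 0),
            foveal_pit_depth >= 0)
  if (within_subject_correlation < 0 || within_subject_correlation > 1)
    stop("within_subject_correlation must lie in [0, 1]")
  structure(list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    grid = as.integer(grid),
    voxel_scale = as.numeric(voxel_scale),
    foveal_pit_depth = as.numeric(foveal_pit_depth),
    within_subject_correlation = as.numeric(within_subject_correlation),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Separable Gaussian smoothing with edge-replicated (symmetric) padding.
gaussian_kernel <- function(sigma) {
  m <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-m:m)^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_separable <- function(M, sigma_x, sigma_y) {
  conv_axis <- function(A, k) {
    # convolve along rows (first dim) with symmetric extension
    m <- (length(k) - 1L) / 2L
    n <- nrow(A)
    idx <- c(pmin(m:1, n), 1:n, pmax(n - (1:m) + 1L, 1L))
    Ap <- A[idx, , drop = FALSE]
    K <- matrix(0, n, n + 2L * m)
    for (t in seq_along(k)) {
      K[cbind(1:n, (1:n) + t - 1L)] <- k[t]
    }
    K %*% Ap
  }
  M <- conv_axis(M, gaussian_kernel(sigma_x))
  t(conv_axis(t(M), gaussian_kernel(sigma_y)))
}

# Standardised correlated field (mean 0, sd 1) of a given shape.
standard_field <- function(shape, clx, cly, seed) {
  raw <- with_substream(seed, matrix(rnorm(prod(shape)), shape[1], shape[2]))
  f <- smooth_separable(raw, clx, cly)
  (f - mean(f)) / sd(as.vector(f))
}

#' Generate one layer's texture field
#'
#' Correlated Gaussian random field with the class's correlation lengths,
#' returned as `base_intensity + contrast_gain * noise_sd * field` where
#' `field` has unit marginal variance. Deterministic given `seed`.
#'
#' @param params A [class_texture_params()] object.
#' @param layer Layer name, one of [retinal_layers()].
#' @param shape Integer vector `(nx, ny)`.
#' @param seed Integer sub-stream seed.
#' @return A numeric `nx x ny` matrix of grey values.
#' @export
generate_layer_texture <- function(params, layer, shape, seed) {
  stopifnot(inherits(params, "class_texture_params"),
            length(shape) == 2, all(shape >= 1))
  layer <- match.arg(layer, retinal_layers())
  clx <- params$correlation_length_x[[layer]]
  cly <- params$correlation_length_y[[layer]]
  if (clx <= 0 || cly <= 0) stop("correlation lengths must be > 0")
  base <- params$base_intensity[[layer]]
  amp <- params$contrast_gain[[layer]] * params$noise_sd[[layer]]
  if (amp == 0) return(matrix(base, shape[1], shape[2]))
  base + amp * standard_field(shape, clx, cly, seed)
}

# Baseline layer thicknesses (µm), ILM downwards: the six inner layers then
# the ONL-bottom-to-RPE-top outer band. Chosen to give a plausible total
# macular thickness around 280 µm.
base_layer_thickness <- function() {
  c(RNFL = 30, GCL = 35, IPL = 32, INL = 32, OPL = 28, ONL = 75, OUTER = 50)
}

# Fraction of the foveal depression carried by each of the 8 boundaries
# (ILM full, fading to zero at the outer boundaries): inner layers thin
# towards the foveal centre, as in real maculae.
pit_weights <- function() c(1, 0.75, 0.5, 0.3, 0.15, 0.05, 0, 0)

#' Generate layer boundary surfaces
#'
#' Smooth, strictly ordered boundary depth maps over the en-face grid with
#' a radially symmetric Gaussian foveal depression of depth
#' `foveal_pit_depth` at the grid centre. With `foveal_pit_depth = 0` the
#' surfaces are flat and parallel.
#'
#' @param config A [cohort_config()].
#' @param thickness_scale Optional positive multipliers (length 7, one per
#'   layer band) letting cohorts vary total thickness between subjects.
#' @return A [layer_surfaces()] object (depths in µm).
#' @export
generate_surfaces <- function(config, thickness_scale = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  nx <- config$grid[1]; ny <- config$grid[2]
  th <- base_layer_thickness()
  if (!is.null(thickness_scale)) {
    stopifnot(length(thickness_scale) == length(th), all(thickness_scale > 0))
    th <- th * thickness_scale
  }
  base_depth <- 100 + c(0, cumsum(th))  # 8 boundary depths, µm
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  dx <- (seq_len(nx) - cx) * config$voxel_scale[1]
  dy <- (seq_len(ny) - cy) * config$voxel_scale[2]
  r2 <- outer(dx^2, dy^2, "+")
  pit_sigma <- 400  # µm; depression mostly inside the central subfield
  pit <- config$foveal_pit_depth * exp(-r2 / (2 * pit_sigma^2))
  w <- pit_weights()
  depths <- array(0, dim = c(nx, ny, 8L),
                  dimnames = list(NULL, NULL, surface_names()))
  # build downwards from the ILM so each layer's foveal thinning is capped
  # at 85% of its baseline thickness: ordering holds for any pit depth
  depths[, , 1] <- base_depth[1] + w[1] * pit
  for (i in 1:7) {
    thinning <- pmin((w[i] - w[i + 1]) * pit, 0.85 * th[i])
    depths[, , i + 1] <- depths[, , i] + (th[i] - thinning)
  }
  layer_surfaces(depths)
}

# Build an eye's intensity volume from per-layer en-face fields + surfaces.
# Voxel k covers depth [(k-1)*dz, k*dz); its value is the field of the layer
# containing the voxel start. Vitreous / outer-segment band / sub-RPE get
# fixed grey values.
assemble_volume <- function(fields, surfaces, config, laterality) {
  nx <- config$grid[1]; ny <- config$grid[2]; nz <- config$grid[3]
  dz <- config$voxel_scale[3]
  d <- surfaces$depths
  vol <- array(30, dim = c(nx, ny, nz))  # vitreous background
  zstart <- (seq_len(nz) - 1L) * dz
  bands <- c(retinal_layers(), "OUTER")
  band_field <- c(fields, list(OUTER = matrix(150, nx, ny)))
  for (b in seq_along(bands)) {
    upper <- d[, , b]; lower <- d[, , b + 1L]
    for (k in seq_len(nz)) {
      m <- zstart[k] >= upper & zstart[k] < lower
      if (any(m)) {
        slice <- vol[, , k]
        slice[m] <- band_field[[b]][m]
        vol[, , k] <- slice
      }
    }
  }
  below <- d[, , 8L]
  for (k in seq_len(nz)) {
    m <- zstart[k] >= below
    if (any(m)) { slice <- vol[, , k]; slice[m] <- 60; vol[, , k] <- slice }
  }
  oct_volume(vol, config$voxel_scale, laterality)
}

# Per-layer en-face texture fields for one eye, in right-eye orientation.
eye_fields <- function(config, params, subject_idx, eye) {
  shape <- config$grid[1:2]
  rho <- config$within_subject_correlation
  out <- list()
  for (layer in retinal_layers()) {
    shared_seed <- substream_seed(config$seed, "field", subject_idx, "shared", layer)
    own_seed <- substream_seed(config$seed, "field", subject_idx, eye, layer)
    clx <- params$correlation_length_x[[layer]]
    cly <- params$correlation_length_y[[layer]]
    base <- params$base_intensity[[layer]]
    amp <- params$contrast_gain[[layer]] * params$noise_sd[[layer]]
    if (amp == 0) {
      out[[layer]] <- matrix(base, shape[1], shape[2])
      next
    }
    f <- sqrt(rho) * standard_field(shape, clx, cly, shared_seed)
    if (rho < 1)
      f <- f + sqrt(1 - rho) * standard_field(shape, clx, cly, own_seed)
    out[[layer]] <- base + amp * f
  }
  out
}

# Generate one eye record. Left eyes are the horizontal mirror (reversed x)
# of the same right-oriented fields and surfaces.
generate_eye <- function(config, params, subject_id, subject_idx, laterality) {
  fields <- eye_fields(config, params, subject_idx, laterality)
  tsc_seed <- substream_seed(config$seed, "thickness", subject_idx)
  tsc <- with_substream(tsc_seed,
                        pmax(0.7, 1 + rnorm(length(base_layer_thickness()), 0, 0.04)))
  surfaces <- generate_surfaces(config, thickness_scale = tsc)
  if (laterality == "left") {
    fields <- lapply(fields, function(f) f[rev(seq_len(nrow(f))), , drop = FALSE])
    surfaces <- layer_surfaces(surfaces$depths[rev(seq_len(config$grid[1])), , ,
                                               drop = FALSE])
  }
  vol <- assemble_volume(fields, surfaces, config, laterality)
  structure(list(subject_id = subject_id,
                 laterality = laterality,
                 class_label = params$class_label,
                 volume = vol,
                 surfaces = surfaces),
            class = "eye_record")
}

#' Generate a synthetic OCT cohort
#'
#' For each subject, two eyes are produced. The left eye's texture fields
#' and surfaces are the horizontal mirror of right-eye orientation, and a
#' fraction `within_subject_correlation` of each layer's texture field is
#' shared between the two eyes. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param params Named list of [class_texture_params()], one per class
#'   (default [default_class_params()]).
#' @return A list of `eye_record` objects
#'   (`2 * 3 * n_subjects_per_class` of them).
#' @export
generate_cohort <- function(config, params = default_class_params()) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- diagnostic_classes()
  stopifnot(all(classes %in% names(params)))
  records <- list()
  idx <- 0L
  for (cl in classes) {
    for (s in seq_len(config$n_subjects_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", cl, s)
      for (lat in c("right", "left")) {
        records[[length(records) + 1L]] <-
          generate_eye(config, params[[cl]], sid, idx, lat)
      }
    }
  }
  records
}

#' Cohort manifest table
#'
#' @param cohort A list of eye records from [generate_cohort()].
#' @return A data.frame with one row per eye: subject_id, laterality,
#'   class_label.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    laterality = vapply(cohort, `[[`, "", "laterality"),
    class_label = vapply(cohort, `[[`, "", "class_label"),
    stringsAsFactors = FALSE
  )
}
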