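# Feature extraction: quantization and the 86-feature vector per
# (eye, layer).

#' Downsample and quantize an MVF image
#'
#' Local-mean downsampling to `size x size` pixels followed by a linear
#' min-max mapping of the image's own intensity range onto `levels`
#' equal-width bins (a constant image maps to level 0). Per-image scaling
#' removes global brightness differences between eyes and devices.
#'
#' @param image An [mvf_image()] (laterality-normalised) or numeric
#'   matrix.
#' @param size Output side length (default 128).
#' @param levels Number of grey levels (default 16).
#' @return A `quantized_image`: `$values` is an integer `size x size`
#'   matrix in `0..levels-1`.
#' @export
downsample_quantize <- function(image, size = 128L, levels = 16L) {
  X <- if (inherits(image, "mvf_image")) {
    if (!image$normalised) stop("MVF image must be laterality-normalised first")
    image$values
  } else {
    stopifnot(is.matrix(image))
    image
  }
  if (!all(is.finite(X))) stop("image values must be finite")
  X <- resample_mean(X, size)
  rng <- range(X)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((X - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  } else {
    matrix(0L, size, size)
  }
  structure(list(values = matrix(as.integer(q), size, size),
                 levels = as.integer(levels),
                 source_dim = dim(X)),
            class = "quantized_image")
}

# Area-style local-mean resampling of both axes to `size`. Output bin o
# averages input indices floor((o-1)*n/size)+1 .. floor(o*n/size) (at
# least one index when upsampling).
resample_mean <- function(X, size) {
  bin_matrix <- function(n) {
    G <- matrix(0, size, n)
    for (o in seq_len(size)) {
      lo <- floor((o - 1) * n / size) + 1
      hi <- max(lo, floor(o * n / size))
      G[o, lo:hi] <- 1 / (hi - lo + 1)
    }
    G
  }
  Gx <- bin_matrix(nrow(X)); Gy <- bin_matrix(ncol(X))
  Gx %*% X %*% t(Gy)
}

#' Extract the 86-feature texture vector for one layer image
#'
#' Concatenates the 80 quadrant-aggregated GLCM features
#' ([downsample_quantize()] -> [block_features()] ->
#' [aggregate_quadrants()]) with the 6 global DTCWT directional variances
#' ([dtcwt_features()]).
#'
#' @param image A laterality-normalised [mvf_image()].
#' @param size,levels Quantization parameters (see
#'   [downsample_quantize()]).
#' @return A `feature_vector`: named numeric of length 86 with `origin`
#'   (quadrant name or `"global"`) and `layer` attributes.
#' @export
extract_features <- function(image, size = 128L, levels = 16L) {
  stopifnot(inherits(image, "mvf_image"))
  if (!image$normalised) stop("MVF image must be laterality-normalised first")
  loc <- aggregate_quadrants(block_features(downsample_quantize(image, size, levels)))
  glob <- dtcwt_features(image)
  out <- c(unclass(loc), glob)
  attr(out, "origin") <- c(attr(loc, "origin"), rep("global", length(glob)))
  attr(out, "layer") <- image$layer
  class(out) <- "feature_vector"
  out
}

#' Feature name manifest
#'
#' @return A data.frame over the 86 feature names: `name`, `origin`
#'   (quadrant or `"global"`), `metric` and `quadrant` (NA for global
#'   features).
#' @export
feature_manifest <- function() {
  qn <- names(quadrant_blocks())
  loc <- expand.grid(metric = glcm_metric_names(), quadrant = qn,
                     stringsAsFactors = FALSE)[, 2:1]
  loc <- loc[order(match(loc$quadrant, qn)), ]
  glob_names <- paste0("G_var_", c("p15", "p45", "p75", "m75", "m45", "m15"))
  data.frame(
    name = c(paste(loc$quadrant, loc$metric, sep = "_"), glob_names),
    origin = c(quadrant_origins()[loc$quadrant], rep("global", 6)),
    metric = c(loc$metric, rep("dtcwt_variance", 6)),
    quadrant = c(loc$quadrant, rep(NA_character_, 6)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Feature table for a cohort
#'
#' Computes MVF images, normalises orientation, and extracts the
#' 86-feature vector for every (eye, layer) pair of a cohort.
#'
#' @param cohort List of eye records ([generate_cohort()]).
#' @param layers Layers to analyse (default all six).
#' @param size,levels Quantization parameters.
#' @return A data.frame with identifier columns (`subject_id`, `eye`,
#'   `class_label`, `layer`) followed by the 86 feature columns.
#' @export
cohort_features <- function(cohort, layers = retinal_layers(),
                            size = 128L, levels = 16L) {
  rows <- vector("list", length(cohort) * length(layers))
  n <- 0L
  for (rec in cohort) {
    cs <- depth_cumsum(rec$volume)
    for (layer in layers) {
      mvf <- compute_mvf(rec$volume, rec$surfaces, layer, .depth_cumsum = cs)
      fv <- extract_features(normalise_orientation(mvf), size, levels)
      n <- n + 1L
      rows[[n]] <- data.frame(
        subject_id = rec$subject_id, eye = rec$laterality,
        class_label = rec$class_label, layer = layer,
        as.list(unclass(fv)[seq_along(unclass(fv))]),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
  }
  do.call(rbind, rows[seq_len(n)])
}
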