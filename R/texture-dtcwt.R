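# Global texture: level-1 dual-tree complex wavelet transform and the
# variances of the six directional subband magnitudes.
#
# At decomposition level one the dual tree is realised with a single
# odd-length linear-phase biorthogonal filter pair; the two trees differ
# by a one-sample delay obtained from the polyphase components of the
# filtered image, which the quad-to-complex step combines into six
# approximately analytic, directionally selective complex subbands
# (+-15, +-45, +-75 degrees). The analysis pair used here is the CDF 9/7
# (Antonini) biorthogonal pair.

# CDF 9/7 analysis lowpass (9 taps) and highpass (7 taps), zero-phase.
dtcwt_h0 <- function() {
  c(0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
    0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
    -0.11062440441843718, -0.023849465019556843, 0.03782845550726404)
}

dtcwt_h1 <- function() {
  c(-0.06453888262869706, 0.04068941760916406, 0.41809227322161724,
    -0.7884856164055829, 0.41809227322161724, 0.04068941760916406,
    -0.06453888262869706)
}

# Filter the rows (first dimension) with symmetric (edge-repeated)
# extension; output has the input size.
conv_sym <- function(M, h) {
  m <- (length(h) - 1L) / 2L
  n <- nrow(M)
  idx <- c(pmin(m:1, n), seq_len(n), pmax(n - seq_len(m) + 1L, 1L))
  Mp <- M[idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * m)
  for (t in seq_along(h)) K[cbind(seq_len(n), seq_len(n) + t - 1L)] <- h[t]
  K %*% Mp
}

# Quad-to-complex: combine the four polyphase samples of a real highpass
# subband into the two complex subbands of opposite orientation.
q2c <- function(Y) {
  a <- Y[seq(1, nrow(Y), 2), seq(1, ncol(Y), 2), drop = FALSE]
  b <- Y[seq(1, nrow(Y), 2), seq(2, ncol(Y), 2), drop = FALSE]
  cc <- Y[seq(2, nrow(Y), 2), seq(1, ncol(Y), 2), drop = FALSE]
  d <- Y[seq(2, nrow(Y), 2), seq(2, ncol(Y), 2), drop = FALSE]
  s <- sqrt(0.5)
  p <- (a + 1i * b) * s
  q <- (d - 1i * cc) * s
  list(p - q, p + q)
}

#' Level-1 dual-tree complex wavelet subbands
#'
#' One-level decomposition of a real image (even dimensions required)
#' into six directionally selective complex subbands, ordered
#' `(+15, +45, +75, -75, -45, -15)` degrees.
#'
#' @param X Numeric matrix with even numbers of rows and columns.
#' @return Named list of six complex matrices
#'   (`p15, p45, p75, m75, m45, m15`).
#' @export
dtcwt_level1 <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) %% 2 != 0 || ncol(X) %% 2 != 0)
    stop("image dimensions must be even")
  if (nrow(X) < 8 || ncol(X) < 8)
    stop("image too small for one decomposition level")
  h0 <- dtcwt_h0(); h1 <- dtcwt_h1()
  Lo <- conv_sym(X, h0); Hi <- conv_sym(X, h1)
  LH <- t(conv_sym(t(Hi), h0))  # highpass along x only
  HL <- t(conv_sym(t(Lo), h1))  # highpass along y only
  HH <- t(conv_sym(t(Hi), h1))  # highpass along both
  z15 <- q2c(LH); z75 <- q2c(HL); z45 <- q2c(HH)
  list(p15 = z15[[1]], p45 = z45[[1]], p75 = z75[[1]],
       m75 = z75[[2]], m45 = z45[[2]], m15 = z15[[2]])
}

#' Six DTCWT directional-variance features
#'
#' Variance (population, 1/N) of the magnitudes of the complex
#' coefficients in each of the six level-1 directional subbands. Constant
#' images give six zeros; an additive constant offset leaves the features
#' unchanged.
#'
#' @param image An [mvf_image()] (laterality-normalised) or a plain
#'   numeric matrix. Odd dimensions are padded by edge replication.
#' @return Named numeric vector of 6 features
#'   (`G_var_p15 ... G_var_m15`).
#' @export
dtcwt_features <- function(image) {
  X <- if (inherits(image, "mvf_image")) {
    if (!image$normalised) stop("MVF image must be laterality-normalised first")
    image$values
  } else {
    stopifnot(is.matrix(image))
    image
  }
  if (!all(is.finite(X))) stop("image values must be finite")
  if (nrow(X) %% 2 != 0) X <- rbind(X, X[nrow(X), ])
  if (ncol(X) %% 2 != 0) X <- cbind(X, X[, ncol(X)])
  z <- dtcwt_level1(X)
  pvar <- function(v) mean(v^2) - mean(v)^2
  out <- vapply(z, function(zz) pvar(Mod(zz)), 0)
  names(out) <- paste0("G_var_", names(z))
  out
}
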