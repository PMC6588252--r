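# Local texture: grey-level co-occurrence matrices over a 7x7 block grid,
# 20 metrics per block (supremum over four directions), aggregated into
# four macular quadrant features.

#' Names of the 20 GLCM metrics
#'
#' The extended-Haralick set used for every co-occurrence matrix:
#' autocorrelation, contrast, correlation, cluster prominence, cluster
#' shade, dissimilarity, energy, entropy, homogeneity, maximum
#' probability, variance (sum of squares), sum average, sum variance, sum
#' entropy, difference variance, difference entropy, the two informational
#' measures of correlation (IMC1, IMC2), inverse difference normalised and
#' inverse difference moment normalised. Entropies are in bits (log2);
#' IMC2 uses natural-log entropies internally (its classical form).
#'
#' @return Character vector of length 20.
#' @export
glcm_metric_names <- function() {
  c("autocorrelation", "contrast", "correlation", "cluster_prominence",
    "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
    "maximum_probability", "variance", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2", "idn", "idmn")
}

# Pixel offsets of the four co-occurrence directions in the (x, y) en-face
# plane at unit distance. 0 deg runs along the temporal-nasal x axis.
glcm_offsets <- function() {
  list(`0` = c(1L, 0L), `45` = c(1L, 1L), `90` = c(0L, 1L), `135` = c(-1L, 1L))
}

resolve_offset <- function(direction) {
  offs <- glcm_offsets()
  if (is.character(direction) || (is.numeric(direction) && length(direction) == 1)) {
    key <- as.character(direction)
    if (!key %in% names(offs)) stop("unknown direction: ", key)
    return(offs[[key]])
  }
  if (is.numeric(direction) && length(direction) == 2) return(as.integer(direction))
  stop("direction must be an angle (0, 45, 90, 135) or a length-2 offset")
}

#' Grey-level co-occurrence matrix of a block
#'
#' Symmetric, normalised (entries sum to 1) co-occurrence matrix of the
#' integer block at unit distance in the given direction.
#'
#' @param block Integer matrix with values in `0..levels-1`, indexed
#'   `[x, y]`.
#' @param direction Angle in degrees (0, 45, 90, 135) or a length-2
#'   `(dx, dy)` offset.
#' @param levels Number of grey levels (default 16).
#' @return A `levels x levels` matrix summing to 1.
#' @export
glcm <- function(block, direction, levels = 16L) {
  stopifnot(is.matrix(block))
  if (any(block < 0) || any(block >= levels))
    stop("block values must lie in 0..levels-1")
  off <- resolve_offset(direction)
  dx <- off[1]; dy <- off[2]
  nr <- nrow(block); nc <- ncol(block)
  xs <- seq(max(1L, 1L - dx), min(nr, nr - dx))
  ys <- seq(max(1L, 1L - dy), min(nc, nc - dy))
  if (length(xs) < 1 || length(ys) < 1 || (nr - abs(dx)) < 1 || (nc - abs(dy)) < 1)
    stop("block too small for the requested offset")
  i <- block[xs, ys, drop = FALSE]
  j <- block[xs + dx, ys + dy, drop = FALSE]
  code <- c(as.integer(j) * levels + as.integer(i) + 1L,
            as.integer(i) * levels + as.integer(j) + 1L)
  counts <- tabulate(code, nbins = levels * levels)
  matrix(counts / sum(counts), levels, levels)
}

# Vectorised metric computation for m normalised GLCMs stacked as an
# m x levels^2 matrix (column-major cell order). Returns an m x 20 matrix.
glcm_metrics_multi <- function(P, levels = 16L) {
  L <- levels
  m <- nrow(P)
  iv <- rep(seq_len(L), times = L)   # row index of each cell
  jv <- rep(seq_len(L), each = L)    # column index
  # marginals
  Ii <- matrix(0, L * L, L); Ii[cbind(seq_len(L * L), iv)] <- 1
  px <- P %*% Ii
  lv <- seq_len(L)
  mu <- as.vector(px %*% lv)
  sig2 <- as.vector(px %*% lv^2) - mu^2
  # sum and difference distributions
  sval <- 2:(2 * L)
  Si <- matrix(0, L * L, length(sval)); Si[cbind(seq_len(L * L), iv + jv - 1L)] <- 1
  ps <- P %*% Si
  dval <- 0:(L - 1)
  Di <- matrix(0, L * L, L); Di[cbind(seq_len(L * L), abs(iv - jv) + 1L)] <- 1
  pd <- P %*% Di
  ent <- function(M, base = 2) {
    T <- M * log(M, base = base); T[M <= 0] <- 0
    -rowSums(T)
  }
  autocorrelation <- as.vector(P %*% (iv * jv))
  contrast <- as.vector(P %*% (iv - jv)^2)
  correlation <- ifelse(sig2 > 1e-12, (autocorrelation - mu^2) / sig2, 0)
  Sv <- matrix(sval, m, length(sval), byrow = TRUE) - 2 * mu
  cluster_prominence <- rowSums(ps * Sv^4)
  cluster_shade <- rowSums(ps * Sv^3)
  dissimilarity <- as.vector(P %*% abs(iv - jv))
  energy <- rowSums(P^2)
  entropy <- ent(P)
  homogeneity <- as.vector(P %*% (1 / (1 + (iv - jv)^2)))
  maximum_probability <- apply(P, 1, max)
  variance <- sig2
  sum_average <- as.vector(ps %*% sval)
  sum_variance <- rowSums(ps * (matrix(sval, m, length(sval), byrow = TRUE) -
                                  sum_average)^2)
  sum_entropy <- ent(ps)
  difference_variance <- rowSums(pd * (matrix(dval, m, L, byrow = TRUE) -
                                         dissimilarity)^2)
  difference_entropy <- ent(pd)
  PxPy <- px[, iv, drop = FALSE] * px[, jv, drop = FALSE]
  HX <- ent(px)
  T1 <- P * log2(PxPy); T1[P <= 0 | PxPy <= 0] <- 0
  HXY1 <- -rowSums(T1)
  imc1 <- ifelse(HX > 1e-12, (entropy - HXY1) / HX, 0)
  # IMC2 in its classical natural-log form
  HXYn <- ent(P, base = exp(1))
  T2 <- PxPy * log(PxPy); T2[PxPy <= 0] <- 0
  HXY2n <- -rowSums(T2)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2n - HXYn))))
  idn <- as.vector(P %*% (1 / (1 + abs(iv - jv) / L)))
  idmn <- as.vector(P %*% (1 / (1 + (iv - jv)^2 / L^2)))
  out <- cbind(autocorrelation, contrast, correlation, cluster_prominence,
               cluster_shade, dissimilarity, energy, entropy, homogeneity,
               maximum_probability, variance, sum_average, sum_variance,
               sum_entropy, difference_variance, difference_entropy,
               imc1, imc2, idn, idmn)
  colnames(out) <- glcm_metric_names()
  out
}

#' The 20 GLCM metrics of one co-occurrence matrix
#'
#' @param matrix_ A normalised co-occurrence matrix (entries sum to 1).
#' @return Named numeric vector of the 20 metrics (see
#'   [glcm_metric_names()]).
#' @export
glcm_metrics <- function(matrix_) {
  stopifnot(is.matrix(matrix_), nrow(matrix_) == ncol(matrix_))
  if (abs(sum(matrix_) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalised (entries summing to 1)")
  drop(glcm_metrics_multi(matrix(as.vector(matrix_), nrow = 1),
                          levels = nrow(matrix_)))
}

#' Per-block direction-supremum GLCM metrics
#'
#' Splits the quantized image into a 7x7 grid of square blocks (the image
#' is cropped centrally to a multiple of 7 first; 128 -> 126 with 18x18
#' blocks) and computes, for each block and metric, the supremum over the
#' four unit-distance co-occurrence directions.
#'
#' @param qimg A `quantized_image` from [downsample_quantize()].
#' @return A `block_grid` object: `$metrics` is a `7 x 7 x 20` array
#'   indexed `[x_block, y_block, metric]`, `$block_size` the block pixel
#'   extent.
#' @export
block_features <- function(qimg) {
  stopifnot(inherits(qimg, "quantized_image"))
  v <- qimg$values
  L <- qimg$levels
  n <- nrow(v)
  bs <- n %/% 7L
  work <- 7L * bs
  margin <- (n - work) %/% 2L
  v <- v[margin + seq_len(work), margin + seq_len(work), drop = FALSE]
  bx <- (seq_len(work) - 1L) %/% bs + 1L
  bid <- matrix(bx, work, work) + (matrix(bx, work, work, byrow = TRUE) - 1L) * 7L
  sup <- NULL
  for (dir in names(glcm_offsets())) {
    off <- glcm_offsets()[[dir]]
    dx <- off[1]; dy <- off[2]
    xs <- seq(max(1L, 1L - dx), min(work, work - dx))
    ys <- seq(max(1L, 1L - dy), min(work, work - dy))
    i <- v[xs, ys, drop = FALSE]
    j <- v[xs + dx, ys + dy, drop = FALSE]
    b1 <- bid[xs, ys, drop = FALSE]
    b2 <- bid[xs + dx, ys + dy, drop = FALSE]
    keep <- b1 == b2
    ii <- as.integer(i[keep]); jj <- as.integer(j[keep]); bb <- b1[keep]
    cell <- (bb - 1L) * (L * L)
    code <- c(cell + jj * L + ii + 1L, cell + ii * L + jj + 1L)
    counts <- tabulate(code, nbins = 49L * L * L)
    P <- t(matrix(counts, nrow = L * L))
    P <- P / rowSums(P)
    M <- glcm_metrics_multi(P, levels = L)
    sup <- if (is.null(sup)) M else pmax(sup, M)
  }
  metrics <- array(sup, dim = c(7L, 7L, 20L),
                   dimnames = list(NULL, NULL, glcm_metric_names()))
  structure(list(metrics = metrics, block_size = bs, levels = L),
            class = "block_grid")
}

# Quadrant block index sets in the 7x7 grid (right-eye orientation):
# temporal = x blocks 1..3, nasal = 5..7, superior = y blocks 1..3,
# inferior = 5..7; the central row and column (4) through the fovea are
# excluded.
quadrant_blocks <- function() {
  list(ST = list(x = 1:3, y = 1:3), SN = list(x = 5:7, y = 1:3),
       IT = list(x = 1:3, y = 5:7), IN = list(x = 5:7, y = 5:7))
}

quadrant_origins <- function() {
  c(ST = "superior-temporal", SN = "superior-nasal",
    IT = "inferior-temporal", IN = "inferior-nasal")
}

#' Aggregate block metrics into 80 quadrant features
#'
#' Each quadrant feature is the mean of a metric over the corresponding
#' 3x3 corner blocks of the 7x7 grid, leaving out the central row and
#' column through the fovea.
#'
#' @param grid A `block_grid` from [block_features()].
#' @return Named numeric vector of 80 features (`<quadrant>_<metric>`)
#'   with an `origin` attribute naming each feature's quadrant.
#' @export
aggregate_quadrants <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  qb <- quadrant_blocks()
  out <- numeric(0)
  origin <- character(0)
  for (q in names(qb)) {
    sub <- grid$metrics[qb[[q]]$x, qb[[q]]$y, , drop = FALSE]
    v <- apply(sub, 3, mean)
    names(v) <- paste(q, glcm_metric_names(), sep = "_")
    out <- c(out, v)
    origin <- c(origin, rep(quadrant_origins()[[q]], 20L))
  }
  attr(out, "origin") <- origin
  out
}
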