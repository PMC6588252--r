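norm_mvf <- function(vals, layer = "GCL") {
  normalise_orientation(mvf_image(vals, layer, "right"))
}

test_that("downsample_quantize has a fixed output contract and exact binning", {
  for (dims in list(c(512, 128), c(128, 128), c(100, 60), c(64, 64))) {
    q <- downsample_quantize(norm_mvf(matrix(rnorm(prod(dims)), dims[1], dims[2])))
    expect_equal(dim(q$values), c(128, 128))
    expect_true(all(q$values %in% 0:15))
  }
  qc <- downsample_quantize(norm_mvf(matrix(7, 128, 128)))
  expect_true(all(qc$values == 0))

  # linear ramp along x spanning the range: 16 equal-width monotone bands
  ramp <- matrix(rep(seq(0, 1, length.out = 128), 128), 128, 128)
  q <- downsample_quantize(norm_mvf(ramp))
  lev <- q$values[, 1]
  oracle <- pmin(floor((ramp[, 1] - min(ramp)) / diff(range(ramp)) * 16), 15)
  expect_equal(lev, as.integer(oracle))
  expect_true(all(diff(lev) >= 0))
  expect_equal(as.vector(table(lev)), rep(8L, 16))

  expect_error(downsample_quantize(norm_mvf(matrix(c(1, NA, 2, 3), 2, 2))),
               "finite")
})

test_that("co-occurrence matrices match hand enumeration on tiny blocks", {
  M <- glcm(matrix(0L, 2, 2), direction = "90", levels = 4)
  expect_equal(M[1, 1], 1)
  expect_equal(sum(M), 1)

  # pairs (0,1) and (2,3) along the second axis, symmetrised
  B <- rbind(c(0L, 1L), c(2L, 3L))
  M2 <- glcm(B, direction = c(0, 1), levels = 4)
  expect_equal(M2[1, 2], 0.25)
  expect_equal(M2[2, 1], 0.25)
  expect_equal(M2[3, 4], 0.25)
  expect_equal(M2[4, 3], 0.25)
  expect_equal(sum(M2 != 0), 4)

  expect_error(glcm(matrix(0L, 1, 3), direction = "0"), "too small")
})

test_that("co-occurrence matrices equal the brute-force pair-counting oracle", {
  set.seed(42)
  for (i in 1:50) {
    lv <- sample(c(4L, 16L), 1)
    B <- matrix(sample(0:(lv - 1), 64, replace = TRUE), 8, 8)
    for (dir in c("0", "45", "90", "135")) {
      off <- octexture:::resolve_offset(dir)
      got <- glcm(B, dir, levels = lv)
      expect_equal(got, oracle_glcm(B, off, levels = lv))
      expect_equal(sum(got), 1)
      expect_equal(got, t(got))  # symmetry
    }
  }
})

test_that("the 20 metrics match closed forms and an independent textbook implementation", {
  L <- 16
  # degenerate texture: all mass at one cell
  M <- matrix(0, L, L); M[1, 1] <- 1
  m <- glcm_metrics(M)
  expect_equal(m[["energy"]], 1)
  expect_equal(m[["entropy"]], 0)
  expect_equal(m[["contrast"]], 0)
  expect_equal(m[["maximum_probability"]], 1)

  # uniform co-occurrence: energy 1/256, entropy 8 bits
  U <- matrix(1 / 256, L, L)
  mu <- glcm_metrics(U)
  expect_equal(mu[["energy"]], 1 / 256)
  expect_equal(mu[["entropy"]], 8)

  # checkerboard and random blocks against the loop-based oracle
  cb <- matrix(rep_len(c(0L, 15L), 64), 8, 8)
  set.seed(7)
  blocks <- c(list(cb), lapply(1:10, function(i)
    matrix(sample(0:15, 100, replace = TRUE), 10, 10)))
  for (B in blocks) {
    for (dir in c("0", "45", "90", "135")) {
      P <- glcm(B, dir)
      expect_equal(glcm_metrics(P), oracle_glcm_metrics(P), tolerance = 1e-10)
    }
  }

  expect_error(glcm_metrics(matrix(1, 16, 16)), "normalised")
})

test_that("block metrics take the supremum over the four directions", {
  # fast blockwise path agrees with per-block glcm() + glcm_metrics()
  set.seed(11)
  img <- matrix(rnorm(128 * 128), 128, 128)
  # horizontal stripes (variation along y): contrast largest for 90 degrees
  stripes <- matrix(rep(rep(c(0, 1), each = 4), length.out = 128), 128, 128,
                    byrow = TRUE)
  for (vals in list(img, stripes)) {
    q <- downsample_quantize(norm_mvf(vals))
    bg <- block_features(q)
    v <- q$values[2:127, 2:127]
    for (bx in c(1, 4, 7)) {
      for (by in c(2, 5)) {
        block <- v[(bx - 1) * 18 + 1:18, (by - 1) * 18 + 1:18]
        per_dir <- sapply(c("0", "45", "90", "135"), function(d)
          glcm_metrics(glcm(block, d)))
        sup <- apply(per_dir, 1, max)
        expect_equal(bg$metrics[bx, by, ], sup, tolerance = 1e-10)
        # supremum dominance over each single direction
        for (d in 1:4)
          expect_true(all(bg$metrics[bx, by, ] >= per_dir[, d] - 1e-12))
      }
    }
  }
  # striped image: vertical-offset contrast attains the supremum
  q <- downsample_quantize(norm_mvf(stripes))
  bg <- block_features(q)
  v <- q$values[2:127, 2:127]
  block <- v[1:18, 1:18]
  per_dir <- sapply(c("0", "45", "90", "135"), function(d)
    glcm_metrics(glcm(block, d))[["contrast"]])
  expect_equal(unname(bg$metrics[1, 1, "contrast"]), unname(per_dir[["90"]]))
  expect_gt(per_dir[["90"]], per_dir[["0"]])
})

test_that("quadrant aggregation averages exactly the 3x3 corner blocks", {
  set.seed(3)
  A <- array(rnorm(7 * 7 * 20), dim = c(7, 7, 20),
             dimnames = list(NULL, NULL, glcm_metric_names()))
  grid <- structure(list(metrics = A, block_size = 18, levels = 16),
                    class = "block_grid")
  feats <- aggregate_quadrants(grid)
  expect_length(feats, 80)
  # index-set oracle
  expect_equal(feats[["ST_contrast"]], mean(A[1:3, 1:3, "contrast"]))
  expect_equal(feats[["SN_energy"]], mean(A[5:7, 1:3, "energy"]))
  expect_equal(feats[["IT_imc2"]], mean(A[1:3, 5:7, "imc2"]))
  expect_equal(feats[["IN_idmn"]], mean(A[5:7, 5:7, "idmn"]))

  # identical blocks: every quadrant feature equals the common value
  A1 <- array(rep(as.vector(A[1, 1, ]), each = 49), dim = c(7, 7, 20),
              dimnames = dimnames(A))
  g1 <- structure(list(metrics = A1, block_size = 18, levels = 16),
                  class = "block_grid")
  f1 <- aggregate_quadrants(g1)
  for (q in c("ST", "SN", "IT", "IN"))
    expect_equal(unname(f1[paste(q, glcm_metric_names(), sep = "_")]),
                 unname(A[1, 1, ]))

  # indicator corner: only the matching quadrant responds
  A2 <- array(0, dim = c(7, 7, 20), dimnames = dimnames(A))
  A2[1:3, 1:3, "contrast"] <- 5
  g2 <- structure(list(metrics = A2, block_size = 18, levels = 16),
                  class = "block_grid")
  f2 <- aggregate_quadrants(g2)
  expect_equal(f2[["ST_contrast"]], 5)
  expect_equal(f2[["SN_contrast"]], 0)
  expect_equal(f2[["IT_contrast"]], 0)
  expect_equal(f2[["IN_contrast"]], 0)
})

test_that("feature vectors have 86 uniquely named entries with an 80/6 origin split", {
  set.seed(5)
  vals <- matrix(rnorm(128 * 128), 128, 128)
  fv <- extract_features(norm_mvf(vals))
  v <- unclass(fv)
  expect_length(v, 86)
  expect_equal(anyDuplicated(names(v)), 0)
  origin <- attr(fv, "origin")
  expect_equal(sum(origin == "global"), 6)
  expect_equal(sum(origin != "global"), 80)
  expect_equal(names(v), feature_manifest()$name)
  # unnormalised input is refused
  expect_error(extract_features(mvf_image(vals, "GCL", "right")), "normalised")
})

test_that("mirror-identical left and right eyes give identical features", {
  set.seed(8)
  vals <- matrix(rnorm(128 * 128), 128, 128)
  fr <- extract_features(norm_mvf(vals))
  fl <- extract_features(normalise_orientation(
    mvf_image(vals[128:1, ], "GCL", "left")))
  expect_equal(unclass(fl), unclass(fr))
})
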