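# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately re-derive results with naive loops, separate from the
# vectorised implementations in the package.

# A small, fast cohort configuration (coarse voxels keep the 6 mm ETDRS
# field covered on a small grid).
small_cfg <- function(n = 2, seed = 7, rho = 0.5, pit = 100,
                      grid = c(32, 32, 48), voxel = c(188, 188, 8)) {
  cohort_config(n_subjects_per_class = n, grid = grid, voxel_scale = voxel,
                foveal_pit_depth = pit, within_subject_correlation = rho,
                seed = seed)
}

# Exhaustive per-A-scan mean between boundaries, re-deriving the half-open
# [upper, lower) voxel convention with scalar loops.
oracle_mvf <- function(volume, surfaces, layer) {
  li <- match(layer, retinal_layers())
  d <- surfaces$depths
  dz <- volume$voxel_scale[3]
  dims <- dim(volume$intensity)
  out <- matrix(NA_real_, dims[1], dims[2])
  for (x in seq_len(dims[1])) {
    for (y in seq_len(dims[2])) {
      u <- d[x, y, li]; l <- d[x, y, li + 1]
      ks <- which(((seq_len(dims[3]) - 1) * dz >= u - 1e-9) &
                    ((seq_len(dims[3]) - 1) * dz < l - 1e-9))
      if (length(ks) == 0) {
        kb <- min(max(floor(u / dz + 1e-9) + 1, 1), dims[3])
        out[x, y] <- volume$intensity[x, y, kb]
      } else {
        out[x, y] <- mean(volume$intensity[x, y, ks])
      }
    }
  }
  out
}

# Brute-force symmetric normalised GLCM by explicit pair enumeration.
oracle_glcm <- function(block, off, levels = 16) {
  M <- matrix(0, levels, levels)
  nr <- nrow(block); nc <- ncol(block)
  for (x in seq_len(nr)) {
    for (y in seq_len(nc)) {
      x2 <- x + off[1]; y2 <- y + off[2]
      if (x2 >= 1 && x2 <= nr && y2 >= 1 && y2 <= nc) {
        i <- block[x, y] + 1; j <- block[x2, y2] + 1
        M[i, j] <- M[i, j] + 1
        M[j, i] <- M[j, i] + 1
      }
    }
  }
  M / sum(M)
}

# Textbook-formula GLCM metrics with explicit loops (log2 entropies,
# natural-log IMC2), independent of the vectorised implementation.
oracle_glcm_metrics <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  ac <- ctr <- dis <- hom <- idn <- idmn <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ac <- ac + i * j * p
    ctr <- ctr + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    hom <- hom + p / (1 + (i - j)^2)
    idn <- idn + p / (1 + abs(i - j) / L)
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
  }
  corr <- if (sig2 > 1e-12) (ac - mu^2) / sig2 else 0
  cs <- cp <- 0
  for (i in 1:L) for (j in 1:L) {
    cs <- cs + (i + j - 2 * mu)^3 * P[i, j]
    cp <- cp + (i + j - 2 * mu)^4 * P[i, j]
  }
  h2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  ent <- -sum(h2(P))
  ps <- sapply(2:(2 * L), function(s) sum(P[outer(1:L, 1:L, "+") == s]))
  pd <- sapply(0:(L - 1), function(dd) sum(P[abs(outer(1:L, 1:L, "-")) == dd]))
  sa <- sum((2:(2 * L)) * ps)
  sv <- sum(((2:(2 * L)) - sa)^2 * ps)
  se <- -sum(h2(ps))
  dv <- sum(((0:(L - 1)) - dis)^2 * pd)
  de <- -sum(h2(pd))
  hx <- -sum(h2(px))
  hxy1 <- -sum(ifelse(P > 0, P * log2(px[row(P)] * py[col(P)]), 0))
  imc1 <- if (hx > 1e-12) (ent - hxy1) / hx else 0
  entn <- -sum(ifelse(P > 0, P * log(P), 0))
  pxpy <- px[row(P)] * py[col(P)]
  hxy2n <- -sum(ifelse(pxpy > 0, pxpy * log(pxpy), 0))
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2n - entn))))
  c(autocorrelation = ac, contrast = ctr, correlation = corr,
    cluster_prominence = cp, cluster_shade = cs, dissimilarity = dis,
    energy = sum(P^2), entropy = ent, homogeneity = hom,
    maximum_probability = max(P), variance = sig2, sum_average = sa,
    sum_variance = sv, sum_entropy = se, difference_variance = dv,
    difference_entropy = de, imc1 = imc1, imc2 = imc2, idn = idn,
    idmn = idmn)
}

# Naive level-1 DTCWT: explicit symmetric-extension convolution and the
# polyphase quad-to-complex combination, all with scalar loops.
oracle_dtcwt_level1 <- function(X) {
  h0 <- octexture:::dtcwt_h0(); h1 <- octexture:::dtcwt_h1()
  conv_rows <- function(M, h) {
    m <- (length(h) - 1) / 2
    n <- nrow(M)
    out <- matrix(0, n, ncol(M))
    for (cc in seq_len(ncol(M))) {
      ext <- c(M[pmin(m:1, n), cc], M[, cc], M[pmax(n - (1:m) + 1, 1), cc])
      for (r in seq_len(n)) out[r, cc] <- sum(h * ext[r:(r + 2 * m)])
    }
    out
  }
  Lo <- conv_rows(X, h0); Hi <- conv_rows(X, h1)
  LH <- t(conv_rows(t(Hi), h0)); HL <- t(conv_rows(t(Lo), h1))
  HH <- t(conv_rows(t(Hi), h1))
  q2c <- function(Y) {
    a <- Y[seq(1, nrow(Y), 2), seq(1, ncol(Y), 2)]
    b <- Y[seq(1, nrow(Y), 2), seq(2, ncol(Y), 2)]
    cc <- Y[seq(2, nrow(Y), 2), seq(1, ncol(Y), 2)]
    d <- Y[seq(2, nrow(Y), 2), seq(2, ncol(Y), 2)]
    p <- (a + 1i * b) / sqrt(2); q <- (d - 1i * cc) / sqrt(2)
    list(p - q, p + q)
  }
  z15 <- q2c(LH); z75 <- q2c(HL); z45 <- q2c(HH)
  list(p15 = z15[[1]], p45 = z45[[1]], p75 = z75[[1]],
       m75 = z75[[2]], m45 = z45[[2]], m15 = z15[[2]])
}

# Independent restatement of the voting rule, written directly from the
# plurality / three-way-tie / pairwise-tie-break description.
oracle_decide <- function(a, b, c, n_layers) {
  # a = HC votes in HC-AD, b = HC votes in HC-PD, c = AD votes in AD-PD
  hc <- a + b
  ad <- (n_layers - a) + c
  pd <- (n_layers - b) + (n_layers - c)
  v <- c(HC = hc, AD = ad, PD = pd)
  top <- names(v)[v == max(v)]
  if (length(top) == 1) return(top)
  if (length(top) == 3) return("Unknown")
  sub <- if (setequal(top, c("HC", "AD"))) c(HC = a, AD = n_layers - a)
  else if (setequal(top, c("HC", "PD"))) c(HC = b, PD = n_layers - b)
  else c(AD = c, PD = n_layers - c)
  if (sub[1] == sub[2]) return("Unknown")
  names(sub)[which.max(sub)]
}

# Stub model bank: every (layer, pair) decision is a fixed label.
stub_bank <- function(decisions, layers) {
  bank <- list()
  for (layer in layers) {
    for (pair in list(c("HC", "AD"), c("HC", "PD"), c("AD", "PD"))) {
      key <- paste(layer, paste(pair, collapse = "-"), sep = "|")
      lab <- decisions[[key]]
      bank[[key]] <- list(
        layer = layer, pair = pair, features = "ST_contrast",
        feature_idx = 1L,
        zscore = list(mean = rep(0, 86), sd = rep(1, 86),
                      zero_variance = rep(FALSE, 86)),
        model = local({ l <- lab; function(X) l }))
    }
  }
  structure(bank, class = "model_bank", layers = layers)
}

# Synthetic per-layer feature tables for classification tests: class-
# dependent shifts on a few informative columns, noise elsewhere.
make_feature_table <- function(n_per_class, layers, seed = 1, effect = 2) {
  fm <- feature_manifest()$name
  set.seed(seed)
  rows <- list()
  for (cl in c("HC", "AD", "PD")) {
    shift <- switch(cl, HC = 0, AD = effect, PD = -effect)
    for (s in seq_len(n_per_class)) {
      sid <- sprintf("%s%03d", cl, s)
      subj_eff <- rnorm(1, 0, 0.3)
      for (eye in c("right", "left")) {
        for (layer in layers) {
          v <- rnorm(length(fm))
          v[1:5] <- v[1:5] + shift + subj_eff
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, eye = eye, class_label = cl, layer = layer,
            as.list(setNames(v, fm)), check.names = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
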