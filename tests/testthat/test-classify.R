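test_that("z-scoring uses training statistics only and flags zero variance", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(zs <- zscore_fit(X), "zero-variance")
  expect_equal(unname(zs$mean["a"]), 2)
  expect_equal(unname(zs$sd["a"]), 1)
  Z <- zscore_apply(X, zs)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(Z[, "b"]), c(0, 0, 0))
  # held-out rows are transformed with the training statistics
  Znew <- zscore_apply(cbind(a = 10, b = 7), zs)
  expect_equal(unname(Znew[1, "a"]), (10 - 2) / 1)
  expect_error(zscore_fit(X[0, , drop = FALSE]), "empty")
})

test_that("forward selection finds a planted separating feature first", {
  set.seed(13)
  n <- 40
  y <- factor(rep(c("HC", "AD"), each = n / 2), levels = c("HC", "AD"))
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  X[, 4] <- ifelse(y == "HC", -2, 2) + rnorm(n, 0, 0.2)
  X <- zscore_apply(X, zscore_fit(X))
  sel <- forward_select(X, y, n_features = 3, seed = 5)
  expect_equal(sel[1], 4L)
  expect_length(sel, 3)
  expect_equal(anyDuplicated(sel), 0)
  # deterministic under a fixed seed
  expect_identical(as.integer(forward_select(X, y, n_features = 3, seed = 5)),
                   as.integer(sel))
  expect_error(forward_select(X, y, n_features = 20), "fewer candidate")
})

test_that("with n_features = 1 the selection reduces to the scorer argmax", {
  set.seed(19)
  n <- 30
  y <- factor(rep(c("HC", "PD"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, 8)
  scorer <- function(Xs, yy) abs(cor(Xs[, ncol(Xs)], as.numeric(yy)))
  sel <- forward_select(X, y, n_features = 1, scorer = scorer)
  single <- vapply(1:8, function(f) scorer(X[, f, drop = FALSE], y), 0)
  expect_equal(as.integer(sel), which.max(single))
})

test_that("the RBF SVM separates blobs and obeys label symmetry", {
  set.seed(23)
  n <- 30
  y <- factor(rep(c("HC", "AD"), each = n / 2), levels = c("HC", "AD"))
  X <- matrix(rnorm(n * 2, sd = 0.4), n, 2) +
    ifelse(matrix(y == "HC", n, 2), -2, 2)
  fit <- train_binary(X, y)
  expect_equal(as.character(predict(fit, X)), as.character(y))
  # swapping labels flips every prediction
  y2 <- factor(ifelse(y == "HC", "AD", "HC"), levels = c("HC", "AD"))
  fit2 <- train_binary(X, y2)
  expect_equal(as.character(predict(fit2, X)), as.character(y2))
  # deterministic predictions
  expect_equal(predict(fit, X), predict(fit, X))
  expect_error(train_binary(X, factor(rep("HC", n), levels = c("HC", "AD"))),
               "single-class")
})

test_that("the voting rule matches an exhaustive enumeration of tallies", {
  layers <- paste0("L", 1:5)
  pairs <- list(c("HC", "AD"), c("HC", "PD"), c("AD", "PD"))
  mismatches <- 0
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) {
    tally <- c(HC = a + b, AD = (5 - a) + cc, PD = (5 - b) + (5 - cc))
    pt <- list(`HC-AD` = c(HC = a, AD = 5 - a),
               `HC-PD` = c(HC = b, PD = 5 - b),
               `AD-PD` = c(AD = cc, PD = 5 - cc))
    got <- decide_vote(tally, pt)
    want <- oracle_decide(a, b, cc, 5)
    if (!identical(got, want)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)

  # hand-checked tally cases
  expect_equal(decide_vote(c(HC = 5, AD = 10, PD = 0),
                           list(`HC-AD` = c(HC = 0, AD = 5),
                                `HC-PD` = c(HC = 5, PD = 0),
                                `AD-PD` = c(AD = 5, PD = 0))), "AD")
  expect_equal(decide_vote(c(HC = 5, AD = 5, PD = 5),
                           list(`HC-AD` = c(HC = 2, AD = 3),
                                `HC-PD` = c(HC = 3, PD = 2),
                                `AD-PD` = c(AD = 2, PD = 3))), "Unknown")
  # two-way top tie resolved by the pairwise sub-tally (HC beats AD 3-2)
  expect_equal(decide_vote(c(HC = 6, AD = 6, PD = 3),
                           list(`HC-AD` = c(HC = 3, AD = 2),
                                `HC-PD` = c(HC = 3, PD = 2),
                                `AD-PD` = c(AD = 4, PD = 1))), "HC")
})

test_that("voted classification conserves votes and respects a stub bank", {
  layers <- c("GCL", "IPL", "INL", "OPL", "ONL")
  decisions <- list()
  for (layer in layers) {
    decisions[[paste(layer, "HC-AD", sep = "|")]] <- "AD"
    decisions[[paste(layer, "HC-PD", sep = "|")]] <- "HC"
    decisions[[paste(layer, "AD-PD", sep = "|")]] <- "AD"
  }
  bank <- stub_bank(decisions, layers)
  ef <- setNames(lapply(layers, function(l)
    matrix(0, 1, 86, dimnames = list(NULL, feature_manifest()$name))), layers)
  out <- vote_classify(ef, bank)
  expect_equal(sum(out$tally), 3 * length(layers))
  expect_equal(unname(out$tally["AD"]), 10)
  expect_equal(out$label, "AD")
  # a missing model is a configuration error
  expect_error(vote_classify(ef, bank[-1], layers = layers), "missing model")
})

test_that("cross-validation is reproducible, exhaustive and leak-free", {
  feats <- make_feature_table(6, c("GCL", "IPL"), seed = 2, effect = 3)
  cfg <- cv_config(k = 3, n_runs = 2, layers = c("GCL", "IPL"), seed = 11)
  runs1 <- run_cv(feats, cfg)
  runs2 <- run_cv(feats, cfg)
  expect_identical(runs1[[1]]$predictions, runs2[[1]]$predictions)
  expect_identical(runs1[[2]]$predictions, runs2[[2]]$predictions)

  # each eye predicted exactly once per run, both eyes share the fold
  pr <- runs1[[1]]$predictions
  expect_equal(nrow(pr), 36)
  expect_equal(anyDuplicated(paste(pr$subject_id, pr$eye)), 0)
  folds_per_subject <- tapply(pr$fold, pr$subject_id, function(v)
    length(unique(v)))
  expect_true(all(folds_per_subject == 1))
  expect_equal(sum(runs1[[1]]$confusion), 36)

  # leakage guard: garbling the held-out rows of fold 1 leaves fold 1's
  # fitted artefacts (z-score parameters, selected features, SVM
  # coefficients) unchanged
  fold1_subjects <- unique(pr$subject_id[pr$fold == 1])
  feats2 <- feats
  rows <- feats2$subject_id %in% fold1_subjects
  fm <- feature_manifest()$name
  set.seed(99)
  feats2[rows, fm] <- matrix(rnorm(sum(rows) * length(fm)) * 50,
                             sum(rows), length(fm))
  runs3 <- run_cv(feats2, cfg)
  expect_identical(runs1[[1]]$models[[1]], runs3[[1]]$models[[1]])
})
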