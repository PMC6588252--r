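# Classification: z-scoring, greedy forward feature selection, the bank of
# binary RBF-SVMs, one-vs-one voting with tie handling, and repeated
# k-fold cross-validation.

#' Fit and apply per-feature z-score normalisation
#'
#' `zscore_fit()` computes per-feature mean and sample standard deviation
#' from training rows only; `zscore_apply()` standardises any table with
#' those training statistics. Zero-variance features are flagged at fit
#' time and map to 0.
#'
#' @param X Numeric matrix (rows = eyes, columns = features).
#' @param params A fit object from `zscore_fit()`.
#' @return `zscore_fit()`: list with `mean`, `sd` and `zero_variance`;
#'   `zscore_apply()`: the transformed matrix.
#' @export
zscore_fit <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) == 0) stop("empty training set")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  zero <- s == 0 | !is.finite(s)
  if (any(zero))
    warning("zero-variance feature(s): ",
            paste(colnames(X)[zero], collapse = ", "))
  list(mean = mu, sd = s, zero_variance = zero)
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(X, params) {
  stopifnot(is.matrix(X), ncol(X) == length(params$mean))
  s <- ifelse(params$zero_variance, 1, params$sd)
  Z <- sweep(sweep(X, 2, params$mean), 2, s, "/")
  Z[, params$zero_variance] <- 0
  Z
}

# Deterministic stratified fold assignment of indices 1..n into k folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_substream(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Greedy forward feature selection
#'
#' At each step every remaining feature is scored jointly with the current
#' set and the best is kept, until `n_features` are selected. The default
#' scorer is stratified internal cross-validated accuracy of an RBF-kernel
#' SVM (C = 1, gamma = 1/d on z-scored features) within the provided
#' rows. Ties are broken towards the lowest feature index, making the
#' selection deterministic given `seed`.
#'
#' @param X Numeric matrix of z-scored candidate features.
#' @param y Binary factor (or vector coercible to one).
#' @param n_features Number of features to select (default 6).
#' @param scorer Optional custom scorer `function(X_sub, y) -> accuracy`;
#'   when supplied, a pure-R greedy loop is used.
#' @param internal_k Internal cross-validation folds for the default
#'   scorer (default 5, capped by the smaller class size).
#' @param seed Integer seed for the internal fold assignment.
#' @param cost SVM cost parameter (default 1).
#' @return Integer vector of selected column indices (in selection
#'   order), with the per-step scores as the `scores` attribute.
#' @export
forward_select <- function(X, y, n_features = 6L, scorer = NULL,
                           internal_k = 5L, seed = 1L, cost = 1) {
  stopifnot(is.matrix(X))
  y <- factor(y)
  if (nlevels(y) != 2) stop("forward_select requires binary labels")
  if (ncol(X) < n_features)
    stop("fewer candidate features (", ncol(X), ") than requested (",
         n_features, ")")
  if (!is.null(scorer)) {
    chosen <- integer(0)
    scores <- numeric(0)
    for (step in seq_len(n_features)) {
      cand <- setdiff(seq_len(ncol(X)), chosen)
      acc <- vapply(cand, function(f) {
        scorer(X[, c(chosen, f), drop = FALSE], y)
      }, 0)
      best <- cand[which.max(acc)]  # which.max takes the first = lowest index
      chosen <- c(chosen, best)
      scores <- c(scores, max(acc))
    }
    return(structure(chosen, scores = scores))
  }
  k <- max(2L, min(internal_k, min(table(y))))
  fold <- stratified_folds(as.character(y), k, seed)
  res <- forward_select_smo(X, as.integer(y == levels(y)[2]), fold,
                            as.integer(n_features), cost)
  structure(as.integer(res$selected), scores = as.numeric(res$scores))
}

#' Train one binary RBF-SVM
#'
#' @param X Numeric matrix of z-scored selected features.
#' @param y Binary factor of class labels.
#' @param cost SVM cost parameter (default 1).
#' @return A fitted `e1071::svm` model.
#' @export
train_binary <- function(X, y, cost = 1) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("single-class training data")
  y <- droplevels(y)
  e1071::svm(X, y, kernel = "radial", cost = cost, gamma = 1 / ncol(X),
             scale = FALSE)
}

class_pairs <- function() {
  list(c("HC", "AD"), c("HC", "PD"), c("AD", "PD"))
}

pair_key <- function(pair) paste(pair, collapse = "-")

# Predict labels with a bank entry; stubs (plain functions) are allowed so
# the voting logic can be exercised in isolation.
predict_model <- function(model, X) {
  if (is.function(model)) as.character(model(X))
  else as.character(predict(model, X))
}

#' Train the bank of binary SVM models
#'
#' One model per (layer, class pair): restrict to training eyes of the two
#' classes, z-score the 86 features on those rows, forward-select
#' `n_features` of them, and fit the RBF-SVM. Three pairs x 6 layers gives
#' 18 models; dropping the RNFL gives 15.
#'
#' @param feats Named list (by layer) of numeric matrices
#'   `eyes x 86 features`, all with identical row order.
#' @param labels Class factor/character for the rows.
#' @param layers Layers to build models for.
#' @param n_features Features per model (default 6).
#' @param seed Integer seed (internal CV folds of the selection).
#' @param selected Optional pre-computed selection: named list
#'   `layer|pair -> integer feature indices` (used by the
#'   `selection = "global"` cross-validation variant).
#' @return A `model_bank`: list of entries with `layer`, `pair`,
#'   `features` (names), `feature_idx`, `zscore`, and the fitted `model`.
#' @export
train_model_bank <- function(feats, labels, layers = names(feats),
                             n_features = 6L, seed = 1L, selected = NULL) {
  labels <- as.character(labels)
  bank <- list()
  for (layer in layers) {
    Xl <- feats[[layer]]
    if (is.null(Xl)) stop("no features for layer ", layer)
    for (pair in class_pairs()) {
      key <- paste(layer, pair_key(pair), sep = "|")
      rows <- labels %in% pair
      Xp <- Xl[rows, , drop = FALSE]
      yp <- factor(labels[rows], levels = pair)
      zs <- suppressWarnings(zscore_fit(Xp))
      Z <- zscore_apply(Xp, zs)
      idx <- if (!is.null(selected)) selected[[key]]
      else forward_select(Z, yp, n_features = n_features,
                          seed = substream_seed(seed, "select", key))
      fit <- train_binary(Z[, idx, drop = FALSE], yp)
      bank[[key]] <- list(layer = layer, pair = pair,
                          features = colnames(Xl)[idx], feature_idx = idx,
                          zscore = zs, model = fit)
    }
  }
  structure(bank, class = "model_bank", layers = layers)
}

#' Resolve a one-vs-one vote tally into a prediction
#'
#' Strict plurality wins. A three-way tie yields `"Unknown"`. A two-way
#' tie for the top is decided by the pairwise sub-tally between the two
#' tied classes; if that sub-tally is itself tied the eye is `"Unknown"`.
#'
#' @param tally Named integer vector of votes per class (HC, AD, PD).
#' @param pair_tallies Named list `"A-B" -> c(A = votes, B = votes)` of
#'   the per-pair vote counts.
#' @return A single label: one of the classes or `"Unknown"`.
#' @export
decide_vote <- function(tally, pair_tallies) {
  top <- names(tally)[tally == max(tally)]
  if (length(top) == 1) return(top)
  if (length(top) == 3) return("Unknown")
  # two-way tie: the pairwise sub-tally between the tied classes decides
  pair <- NULL
  for (p in class_pairs()) if (setequal(p, top)) pair <- p
  sub <- pair_tallies[[pair_key(pair)]]
  if (sub[[pair[1]]] > sub[[pair[2]]]) return(pair[1])
  if (sub[[pair[2]]] > sub[[pair[1]]]) return(pair[2])
  "Unknown"
}

#' Classify one eye by one-vs-one voting over layers
#'
#' Each (layer, pair) model casts one vote for one of its two classes;
#' the tally is resolved by [decide_vote()].
#'
#' @param eye_feats Named list (by layer) of 1 x 86 feature matrices for
#'   the eye.
#' @param bank A `model_bank` covering every (layer, pair).
#' @param layers Layers to use (default: the bank's layers).
#' @return A list with `label`, `tally` and `pair_tallies`.
#' @export
vote_classify <- function(eye_feats, bank, layers = attr(bank, "layers")) {
  classes <- diagnostic_classes()
  tally <- setNames(integer(3), classes)
  pair_tallies <- setNames(
    lapply(class_pairs(), function(p) setNames(c(0L, 0L), p)),
    vapply(class_pairs(), pair_key, ""))
  for (layer in layers) {
    for (pair in class_pairs()) {
      key <- paste(layer, pair_key(pair), sep = "|")
      entry <- bank[[key]]
      if (is.null(entry)) stop("missing model for ", key)
      Z <- zscore_apply(eye_feats[[layer]], entry$zscore)
      winner <- predict_model(entry$model, Z[, entry$feature_idx, drop = FALSE])
      tally[winner] <- tally[winner] + 1L
      pk <- pair_key(pair)
      pair_tallies[[pk]][winner] <- pair_tallies[[pk]][winner] + 1L
    }
  }
  list(label = decide_vote(tally, pair_tallies),
       tally = tally, pair_tallies = pair_tallies)
}

#' Cross-validation configuration
#'
#' @param k Number of folds (2, 5 and 10 are the standard choices).
#' @param n_runs Number of repeated runs.
#' @param layers Layers used for voting (default: the five inner layers
#'   without the RNFL).
#' @param unit Partition unit: `"subject"` keeps both eyes of a subject in
#'   the same fold (default); `"eye"` splits eyes independently.
#' @param n_features Features per binary model (default 6).
#' @param selection `"per-fold"` (default) re-runs feature selection
#'   inside every training fold; `"global"` selects once per run on the
#'   full dataset (the laxer reading).
#' @param seed Integer master seed.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 10L, n_runs = 1L, layers = classification_layers(),
                      unit = c("subject", "eye"), n_features = 6L,
                      selection = c("per-fold", "global"), seed = 1L) {
  stopifnot(k >= 2, n_runs >= 1)
  structure(list(k = as.integer(k), n_runs = as.integer(n_runs),
                 layers = layers, unit = match.arg(unit),
                 n_features = as.integer(n_features),
                 selection = match.arg(selection), seed = as.integer(seed)),
            class = "cv_config")
}

# Pivot the long feature table into per-layer matrices + an eye info table.
split_features_by_layer <- function(features, layers) {
  fm <- feature_manifest()$name
  miss <- setdiff(fm, colnames(features))
  if (length(miss)) stop("feature table lacks columns: ", miss[1], " ...")
  eye_id <- paste(features$subject_id, features$eye, sep = ":")
  ids <- unique(eye_id)
  info <- features[!duplicated(eye_id), c("subject_id", "eye", "class_label")]
  rownames(info) <- ids
  feats <- list()
  for (layer in layers) {
    sub <- features[features$layer == layer, , drop = FALSE]
    M <- as.matrix(sub[, fm, drop = FALSE])
    rownames(M) <- paste(sub$subject_id, sub$eye, sep = ":")
    if (!setequal(rownames(M), ids)) stop("incomplete layer ", layer)
    feats[[layer]] <- M[ids, , drop = FALSE]
  }
  list(feats = feats, info = info, ids = ids)
}

# Draw a stratified partition of the unit ids into k folds such that every
# training set contains all classes; bounded redraws.
draw_partition <- function(unit_class, k, seed) {
  for (try in 1:25) {
    fold <- stratified_folds(unit_class, k, substream_seed(seed, "part", try))
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(unit_class[fold != f])) == length(unique(unit_class))
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not draw a partition with every class in every training fold")
}

#' Repeated k-fold cross-validation of the voted SVM bank
#'
#' Per run: a stratified random partition (by subject unless
#' `unit = "eye"`), then per fold the full leak-free pipeline on the
#' training eyes only — z-score fit, forward selection and SVM training —
#' followed by voted classification of the held-out eyes.
#'
#' @param features Long feature table from [cohort_features()].
#' @param cfg A [cv_config()].
#' @return A list of run results, each with `predictions` (data.frame:
#'   subject_id, eye, fold, truth, predicted), `confusion` (3x4 matrix),
#'   and `models` (per-fold model summaries: selected features, z-score
#'   parameters, SVM coefficients).
#' @export
run_cv <- function(features, cfg = cv_config()) {
  stopifnot(inherits(cfg, "cv_config"))
  sp <- split_features_by_layer(features, cfg$layers)
  info <- sp$info
  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    run_seed <- substream_seed(cfg$seed, "run", r)
    if (cfg$unit == "subject") {
      subj <- unique(info$subject_id)
      subj_class <- info$class_label[match(subj, info$subject_id)]
      sfold <- draw_partition(subj_class, cfg$k, run_seed)
      fold <- sfold[match(info$subject_id, subj)]
    } else {
      fold <- draw_partition(info$class_label, cfg$k, run_seed)
    }
    global_sel <- NULL
    if (cfg$selection == "global") {
      gb <- train_model_bank(sp$feats, info$class_label, cfg$layers,
                             n_features = cfg$n_features,
                             seed = substream_seed(run_seed, "global"))
      global_sel <- lapply(gb, `[[`, "feature_idx")
    }
    preds <- character(nrow(info))
    models <- list()
    for (f in seq_len(cfg$k)) {
      tr <- fold != f
      bank <- train_model_bank(
        lapply(sp$feats, function(M) M[tr, , drop = FALSE]),
        info$class_label[tr], cfg$layers,
        n_features = cfg$n_features,
        seed = substream_seed(run_seed, "fold", f),
        selected = global_sel)
      models[[f]] <- lapply(bank, function(e) {
        list(layer = e$layer, pair = e$pair, features = e$features,
             zscore = e$zscore,
             svm_coefs = as.numeric(e$model$coefs), svm_rho = e$model$rho)
      })
      for (i in which(!tr)) {
        ef <- lapply(sp$feats, function(M) M[i, , drop = FALSE])
        preds[i] <- vote_classify(ef, bank, cfg$layers)$label
      }
    }
    predictions <- data.frame(subject_id = info$subject_id, eye = info$eye,
                              fold = fold, truth = info$class_label,
                              predicted = preds, stringsAsFactors = FALSE)
    runs[[r]] <- list(predictions = predictions,
                      confusion = confusion(preds, info$class_label),
                      models = models, seed = run_seed)
  }
  runs
}
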