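# Performance metrics and study summaries: 3x4 confusion matrix,
# per-class sensitivity/specificity, accuracy, two-eye agreement, Unknown
# rate, run distributions, feature-origin tallies, feature-thickness
# correlations and per-sector thickness ANOVA.

prediction_levels <- function() c(diagnostic_classes(), "Unknown")

#' Build the 3x4 confusion matrix
#'
#' Rows are the true classes (HC, AD, PD); columns the predicted classes
#' plus the `Unknown` tie outcome.
#'
#' @param predicted Character/factor of predictions (classes or
#'   `"Unknown"`).
#' @param truth Character/factor of true classes.
#' @return Integer 3x4 matrix.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (!all(truth %in% diagnostic_classes()))
    stop("true labels outside {HC, AD, PD}")
  if (!all(predicted %in% prediction_levels()))
    stop("predicted labels outside {HC, AD, PD, Unknown}")
  table(factor(truth, levels = diagnostic_classes()),
        factor(predicted, levels = prediction_levels())) |>
    unclass()
}

#' Per-class sensitivity and specificity, and accuracy
#'
#' Sensitivity of class c is the fraction of its eyes predicted c;
#' specificity the fraction of the other classes' eyes not predicted c.
#' `Unknown` predictions are never "predicted c", so they count against
#' sensitivity and accuracy and in favour of specificity. All values are
#' percentages; metrics with an empty denominator are `NA`.
#'
#' @param cm A 3x4 confusion matrix from [confusion()].
#' @return List with `sensitivity` and `specificity` (named per class)
#'   and `accuracy`.
#' @export
class_metrics <- function(cm) {
  stopifnot(nrow(cm) == 3, ncol(cm) == 4)
  classes <- diagnostic_classes()
  sens <- spec <- setNames(numeric(3), classes)
  for (c1 in classes) {
    row_total <- sum(cm[c1, ])
    sens[c1] <- if (row_total > 0) 100 * cm[c1, c1] / row_total else NA_real_
    others <- setdiff(classes, c1)
    neg_total <- sum(cm[others, ])
    spec[c1] <- if (neg_total > 0)
      100 * (neg_total - sum(cm[others, c1])) / neg_total else NA_real_
  }
  total <- sum(cm)
  acc <- if (total > 0) 100 * sum(diag(cm[, classes])) / total else NA_real_
  list(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' Two-eye agreement metrics
#'
#' Among subjects with exactly two classified eyes: the percentage whose
#' eyes received the same classification, and — among those — the
#' percentage whose shared classification is the correct class (a shared
#' `Unknown` counts as agreeing but never as correct). Subjects with a
#' single eye are excluded and reported separately.
#'
#' @param predictions Data.frame with `subject_id`, `predicted`, `truth`.
#' @return List with `pct_same`, `pct_correct_given_same`, `n_subjects`,
#'   `n_single_eye`.
#' @export
two_eye_metrics <- function(predictions) {
  sp <- split(predictions, predictions$subject_id)
  two <- Filter(function(d) nrow(d) == 2, sp)
  n_single <- sum(vapply(sp, nrow, 0L) != 2)
  if (length(two) == 0)
    return(list(pct_same = NA_real_, pct_correct_given_same = NA_real_,
                n_subjects = 0L, n_single_eye = n_single))
  same <- vapply(two, function(d) d$predicted[1] == d$predicted[2], TRUE)
  pct_same <- 100 * mean(same)
  if (!any(same)) {
    pcs <- NA_real_
  } else {
    agreed <- two[same]
    correct <- vapply(agreed, function(d) {
      d$predicted[1] != "Unknown" && d$predicted[1] == d$truth[1]
    }, TRUE)
    pcs <- 100 * mean(correct)
  }
  list(pct_same = pct_same, pct_correct_given_same = pcs,
       n_subjects = length(two), n_single_eye = n_single)
}

#' Percentage of eyes classified Unknown
#'
#' @param predicted Character/factor of predictions.
#' @return Percentage in `[0, 100]`.
#' @export
unknown_rate <- function(predicted) {
  100 * mean(as.character(predicted) == "Unknown")
}

#' Performance metrics for one cross-validation run
#'
#' @param run A run result from [run_cv()] (or any list with a
#'   `predictions` data.frame).
#' @return One-row data.frame: per-class sensitivity/specificity,
#'   accuracy, two-eye agreement metrics and Unknown rate (all %).
#' @export
run_metrics <- function(run) {
  pr <- run$predictions
  cm <- confusion(pr$predicted, pr$truth)
  m <- class_metrics(cm)
  te <- two_eye_metrics(pr)
  data.frame(sen_HC = m$sensitivity["HC"], spe_HC = m$specificity["HC"],
             sen_AD = m$sensitivity["AD"], spe_AD = m$specificity["AD"],
             sen_PD = m$sensitivity["PD"], spe_PD = m$specificity["PD"],
             accuracy = m$accuracy,
             two_eyes = te$pct_same,
             two_eyes_correct = te$pct_correct_given_same,
             unknown = unknown_rate(pr$predicted),
             row.names = NULL)
}

#' Distribution summary over runs
#'
#' Max, third quartile, median, first quartile and min of each metric
#' over repeated runs. Quantiles use linear interpolation between order
#' statistics (type 7).
#'
#' @param metrics Data.frame of per-run metrics ([run_metrics()] rows).
#' @return Data.frame with rows Max, Q3, Median, Q1, Min.
#' @export
summarize_runs <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(NA_real_, 5))
    unname(quantile(v, c(1, 0.75, 0.5, 0.25, 0), type = 7))
  }
  out <- as.data.frame(lapply(metrics, qs))
  rownames(out) <- c("Max", "Q3", "Median", "Q1", "Min")
  out
}

#' Tally selected features by regional origin
#'
#' Counts, per class pair, how many selected features (aggregated over
#' layers and, if present, folds) come from each macular quadrant or from
#' the global wavelet features.
#'
#' @param specs Data.frame with columns `pair`, `feature` (and anything
#'   else); or a `model_bank`, or the `models` element of a run result.
#' @return Data.frame: `pair`, `origin`, `count`, `pct` (within pair).
#' @export
feature_origin_tally <- function(specs) {
  if (inherits(specs, "model_bank") || (is.list(specs) && !is.data.frame(specs))) {
    entries <- if (inherits(specs, "model_bank")) specs else unlist(specs, recursive = FALSE)
    specs <- do.call(rbind, lapply(entries, function(e) {
      data.frame(pair = pair_key(e$pair), feature = e$features,
                 stringsAsFactors = FALSE)
    }))
  }
  fm <- feature_manifest()
  specs$origin <- fm$origin[match(specs$feature, fm$name)]
  if (anyNA(specs$origin)) stop("unknown feature name in specs")
  tab <- as.data.frame(table(pair = specs$pair, origin = specs$origin),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  totals <- tapply(tab$count, tab$pair, sum)
  tab$pct <- 100 * tab$count / as.numeric(totals[tab$pair])
  tab[order(tab$pair, tab$origin), ]
}

#' Quadrant mean layer thickness
#'
#' Mean thickness of one layer over the same 3x3-block quadrant
#' footprints used by the texture features, so that a local texture
#' feature and its thickness share spatial support. The map is resampled
#' to the texture working grid first. Left-eye surfaces are mirrored to
#' right-eye orientation.
#'
#' @param eye An `eye_record`.
#' @param layer One of [retinal_layers()].
#' @param size Texture grid side (default 128).
#' @return Named numeric: mean thickness (µm) in quadrants ST, SN, IT, IN.
#' @export
quadrant_layer_thickness <- function(eye, layer, size = 128L) {
  tk <- layer_thickness(eye$surfaces, layer)
  if (eye$laterality == "left") tk <- tk[rev(seq_len(nrow(tk))), , drop = FALSE]
  tk <- resample_mean(tk, size)
  bs <- size %/% 7L
  work <- 7L * bs
  margin <- (size - work) %/% 2L
  tk <- tk[margin + seq_len(work), margin + seq_len(work), drop = FALSE]
  qb <- quadrant_blocks()
  vapply(qb, function(q) {
    xs <- (rep(q$x, each = bs) - 1L) * bs + seq_len(bs)
    ys <- (rep(q$y, each = bs) - 1L) * bs + seq_len(bs)
    mean(tk[xs, ys])
  }, 0)
}

#' Pearson correlation of selected features with quadrant thickness
#'
#' For each selected local feature, the Pearson correlation between the
#' feature and the mean thickness of its own layer in its own quadrant,
#' computed within each class group. Correlations are classed strong
#' (|r| > 0.7), moderate (0.5-0.7) or weak.
#'
#' @param features Long feature table ([cohort_features()]).
#' @param thickness Data.frame with `subject_id`, `eye`, `layer` and
#'   quadrant columns `ST`, `SN`, `IT`, `IN` (µm), one row per
#'   (eye, layer) — see [quadrant_layer_thickness()].
#' @param selected Data.frame with `layer` and `feature` columns naming
#'   the selected local features.
#' @return Data.frame: `feature`, `layer`, `quadrant`, `group`, `n`, `r`,
#'   `strength` (`NA` r when fewer than 3 pairs).
#' @export
feature_thickness_correlation <- function(features, thickness, selected) {
  fm <- feature_manifest()
  out <- list()
  for (i in seq_len(nrow(selected))) {
    feat <- selected$feature[i]; layer <- selected$layer[i]
    quad <- fm$quadrant[match(feat, fm$name)]
    if (is.na(quad)) next  # global features have no quadrant thickness
    fsub <- features[features$layer == layer, , drop = FALSE]
    tsub <- thickness[thickness$layer == layer, , drop = FALSE]
    key <- paste(fsub$subject_id, fsub$eye)
    tkey <- paste(tsub$subject_id, tsub$eye)
    tk <- tsub[[quad]][match(key, tkey)]
    for (g in unique(fsub$class_label)) {
      rows <- fsub$class_label == g
      n <- sum(rows)
      r <- if (n >= 3) cor(fsub[[feat]][rows], tk[rows]) else NA_real_
      strength <- if (is.na(r)) NA_character_
      else if (abs(r) > 0.7) "strong"
      else if (abs(r) >= 0.5) "moderate" else "weak"
      out[[length(out) + 1L]] <- data.frame(
        feature = feat, layer = layer, quadrant = quad, group = g,
        n = n, r = r, strength = strength, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' One-way ANOVA of sector thickness across groups
#'
#' Conventional one-way ANOVA of each ETDRS sector's thickness across the
#' diagnostic groups.
#'
#' @param sectors Data.frame/matrix with one row per eye and one column
#'   per sector (µm).
#' @param groups Class labels per eye (>= 2 groups, >= 2 eyes each).
#' @return Data.frame: `sector`, `F`, `p`.
#' @export
sector_anova <- function(sectors, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two eyes")
  sectors <- as.data.frame(sectors)
  out <- lapply(names(sectors), function(s) {
    v <- sectors[[s]]
    if (var(v) == 0) {
      warning("degenerate sector ", s, ": zero variance")
      return(data.frame(sector = s, F = NA_real_, p = NA_real_))
    }
    fit <- summary(aov(v ~ groups))[[1]]
    data.frame(sector = s, F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
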