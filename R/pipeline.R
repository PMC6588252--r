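# End-to-end convenience: generate a cohort subject by subject and keep
# only the derived tables (features, ETDRS sectors, quadrant thickness),
# so large cohorts never hold all volumes in memory at once. Thanks to
# the named RNG sub-streams the result is identical to running
# generate_cohort() followed by cohort_features().

#' Simulate a cohort and extract all derived tables
#'
#' @param config A [cohort_config()].
#' @param params Per-class [class_texture_params()] list.
#' @param layers Layers to extract features for.
#' @param size,levels Quantization parameters.
#' @return List with `features` (long table, see [cohort_features()]),
#'   `sectors` (one row per eye: nine ETDRS sector means),
#'   `quadrant_thickness` (one row per (eye, layer): quadrant mean layer
#'   thickness in µm) and `manifest`.
#' @export
simulate_study <- function(config, params = default_class_params(),
                           layers = retinal_layers(),
                           size = 128L, levels = 16L) {
  classes <- diagnostic_classes()
  feats <- list(); sect <- list(); qth <- list(); man <- list()
  idx <- 0L
  for (cl in classes) {
    for (s in seq_len(config$n_subjects_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", cl, s)
      for (lat in c("right", "left")) {
        eye <- generate_eye(config, params[[cl]], sid, idx, lat)
        feats[[length(feats) + 1L]] <- cohort_features(list(eye), layers,
                                                       size, levels)
        sect[[length(sect) + 1L]] <- data.frame(
          subject_id = sid, eye = lat, class_label = cl,
          as.list(eye_thickness_sectors(eye)),
          stringsAsFactors = FALSE, check.names = FALSE)
        qth[[length(qth) + 1L]] <- do.call(rbind, lapply(layers, function(ly) {
          data.frame(subject_id = sid, eye = lat, class_label = cl,
                     layer = ly, as.list(quadrant_layer_thickness(eye, ly, size)),
                     stringsAsFactors = FALSE, check.names = FALSE)
        }))
        man[[length(man) + 1L]] <- data.frame(
          subject_id = sid, laterality = lat, class_label = cl,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(features = do.call(rbind, feats),
       sectors = do.call(rbind, sect),
       quadrant_thickness = do.call(rbind, qth),
       manifest = do.call(rbind, man))
}
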