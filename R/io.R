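# Plain-text input/output: cohort manifests and per-eye numeric arrays,
# feature tables, thickness sectors, predictions and model specs.

#' Write / read a cohort as plain numeric-array files
#'
#' Each eye is stored as a whitespace-delimited text file holding the
#' volume (preceded by its dimensions) and the boundary surfaces, plus a
#' manifest CSV (`subject_id`, `laterality`, `class_label`, `file`).
#' Intended for small volumes and interchange with other tools; large
#' cohorts are better regenerated from their seed.
#'
#' @param cohort List of eye records.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()`: the manifest (invisibly); `read_cohort()`:
#'   the list of eye records.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort_manifest(cohort)
  manifest$file <- sprintf("%s_%s.txt", manifest$subject_id, manifest$laterality)
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    con <- file(file.path(dir, manifest$file[i]), "w")
    writeLines(paste(dim(rec$volume$intensity), collapse = " "), con)
    writeLines(paste(rec$volume$voxel_scale, collapse = " "), con)
    writeLines(paste(format(as.vector(rec$volume$intensity), digits = 10, trim = TRUE),
                     collapse = " "), con)
    writeLines(paste(format(as.vector(rec$surfaces$depths), digits = 10, trim = TRUE),
                     collapse = " "), con)
    close(con)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    lines <- readLines(file.path(dir, manifest$file[i]))
    dims <- as.integer(strsplit(lines[1], " ")[[1]])
    scale <- as.numeric(strsplit(lines[2], " ")[[1]])
    vol <- array(as.numeric(strsplit(lines[3], " +")[[1]]), dim = dims)
    dep <- array(as.numeric(strsplit(lines[4], " +")[[1]]),
                 dim = c(dims[1], dims[2], 8L))
    structure(list(subject_id = manifest$subject_id[i],
                   laterality = manifest$laterality[i],
                   class_label = manifest$class_label[i],
                   volume = oct_volume(vol, scale, manifest$laterality[i]),
                   surfaces = layer_surfaces(dep)),
              class = "eye_record")
  })
}

#' Write / read the long feature table
#'
#' @param features Data.frame from [cohort_features()].
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write per-run predictions and model specs
#'
#' `write_predictions()` stacks each run's prediction table into one CSV
#' with a `run` column. `write_model_specs()` stores the selected
#' features of every (run, fold, layer, pair) model as JSON.
#'
#' @param runs List of run results from [run_cv()].
#' @param path Output file path.
#' @export
write_predictions <- function(runs, path) {
  tabs <- lapply(seq_along(runs), function(r) {
    cbind(run = r, runs[[r]]$predictions)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
}

#' @rdname write_predictions
#' @export
write_model_specs <- function(runs, path) {
  specs <- lapply(seq_along(runs), function(r) {
    lapply(runs[[r]]$models, function(fold_models) {
      lapply(fold_models, function(m) {
        list(layer = m$layer, pair = pair_key(m$pair), features = m$features)
      })
    })
  })
  jsonlite::write_json(specs, path, auto_unbox = TRUE)
}
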