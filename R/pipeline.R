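#' Read an eye photograph as an 8-bit grayscale matrix
#'
#' PNG, JPEG and TIFF are supported (via EBImage). RGB images are converted to
#' gray with the standard luminance weights 0.2989 R + 0.5870 G + 0.1140 B.
#'
#' @param path image file path.
#' @return Numeric matrix, gray-levels in \[0, 255\].
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path)) {
    iristex_error(sprintf("cannot read image '%s': file not found", path),
                  "iristex_io_error")
  }
  img <- tryCatch(EBImage::readImage(path), error = function(e) {
    iristex_error(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
                  "iristex_io_error")
  })
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    if (dim(dat)[3] >= 3) {
      dat <- 0.2989 * dat[, , 1] + 0.5870 * dat[, , 2] + 0.1140 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  t(dat) * 255 # EBImage indexes [x, y]
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image gray-level matrix in \[0, 255\].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_eye_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read / write a feature table
#'
#' CSV with a header row: 136 feature columns (names = [feature_names()]) plus
#' a `label` column. `read_feature_table(write_feature_table(x))` round-trips
#' the values.
#'
#' @param features numeric matrix, rows = images, named columns.
#' @param labels 0/1 vector.
#' @param path CSV path.
#' @return `write_feature_table`: invisibly, `path`. `read_feature_table`: list
#'   with `X` (matrix) and `y` (integer labels).
#' @export
write_feature_table <- function(features, labels, path) {
  df <- as.data.frame(features, check.names = FALSE)
  df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    iristex_error(sprintf("cannot read feature table '%s'", path), "iristex_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  y <- as.integer(df$label)
  df$label <- NULL
  list(X = as.matrix(df), y = y)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of the full pipeline. `NULL` segmentation
#' configs mean the anatomical defaults of [locate_pupil()]/[locate_iris()].
#'
#' @param roi a [roi_spec()].
#' @param clahe a [clahe_params()], or `NULL` to skip enhancement.
#' @param wavelet wavelet name.
#' @param glcm_levels,glrlm_levels texture quantization levels.
#' @param relieff_k ReliefF neighbor count.
#' @param k_list feature-subset sizes to evaluate.
#' @param classifiers list of presets (default: full registry).
#' @param n_folds CV folds.
#' @param seed root seed for every stochastic stage.
#' @param pupil_config,iris_config optional [search_config()]s.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(roi = roi_spec(), clahe = clahe_params(),
                            wavelet = "haar", glcm_levels = 8L,
                            glrlm_levels = 16L, relieff_k = 10L,
                            k_list = c(25L, 50L, 75L),
                            classifiers = classifier_registry(),
                            n_folds = 5L, seed = 1L,
                            pupil_config = NULL, iris_config = NULL) {
  structure(list(roi = roi, clahe = clahe, wavelet = wavelet,
                 glcm_levels = glcm_levels, glrlm_levels = glrlm_levels,
                 relieff_k = relieff_k, k_list = k_list,
                 classifiers = classifiers, n_folds = n_folds, seed = seed,
                 pupil_config = pupil_config, iris_config = iris_config),
            class = "pipeline_config")
}

# Segment -> normalize -> crop -> enhance -> extract for one image.
image_to_features <- function(image, config) {
  geom <- segment_eye(image, config$pupil_config, config$iris_config)
  norm <- rubber_sheet(image, geom)
  roi <- crop_heart_roi(norm, config$roi)
  if (!is.null(config$clahe)) roi <- enhance_clahe(roi, config$clahe)
  list(features = extract_feature_vector(roi, wavelet = config$wavelet,
                                         glcm_levels = config$glcm_levels,
                                         glrlm_levels = config$glrlm_levels),
       geometry = geom)
}

#' Run the full screening pipeline on a cohort
#'
#' Executes segmentation, normalization, ROI cropping, enhancement and feature
#' extraction per image, then ReliefF ranking and cross-validated evaluation of
#' the configured classifier presets for each feature-subset size. Per-image
#' failures (e.g. segmentation not finding a boundary) are recorded in the run
#' manifest and the image is excluded; the run aborts only if every image
#' fails.
#'
#' @param images list of gray-level matrices, OR a `"synthetic_cohort"`, OR a
#'   data frame manifest with columns `filename` and `label` (paths read via
#'   [read_eye_image()], relative to `manifest_dir`).
#' @param labels 0/1 vector (ignored when `images` carries labels).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, `features.csv`,
#'   `ranking.json` and `report.json` are written there.
#' @param manifest_dir base directory of manifest file paths.
#' @return List with `features` (matrix), `labels`, `ranking`
#'   ([relieff_rank()]), `reports` (named list per subset size: data frame from
#'   [evaluate_registry()]), `manifest` (per-image status data frame).
#' @export
run_pipeline <- function(images, labels = NULL, config = pipeline_config(),
                         out_dir = NULL, manifest_dir = ".") {
  if (inherits(images, "synthetic_cohort")) {
    labels <- images$labels
    sources <- sprintf("synthetic_%03d", seq_along(images$images))
    images <- images$images
  } else if (is.data.frame(images)) {
    manifest_df <- images
    labels <- as.integer(manifest_df$label)
    sources <- as.character(manifest_df$filename)
    images <- lapply(file.path(manifest_dir, sources), read_eye_image)
  } else {
    sources <- sprintf("image_%03d", seq_along(images))
  }
  if (length(images) < 2 || is.null(labels) || length(unique(labels)) < 2) {
    iristex_error("need at least 2 images with both labels", "iristex_value_error")
  }

  rows <- vector("list", length(images))
  status <- character(length(images))
  for (i in seq_along(images)) {
    res <- tryCatch(image_to_features(images[[i]], config), error = identity)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      rows[i] <- list(NULL)
    } else {
      status[i] <- "ok"
      rows[[i]] <- res$features
    }
  }
  ok <- status == "ok"
  if (!any(ok)) iristex_error("every image failed a pipeline stage", "iristex_pipeline_error")
  manifest <- data.frame(source = sources, label = labels, status = status)

  X <- do.call(rbind, rows[ok])
  y <- labels[ok]
  k_nb <- min(config$relieff_k, min(table(y)) - 1L) # honour the per-class bound
  ranking <- relieff_rank(X, y, k_neighbors = k_nb, seed = config$seed)
  reports <- list()
  for (k in config$k_list) {
    k_use <- min(k, ncol(X))
    idx <- select_top(ranking, k_use)
    reports[[as.character(k)]] <- evaluate_registry(
      X[, idx, drop = FALSE], y, configs = config$classifiers,
      n_folds = config$n_folds, seed = config$seed)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_table(X, y, file.path(out_dir, "features.csv"))
    jsonlite::write_json(
      list(weights = unname(ranking$weights), order = ranking$order,
           selected = lapply(config$k_list, function(k)
             select_top(ranking, min(k, ncol(X))))),
      file.path(out_dir, "ranking.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(reports, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(manifest, file.path(out_dir, "run_manifest.csv"),
                     row.names = FALSE)
  }

  list(features = X, labels = y, ranking = ranking, reports = reports,
       manifest = manifest)
}
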