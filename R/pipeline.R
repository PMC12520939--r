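# fixed stage-keyed derivation of child seeds from the global run seed,
# kept below 2^31 so stages can be rerun in isolation
derive_seed <- function(seed, stage) {
  stage_id <- match(stage, c("simulate", "unmix", "phenotype",
                             "classify", "evaluate"))
  as.integer((as.double(seed) * 7919 + stage_id * 104729) %% 2147483629)
}

#' Default pipeline configuration
#'
#' One list with per-stage sections; \code{\link{run_pipeline}} accepts
#' the same structure from a YAML file. The default cohort is the
#' six-leukemia-class study design (AML M2-M5, B-ALL Ph- and Ph+), 30
#' cells per class.
#'
#' @param class_labels Classes simulated (subset of the shipped profile
#'   table).
#' @param cells_per_class Cells per class.
#' @param noise_sigma,background_level,intensity_cv Cohort noise model;
#'   see \code{\link{cohort_config}}.
#' @param lambda Unmixing penalty.
#' @param min_area Segmentation minimum component area (px).
#' @param A_pred,A_ortho OPLS-DA component counts (NULL = min(K-1, 2)).
#' @param k_folds Cross-validation folds.
#' @return Nested config list.
#' @export
pipeline_config <- function(class_labels = c("AML-M2", "AML-M3",
                                             "AML-M4", "AML-M5",
                                             "ALL-Ph-", "ALL-Ph+"),
                            cells_per_class = 30L,
                            noise_sigma = 0.02,
                            background_level = 0.02,
                            intensity_cv = 0.1,
                            lambda = 1e-3,
                            min_area = 30L,
                            A_pred = NULL, A_ortho = 1L,
                            k_folds = 7L) {
  list(cohort = list(class_labels = class_labels,
                     cells_per_class = cells_per_class,
                     noise_sigma = noise_sigma,
                     background_level = background_level,
                     intensity_cv = intensity_cv),
       unmix = list(lambda = lambda),
       phenotype = list(min_area = min_area),
       classify = list(A_pred = A_pred, A_ortho = A_ortho),
       evaluate = list(k_folds = k_folds))
}

read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (sec in names(base))
    for (key in names(y[[sec]]))
      base[[sec]][[key]] <- y[[sec]][[key]]
  base
}

#' Run the full in-silico phenotyping pipeline
#'
#' Executes simulate -> unmix -> phenotype -> classify -> evaluate as
#' one reproducible run. Every intermediate artifact is written under
#' \code{out_dir} (cohort TIFFs, chemical-map TIFFs, feature CSV,
#' model JSON, metrics JSON) together with a run manifest holding the
#' effective config, the seed, per-artifact MD5 hashes, stage timings
#' and the package version. The global seed fans out to fixed per-stage
#' child seeds; a rerun with the same config and seed reproduces the
#' truth CSV, feature CSV and metrics JSON byte for byte.
#'
#' Segmented cells are assigned class labels by greedy IoU matching
#' against the truth masks; unmatched segments are dropped from the
#' feature table (and counted in the manifest).
#'
#' @param config A config list from \code{\link{pipeline_config}} or a
#'   YAML path with the same structure.
#' @param out_dir Output directory.
#' @param seed Integer global seed.
#' @param quiet Suppress stage messages.
#' @return The run manifest (list), invisibly; also written to
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = 42L, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]

  # -- simulate ------------------------------------------------------
  t0 <- tic()
  profiles <- default_class_profiles()
  sel <- match(config$cohort$class_labels, profiles$class_label)
  if (anyNA(sel))
    stop("unknown class labels in config", call. = FALSE)
  ccfg <- cohort_config(classes = profiles[sel, ],
                        cells_per_class = config$cohort$cells_per_class,
                        noise_sigma = config$cohort$noise_sigma,
                        background_level = config$cohort$background_level,
                        intensity_cv = config$cohort$intensity_cv,
                        seed = derive_seed(seed, "simulate"))
  library <- synthetic_library()
  cohort_dir <- file.path(out_dir, "cohort")
  say("stage simulate: %d classes x %d cells", length(sel),
      ccfg$cells_per_class)
  cohort <- generate_cohort(ccfg, cohort_dir, library)
  truth <- utils::read.csv(file.path(cohort_dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  timings$simulate <- tic() - t0

  # -- unmix + phenotype per field -----------------------------------
  t0 <- tic()
  ucfg <- unmix_config(lambda = config$unmix$lambda)
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  feats <- list()
  n_unmatched <- 0L
  for (fld in cohort$classes) {
    img <- read_hyperspectral_tiff(file.path(cohort_dir, fld$image))
    maps <- unmix_image(img, library, ucfg)
    map_path <- file.path(maps_dir, paste0("maps_", fld$image))
    write_maps_tiff(maps, map_path)
    tmask <- read_mask_tiff(file.path(cohort_dir, fld$mask))
    mask <- segment_cells(maps, min_area = config$phenotype$min_area)
    ft <- extract_features(mask, maps, source_image = fld$image)
    mm <- match_cells_to_truth(mask, tmask)
    m <- mm$matches
    ft$class <- truth$class[match(m$truth_id[match(ft$cell_id, m$cell_id)],
                                  truth$cell_id)]
    ft$truth_id <- m$truth_id[match(ft$cell_id, m$cell_id)]
    n_unmatched <- n_unmatched + sum(is.na(ft$class))
    feats[[fld$class_label]] <- ft[!is.na(ft$class), ]
  }
  features <- do.call(rbind, feats)
  features$cell_id <- features$truth_id   # cohort-unique ids
  features$truth_id <- NULL
  rownames(features) <- NULL
  features <- features[order(features$cell_id), ]
  feat_path <- file.path(out_dir, "features.csv")
  write_feature_csv(features, feat_path)
  say("stage phenotype: %d cells (%d segments unmatched)",
      nrow(features), n_unmatched)
  timings$unmix_phenotype <- tic() - t0

  # -- classify ------------------------------------------------------
  t0 <- tic()
  resub <- resubstitution_metrics(features, features$class,
                                  A_pred = config$classify$A_pred,
                                  A_ortho = config$classify$A_ortho)
  write_oplsda_json(resub$model, file.path(out_dir, "model.json"))
  sc <- scores_plot_data(resub$model, features$class)
  utils::write.csv(sc, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  timings$classify <- tic() - t0

  # -- evaluate ------------------------------------------------------
  t0 <- tic()
  cv <- cross_validate(features, features$class,
                       k = config$evaluate$k_folds,
                       A_pred = config$classify$A_pred,
                       A_ortho = config$classify$A_ortho,
                       seed = derive_seed(seed, "evaluate"))
  metrics <- list(
    n_cells = nrow(features),
    classes = sort(unique(features$class)),
    resubstitution = list(
      accuracy = resub$metrics$total_accuracy,
      precision = as.list(resub$metrics$precision),
      sensitivity = as.list(resub$metrics$sensitivity),
      confusion = unclass(resub$confusion)),
    cross_validation = list(
      k = cv$k,
      accuracy = cv$metrics$total_accuracy,
      precision = as.list(cv$metrics$precision),
      sensitivity = as.list(cv$metrics$sensitivity),
      confusion = unclass(cv$confusion)))
  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(unclass(cv$confusion)),
                   file.path(out_dir, "confusion_cv.csv"))
  say("stage evaluate: resubstitution %.3f, %d-fold CV %.3f",
      resub$metrics$total_accuracy, cv$k, cv$metrics$total_accuracy)
  timings$evaluate <- tic() - t0

  # -- manifest ------------------------------------------------------
  arts <- c(file.path("cohort", "truth.csv"), "features.csv",
            "model.json", "metrics.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, arts)))
  names(hashes) <- arts
  manifest <- list(package_version =
                     as.character(utils::packageVersion("srspheno")),
                   seed = seed, config = config,
                   stage_seeds = list(
                     simulate = derive_seed(seed, "simulate"),
                     evaluate = derive_seed(seed, "evaluate")),
                   timings_sec = timings,
                   unmatched_segments = n_unmatched,
                   artifact_md5 = hashes,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
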