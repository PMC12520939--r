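#' Default class-profile table for the synthetic cohort generator
#'
#' Loads the editable YAML shipped in \code{inst/extdata/class_profiles.yaml}.
#' Eleven hematopoietic populations are parameterized: four FAB AML
#' subtypes (M2-M5), two B-ALL groups (Philadelphia-chromosome negative
#' and positive) and five normal populations (HSPC, granulocyte,
#' monocyte, B cell, T cell). Mean per-pixel abundances (a.u., on the
#' unit-norm reference scale) encode the qualitative contrasts the
#' biology implies: AML blasts carry more protein and lipid and less
#' nucleic acid than granulocytes; M5 exceeds monocytes in all four
#' components; M3 has the highest unsaturated and M5 the highest
#' saturated lipid among AML subtypes; ALL cells are lipid-poor relative
#' to every AML subtype, with Ph+ at least as unsaturated-lipid-rich as
#' Ph-. Magnitudes are simulator plumbing, not measured values.
#'
#' @param path Optional path to an alternative YAML.
#' @return data.frame with columns \code{class_label}, the four mean
#'   abundances, \code{cv_abundance}, \code{mean_radius_px},
#'   \code{cv_radius}.
#' @export
default_class_profiles <- function(path = system.file(
    "extdata", "class_profiles.yaml", package = "srspheno")) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$classes, function(cl) {
    data.frame(class_label = cl$class_label,
               protein = cl$mean_abundance[[1]],
               nucleic_acid = cl$mean_abundance[[2]],
               unsaturated_lipid = cl$mean_abundance[[3]],
               saturated_lipid = cl$mean_abundance[[4]],
               cv_abundance = cl$cv_abundance,
               mean_radius_px = cl$mean_radius_px,
               cv_radius = cl$cv_radius,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort configuration
#'
#' @param classes Profile data.frame as from
#'   \code{\link{default_class_profiles}} (any subset of rows).
#' @param cells_per_class Cells simulated per class (>= 1).
#' @param image_size \code{c(H, W)} pixels of each rendered field.
#' @param noise_sigma Additive i.i.d. Gaussian noise s.d. per channel
#'   (a.u.); approximates shot-noise-limited SRS detection.
#' @param background_level Constant background intensity (a.u.).
#' @param intensity_cv CV of the per-cell multiplicative global
#'   intensity factor emulating inter-sample (patient) variation; 0
#'   disables it.
#' @param seed Integer seed; all randomness derives from it.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(classes = default_class_profiles(),
                          cells_per_class = 30L,
                          image_size = c(320L, 320L),
                          noise_sigma = 0.02,
                          background_level = 0.02,
                          intensity_cv = 0.1,
                          seed = 1L) {
  stopifnot(cells_per_class >= 1L, noise_sigma >= 0,
            background_level >= 0, intensity_cv >= 0,
            length(image_size) == 2L)
  if (any(classes$cv_abundance <= 0 | classes$cv_abundance > 1) ||
      any(classes$cv_radius <= 0 | classes$cv_radius > 1))
    stop("cv values must lie in (0, 1]", call. = FALSE)
  if (any(classes$mean_radius_px < 2))
    stop("mean_radius_px must be >= 2", call. = FALSE)
  if (any(classes[, SRS_COMPONENTS] < 0))
    stop("mean abundances must be nonnegative", call. = FALSE)
  structure(list(classes = classes,
                 cells_per_class = as.integer(cells_per_class),
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma,
                 background_level = background_level,
                 intensity_cv = intensity_cv,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' The YAML mirrors \code{\link{cohort_config}}; a \code{classes} block
#' (same schema as \code{class_profiles.yaml}) is optional and defaults
#' to the shipped profile table, optionally subset via
#' \code{class_labels}.
#'
#' @param path YAML path.
#' @return A \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- if (!is.null(y$classes)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(list(classes = y$classes), tmp)
    default_class_profiles(tmp)
  } else default_class_profiles()
  if (!is.null(y$class_labels)) {
    miss <- setdiff(y$class_labels, classes$class_label)
    if (length(miss))
      stop("unknown class labels in config: ",
           paste(miss, collapse = ", "), call. = FALSE)
    classes <- classes[match(y$class_labels, classes$class_label), ]
  }
  args <- y[intersect(names(y), c("cells_per_class", "image_size",
                                  "noise_sigma", "background_level",
                                  "intensity_cv", "seed"))]
  args$classes <- classes
  do.call(cohort_config, args)
}

# mean/cv -> log-normal parameters (mean preserved exactly)
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample per-cell ground truth for one class
#'
#' Per-cell abundances and radii are drawn log-normally around the
#' profile means with the profile CVs (nonnegative, right-skewed
#' cell-to-cell variation). An optional multiplicative global intensity
#' factor (log-normal, CV \code{intensity_cv}) scales all four
#' abundances of a cell jointly, emulating inter-sample intensity
#' variation; the factor is folded into the recorded true abundances.
#'
#' @param profile One row of a class-profile data.frame.
#' @param n Number of cells (>= 1).
#' @param seed Integer seed.
#' @param intensity_cv CV of the global intensity factor (0 = off).
#' @return data.frame with \code{cell_id}, \code{class_label},
#'   \code{radius_px} and the four true abundances; centers and areas
#'   are assigned at render time.
#' @export
sample_cells <- function(profile, n, seed, intensity_cv = 0.1) {
  stopifnot(n >= 1L)
  withr::with_seed(as.integer(seed), {
    ab <- sapply(SRS_COMPONENTS, function(cmp) {
      mu <- profile[[cmp]]
      if (mu <= 0) return(rep(0, n))
      p <- lnorm_pars(mu, profile$cv_abundance)
      stats::rlnorm(n, p$meanlog, p$sdlog)
    })
    ab <- matrix(ab, nrow = n, dimnames = list(NULL, SRS_COMPONENTS))
    if (intensity_cv > 0) {
      p <- lnorm_pars(1, intensity_cv)
      ab <- ab * stats::rlnorm(n, p$meanlog, p$sdlog)
    }
    pr <- lnorm_pars(profile$mean_radius_px, profile$cv_radius)
    rad <- pmax(2, stats::rlnorm(n, pr$meanlog, pr$sdlog))
    data.frame(cell_id = seq_len(n), class_label = profile$class_label,
               radius_px = rad, ab, stringsAsFactors = FALSE)
  })
}

# non-overlapping disk placement by rejection sampling
place_cells <- function(radii, H, W, max_attempts = 1000L) {
  n <- length(radii)
  rows <- cols <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    if (2 * r + 2 > min(H, W))
      stop("placement-failure: cell radius exceeds field size",
           call. = FALSE)
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cr <- stats::runif(1, r + 1, H - r)
      cc <- stats::runif(1, r + 1, W - r)
      if (i == 1L ||
          all(sqrt((rows[seq_len(i - 1)] - cr)^2 +
                   (cols[seq_len(i - 1)] - cc)^2) >
              radii[seq_len(i - 1)] + r + 1)) {
        rows[i] <- cr; cols[i] <- cc; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("placement-failure: could not place all cells without overlap",
           call. = FALSE)
  }
  cbind(row = rows, col = cols)
}

#' Render one field: hyperspectral stack plus truth mask
#'
#' The forward model inverted by the unmixing stage: inside a cell each
#' pixel's spectrum is the library mix of that cell's true abundances
#' plus background and additive Gaussian channel noise; outside cells it
#' is background plus noise. Cells are filled disks placed without
#' overlap by rejection sampling (at most 1000 attempts per cell).
#'
#' @param cells data.frame from \code{\link{sample_cells}} (one or more
#'   classes row-bound; \code{cell_id} must be unique).
#' @param library A \code{spectral_library}.
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer seed for placement and noise.
#' @return list with \code{image} (\code{hyperspectral_image}),
#'   \code{truth_mask} (integer matrix, 0 = background, values =
#'   \code{cell_id}) and \code{cells} (input data.frame with added
#'   \code{center_row}, \code{center_col}, \code{true_area_px};
#'   0-based centers).
#' @export
render_field <- function(cells, library, config, seed) {
  H <- config$image_size[1]; W <- config$image_size[2]
  C <- library$axis$n_channels
  X <- library$matrix
  withr::with_seed(as.integer(seed), {
    pos <- if (nrow(cells) > 0) place_cells(cells$radius_px, H, W)
           else matrix(0, 0, 2)
    mask <- matrix(0L, H, W)
    area <- integer(nrow(cells))
    rr <- matrix(seq_len(H), H, W)         # 1-based grid
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(nrow(cells))) {
      inside <- (rr - pos[i, 1])^2 + (cc - pos[i, 2])^2 <=
        cells$radius_px[i]^2
      mask[inside] <- cells$cell_id[i]
      area[i] <- sum(inside)
    }
    cube <- array(stats::rnorm(H * W * C, config$background_level,
                               config$noise_sigma), c(H, W, C))
    if (nrow(cells) > 0) {
      idx <- which(mask > 0)
      ab <- as.matrix(cells[match(mask[idx], cells$cell_id),
                            SRS_COMPONENTS])
      sig <- ab %*% t(X)                   # n_px x C pure signal
      for (k in seq_len(C)) {
        plane <- cube[, , k]
        plane[idx] <- plane[idx] + sig[, k]
        cube[, , k] <- plane
      }
    }
    cells$center_row <- pos[, 1] - 1       # 0-based convention
    cells$center_col <- pos[, 2] - 1
    cells$true_area_px <- area
    list(image = hyperspectral_image(cube, library$axis),
         truth_mask = mask, cells = cells)
  })
}

#' Generate a seeded synthetic cohort on disk
#'
#' Renders one field per class (all of that class's cells in one image),
#' writing per-field hyperspectral TIFF stacks with axis sidecars, truth
#' label-mask TIFFs, a truth CSV
#' (\code{cell_id,class,protein,nucleic_acid,unsaturated_lipid,saturated_lipid,area_px})
#' and a manifest JSON. Cell ids are unique across the cohort.
#' Deterministic for a fixed config seed.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param out_dir Output directory (created if needed).
#' @param library Spectral library; default synthetic standards.
#' @return The manifest as a list (also written to
#'   \code{manifest.json}): per-field file paths plus the truth CSV path.
#' @export
generate_cohort <- function(config, out_dir,
                            library = synthetic_library()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- config$classes
  fields <- list()
  truth <- list()
  offset <- 0L
  for (i in seq_len(nrow(classes))) {
    cls <- classes$class_label[i]
    cells <- sample_cells(classes[i, ], config$cells_per_class,
                          seed = config$seed + 101L * i,
                          intensity_cv = config$intensity_cv)
    cells$cell_id <- cells$cell_id + offset
    offset <- offset + nrow(cells)
    fld <- render_field(cells, library, config,
                        seed = config$seed + 101L * i + 50L)
    tag <- sprintf("%02d_%s", i, gsub("\\+", "pos",
                   gsub("-", "neg", gsub("[^A-Za-z0-9+-]+", "_", cls))))
    img_path <- file.path(out_dir, paste0("field_", tag, ".tif"))
    msk_path <- file.path(out_dir, paste0("mask_", tag, ".tif"))
    write_hyperspectral_tiff(fld$image, img_path)
    write_mask_tiff(fld$truth_mask, msk_path)
    fields[[cls]] <- list(class_label = cls, image = basename(img_path),
                          mask = basename(msk_path))
    truth[[cls]] <- data.frame(cell_id = fld$cells$cell_id,
                               class = fld$cells$class_label,
                               fld$cells[, SRS_COMPONENTS],
                               area_px = fld$cells$true_area_px,
                               stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  manifest <- list(seed = config$seed,
                   cells_per_class = config$cells_per_class,
                   image_size = config$image_size,
                   noise_sigma = config$noise_sigma,
                   background_level = config$background_level,
                   intensity_cv = config$intensity_cv,
                   classes = unname(fields),
                   truth_csv = "truth.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
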