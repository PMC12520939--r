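#' Chemical components resolved by the unmixing model
#'
#' Fixed component order used everywhere in the package: protein
#' (BSA-like CH3 band), nucleic acid, unsaturated lipid (triolein-like,
#' =C-H band near 3010 cm-1) and saturated lipid (palmitic-acid-like CH2
#' band near 2850 cm-1).
#'
#' @format Character vector of length 4.
#' @export
SRS_COMPONENTS <- c("protein", "nucleic_acid", "unsaturated_lipid",
                    "saturated_lipid")

#' Build an evenly spaced spectral axis
#'
#' Defines the Raman-shift axis of a hyperspectral stack. The default
#' acquisition window is the C-H stretch region, 2800-3050 cm-1, where
#' lipids (CH2 ~2850, =C-H ~3010), proteins (CH3 ~2930) and nucleic acids
#' (~2955) have strong overlapping bands.
#'
#' @param start_cm1 First Raman shift (cm-1); must be < \code{end_cm1}.
#' @param end_cm1 Last Raman shift (cm-1), included in the axis.
#' @param n_channels Number of channels (>= 2).
#' @return A \code{spectral_axis} object: list with \code{wavenumbers}
#'   (strictly increasing numeric vector) and \code{n_channels}.
#' @examples
#' ax <- spectral_axis(2800, 3050, 126)
#' diff(ax$wavenumbers)[1]  # 2 cm-1 spacing
#' @export
spectral_axis <- function(start_cm1 = 2800, end_cm1 = 3050,
                          n_channels = 126L) {
  if (!is.numeric(start_cm1) || !is.numeric(end_cm1) ||
      length(start_cm1) != 1L || length(end_cm1) != 1L)
    stop("axis bounds must be single numbers", call. = FALSE)
  if (start_cm1 >= end_cm1)
    stop("invalid spectral axis: start_cm1 must be < end_cm1", call. = FALSE)
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L)
    stop("invalid spectral axis: n_channels must be >= 2", call. = FALSE)
  structure(list(wavenumbers = seq(start_cm1, end_cm1,
                                   length.out = n_channels),
                 n_channels = n_channels),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("spectral_axis: %d channels, %.1f-%.1f cm-1\n",
              x$n_channels, min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_channels == b$n_channels &&
    max(abs(a$wavenumbers - b$wavenumbers)) < tol
}

new_reference_spectrum <- function(component_name, axis, intensities,
                                   normalization = c("raw", "l2")) {
  normalization <- match.arg(normalization)
  component_name <- match.arg(component_name, SRS_COMPONENTS)
  intensities <- as.numeric(intensities)
  if (length(intensities) != axis$n_channels)
    stop("intensities length must equal axis n_channels", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("reference intensities must be finite and nonnegative",
         call. = FALSE)
  structure(list(component_name = component_name, axis = axis,
                 intensities = intensities,
                 normalization = normalization),
            class = "reference_spectrum")
}

#' Synthesize an idealized reference spectrum
#'
#' Builds a standard's spectrum as a sum of Gaussian bands on a given
#' axis. Used to emulate measured standards (BSA, DNA, triolein,
#' palmitic acid) when no instrument data are at hand; the default band
#' tables in \code{\link{default_peak_table}} follow standard C-H stretch
#' assignments and are free parameters, not measured values.
#'
#' @param component_name One of \code{SRS_COMPONENTS}.
#' @param axis A \code{\link{spectral_axis}}.
#' @param peaks Numeric matrix (or coercible list) with columns
#'   \code{center} (cm-1), \code{width} (Gaussian sigma, cm-1, > 0) and
#'   \code{height} (a.u., > 0); one row per band.
#' @return A \code{reference_spectrum} with \code{normalization = "raw"}.
#' @export
synthesize_reference_spectrum <- function(component_name, axis, peaks) {
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, peaks)
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 1L)
    stop("peaks must contain at least one band", call. = FALSE)
  if (ncol(peaks) != 3L)
    stop("peaks must have columns center, width, height", call. = FALSE)
  if (any(peaks[, 2] <= 0) || any(peaks[, 3] <= 0))
    stop("peak widths and heights must be > 0", call. = FALSE)
  nu <- axis$wavenumbers
  y <- numeric(length(nu))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks[i, 3] * exp(-0.5 * ((nu - peaks[i, 1]) / peaks[i, 2])^2)
  new_reference_spectrum(component_name, axis, y, "raw")
}

#' Default Gaussian band tables for the four standards
#'
#' Band positions follow the usual C-H stretch assignments: CH2
#' symmetric stretch near 2850 cm-1 (lipid acyl chains), CH2 asymmetric
#' shoulder near 2880, CH3 stretch near 2930 (protein), a nucleic-acid
#' band near 2955 and the olefinic =C-H stretch near 3010 cm-1 that
#' singles out unsaturated lipids. Heights and widths are arbitrary
#' units chosen so the four columns are mutually distinguishable.
#'
#' @return Named list (one entry per component) of 3-column matrices
#'   \code{(center, width, height)}.
#' @export
default_peak_table <- function() {
  list(
    protein = rbind(c(2930, 15, 1.00), c(2880, 22, 0.35),
                    c(2975, 14, 0.30)),
    nucleic_acid = rbind(c(2955, 13, 1.00), c(2900, 20, 0.35),
                         c(3020, 18, 0.15)),
    unsaturated_lipid = rbind(c(2850, 14, 0.80), c(3010, 11, 0.65),
                              c(2895, 18, 0.30)),
    saturated_lipid = rbind(c(2850, 11, 1.00), c(2880, 11, 0.50),
                            c(2930, 14, 0.20))
  )
}

#' Assemble a four-component spectral library
#'
#' Resamples one reference spectrum per component onto a common axis by
#' linear interpolation (zero outside the source span), l2-normalizes
#' each column and checks that the four columns are linearly
#' independent. The resulting matrix is the design matrix of the
#' pixel-wise unmixing problem.
#'
#' @param specs List of exactly 4 \code{reference_spectrum} objects, one
#'   per component (any order; stored in canonical component order).
#' @param target_axis \code{\link{spectral_axis}} of the library.
#' @return A \code{spectral_library}: list with \code{axis},
#'   \code{references} (canonically ordered), and \code{matrix}
#'   (\code{n_channels x 4}, unit-norm columns named by component).
#' @export
assemble_library <- function(specs, target_axis) {
  if (length(specs) != 4L)
    stop("exactly one reference spectrum per component is required",
         call. = FALSE)
  comps <- vapply(specs, function(s) s$component_name, character(1))
  if (anyDuplicated(comps) || !setequal(comps, SRS_COMPONENTS))
    stop("specs must cover each of the 4 components exactly once",
         call. = FALSE)
  specs <- specs[match(SRS_COMPONENTS, comps)]
  nu <- target_axis$wavenumbers
  cols <- lapply(specs, function(s) {
    y <- stats::approx(s$axis$wavenumbers, s$intensities, xout = nu,
                       method = "linear", rule = 1)$y
    y[is.na(y)] <- 0
    nrm <- sqrt(sum(y^2))
    if (nrm == 0)
      stop("degenerate library: a reference is zero on the target axis",
           call. = FALSE)
    y / nrm
  })
  X <- do.call(cbind, cols)
  colnames(X) <- SRS_COMPONENTS
  if (min(svd(X, nu = 0, nv = 0)$d) <= 1e-6)
    stop("degenerate library: reference spectra are not linearly independent",
         call. = FALSE)
  refs <- lapply(seq_len(4L), function(k)
    new_reference_spectrum(SRS_COMPONENTS[k], target_axis, X[, k], "l2"))
  structure(list(axis = target_axis, references = refs, matrix = X),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: 4 components x %d channels (%.0f-%.0f cm-1)\n",
              x$axis$n_channels, min(x$axis$wavenumbers),
              max(x$axis$wavenumbers)))
  invisible(x)
}

#' Build the default synthetic library
#'
#' Convenience wrapper: synthesizes the four standards from
#' \code{\link{default_peak_table}} on \code{axis} and assembles them.
#'
#' @param axis \code{\link{spectral_axis}}; default C-H window axis.
#' @param peak_table Band tables as in \code{\link{default_peak_table}}.
#' @return A \code{spectral_library}.
#' @examples
#' lib <- synthetic_library()
#' round(crossprod(lib$matrix), 2)  # unit diagonal, off-diagonal overlap
#' @export
synthetic_library <- function(axis = spectral_axis(),
                              peak_table = default_peak_table()) {
  specs <- lapply(SRS_COMPONENTS, function(cmp)
    synthesize_reference_spectrum(cmp, axis, peak_table[[cmp]]))
  assemble_library(specs, axis)
}

#' Read a reference spectrum from CSV
#'
#' Expects a UTF-8 CSV with header \code{wavenumber_cm1,intensity}.
#'
#' @param path File path.
#' @param component_name One of \code{SRS_COMPONENTS}.
#' @return A raw \code{reference_spectrum} on the file's own axis.
#' @export
read_spectrum_csv <- function(path, component_name) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavenumber_cm1", "intensity") %in% names(d)))
    stop("spectrum CSV needs columns wavenumber_cm1,intensity: ", path,
         call. = FALSE)
  o <- order(d$wavenumber_cm1)
  wn <- d$wavenumber_cm1[o]
  ax <- structure(list(wavenumbers = wn, n_channels = length(wn)),
                  class = "spectral_axis")
  if (length(wn) < 2L || any(diff(wn) <= 0))
    stop("spectrum CSV wavenumbers must be distinct: ", path, call. = FALSE)
  new_reference_spectrum(component_name, ax, d$intensity[o], "raw")
}

#' Write a reference spectrum to CSV
#'
#' @param spec A \code{reference_spectrum}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavenumber_cm1 = spec$axis$wavenumbers,
                              intensity = spec$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a spectral library from a JSON manifest
#'
#' The manifest maps each component to a spectrum CSV and defines the
#' target axis:
#' \code{{"axis": {"start_cm1":..,"end_cm1":..,"n_channels":..},
#' "spectra": {"protein": "bsa.csv", ...}}}. Relative paths resolve
#' against the manifest's directory.
#'
#' @param path Manifest JSON path.
#' @return A \code{spectral_library}.
#' @export
read_library_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ax <- spectral_axis(m$axis$start_cm1, m$axis$end_cm1, m$axis$n_channels)
  base <- dirname(normalizePath(path))
  specs <- lapply(SRS_COMPONENTS, function(cmp) {
    f <- m$spectra[[cmp]]
    if (is.null(f)) stop("manifest missing component: ", cmp, call. = FALSE)
    if (!file.exists(f)) f <- file.path(base, f)
    read_spectrum_csv(f, cmp)
  })
  assemble_library(specs, ax)
}
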