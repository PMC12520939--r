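#' Construct a hyperspectral image
#'
#' @param data H x W x C numeric array of intensities (a.u.); finite.
#' @param axis \code{\link{spectral_axis}} with \code{C} channels.
#' @return A \code{hyperspectral_image} object.
#' @export
hyperspectral_image <- function(data, axis) {
  if (length(dim(data)) != 3L)
    stop("data must be an H x W x C array", call. = FALSE)
  if (dim(data)[3] != axis$n_channels)
    stop("third dimension must equal axis n_channels", call. = FALSE)
  if (any(!is.finite(data)))
    stop("hyperspectral data must be finite", call. = FALSE)
  structure(list(data = data, axis = axis), class = "hyperspectral_image")
}

#' @export
print.hyperspectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyperspectral_image: %d x %d px, %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# tiff::writeTIFF stores samples in [0,1]; intensities are rescaled by a
# per-file factor recorded in the sidecar JSON so arbitrary nonnegative
# (or signed) values round-trip at 32-bit float precision.
#' Write a hyperspectral stack as a multi-page 32-bit TIFF
#'
#' One page per channel, page order = ascending wavenumber. The spectral
#' axis and the intensity scale factor are stored in a sidecar JSON at
#' \code{paste0(path, ".json")}.
#'
#' @param img A \code{\link{hyperspectral_image}}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_hyperspectral_tiff <- function(img, path) {
  d <- img$data
  lo <- min(d); hi <- max(d)
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(seq_len(dim(d)[3]),
                  function(k) (d[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "hyperspectral_stack",
         axis = list(start_cm1 = min(img$axis$wavenumbers),
                     end_cm1 = max(img$axis$wavenumbers),
                     n_channels = img$axis$n_channels),
         offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hyperspectral stack written by \code{write_hyperspectral_tiff}
#'
#' @param path TIFF path; the sidecar JSON \code{paste0(path, ".json")}
#'   must be present.
#' @return A \code{\link{hyperspectral_image}}.
#' @export
read_hyperspectral_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing axis sidecar JSON: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  cube <- array(0, c(H, W, length(pages)))
  for (k in seq_along(pages))
    cube[, , k] <- pages[[k]] * meta$scale + meta$offset
  ax <- spectral_axis(meta$axis$start_cm1, meta$axis$end_cm1,
                      meta$axis$n_channels)
  hyperspectral_image(cube, ax)
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param mask Integer matrix; 0 = background, k >= 1 = cell k.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535L)
    stop("label mask exceeds 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit label mask TIFF
#'
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write chemical maps as a 5-page 32-bit TIFF
#'
#' Pages 1-4 are the component coefficient maps in canonical order,
#' page 5 the per-pixel RMS reconstruction residual; scale metadata in a
#' sidecar JSON.
#'
#' @param maps A \code{chemical_maps} object (see
#'   \code{\link{unmix_image}}).
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_maps_tiff <- function(maps, path) {
  stk <- c(lapply(seq_len(4L), function(k) maps$maps[, , k]),
           list(maps$residual))
  lo <- min(vapply(stk, min, 0)); hi <- max(vapply(stk, max, 0))
  scale <- max(hi - lo, 1e-12)
  tiff::writeTIFF(lapply(stk, function(m) (m - lo) / scale), path,
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "chemical_maps", components = SRS_COMPONENTS,
         lambda = maps$lambda_used, offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read chemical maps written by \code{write_maps_tiff}
#'
#' @param path TIFF path with sidecar JSON.
#' @return A \code{chemical_maps} object.
#' @export
read_maps_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  cube <- array(0, c(H, W, 4L))
  for (k in 1:4) cube[, , k] <- pages[[k]] * meta$scale + meta$offset
  res <- pages[[5]] * meta$scale + meta$offset
  new_chemical_maps(cube, meta$lambda, res)
}
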