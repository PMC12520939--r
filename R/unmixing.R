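#' Unmixing configuration
#'
#' Controls the penalized least-squares problem solved per pixel:
#' \deqn{\hat c = \arg\min_c \tfrac12 \|s - X c\|_2^2 + \lambda \|c\|_1,
#'       \quad c \ge 0 \textrm{ (when nonnegative)}}
#' where \eqn{X} is the unit-norm 4-column reference library and \eqn{s}
#' the pixel spectrum.
#'
#' @param lambda L1 penalty, >= 0. The default 1e-3 is relative to
#'   unit-norm references and unit-scale spectra.
#' @param nonnegative Clamp coefficients at zero (default); biomolecular
#'   abundances are physically nonnegative.
#' @param max_iter Maximum coordinate-descent sweeps (>= 1).
#' @param tol Convergence tolerance on the maximum coefficient change
#'   per sweep (> 0); the tight default makes pure standards recover
#'   their unit coefficient to well below 1e-8.
#' @return An \code{unmix_config} list.
#' @export
unmix_config <- function(lambda = 1e-3, nonnegative = TRUE,
                         max_iter = 1000L, tol = 1e-10) {
  stopifnot(lambda >= 0, max_iter >= 1L, tol > 0)
  structure(list(lambda = lambda, nonnegative = isTRUE(nonnegative),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "unmix_config")
}

# Cyclic coordinate descent with soft-thresholding, vectorized over
# pixels: S is C x N (one column per pixel). Coordinate order is the
# fixed library component order, so the solver is fully deterministic.
# Each update minimizes the objective exactly in one coordinate, so the
# objective is nonincreasing across sweeps.
cd_lasso <- function(S, X, lambda, nonnegative, max_iter, tol) {
  G <- crossprod(X)                     # 4 x 4 Gram
  B <- crossprod(X, S)                  # 4 x N
  p <- ncol(X); N <- ncol(S)
  C <- matrix(0, p, N)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(p)) {
      rk <- B[k, ] - G[k, -k, drop = FALSE] %*% C[-k, , drop = FALSE]
      ck <- if (nonnegative) {
        pmax(0, (rk - lambda) / G[k, k])
      } else {
        sign(rk) * pmax(0, abs(rk) - lambda) / G[k, k]
      }
      delta <- max(delta, max(abs(ck - C[k, ])))
      C[k, ] <- ck
    }
    if (delta < tol) break
  }
  C
}

#' Unmix a single pixel spectrum
#'
#' Solves the sparsity-constrained (LASSO) unmixing problem for one
#' spectrum by cyclic coordinate descent with soft-thresholding and,
#' by default, nonnegative clamping.
#'
#' @param spectrum Numeric vector, length = library channel count;
#'   finite.
#' @param library A \code{spectral_library}.
#' @param cfg An \code{\link{unmix_config}}.
#' @return Named 4-vector of abundance coefficients in canonical
#'   component order.
#' @examples
#' lib <- synthetic_library(spectral_axis(2800, 3050, 51))
#' lasso_unmix_pixel(lib$matrix[, 1], lib, unmix_config(lambda = 0))
#' @export
lasso_unmix_pixel <- function(spectrum, library, cfg = unmix_config()) {
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != library$axis$n_channels)
    stop("spectrum length must equal library channel count",
         call. = FALSE)
  if (any(!is.finite(spectrum)))
    stop("spectrum must be finite", call. = FALSE)
  c_hat <- cd_lasso(matrix(spectrum, ncol = 1), library$matrix,
                    cfg$lambda, cfg$nonnegative, cfg$max_iter, cfg$tol)
  stats::setNames(as.numeric(c_hat), SRS_COMPONENTS)
}

new_chemical_maps <- function(cube, lambda_used, residual) {
  dimnames(cube) <- list(NULL, NULL, SRS_COMPONENTS)
  structure(list(maps = cube, lambda_used = lambda_used,
                 residual = residual),
            class = "chemical_maps")
}

#' @export
print.chemical_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("chemical_maps: %d x %d px, 4 components, lambda = %g\n",
              d[1], d[2], x$lambda_used))
  invisible(x)
}

#' Pixel-wise LASSO unmixing of a hyperspectral image
#'
#' Applies \code{\link{lasso_unmix_pixel}} independently to every pixel
#' (no spatial coupling), producing one coefficient map per component
#' plus a per-pixel RMS reconstruction-residual image. The image axis
#' must equal the library axis exactly; no silent resampling.
#'
#' @param img A \code{\link{hyperspectral_image}}.
#' @param library A \code{spectral_library} on the same axis.
#' @param cfg An \code{\link{unmix_config}}.
#' @return A \code{chemical_maps} object: \code{maps} (H x W x 4 array,
#'   canonical order), \code{lambda_used}, \code{residual} (H x W RMS).
#' @export
unmix_image <- function(img, library, cfg = unmix_config()) {
  if (!axes_equal(img$axis, library$axis))
    stop("image axis must equal library axis (no silent resampling)",
         call. = FALSE)
  d <- dim(img$data)
  H <- d[1]; W <- d[2]; C <- d[3]
  S <- t(matrix(img$data, H * W, C))     # C x N
  Cmat <- cd_lasso(S, library$matrix, cfg$lambda, cfg$nonnegative,
                   cfg$max_iter, cfg$tol)
  R <- S - library$matrix %*% Cmat
  rms <- sqrt(colMeans(R^2))
  cube <- array(t(Cmat), c(H, W, 4L))
  new_chemical_maps(cube, cfg$lambda, matrix(rms, H, W))
}

#' Reconstruction quality report
#'
#' Scalar QC summaries of an unmixing result: mean and 95th-percentile
#' per-pixel RMS residual against the given image, and the fraction of
#' pixels whose largest coefficient reaches \code{sat_level} — a
#' heuristic flag for implausibly strong mixes on the unit-norm
#' reference scale.
#'
#' @param maps \code{chemical_maps}.
#' @param library \code{spectral_library} used for the fit.
#' @param img The unmixed \code{\link{hyperspectral_image}}.
#' @param sat_level Coefficient level regarded as saturated (a.u.).
#' @return list with \code{mean_residual}, \code{p95_residual},
#'   \code{frac_saturated}.
#' @export
reconstruction_report <- function(maps, library, img, sat_level = 1.5) {
  d <- dim(img$data)
  if (!all(dim(maps$maps)[1:2] == d[1:2]))
    stop("map and image dimensions differ", call. = FALSE)
  S <- t(matrix(img$data, d[1] * d[2], d[3]))
  Cmat <- t(matrix(maps$maps, d[1] * d[2], 4L))
  rms <- sqrt(colMeans((S - library$matrix %*% Cmat)^2))
  peak <- apply(Cmat, 2, max)
  list(mean_residual = mean(rms),
       p95_residual = as.numeric(stats::quantile(rms, 0.95)),
       frac_saturated = mean(peak >= sat_level))
}

#' Select the LASSO penalty by cross-validated reconstruction error
#'
#' On a random pixel subsample, hold out spectral channels in k folds:
#' for each candidate penalty, fit on the retained channels and measure
#' squared reconstruction error on the held-out channels; return the
#' penalty minimizing the mean held-out error.
#'
#' @param img \code{\link{hyperspectral_image}}.
#' @param library \code{spectral_library}.
#' @param grid Candidate penalties.
#' @param frac Fraction of pixels to subsample.
#' @param k Channel folds.
#' @param seed Integer seed.
#' @param cfg Base \code{\link{unmix_config}} (its lambda is ignored).
#' @return list with \code{lambda} (selected) and \code{cv_error} (per
#'   grid point).
#' @export
select_lambda_cv <- function(img, library,
                             grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                             frac = 0.01, k = 5L, seed = 1L,
                             cfg = unmix_config()) {
  d <- dim(img$data)
  N <- d[1] * d[2]
  withr::with_seed(as.integer(seed), {
    pix <- sample.int(N, max(20L, ceiling(frac * N)))
    folds <- sample(rep_len(seq_len(k), d[3]))
  })
  S <- t(matrix(img$data, N, d[3]))[, pix, drop = FALSE]
  X <- library$matrix
  err <- vapply(grid, function(lam) {
    e <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      Cf <- cd_lasso(S[tr, , drop = FALSE], X[tr, , drop = FALSE],
                     lam, cfg$nonnegative, cfg$max_iter, cfg$tol)
      e <- e + mean((S[!tr, , drop = FALSE] -
                       X[!tr, , drop = FALSE] %*% Cf)^2)
    }
    e / k
  }, numeric(1))
  list(lambda = grid[which.min(err)],
       cv_error = stats::setNames(err, as.character(grid)))
}
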