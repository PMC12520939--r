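# merge 4-connected components that touch diagonally -> 8-connectivity
merge_diagonal <- function(L) {
  H <- nrow(L); W <- ncol(L)
  pairs <- rbind(
    cbind(as.vector(L[-H, -W]), as.vector(L[-1, -1])),  # down-right
    cbind(as.vector(L[-H, -1]), as.vector(L[-1, -W])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(L)
  K <- max(L)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(K), find, integer(1))
  out <- L
  out[L > 0] <- root[L[L > 0]]
  out
}

#' Segment single cells from chemical maps
#'
#' Works on the total-signal image (sum of the four coefficient maps,
#' which maximizes SNR): binarize by Otsu's threshold (default) or a
#' fixed value, fill holes, label connected components
#' (8-connectivity), drop components smaller than \code{min_area}, and
#' relabel 1..K in raster order of the component centroids. An
#' all-constant total image under Otsu yields an empty mask (K = 0),
#' not an error.
#'
#' @param maps A \code{chemical_maps} object.
#' @param min_area Minimum component area in pixels.
#' @param threshold \code{"otsu"} or a fixed numeric threshold on the
#'   total-signal scale.
#' @return Integer H x W label mask; 0 = background.
#' @export
segment_cells <- function(maps, min_area = 30L, threshold = "otsu") {
  tot <- maps$maps[, , 1] + maps$maps[, , 2] +
    maps$maps[, , 3] + maps$maps[, , 4]
  H <- nrow(tot); W <- ncol(tot)
  rng <- range(tot)
  if (identical(threshold, "otsu")) {
    if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
      return(matrix(0L, H, W))            # constant image: no foreground
    tot01 <- (tot - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(tot01), range = c(0, 1))
    bin <- tot01 > thr
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    bin <- tot > threshold
  }
  if (!any(bin)) return(matrix(0L, H, W))
  bin <- EBImage::fillHull(EBImage::Image(bin * 1))
  L <- EBImage::imageData(EBImage::bwlabel(bin))
  L <- merge_diagonal(matrix(as.integer(L), H, W))
  sizes <- tabulate(L[L > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) return(matrix(0L, H, W))
  # centroid raster order (row-major), then contiguous relabel
  idx <- which(L > 0)
  lab <- L[idx]
  rows <- (idx - 1) %% H + 1
  cols <- (idx - 1) %/% H + 1
  cr <- tapply(rows, lab, mean)[as.character(keep)]
  cc <- tapply(cols, lab, mean)[as.character(keep)]
  ord <- keep[order(cr, cc)]
  relab <- integer(max(L))
  relab[ord] <- seq_along(ord)
  out <- matrix(0L, H, W)
  out[idx] <- relab[lab]
  out
}

#' Extract the 5-feature phenotype per cell
#'
#' For every labeled cell, measures cellular area (pixel count, or
#' micrometers squared when \code{pixel_size} is given) and the
#' integrated content of each biomolecular component: the sum of that
#' component's unmixing coefficients over the cell mask (a total-amount
#' measure that co-varies with area). A mean-per-pixel variant is
#' available via \code{content = "mean"}.
#'
#' @param mask Integer label mask from \code{\link{segment_cells}} (or
#'   a truth mask).
#' @param maps \code{chemical_maps} with matching dimensions.
#' @param pixel_size Optional pixel edge length in micrometers; area is
#'   then reported in square micrometers.
#' @param content \code{"sum"} (default) or \code{"mean"}.
#' @param source_image Provenance string stored per record.
#' @return data.frame feature table with columns \code{cell_id},
#'   \code{source_image}, \code{class}, \code{area}, \code{protein},
#'   \code{nucleic_acid}, \code{saturated_lipid},
#'   \code{unsaturated_lipid}, ordered by label id.
#' @export
extract_features <- function(mask, maps, pixel_size = NULL,
                             content = c("sum", "mean"),
                             source_image = NA_character_) {
  content <- match.arg(content)
  if (!all(dim(mask) == dim(maps$maps)[1:2]))
    stop("mask and maps dimensions differ", call. = FALSE)
  labs <- sort(unique(mask[mask > 0]))
  empty <- data.frame(cell_id = integer(0),
                      source_image = character(0), class = character(0),
                      area = numeric(0), protein = numeric(0),
                      nucleic_acid = numeric(0),
                      saturated_lipid = numeric(0),
                      unsaturated_lipid = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(labs) == 0) return(empty)
  idx <- which(mask > 0)
  lab <- factor(mask[idx], levels = labs)
  npx <- as.numeric(table(lab))
  agg <- function(k) {
    v <- maps$maps[, , k][idx]
    s <- as.numeric(tapply(v, lab, sum))
    if (content == "mean") s / npx else s
  }
  area <- if (is.null(pixel_size)) npx else npx * pixel_size^2
  data.frame(cell_id = as.integer(labs), source_image = source_image,
             class = NA_character_, area = area,
             protein = agg(1), nucleic_acid = agg(2),
             saturated_lipid = agg(4), unsaturated_lipid = agg(3),
             stringsAsFactors = FALSE)
}

#' Match segmented cells to ground-truth cells by IoU
#'
#' Greedy maximum-IoU matching between two label masks; each segmented
#' label and each truth label is used at most once.
#'
#' @param mask Segmentation label mask.
#' @param truth Ground-truth label mask of the same dimensions.
#' @return list with \code{matches} (data.frame \code{cell_id},
#'   \code{truth_id}, \code{iou}), \code{unmatched_cells} and
#'   \code{unmatched_truth} (label vectors).
#' @export
match_cells_to_truth <- function(mask, truth) {
  if (!all(dim(mask) == dim(truth)))
    stop("mask and truth dimensions differ", call. = FALSE)
  any_fg <- mask > 0 | truth > 0
  tab <- table(mask = mask[any_fg], truth = truth[any_fg])
  m_labs <- setdiff(as.integer(rownames(tab)), 0L)
  t_labs <- setdiff(as.integer(colnames(tab)), 0L)
  m_sz <- tabulate(mask[mask > 0], nbins = max(c(m_labs, 1L)))
  t_sz <- tabulate(truth[truth > 0], nbins = max(c(t_labs, 1L)))
  cand <- expand.grid(m = m_labs, t = t_labs)
  inter <- mapply(function(m, t) {
    i <- tab[as.character(m), as.character(t)]
    as.numeric(i)
  }, cand$m, cand$t)
  cand$iou <- inter / (m_sz[cand$m] + t_sz[cand$t] - inter)
  cand <- cand[cand$iou > 0, , drop = FALSE]
  cand <- cand[order(-cand$iou), , drop = FALSE]
  used_m <- used_t <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$m[r] %in% used_m) && !(cand$t[r] %in% used_t)) {
      keep[r] <- TRUE
      used_m <- c(used_m, cand$m[r]); used_t <- c(used_t, cand$t[r])
    }
  }
  matches <- data.frame(cell_id = cand$m[keep], truth_id = cand$t[keep],
                        iou = cand$iou[keep])
  matches <- matches[order(matches$cell_id), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_cells = setdiff(m_labs, matches$cell_id),
       unmatched_truth = setdiff(t_labs, matches$truth_id))
}

#' Write / read a feature-table CSV
#'
#' Columns:
#' \code{cell_id,source_image,class,area,protein,nucleic_acid,saturated_lipid,unsaturated_lipid}
#' (\code{class} empty when unknown).
#'
#' @param features Feature-table data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("cell_id", "source_image", "class", "area", "protein",
            "nucleic_acid", "saturated_lipid", "unsaturated_lipid")
  utils::write.csv(features[, cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$class[d$class == ""] <- NA_character_
  d
}
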