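#' Physical area of one output-grid cell
#'
#' The network output grid is `factor` times coarser than the working
#' resolution, so one output pixel covers
#' `(factor * pixel_size_um)^2` square micrometres (8.6677e-4 mm2 for the
#' default 32x downsampling at 0.92 um/pixel).
#'
#' @param factor Network downsampling factor (default 32).
#' @param pixel_size_um Working pixel pitch (default 0.92).
#' @return Cell area in mm2.
#' @export
cell_area_mm2 <- function(factor = 32L, pixel_size_um = 0.92) {
  (factor * pixel_size_um * 1e-3)^2
}

min_pixels_for_area <- function(min_area_mm2, cell_mm2) {
  # smallest pixel count whose area strictly exceeds min_area_mm2
  if (min_area_mm2 <= 0) return(0L)
  as.integer(floor(min_area_mm2 / cell_mm2 + 1e-9))
}

#' Extract predicted cribriform regions from a probability map
#'
#' Pixels with cribriform probability strictly greater than `cutoff` are
#' grouped into connected components; when a positive `min_area_mm2` is
#' given, only components whose cumulative pixel area is strictly larger
#' than it are kept.
#'
#' @param prob_map Numeric matrix of cribriform probabilities on the
#'   output grid.
#' @param cutoff Probability cut-off in `[0, 1]` (strict).
#' @param connectivity 8 (default) or 4.
#' @param min_area_mm2 Minimum region area filter (default 0 = no filter).
#' @param cell_mm2 Area of one grid cell (see [cell_area_mm2()]).
#' @return Data frame with one row per region (`id`, `n_pixels`,
#'   `area_mm2`, `max_prob`, `mean_prob`); the relabelled component matrix
#'   is attached as attribute `labels`.
#' @export
extract_regions <- function(prob_map, cutoff, connectivity = 8L,
                            min_area_mm2 = 0, cell_mm2 = cell_area_mm2()) {
  stopifnot(cutoff >= 0, cutoff <= 1, connectivity %in% c(4L, 8L))
  lab <- label_components_cpp(prob_map > cutoff, as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp == 0L) {
    out <- data.frame(id = integer(0), n_pixels = integer(0),
                      area_mm2 = numeric(0), max_prob = numeric(0),
                      mean_prob = numeric(0))
    attr(out, "labels") <- lab
    return(out)
  }
  fg <- lab > 0
  g <- lab[fg]
  v <- prob_map[fg]
  npx <- tabulate(g, nbins = ncomp)
  mx <- vapply(split(v, g), max, numeric(1))
  sums <- vapply(split(v, g), sum, numeric(1))
  out <- data.frame(id = seq_len(ncomp), n_pixels = npx,
                    area_mm2 = npx * cell_mm2, max_prob = unname(mx),
                    mean_prob = unname(sums) / npx)
  keep <- out$n_pixels > min_pixels_for_area(min_area_mm2, cell_mm2)
  out <- out[keep, , drop = FALSE]
  remap <- integer(ncomp + 1L)  # old id (+1 for background 0) -> new id
  remap[out$id + 1L] <- seq_len(nrow(out))
  relab <- matrix(remap[lab + 1L], nrow(lab), ncol(lab))
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "labels") <- relab
  out
}

#' Qualifying-region score of a biopsy probability map
#'
#' The largest cut-off below which the biopsy is predicted
#' cribriform-positive, i.e. the highest probability level at which the
#' thresholded map still contains a connected region passing the area
#' filter. Sweeping cut-offs over all pixel probabilities and thresholding
#' this score are equivalent.
#'
#' @inheritParams extract_regions
#' @return Scalar score in `[0, 1]` (0 when no region ever qualifies).
#' @export
biopsy_score <- function(prob_map, min_area_mm2 = 0,
                         cell_mm2 = cell_area_mm2(), connectivity = 8L) {
  region_score_cpp(prob_map, min_pixels_for_area(min_area_mm2, cell_mm2),
                   as.integer(connectivity))
}

#' Biopsy-wise ROC analysis of cribriform detection
#'
#' A biopsy is reference-positive when it carries at least one cribriform
#' annotation, and predicted positive at a given cut-off when its
#' probability map contains at least one predicted cribriform region
#' (after the optional area filter). Cut-offs sweep all distinct biopsy
#' scores plus 0 and 1; a closing operating point (all biopsies predicted
#' positive) completes the curve so the area under the curve corresponds
#' to the Mann-Whitney statistic of the scores.
#'
#' @param prob_maps List of per-biopsy cribriform probability matrices.
#' @param positive Logical vector: reference cribriform status per biopsy.
#' @param min_area_mm2,cell_mm2,connectivity See [extract_regions()].
#' @return An object of class `cribnet_curve` (`type = "roc"`): data frame
#'   `points` with decreasing `cutoff`, `sensitivity` and `x` (false
#'   positive rate), plus `auc` (trapezoid).
#' @export
biopsy_roc <- function(prob_maps, positive, min_area_mm2 = 0,
                       cell_mm2 = cell_area_mm2(), connectivity = 8L) {
  stopifnot(length(prob_maps) == length(positive))
  if (!any(positive) || all(positive)) {
    stop("ROC needs at least one positive and one negative biopsy")
  }
  scores <- vapply(prob_maps, biopsy_score, numeric(1),
                   min_area_mm2 = min_area_mm2, cell_mm2 = cell_mm2,
                   connectivity = connectivity)
  cutoffs <- sort(unique(c(0, 1, scores)), decreasing = TRUE)
  pts <- lapply(cutoffs, function(ct) {
    pred <- scores > ct
    data.frame(cutoff = ct,
               sensitivity = mean(pred[positive]),
               x = mean(pred[!positive]))
  })
  pts <- do.call(rbind, pts)
  # closing point: every biopsy called positive
  pts <- rbind(pts, data.frame(cutoff = -1, sensitivity = 1, x = 1))
  auc <- sum(diff(pts$x) * (head(pts$sensitivity, -1) +
                            tail(pts$sensitivity, -1)) / 2)
  structure(list(points = pts, auc = auc, type = "roc",
                 scores = scores), class = "cribnet_curve")
}

#' Annotation-wise FROC analysis of cribriform detection
#'
#' An annotated cribriform region counts as detected at a cut-off when at
#' least one pixel of a predicted cribriform region overlaps it; every
#' predicted region overlapping no cribriform annotation is a false
#' positive. Sensitivity (fraction of annotations detected) is plotted
#' against the mean number of false-positive regions per biopsy.
#'
#' @param prob_maps List of per-biopsy probability matrices (output grid).
#' @param annotation_maps List of integer matrices on the same grid: 0
#'   outside cribriform annotations, `1..m` identifying the m annotated
#'   regions of that biopsy.
#' @param cutoffs Cut-offs to evaluate; default: all distinct positive
#'   pixel values when few, otherwise 101 quantiles.
#' @param connectivity,min_area_mm2,cell_mm2 See [extract_regions()].
#' @return A `cribnet_curve` (`type = "froc"`): `points` has decreasing
#'   `cutoff`, `sensitivity` and `x` (mean false positives per biopsy).
#' @export
annotation_froc <- function(prob_maps, annotation_maps, cutoffs = NULL,
                            connectivity = 8L, min_area_mm2 = 0,
                            cell_mm2 = cell_area_mm2()) {
  stopifnot(length(prob_maps) == length(annotation_maps))
  n_ann_per <- vapply(annotation_maps, max, numeric(1))
  total_ann <- sum(n_ann_per)
  if (total_ann == 0) stop("FROC needs at least one cribriform annotation")
  if (is.null(cutoffs)) {
    vals <- sort(unique(unlist(lapply(prob_maps, function(m) m[m > 0]))))
    cutoffs <- if (length(vals) <= 512L) {
      unique(c(0, vals))
    } else {
      unique(c(0, quantile(vals, probs = seq(0, 1, length.out = 101),
                           names = FALSE)))
    }
  }
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  n_biopsies <- length(prob_maps)
  pts <- lapply(cutoffs, function(ct) {
    hits <- 0
    fp <- 0
    for (b in seq_along(prob_maps)) {
      regs <- extract_regions(prob_maps[[b]], ct, connectivity,
                              min_area_mm2, cell_mm2)
      lab <- attr(regs, "labels")
      amap <- annotation_maps[[b]]
      hit_ids <- integer(0)
      if (nrow(regs) > 0) {
        fg <- lab > 0
        over_by_region <- split(amap[fg], lab[fg])
        for (ov in over_by_region) {
          ov <- unique(ov[ov > 0])
          if (length(ov) == 0) fp <- fp + 1 else {
            hit_ids <- union(hit_ids, ov)
          }
        }
      }
      hits <- hits + length(hit_ids)
    }
    data.frame(cutoff = ct, sensitivity = hits / total_ann,
               x = fp / n_biopsies)
  })
  structure(list(points = do.call(rbind, pts), auc = NA_real_,
                 type = "froc"), class = "cribnet_curve")
}

#' Contour-restricted cribriform decision for an image region
#'
#' Predictions outside the contoured region are discarded; the image is
#' called cribriform when at least one in-contour output pixel carries a
#' cribriform probability strictly greater than the cut-off.
#'
#' @param prob_map Probability matrix on the output grid.
#' @param contour_mask Logical matrix on the same grid.
#' @param cutoff Probability cut-off.
#' @return Logical decision.
#' @export
contour_decision <- function(prob_map, contour_mask, cutoff) {
  stopifnot(identical(dim(prob_map), dim(contour_mask)))
  if (!any(contour_mask)) stop("the contour mask is empty")
  any(prob_map[contour_mask] > cutoff)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement. When both raters are constant and
#' identical (`p_e = 1`) the agreement is perfect by convention and 1 is
#' returned.
#'
#' @param a,b Equal-length label vectors (coerced to character).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) < 2L) stop("kappa needs at least 2 items")
  a <- as.character(a)
  b <- as.character(b)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' @export
print.cribnet_curve <- function(x, ...) {
  cat(toupper(x$type), "curve with", nrow(x$points), "operating points")
  if (x$type == "roc") cat(sprintf("; AUC = %.3f", x$auc))
  cat("\n")
  invisible(x)
}
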