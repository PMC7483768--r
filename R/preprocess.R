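#' Optical density transform of an RGB image
#'
#' Computes `OD_c = -log10(I_c / I_max)` per channel. Unstained (white)
#' background has optical density near zero. Zero intensities are clamped to
#' one intensity unit (1/255 of the reference intensity, images being 8-bit
#' at origin) before the logarithm, and intensities above `i_max` are capped
#' so the transform stays finite and non-negative.
#'
#' @param image Numeric `H x W x 3` array with intensities in `[0, i_max]`.
#' @param i_max Reference (maximum) intensity per channel. `NULL` (default)
#'   uses the per-image per-channel maximum; a scalar is recycled.
#' @return An object of class `cribnet_od`: list with the `H x W x 3` array
#'   `od` and the per-channel `i_max` used.
#' @export
optical_density <- function(image, i_max = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (is.null(i_max)) {
    i_max <- apply(image, 3, max)
  } else {
    i_max <- rep_len(i_max, 3L)
  }
  if (any(i_max <= 0)) stop("i_max must be positive for every channel")
  od <- array(0, dim = dim(image))
  for (ch in 1:3) {
    unit <- i_max[ch] / 255
    intens <- pmin(pmax(image[, , ch], unit), i_max[ch])
    od[, , ch] <- -log10(intens / i_max[ch])
  }
  structure(list(od = od, i_max = i_max), class = "cribnet_od")
}

#' Background mask from an optical density map
#'
#' A pixel is background when its optical density falls below `threshold`
#' in *any* channel (the default reading) or in *all* channels
#' (`mode = "all"`). The comparison is strict.
#'
#' @param od A [optical_density()] result.
#' @param threshold Optical density threshold (default 0.12).
#' @param mode `"any"` or `"all"`.
#' @return Logical `H x W` matrix, `TRUE` for background.
#' @export
background_mask <- function(od, threshold = 0.12, mode = c("any", "all")) {
  mode <- match.arg(mode)
  below <- od$od < threshold
  if (mode == "any") {
    below[, , 1] | below[, , 2] | below[, , 3]
  } else {
    below[, , 1] & below[, , 2] & below[, , 3]
  }
}

#' Area-averaging downsample (working resolution from scanner resolution)
#'
#' @param image Numeric `H x W x C` array.
#' @param factor Integer downsampling factor (default 4, e.g. 0.23 to
#'   0.92 um/pixel). Trailing rows/columns that do not fill a block are
#'   dropped.
#' @return Downsampled array.
#' @export
resample_image <- function(image, factor = 4L) {
  d <- dim(image)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  out <- array(0, dim = c(H %/% factor, W %/% factor, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- pool_mean_cpp(image[seq_len(H), seq_len(W), ch], factor)
  }
  out
}

#' Average-pool a one-hot mask stack to the network output grid
#'
#' Each output cell is the mean of its `kernel x kernel` block, so the
#' pooled per-class values are soft memberships that still sum to 1 per
#' cell.
#'
#' @param y_full Numeric `H x W x K` one-hot mask stack, or an integer
#'   label map (then `n_classes` must be given).
#' @param kernel Pooling kernel/stride (default 32).
#' @param n_classes Number of classes when `y_full` is a label map.
#' @return Numeric `(H/kernel) x (W/kernel) x K` array.
#' @export
pool_mask <- function(y_full, kernel = 32L, n_classes = NULL) {
  if (is.matrix(y_full)) {
    if (is.null(n_classes)) stop("n_classes required for a label map input")
    if (nrow(y_full) %% kernel != 0L || ncol(y_full) %% kernel != 0L) {
      stop("mask dimensions must be a multiple of the pooling kernel")
    }
    return(pool_labels_cpp(y_full, as.integer(kernel),
                           as.integer(n_classes)))
  }
  d <- dim(y_full)
  if (d[1] %% kernel != 0L || d[2] %% kernel != 0L) {
    stop("mask dimensions must be a multiple of the pooling kernel")
  }
  out <- array(0, dim = c(d[1] %/% kernel, d[2] %/% kernel, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- pool_mean_cpp(y_full[, , k], as.integer(kernel))
  }
  out
}

pad_geometry <- function(H, W, patch, stride) {
  pad0 <- stride %/% 2L
  grow <- function(n) {
    n1 <- n + 2L * pad0
    if (n1 < patch) n1 <- patch
    rem <- (n1 - patch) %% stride
    if (rem != 0L) n1 <- n1 + (stride - rem)
    n1
  }
  list(top = pad0, left = pad0, H = grow(H), W = grow(W))
}

pad_image <- function(image, geom, fill) {
  d <- dim(image)
  out <- array(0, dim = c(geom$H, geom$W, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- fill[ch]
    out[geom$top + seq_len(d[1]), geom$left + seq_len(d[2]), ch] <-
      image[, , ch]
  }
  out
}

pad_label_map <- function(label_map, geom, fill = 1L) {
  out <- matrix(as.integer(fill), geom$H, geom$W)
  out[geom$top + seq_len(nrow(label_map)),
      geom$left + seq_len(ncol(label_map))] <- label_map
  out
}

#' Tile a biopsy image into half-overlapping patches
#'
#' The image is padded with background (per-channel reference white) by half
#' a stride on every side, then up to a multiple of the stride, so that all
#' tissue lies inside some patch's centre window. Patches whose background
#' fraction exceeds `max_background` (strictly) are discarded. Each retained
#' patch carries its full-resolution label map and the block-averaged soft
#' reference produced with `pool_factor`.
#'
#' @param image Numeric `H x W x 3` array in `[0, 1]`.
#' @param label_map Optional integer label map of the same spatial size
#'   (e.g. from [rasterize_label_map()]); padding fills with the
#'   non-labelled class.
#' @param patch Patch size in pixels (default 1024).
#' @param stride Tiling stride (default `patch / 2`).
#' @param max_background Discard threshold on the patch background fraction
#'   (default 0.995). Use `1` to keep every patch (prediction mode).
#' @param pool_factor Pooling kernel for the patch reference masks
#'   (default 32, the network output grid).
#' @param n_classes Number of classes for the pooled reference.
#' @param od_threshold,od_mode Background criterion, see
#'   [background_mask()].
#' @param i_max Reference intensity for [optical_density()] (`NULL` =
#'   per-image maximum).
#' @return A list with `patches` (each a list `image`, `origin` (0-based
#'   `(row, col)` in the padded frame), `label_map`, `y_pooled`,
#'   `background_fraction`), `geom` (padding geometry), `report` (a data
#'   frame of all grid origins with their background fraction and retention
#'   status), and `shape` (original image size).
#' @export
tile <- function(image, label_map = NULL, patch = 1024L,
                 stride = patch %/% 2L, max_background = 0.995,
                 pool_factor = 32L, n_classes = 7L, od_threshold = 0.12,
                 od_mode = "any", i_max = NULL) {
  d <- dim(image)
  if (patch %% pool_factor != 0L) {
    stop("patch size must be a multiple of pool_factor")
  }
  od0 <- optical_density(image, i_max)
  geom <- pad_geometry(d[1], d[2], patch, stride)
  img_p <- pad_image(image, geom, fill = pmin(od0$i_max, 1))
  lab_p <- if (!is.null(label_map)) pad_label_map(label_map, geom) else NULL
  bg <- background_mask(optical_density(img_p, od0$i_max), od_threshold,
                        od_mode)
  rows <- seq(0L, geom$H - patch, by = stride)
  cols <- seq(0L, geom$W - patch, by = stride)
  patches <- list()
  rep_rows <- list()
  for (r0 in rows) {
    for (c0 in cols) {
      ri <- r0 + seq_len(patch)
      ci <- c0 + seq_len(patch)
      frac <- mean(bg[ri, ci])
      keep <- !(frac > max_background)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        row = r0, col = c0, background_fraction = frac, retained = keep)
      if (!keep) next
      p <- list(image = img_p[ri, ci, , drop = FALSE],
                origin = c(row = r0, col = c0),
                background_fraction = frac)
      if (!is.null(lab_p)) {
        p$label_map <- lab_p[ri, ci]
        p$y_pooled <- pool_labels_cpp(p$label_map, as.integer(pool_factor),
                                      as.integer(n_classes))
      }
      patches[[length(patches) + 1L]] <- p
    }
  }
  list(patches = patches, geom = geom,
       report = do.call(rbind, rep_rows),
       shape = d[1:2])
}

#' Reassemble patch predictions into a biopsy probability map
#'
#' Only the central half-window of each patch output is kept (for a 32x32
#' patch output, rows/cols 8..23): with half-overlapping patches these
#' centre windows partition the padded grid, so every output pixel is
#' sourced from exactly one patch. The result is cropped back to the
#' unpadded extent.
#'
#' @param preds List of lists `origin` (0-based `(row, col)` in the padded
#'   frame) and `prob` (`o x o x K` patch output).
#' @param geom Padding geometry as returned by [tile()].
#' @param shape Original image size `(H, W)`.
#' @param patch,stride Tiling parameters used.
#' @param factor Network downsampling factor (patch size / patch output
#'   size).
#' @return Numeric `ceil(H/factor) x ceil(W/factor) x K` probability array.
#' @export
reassemble <- function(preds, geom, shape, patch, stride = patch %/% 2L,
                       factor = 32L) {
  o <- patch %/% factor
  K <- dim(preds[[1]]$prob)[3]
  OH <- geom$H %/% factor
  OW <- geom$W %/% factor
  out <- array(NA_real_, dim = c(OH, OW, K))
  have <- matrix(FALSE, OH, OW)
  win <- (o %/% 4L) + seq_len(o %/% 2L)  # central half-window
  rows <- seq(0L, geom$H - patch, by = stride)
  cols <- seq(0L, geom$W - patch, by = stride)
  grid <- paste(rep(rows, each = length(cols)), rep(cols, length(rows)))
  seen <- setNames(rep(FALSE, length(grid)), grid)
  for (p in preds) {
    key <- paste(p$origin[1], p$origin[2])
    if (!key %in% grid) {
      stop("prediction origin (", p$origin[1], ", ", p$origin[2],
           ") is not on the tiling grid")
    }
    seen[key] <- TRUE
    orr <- p$origin[1] %/% factor
    occ <- p$origin[2] %/% factor
    out[orr + win, occ + win, ] <- p$prob[win, win, , drop = FALSE]
    have[orr + win, occ + win] <- TRUE
  }
  r0 <- geom$top %/% factor
  c0 <- geom$left %/% factor
  nr <- ceiling(shape[1] / factor)
  nc <- ceiling(shape[2] / factor)
  if (!all(have[r0 + seq_len(nr), c0 + seq_len(nc)])) {
    missing <- names(seen)[!seen]
    stop("missing patch prediction(s) for grid origin(s): ",
         paste(head(missing, 3), collapse = "; "))
  }
  out[r0 + seq_len(nr), c0 + seq_len(nc), , drop = FALSE]
}
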