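#' Predict a whole biopsy with a single network
#'
#' Tiles the biopsy into half-overlapping patches (no background discard:
#' every grid patch is inferred), runs the network in inference mode and
#' reassembles the coarse probability maps from the patch centre windows.
#'
#' @param network A [build_network()] result.
#' @param image Numeric `H x W x 3` biopsy image.
#' @param patch,stride Tiling parameters; default from the network input
#'   size.
#' @param batch_size Patches per forward batch.
#' @return Probability array `ceil(H/f) x ceil(W/f) x K` on the output
#'   grid.
#' @export
predict_biopsy <- function(network, image,
                           patch = network$config$input_size,
                           stride = patch %/% 2L, batch_size = 7L) {
  tl <- tile(image, label_map = NULL, patch = patch, stride = stride,
             max_background = 1,
             pool_factor = network$config$downsample_factor,
             n_classes = network$config$n_classes)
  preds <- predict_patches(network, tl$patches, batch_size)
  reassemble(preds, tl$geom, tl$shape, patch, stride,
             network$config$downsample_factor)
}

predict_patches <- function(network, patches, batch_size = 7L) {
  preds <- vector("list", length(patches))
  i <- 1L
  while (i <= length(patches)) {
    idx <- i:min(i + batch_size - 1L, length(patches))
    xb <- simplify2array(lapply(patches[idx], patch_image_double))
    if (length(dim(xb)) == 3L) dim(xb) <- c(dim(xb), 1L)
    pb <- net_forward(network, xb, train = FALSE)
    if (length(dim(pb)) == 3L) dim(pb) <- c(dim(pb), 1L)
    for (j in seq_along(idx)) {
      preds[[idx[j]]] <- list(origin = patches[[idx[j]]]$origin,
                              prob = pb[, , , j])
    }
    i <- i + batch_size
  }
  preds
}

#' Predict a whole biopsy with an ensemble
#'
#' The ensemble prediction is the arithmetic mean of the member
#' probability maps. Members that selected the same checkpoint of the
#' same training run share one forward pass (weighted by multiplicity),
#' which leaves the mean unchanged.
#'
#' @param ensemble A [build_ensemble()] result.
#' @param image Biopsy image.
#' @param patch,stride,batch_size As in [predict_biopsy()].
#' @param member_maps Also return the per-member maps (needed to compare
#'   member and ensemble performance).
#' @return The mean probability array; with `member_maps = TRUE`, a list
#'   `mean` plus `members` (one map per ensemble member, in member order).
#' @export
predict_biopsy_ensemble <- function(ensemble, image,
                                    patch = ensemble$net_config$input_size,
                                    stride = patch %/% 2L,
                                    batch_size = 7L,
                                    member_maps = FALSE) {
  net <- build_network(ensemble$net_config, seed = 1L)
  keys <- vapply(ensemble$members, function(m) {
    paste(m$repetition, m$iteration, sep = "_")
  }, character(1))
  uniq <- unique(keys)
  maps <- list()
  for (k in uniq) {
    m <- ensemble$members[[match(k, keys)]]
    set_network_weights(net, m$weights)
    maps[[k]] <- predict_biopsy(net, image, patch, stride, batch_size)
  }
  per_member <- lapply(keys, function(k) maps[[k]])
  mean_map <- Reduce(`+`, per_member) / length(per_member)
  if (member_maps) {
    list(mean = mean_map, members = per_member)
  } else {
    mean_map
  }
}

#' Pool cribriform annotations onto the output grid with identities
#'
#' Each cribriform annotation region is rasterized separately and pooled
#' to the output grid; a cell belongs to the annotation when any of its
#' block pixels does (pooled fraction > 0). Overlaps keep the later
#' region's id.
#'
#' @param regions List of [annotation_region()]s (all labels; only
#'   cribriform ones are used).
#' @param height,width Image size in pixels.
#' @param factor Output-grid downsampling factor.
#' @param labelset A [label_set()].
#' @return Integer `ceil(height/factor) x ceil(width/factor)` matrix, 0
#'   outside annotations, `1..m` inside the m cribriform regions.
#' @export
annotation_id_map <- function(regions, height, width, factor = 32L,
                              labelset = label_set()) {
  crib <- Filter(function(r) {
    label_index(labelset, r$label) == cribriform_index(labelset)
  }, regions)
  OH <- as.integer(ceiling(height / factor))
  OW <- as.integer(ceiling(width / factor))
  out <- matrix(0L, OH, OW)
  if (length(crib) == 0) return(out)
  Hp <- OH * factor
  Wp <- OW * factor
  for (j in seq_along(crib)) {
    lm <- matrix(1L, Hp, Wp)
    fill_polygon_cpp(lm, crib[[j]]$polygon, 2L, 1L)
    frac <- pool_mean_cpp(matrix(as.numeric(lm == 2L), Hp, Wp),
                          as.integer(factor))
    out[frac > 0] <- j
  }
  out
}
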