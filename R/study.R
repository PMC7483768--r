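#' Run the desk-scale synthetic validation study
#'
#' End-to-end exercise of the whole pipeline at desk scale: generate a
#' synthetic biopsy dataset (512 x 1536 canvas at 0.92 um/pixel), split it
#' into training, validation and held-out test biopsies (stratified on
#' cribriform positivity), train an ensemble of alpha-selected networks
#' (3 blocks, 256-px patches, batch 7), predict the held-out biopsies and
#' evaluate cribriform detection biopsy-wise (ROC) and annotation-wise
#' (FROC).
#'
#' @param seed Root seed; the dataset, split, initialization and batch
#'   order all derive from it.
#' @param dir Working directory for the generated dataset.
#' @param n_biopsies Total synthetic biopsies (default 60: 40 train, 10
#'   validation, 10 held-out test).
#' @param n_test,n_val Held-out and validation set sizes.
#' @param iterations SGD iterations per training repeat (default 2000).
#' @param checkpoint_interval Iterations between checkpoints.
#' @param n_repeats Training repeats (ensemble members =
#'   `n_repeats * length(alphas)`).
#' @param alphas Selection-metric weights.
#' @param verbose Print progress.
#' @return List with the ensemble biopsy-wise ROC and AUC using the
#'   minimum-area filter (`roc`, `auc`; the filter, in `min_area_mm2`,
#'   sits just below the smallest cribriform annotation of the
#'   training/validation sets, mirroring the clinical-scale filter
#'   rule), the unfiltered AUC (`auc_all_regions`), per-member filtered
#'   AUCs (`member_aucs`, `mean_member_auc`), the (unfiltered) FROC
#'   curve (`froc`) and its sensitivity at up to 5 false positives per
#'   biopsy (`sens_at_5fp`), the number of test biopsies and cribriform
#'   annotations, and the trained `ensemble`.
#' @export
run_desk_study <- function(seed = 1L,
                           dir = file.path(tempdir(),
                                           paste0("cribnet_study_",
                                                  seed)),
                           n_biopsies = 60L, n_test = 10L, n_val = 10L,
                           iterations = 2000L,
                           checkpoint_interval = 500L, n_repeats = 1L,
                           alphas = c(0.2, 0.3, 0.4, 1),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  ls7 <- label_set()
  sc <- synthesis_config(canvas_px = c(512L, 1536L))
  say("generating ", n_biopsies, " synthetic biopsies ...")
  recs <- generate_dataset(n_biopsies, sc, seed = seed, dir = dir)
  set.seed(seed + 1L)
  sp <- split_dataset(recs, n_test = n_test, n_val = n_val, labelset = ls7)
  ncfg <- network_config(n_blocks = 3L, base_features = 4L,
                         se_ratio = 4L, input_size = 256L)
  say("tiling training data ...")
  pool <- build_patch_pool(sp$train, dir, 256L, 128L, 4L, ls7)
  valp <- build_patch_pool(sp$val, dir, 256L, 128L, 4L, ls7)
  tc <- train_config(iterations = iterations,
                     checkpoint_interval = checkpoint_interval,
                     seed = seed + 2L)
  say("training ", n_repeats, " x ", length(alphas),
      " ensemble member(s) ...")
  ens <- build_ensemble(ncfg, pool, valp, tc, n_repeats = n_repeats,
                        alphas = alphas, labelset = ls7)
  crib <- cribriform_index(ls7)
  mean_maps <- vector("list", length(sp$test))
  member_maps <- NULL
  ann_maps <- vector("list", length(sp$test))
  positive <- logical(length(sp$test))
  say("predicting ", length(sp$test), " held-out biopsies ...")
  for (i in seq_along(sp$test)) {
    rec <- sp$test[[i]]
    bx <- read_biopsy(rec, dir)
    pr <- predict_biopsy_ensemble(ens, bx$image, member_maps = TRUE)
    mean_maps[[i]] <- pr$mean[, , crib]
    if (is.null(member_maps)) {
      member_maps <- replicate(length(pr$members), list(),
                               simplify = FALSE)
    }
    for (j in seq_along(pr$members)) {
      member_maps[[j]][[i]] <- pr$members[[j]][, , crib]
    }
    regions <- parse_annotations(file.path(dir, rec$annotation_path),
                                 ls7)
    ann_maps[[i]] <- annotation_id_map(regions, nrow(bx$label_map),
                                       ncol(bx$label_map), 4L, ls7)
    positive[i] <- rec$counts[["G4 cribriform"]] > 0
  }
  cell <- cell_area_mm2(4L)
  # minimum-area filter for the headline biopsy-wise analysis, chosen by
  # the same rule as at clinical scale: just below the smallest
  # cribriform annotation (measured on training/validation annotations
  # only, never on the held-out set)
  crib_areas <- unlist(lapply(c(sp$train, sp$val), function(rec) {
    regs <- parse_annotations(file.path(dir, rec$annotation_path), ls7)
    vapply(Filter(function(r) r$label == "G4 cribriform", regs),
           `[[`, numeric(1), "area_mm2")
  }))
  min_area <- 0.97 * min(crib_areas)
  roc_all <- biopsy_roc(mean_maps, positive, min_area_mm2 = 0,
                        cell_mm2 = cell)
  roc <- biopsy_roc(mean_maps, positive, min_area_mm2 = min_area,
                    cell_mm2 = cell)
  member_aucs <- vapply(member_maps, function(mm) {
    biopsy_roc(mm, positive, min_area_mm2 = min_area,
               cell_mm2 = cell)$auc
  }, numeric(1))
  froc <- annotation_froc(mean_maps, ann_maps, cell_mm2 = cell)
  at5 <- froc$points$x <= 5
  sens5 <- if (any(at5)) max(froc$points$sensitivity[at5]) else 0
  say(sprintf("ensemble AUC %.3f | mean member AUC %.3f | FROC sens %.3f",
              roc$auc, mean(member_aucs), sens5))
  list(seed = seed, n_test = length(sp$test), positive = positive,
       auc = roc$auc, auc_all_regions = roc_all$auc,
       min_area_mm2 = min_area, roc = roc,
       member_aucs = member_aucs,
       mean_member_auc = mean(member_aucs), froc = froc,
       sens_at_5fp = sens5,
       n_annotations = sum(vapply(ann_maps, max, numeric(1))),
       ensemble = ens)
}
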