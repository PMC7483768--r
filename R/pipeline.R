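#' Assemble a run configuration
#'
#' A run configuration composes the module configurations under a profile.
#' The `"full"` profile mirrors the clinical-scale setting (1024-px
#' patches, 6 blocks, 60000 iterations); the `"desk"` profile is the
#' scaled-down setting used for synthetic end-to-end runs (512 x 1536
#' canvas, 256-px patches, 3 blocks, 2000 iterations). Explicit settings
#' override the profile defaults.
#'
#' @param config `NULL`, a YAML file path, or a nested list of settings.
#' @param run_dir Run directory for all artifacts.
#' @param seed Root seed; all module seeds derive from it.
#' @param profile `"desk"` or `"full"`.
#' @return List of class `cribnet_runconfig` including `config_hash`.
#' @export
run_config <- function(config = NULL, run_dir = NULL, seed = NULL,
                       profile = NULL) {
  user <- list()
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  }
  profile <- profile %||% user$profile %||% "desk"
  base <- if (profile == "full") {
    list(
      synth = list(n_biopsies = 128L, canvas_px = c(2048L, 6144L)),
      network = list(n_blocks = 6L, base_features = 32L, se_ratio = 16L,
                     input_size = 1024L),
      folds = list(k = 8L),
      train = list(iterations = 60000L, checkpoint_interval = 500L,
                   n_repeats = 4L, alphas = c(0.2, 0.3, 0.4, 1),
                   folds = 1L, n_test = NULL),
      evaluate = list(min_area_mm2 = 0.0150, connectivity = 8L)
    )
  } else {
    list(
      synth = list(n_biopsies = 12L, canvas_px = c(512L, 1536L)),
      network = list(n_blocks = 3L, base_features = 4L, se_ratio = 4L,
                     input_size = 256L),
      folds = list(k = 4L),
      train = list(iterations = 2000L, checkpoint_interval = 500L,
                   n_repeats = 1L, alphas = c(0.2, 0.3, 0.4, 1),
                   folds = 1L, n_test = NULL),
      evaluate = list(min_area_mm2 = 0, connectivity = 8L)
    )
  }
  cfg <- modifyList(base, user[setdiff(names(user),
                                       c("run_dir", "seed", "profile"))])
  cfg$profile <- profile
  cfg$seed <- as.integer(seed %||% user$seed %||% 1L)
  cfg$run_dir <- run_dir %||% user$run_dir %||%
    file.path(tempdir(), "cribnet_run")
  hash_cfg <- cfg[setdiff(names(cfg), "run_dir")]
  cfg$config_hash <- digest::digest(hash_cfg, algo = "sha1")
  class(cfg) <- "cribnet_runconfig"
  cfg
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run the '", producer,
         "' command first")
  }
  path
}

write_meta_json <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

net_config_from <- function(cfg) {
  network_config(n_blocks = cfg$network$n_blocks,
                 base_features = cfg$network$base_features,
                 se_ratio = cfg$network$se_ratio,
                 input_size = cfg$network$input_size)
}

#' Run one pipeline command
#'
#' Commands: `synth` (generate the synthetic dataset), `folds`
#' (bin-packing fold assignment), `train` (per-fold ensemble training),
#' `predict` (reassembled ensemble probability maps for the test
#' biopsies), `evaluate` (biopsy-wise ROC and annotation-wise FROC) and
#' `report` (aggregated JSON summary). Every artifact embeds the
#' configuration hash; a command whose inputs are missing names the
#' command that must run first.
#'
#' @param command One of `synth`, `folds`, `train`, `predict`,
#'   `evaluate`, `report`.
#' @param config A [run_config()] (or anything it accepts).
#' @return The main artifact path, invisibly.
#' @export
run_pipeline <- function(command = c("synth", "folds", "train", "predict",
                                     "evaluate", "report"),
                         config = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "cribnet_runconfig")) config else
    run_config(config)
  dir.create(cfg$run_dir, showWarnings = FALSE, recursive = TRUE)
  switch(command,
         synth = cmd_synth(cfg),
         folds = cmd_folds(cfg),
         train = cmd_train(cfg),
         predict = cmd_predict(cfg),
         evaluate = cmd_evaluate(cfg),
         report = cmd_report(cfg))
}

cmd_synth <- function(cfg) {
  dir <- file.path(cfg$run_dir, "synth")
  sc <- synthesis_config(canvas_px = cfg$synth$canvas_px)
  generate_dataset(cfg$synth$n_biopsies, sc, seed = cfg$seed, dir = dir)
  write_meta_json(list(config_hash = cfg$config_hash,
                       n_biopsies = cfg$synth$n_biopsies),
                  file.path(dir, "synth.json"))
  invisible(file.path(dir, "manifest.json"))
}

cmd_folds <- function(cfg) {
  man <- require_artifact(file.path(cfg$run_dir, "synth", "manifest.json"),
                          "synth")
  records <- load_manifest(man)
  fa <- bin_pack_folds(records, k = cfg$folds$k)
  out <- file.path(cfg$run_dir, "folds.json")
  write_meta_json(list(config_hash = cfg$config_hash, k = fa$k,
                       fold = as.list(fa$fold),
                       tallies = as.data.frame(fa$tallies)), out)
  invisible(out)
}

load_fold_split <- function(cfg) {
  fj <- jsonlite::read_json(require_artifact(
    file.path(cfg$run_dir, "folds.json"), "folds"))
  fold <- setNames(as.integer(unlist(fj$fold)), names(fj$fold))
  records <- load_manifest(file.path(cfg$run_dir, "synth",
                                     "manifest.json"))
  list(fold = fold, records = records, k = fj$k)
}

#' Build a training patch pool from dataset records
#'
#' Reads each biopsy image and label map, tiles it into half-overlapping
#' patches (background-dominated patches discarded), compresses the patch
#' images to 8-bit storage and indexes each patch by the labels it
#' contains.
#'
#' @param records List of [biopsy_record()]s.
#' @param dir Directory holding the dataset files.
#' @param patch,stride Tiling parameters.
#' @param pool_factor Network output-grid factor for the pooled
#'   references.
#' @param labelset A [label_set()].
#' @return List of patches suitable for [train_one()].
#' @export
build_patch_pool <- function(records, dir, patch, stride, pool_factor,
                             labelset = label_set()) {
  pool <- list()
  for (rec in records) {
    bx <- read_biopsy(rec, dir)
    tl <- tile(bx$image, bx$label_map, patch = patch, stride = stride,
               pool_factor = pool_factor,
               n_classes = length(labelset$labels))
    for (p in tl$patches) {
      p$labels <- sort(unique(as.vector(p$label_map)))
      p$biopsy <- rec$id
      pool[[length(pool) + 1L]] <- compress_patch(p)
    }
  }
  pool
}

cmd_train <- function(cfg) {
  sp <- load_fold_split(cfg)
  synth_dir <- file.path(cfg$run_dir, "synth")
  ncfg <- net_config_from(cfg)
  ids <- vapply(sp$records, function(r) as.character(r$id), character(1))
  for (f in cfg$train$folds) {
    val_f <- (f %% sp$k) + 1L
    test_ids <- ids[sp$fold[ids] == f]
    val_ids <- ids[sp$fold[ids] == val_f]
    train_ids <- setdiff(ids, c(test_ids, val_ids))
    pool <- build_patch_pool(sp$records[ids %in% train_ids], synth_dir,
                             ncfg$input_size, ncfg$input_size %/% 2L,
                             ncfg$downsample_factor)
    val_pool <- build_patch_pool(sp$records[ids %in% val_ids], synth_dir,
                                 ncfg$input_size, ncfg$input_size %/% 2L,
                                 ncfg$downsample_factor)
    tc <- train_config(iterations = cfg$train$iterations,
                       checkpoint_interval = cfg$train$checkpoint_interval,
                       alphas = cfg$train$alphas,
                       seed = cfg$seed + 1000L * f)
    ens <- build_ensemble(ncfg, pool, val_pool, tc,
                          n_repeats = cfg$train$n_repeats,
                          alphas = cfg$train$alphas)
    fd <- file.path(cfg$run_dir, "train", sprintf("fold_%d", f))
    dir.create(fd, showWarnings = FALSE, recursive = TRUE)
    saveRDS(ens, file.path(fd, "ensemble.rds"))
    write.csv(do.call(rbind, Map(function(lg, r) {
      lg$repetition <- r
      lg
    }, ens$logs, seq_along(ens$logs))), file.path(fd, "log.csv"),
    row.names = FALSE)
    write_meta_json(list(
      config_hash = cfg$config_hash, fold = f, test = as.list(test_ids),
      val = as.list(val_ids), train = as.list(train_ids),
      members = lapply(ens$members, function(m) {
        list(alpha = m$alpha, repetition = m$repetition,
             iteration = m$iteration, V = m$V)
      })), file.path(fd, "selection.json"))
  }
  invisible(file.path(cfg$run_dir, "train"))
}

cmd_predict <- function(cfg) {
  synth_dir <- file.path(cfg$run_dir, "synth")
  sp <- load_fold_split(cfg)
  for (f in cfg$train$folds) {
    fd <- file.path(cfg$run_dir, "train", sprintf("fold_%d", f))
    ens <- readRDS(require_artifact(file.path(fd, "ensemble.rds"),
                                    "train"))
    sel <- jsonlite::read_json(file.path(fd, "selection.json"))
    test_ids <- unlist(sel$test)
    maps <- list()
    for (id in test_ids) {
      rec <- sp$records[[match(id, vapply(sp$records, `[[`, "", "id"))]]
      bx <- read_biopsy(rec, synth_dir)
      maps[[id]] <- predict_biopsy_ensemble(ens, bx$image,
                                            member_maps = TRUE)
    }
    pd <- file.path(cfg$run_dir, "predict")
    dir.create(pd, showWarnings = FALSE, recursive = TRUE)
    saveRDS(maps, file.path(pd, sprintf("maps_fold_%d.rds", f)))
    write_meta_json(list(config_hash = cfg$config_hash, fold = f,
                         biopsies = as.list(test_ids)),
                    file.path(pd, sprintf("predict_fold_%d.json", f)))
  }
  invisible(file.path(cfg$run_dir, "predict"))
}

cmd_evaluate <- function(cfg) {
  synth_dir <- file.path(cfg$run_dir, "synth")
  sp <- load_fold_split(cfg)
  ncfg <- net_config_from(cfg)
  cell <- cell_area_mm2(ncfg$downsample_factor)
  ed <- file.path(cfg$run_dir, "evaluate")
  dir.create(ed, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  for (f in cfg$train$folds) {
    maps <- readRDS(require_artifact(
      file.path(cfg$run_dir, "predict", sprintf("maps_fold_%d.rds", f)),
      "predict"))
    ids <- names(maps)
    recs <- sp$records[match(ids, vapply(sp$records, `[[`, "", "id"))]
    crib_lab <- "G4 cribriform"
    positive <- vapply(recs, function(r) {
      !is.null(r$counts) && r$counts[[crib_lab]] > 0
    }, logical(1))
    mean_maps <- lapply(maps, function(m) {
      m$mean[, , cribriform_index(label_set())]
    })
    ann_maps <- lapply(recs, function(r) {
      regions <- parse_annotations(file.path(synth_dir, r$annotation_path))
      img_dim <- dim(png::readPNG(file.path(synth_dir, r$image_path)))
      annotation_id_map(regions, img_dim[1], img_dim[2],
                        ncfg$downsample_factor)
    })
    res <- list(config_hash = cfg$config_hash, fold = f,
                n_biopsies = length(ids))
    if (any(positive) && !all(positive)) {
      roc_all <- biopsy_roc(mean_maps, positive, 0, cell)
      res$roc_auc_all <- roc_all$auc
      roc_f <- biopsy_roc(mean_maps, positive, cfg$evaluate$min_area_mm2,
                          cell)
      res$roc_auc_filtered <- roc_f$auc
      write.csv(roc_all$points,
                file.path(ed, sprintf("roc_fold_%d.csv", f)),
                row.names = FALSE)
    }
    if (sum(vapply(ann_maps, max, numeric(1))) > 0) {
      froc <- annotation_froc(mean_maps, ann_maps,
                              connectivity = cfg$evaluate$connectivity,
                              cell_mm2 = cell)
      write.csv(froc$points,
                file.path(ed, sprintf("froc_fold_%d.csv", f)),
                row.names = FALSE)
      res$froc_max_sensitivity <- max(froc$points$sensitivity)
    }
    summaries[[sprintf("fold_%d", f)]] <- res
    write_meta_json(res, file.path(ed, sprintf("evaluate_fold_%d.json",
                                               f)))
  }
  invisible(ed)
}

cmd_report <- function(cfg) {
  ed <- file.path(cfg$run_dir, "evaluate")
  files <- sort(list.files(ed, pattern = "^evaluate_fold_.*\\.json$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("missing artifact 'evaluate_fold_*.json': run the 'evaluate' ",
         "command first")
  }
  folds <- lapply(files, jsonlite::read_json)
  names(folds) <- vapply(folds, function(x) sprintf("fold_%d", x$fold),
                         character(1))
  report <- list(config_hash = cfg$config_hash, profile = cfg$profile,
                 seed = cfg$seed, folds = folds)
  out <- file.path(cfg$run_dir, "report.json")
  write_meta_json(report, out)
  invisible(out)
}

#' Run a sequence of pipeline commands
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param commands Commands to run, in order.
#' @return The last command's artifact path, invisibly.
#' @export
run_chain <- function(config, commands = c("synth", "folds", "train",
                                           "predict", "evaluate",
                                           "report")) {
  cfg <- if (inherits(config, "cribnet_runconfig")) config else
    run_config(config)
  out <- NULL
  for (cmd in commands) out <- run_pipeline(cmd, cfg)
  invisible(out)
}
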