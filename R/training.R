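#' Configure on-the-fly augmentation
#'
#' Geometric transforms (identical for image and masks, applied in the
#' order flip, rotate, scale, translate; bilinear for the image, nearest
#' neighbour for the label map) and photometric transforms (image only):
#' random flips, rotation up to 5 degrees about the image centre, scaling
#' in 0.9..1.1, translation up to 10 percent of the image size, a global
#' per-channel intensity shift up to 0.05, and a linear rescale of the
#' intensity range to a minimum in `[0, 0.1]` and maximum in `[0.9, 1]`.
#'
#' @param flip_prob Probability of each of the vertical/horizontal flips.
#' @param max_rotate_deg Maximum absolute rotation (degrees).
#' @param scale_range Scale factor range.
#' @param translate_frac Maximum translation as a fraction of image size.
#' @param channel_shift Maximum absolute per-channel intensity shift.
#' @param rescale_min,rescale_max Ranges for the linear intensity rescale.
#' @param fill Out-of-canvas image fill (background white).
#' @return List of class `cribnet_augconfig`.
#' @export
augment_config <- function(flip_prob = 0.5, max_rotate_deg = 5,
                           scale_range = c(0.9, 1.1),
                           translate_frac = 0.1, channel_shift = 0.05,
                           rescale_min = c(0, 0.1),
                           rescale_max = c(0.9, 1), fill = 1) {
  structure(list(flip_prob = flip_prob, max_rotate_deg = max_rotate_deg,
                 scale_range = scale_range,
                 translate_frac = translate_frac,
                 channel_shift = channel_shift, rescale_min = rescale_min,
                 rescale_max = rescale_max, fill = fill),
            class = "cribnet_augconfig")
}

#' Augment a patch and its label map
#'
#' Draws transform parameters from the R random number stream, so an
#' enclosing `set.seed()` makes the augmentation reproducible.
#'
#' @param image Numeric `(H, W, 3)` array in `[0, 1]`.
#' @param label_map Integer `H x W` label map aligned with `image`.
#' @param cfg An [augment_config()].
#' @param params Optional fixed parameter list (as returned in the
#'   `params` attribute) to re-apply a specific transform.
#' @return List with transformed `image` and `label_map`; the drawn
#'   parameters are attached as attribute `params`.
#' @export
augment <- function(image, label_map, cfg = augment_config(),
                    params = NULL) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (is.null(params)) {
    params <- draw_augment_params(cfg, H, W)
  }
  warped <- affine_warp_cpp(image, label_map, augment_affine(params, H, W),
                            rep_len(cfg$fill, 3), 1L)
  img <- warped$image
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] + params$shift[ch]
  }
  img <- pmin(pmax(img, 0), 1)
  img <- params$res_min + img * (params$res_max - params$res_min)
  out <- list(image = img, label_map = warped$labels)
  attr(out, "params") <- params
  out
}

draw_augment_params <- function(cfg, H, W) {
  list(
    flip_v = runif(1) < cfg$flip_prob,
    flip_h = runif(1) < cfg$flip_prob,
    theta = runif(1, -1, 1) * cfg$max_rotate_deg * pi / 180,
    scale = runif(1, cfg$scale_range[1], cfg$scale_range[2]),
    t_row = runif(1, -1, 1) * cfg$translate_frac * H,
    t_col = runif(1, -1, 1) * cfg$translate_frac * W,
    shift = runif(3, -cfg$channel_shift, cfg$channel_shift),
    res_min = runif(1, cfg$rescale_min[1], cfg$rescale_min[2]),
    res_max = runif(1, cfg$rescale_max[1], cfg$rescale_max[2]))
}

# forward map: p_out = L (p_in - c) + c + t with L = scale * Rot * Flip;
# the warp samplers need the inverse map p_in = L^-1 (p_out - c - t) + c
augment_affine <- function(params, H, W) {
  Fm <- diag(c(if (params$flip_v) -1 else 1,
               if (params$flip_h) -1 else 1))
  Rm <- matrix(c(cos(params$theta), sin(params$theta),
                 -sin(params$theta), cos(params$theta)), 2, 2)
  L <- params$scale * Rm %*% Fm
  Li <- solve(L)
  cvec <- c((H - 1) / 2, (W - 1) / 2)
  tvec <- c(params$t_row, params$t_col)
  cbind(Li, cvec - Li %*% (cvec + tvec))
}

#' Balanced batch sampler over label-indexed patch pools
#'
#' Every training batch contains one patch drawn from each label's pool,
#' so all 7 labels are represented in every batch (a patch containing
#' several labels belongs to several pools and may be drawn for any of
#' them). Pools are sampled without replacement and reshuffled on
#' exhaustion.
#'
#' @param patch_labels List (one element per patch) of integer label
#'   indices contained in that patch.
#' @param n_labels Number of classes (default 7).
#' @param labelset A [label_set()] used for error messages.
#' @return A function that returns the next batch as an integer vector of
#'   patch indices (one per label, in label order).
#' @export
balanced_batch_sampler <- function(patch_labels, n_labels = 7L,
                                   labelset = label_set()) {
  pools <- lapply(seq_len(n_labels), function(l) {
    which(vapply(patch_labels, function(x) l %in% x, logical(1)))
  })
  empty <- which(vapply(pools, length, integer(1)) == 0L)
  if (length(empty) > 0L) {
    stop("no training patch contains label(s): ",
         paste(labelset$labels[empty], collapse = ", "))
  }
  shuffle <- function(x) x[sample.int(length(x))]
  queues <- lapply(pools, shuffle)
  function() {
    batch <- integer(n_labels)
    for (l in seq_len(n_labels)) {
      if (length(queues[[l]]) == 0L) {
        queues[[l]] <<- shuffle(pools[[l]])
      }
      batch[l] <- queues[[l]][1L]
      queues[[l]] <<- queues[[l]][-1L]
    }
    batch
  }
}

#' Training hyperparameters
#'
#' Defaults follow SGD with learning rate 0.01, decay 5e-4 and momentum
#' 0.99, batch size equal to the label-set size (7), and no explicit
#' stopping criterion: the network trains for a fixed iteration count and
#' checkpoints are kept for later selection. `decay_mode = "lr"`
#' (default) applies the decay to the learning rate per update,
#' `lr_t = lr / (1 + decay * t)`; `"l2"` applies it as an L2 weight
#' penalty instead.
#'
#' @param iterations Total SGD iterations (default 60000; desk-scale runs
#'   use 2000).
#' @param lr,decay,momentum SGD hyperparameters.
#' @param decay_mode `"lr"` or `"l2"`.
#' @param batch_size Batch size; must equal the label count.
#' @param checkpoint_interval Iterations between checkpoints (default
#'   500).
#' @param alphas Selection-metric weights evaluated at each checkpoint.
#' @param eps Dice stabiliser.
#' @param seed Seed controlling batch order, augmentation and weight
#'   initialization.
#' @param max_val_patches Cap on validation patches used for the
#'   selection metric.
#' @return List of class `cribnet_trainconfig`.
#' @export
train_config <- function(iterations = 60000L, lr = 0.01, decay = 5e-4,
                         momentum = 0.99, decay_mode = c("lr", "l2"),
                         batch_size = 7L, checkpoint_interval = 500L,
                         alphas = c(0.2, 0.3, 0.4, 1), eps = 1e-5,
                         seed = 1L, max_val_patches = 64L) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(iterations >= 0L, lr > 0, momentum >= 0, momentum < 1,
            checkpoint_interval >= 1L)
  structure(list(iterations = as.integer(iterations), lr = lr,
                 decay = decay, momentum = momentum,
                 decay_mode = decay_mode,
                 batch_size = as.integer(batch_size),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 alphas = alphas, eps = eps, seed = as.integer(seed),
                 max_val_patches = as.integer(max_val_patches)),
            class = "cribnet_trainconfig")
}

patch_image_double <- function(p) {
  img <- p$image
  if (is.raw(img)) {
    d <- attr(img, "dims")
    img <- array(as.integer(img) / 255, dim = d)
  }
  img
}

#' Compress a patch image to 8-bit storage
#' @param p A patch (list with `image`).
#' @return The patch with the image stored as a raw vector.
#' @export
compress_patch <- function(p) {
  if (!is.raw(p$image)) {
    d <- dim(p$image)
    r <- as.raw(pmin(pmax(round(p$image * 255), 0), 255))
    attr(r, "dims") <- d
    p$image <- r
  }
  p$y_pooled <- NULL  # recomputed after augmentation
  p
}

eval_validation <- function(network, val_patches, pool_factor, n_classes,
                            weights, eps, alphas) {
  nb <- 7L
  probs <- NULL
  ys <- NULL
  i <- 1L
  while (i <= length(val_patches)) {
    idx <- i:min(i + nb - 1L, length(val_patches))
    xb <- simplify2array(lapply(val_patches[idx], patch_image_double))
    if (length(dim(xb)) == 3L) dim(xb) <- c(dim(xb), 1L)
    pb <- net_forward(network, xb, train = FALSE)
    if (length(dim(pb)) == 3L) dim(pb) <- c(dim(pb), 1L)
    yb <- simplify2array(lapply(val_patches[idx], function(p) {
      pool_labels_cpp(p$label_map, as.integer(pool_factor),
                      as.integer(n_classes))
    }))
    if (length(dim(yb)) == 3L) dim(yb) <- c(dim(yb), 1L)
    probs <- if (is.null(probs)) pb else abind4(probs, pb)
    ys <- if (is.null(ys)) yb else abind4(ys, yb)
    i <- i + nb
  }
  ld <- dice_loss(ys, probs, weights, eps)
  lsp <- specificity_loss(ys, probs, weights, eps)
  v <- vapply(alphas, function(a) a * ld + (1 - a) * lsp, numeric(1))
  list(dice = ld, specificity = lsp,
       V = setNames(v, paste0("alpha_", alphas)))
}

abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Train one network with per-interval checkpointing
#'
#' Runs SGD on balanced batches of augmented patches, saving a checkpoint
#' (weights plus the selection metric `V` for every requested `alpha`,
#' evaluated on the validation patches) at iteration 0 and every
#' `checkpoint_interval` iterations. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param network A [build_network()] result (trained in place).
#' @param patches Training patch list; each patch holds `image` (double
#'   array or compressed raw), `label_map`, and `labels` (contained label
#'   indices).
#' @param val_patches Validation patches (no augmentation).
#' @param cfg A [train_config()].
#' @param labelset A [label_set()].
#' @param aug An [augment_config()].
#' @return List with `checkpoints` (each: `iteration`, `weights`, `V`,
#'   `dice`, `specificity`) and `log` (data frame of iteration, learning
#'   rate and loss).
#' @export
train_one <- function(network, patches, val_patches, cfg = train_config(),
                      labelset = label_set(), aug = augment_config()) {
  stopifnot(cfg$batch_size == length(labelset$labels))
  set.seed(cfg$seed)
  nc <- network$config$n_classes
  pf <- network$config$downsample_factor
  w <- labelset$weights
  patches <- lapply(patches, compress_patch)  # 8-bit batch assembly
  sampler <- balanced_batch_sampler(lapply(patches, `[[`, "labels"),
                                    length(labelset$labels), labelset)
  if (length(val_patches) > cfg$max_val_patches) {
    val_patches <- val_patches[sort(sample(length(val_patches),
                                           cfg$max_val_patches))]
  }
  checkpoints <- list()
  take_checkpoint <- function(iter) {
    m <- eval_validation(network, val_patches, pf, nc, w, cfg$eps,
                         cfg$alphas)
    checkpoints[[length(checkpoints) + 1L]] <<- list(
      iteration = iter, weights = get_network_weights(network),
      V = m$V, dice = m$dice, specificity = m$specificity)
  }
  take_checkpoint(0L)
  log_iter <- integer(cfg$iterations)
  log_loss <- numeric(cfg$iterations)
  log_lr <- numeric(cfg$iterations)
  H <- network$config$input_size
  if (cfg$iterations > 0L) {
    for (it in seq_len(cfg$iterations)) {
      idx <- sampler()
      prm <- lapply(idx, function(i) draw_augment_params(aug, H, H))
      batch <- assemble_batch_cpp(
        lapply(patches[idx], `[[`, "image"),
        lapply(patches[idx], `[[`, "label_map"),
        lapply(prm, augment_affine, H = H, W = H),
        do.call(rbind, lapply(prm, function(p) {
          c(p$shift, p$res_min, p$res_max)
        })),
        H, H, aug$fill[1], as.integer(pf), as.integer(nc))
      if (cfg$decay_mode == "lr") {
        lr_t <- cfg$lr / (1 + cfg$decay * (it - 1))
        wd <- 0
      } else {
        lr_t <- cfg$lr
        wd <- cfg$decay
      }
      loss <- cnet_train_step(network$ptr, batch$x, batch$y, w, cfg$eps,
                              lr_t, cfg$momentum, wd)
      if (!is.finite(loss)) {
        stop("training diverged at iteration ", it,
             " (non-finite loss); consider a lower learning rate")
      }
      log_iter[it] <- it
      log_loss[it] <- loss
      log_lr[it] <- lr_t
      if (it %% cfg$checkpoint_interval == 0L) take_checkpoint(it)
    }
    if (cfg$iterations %% cfg$checkpoint_interval != 0L) {
      take_checkpoint(cfg$iterations)
    }
  }
  list(checkpoints = checkpoints,
       log = data.frame(iteration = log_iter, lr = log_lr,
                        loss = log_loss))
}

#' Select the checkpoint minimising the validation metric
#'
#' @param checkpoints Checkpoint list from [train_one()].
#' @param alpha The selection-metric weight to use.
#' @return The selected checkpoint (ties broken towards the earliest).
#' @export
select_checkpoint <- function(checkpoints, alpha) {
  stopifnot(length(checkpoints) >= 1L)
  key <- paste0("alpha_", alpha)
  v <- vapply(checkpoints, function(ck) {
    if (!key %in% names(ck$V)) {
      stop("alpha ", alpha, " was not evaluated at the checkpoints")
    }
    ck$V[[key]]
  }, numeric(1))
  checkpoints[[which.min(v)]]  # which.min returns the first minimum
}

#' Train an ensemble of alpha-selected networks
#'
#' The ensemble follows the repeats-times-alphas scheme: the network is
#' retrained `n_repeats` times with distinct seeds (changing both the
#' weight initialization and the patch order), and from each run's
#' checkpoints one member is selected per `alpha` of the validation
#' metric. The ensemble prediction is the arithmetic mean of the member
#' probability maps (members selecting the same checkpoint are evaluated
#' once and weighted accordingly).
#'
#' @param net_config A [network_config()].
#' @param patches,val_patches As in [train_one()].
#' @param cfg A [train_config()]; member seeds are `cfg$seed + repeat - 1`.
#' @param n_repeats Training repeats (paper scheme: 4).
#' @param alphas Selection weights (paper scheme: 0.2, 0.3, 0.4, 1).
#' @param labelset,aug Passed to [train_one()].
#' @return An object of class `cribnet_ensemble` with `members` (weights,
#'   alpha, repeat index, selected iteration), `net_config` and training
#'   `logs`.
#' @export
build_ensemble <- function(net_config, patches, val_patches,
                           cfg = train_config(), n_repeats = 4L,
                           alphas = c(0.2, 0.3, 0.4, 1),
                           labelset = label_set(),
                           aug = augment_config()) {
  members <- list()
  logs <- list()
  for (r in seq_len(n_repeats)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    cfg_r$alphas <- unique(c(alphas, cfg$alphas))
    net <- build_network(net_config, seed = cfg_r$seed)
    run <- train_one(net, patches, val_patches, cfg_r, labelset, aug)
    logs[[r]] <- run$log
    for (a in alphas) {
      ck <- select_checkpoint(run$checkpoints, a)
      members[[length(members) + 1L]] <- list(
        weights = ck$weights, alpha = a, repetition = r,
        iteration = ck$iteration, V = ck$V[[paste0("alpha_", a)]])
    }
  }
  structure(list(members = members, net_config = net_config, logs = logs),
            class = "cribnet_ensemble")
}

#' Stratified train/validation/test split of a dataset
#'
#' Splits biopsies into train, validation and test sets, stratifying the
#' test and validation draws on cribriform positivity (so both contain
#' positive and negative biopsies in dataset proportion) and ensuring that
#' every label occurring in the dataset retains at least one carrier
#' biopsy in the training set (balanced batch construction needs every
#' label's pool to be non-empty).
#'
#' @param records List of [biopsy_record()]s with per-label `counts`.
#' @param n_test,n_val Set sizes.
#' @param labelset A [label_set()].
#' @return List of record lists `train`, `val`, `test`.
#' @export
split_dataset <- function(records, n_test, n_val = 0L,
                          labelset = label_set()) {
  n <- length(records)
  stopifnot(n_test + n_val < n)
  counts <- t(vapply(records, function(r) {
    cnt <- setNames(numeric(length(labelset$labels)), labelset$labels)
    if (!is.null(r$counts)) cnt[names(r$counts)] <- r$counts
    cnt
  }, numeric(length(labelset$labels))))
  crib <- counts[, cribriform_index(labelset)] > 0
  draw_strat <- function(avail, m) {
    pos <- avail[crib[avail]]
    neg <- avail[!crib[avail]]
    m_pos <- min(length(pos) - 1L, m - 1L,
                 max(1L, round(m * mean(crib))))
    c(sample(pos, m_pos), sample(neg, m - m_pos))
  }
  test_idx <- draw_strat(seq_len(n), n_test)
  rest <- setdiff(seq_len(n), test_idx)
  val_idx <- if (n_val > 0L) draw_strat(rest, n_val) else integer(0)
  train_idx <- setdiff(rest, val_idx)
  # make sure no label loses its last training carrier
  present <- which(colSums(counts) > 0)
  for (l in present) {
    if (sum(counts[train_idx, l]) > 0) next
    donor_pool <- c(val_idx, test_idx)
    donor <- donor_pool[counts[donor_pool, l] > 0][1]
    if (is.na(donor)) next
    # exchange with a train biopsy whose removal keeps all labels covered
    for (cand in train_idx) {
      after <- c(setdiff(train_idx, cand), donor)
      if (all(colSums(counts[after, present, drop = FALSE]) > 0)) {
        train_idx <- after
        if (donor %in% val_idx) {
          val_idx <- c(setdiff(val_idx, donor), cand)
        } else {
          test_idx <- c(setdiff(test_idx, donor), cand)
        }
        break
      }
    }
  }
  list(train = records[sort(train_idx)], val = records[sort(val_idx)],
       test = records[sort(test_idx)])
}

#' Assign biopsies to cross-validation folds by bin packing
#'
#' Two passes: cribriform-containing biopsies are first distributed
#' greedily (decreasing cribriform region count, each to the currently
#' lightest fold) so cribriform annotations spread uniformly across
#' folds; the remaining biopsies are then placed to minimise the summed
#' squared deviation of per-fold per-label region counts from uniform
#' targets. Ties break towards the lower fold index / biopsy id order.
#'
#' @param records List of [biopsy_record()]s with per-label `counts`.
#' @param k Number of folds (default 8).
#' @param labelset A [label_set()].
#' @return List of class `cribnet_folds`: `fold` (named integer vector,
#'   biopsy id to fold), `tallies` (k x labels region-count matrix) and
#'   `n_biopsies` per fold.
#' @export
bin_pack_folds <- function(records, k = 8L, labelset = label_set()) {
  n <- length(records)
  if (k > n) stop("cannot split ", n, " biopsies into ", k, " folds")
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  counts <- t(vapply(records, function(r) {
    cnt <- setNames(numeric(length(labelset$labels)), labelset$labels)
    if (!is.null(r$counts)) cnt[names(r$counts)] <- r$counts
    cnt
  }, numeric(length(labelset$labels))))
  rownames(counts) <- ids
  crib <- counts[, cribriform_index(labelset)]
  fold <- setNames(integer(n), ids)
  tall <- matrix(0, k, ncol(counts), dimnames = list(NULL, colnames(counts)))
  nb <- integer(k)
  # pass 1: cribriform carriers, first-fit decreasing on cribriform count
  carriers <- order(-crib, ids)[crib[order(-crib, ids)] > 0]
  for (i in carriers) {
    f <- which.min(tall[, cribriform_index(labelset)])
    fold[i] <- f
    tall[f, ] <- tall[f, ] + counts[i, ]
    nb[f] <- nb[f] + 1L
  }
  # pass 2: remaining biopsies, minimise squared deviation from uniform
  rest <- order(-rowSums(counts), ids)[crib[order(-rowSums(counts), ids)] == 0]
  target_total <- colSums(counts) / k
  for (i in rest) {
    obj <- vapply(seq_len(k), function(f) {
      t2 <- tall
      t2[f, ] <- t2[f, ] + counts[i, ]
      sum((sweep(t2, 2, target_total))^2)
    }, numeric(1))
    f <- which.min(obj)
    fold[i] <- f
    tall[f, ] <- tall[f, ] + counts[i, ]
    nb[f] <- nb[f] + 1L
  }
  structure(list(fold = fold, tallies = tall, n_biopsies = nb, k = k),
            class = "cribnet_folds")
}
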