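make_flat_patch <- function(label_idx, size = 64L, shade = NULL) {
  # solid-colour patch fully covered by one label: a trivially separable
  # task for smoke-testing the optimisation loop
  shade <- shade %||% (label_idx / 8)
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- shade
  img[, , 2] <- 1 - shade
  img[, , 3] <- (label_idx %% 3) / 3 + 0.1
  list(image = img, label_map = matrix(label_idx, size, size),
       labels = label_idx)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a fixed flip applied twice is the identity", {
  set.seed(1)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  lm <- matrix(sample(1:7, 32 * 32, TRUE), 32, 32)
  prm <- list(flip_v = FALSE, flip_h = TRUE, theta = 0, scale = 1,
              t_row = 0, t_col = 0, shift = c(0, 0, 0), res_min = 0,
              res_max = 1)
  once <- augment(img, lm, params = prm)
  twice <- augment(once$image, once$label_map, params = prm)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_identical(twice$label_map, lm)
  expect_false(identical(once$image, img))
})

test_that("sampled augmentation parameters respect the stated ranges", {
  set.seed(2)
  cfg <- augment_config()
  img <- array(0.5, dim = c(8, 8, 3))
  lm <- matrix(1L, 8, 8)
  for (i in 1:2000) {
    p <- attr(augment(img, lm, cfg), "params")
    expect_lte(abs(p$theta), 5 * pi / 180)
    expect_true(p$scale >= 0.9 && p$scale <= 1.1)
    expect_lte(abs(p$t_row), 0.1 * 8)
    expect_lte(abs(p$t_col), 0.1 * 8)
    expect_true(all(abs(p$shift) <= 0.05))
    expect_true(p$res_min >= 0 && p$res_min <= 0.1)
    expect_true(p$res_max >= 0.9 && p$res_max <= 1)
  }
})

test_that("image and mask undergo the same geometric transform", {
  set.seed(3)
  for (i in 1:10) {
    img <- array(0, dim = c(64, 64, 3))
    lm <- matrix(1L, 64, 64)
    r0 <- sample(20:40, 1)
    c0 <- sample(20:40, 1)
    img[r0 + 0:2, c0 + 0:2, ] <- 1  # bright landmark
    lm[r0 + 0:2, c0 + 0:2] <- 5L    # same landmark in the mask
    out <- augment(img, lm, augment_config(fill = 0))
    bright <- which(out$image[, , 1] > 0.5, arr.ind = TRUE)
    marked <- which(out$label_map == 5L, arr.ind = TRUE)
    if (nrow(bright) == 0 || nrow(marked) == 0) next  # moved off-canvas
    expect_lt(max(abs(colMeans(bright) - colMeans(marked))), 1.5)
  }
})

test_that("balanced batches always contain every label", {
  # pool of exactly 7 single-label patches: each batch is all 7 patches
  labels <- lapply(1:7, function(l) l)
  sampler <- balanced_batch_sampler(labels)
  for (i in 1:5) {
    b <- sampler()
    expect_setequal(b, 1:7)
  }

  # multi-label patches: the union of batch labels covers the label set
  set.seed(6)
  pool_labels <- lapply(1:30, function(i) {
    sort(unique(c(sample(7, sample(1:3, 1)), if (i <= 7) i)))
  })
  sampler <- balanced_batch_sampler(pool_labels)
  for (i in 1:20) {
    b <- sampler()
    expect_length(b, 7)
    expect_true(all(1:7 %in% sort(unique(unlist(pool_labels[b])))))
    # the patch drawn for slot l really contains label l
    for (l in 1:7) expect_true(l %in% pool_labels[[b[l]]])
  }

  expect_error(balanced_batch_sampler(lapply(1:5, function(i) 1L)),
               "G3")
})

test_that("without-replacement pools give near-uniform draw counts", {
  set.seed(8)
  pool_labels <- c(lapply(1:7, function(l) l),
                   lapply(rep(7, 2), function(l) l))  # 3 cribriform patches
  sampler <- balanced_batch_sampler(pool_labels)
  draws <- integer(9)
  for (i in 1:300) {
    b <- sampler()
    draws[b] <- draws[b] + 1
  }
  # cribriform slot cycles its 3 patches without replacement
  crib_draws <- draws[c(7, 8, 9)]
  expect_lte(max(crib_draws) - min(crib_draws), 1)
})

test_that("checkpoint selection minimises V with earliest-tie preference", {
  mk <- function(it, v) list(iteration = it, weights = list(),
                             V = c(alpha_1 = v))
  cks <- list(mk(0, -0.1), mk(500, -0.5), mk(1000, -0.3))
  expect_equal(select_checkpoint(cks, 1)$iteration, 500)
  expect_equal(select_checkpoint(cks[1], 1)$iteration, 0)
  # monotone decreasing V: last checkpoint wins
  dec <- list(mk(0, -0.1), mk(500, -0.2), mk(1000, -0.4))
  expect_equal(select_checkpoint(dec, 1)$iteration, 1000)
  # ties break to the earliest
  tie <- list(mk(0, -0.4), mk(500, -0.4))
  expect_equal(select_checkpoint(tie, 1)$iteration, 0)
  expect_error(select_checkpoint(cks, 0.7), "not evaluated")
})

test_that("zero iterations leave only the initial checkpoint", {
  cfg <- network_config(n_blocks = 2L, base_features = 4L, se_ratio = 2L,
                        input_size = 64L)
  net <- build_network(cfg, seed = 1)
  patches <- lapply(1:7, make_flat_patch)
  run <- train_one(net, patches, patches[1:2],
                   train_config(iterations = 0L, seed = 1))
  expect_length(run$checkpoints, 1)
  expect_equal(run$checkpoints[[1]]$iteration, 0)
  expect_equal(nrow(run$log), 0)
})

test_that("training reduces the loss on separable data, deterministically", {
  cfg <- network_config(n_blocks = 2L, base_features = 4L, se_ratio = 2L,
                        input_size = 64L)
  patches <- lapply(1:7, make_flat_patch)
  tc <- train_config(iterations = 60L, checkpoint_interval = 30L,
                     seed = 11, alphas = c(0.3, 1))
  net1 <- build_network(cfg, seed = 11)
  run1 <- train_one(net1, patches, patches[1:3], tc)
  expect_lt(mean(tail(run1$log$loss, 10)), mean(head(run1$log$loss, 10)))
  # V was evaluated for every alpha at every checkpoint
  expect_length(run1$checkpoints, 3)
  expect_named(run1$checkpoints[[2]]$V, c("alpha_0.3", "alpha_1"))
  # alpha = 1 equals the Dice component exactly
  expect_equal(run1$checkpoints[[2]]$V[["alpha_1"]],
               run1$checkpoints[[2]]$dice)

  # rerun with the same seed: identical loss and V trajectories
  net2 <- build_network(cfg, seed = 11)
  run2 <- train_one(net2, patches, patches[1:3], tc)
  expect_equal(run1$log$loss, run2$log$loss, tolerance = 1e-6)
  expect_equal(vapply(run1$checkpoints, function(ck) ck$V[["alpha_1"]],
                      numeric(1)),
               vapply(run2$checkpoints, function(ck) ck$V[["alpha_1"]],
                      numeric(1)), tolerance = 1e-6)
})

test_that("an ensemble of one is its member; means stay normalized", {
  cfg <- network_config(n_blocks = 2L, base_features = 4L, se_ratio = 2L,
                        input_size = 64L)
  patches <- lapply(1:7, make_flat_patch)
  ens <- build_ensemble(cfg, patches, patches[1:2],
                        train_config(iterations = 10L,
                                     checkpoint_interval = 5L, seed = 2),
                        n_repeats = 1L, alphas = 1)
  expect_length(ens$members, 1)
  img <- array(0.5, dim = c(128, 128, 3))
  out <- predict_biopsy_ensemble(ens, img, patch = 64L,
                                 member_maps = TRUE)
  expect_equal(out$mean, out$members[[1]])
  sums <- apply(out$mean, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("bin packing hits the exhaustive optimum on the crafted instance", {
  counts <- c(5, 4, 3, 2, 1, 1)
  recs <- lapply(seq_along(counts), function(i) {
    biopsy_record(sprintf("b%d", i), "x.png",
                  counts = setNames(as.integer(c(0, 0, 0, 0, 0, 0,
                                                 counts[i])),
                                    CRIB_LABELS))
  })
  fa <- bin_pack_folds(recs, k = 3)
  loads <- fa$tallies[, "G4 cribriform"]
  expect_equal(sort(loads), c(5, 5, 6))
  # exhaustive search over all 3^6 assignments confirms 6 is optimal
  best <- Inf
  for (code in 0:(3^6 - 1)) {
    a <- (code %/% 3^(0:5)) %% 3
    loads_c <- vapply(0:2, function(f) sum(counts[a == f]), numeric(1))
    best <- min(best, max(loads_c))
  }
  expect_equal(best, 6)
  expect_equal(max(loads), best)
})

test_that("fold assignment is a balanced partition on random instances", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    cnts <- t(vapply(seq_len(n), function(j) {
      v <- rpois(7, lambda = c(5, 3, 2, 1, 1, 1, 1))
      v[7] <- ifelse(runif(1) < 0.4, rpois(1, 2), 0)
      v
    }, numeric(7)))
    recs <- lapply(seq_len(n), function(j) {
      biopsy_record(sprintf("b%02d", j), "x.png",
                    counts = setNames(as.integer(cnts[j, ]), CRIB_LABELS))
    })
    fa <- bin_pack_folds(recs, k = k)
    # partition: every biopsy in exactly one fold
    expect_length(fa$fold, n)
    expect_true(all(fa$fold %in% seq_len(k)))
    # tallies recomputed from scratch match the stored tallies
    for (f in seq_len(k)) {
      expect_equal(unname(colSums(cnts[fa$fold == f, , drop = FALSE])),
                   unname(fa$tallies[f, ]))
    }
    # greedy bound: spread of cribriform loads <= largest single count
    crib <- fa$tallies[, "G4 cribriform"]
    if (max(cnts[, 7]) > 0) {
      expect_lte(max(crib) - min(crib), max(cnts[, 7]))
    }
  }
  expect_error(bin_pack_folds(list(biopsy_record("a", "x.png")), k = 3),
               "folds")
})

test_that("stratified splits keep every label trainable", {
  set.seed(17)
  recs <- lapply(1:20, function(i) {
    v <- c(3, rpois(5, 0.4), ifelse(i <= 7, 1L, 0L))
    biopsy_record(sprintf("b%02d", i), "x.png",
                  counts = setNames(as.integer(v), CRIB_LABELS))
  })
  # make one label rare: only biopsy 20 carries complex fused
  recs[[20]]$counts[["G4 complex fused"]] <- 2L
  for (rep in 1:10) {
    sp <- split_dataset(recs, n_test = 4, n_val = 3)
    expect_length(sp$train, 13)
    train_counts <- Reduce(`+`, lapply(sp$train, `[[`, "counts"))
    expect_true(all(train_counts[c("G3", "G4 complex fused",
                                   "G4 cribriform")] > 0))
    test_pos <- vapply(sp$test, function(r) {
      r$counts[["G4 cribriform"]] > 0
    }, logical(1))
    expect_true(any(test_pos) && !all(test_pos))
  }
})
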