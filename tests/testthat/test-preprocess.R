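test_that("optical density follows the log-ratio definition", {
  img <- array(1, dim = c(4, 4, 3))
  od <- optical_density(img, i_max = 1)
  expect_true(all(od$od == 0))

  img[, , 1] <- 0.1
  od <- optical_density(img, i_max = 1)
  expect_equal(od$od[1, 1, 1], 1)  # I = I_max / 10

  img[, , 2] <- 0.7586
  od <- optical_density(img, i_max = 1)
  expect_equal(od$od[1, 1, 2], 0.12, tolerance = 1e-3)

  # zero intensities are clamped, not -Inf
  img[, , 3] <- 0
  od <- optical_density(img, i_max = 1)
  expect_true(all(is.finite(od$od)))
  expect_equal(od$od[1, 1, 3], log10(255), tolerance = 1e-9)

  expect_error(optical_density(img, i_max = 0), "positive")
})

test_that("background mask distinguishes the any/all channel readings", {
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 0.95  # bright red channel: OD < 0.12
  img[, , 2] <- 0.55  # OD ~ 0.26
  img[, , 3] <- 0.60
  od <- optical_density(img, i_max = 1)
  expect_true(all(background_mask(od, mode = "any")))
  expect_false(any(background_mask(od, mode = "all")))

  white <- optical_density(array(1, dim = c(2, 2, 3)), i_max = 1)
  expect_true(all(background_mask(white, mode = "all")))
})

test_that("tiling enumerates the stride grid and discards background", {
  # tissue-coloured 1024x1536 image: padded to 1536x2048, giving a 3x4 grid
  img <- array(0.5, dim = c(1024, 1536, 3))
  tl <- tile(img, patch = 1024L, stride = 512L, i_max = 1)
  expect_equal(tl$geom$H, 1536)
  expect_equal(tl$geom$W, 2048)
  expect_equal(nrow(tl$report), 2 * 3)
  expect_true(all(tl$report$retained))
  expect_false(anyDuplicated(tl$report[, c("row", "col")]) > 0)
  # tiling is exhaustive over the padded canvas
  cover <- matrix(FALSE, tl$geom$H, tl$geom$W)
  for (i in seq_len(nrow(tl$report))) {
    cover[tl$report$row[i] + 1:1024, tl$report$col[i] + 1:1024] <- TRUE
  }
  expect_true(all(cover))

  # an all-white image yields no patches at all
  white <- array(1, dim = c(1024, 1024, 3))
  expect_length(tile(white, patch = 1024L, i_max = 1)$patches, 0)

  # tissue only in the left half: right-edge patches are dropped
  half <- array(1, dim = c(1024, 2048, 3))
  half[, 1:512, ] <- 0.5
  tlh <- tile(half, patch = 1024L, stride = 512L, i_max = 1)
  cols_kept <- unique(vapply(tlh$patches, function(p) p$origin["col"],
                             numeric(1)))
  expect_true(all(cols_kept < 1024))
})

test_that("average pooling conserves mass and matches a block-mean oracle", {
  lm <- matrix(1L, 64, 64)
  lm[1:16, 1:48] <- 2L
  y <- label_map_to_masks(lm, 3)
  pooled <- pool_mask(y, kernel = 32L)
  expect_equal(dim(pooled), c(2, 2, 3))
  # block fractions sum to 1 per cell
  expect_equal(apply(pooled, c(1, 2), sum), matrix(1, 2, 2))
  # mass conservation: pooled sum * kernel^2 equals full-resolution sum
  for (k in 1:3) {
    expect_equal(sum(pooled[, , k]) * 32^2, sum(y[, , k]))
  }
  # all-ones class pools to 1; a block with 256/1024 set pools to 0.25
  expect_equal(pooled[2, 2, 1], 1)
  expect_equal(pooled[1, 2, 2], 16 * 16 / 1024)  # rows 1:16 of cols 33:48

  # random one-hot stack against a naive double-loop oracle
  set.seed(9)
  lm <- matrix(sample(1:3, 64 * 64, replace = TRUE), 64, 64)
  p2 <- pool_mask(lm, kernel = 16L, n_classes = 3L)
  for (i in 1:4) {
    for (j in 1:4) {
      block <- lm[(i - 1) * 16 + 1:16, (j - 1) * 16 + 1:16]
      for (k in 1:3) {
        expect_equal(p2[i, j, k], mean(block == k), tolerance = 1e-7)
      }
    }
  }

  expect_error(pool_mask(array(1, dim = c(30, 30, 2)), kernel = 32L),
               "multiple")
})

test_that("reassembly takes each output pixel from one patch centre", {
  # stub predictor writing the patch index everywhere lets us trace the
  # provenance of every reassembled pixel
  img <- array(0.5, dim = c(512, 1024, 3))
  tl <- tile(img, patch = 256L, stride = 128L, pool_factor = 4L,
             i_max = 1, max_background = 1)
  preds <- lapply(seq_along(tl$patches), function(i) {
    list(origin = tl$patches[[i]]$origin,
         prob = array(i, dim = c(64, 64, 1)))
  })
  out <- reassemble(preds, tl$geom, tl$shape, patch = 256L, factor = 4L)
  expect_equal(dim(out), c(128, 256, 1))
  # each pixel must come from the patch whose centre window contains it
  for (i in seq_along(preds)) {
    orr <- preds[[i]]$origin[1] / 4
    occ <- preds[[i]]$origin[2] / 4
    win <- 16 + 1:32
    rows <- orr + win - tl$geom$top / 4
    cols <- occ + win - tl$geom$left / 4
    rows <- rows[rows >= 1 & rows <= 128]
    cols <- cols[cols >= 1 & cols <= 256]
    if (length(rows) && length(cols)) {
      expect_true(all(out[rows, cols, 1] == i))
    }
  }

  # constant predictor reassembles to a constant map
  cpreds <- lapply(preds, function(p) {
    p$prob <- array(0.25, dim = c(64, 64, 1)); p
  })
  cm <- reassemble(cpreds, tl$geom, tl$shape, patch = 256L, factor = 4L)
  expect_true(all(cm == 0.25))

  # a missing patch for a covered location is an error naming the origin
  expect_error(
    reassemble(preds[-1], tl$geom, tl$shape, patch = 256L, factor = 4L),
    "missing patch")
})

test_that("area-average resampling reduces by the requested factor", {
  set.seed(2)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  small <- resample_image(img, 4L)
  expect_equal(dim(small), c(8, 8, 3))
  expect_equal(small[1, 1, 2], mean(img[1:4, 1:4, 2]))
})
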