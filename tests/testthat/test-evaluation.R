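test_that("region extraction respects cutoff, connectivity and area filter", {
  pm <- matrix(0, 8, 8)
  expect_equal(nrow(extract_regions(pm, 0.5)), 0)

  # two blobs touching only diagonally
  pm2 <- matrix(0, 6, 6)
  pm2[2, 2] <- 0.9
  pm2[3, 3] <- 0.8
  expect_equal(nrow(extract_regions(pm2, 0.5, connectivity = 8L)), 1)
  expect_equal(nrow(extract_regions(pm2, 0.5, connectivity = 4L)), 2)

  # the 0.0150 mm2 filter on the 29.44 um grid: 18 px pass, 17 px fail
  cell <- cell_area_mm2(32L, 0.92)
  expect_lt(abs(cell - 8.667136e-4), 1e-9)  # (32 * 0.92 um)^2 per cell
  mk <- function(n) {
    m <- matrix(0, 10, 10)
    m[seq_len(n)] <- 0.9  # column-major: a single 8-connected component
    m
  }
  r18 <- extract_regions(mk(18), 0.5, min_area_mm2 = 0.0150,
                         cell_mm2 = cell)
  expect_equal(nrow(r18), 1)
  expect_gt(r18$area_mm2, 0.0150)
  r17 <- extract_regions(mk(17), 0.5, min_area_mm2 = 0.0150,
                         cell_mm2 = cell)
  expect_equal(nrow(r17), 0)

  # cutoff semantics are strictly greater-than
  pm3 <- matrix(0.5, 2, 2)
  expect_equal(nrow(extract_regions(pm3, 0.5)), 0)
  expect_equal(nrow(extract_regions(pm3, 0.4999)), 1)
})

test_that("regions at a higher cutoff nest inside lower-cutoff regions", {
  set.seed(12)
  for (i in 1:10) {
    pm <- matrix(runif(30 * 30), 30, 30)
    c1 <- runif(1, 0.1, 0.5)
    c2 <- runif(1, c1 + 0.05, 0.9)
    lo <- attr(extract_regions(pm, c1), "labels")
    hi <- extract_regions(pm, c2)
    hilab <- attr(hi, "labels")
    for (j in seq_len(nrow(hi))) {
      parents <- unique(lo[hilab == j])
      expect_length(parents, 1)
      expect_gt(parents, 0)
    }
  }
})

test_that("the biopsy score equals a direct cutoff sweep", {
  set.seed(31)
  for (i in 1:10) {
    pm <- matrix(round(runif(100), 2), 10, 10)
    min_area <- sample(0:3, 1) * 5e-4
    cell <- 8.6677e-4
    s <- biopsy_score(pm, min_area, cell)
    for (ct in c(0, 0.3, s - 1e-9, s, 0.99)) {
      if (ct < 0) next
      predicted <- nrow(extract_regions(pm, ct, 8L, min_area, cell)) > 0
      expect_equal(predicted, s > ct,
                   info = sprintf("i=%d cutoff=%.4f score=%.4f", i, ct, s))
    }
  }
})

test_that("biopsy ROC equals the Mann-Whitney statistic of biopsy scores", {
  mk <- function(v) matrix(v, 4, 4)
  # crafted 4-biopsy instance with distinct qualifying probabilities
  maps <- list(mk(0.9), mk(0.7), mk(0.6), mk(0.2))
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  roc <- biopsy_roc(maps, pos)
  scores <- vapply(maps, biopsy_score, numeric(1))
  mw <- mean(outer(scores[pos], scores[!pos],
                   function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc$auc, mw)

  # random instances, including ties
  set.seed(90)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    maps <- lapply(seq_len(n), function(j) {
      matrix(sample(seq(0, 1, 0.1), 16, replace = TRUE), 4, 4)
    })
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    roc <- biopsy_roc(maps, pos)
    s <- vapply(maps, biopsy_score, numeric(1))
    mw <- mean(outer(s[pos], s[!pos],
                     function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc$auc, mw, tolerance = 1e-12)
    # curve invariants
    expect_true(all(diff(roc$points$cutoff) < 0))
    expect_true(all(diff(roc$points$sensitivity) >= 0))
    expect_true(all(roc$points$sensitivity >= 0 &
                    roc$points$sensitivity <= 1))
    expect_true(all(roc$points$x >= 0 & roc$points$x <= 1))
  }

  # degenerate cases
  expect_error(biopsy_roc(maps, rep(TRUE, length(maps))), "positive")
  same <- list(mk(0.5), mk(0.5), mk(0.5), mk(0.5))
  expect_equal(biopsy_roc(same, c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  perfect <- biopsy_roc(list(mk(0.9), mk(0.8), mk(0.1), mk(0.05)),
                        c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
})

test_that("FROC reproduces hand enumeration on a crafted biopsy", {
  # 1 biopsy, 2 annotations, 3 detections: 1 hit, 2 misses
  pm <- matrix(0, 12, 12)
  pm[2:3, 2:3] <- 0.9    # detection A (hits annotation 1)
  pm[8:9, 2:3] <- 0.8    # detection B (no annotation)
  pm[2:3, 9:10] <- 0.7   # detection C (no annotation)
  amap <- matrix(0L, 12, 12)
  amap[2:3, 2:3] <- 1L   # annotation 1 (hit by A)
  amap[8:9, 9:10] <- 2L  # annotation 2 (missed)
  froc <- annotation_froc(list(pm), list(amap), cutoffs = 0.5)
  expect_equal(froc$points$sensitivity, 0.5)
  expect_equal(froc$points$x, 2.0)

  # no detections at all
  froc0 <- annotation_froc(list(matrix(0, 5, 5)),
                           list({
                             m <- matrix(0L, 5, 5)
                             m[2, 2] <- 1L
                             m
                           }), cutoffs = 0.5)
  expect_equal(froc0$points$sensitivity, 0)
  expect_equal(froc0$points$x, 0)

  # a detection exactly coincident with its annotation: hit, no FP
  pm1 <- matrix(0, 5, 5)
  pm1[2:3, 2:3] <- 0.9
  am1 <- matrix(0L, 5, 5)
  am1[2:3, 2:3] <- 1L
  froc1 <- annotation_froc(list(pm1), list(am1), cutoffs = 0.5)
  expect_equal(froc1$points$sensitivity, 1)
  expect_equal(froc1$points$x, 0)

  expect_error(annotation_froc(list(pm), list(matrix(0L, 12, 12))),
               "annotation")
})

test_that("FROC sensitivity and FP rate fall as the cutoff rises", {
  set.seed(21)
  for (i in 1:50) {
    pm <- bump_map(40, 60, n_bumps = sample(2:5, 1))
    centers <- attr(pm, "centers")
    amap <- matrix(0L, 40, 60)
    # annotate the cores of a random subset of bumps: hits keep their
    # peak while they exist, the rest are false positives
    ann <- which(runif(nrow(centers)) < 0.5)
    for (j in seq_along(ann)) {
      rr <- round(centers[ann[j], 1]) + 1
      cc <- round(centers[ann[j], 2]) + 1
      amap[max(1, rr - 1):min(40, rr + 1),
           max(1, cc - 1):min(60, cc + 1)] <- j
    }
    if (length(ann) == 0) next
    froc <- annotation_froc(list(pm), list(amap),
                            cutoffs = seq(0.05, 0.95, by = 0.1))
    expect_true(all(diff(froc$points$sensitivity) >= 0))  # cutoffs desc
    expect_true(all(diff(froc$points$x) >= 0))
  }
})

test_that("contour restriction governs the image-level decision", {
  pm <- matrix(0, 10, 10)
  contour <- matrix(FALSE, 10, 10)
  contour[3:7, 3:7] <- TRUE
  expect_false(contour_decision(pm, contour, 0.0125))
  # single in-contour pixel at 0.02: called at 0.0125, not at 0.1
  pm[5, 5] <- 0.02
  expect_true(contour_decision(pm, contour, 0.0125))
  expect_false(contour_decision(pm, contour, 0.1))
  # a high-probability blob strictly outside the contour never triggers
  pm2 <- matrix(0, 10, 10)
  pm2[9:10, 9:10] <- 0.99
  expect_false(contour_decision(pm2, contour, 0.0125))
  expect_error(contour_decision(pm, matrix(FALSE, 10, 10), 0.5), "empty")
})

test_that("Cohen's kappa matches hand-computed agreement", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # rater B constant, rater A balanced: chance-level agreement
  expect_equal(cohens_kappa(rep(c("x", "y"), 10), rep("x", 20)), 0)
  # 2x2 table a=20 b=5 c=10 d=15: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- c(rep("pos", 25), rep("neg", 25))
  b <- c(rep("pos", 20), rep("neg", 5), rep("pos", 10), rep("neg", 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  expect_error(cohens_kappa(c("a", "b"), c("a")), "length")
})

test_that("connected component labelling agrees with an independent oracle", {
  skip_if_not_installed("EBImage")
  set.seed(14)
  for (i in 1:5) {
    m <- matrix(runif(400) > 0.6, 20, 20)
    ours <- cribnet:::label_components_cpp(m, 4L)
    ref <- EBImage::bwlabel(matrix(as.numeric(m), 20, 20))
    # same partition: component counts and co-membership agree
    expect_equal(max(ours), max(ref))
    expect_equal(length(unique(paste(ours, ref))) - 1, max(ref))
  }
})
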