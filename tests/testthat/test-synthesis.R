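test_that("archetype specs enforce their invariants", {
  expect_error(archetype_spec("G4 cribriform", c(1, 1), c(50, 80),
                              c(2L, 4L)), "at least 3 lumina")
  expect_error(archetype_spec("G3", c(1, 1), c(20, 30), c(1L, 1L),
                              fusion_degree = 0.5), "not fused")
  expect_error(he_colors(background = c(1.2, 0, 0)), "0, 1")
})

test_that("generation is deterministic and masks match the annotations", {
  cfg <- small_synth_config(seed = 21)
  b1 <- generate_biopsy(cfg)
  b2 <- generate_biopsy(cfg)
  expect_identical(b1$image, b2$image)
  expect_identical(b1$label_map, b2$label_map)
  # pixel-exact mask/annotation agreement
  relab <- rasterize_label_map(b1$regions, nrow(b1$label_map),
                               ncol(b1$label_map))
  expect_identical(relab, b1$label_map)
  # per-pixel one-hot partition
  sums <- apply(b1$masks, c(1, 2), sum)
  expect_true(all(sums == 1))
})

test_that("zero archetypes yield a pure stroma strip", {
  cfg <- small_synth_config(seed = 3)
  cfg$counts <- setNames(as.list(rep(0L, 6)),
                         vapply(cfg$archetypes, `[[`, "", "label"))
  bx <- generate_biopsy(cfg)
  expect_length(bx$regions, 0)
  expect_true(all(bx$label_map == 1L))
  expect_gt(mean(bx$strip_mask), 0.1)  # tissue still present
})

test_that("background pixels satisfy the optical-density criterion", {
  bx <- generate_biopsy(small_synth_config(seed = 8))
  bg <- background_mask(optical_density(bx$image))
  expect_gte(mean(bg[!bx$strip_mask]), 0.99)
  # and the strip itself is recovered as foreground
  expect_gte(mean((!bg) == bx$strip_mask), 0.99)
})

test_that("archetypes share colours: morphology is the only separator", {
  cfg <- synthesis_config(seed = 15, canvas_px = c(512L, 1536L))
  cfg$counts <- list(`G3` = 0L, `G4 fused` = 2L, `G4 ill-defined` = 0L,
                     `G4 complex fused` = 0L, `G4 glomeruloid` = 0L,
                     `G4 cribriform` = 2L)
  bx <- generate_biopsy(cfg)
  # median chromaticity over the epithelium luminance band: the
  # multiplicative stromal texture cancels out and lumina (bright) and
  # nuclei (dark) are excluded
  epi_chroma <- function(label) {
    px <- bx$label_map == label_index(label_set(), label)
    lum <- bx$image[, , 1] + bx$image[, , 2] + bx$image[, , 3]
    sel <- px & lum / 3 > 0.45 & lum / 3 < 0.62
    sapply(1:3, function(ch) median((bx$image[, , ch] / lum)[sel]))
  }
  d <- abs(epi_chroma("G4 cribriform") - epi_chroma("G4 fused"))
  expect_lt(max(d), cfg$colors$noise)
})

test_that("a requested target area is met within tolerance", {
  # one cribriform gland of target area a = 0.0155 mm2
  a <- 0.0155
  r_um <- sqrt(a * 1e6 / pi)
  cfg <- synthesis_config(seed = 5, canvas_px = c(512L, 1536L))
  cfg$archetypes$`G4 cribriform`$radius_um <- c(r_um, r_um)
  cfg$counts <- list(`G3` = 0L, `G4 fused` = 0L, `G4 ill-defined` = 0L,
                     `G4 complex fused` = 0L, `G4 glomeruloid` = 0L,
                     `G4 cribriform` = 1L)
  bx <- generate_biopsy(cfg)
  area <- sum(bx$label_map == 7L) * (0.92e-3)^2
  expect_lt(abs(area - a) / a, 0.2)
})

test_that("unplaceable archetypes raise an error naming the label", {
  cfg <- small_synth_config(seed = 2)
  cfg$archetypes$`G4 cribriform`$radius_um <- c(300, 300)  # too large
  cfg$counts <- list(`G3` = 0L, `G4 fused` = 0L, `G4 ill-defined` = 0L,
                     `G4 complex fused` = 0L, `G4 glomeruloid` = 0L,
                     `G4 cribriform` = 1L)
  expect_error(generate_biopsy(cfg), "G4 cribriform")
})

test_that("datasets cover all labels and honour the cribriform prevalence", {
  dir <- withr::local_tempdir()
  recs <- generate_dataset(8, small_synth_config(), seed = 4, dir = dir)
  expect_length(recs, 8)
  counts <- Reduce(`+`, lapply(recs, `[[`, "counts"))
  expect_true(all(counts[-1] >= 1))  # every archetype occurs somewhere
  # files exist and the manifest round-trips
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_manifest(file.path(dir, "manifest.json"))
  expect_equal(vapply(back, `[[`, "", "id"),
               vapply(recs, `[[`, "", "id"))
  # the written annotation XML reproduces the rendered mask
  bx <- read_biopsy(back[[1]], dir)
  regions <- parse_annotations(file.path(dir, back[[1]]$annotation_path))
  relab <- rasterize_label_map(regions, nrow(bx$label_map),
                               ncol(bx$label_map))
  expect_equal(mean(relab == bx$label_map), 1, tolerance = 1e-4)

  # identical seeds give identical manifests
  dir2 <- withr::local_tempdir()
  recs2 <- generate_dataset(8, small_synth_config(), seed = 4, dir = dir2)
  expect_equal(lapply(recs, `[[`, "counts"), lapply(recs2, `[[`, "counts"))
})

test_that("the cribriform-positive fraction tracks the requested rate", {
  dir <- withr::local_tempdir()
  recs <- generate_dataset(40, small_synth_config(), seed = 10, dir = dir)
  pos <- vapply(recs, function(r) r$counts[["G4 cribriform"]] > 0,
                logical(1))
  expect_lt(abs(mean(pos) - 0.35), 0.10)
})
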