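test_that("label set validates its invariants", {
  ls7 <- label_set()
  expect_length(ls7$labels, 7)
  expect_equal(sum(ls7$weights), 1, tolerance = 1e-12)
  expect_equal(ls7$weights[cribnet:::cribriform_index(ls7)], 0.4)
  expect_equal(sort(unique(ls7$weights)), c(0.1, 0.4))
  expect_error(label_set(labels = CRIB_LABELS[1:5]), "exactly 7")
  expect_error(label_set(weights = rep(0.2, 7)), "sum to 1")
  expect_equal(label_index(ls7, "G4 CRIBRIFORM"), 7L)
  expect_error(label_index(ls7, "G6"), "unknown label")
})

test_that("annotation write/parse round-trips vertices and labels", {
  ls7 <- label_set()
  set.seed(42)
  regions <- lapply(1:3, function(i) {
    poly <- cbind(row = runif(5, 10, 200), col = runif(5, 10, 400))
    annotation_region(poly, sample(ls7$labels, 1), ls7,
                      name = paste("ann", i))
  })
  f <- withr::local_tempfile(fileext = ".xml")
  write_annotations(regions, f)
  back <- parse_annotations(f, ls7)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$label, regions[[i]]$label)
    expect_lt(max(abs(back[[i]]$polygon - regions[[i]]$polygon)), 0.01)
    expect_equal(back[[i]]$area_mm2, regions[[i]]$area_mm2,
                 tolerance = 0.01)
  }
})

test_that("an empty annotation file parses to an empty list", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_annotations(list(), f)
  expect_length(parse_annotations(f), 0)
})

test_that("group names map case-insensitively; bad input errors", {
  ls7 <- label_set()
  f <- withr::local_tempfile(fileext = ".xml")
  r <- annotation_region(square_polygon(5, 40), "G4 cribriform", ls7)
  r$label <- "G4 CRIBRIFORM"  # shout-case group in the file
  write_annotations(list(r), f)
  expect_equal(parse_annotations(f, ls7)[[1]]$label, "G4 cribriform")

  writeLines(c("<ASAP_Annotations><Annotations>",
               "<Annotation Name='a1' PartOfGroup='not-a-label'>",
               "<Coordinates>",
               "<Coordinate Order='0' X='1' Y='1'/>",
               "<Coordinate Order='1' X='9' Y='1'/>",
               "<Coordinate Order='2' X='9' Y='9'/>",
               "</Coordinates></Annotation></Annotations>",
               "</ASAP_Annotations>"), f)
  expect_error(parse_annotations(f, ls7), "not-a-label")

  writeLines(c("<ASAP_Annotations><Annotations>",
               "<Annotation Name='a2' PartOfGroup='G3'>",
               "<Coordinates>",
               "<Coordinate Order='0' X='1' Y='1'/>",
               "<Coordinate Order='1' X='9' Y='1'/>",
               "</Coordinates></Annotation></Annotations>",
               "</ASAP_Annotations>"), f)
  expect_error(parse_annotations(f, ls7), "a2")
})

test_that("a small-area region survives the round-trip with area intact", {
  # a realistic smallest-cribriform-sized region, about 0.0155 mm2:
  # radius r with pi r^2 * (0.92e-3)^2 = 0.0155 -> r ~ 76.4 px
  ls7 <- label_set()
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- 76.4
  poly <- cbind(row = 100 + r * sin(th), col = 100 + r * cos(th))
  reg <- annotation_region(poly, "G4 cribriform", ls7)
  expect_equal(reg$area_mm2, 0.0155, tolerance = 0.01)
  f <- withr::local_tempfile(fileext = ".xml")
  write_annotations(list(reg), f)
  back <- parse_annotations(f, ls7)[[1]]
  expect_equal(back$area_mm2, reg$area_mm2, tolerance = 0.01)
})

test_that("rasterization assigns every pixel exactly one class", {
  ls7 <- label_set()
  # axis-aligned 100x100 square: pixel-centre convention gives 100 rows
  # and columns from 10..109 inclusive
  sq <- annotation_region(square_polygon(10, 109), "G3", ls7)
  masks <- rasterize_annotations(list(sq), 128, 128, ls7)
  expect_equal(sum(masks[, , label_index(ls7, "G3")]), 100 * 100)
  expect_true(all(apply(masks, c(1, 2), sum) == 1))

  # empty region list: everything is non-labelled
  m0 <- rasterize_annotations(list(), 64, 64, ls7)
  expect_equal(sum(m0[, , 1]), 64 * 64)
  expect_true(all(m0[, , -1] == 0))

  # two disjoint squares with different labels stay disjoint
  r1 <- annotation_region(square_polygon(2, 20), "G3", ls7)
  r2 <- annotation_region(square_polygon(30, 50), "G4 fused", ls7)
  m2 <- rasterize_annotations(list(r1, r2), 64, 64, ls7)
  expect_true(all(apply(m2, c(1, 2), sum) == 1))
  expect_equal(sum(m2[, , 2] * m2[, , 3]), 0)

  # overlapping polygons: later region wins, with a warning
  r3 <- annotation_region(square_polygon(10, 40), "G4 cribriform", ls7)
  expect_warning(m3 <- rasterize_label_map(list(r1, r3), 64, 64, ls7),
                 "later region wins")
  expect_equal(m3[15, 15], 7L)
})

test_that("shoelace area matches rasterized pixel count for convex polygons", {
  set.seed(7)
  for (i in 1:5) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    r <- runif(1, 15, 40)
    poly <- cbind(row = 60 + r * sin(th), col = 60 + r * cos(th))
    area_sl <- polygon_area_px(poly)
    lm <- matrix(1L, 128L, 128L)
    cribnet:::fill_polygon_cpp(lm, poly, 2L, 1L)
    expect_equal(sum(lm == 2L), area_sl, tolerance = 0.02 * area_sl)
  }
})

test_that("manifest save/load is the identity", {
  recs <- lapply(1:8, function(i) {
    biopsy_record(sprintf("b%02d", i), sprintf("b%02d.png", i),
                  sprintf("b%02d.xml", i),
                  counts = setNames(as.integer(rmultinom(1, 10, rep(1, 7))),
                                    CRIB_LABELS))
  })
  f <- withr::local_tempfile(fileext = ".json")
  save_manifest(recs, f)
  back <- load_manifest(f)
  expect_equal(length(back), 8)
  for (i in 1:8) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$counts, recs[[i]]$counts)
    expect_equal(back[[i]]$pixel_size_um, recs[[i]]$pixel_size_um)
  }
})
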