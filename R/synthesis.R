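#' Describe a growth-pattern archetype for the synthetic generator
#'
#' Archetypes are geometric caricatures of the annotated Gleason growth
#' patterns: a G3 gland is a single ring with one lumen, fused glands are
#' short chains of merged rings, complex fused glands carry several
#' irregular lumina, a glomeruloid gland is one large lumen with an
#' epithelial tuft attached to its wall, an ill-defined gland is a diffuse
#' nuclear cluster without lumina, and a cribriform gland is a confluent
#' epithelial blob perforated by at least three small round lumina
#' (sieve-like). All archetypes share the same stain palette, so they can
#' only be told apart by morphology.
#'
#' @param label Label name from [CRIB_LABELS].
#' @param count_range Per-biopsy instance count range (inclusive).
#' @param radius_um Characteristic gland radius range in micrometres.
#' @param lumina_range Lumina count range per gland (cribriform must be
#'   at least 3; single-lumen patterns use `c(1, 1)`; ill-defined
#'   `c(0, 0)`).
#' @param fusion_degree Degree of ring merging in `[0, 1]` (0 for G3).
#' @param nuclear_density Epithelial nuclei per 1000 square micrometres.
#' @param prevalence Probability that a biopsy contains the archetype at
#'   all (used by [generate_dataset()]).
#' @return An object of class `cribnet_archetype`.
#' @export
archetype_spec <- function(label, count_range, radius_um, lumina_range,
                           fusion_degree = 0, nuclear_density = 8,
                           prevalence = 1) {
  stopifnot(length(count_range) == 2L, count_range[1] <= count_range[2],
            length(radius_um) == 2L, radius_um[1] <= radius_um[2],
            radius_um[1] > 0,
            length(lumina_range) == 2L,
            lumina_range[1] <= lumina_range[2],
            fusion_degree >= 0, fusion_degree <= 1,
            prevalence >= 0, prevalence <= 1)
  if (tolower(label) == "g4 cribriform" && lumina_range[1] < 3) {
    stop("cribriform archetypes must have at least 3 lumina per gland")
  }
  if (tolower(label) == "g3" && fusion_degree != 0) {
    stop("G3 glands are not fused (fusion_degree must be 0)")
  }
  structure(list(label = label, count_range = as.integer(count_range),
                 radius_um = radius_um,
                 lumina_range = as.integer(lumina_range),
                 fusion_degree = fusion_degree,
                 nuclear_density = nuclear_density,
                 prevalence = prevalence),
            class = "cribnet_archetype")
}

#' Default archetype mix
#'
#' Prevalences follow the per-biopsy label frequencies of a clinical
#' needle-biopsy cohort in which roughly a third of biopsies harbour a
#' cribriform region, G3 is nearly ubiquitous, and complex fused or
#' glomeruloid patterns are rare.
#'
#' @return Named list of [archetype_spec()]s (all labels except
#'   non-labelled).
#' @export
default_archetypes <- function() {
  list(
    `G3` = archetype_spec("G3", c(2L, 4L), c(25, 40), c(1L, 1L),
                          0, 10, prevalence = 0.95),
    `G4 fused` = archetype_spec("G4 fused", c(1L, 2L), c(45, 70),
                                c(2L, 3L), 0.7, 9, prevalence = 0.45),
    `G4 ill-defined` = archetype_spec("G4 ill-defined", c(1L, 2L),
                                      c(40, 60), c(0L, 0L), 0, 9,
                                      prevalence = 0.55),
    `G4 complex fused` = archetype_spec("G4 complex fused", c(1L, 1L),
                                        c(55, 80), c(4L, 6L), 0.85, 9,
                                        prevalence = 0.15),
    `G4 glomeruloid` = archetype_spec("G4 glomeruloid", c(1L, 1L),
                                      c(40, 55), c(1L, 1L), 0, 9,
                                      prevalence = 0.25),
    `G4 cribriform` = archetype_spec("G4 cribriform", c(1L, 2L),
                                     c(55, 85), c(6L, 12L), 0, 11,
                                     prevalence = 0.35)
  )
}

#' H&E-like colour model for the renderer
#'
#' Tissue colours are chosen so that every stained pixel keeps an optical
#' density of at least 0.12 in *all* channels (the background criterion is
#' per-channel), while unstained background and gland lumina sit near
#' white. All gland archetypes share the epithelium colour.
#'
#' @param hematoxylin,eosin,epithelium,lumen,background RGB triplets in
#'   `[0, 1]`.
#' @param noise Amplitude (standard deviation) of the smoothed additive
#'   texture noise.
#' @return Named list of colours.
#' @export
he_colors <- function(hematoxylin = c(0.32, 0.26, 0.55),
                      eosin = c(0.68, 0.50, 0.62),
                      epithelium = c(0.60, 0.42, 0.58),
                      lumen = c(0.72, 0.71, 0.74),
                      background = c(0.965, 0.960, 0.970),
                      noise = 0.015) {
  cols <- list(hematoxylin = hematoxylin, eosin = eosin,
               epithelium = epithelium, lumen = lumen,
               background = background, noise = noise)
  for (nm in setdiff(names(cols), "noise")) {
    if (any(cols[[nm]] < 0 | cols[[nm]] > 1)) {
      stop("colour '", nm, "' must lie in [0, 1]")
    }
  }
  cols
}

#' Configure the synthetic biopsy generator
#'
#' @param seed Integer seed; a fixed seed yields a bit-identical biopsy.
#' @param canvas_px Canvas size `(H, W)` in pixels (default 2048 x 6144;
#'   the desk profile uses 512 x 1536).
#' @param pixel_size_um Pixel pitch (default 0.92).
#' @param strip_width_um Width of the needle-biopsy tissue strip; default
#'   45 percent of the canvas height.
#' @param archetypes List of [archetype_spec()]s.
#' @param counts Optional named integer vector fixing the per-archetype
#'   instance counts (overrides the count ranges; used by
#'   [generate_dataset()]).
#' @param colors A [he_colors()] palette.
#' @param labelset A [label_set()].
#' @return An object of class `cribnet_synthconfig`.
#' @export
synthesis_config <- function(seed = 1L, canvas_px = c(2048L, 6144L),
                             pixel_size_um = 0.92, strip_width_um = NULL,
                             archetypes = default_archetypes(),
                             counts = NULL, colors = he_colors(),
                             labelset = label_set()) {
  canvas_px <- as.integer(canvas_px)
  if (is.null(strip_width_um)) {
    strip_width_um <- 0.45 * canvas_px[1] * pixel_size_um
  }
  if (strip_width_um / pixel_size_um > 0.85 * canvas_px[1]) {
    stop("canvas is too small for the requested tissue-strip width")
  }
  structure(list(seed = as.integer(seed), canvas_px = canvas_px,
                 pixel_size_um = pixel_size_um,
                 strip_width_um = strip_width_um,
                 archetypes = archetypes, counts = counts,
                 colors = colors, labelset = labelset),
            class = "cribnet_synthconfig")
}

star_polygon <- function(center, radius, n_vertices = 48L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  for (k in 2:5) {
    r <- r + runif(1, 0, 0.05) * cos(k * th + runif(1, 0, 2 * pi))
  }
  r <- pmin(pmax(r, 0.82), 1.18) * radius
  cbind(row = center[1] + r * sin(th), col = center[2] + r * cos(th))
}

# lumina geometry per archetype, in gland-local coordinates
plan_lumina <- function(spec, r_px) {
  lab <- tolower(spec$label)
  k <- if (spec$lumina_range[2] >= spec$lumina_range[1]) {
    sample(seq(spec$lumina_range[1], spec$lumina_range[2]), 1L)
  } else 0L
  if (k == 0L) return(NULL)
  if (lab == "g3") {
    return(data.frame(dr = 0, dc = 0, r = 0.42 * r_px, tuft = FALSE))
  }
  if (lab == "g4 glomeruloid") {
    return(data.frame(dr = 0, dc = 0, r = 0.55 * r_px, tuft = TRUE))
  }
  if (lab == "g4 fused") {
    phi <- runif(1, 0, pi)
    spread <- 0.52 * r_px
    tpos <- seq(-spread, spread, length.out = k)
    return(data.frame(
      dr = tpos * sin(phi) + rnorm(k, 0, 0.08 * r_px),
      dc = tpos * cos(phi) + rnorm(k, 0, 0.08 * r_px),
      r = 0.26 * r_px * runif(k, 0.8, 1.2), tuft = FALSE))
  }
  if (lab == "g4 complex fused") {
    pts <- scatter_in_disk(k, 0.58 * r_px, 0.45 * r_px)
    return(data.frame(dr = pts[, 1], dc = pts[, 2],
                      r = 0.18 * r_px * runif(nrow(pts), 0.7, 1.3),
                      tuft = FALSE))
  }
  # cribriform: many small, tightly packed lumina
  rl <- 0.13 * r_px
  pts <- scatter_in_disk(k, 0.70 * r_px, 2.4 * rl)
  while (nrow(pts) < 3L) {  # guaranteed sieve: relax packing if needed
    rl <- rl * 0.9
    pts <- scatter_in_disk(k, 0.72 * r_px, 2.2 * rl)
  }
  data.frame(dr = pts[, 1], dc = pts[, 2],
             r = rl * runif(nrow(pts), 0.85, 1.15), tuft = FALSE)
}

scatter_in_disk <- function(k, radius, min_sep) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < k && tries < 400L) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi)
    d <- radius * sqrt(runif(1))
    p <- c(d * sin(a), d * cos(a))
    if (nrow(pts) == 0 ||
        all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_sep)) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

#' Generate one synthetic needle biopsy
#'
#' Renders an elongated H&E-like tissue strip on a white background,
#' populated with the requested growth-pattern archetypes. Every placed
#' gland contributes one polygon annotation; the returned label map is
#' produced by rasterizing exactly those polygons, so annotations and
#' reference masks agree pixel for pixel. The output is deterministic for
#' a fixed config.
#'
#' @param config A [synthesis_config()].
#' @return A list of class `cribnet_biopsy`: `image` (`H x W x 3` in
#'   `[0, 1]`), `label_map` (`H x W` integer), `masks` (per-class 0/1
#'   stack), `regions` (list of [annotation_region()]), `strip_mask`
#'   (logical tissue-strip truth) and `config`.
#' @export
generate_biopsy <- function(config) {
  set.seed(config$seed)
  H <- config$canvas_px[1]
  W <- config$canvas_px[2]
  px <- config$pixel_size_um
  ls7 <- config$labelset
  cols <- config$colors

  # --- tissue strip geometry -------------------------------------------
  half_px <- config$strip_width_um / 2 / px
  xs <- seq(0, W - 1, length.out = 64L)
  cy <- H / 2 + runif(1, -0.04, 0.04) * H +
    0.05 * H * sin(2 * pi * xs / W * runif(1, 0.8, 1.6) + runif(1, 0, 2 * pi))
  hw <- half_px * (0.86 + 0.14 * sin(2 * pi * xs / W * runif(1, 1.5, 3) +
                                     runif(1, 0, 2 * pi)))
  taper <- pmin(1, (pmin(xs, W - 1 - xs) / (0.06 * W) + 0.15))
  hw <- hw * pmin(taper, 1)
  cy_at <- function(col) stats::approx(xs, cy, col, rule = 2)$y
  hw_at <- function(col) stats::approx(xs, hw, col, rule = 2)$y
  # strip mask column-wise from the piecewise-linear envelope
  allc <- seq(0, W - 1)
  cyv <- cy_at(allc)
  hwv <- hw_at(allc)
  rowm <- matrix(seq_len(H) - 1, H, W)
  strip_mask <- rowm >= rep(cyv - hwv, each = H) &
    rowm <= rep(cyv + hwv, each = H)

  # --- place archetype instances ---------------------------------------
  # draw all requested instances first, then place them largest-first
  # (dense canvases pack far more reliably that way); if placement still
  # fails the radius backs off within the archetype's stated range
  drawn <- list()
  for (nm in names(config$archetypes)) {
    spec <- config$archetypes[[nm]]
    n <- if (!is.null(config$counts)) {
      as.integer(config$counts[[spec$label]] %||% 0L)
    } else {
      sample(seq(spec$count_range[1], spec$count_range[2]), 1L)
    }
    if (n == 0L) next
    for (j in seq_len(n)) {
      drawn[[length(drawn) + 1L]] <- list(
        spec = spec, r_px = runif(1, spec$radius_um[1],
                                  spec$radius_um[2]) / px)
    }
  }
  ord <- order(-vapply(drawn, `[[`, numeric(1), "r_px"))
  instances <- list()
  placed <- matrix(numeric(0), ncol = 3)  # row, col, radius
  for (d_i in drawn[ord]) {
    spec <- d_i$spec
    r_px <- d_i$r_px
    r_min <- spec$radius_um[1] / px
    ok <- FALSE
    repeat {
      for (try in seq_len(300L)) {
        cc <- runif(1, 1.18 * r_px + 6, W - 1 - 1.18 * r_px - 6)
        margin <- hw_at(cc) - 1.18 * r_px - 4
        if (margin <= 0) next
        cr <- cy_at(cc) + runif(1, -margin, margin)
        if (nrow(placed) > 0) {
          # star polygons wobble up to 1.18x the nominal radius
          d <- sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2)
          if (any(d < 1.18 * (placed[, 3] + r_px) + 2)) next
        }
        ok <- TRUE
        break
      }
      if (ok || r_px * 0.9 < r_min) break
      r_px <- r_px * 0.9  # back off within the archetype's radius range
    }
    if (!ok) {
      stop("cannot place archetype '", spec$label,
           "' (radius ", round(r_px), " px) on the canvas without ",
           "exceeding the tissue strip")
    }
    placed <- rbind(placed, c(cr, cc, r_px))
    poly <- star_polygon(c(cr, cc), r_px)
    instances[[length(instances) + 1L]] <- list(
      label = spec$label, center = c(cr, cc), r_px = r_px,
      polygon = poly, lumina = plan_lumina(spec, r_px), spec = spec)
  }
  regions <- lapply(seq_along(instances), function(i) {
    annotation_region(instances[[i]]$polygon, instances[[i]]$label, ls7,
                      px, name = sprintf("%s %d", instances[[i]]$label, i))
  })
  label_map <- rasterize_label_map(regions, H, W, ls7)

  # --- render -----------------------------------------------------------
  img <- array(rep(cols$background, each = H * W), dim = c(H, W, 3))
  # low-frequency stromal texture, computed at quarter resolution
  h4 <- ceiling(H / 4)
  w4 <- ceiling(W / 4)
  tex4 <- gauss_blur_cpp(matrix(runif(h4 * w4), h4, w4), 1.5)
  tex <- tex4[rep(seq_len(h4), each = 4)[seq_len(H)],
              rep(seq_len(w4), each = 4)[seq_len(W)]]
  tex <- (tex - min(tex)) / (max(tex) - min(tex) + 1e-12)
  sm <- which(strip_mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sm] <- cols$eosin[ch] * (0.92 + 0.12 * tex[sm])
    img[, , ch] <- plane
  }
  # stromal (fibroblast) nuclei
  n_str <- round(length(sm) * px^2 / 1000 * 0.5)
  if (n_str > 0) {
    pick <- sample(sm, min(n_str, length(sm)))
    prm <- cbind((pick - 1) %% H, (pick - 1) %/% H,
                 runif(length(pick), 3.5, 5.5), runif(length(pick), 1.0, 1.6),
                 runif(length(pick), 0, pi), 0.8)
    colr <- matrix(rep(cols$hematoxylin * 1.25, each = nrow(prm)),
                   ncol = 3)
    img <- draw_ellipses_cpp(img, prm, pmin(colr, 1))
  }
  # glands
  for (inst in instances) {
    gm <- which(polygon_mask_cpp(H, W, inst$polygon))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[gm] <- cols$epithelium[ch] * (0.94 + 0.12 * tex[gm])
      img[, , ch] <- plane
    }
    img <- render_gland_interior(img, inst, cols, px)
  }
  # smoothed additive noise, per channel
  for (ch in 1:3) {
    nz <- gauss_blur_cpp(matrix(rnorm(H * W), H, W), 1.2)
    nz <- nz / stats::sd(nz) * cols$noise
    img[, , ch] <- pmin(pmax(img[, , ch] + nz, 0), 1)
  }

  structure(list(image = img, label_map = label_map,
                 masks = label_map_to_masks(label_map,
                                            length(ls7$labels)),
                 regions = regions, strip_mask = strip_mask,
                 config = config),
            class = "cribnet_biopsy")
}

render_gland_interior <- function(img, inst, cols, px) {
  H <- dim(img)[1]
  cr <- inst$center[1]
  cc <- inst$center[2]
  lum <- inst$lumina
  lab <- tolower(inst$label)
  nuc <- matrix(numeric(0), ncol = 6)
  add_ring <- function(nuc, rr, cc0, radius, spacing = 5.5) {
    n <- max(6L, round(2 * pi * radius / spacing))
    a <- seq(0, 2 * pi, length.out = n + 1L)[-1] + runif(1, 0, 1)
    rbind(nuc, cbind(rr + (radius + rnorm(n, 0, 0.8)) * sin(a),
                     cc0 + (radius + rnorm(n, 0, 0.8)) * cos(a),
                     runif(n, 1.9, 2.7), runif(n, 1.4, 2.0),
                     runif(n, 0, pi), 0.9))
  }
  if (!is.null(lum)) {
    prm <- cbind(cr + lum$dr, cc + lum$dc, lum$r, lum$r, 0, 1)
    colr <- matrix(rep(cols$lumen, each = nrow(prm)), ncol = 3)
    img <- draw_ellipses_cpp(img, prm, colr)
    for (i in seq_len(nrow(lum))) {
      nuc <- add_ring(nuc, cr + lum$dr[i], cc + lum$dc[i],
                      lum$r[i] + 2.5)
      if (lum$tuft[i]) {  # glomeruloid: epithelial tuft on the lumen wall
        psi <- runif(1, 0, 2 * pi)
        tr <- 0.45 * lum$r[i]
        tc <- c(cr + lum$dr[i] + (lum$r[i] - tr) * sin(psi),
                cc + lum$dc[i] + (lum$r[i] - tr) * cos(psi))
        img <- draw_ellipses_cpp(
          img, cbind(tc[1], tc[2], tr, tr, 0, 1),
          matrix(cols$epithelium, ncol = 3))
        nuc <- add_ring(nuc, tc[1], tc[2], tr * 0.7, spacing = 4.5)
      }
    }
  }
  # outer epithelial rim
  nuc <- add_ring(nuc, cr, cc, 0.88 * inst$r_px)
  if (lab == "g4 ill-defined") {  # diffuse nuclear cluster, no lumina
    area_px <- pi * (0.85 * inst$r_px)^2
    n <- round(area_px * px^2 / 1000 * inst$spec$nuclear_density)
    a <- runif(n, 0, 2 * pi)
    d <- 0.85 * inst$r_px * sqrt(runif(n))
    nuc <- rbind(nuc, cbind(cr + d * sin(a), cc + d * cos(a),
                            runif(n, 1.9, 2.7), runif(n, 1.4, 2.0),
                            runif(n, 0, pi), 0.9))
  }
  if (nrow(nuc) > 0) {
    jit <- matrix(runif(nrow(nuc) * 3, -0.04, 0.04), ncol = 3)
    colr <- sweep(jit, 2, cols$hematoxylin, "+")
    img <- draw_ellipses_cpp(img, nuc, pmin(pmax(colr, 0), 1))
  }
  img
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed %% 65521L) * 7919 + 104729 * i) %% 2147483629)
}

#' Generate a synthetic biopsy dataset on disk
#'
#' Draws a dataset plan (which archetypes appear in which biopsy, honouring
#' the per-archetype prevalences), then renders each biopsy with a
#' deterministically derived seed. The number of cribriform-positive
#' biopsies is fixed to `round(prevalence * n)` (their identity is random),
#' and every label is guaranteed to occur somewhere in the dataset. Each
#' biopsy is written as a PNG image, an ASAP-style XML annotation file and
#' an indexed-PNG label map; the manifest is JSON and the generator
#' configuration is saved as YAML.
#'
#' @param n_biopsies Number of biopsies (at least 1).
#' @param base_config A [synthesis_config()]; per-biopsy seeds and counts
#'   are derived from it.
#' @param seed Dataset-level seed.
#' @param dir Output directory (created if needed).
#' @return The manifest: list of [biopsy_record()]s (invisibly also written
#'   to `manifest.json`).
#' @export
generate_dataset <- function(n_biopsies, base_config = synthesis_config(),
                             seed = 1L, dir) {
  stopifnot(n_biopsies >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls7 <- base_config$labelset
  specs <- base_config$archetypes
  set.seed(seed)
  # plan: counts[biopsy, archetype]
  plan <- matrix(0L, n_biopsies, length(specs),
                 dimnames = list(NULL, vapply(specs, `[[`, "", "label")))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (tolower(sp$label) == "g4 cribriform") {
      n_pos <- max(1L, round(sp$prevalence * n_biopsies))
      pos <- sample(n_biopsies, n_pos)
    } else {
      pos <- which(runif(n_biopsies) < sp$prevalence)
    }
    cnts <- sample(seq(sp$count_range[1], max(sp$count_range)),
                   length(pos), replace = TRUE)
    plan[pos, j] <- pmax(cnts, 1L)
  }
  # coverage: every archetype occurs at least once in the dataset
  for (j in seq_along(specs)) {
    if (sum(plan[, j]) == 0L) plan[1L + (j - 1L) %% n_biopsies, j] <- 1L
  }
  records <- vector("list", n_biopsies)
  for (i in seq_len(n_biopsies)) {
    cfg_i <- base_config
    cfg_i$seed <- derive_seed(seed, i)
    cfg_i$counts <- setNames(as.list(plan[i, ]), colnames(plan))
    bx <- generate_biopsy(cfg_i)
    id <- sprintf("biopsy_%03d", i)
    png::writePNG(bx$image, file.path(dir, paste0(id, ".png")))
    write_annotations(bx$regions, file.path(dir, paste0(id, ".xml")))
    png::writePNG((bx$label_map - 1L) / 255,
                  file.path(dir, paste0(id, "_mask.png")))
    labs <- vapply(bx$regions, `[[`, "", "label")
    counts <- setNames(integer(length(ls7$labels)), ls7$labels)
    tab <- table(labs)
    counts[names(tab)] <- as.integer(tab)
    records[[i]] <- biopsy_record(
      id, paste0(id, ".png"), paste0(id, ".xml"), paste0(id, "_mask.png"),
      counts, base_config$pixel_size_um)
  }
  save_manifest(records, file.path(dir, "manifest.json"))
  cfg_out <- base_config
  cfg_out$archetypes <- lapply(specs, unclass)
  cfg_out$labelset <- NULL
  yaml::write_yaml(unclass(cfg_out), file.path(dir, "dataset_config.yaml"))
  invisible(records)
}

#' Read a generated biopsy back from disk
#'
#' @param record A [biopsy_record()].
#' @param dir Directory holding the dataset files.
#' @return List with `image`, `label_map` and `record`.
#' @export
read_biopsy <- function(record, dir) {
  img <- png::readPNG(file.path(dir, record$image_path))
  lm <- NULL
  if (!is.null(record$mask_path)) {
    m <- png::readPNG(file.path(dir, record$mask_path))
    lm <- matrix(as.integer(round(m * 255)) + 1L, nrow(m), ncol(m))
  }
  list(image = img, label_map = lm, record = record)
}
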