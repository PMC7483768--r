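#' Construct an annotated polygon region
#'
#' Polygons live in working-resolution pixel coordinates (0-based `(row,
#' col)`, pixel centres at integers). The physical area is computed from the
#' polygon by the shoelace formula and the pixel pitch.
#'
#' @param polygon Numeric matrix with columns `(row, col)` and at least 3
#'   vertices.
#' @param label Label name; must belong to `labelset`.
#' @param labelset A [label_set()].
#' @param pixel_size_um Pixel pitch in micrometres (default 0.92).
#' @param name Optional annotation name.
#' @return An object of class `cribnet_region` with fields `polygon`,
#'   `label`, `area_mm2`, `pixel_size_um` and `name`.
#' @export
annotation_region <- function(polygon, label, labelset = label_set(),
                              pixel_size_um = 0.92, name = NULL) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) {
    stop("polygon for annotation '", name %||% label,
         "' has fewer than 3 vertices")
  }
  if (ncol(polygon) != 2L) stop("polygon must have two columns (row, col)")
  label <- labelset$labels[label_index(labelset, label)]
  area_px <- polygon_area_px(polygon)
  if (area_px <= 0) stop("polygon of annotation '", name %||% label,
                         "' has zero area")
  structure(
    list(polygon = polygon, label = label,
         area_mm2 = area_px * (pixel_size_um * 1e-3)^2,
         pixel_size_um = pixel_size_um,
         name = name %||% label),
    class = "cribnet_region"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon area in pixels by the shoelace formula
#' @param polygon Vertex matrix `(row, col)`.
#' @return Absolute polygon area in squared pixels.
#' @export
polygon_area_px <- function(polygon) {
  r <- polygon[, 1]
  c <- polygon[, 2]
  n <- length(r)
  j <- c(n, seq_len(n - 1))
  abs(sum(c[j] * r - c * r[j])) / 2
}

#' Parse an ASAP-style XML annotation file
#'
#' Reads `Annotation` elements carrying `Coordinate` children. The group
#' name (`PartOfGroup`) is mapped case-insensitively to the label set. ASAP
#' stores coordinates as `X` = column and `Y` = row.
#'
#' @param file Path to the XML file.
#' @param labelset A [label_set()].
#' @param pixel_size_um Pixel pitch used to derive physical region areas.
#' @return A list of [annotation_region()] objects (empty when the file
#'   contains no annotations).
#' @export
parse_annotations <- function(file, labelset = label_set(),
                              pixel_size_um = 0.92) {
  doc <- xml2::read_xml(file)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  out <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    nm <- xml2::xml_attr(a, "Name")
    grp <- xml2::xml_attr(a, "PartOfGroup")
    if (is.na(grp) || !tolower(trimws(grp)) %in% tolower(labelset$labels)) {
      stop("annotation '", nm, "' carries unknown group name '", grp, "'")
    }
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    if (length(coords) < 3L) {
      stop("annotation '", nm, "' is a malformed polygon (",
           length(coords), " vertices)")
    }
    ord <- as.integer(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))
    y <- as.numeric(xml2::xml_attr(coords, "Y"))
    o <- order(ord)
    out[[i]] <- annotation_region(cbind(row = y[o], col = x[o]), grp,
                                  labelset, pixel_size_um, name = nm)
  }
  out
}

#' Write regions to an ASAP-style XML annotation file
#'
#' Vertices survive a write/parse round-trip to better than 0.01 px.
#'
#' @param regions List of [annotation_region()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotations <- function(regions, file) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  groups <- unique(vapply(regions, function(r) r$label, character(1)))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = r$name %||% sprintf("Annotation %d", i),
                             Type = "Polygon", PartOfGroup = r$label,
                             Color = "#F4FA58")
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (j in seq_len(nrow(r$polygon))) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(j - 1L),
                          X = sprintf("%.4f", r$polygon[j, 2]),
                          Y = sprintf("%.4f", r$polygon[j, 1]))
    }
  }
  grps <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in groups) {
    xml2::xml_add_child(grps, "Group", Name = g, PartOfGroup = "None",
                        Color = "#F4FA58")
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Rasterize annotations into a 1-based label map
#'
#' Every pixel is assigned exactly one class: pixels whose centre falls
#' inside (or on the boundary of) a region polygon receive that region's
#' class, all remaining pixels the non-labelled class. Overlapping regions
#' of different labels are resolved by drawing order (later region wins)
#' with a warning.
#'
#' @param regions List of [annotation_region()] objects.
#' @param height,width Raster dimensions in pixels.
#' @param labelset A [label_set()].
#' @return Integer `height x width` matrix of class indices in `1:7`.
#' @export
rasterize_label_map <- function(regions, height, width,
                                labelset = label_set()) {
  lm <- matrix(1L, nrow = height, ncol = width)
  n_over <- 0L
  for (r in regions) {
    idx <- label_index(labelset, r$label)
    n_over <- n_over +
      fill_polygon_cpp(lm, r$polygon, as.integer(idx), 1L)
  }
  if (n_over > 0L) {
    warning("overlapping annotations of different labels: ", n_over,
            " pixels resolved by drawing order (later region wins)")
  }
  lm
}

#' Rasterize annotations into a per-class binary mask stack
#'
#' @inheritParams rasterize_label_map
#' @return Numeric `height x width x 7` array of 0/1 masks; per pixel the
#'   class masks sum to exactly 1.
#' @export
rasterize_annotations <- function(regions, height, width,
                                  labelset = label_set()) {
  label_map_to_masks(rasterize_label_map(regions, height, width, labelset),
                     length(labelset$labels))
}

#' Expand a label map into one-hot class masks
#' @param label_map Integer matrix of 1-based class indices.
#' @param n_classes Number of classes.
#' @return Numeric `H x W x n_classes` array.
#' @export
label_map_to_masks <- function(label_map, n_classes = 7L) {
  H <- nrow(label_map)
  W <- ncol(label_map)
  out <- array(0, dim = c(H, W, n_classes))
  for (k in seq_len(n_classes)) {
    out[, , k] <- as.numeric(label_map == k)
  }
  out
}

#' Create a biopsy record for a dataset manifest
#'
#' @param id Biopsy identifier.
#' @param image_path,annotation_path,mask_path File paths (relative to the
#'   manifest location or absolute).
#' @param counts Named integer vector of per-label region counts.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return An object of class `cribnet_record`.
#' @export
biopsy_record <- function(id, image_path, annotation_path = NULL,
                          mask_path = NULL, counts = NULL,
                          pixel_size_um = 0.92) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(
    list(id = id, image_path = image_path,
         annotation_path = annotation_path, mask_path = mask_path,
         counts = counts, pixel_size_um = pixel_size_um),
    class = "cribnet_record"
  )
}

#' Save or load a dataset manifest (JSON)
#'
#' A manifest is a list of [biopsy_record()]s; save followed by load is the
#' identity on all record fields.
#'
#' @param records List of [biopsy_record()]s.
#' @param file JSON path.
#' @return `save_manifest` returns `file` invisibly; `load_manifest` the
#'   list of records.
#' @export
save_manifest <- function(records, file) {
  payload <- lapply(records, function(r) {
    list(id = r$id, image_path = r$image_path,
         annotation_path = r$annotation_path, mask_path = r$mask_path,
         counts = as.list(r$counts), pixel_size_um = r$pixel_size_um)
  })
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(file) {
  payload <- jsonlite::read_json(file)
  lapply(payload, function(p) {
    cnt <- if (length(p$counts)) {
      setNames(as.integer(unlist(p$counts)), names(p$counts))
    } else NULL
    biopsy_record(p$id, p$image_path, p$annotation_path, p$mask_path,
                  cnt, p$pixel_size_um)
  })
}
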