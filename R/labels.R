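#' The 7-class growth-pattern vocabulary
#'
#' Ordered class names used throughout the pipeline. The first class absorbs
#' background and any tissue that is not a Gleason grade 3 or 4 growth
#' pattern (benign tissue, G5, mucinous, perineural growth, ...).
#' @export
CRIB_LABELS <- c(
  "non-labelled", "G3", "G4 fused", "G4 ill-defined",
  "G4 complex fused", "G4 glomeruloid", "G4 cribriform"
)

#' Create a label set with per-class loss weights
#'
#' The label set couples the ordered 7-class vocabulary with the per-class
#' weights \eqn{w_l} of the soft Dice loss. By default the cribriform class
#' receives weight 0.4 and every other class 0.1, so that the weights sum
#' to 1; the non-cribriform classes take part in the loss only to aid
#' convergence.
#'
#' @param labels Character vector of exactly 7 class names.
#' @param weights Numeric vector of per-class weights summing to 1. Defaults
#'   to 0.4 for the cribriform class and 0.1 elsewhere.
#' @return An object of class `cribnet_labelset` with elements `labels` and
#'   `weights`.
#' @export
#' @examples
#' ls7 <- label_set()
#' ls7$weights
label_set <- function(labels = CRIB_LABELS, weights = NULL) {
  if (length(labels) != 7L) {
    stop("a label set must contain exactly 7 labels, got ", length(labels))
  }
  if (anyDuplicated(tolower(labels))) stop("labels must be unique")
  if (is.null(weights)) {
    weights <- rep(0.1, 7L)
    weights[match("g4 cribriform", tolower(labels))] <- 0.4
  }
  if (length(weights) != 7L) stop("weights must have length 7")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("class weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  structure(list(labels = labels, weights = weights),
            class = "cribnet_labelset")
}

#' Map a label name to its class index (case-insensitive)
#'
#' @param labelset A [label_set()].
#' @param name Character vector of label names.
#' @return Integer indices into `labelset$labels`.
#' @export
label_index <- function(labelset, name) {
  idx <- match(tolower(trimws(name)), tolower(labelset$labels))
  if (anyNA(idx)) {
    stop("unknown label name: ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @export
print.cribnet_labelset <- function(x, ...) {
  cat("Label set (", length(x$labels), " classes):\n", sep = "")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %d. %-18s w = %.2f\n", i, x$labels[i], x$weights[i]))
  }
  invisible(x)
}

cribriform_index <- function(labelset) {
  label_index(labelset, "G4 cribriform")
}
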