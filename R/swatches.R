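# Reference swatch sets for 24-patch colour checker cards.
#
# Ordering convention ("column-major portrait"): the card is held in
# portrait orientation, 4 columns wide by 6 rows tall, with the light-blue
# anchor swatch in the top-right corner. Swatches are numbered down the
# columns: column 1 rows 1..6 are swatches 1..6, column 2 rows 1..6 are
# 7..12, and so on. The anchor swatch is therefore number 19 (column 4,
# row 1). Reference CSVs must list swatches in this order.

SWATCH_ORDER_CONVENTION <- "column-major-portrait-anchor-top-right"
ANCHOR_INDEX <- 19L

#' Construct a reference swatch set
#'
#' A swatch set holds the 24 known sRGB values of a colour checker card in
#' the package's ordering convention (see [load_reference_swatches()]).
#'
#' @param rgb A 24 x 3 numeric matrix (or data frame with columns R, G, B)
#'   of sRGB values in `[0, 255]`.
#' @param order_convention Ordering tag; only the package's column-major
#'   portrait convention is defined.
#' @return An object of class `swatch_set`: a 24 x 3 matrix with columns
#'   R, G, B and attribute `order_convention`.
#' @export
swatch_set <- function(rgb, order_convention = SWATCH_ORDER_CONVENTION) {
  rgb <- as.matrix(rgb)
  if (nrow(rgb) != 24L)
    stop("a swatch set must have exactly 24 entries, got ", nrow(rgb), " rows")
  if (ncol(rgb) != 3L)
    stop("swatch values must have 3 columns (R, G, B)")
  bad <- which(apply(rgb, 1, function(v) any(!is.finite(v) | v < 0 | v > 255)))
  if (length(bad))
    stop("swatch value outside [0, 255] in row ", bad[1])
  if (anyDuplicated(rgb))
    stop("swatch triples must be distinct")
  storage.mode(rgb) <- "double"
  colnames(rgb) <- c("R", "G", "B")
  rownames(rgb) <- NULL
  structure(rgb, order_convention = order_convention, class = "swatch_set")
}

#' Load reference swatch values from CSV
#'
#' Reads a 24-row CSV with header `R,G,B` holding the known sRGB values of
#' the colour checker, listed in the package's column-major portrait
#' ordering: columns of the portrait card left to right, rows top to
#' bottom within each column, anchor (light-blue) swatch at position 19.
#'
#' @param path Path to the CSV file.
#' @return A [swatch_set()].
#' @examples
#' ref <- load_reference_swatches(
#'   system.file("extdata", "swatches_synthetic.csv", package = "phytochroma"))
#' nrow(ref)
#' @export
load_reference_swatches <- function(path) {
  if (!file.exists(path)) stop("swatch reference file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("R", "G", "B") %in% names(df)))
    stop("swatch reference CSV must have header R,G,B")
  if (nrow(df) != 24L)
    stop("swatch reference CSV must have 24 data rows, got ",
         nrow(df), " rows")
  swatch_set(df[, c("R", "G", "B")])
}

#' Write swatch values to CSV
#'
#' Writes a 24 x 3 set of RGB triples in the same dialect that
#' [load_reference_swatches()] reads (header `R,G,B`, package ordering).
#'
#' @param swatches A [swatch_set()] or 24 x 3 matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_swatch_csv <- function(swatches, path) {
  m <- as.matrix(swatches)
  stopifnot(nrow(m) == 24L, ncol(m) == 3L)
  df <- data.frame(R = m[, 1], G = m[, 2], B = m[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled synthetic reference swatch set
#'
#' The package ships a synthetic 24-swatch reference card
#' (`extdata/swatches_synthetic.csv`): 24 distinct sRGB values spanning the
#' gamut (skin tones, primaries, pastels and a six-step neutral ramp), with
#' a light-blue anchor swatch at the convention's anchor position. It is
#' used by the synthetic scene renderer and the test-suite; photographs of
#' a real card must be paired with that card's own reference CSV in the
#' same ordering.
#'
#' @return A [swatch_set()].
#' @export
synthetic_reference_swatches <- function() {
  load_reference_swatches(
    system.file("extdata", "swatches_synthetic.csv", package = "phytochroma"))
}

#' @export
as.matrix.swatch_set <- function(x, ...) {
  matrix(unclass(x), nrow = 24L, ncol = 3L,
         dimnames = list(NULL, c("R", "G", "B")))
}

# default anchor colour (light blue, swatch 19 of the bundled set)
.default_anchor_rgb <- function() c(129, 196, 231)
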