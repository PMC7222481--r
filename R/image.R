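#' @useDynLib cardioseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an intensity image
#'
#' Images are plain numeric matrices (row = image row, origin top-left)
#' carrying a nominal bit depth and a channel tag as attributes.  All
#' intensities are kept on the raw stored scale until a pipeline stage
#' explicitly normalizes.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bit_depth nominal quantization, 8 or 16.
#' @param channel_tag `"nuclear"` or `"cytoplasm"`.
#' @return the matrix with `bit_depth` and `channel_tag` attributes.
#' @export
cm_image <- function(pixels, bit_depth = 8L, channel_tag = c("cytoplasm", "nuclear")) {
  channel_tag <- match.arg(channel_tag)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a matrix with at least one row and column")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (any(pixels > 2^bit_depth - 1))
    stop("intensities exceed 2^bit_depth - 1")
  structure(pixels, bit_depth = as.integer(bit_depth), channel_tag = channel_tag)
}

#' Nominal bit depth of an image
#' @param img image matrix.
#' @return integer bit depth (defaults to 8 when the attribute is absent).
#' @export
bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

#' Pair the nuclear and cytoplasm channels of one field of view
#'
#' @param nuclear nuclear-channel image (DAPI-like).
#' @param cytoplasm cytoplasmic-marker image (alpha-actinin-like).
#' @return a `cm_pair` list with elements `nuclear` and `cytoplasm`.
#' @export
channel_pair <- function(nuclear, cytoplasm) {
  if (!all(dim(nuclear) == dim(cytoplasm)))
    stop("nuclear and cytoplasm channels must share the same shape")
  structure(list(nuclear = nuclear, cytoplasm = cytoplasm), class = "cm_pair")
}

#' Read a single-plane grayscale TIFF
#'
#' No intensity rescaling is performed: 8-bit files yield integers in
#' 0..255, 16-bit files integers in 0..65535.
#'
#' @param path file path.
#' @param channel_tag `"nuclear"` or `"cytoplasm"`.
#' @return an image matrix with `bit_depth` and `channel_tag` attributes.
#' @export
read_image <- function(path, channel_tag = c("cytoplasm", "nuclear")) {
  channel_tag <- match.arg(channel_tag)
  if (!file.exists(path)) stop("file not found: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(px)) == 3L)
    stop("expected single-plane grayscale TIFF, got ", dim(px)[3],
         " samples along the channel axis")
  bps <- attr(px, "bits.per.sample")
  bd <- if (is.null(bps)) 8L else as.integer(bps)
  if (!bd %in% c(8L, 16L)) stop("unsupported bit depth: ", bd)
  img <- matrix(as.numeric(px), nrow(px), ncol(px))
  structure(img, bit_depth = bd, channel_tag = channel_tag)
}

#' Write an image to a single-plane grayscale TIFF
#'
#' @param img image matrix (integers on the raw scale).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  bd <- bit_depth(img)
  scale <- 2^bd - 1
  tiff::writeTIFF(matrix(pmin(pmax(round(img), 0), scale) / scale,
                         nrow(img), ncol(img)),
                  path, bits.per.sample = bd, compression = "none")
  invisible(path)
}

#' Write a label mask as a 16-bit TIFF
#'
#' Pixel values equal the label ids bit-exactly on re-read.
#'
#' @param mask integer label matrix (0 = background).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  k <- max(mask)
  if (k > 65535) stop("label mask has ", k, " objects; 16-bit TIFF holds at most 65535")
  tiff::writeTIFF(matrix(mask / 65535, nrow(mask), ncol(mask)),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path file path.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(px), nrow(px), ncol(px))
}

#' Relabel a mask to the contiguous id range 1..K
#'
#' The partition is preserved: two pixels share a label before relabeling
#' iff they share one after.  Ids are assigned in increasing order of the
#' original ids.
#'
#' @param mask integer label matrix.
#' @return relabeled matrix.
#' @export
relabel_mask <- function(mask) {
  ids <- sort(unique(mask[mask > 0]))
  if (length(ids) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask > 0] <- match(mask[mask > 0], ids)
  out
}

#' Write a single-cell feature table to CSV
#'
#' One row per cell with columns `image_id`, `condition`, `cell_id`, then
#' the feature columns in registry order.  Floats are serialized with full
#' precision (17 significant digits) so a CSV round trip reproduces values
#' to machine precision.
#'
#' @param records data.frame of cell records (as built by [measure_image()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  lead <- c("image_id", "condition", "cell_id")
  if (nrow(records) == 0L && ncol(records) == 0L)
    records <- as.data.frame(setNames(rep(list(numeric(0)), 3), lead))
  if (!all(lead %in% names(records)))
    stop("cell table must carry image_id, condition and cell_id columns")
  feats <- setdiff(names(records), lead)
  known <- feats %in% feature_registry()
  if (!all(known))
    stop("unknown feature columns: ", paste(feats[!known], collapse = ", "))
  ord <- c(lead, intersect(feature_registry(), feats))
  out <- records[, ord, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & !(names(out) %in% lead)
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#' @param path file path.
#' @return data.frame with numeric feature columns.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# internal: binary-mask validation
assert_binary <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  invisible(TRUE)
}
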