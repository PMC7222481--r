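#' Nuclei detection parameters
#'
#' @param min_area smallest object (px^2) retained before watershed
#'   splitting; rejects stain debris.
#' @param merge_radius disc radius (px) of the closing used to merge
#'   closely apposed nuclei (bi-nucleated cells) into one seed.
#' @param connectivity pixel connectivity, 4 or 8.
#' @return a `nuclei_params` list.
#' @export
nuclei_params <- function(min_area = 50, merge_radius = 1, connectivity = 8) {
  if (min_area < 0) stop("min_area must be >= 0")
  if (merge_radius < 0) stop("merge_radius must be >= 0")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(min_area = min_area, merge_radius = merge_radius,
                 connectivity = connectivity), class = "nuclei_params")
}

# Integer-level histogram used by otsu_threshold; non-integer images are
# binned to 256 levels over their observed range.
.otsu_levels <- function(img) {
  v <- as.numeric(img)
  if (all(v == round(v))) {
    list(values = v, levels = sort(unique(v)))
  } else {
    rng <- range(v)
    lv <- seq(rng[1], rng[2], length.out = 256)
    binned <- lv[pmin(pmax(round((v - rng[1]) / diff(rng) * 255) + 1, 1), 256)]
    list(values = binned, levels = sort(unique(binned)))
  }
}

#' Otsu threshold
#'
#' Chooses the threshold maximizing the between-class variance of the
#' gray-level histogram; the mask marks pixels strictly above the
#' threshold.  The selected threshold is attached as attribute
#' `"threshold"`.
#'
#' @param img image matrix with at least two distinct gray levels.
#' @return binary mask (0/1 integer matrix) with attribute `threshold`.
#' @export
otsu_threshold <- function(img) {
  lv <- .otsu_levels(img)
  vals <- lv$levels
  if (length(vals) < 2L) stop("degenerate histogram: image has fewer than 2 gray levels")
  h <- tabulate(match(lv$values, vals), nbins = length(vals))
  n <- sum(h)
  w <- cumsum(h)                      # class-0 mass up to and incl. level k
  mu <- cumsum(h * vals)              # class-0 intensity mass
  mu_t <- mu[length(mu)]
  # candidate thresholds: after level k (k = 1..q-1); mask = intensity > vals[k]
  k <- seq_len(length(vals) - 1L)
  w0 <- w[k] / n
  w1 <- 1 - w0
  m0 <- mu[k] / w[k]
  m1 <- (mu_t - mu[k]) / (n - w[k])
  sb <- w0 * w1 * (m0 - m1)^2
  kstar <- k[which.max(sb)]
  thr <- vals[kstar]
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > thr] <- 1L
  attr(mask, "threshold") <- thr
  mask
}

# remove connected components smaller than min_area
.filter_min_area <- function(mask, min_area, connectivity = 8) {
  if (min_area <= 0 || !any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sz <- tabulate(lab[lab > 0])
  drop <- which(sz < min_area)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}

#' Split touching nuclei with a distance-transform watershed
#'
#' The Euclidean distance transform of the foreground is flooded from its
#' regional maxima (with an h-maxima suppression of one distance unit to
#' avoid plateau fragmentation); each catchment basin becomes one label.
#' Components below `min_area` are removed before the transform.  The
#' union of the output labels equals the filtered input mask: splitting
#' never changes the foreground support.
#'
#' @param mask binary mask.
#' @param params a [nuclei_params()].
#' @return label mask (0 background, 1..K nuclei).
#' @export
split_nuclei_distance <- function(mask, params = nuclei_params()) {
  assert_binary(mask)
  mask <- .filter_min_area(mask, params$min_area, params$connectivity)
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  relabel_mask(matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask)))
}

#' Split nuclei with a grayscale watershed (comparator method)
#'
#' Watershed on the intensity image restricted to the mask, seeded at
#' intensity regional maxima.  Provided as the comparator whose overcutting
#' failure mode on unevenly stained nuclei motivates the distance-based
#' default.
#'
#' @param img intensity image (preprocessed nuclear channel).
#' @param mask binary nuclei mask.
#' @param tolerance h-maxima suppression depth in intensity units.
#' @return label mask.
#' @export
split_nuclei_grayscale <- function(img, mask, tolerance = 1) {
  assert_binary(mask)
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  topo <- img * mask
  ws <- EBImage::watershed(topo, tolerance = tolerance, ext = 1)
  out <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
  out[mask == 0] <- 0L
  relabel_mask(out)
}

#' Merge closely located nuclei into single seeds
#'
#' A morphological closing (dilation then erosion by a disc of
#' `merge_radius`) is applied to the union binary support; labels whose
#' closed supports become connected are merged into one id.  The pixel
#' support of the output equals the input support — only ids change.
#' `merge_radius = 0` is the identity.
#'
#' @param labels label mask.
#' @param merge_radius disc radius in pixels (>= 0).
#' @return merged, relabeled mask.
#' @export
merge_close_nuclei <- function(labels, merge_radius = 1) {
  if (merge_radius < 0) stop("merge_radius must be >= 0")
  if (merge_radius == 0 || !any(labels > 0)) return(relabel_mask(labels))
  supp <- matrix(0L, nrow(labels), ncol(labels))
  supp[labels > 0] <- 1L
  brush <- EBImage::makeBrush(2 * as.integer(merge_radius) + 1, shape = "disc")
  closed <- EBImage::closing(supp, brush)
  comp <- EBImage::bwlabel(closed)
  # map each label to the closed component it lies in; labels sharing a
  # component collapse to one id
  ids <- sort(unique(labels[labels > 0]))
  comp_of <- vapply(ids, function(k) {
    cc <- comp[labels == k]
    as.integer(cc[cc > 0][1])
  }, integer(1))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- comp_of[match(labels[labels > 0], ids)]
  relabel_mask(out)
}

#' Detect single-nucleus seeds in the preprocessed nuclear channel
#'
#' Otsu thresholding, small-object rejection, distance-transform watershed
#' splitting, then merging of closely apposed nuclei.  A blank channel
#' (fewer than two gray levels, or nothing surviving the area filter)
#' yields an empty label mask rather than an error.
#'
#' @param img preprocessed nuclear-channel image.
#' @param params a [nuclei_params()].
#' @return seed label mask; Otsu threshold attached as attribute
#'   `"threshold"` when defined.
#' @export
detect_nuclei <- function(img, params = nuclei_params()) {
  mask <- tryCatch(otsu_threshold(img), error = function(e) NULL)
  if (is.null(mask)) return(matrix(0L, nrow(img), ncol(img)))
  labels <- split_nuclei_distance(mask, params)
  labels <- merge_close_nuclei(labels, params$merge_radius)
  attr(labels, "threshold") <- attr(mask, "threshold")
  labels
}
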