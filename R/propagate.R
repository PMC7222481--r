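#' Propagation parameters
#'
#' @param lambda_reg regularization factor weighting spatial distance
#'   against intensity difference in the step cost.  The default 1 gives
#'   both terms the same impact; large values approach the geodesic
#'   Voronoi partition of the mask, small values lock boundaries onto
#'   intensity edges.
#' @param connectivity 4 or 8 (diagonal steps cost sqrt(2) under 8).
#' @return a `propagation_params` list.
#' @export
propagation_params <- function(lambda_reg = 1.0, connectivity = 8) {
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(lambda_reg = lambda_reg, connectivity = connectivity),
            class = "propagation_params")
}

#' Union the cell mask with the seed support
#'
#' Guarantees that every nucleus can initiate growth even where the
#' cytoplasmic signal fell below the masking threshold.
#'
#' @param cell_mask binary mask.
#' @param seeds seed label mask.
#' @return binary mask covering `cell_mask | seeds`.
#' @export
augment_mask_with_seeds <- function(cell_mask, seeds) {
  if (!all(dim(cell_mask) == dim(seeds))) stop("shapes must match")
  out <- cell_mask
  out[seeds > 0] <- 1L
  out
}

#' Propagate nucleus seeds through the cell mask
#'
#' Multi-source lowest-cumulative-cost region growing: each masked pixel
#' is assigned the label of the seed reachable at minimal path cost, where
#' a step from pixel p to neighbour n costs
#' \deqn{\sqrt{\Delta I(p,n)^2 + \lambda \cdot \mathrm{step}^2},}
#' with \eqn{\Delta I} the intensity difference on the image normalized to
#' `[0, 1]` by its full range (so \eqn{\lambda = 1} genuinely balances the
#' two terms) and step the Euclidean neighbour distance.  Growth never
#' leaves the mask; seed pixels always keep their own label; cost ties are
#' broken toward the lowest seed id (compared at 1e-12 resolution) so the
#' output is deterministic.  Mask components containing no seed remain
#' background.
#'
#' @param cyto cytoplasm-channel intensity image.
#' @param seeds nucleus seed label mask.
#' @param cell_mask binary mask of propagable territory (normally already
#'   augmented with the seed support, see [augment_mask_with_seeds()]).
#' @param params a [propagation_params()].
#' @return cell label mask; seed ids entirely outside the mask are
#'   reported in attribute `orphan_seeds`.
#' @export
propagate_cells <- function(cyto, seeds, cell_mask, params = propagation_params()) {
  if (!all(dim(cyto) == dim(seeds)) || !all(dim(cyto) == dim(cell_mask)))
    stop("cyto, seeds and cell_mask must share one shape")
  assert_binary(cell_mask)
  rng <- range(cyto)
  norm <- if (diff(rng) > 0) (cyto - rng[1]) / diff(rng) else cyto * 0
  ids <- sort(unique(seeds[seeds > 0]))
  orphans <- ids[vapply(ids, function(k) !any(cell_mask[seeds == k] > 0), logical(1))]
  out <- .propagate_core(norm, matrix(as.integer(seeds), nrow(seeds), ncol(seeds)),
                         matrix(as.logical(cell_mask), nrow(cell_mask), ncol(cell_mask)),
                         params$lambda_reg, as.integer(params$connectivity), 1e-12)
  attr(out, "orphan_seeds") <- orphans
  out
}
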