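#' Pixel-level precision, recall and F-score
#'
#' True/false positives and false negatives are counted pixelwise on the
#' foreground; the F-score is the harmonic mean
#' `2 * recall * precision / (recall + precision)`.  When both masks are
#' entirely background, precision and recall are 1 by convention.
#' Swapping `pred` and `ref` exactly swaps precision and recall.
#'
#' @param pred,ref binary masks of identical shape.
#' @return list with `precision`, `recall`, `f_score`.
#' @export
pixel_prf <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("pred and ref must share one shape")
  assert_binary(pred); assert_binary(ref)
  tp <- sum(pred == 1 & ref == 1)
  fp <- sum(pred == 1 & ref == 0)
  fn <- sum(pred == 0 & ref == 1)
  if (tp + fp + fn == 0) return(list(precision = 1, recall = 1, f_score = 1))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * recall * precision / (recall + precision) else 0
  list(precision = precision, recall = recall, f_score = f)
}

#' Evaluate a set of predicted masks against references
#'
#' Per-image precision/recall/F-score followed by their mean and standard
#' error across images (the per-image-then-mean aggregation of a
#' mean/SEM results table).  Note that the mean F-score is not the
#' F-score of the mean precision and recall.  Pooled-pixel aggregation is
#' available with `pooled = TRUE`.
#'
#' @param preds,refs equal-length lists of binary masks.
#' @param pooled also report metrics pooled over all pixels.
#' @return list with `per_image` (data.frame), `mean`, `sem`, and
#'   optionally `pooled`.
#' @export
evaluate_masks <- function(preds, refs, pooled = FALSE) {
  if (!length(preds) || length(preds) != length(refs))
    stop("preds and refs must be non-empty lists of equal length")
  per <- do.call(rbind, lapply(seq_along(preds), function(i) {
    m <- pixel_prf(preds[[i]], refs[[i]])
    data.frame(image = i, precision = m$precision, recall = m$recall,
               f_score = m$f_score)
  }))
  cols <- c("precision", "recall", "f_score")
  mu <- colMeans(per[cols])
  sem <- vapply(per[cols], function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0, numeric(1))
  out <- list(per_image = per, mean = mu, sem = sem)
  if (pooled) {
    tp <- sum(vapply(seq_along(preds), function(i)
      sum(preds[[i]] == 1 & refs[[i]] == 1), numeric(1)))
    fp <- sum(vapply(seq_along(preds), function(i)
      sum(preds[[i]] == 1 & refs[[i]] == 0), numeric(1)))
    fn <- sum(vapply(seq_along(preds), function(i)
      sum(preds[[i]] == 0 & refs[[i]] == 1), numeric(1)))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    out$pooled <- c(precision = p, recall = r, f_score = 2 * p * r / (p + r))
  }
  out
}

#' Fraction of correctly segmented nuclei
#'
#' A reference nucleus counts as correct iff exactly one predicted
#' nucleus claims the majority (> 50%) of its pixels and that predicted
#' nucleus is not also the majority claimant of another reference nucleus
#' (a one-to-one majority rule).  Two nuclei merged into one prediction
#' therefore both fail; an overcut nucleus fails when no single fragment
#' retains a majority of its pixels.
#'
#' @param pred,ref label masks of identical shape; `ref` must contain at
#'   least one nucleus.
#' @return fraction in `[0, 1]`.
#' @export
nuclei_correctness <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("pred and ref must share one shape")
  ref_ids <- sort(unique(ref[ref > 0]))
  if (!length(ref_ids)) stop("reference mask contains no nuclei")
  claim <- integer(length(ref_ids))          # majority pred label per ref, 0 if none
  for (idx in seq_along(ref_ids)) {
    px <- pred[ref == ref_ids[idx]]
    tab <- table(px[px > 0])
    if (length(tab) && max(tab) > length(px) / 2)
      claim[idx] <- as.integer(names(tab)[which.max(tab)])
  }
  # a claimant shared by two reference nuclei invalidates both
  dup <- unique(claim[claim > 0][duplicated(claim[claim > 0])])
  ok <- claim > 0 & !(claim %in% dup)
  sum(ok) / length(ref_ids)
}

#' Two-sample Kolmogorov–Smirnov comparison
#'
#' `D = sup |ECDF_treated - ECDF_control|` with the two-sided p-value from
#' [stats::ks.test()]: exact for small tie-free samples, asymptotic
#' otherwise (ties force the asymptotic approximation).  Significance is
#' declared at `p < 0.05`, matching the screening convention of comparing
#' each treated condition against vehicle control without multiplicity
#' correction; a Benjamini-Hochberg option is available downstream in
#' [dose_response_report()].
#'
#' @param treated,control numeric vectors with at least 5 observations
#'   each.
#' @param alpha significance level.
#' @return list with `statistic`, `p_value`, `significant`.
#' @export
ks_compare <- function(treated, control, alpha = 0.05) {
  treated <- treated[is.finite(treated)]
  control <- control[is.finite(control)]
  if (length(treated) < 5 || length(control) < 5)
    stop("both samples need at least 5 observations")
  kt <- suppressWarnings(stats::ks.test(treated, control))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha)
}

#' Dose-response feature statistics versus control
#'
#' For every feature and condition: mean, SEM, KS statistic and p-value
#' against the control condition, and a significance flag.  The per-image
#' cell count is summarized separately and expressed as percent of the
#' control mean — the viability read-out.
#'
#' @param records data.frame of cell records from [measure_image()] rows
#'   (all conditions together; must carry `condition` and `image_id`).
#' @param control_name condition label used as control.
#' @param features feature columns to test; defaults to the full registry.
#' @param alpha significance level.
#' @param adjust `"none"` (default, the screening convention) or `"BH"`
#'   for Benjamini-Hochberg adjustment across the feature x condition
#'   grid.
#' @return list with `features` (one row per feature x non-control
#'   condition) and `cell_number` (per condition: mean per-image count,
#'   SEM, percent of control).
#' @export
dose_response_report <- function(records, control_name = "control",
                                 features = NULL, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!control_name %in% records$condition)
    stop("control condition '", control_name, "' not present")
  if (is.null(features))
    features <- intersect(feature_registry(), names(records))
  conds <- setdiff(unique(records$condition), control_name)
  ctrl <- records[records$condition == control_name, , drop = FALSE]
  rows <- list()
  for (cond in conds) {
    tr <- records[records$condition == cond, , drop = FALSE]
    for (f in features) {
      x <- tr[[f]][is.finite(tr[[f]])]
      y <- ctrl[[f]][is.finite(ctrl[[f]])]
      ks <- if (length(x) >= 5 && length(y) >= 5) ks_compare(x, y, alpha)
            else list(statistic = NA_real_, p_value = NA_real_, significant = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, feature = f,
        mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
        ks_D = ks$statistic, p_value = ks$p_value,
        stringsAsFactors = FALSE)
    }
  }
  feat <- do.call(rbind, rows)
  if (adjust == "BH") feat$p_value <- stats::p.adjust(feat$p_value, "BH")
  feat$significant <- feat$p_value < alpha
  # per-image cell counts -> viability as percent of control
  counts <- stats::aggregate(cell_id ~ condition + image_id, records, length)
  names(counts)[3] <- "cell_number"
  by_cond <- stats::aggregate(cell_number ~ condition, counts, mean)
  sem_cond <- stats::aggregate(cell_number ~ condition, counts,
                               function(x) stats::sd(x) / sqrt(length(x)))
  ctrl_mean <- by_cond$cell_number[by_cond$condition == control_name]
  cn <- data.frame(condition = by_cond$condition,
                   mean_cells = by_cond$cell_number,
                   sem_cells = sem_cond$cell_number,
                   pct_of_control = 100 * by_cond$cell_number / ctrl_mean,
                   stringsAsFactors = FALSE)
  list(features = feat, cell_number = cn)
}
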