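#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config file: blocks `preprocess`,
#' `nuclei`, `cell_mask`, `propagate`, `phenotype` plus a run `seed` and
#' schema `version`.  Unknown keys are rejected when a file is loaded.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(version = 1L,
       seed = 1L,
       preprocess = unclass(preprocess_params()),
       nuclei = unclass(nuclei_params()),
       cell_mask = list(q = 256L, C = 4L, m = 2, tol = 1e-4, max_iter = 300L),
       propagate = unclass(propagation_params()),
       phenotype = list(bins = 256L))
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()]; unknown keys are an
#' error so typos cannot silently disable a parameter.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return resolved configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
      badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(badk))
        stop("unknown keys in block '", blk, "': ", paste(badk, collapse = ", "))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  cfg
}

#' Segment one channel pair end to end
#'
#' Runs preprocessing, nucleus seed detection, EnFCM cell masking, seed
#' augmentation and seeded propagation.  When `out_dir` is given, the
#' seed and cell label masks are written as 16-bit TIFFs together with a
#' JSON run log (thresholds, iteration count, orphan seeds, counts, wall
#' time) and the effective configuration.
#'
#' @param pair a [channel_pair()] of raw images.
#' @param config configuration list from [read_pipeline_config()].
#' @param out_dir optional output directory.
#' @param image_id identifier used in file names and the log.
#' @return list with `seeds`, `cells` (label masks), `cell_mask`, and
#'   `log`.
#' @export
run_segment <- function(pair, config = default_config(), out_dir = NULL,
                        image_id = "img") {
  t0 <- proc.time()[["elapsed"]]
  pp <- do.call(preprocess_params, config$preprocess)
  pre <- preprocess_pair(pair, pp)
  np <- do.call(nuclei_params, config$nuclei)
  seeds <- detect_nuclei(pre$nuclear, np)
  cm <- config$cell_mask
  mask <- if (max(pre$cytoplasm) > min(pre$cytoplasm)) {
    mask_cells(pre$cytoplasm, q = cm$q, C = cm$C, m = cm$m,
               tol = cm$tol, max_iter = cm$max_iter)
  } else matrix(0L, nrow(pre$cytoplasm), ncol(pre$cytoplasm))
  aug <- augment_mask_with_seeds(mask, seeds)
  prp <- do.call(propagation_params, config$propagate)
  cells <- propagate_cells(pre$cytoplasm, seeds, aug, prp)
  model <- attr(mask, "model")
  log <- list(image_id = image_id,
              nucleus_threshold = attr(seeds, "threshold"),
              cell_threshold = attr(mask, "threshold"),
              enfcm_iterations = if (!is.null(model)) model$iterations else NA,
              n_seeds = length(unique(seeds[seeds > 0])),
              n_cells = length(unique(cells[cells > 0])),
              orphan_seeds = attr(cells, "orphan_seeds"),
              elapsed_s = proc.time()[["elapsed"]] - t0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_label_mask(seeds, file.path(out_dir, paste0(image_id, "_seeds.tif")))
    write_label_mask(cells, file.path(out_dir, paste0(image_id, "_cells.tif")))
    jsonlite::write_json(log, file.path(out_dir, paste0(image_id, "_log.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(config, file.path(out_dir, "effective_config.yaml"))
  }
  list(seeds = seeds, cells = cells, cell_mask = mask, log = log)
}

#' Measure features for a batch of segmented images
#'
#' @param segs list of [run_segment()] results (or lists with `cells` and
#'   `seeds`).
#' @param pairs list of matching [channel_pair()]s.
#' @param image_ids,conditions identifiers per image.
#' @param config configuration list.
#' @param out_csv optional path; when given the combined table is written
#'   via [write_cell_table()] (skipped when the file already exists, so an
#'   interrupted batch resumes idempotently).
#' @return combined cell-record data.frame.
#' @export
run_features <- function(segs, pairs, image_ids = NULL, conditions = "control",
                         config = default_config(), out_csv = NULL) {
  n <- length(segs)
  if (is.null(image_ids)) image_ids <- sprintf("img%02d", seq_len(n))
  conditions <- rep_len(conditions, n)
  if (!is.null(out_csv) && file.exists(out_csv))
    return(read_cell_table(out_csv))
  tabs <- lapply(seq_len(n), function(i)
    measure_image(segs[[i]]$cells, pairs[[i]], segs[[i]]$seeds,
                  image_id = image_ids[i], condition = conditions[i],
                  bins = config$phenotype$bins))
  out <- do.call(rbind, tabs)
  if (!is.null(out_csv)) write_cell_table(out, out_csv)
  out
}

#' Evaluate predicted masks against references
#'
#' Wraps [evaluate_masks()] (and [nuclei_correctness()] when label masks
#' are supplied) and optionally writes a results table with per-image rows
#' followed by Mean and SEM rows.
#'
#' @param preds,refs lists of binary masks (foreground evaluation).
#' @param pred_labels,ref_labels optional lists of label masks for the
#'   nuclei-count correctness fraction.
#' @param out_csv optional output path.
#' @return list with `masks` ([evaluate_masks()] result) and optional
#'   `nuclei_correct` vector.
#' @export
run_evaluate <- function(preds, refs, pred_labels = NULL, ref_labels = NULL,
                         out_csv = NULL) {
  ev <- evaluate_masks(preds, refs)
  out <- list(masks = ev)
  if (!is.null(pred_labels)) {
    out$nuclei_correct <- vapply(seq_along(pred_labels), function(i)
      nuclei_correctness(pred_labels[[i]], ref_labels[[i]]), numeric(1))
  }
  if (!is.null(out_csv)) {
    per <- ev$per_image
    tab <- rbind(cbind(row = as.character(per$image), per[-1]),
                 data.frame(row = "Mean", precision = ev$mean["precision"],
                            recall = ev$mean["recall"], f_score = ev$mean["f_score"]),
                 data.frame(row = "SEM", precision = ev$sem["precision"],
                            recall = ev$sem["recall"], f_score = ev$sem["f_score"]))
    utils::write.csv(tab, out_csv, row.names = FALSE)
  }
  out
}
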