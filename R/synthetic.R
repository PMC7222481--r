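#' Synthetic scene parameters
#'
#' Describes one dual-channel field of view of cultured cardiomyocytes.
#' Cell count defaults to the plating-density regime: "spread" monolayers
#' at ~500 cells/mm^2 and "clustered" cultures at ~2000 cells/mm^2, with a
#' 0.64 um/px calibration (20x objective on a montage-tiling CCD).  A
#' quarter of cells are
#' weakly stained at ~30% of the strong amplitude — the heterogeneity that
#' makes a single global threshold fail — and the cytoplasmic signal is
#' modulated by a sinusoidal striation standing in for sarcomeric Z-disc
#' periodicity.
#'
#' @param width,height raster size in pixels.
#' @param density_regime `"spread"` or `"clustered"`.
#' @param n_cells cell count; `NULL` derives it from the density regime.
#' @param frac_binucleate fraction of cells with two closely apposed
#'   nuclei.
#' @param weak_cell_fraction fraction of weakly stained cells.
#' @param weak_amplitude relative amplitude of weak cells.
#' @param striation_period,striation_contrast sarcomere-like modulation
#'   (px; fraction of amplitude).
#' @param noise_sd additive Gaussian read-noise sd (intensity units; shot
#'   noise is Poisson on top).
#' @param um_per_px spatial calibration used to convert the density
#'   regimes to cell counts.
#' @param dose_effect list with `cell_loss_fraction`, `shrink_factor`,
#'   `rounding_factor`, `nuclear_condensation`.
#' @param seed RNG seed; fixed seed gives bit-identical scenes.
#' @param bit_depth output quantization.
#' @return a `scene_params` list.
#' @export
scene_params <- function(width = 512, height = 512,
                         density_regime = c("spread", "clustered"),
                         n_cells = NULL,
                         frac_binucleate = 0.15,
                         weak_cell_fraction = 0.25,
                         weak_amplitude = 0.3,
                         striation_period = 6,
                         striation_contrast = 0.3,
                         noise_sd = 3,
                         um_per_px = 0.64,
                         dose_effect = list(cell_loss_fraction = 0,
                                            shrink_factor = 1,
                                            rounding_factor = 0,
                                            nuclear_condensation = 0),
                         seed = 1,
                         bit_depth = 8L) {
  density_regime <- match.arg(density_regime)
  if (is.null(n_cells)) {
    dens <- if (density_regime == "spread") 500 else 2000
    area_mm2 <- width * height * (um_per_px / 1000)^2
    n_cells <- max(1L, round(dens * area_mm2))
  }
  stopifnot(n_cells >= 0, frac_binucleate >= 0, frac_binucleate <= 1,
            weak_cell_fraction >= 0, weak_cell_fraction <= 1)
  de <- utils::modifyList(list(cell_loss_fraction = 0, shrink_factor = 1,
                               rounding_factor = 0, nuclear_condensation = 0),
                          dose_effect)
  structure(list(width = width, height = height,
                 density_regime = density_regime, n_cells = as.integer(n_cells),
                 frac_binucleate = frac_binucleate,
                 weak_cell_fraction = weak_cell_fraction,
                 weak_amplitude = weak_amplitude,
                 striation_period = striation_period,
                 striation_contrast = striation_contrast,
                 noise_sd = noise_sd, um_per_px = um_per_px,
                 dose_effect = de, seed = seed, bit_depth = as.integer(bit_depth)),
            class = "scene_params")
}

# dart-throwing placement with a minimum center distance; bounded retries
.place_centers <- function(n, width, height, min_dist, clustered = FALSE,
                           margin = 20, max_tries = 4000) {
  centers <- matrix(numeric(0), 0, 2)
  if (clustered) {
    k <- max(1, round(n / 18))
    hubs <- cbind(stats::runif(k, margin, height - margin),
                  stats::runif(k, margin, width - margin))
  }
  tries <- 0
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1
    if (clustered) {
      hub <- hubs[sample.int(nrow(hubs), 1), ]
      cand <- hub + stats::rnorm(2, 0, min(width, height) / 8)
    } else {
      cand <- c(stats::runif(1, margin, height - margin),
                stats::runif(1, margin, width - margin))
    }
    if (cand[1] < margin || cand[1] > height - margin ||
        cand[2] < margin || cand[2] > width - margin) next
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_dist)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n)
    stop("packing error: could not place ", n, " cells at this density")
  centers
}

# smooth random background field in [0,1]
.smooth_field <- function(nr, nc, sigma = 40) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  rad <- min(2 * ceiling(3 * sigma) + 1, 2 * ((min(nr, nc) - 1) %/% 2) - 1)
  f <- EBImage::imageData(EBImage::gblur(f, sigma = sigma, radius = rad,
                                         boundary = "replicate"))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  (f - rng[1]) / diff(rng)
}

#' Generate one synthetic dual-channel scene with ground truth
#'
#' Cells are drawn as randomly oriented ellipses packed with limited
#' overlap (overlapping pixels go to the nearer cell, giving touching
#' cells with weak edges); each cell carries one nucleus — or two closely
#' apposed ones for bi-nucleated cells.  The cytoplasm channel combines
#' per-cell amplitude (weak cells at `weak_amplitude` of strong), a
#' sinusoidal striation along a random per-cell orientation, a smooth
#' aspecific background field, Poisson shot noise and Gaussian read noise.
#' The nuclear channel renders smooth nuclear blobs; dose-dependent
#' condensation makes nuclei smaller, brighter and more variegated.
#' Output is reproducible bit-for-bit for a fixed seed.
#'
#' @param params a [scene_params()].
#' @return list with `pair` (a [channel_pair()]), and `truth`:
#'   `cell_labels`, `nucleus_labels` and the planted `per_cell` table.
#' @export
generate_scene <- function(params = scene_params()) {
  set.seed(params$seed)
  nr <- params$height; nc <- params$width
  de <- params$dose_effect
  n0 <- params$n_cells
  n <- max(0L, round(n0 * (1 - de$cell_loss_fraction)))

  full <- 2^params$bit_depth - 1
  cyto <- matrix(0, nr, nc)
  nucimg <- matrix(0, nr, nc)
  cell_labels <- matrix(0L, nr, nc)
  nucleus_labels <- matrix(0L, nr, nc)
  per_cell <- NULL

  if (n > 0) {
    shrink <- de$shrink_factor
    base_a <- stats::runif(n, 28, 42) * shrink
    ecc <- stats::runif(n, 0.5, 0.8)
    ecc <- ecc + de$rounding_factor * (1 - ecc)       # toward circular
    base_b <- base_a * ecc
    phi <- stats::runif(n, 0, pi)
    # subconfluent monolayer spacing: cells touch but rarely engulf each other
    min_dist <- if (params$density_regime == "spread") {
      0.75 * sqrt(nr * nc / n)
    } else {
      # nuclei are rigid bodies: centers never closer than two nuclear radii
      max(0.45 * sqrt(nr * nc / n), 22)
    }
    centers <- .place_centers(n, nc, nr, min_dist,
                              clustered = params$density_regime == "clustered",
                              margin = 16)
    weak <- stats::runif(n) < params$weak_cell_fraction
    amp <- ifelse(weak, params$weak_amplitude, 1) * 0.72 * full *
      exp(stats::rnorm(n, 0, 0.2))
    stri_dir <- stats::runif(n, 0, pi)
    binuc <- stats::runif(n) < params$frac_binucleate

    # nearest-ellipse label assignment
    dist_best <- matrix(Inf, nr, nc)
    for (k in seq_len(n)) {
      a <- base_a[k]; b <- base_b[k]
      r0 <- centers[k, 1]; c0 <- centers[k, 2]
      rs <- max(1, floor(r0 - a)):min(nr, ceiling(r0 + a))
      cs <- max(1, floor(c0 - a)):min(nc, ceiling(c0 + a))
      dr <- outer(rs - r0, rep(1, length(cs)))
      dc <- outer(rep(1, length(rs)), cs - c0)
      u <- dr * cos(phi[k]) + dc * sin(phi[k])
      v <- -dr * sin(phi[k]) + dc * cos(phi[k])
      d <- sqrt((u / a)^2 + (v / b)^2)
      inside <- d <= 1
      sub_best <- dist_best[rs, cs]
      take <- inside & d < sub_best
      sub_lab <- cell_labels[rs, cs]
      sub_lab[take] <- k
      sub_best[take] <- d[take]
      cell_labels[rs, cs] <- sub_lab
      dist_best[rs, cs] <- sub_best
    }

    # cytoplasm signal: amplitude x striation x radial taper
    for (k in seq_len(n)) {
      px <- which(cell_labels == k)
      if (!length(px)) next
      rr <- (px - 1) %% nr + 1
      cc <- (px - 1) %/% nr + 1
      u <- (rr - centers[k, 1]) * cos(stri_dir[k]) +
           (cc - centers[k, 2]) * sin(stri_dir[k])
      stri <- 1 - params$striation_contrast / 2 +
        (params$striation_contrast / 2) * sin(2 * pi * u / params$striation_period)
      taper <- 1 - 0.15 * dist_best[px]^2
      cyto[px] <- amp[k] * stri * taper
    }

    # nuclei
    nuc_id <- 0L
    rows <- list()
    cond <- de$nuclear_condensation
    for (k in seq_len(n)) {
      r_n <- stats::runif(1, 7, 10) * shrink * (1 - 0.35 * cond)
      n_nuc <- if (binuc[k]) 2L else 1L
      nuc_amp <- 0.65 * full * (1 + 0.6 * cond) * exp(stats::rnorm(1, 0, 0.06))
      nuc_amp <- min(nuc_amp, full)
      offs <- if (n_nuc == 2L) {
        ang <- stats::runif(1, 0, pi)
        sep <- 0.95 * r_n                      # abutting twin nuclei
        rbind(c(sin(ang), cos(ang)) * sep, -c(sin(ang), cos(ang)) * sep)
      } else matrix(0, 1, 2)
      for (jn in seq_len(n_nuc)) {
        nuc_id <- nuc_id + 1L
        ctr <- centers[k, ] + offs[jn, ]
        rs <- max(1, floor(ctr[1] - r_n)):min(nr, ceiling(ctr[1] + r_n))
        cs <- max(1, floor(ctr[2] - r_n)):min(nc, ceiling(ctr[2] + r_n))
        dr <- outer(rs - ctr[1], rep(1, length(cs)))
        dc <- outer(rep(1, length(rs)), cs - ctr[2])
        d <- sqrt(dr^2 + dc^2) / r_n
        inside <- d <= 1
        prof <- nuc_amp * sqrt(pmax(1 - d^2, 0))
        if (cond > 0)
          prof <- prof * (1 + cond * 0.8 *
                            matrix(stats::rnorm(length(prof)), nrow(prof)))
        sub <- nucimg[rs, cs]
        sub[inside] <- pmax(sub[inside], prof[inside])
        nucimg[rs, cs] <- sub
        subl <- nucleus_labels[rs, cs]
        subl[inside] <- nuc_id
        nucleus_labels[rs, cs] <- subl
        rows[[nuc_id]] <- data.frame(cell = k, nucleus = nuc_id,
                                     center_r = ctr[1], center_c = ctr[2])
      }
    }
    nuc_tab <- do.call(rbind, rows)
    # clip nuclei to their own cell so every nucleus lies inside its cell
    cell_of <- nuc_tab$cell[match(nucleus_labels[nucleus_labels > 0], nuc_tab$nucleus)]
    bad <- which(nucleus_labels > 0)[cell_labels[nucleus_labels > 0] != cell_of]
    if (length(bad)) {
      nucleus_labels[bad] <- 0L
      nucimg[bad] <- 0
    }
    surviving <- sort(unique(nucleus_labels[nucleus_labels > 0]))
    nuc_tab <- nuc_tab[nuc_tab$nucleus %in% surviving, , drop = FALSE]
    nuc_tab$nucleus <- match(nuc_tab$nucleus, surviving)
    nucleus_labels <- relabel_mask(nucleus_labels)
    per_cell <- data.frame(cell = seq_len(n),
                           center_r = centers[, 1], center_c = centers[, 2],
                           area = tabulate(cell_labels[cell_labels > 0], nbins = n),
                           weak_flag = weak, binucleate_flag = binuc)
    attr(per_cell, "nuclei") <- nuc_tab
  }

  # aspecific background + noise, then quantize
  bg_c <- 4 + 8 * .smooth_field(nr, nc, sigma = 40)
  bg_n <- 2 + 4 * .smooth_field(nr, nc, sigma = 40)
  cyto_n <- stats::rpois(nr * nc, pmax(cyto + bg_c, 0)) +
    stats::rnorm(nr * nc, 0, params$noise_sd)
  nuc_n <- stats::rpois(nr * nc, pmax(nucimg + bg_n, 0)) +
    stats::rnorm(nr * nc, 0, params$noise_sd)
  cyto <- matrix(pmin(pmax(round(cyto_n), 0), full), nr, nc)
  nucimg <- matrix(pmin(pmax(round(nuc_n), 0), full), nr, nc)

  pair <- channel_pair(
    structure(nucimg, bit_depth = params$bit_depth, channel_tag = "nuclear"),
    structure(cyto, bit_depth = params$bit_depth, channel_tag = "cytoplasm"))
  list(pair = pair,
       truth = list(cell_labels = cell_labels,
                    nucleus_labels = nucleus_labels,
                    per_cell = per_cell))
}

#' Generate a replicated dose-response series
#'
#' For each condition, `n_replicates` scenes are generated with the
#' condition's dose effect applied (cell loss, shrinkage, rounding,
#' nuclear condensation), emulating a drug titration with vehicle
#' control.  Replicate r of condition j uses seed
#' `base$seed + 1000 * j + r`, so the series is reproducible.
#'
#' @param base a [scene_params()] describing the control condition.
#' @param conditions named list of dose-effect lists; must include an
#'   all-zero control entry (use [dose_conditions()] for a standard
#'   titration).
#' @param n_replicates scenes per condition.
#' @return named list (per condition) of lists of [generate_scene()]
#'   outputs.
#' @export
generate_dose_series <- function(base = scene_params(),
                                 conditions = dose_conditions(),
                                 n_replicates = 5) {
  if (!"control" %in% names(conditions))
    stop("conditions must include a 'control' entry")
  out <- list()
  for (j in seq_along(conditions)) {
    nm <- names(conditions)[j]
    reps <- lapply(seq_len(n_replicates), function(r) {
      p <- base
      p$dose_effect <- utils::modifyList(base$dose_effect, conditions[[j]])
      p$seed <- base$seed + 1000 * j + r
      generate_scene(p)
    })
    out[[nm]] <- reps
  }
  out
}

#' Standard planted dose-effect titration
#'
#' Six conditions (control + 5 doses) with monotonically increasing cell
#' loss, shrinkage, rounding and nuclear condensation — the phenotype
#' course of a cardiotoxic titration.
#'
#' @return named list of dose-effect lists.
#' @export
dose_conditions <- function() {
  list(
    control = list(),
    dose1 = list(cell_loss_fraction = 0.10, shrink_factor = 0.95,
                 rounding_factor = 0.10, nuclear_condensation = 0.10),
    dose2 = list(cell_loss_fraction = 0.25, shrink_factor = 0.90,
                 rounding_factor = 0.20, nuclear_condensation = 0.20),
    dose3 = list(cell_loss_fraction = 0.45, shrink_factor = 0.80,
                 rounding_factor = 0.35, nuclear_condensation = 0.40),
    dose4 = list(cell_loss_fraction = 0.70, shrink_factor = 0.70,
                 rounding_factor = 0.50, nuclear_condensation = 0.60),
    dose5 = list(cell_loss_fraction = 0.88, shrink_factor = 0.60,
                 rounding_factor = 0.60, nuclear_condensation = 0.80))
}
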