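# Synthetic-data generator: multi-channel fields with planted nuclei,
# LAMP1-like vesicles and marker puncta; screening plates with per-gene
# knockdown effects; damage-response time courses; SILAC proximity tables.
# Every generator records full ground truth and is bit-reproducible under
# (config, seed).

CANONICAL_ROLES <- c(
  "nucleus", "lysosome", "ubiquitin_FK2", "ubiquitin_K48",
  "ubiquitin_K63", "gal3", "poi"
)

#' Simulation configuration for synthetic microscopy fields
#'
#' Physical sizes are in micrometers and converted through `pixel_size`.
#' "Damage" (e.g. LLOMe treatment) is modelled purely as an increase in the
#' per-vesicle marker positivity fraction; geometry is unaffected.
#'
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_cells number of cells (nuclei) to plant.
#' @param nucleus_radius `c(mean, sd)` of the nucleus radius in um.
#' @param vesicles_per_cell_mean Poisson mean of vesicles per cell.
#' @param vesicle_radius `c(meanlog, sdlog)` of the log-normal vesicle
#'   radius in um.
#' @param positivity_fraction named vector, per marker role, probability in
#'   `[0, 1]` that a vesicle carries that marker.
#' @param amplitudes named per-channel peak signal (arbitrary units, before
#'   PSF blur); unnamed roles fall back to `default_amplitude`.
#' @param default_amplitude amplitude for channels absent from `amplitudes`.
#' @param background named or scalar per-channel offset.
#' @param psf_sigma Gaussian point-spread-function sigma in um.
#' @param noise list with `gaussian_sd` (read noise, intensity units) and
#'   `poisson_gain` (intensity units per photon; 0 disables shot noise).
#' @param bit_depth sensor bit depth (clip ceiling `2^bit_depth - 1`).
#' @param min_vesicle_separation minimum clearance between vesicle centers,
#'   in units of the sum of the two radii (default 2 keeps one diameter of
#'   clearance so detection ground truth is unambiguous).
#' @param allow_overlap if `TRUE`, vesicle placement skips the separation
#'   rejection step.
#' @param marker_radius_factor marker disk radius relative to its vesicle.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       image_shape = c(256L, 256L),
                       pixel_size = 0.25,
                       n_cells = 10L,
                       nucleus_radius = c(3, 0.3),
                       vesicles_per_cell_mean = 15,
                       vesicle_radius = c(meanlog = log(0.5), sdlog = 0.15),
                       positivity_fraction = c(ubiquitin_FK2 = 0.8,
                                               ubiquitin_K48 = 0.8),
                       amplitudes = c(nucleus = 8000, lysosome = 5000),
                       default_amplitude = 5000,
                       background = 300,
                       psf_sigma = 0.2,
                       noise = list(gaussian_sd = 25, poisson_gain = 0.5),
                       bit_depth = 16L,
                       min_vesicle_separation = 2,
                       allow_overlap = FALSE,
                       marker_radius_factor = 0.8) {
  if (length(image_shape) != 2 || any(image_shape <= 0)) {
    stop_config("image_shape must be two positive integers")
  }
  if (pixel_size <= 0) stop_config("pixel_size must be > 0")
  if (n_cells < 0) stop_config("n_cells must be >= 0")
  if (any(nucleus_radius[1] <= 0)) stop_config("nucleus radius mean must be > 0")
  if (any(positivity_fraction < 0 | positivity_fraction > 1)) {
    stop_config("positivity_fraction values must lie in [0, 1]")
  }
  if (is.null(names(positivity_fraction)) && length(positivity_fraction) > 0) {
    stop_config("positivity_fraction must be named by marker role")
  }
  structure(list(
    rng_seed = as.integer(rng_seed),
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    n_cells = as.integer(n_cells),
    nucleus_radius = nucleus_radius,
    vesicles_per_cell_mean = vesicles_per_cell_mean,
    vesicle_radius = vesicle_radius,
    positivity_fraction = positivity_fraction,
    amplitudes = amplitudes,
    default_amplitude = default_amplitude,
    background = background,
    psf_sigma = psf_sigma,
    noise = noise,
    bit_depth = as.integer(bit_depth),
    min_vesicle_separation = min_vesicle_separation,
    allow_overlap = allow_overlap,
    marker_radius_factor = marker_radius_factor
  ), class = "sim_config")
}

channel_background <- function(config, role) {
  bg <- config$background
  if (length(bg) == 1 && is.null(names(bg))) return(unname(bg))
  unname(bg[role] %||% 0)
}

channel_amplitude <- function(config, role) {
  a <- config$amplitudes[role]
  if (is.na(a)) a <- config$default_amplitude
  unname(a)
}

# Sample n points with pairwise minimum distance by rejection.
sample_separated <- function(n, shape, margin, min_dist, max_tries = 20000) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- c(runif(1, margin, shape[1] - 1 - margin),
              runif(1, margin, shape[2] - 1 - margin))
    if (nrow(pts) == 0 ||
        all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >= min_dist^2)) {
      pts <- rbind(pts, cand)
    }
  }
  if (nrow(pts) < n) {
    stop_config("could not place %d separated nuclei in a %dx%d field",
                n, shape[1], shape[2])
  }
  pts
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' Plants `n_cells` nuclei (uniform disks), partitions the field into cells
#' by the nucleus-seeded Voronoi diagram, scatters vesicles uniformly in the
#' cytoplasm of each cell, labels each vesicle positive/negative per marker
#' by a Bernoulli draw at the configured positivity fraction, then renders
#' each channel as background + PSF-blurred disks + camera noise.
#'
#' @param config a [sim_config()].
#' @param overrides optional list; `overrides$positivity` is a named list
#'   (per marker role) of either a scalar fraction or one fraction per cell,
#'   replacing `config$positivity_fraction` for that marker.
#' @return list with `field` (an [image_field()]) and `truth` (class
#'   `ground_truth`: `cells` and `vesicles` data frames plus the realized
#'   per-marker positive fractions).
#' @export
generate_field <- function(config, overrides = NULL) {
  stopifnot(inherits(config, "sim_config"))
  shape <- config$image_shape
  px <- config$pixel_size
  markers <- names(config$positivity_fraction)
  with_seed(config$rng_seed, {
    nuc_r_px <- pmax(2, rnorm(config$n_cells,
                              config$nucleus_radius[1],
                              config$nucleus_radius[2]) / px)
    if (config$n_cells > 0) {
      margin <- max(nuc_r_px) + 2
      min_dist <- 4 * config$nucleus_radius[1] / px
      centers <- sample_separated(config$n_cells, shape, margin, min_dist)
    } else {
      centers <- matrix(numeric(0), 0, 2)
    }
    cells <- data.frame(
      cell_id = seq_len(config$n_cells),
      center_row = centers[, 1][seq_len(config$n_cells)],
      center_col = centers[, 2][seq_len(config$n_cells)],
      nucleus_radius_px = nuc_r_px[seq_len(config$n_cells)]
    )

    vesicles <- list()
    vid <- 0
    all_pos <- matrix(numeric(0), 0, 2)
    all_rad <- numeric(0)
    cell_lab <- if (config$n_cells > 0) {
      .nearest_seed(matrix(TRUE, shape[1], shape[2]),
                    cells$center_row, cells$center_col)
    } else {
      matrix(0L, shape[1], shape[2])
    }
    for (ci in seq_len(config$n_cells)) {
      n_ves <- rpois(1, config$vesicles_per_cell_mean)
      if (n_ves == 0) next
      radii <- rlnorm(n_ves, config$vesicle_radius[1],
                      config$vesicle_radius[2]) / px
      # candidate pixels: this cell's Voronoi region, outside the nucleus,
      # away from the field border
      in_cell <- which(cell_lab == ci, arr.ind = TRUE)
      d_nuc <- sqrt((in_cell[, 1] - 1 - cells$center_row[ci])^2 +
                    (in_cell[, 2] - 1 - cells$center_col[ci])^2)
      placed <- 0
      tries <- 0
      while (placed < n_ves && tries < 4000) {
        tries <- tries + 1
        r_v <- radii[placed + 1]
        ok_pix <- d_nuc > cells$nucleus_radius_px[ci] + r_v + 1 &
          in_cell[, 1] - 1 > r_v + 1 & in_cell[, 1] - 1 < shape[1] - r_v - 2 &
          in_cell[, 2] - 1 > r_v + 1 & in_cell[, 2] - 1 < shape[2] - r_v - 2
        cand_set <- which(ok_pix)
        if (length(cand_set) == 0) break
        pick <- in_cell[cand_set[sample.int(length(cand_set), 1)], ] - 1
        if (!config$allow_overlap && nrow(all_pos) > 0) {
          d2 <- (all_pos[, 1] - pick[1])^2 + (all_pos[, 2] - pick[2])^2
          need <- (config$min_vesicle_separation * (all_rad + r_v))^2
          if (any(d2 < need)) next
        }
        placed <- placed + 1
        vid <- vid + 1
        all_pos <- rbind(all_pos, pick)
        all_rad <- c(all_rad, r_v)
        vesicles[[vid]] <- data.frame(
          vesicle_id = vid, cell_id = ci,
          row = pick[1], col = pick[2], radius_px = r_v
        )
      }
    }
    vesicles <- if (vid > 0) do.call(rbind, vesicles) else data.frame(
      vesicle_id = integer(0), cell_id = integer(0),
      row = numeric(0), col = numeric(0), radius_px = numeric(0)
    )

    # marker positivity labels
    for (m in markers) {
      f <- config$positivity_fraction[[m]]
      ov <- overrides$positivity[[m]]
      if (!is.null(ov)) {
        if (any(ov < 0 | ov > 1)) {
          stop_config("positivity override for %s outside [0, 1]", m)
        }
        f_vec <- if (length(ov) == 1) rep(ov, max(1, config$n_cells)) else ov
      } else {
        f_vec <- rep(f, max(1, config$n_cells))
      }
      lab <- if (nrow(vesicles) > 0) {
        rbinom(nrow(vesicles), 1, f_vec[vesicles$cell_id]) == 1
      } else {
        logical(0)
      }
      vesicles[[paste0("positive_", m)]] <- lab
    }

    # render channels
    roles <- c("nucleus", "lysosome", markers)
    channels <- list()
    for (role in roles) {
      img <- matrix(channel_background(config, role), shape[1], shape[2])
      amp <- channel_amplitude(config, role)
      if (role == "nucleus") {
        for (ci in seq_len(nrow(cells))) {
          img <- render_disk(img, c(cells$center_row[ci], cells$center_col[ci]),
                             cells$nucleus_radius_px[ci], amp)
        }
      } else if (role == "lysosome") {
        for (vi in seq_len(nrow(vesicles))) {
          img <- render_disk(img, c(vesicles$row[vi], vesicles$col[vi]),
                             vesicles$radius_px[vi], amp)
        }
      } else {
        pos <- which(vesicles[[paste0("positive_", role)]])
        for (vi in pos) {
          img <- render_disk(img, c(vesicles$row[vi], vesicles$col[vi]),
                             vesicles$radius_px[vi] * config$marker_radius_factor,
                             amp)
        }
      }
      img <- gaussian_blur(img, config$psf_sigma / px)
      img <- apply_camera_noise(img, config$noise$gaussian_sd,
                                config$noise$poisson_gain, config$bit_depth)
      channels[[role]] <- img
    }
    field <- image_field(channels, pixel_size = px, bit_depth = config$bit_depth)

    realized <- vapply(markers, function(m) {
      if (nrow(vesicles) == 0) NA_real_ else
        mean(vesicles[[paste0("positive_", m)]])
    }, numeric(1))
    truth <- structure(list(
      cells = cells,
      vesicles = vesicles,
      cell_labels = cell_lab,
      realized_fraction = realized,
      markers = markers
    ), class = "ground_truth")
    list(field = field, truth = truth)
  })
}

#' Screening plate design
#'
#' Builds the layout of the primary (pools of four siRNAs) or secondary
#' (deconvolved singles) screen: 37 library genes by default, each with
#' `replicates` damage-treated wells per reagent, plus non-targeting
#' (`siCtrl`, treated and untreated) and positive-shift (`ATG5`, `ATG7`)
#' control wells.
#'
#' @param genes character vector of library gene labels.
#' @param reagents `"pool"` (one pool of four per gene) or `"singles"`
#'   (four individual siRNAs per gene).
#' @param replicates treated replicate wells per reagent.
#' @param controls character vector of control labels; `siCtrl` also gets
#'   untreated wells.
#' @return data.frame of class `plate_design` with columns `well_id`,
#'   `gene`, `reagent`, `treatment` (`damaged`/`untreated`), `replicate`,
#'   `is_control`.
#' @export
plate_design <- function(genes = sprintf("E2_%02d", 1:37),
                         reagents = c("pool", "singles"),
                         replicates = 4L,
                         controls = c("siCtrl", "ATG5", "ATG7")) {
  reagents <- match.arg(reagents)
  if (length(genes) == 0) stop_config("plate design needs at least one gene")
  reagent_of <- function(g) {
    if (reagents == "pool") "pool" else sprintf("single_%d", 1:4)
  }
  rows <- list()
  for (g in genes) {
    for (rg in reagent_of(g)) {
      for (rep_i in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, reagent = rg, treatment = "damaged",
          replicate = rep_i, is_control = FALSE
        )
      }
    }
  }
  for (ctl in controls) {
    for (rep_i in seq_len(replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = ctl, reagent = "pool", treatment = "damaged",
        replicate = rep_i, is_control = TRUE
      )
    }
    if (ctl == "siCtrl") {
      for (rep_i in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = ctl, reagent = "pool", treatment = "untreated",
          replicate = rep_i, is_control = TRUE
        )
      }
    }
  }
  design <- do.call(rbind, rows)
  n <- nrow(design)
  plate_rows <- LETTERS[1:16]
  design <- cbind(
    well_id = sprintf("%s%02d", plate_rows[((seq_len(n) - 1) %/% 24) %% 16 + 1],
                      (seq_len(n) - 1) %% 24 + 1),
    design
  )
  if (anyDuplicated(design$well_id)) {
    design$well_id <- sprintf("P%d_%s", (seq_len(n) - 1) %/% 384 + 1,
                              design$well_id)
  }
  class(design) <- c("plate_design", "data.frame")
  design
}

#' Simulate a screening plate
#'
#' Every well's planted marker-positivity fraction is
#' `clamp(baseline * gene_effect + well_noise, 0, 1)`; untreated wells use
#' `untreated_fraction` instead of the treated baseline. At metric-level
#' fidelity the per-cell readouts (vesicle counts Poisson, positives
#' binomial at the well fraction) are drawn directly from the distributions
#' the image path realizes; at image-level fidelity full fields are
#' rendered and must be quantified downstream.
#'
#' @param design a [plate_design()].
#' @param config a [sim_config()]; supplies the treated baseline positivity
#'   per staining, vesicle counts and (for image fidelity) the optics.
#' @param gene_effects named numeric vector of multiplicative effects on the
#'   positivity fraction; names must be design genes (controls `ATG5`/`ATG7`
#'   default to 1.25, `siCtrl` to 1).
#' @param fidelity `"metric"` or `"image"`.
#' @param well_sd well-to-well Gaussian noise on the positivity fraction
#'   (fraction units; 0.05 = 5 percentage points).
#' @param cells_per_well cells simulated per well (metric fidelity).
#' @param untreated_fraction positivity fraction of untreated wells.
#' @param hit_effect_cutoff genes with effect at or below this are recorded
#'   as planted true hits in the truth.
#' @return list of class `plate_dataset`: `design`, `fidelity`, `cells`
#'   (metric) or `fields` (image), `truth` (per-well planted fractions,
#'   `gene_effects`, `true_hits`).
#' @export
generate_plate <- function(design, config,
                           gene_effects = NULL,
                           fidelity = c("metric", "image"),
                           well_sd = 0.05,
                           cells_per_well = 100L,
                           untreated_fraction = 0.05,
                           hit_effect_cutoff = 0.6) {
  stopifnot(inherits(design, "plate_design"), inherits(config, "sim_config"))
  fidelity <- match.arg(fidelity)
  stainings <- names(config$positivity_fraction)
  if (length(stainings) == 0) stop_config("config has no marker stainings")

  effects <- c(siCtrl = 1, ATG5 = 1.25, ATG7 = 1.25)
  if (!is.null(gene_effects)) {
    unknown <- setdiff(names(gene_effects), unique(design$gene))
    if (length(unknown) > 0) {
      stop_config("gene_effects names not in design: %s",
                  paste(unknown, collapse = ", "))
    }
    effects[names(gene_effects)] <- gene_effects
  }
  all_genes <- unique(design$gene)
  full_eff <- setNames(rep(1, length(all_genes)), all_genes)
  full_eff[names(effects)[names(effects) %in% all_genes]] <-
    effects[names(effects) %in% all_genes]

  with_seed(config$rng_seed, {
    well_truth <- list()
    cell_rows <- list()
    fields <- list()
    for (wi in seq_len(nrow(design))) {
      w <- design[wi, ]
      for (st in stainings) {
        base <- if (w$treatment == "untreated") untreated_fraction else
          config$positivity_fraction[[st]] * full_eff[[w$gene]]
        p_well <- min(1, max(0, base + rnorm(1, 0, well_sd)))
        well_truth[[length(well_truth) + 1]] <- data.frame(
          well_id = w$well_id, gene = w$gene, reagent = w$reagent,
          treatment = w$treatment, staining = st,
          planted_fraction = p_well
        )
        if (fidelity == "metric") {
          n_ves <- rpois(cells_per_well, config$vesicles_per_cell_mean)
          n_pos <- rbinom(cells_per_well, n_ves, p_well)
          cell_rows[[length(cell_rows) + 1]] <- data.frame(
            well_id = w$well_id, staining = st,
            cell_id = seq_len(cells_per_well),
            n_vesicles = n_ves, n_positive = n_pos,
            percent_positive = ifelse(n_ves > 0, 100 * n_pos / n_ves, NA_real_)
          )
        }
      }
      if (fidelity == "image") {
        cfg_w <- config
        cfg_w$rng_seed <- child_seed(config$rng_seed, wi)
        ov <- list(positivity = setNames(
          lapply(stainings, function(st) {
            tr <- well_truth[[length(well_truth) - length(stainings) +
                                which(stainings == st)]]
            tr$planted_fraction
          }), stainings))
        fields[[w$well_id]] <- generate_field(cfg_w, overrides = ov)
      }
    }
    truth <- list(
      wells = do.call(rbind, well_truth),
      gene_effects = full_eff,
      true_hits = names(full_eff)[full_eff <= hit_effect_cutoff]
    )
    structure(list(
      design = design,
      fidelity = fidelity,
      cells = if (fidelity == "metric") do.call(rbind, cell_rows) else NULL,
      fields = if (fidelity == "image") fields else NULL,
      truth = truth
    ), class = "plate_dataset")
  })
}

#' Damage-response kinetics profile
#'
#' Per-marker positivity-fraction curves after lysosomal damage. Each curve
#' is `baseline + (peak - baseline) * ((t/tp) * exp(1 - t/tp))^shape`, a
#' smooth pulse that rises from baseline, peaks exactly at `tp` minutes and
#' decays. Defaults encode the early K63/p62 response (apparent by 30 min,
#' peak within the hour) and the delayed K48/UBE2QL1 response (peak at
#' 2-3 h).
#'
#' @param time_points sampling times in minutes, ascending.
#' @param markers named list; each entry is `c(baseline, peak, peak_time,
#'   shape)`.
#' @return object of class `kinetics_profile`.
#' @export
kinetics_profile <- function(
    time_points = c(0, 30, 60, 120, 180),
    markers = list(
      ubiquitin_K63 = c(baseline = 0.05, peak = 0.60, peak_time = 60, shape = 2),
      p62           = c(baseline = 0.05, peak = 0.60, peak_time = 60, shape = 2),
      ubiquitin_K48 = c(baseline = 0.05, peak = 0.55, peak_time = 150, shape = 3),
      ube2ql1       = c(baseline = 0.05, peak = 0.55, peak_time = 150, shape = 3)
    )) {
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop_config("time_points must be strictly ascending")
  }
  structure(list(time_points = time_points, markers = markers),
            class = "kinetics_profile")
}

#' Evaluate a kinetics profile at given times
#'
#' @param profile a [kinetics_profile()].
#' @param times minutes; defaults to the profile's own time points.
#' @return matrix of fractions, rows = times, columns = markers.
#' @export
evaluate_kinetics <- function(profile, times = profile$time_points) {
  out <- sapply(names(profile$markers), function(m) {
    p <- profile$markers[[m]]
    f <- ifelse(times <= 0, p[["baseline"]],
                p[["baseline"]] + (p[["peak"]] - p[["baseline"]]) *
                  ((times / p[["peak_time"]]) *
                     exp(1 - times / p[["peak_time"]]))^p[["shape"]])
    f
  })
  out <- matrix(out, nrow = length(times),
                dimnames = list(as.character(times), names(profile$markers)))
  if (any(out < 0 | out > 1)) {
    stop_config("kinetics profile leaves [0, 1]; check peak fractions")
  }
  out
}

#' Simulate a damage-response time course
#'
#' Generates one field per time point with the per-marker positivity
#' fraction set to the profile curve evaluated at that time.
#'
#' @param profile a [kinetics_profile()].
#' @param config a [sim_config()]; its `positivity_fraction` is replaced by
#'   the profile markers.
#' @return list of entries `list(time, field, truth, planted_fraction)`.
#' @export
generate_timecourse <- function(profile, config) {
  stopifnot(inherits(profile, "kinetics_profile"),
            inherits(config, "sim_config"))
  frac <- evaluate_kinetics(profile)
  lapply(seq_along(profile$time_points), function(i) {
    cfg <- config
    cfg$rng_seed <- child_seed(config$rng_seed, i)
    cfg$positivity_fraction <- setNames(frac[i, ], colnames(frac))
    fg <- generate_field(cfg)
    list(time = profile$time_points[i], field = fg$field, truth = fg$truth,
         planted_fraction = frac[i, ])
  })
}

#' Configuration for the synthetic SILAC proximity-labeling dataset
#'
#' Emulates a comparative SILAC experiment mixed 1:1 (so non-enriched
#' proteins are centered at log2 H/L = 0) quantified over replicate runs,
#' with MaxQuant-style contaminant / reverse / site-only flags and
#' missing-completely-at-random per-replicate detection.
#'
#' @param rng_seed integer seed.
#' @param n_proteins number of unflagged library proteins.
#' @param n_replicates biological replicates (>= 2; default 4).
#' @param null_log2_sd per-replicate sd of log2 H/L for null proteins.
#' @param enriched_set named numeric vector mapping protein ids (subset of
#'   `P0001 ...`) to their true mean log2 H/L; by default 40 proteins split
#'   between effects +2 and +3.
#' @param contaminant_fraction,reverse_fraction,site_only_fraction
#'   proportions of extra rows carrying each removal flag.
#' @param detection_prob probability a protein is quantified in a given
#'   replicate (H and L jointly observed).
#' @return object of class `silac_sim_config`.
#' @export
silac_sim_config <- function(rng_seed = 1L,
                             n_proteins = 1500L,
                             n_replicates = 4L,
                             null_log2_sd = 0.3,
                             enriched_set = NULL,
                             contaminant_fraction = 0.02,
                             reverse_fraction = 0.01,
                             site_only_fraction = 0.01,
                             detection_prob = 0.9) {
  if (n_replicates < 2) stop_config("n_replicates must be >= 2 (t-test undefined)")
  fr <- c(contaminant_fraction, reverse_fraction, site_only_fraction,
          detection_prob)
  if (any(fr < 0 | fr > 1)) stop_config("fractions must lie in [0, 1]")
  ids <- sprintf("P%04d", seq_len(n_proteins))
  if (is.null(enriched_set)) {
    n_enr <- min(40L, n_proteins)
    enriched_set <- setNames(rep(c(2, 3), length.out = n_enr),
                             ids[seq_len(n_enr)])
  }
  if (!all(names(enriched_set) %in% ids)) {
    stop_config("enriched_set contains ids outside the protein set")
  }
  structure(list(
    rng_seed = as.integer(rng_seed), n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates), null_log2_sd = null_log2_sd,
    enriched_set = enriched_set,
    contaminant_fraction = contaminant_fraction,
    reverse_fraction = reverse_fraction,
    site_only_fraction = site_only_fraction,
    detection_prob = detection_prob
  ), class = "silac_sim_config")
}

#' Generate a synthetic SILAC protein-quantification table
#'
#' Light intensities are log-normal; per-replicate log2 H/L ratios are
#' Gaussian around 0 (null) or around the protein's true effect (enriched);
#' heavy = light * 2^ratio. Flagged decoy rows (contaminant, reverse,
#' site-only) are appended with null ratios. Undetected replicates carry NA
#' in both channels.
#'
#' @param config a [silac_sim_config()].
#' @return list of class `silac_dataset` with `quant` (one row per protein:
#'   `protein_id`, `gene_symbol`, flags, `light_k`/`heavy_k` columns) and
#'   `truth` (`protein_id`, `true_log2`, `is_enriched`).
#' @export
generate_silac_dataset <- function(config) {
  stopifnot(inherits(config, "silac_sim_config"))
  with_seed(config$rng_seed, {
    n <- config$n_proteins
    k <- config$n_replicates
    ids <- sprintf("P%04d", seq_len(n))
    true_log2 <- setNames(rep(0, n), ids)
    true_log2[names(config$enriched_set)] <- config$enriched_set

    n_flag <- round(n * c(config$contaminant_fraction,
                          config$reverse_fraction,
                          config$site_only_fraction))
    flag_ids <- sprintf("DEC%04d", seq_len(sum(n_flag)))
    all_ids <- c(ids, flag_ids)
    m <- length(all_ids)
    contaminant <- c(rep(FALSE, n),
                     rep(c(TRUE, FALSE, FALSE), n_flag))
    reverse <- c(rep(FALSE, n), rep(c(FALSE, TRUE, FALSE), n_flag))
    site_only <- c(rep(FALSE, n), rep(c(FALSE, FALSE, TRUE), n_flag))
    mu <- c(unname(true_log2), rep(0, m - n))

    quant <- data.frame(
      protein_id = all_ids,
      gene_symbol = sub("^P", "GENE", sub("^DEC", "DECOY", all_ids)),
      contaminant = contaminant, reverse = reverse, site_only = site_only
    )
    for (r in seq_len(k)) {
      light <- rlnorm(m, meanlog = 16, sdlog = 1)
      ratio <- rnorm(m, mu, config$null_log2_sd)
      heavy <- light * 2^ratio
      detected <- runif(m) < config$detection_prob
      light[!detected] <- NA_real_
      heavy[!detected] <- NA_real_
      quant[[sprintf("light_%d", r)]] <- light
      quant[[sprintf("heavy_%d", r)]] <- heavy
    }
    truth <- data.frame(
      protein_id = ids,
      true_log2 = unname(true_log2),
      is_enriched = ids %in% names(config$enriched_set)
    )
    structure(list(quant = quant, truth = truth, n_replicates = k),
              class = "silac_dataset")
  })
}
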