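# Per-cell readouts: percent marker-positive vesicles, per-cell Pearson
# colocalization, strict puncta-count classification, nuclear/cytoplasmic
# intensity ratios, and fold-change normalization against control wells.

#' Classify vesicles as marker-positive
#'
#' Two criteria are offered. `overlap` (default): a vesicle is positive
#' when at least one detected marker-punctum centroid falls inside the
#' vesicle's disk mask. `intensity`: positive when the background-corrected
#' marker mean on the vesicle exceeds `k` robust-noise units of the marker
#' channel.
#'
#' @param vesicles vesicle records (e.g. LAMP1 detections) from
#'   [detect_puncta()], measured by [measure_objects()] if the intensity
#'   criterion is used.
#' @param marker_role marker channel role.
#' @param criterion `"overlap"` or `"intensity"`.
#' @param marker_puncta marker-channel detections (overlap criterion).
#' @param field the [image_field()] (intensity criterion noise scale).
#' @param k intensity threshold in robust-noise units.
#' @return logical vector, one element per vesicle, with the criterion
#'   recorded in attributes `criterion` and `k`.
#' @export
vesicle_is_positive <- function(vesicles, marker_role,
                                criterion = c("overlap", "intensity"),
                                marker_puncta = NULL, field = NULL, k = 3) {
  criterion <- match.arg(criterion)
  if (criterion == "overlap") {
    if (is.null(marker_puncta)) {
      stop_config("overlap criterion needs marker_puncta detections")
    }
    pos <- vapply(seq_len(nrow(vesicles)), function(i) {
      if (nrow(marker_puncta) == 0) return(FALSE)
      d2 <- (marker_puncta$row - vesicles$row[i])^2 +
        (marker_puncta$col - vesicles$col[i])^2
      any(d2 <= vesicles$radius_px[i]^2)
    }, logical(1))
  } else {
    colname <- paste0("corrected_", marker_role)
    if (!colname %in% names(vesicles)) {
      stop_config("vesicles lack measured column %s; run measure_objects()",
                  colname)
    }
    if (is.null(field)) {
      stop_config("intensity criterion needs the field for its noise scale")
    }
    noise <- robust_scale(as.vector(field$channels[[marker_role]]))
    pos <- vesicles[[colname]] > k * noise
  }
  structure(pos, criterion = criterion, k = if (criterion == "intensity") k
            else NA_real_)
}

#' Percent marker-positive vesicles per cell
#'
#' For each cell, `100 * positive / total` over its vesicles. Cells with no
#' vesicles get `NA` and are flagged `excluded` (they are reported, never
#' silently dropped); `cell_ids` forces rows for cells with zero vesicles.
#'
#' @param vesicles vesicle records with a `cell_id` column.
#' @param positive logical vector aligned with `vesicles` (from
#'   [vesicle_is_positive()] or a planted truth column).
#' @param cell_ids optional vector of all cell ids to report.
#' @return data.frame: `cell_id`, `n_vesicles`, `n_positive`,
#'   `percent_positive`, `excluded`.
#' @export
percent_positive_vesicles <- function(vesicles, positive, cell_ids = NULL) {
  stopifnot(length(positive) == nrow(vesicles))
  ids <- sort(unique(c(vesicles$cell_id, cell_ids)))
  n_tot <- tabulate(match(vesicles$cell_id, ids), nbins = length(ids))
  n_pos <- tabulate(match(vesicles$cell_id[positive], ids),
                    nbins = length(ids))
  data.frame(
    cell_id = ids,
    n_vesicles = n_tot,
    n_positive = n_pos,
    percent_positive = ifelse(n_tot > 0, 100 * n_pos / n_tot, NA_real_),
    excluded = n_tot == 0
  )
}

#' Per-cell Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two channels' pixel intensities over a
#' cell region, either over all cell pixels (`whole_cell`) or only pixels
#' above the per-channel median of the region (`above_background`, pixels
#' above background in either channel). A constant channel gives an
#' explicit undefined result (`pcc = NA`, `defined = FALSE`), never a
#' silent 0.
#'
#' @param field an [image_field()].
#' @param role_a,role_b channel roles.
#' @param cell_mask logical matrix selecting the cell's pixels.
#' @param mode `"whole_cell"` or `"above_background"`.
#' @return one-row data.frame: `pcc`, `n_pixels`, `defined`, `mode`.
#' @export
pearson_per_cell <- function(field, role_a, role_b, cell_mask,
                             mode = c("whole_cell", "above_background")) {
  mode <- match.arg(mode)
  a <- field$channels[[role_a]]
  b <- field$channels[[role_b]]
  if (is.null(a) || is.null(b)) stop_config("both channel roles must exist")
  av <- a[cell_mask]
  bv <- b[cell_mask]
  if (mode == "above_background") {
    keep <- av > median(av) | bv > median(bv)
    av <- av[keep]
    bv <- bv[keep]
  }
  if (length(av) < 2 || sd(av) == 0 || sd(bv) == 0) {
    return(data.frame(pcc = NA_real_, n_pixels = length(av),
                      defined = FALSE, mode = mode))
  }
  data.frame(pcc = stats::cor(av, bv), n_pixels = length(av),
             defined = TRUE, mode = mode)
}

#' Pearson colocalization for every cell of a partition
#'
#' @param field an [image_field()].
#' @param role_a,role_b channel roles.
#' @param cells cell `label_map` from [partition_cells()].
#' @param mode see [pearson_per_cell()].
#' @return data.frame with one row per cell.
#' @export
pearson_all_cells <- function(field, role_a, role_b, cells,
                              mode = c("whole_cell", "above_background")) {
  mode <- match.arg(mode)
  n <- max(cells$labels)
  do.call(rbind, lapply(seq_len(n), function(ci) {
    res <- pearson_per_cell(field, role_a, role_b, cells$labels == ci, mode)
    cbind(cell_id = ci, res)
  }))
}

#' Classify cells by puncta count and summarize the population
#'
#' A cell is positive iff its count strictly exceeds `threshold` (the
#' "more than three puncta" rule); the population readout is
#' `100 * positive cells / classified cells`.
#'
#' @param counts integer vector of per-cell puncta counts.
#' @param threshold strict count threshold (default 3).
#' @return list: `positive` (logical per cell), `percent_positive_cells`,
#'   `n_cells`, `threshold`.
#' @export
count_and_classify_puncta <- function(counts, threshold = 3) {
  if (threshold < 0) stop_config("threshold must be >= 0")
  counts <- counts[!is.na(counts)]
  positive <- counts > threshold
  list(
    positive = positive,
    percent_positive_cells = if (length(counts) == 0) NA_real_ else
      100 * mean(positive),
    n_cells = length(counts),
    threshold = threshold
  )
}

#' Cytoplasmic / nuclear intensity ratio
#'
#' Ratio of the background-corrected cytoplasmic mean to the
#' background-corrected nuclear mean of a channel (the translocation
#' readout: the ratio drops when the protein moves into the nucleus).
#' Undefined (`NA`) when the corrected nuclear mean is not positive.
#'
#' @param cells data.frame from [cell_records()].
#' @param role channel role.
#' @param background scalar background to subtract from both means.
#' @return numeric vector of ratios, one per cell.
#' @export
nuclear_cytoplasmic_ratio <- function(cells, role, background = 0) {
  nuc_col <- paste0("nuclear_", role)
  cyt_col <- paste0("cytoplasm_", role)
  if (!all(c(nuc_col, cyt_col) %in% names(cells))) {
    stop_config("cells lack measured columns for role %s", role)
  }
  nuc <- cells[[nuc_col]] - background
  cyt <- cells[[cyt_col]] - background
  if (any(is.na(nuc)) || any(is.na(cyt))) {
    stop_config("empty nucleus or cytoplasm region in cell records")
  }
  ifelse(nuc > 0, cyt / nuc, NA_real_)
}

#' Normalize condition values to a reference condition
#'
#' Two modes mirroring the two normalizations used for damage readouts:
#' `fold_increase` divides by the reference mean (untreated control = 1);
#' `percent_of_control` scales so the reference mean is 100 (treated
#' control = 100%).
#'
#' @param values numeric vector to normalize.
#' @param reference numeric vector of reference-condition values.
#' @param mode `"fold_increase"` or `"percent_of_control"`.
#' @return normalized values with attribute `mode`.
#' @export
fold_change_normalize <- function(values, reference,
                                  mode = c("fold_increase",
                                           "percent_of_control")) {
  mode <- match.arg(mode)
  ref <- mean(reference, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) {
    stop_config("reference mean must be > 0 (got %s)", format(ref))
  }
  out <- if (mode == "fold_increase") values / ref else 100 * values / ref
  structure(out, mode = mode)
}
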