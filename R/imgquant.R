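# Image quantification: nucleus segmentation (Otsu + distance-transform
# watershed), nucleus-seeded Voronoi cell partition, multi-scale
# Laplacian-of-Gaussian puncta detection with a threshold in robust-noise
# units, and per-object intensity measurement with per-cell background
# correction. Coordinates are 0-based (row, col); areas are in pixels.

label_map <- function(labels, kind, channel_role = NA_character_) {
  structure(list(labels = labels, kind = kind, channel_role = channel_role),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> kind=%s, %d objects, %dx%d px\n", x$kind,
              max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Segment nuclei from the nucleus channel
#'
#' Otsu-initialized global threshold on a lightly blurred nucleus channel;
#' touching nuclei are split by watershed on the negated Euclidean distance
#' transform seeded at distance-transform maxima; objects below `min_area`
#' are removed. A field whose Otsu threshold does not clear the background
#' by `blank_guard` robust-noise units is declared empty.
#'
#' @param field an [image_field()] with a `nucleus` channel.
#' @param min_area minimum object area in pixels.
#' @param blur_sigma pre-threshold Gaussian sigma in pixels.
#' @param split_touching if `TRUE`, watershed-split merged nuclei.
#' @param seed_min_distance minimum separation (px) between watershed seeds.
#' @param blank_guard robust-noise multiples the threshold must exceed the
#'   image median by; guards against segmenting pure noise.
#' @return a `label_map` of kind `nucleus`; labels are assigned in raster
#'   order of each object's first pixel (deterministic).
#' @export
segment_nuclei <- function(field, min_area = 40, blur_sigma = 1,
                           split_touching = TRUE, seed_min_distance = 8,
                           blank_guard = 5) {
  stopifnot(inherits(field, "image_field"))
  img <- field$channels$nucleus
  if (is.null(img)) stop_config("field has no nucleus channel")
  sm <- gaussian_blur(img, blur_sigma)
  thr <- otsu_threshold(sm)
  noise <- robust_scale(as.vector(sm))
  # noise == 0 means a perfectly flat background (noise-free render): any
  # structure the threshold finds is then real and the guard is skipped
  blank <- if (noise > 0) thr <= median(sm) + blank_guard * noise else
    diff(range(sm)) == 0
  if (blank) {
    return(label_map(matrix(0L, nrow(img), ncol(img)), "nucleus"))
  }
  mask <- sm > thr
  if (split_touching) {
    dt <- distance_transform(mask)
    peaks <- local_maxima(dt, mask = mask & dt > 1,
                          min_distance = seed_min_distance)
    markers <- matrix(0L, nrow(img), ncol(img))
    if (nrow(peaks) > 0) {
      ord <- order(peaks$row, peaks$col)  # raster order => deterministic labels
      markers[cbind(peaks$row[ord] + 1, peaks$col[ord] + 1)] <-
        seq_len(nrow(peaks))
    }
    lab <- .watershed_markers(-dt, markers, mask)
  } else {
    lab <- label_components(mask)
  }
  lab <- drop_small_and_relabel(lab, min_area)
  label_map(lab, "nucleus")
}

# Remove labels below min_area and relabel 1..n in raster order of each
# surviving object's first pixel.
drop_small_and_relabel <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  first_pix <- vapply(keep, function(l) which(lab == l)[1], numeric(1))
  keep <- keep[order(first_pix)]
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

# 0-based centroids of a label matrix; rows ordered by label.
label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(
    label = seq_len(n),
    row = as.numeric(tapply(idx[, 1] - 1, l, mean)[as.character(seq_len(n))]),
    col = as.numeric(tapply(idx[, 2] - 1, l, mean)[as.character(seq_len(n))]),
    area = tabulate(l, nbins = n)
  )
}

#' Partition the field into cells around segmented nuclei
#'
#' Every pixel is assigned to the cell of the nearest nucleus centroid
#' (Euclidean; ties go to the lowest label), so cell count equals nucleus
#' count and cell label `i` contains nucleus `i`. With zero nuclei the map
#' is empty.
#'
#' @param nuclei nucleus `label_map` from [segment_nuclei()].
#' @param field the [image_field()] (defines the partition extent).
#' @return a `label_map` of kind `cell`.
#' @export
partition_cells <- function(nuclei, field) {
  stopifnot(inherits(nuclei, "label_map"), nuclei$kind == "nucleus")
  shape <- dim(field$channels[[1]])
  cen <- label_centroids(nuclei$labels)
  if (nrow(cen) == 0) {
    return(label_map(matrix(0L, shape[1], shape[2]), "cell"))
  }
  lab <- .nearest_seed(matrix(TRUE, shape[1], shape[2]), cen$row, cen$col)
  label_map(lab, "cell")
}

#' Detect diffraction-limited puncta with a multi-scale LoG filter
#'
#' Scale-normalized Laplacian-of-Gaussian responses are computed over
#' `scales_px`, maximized pixelwise, and local maxima exceeding
#' `threshold_k` robust-noise units (median absolute deviation of the
#' response) are reported as puncta. Each punctum gets the radius
#' `sqrt(2) * scale` of its best-responding scale; its mask is the disk of
#' that radius.
#'
#' @param field an [image_field()].
#' @param role channel role to detect in.
#' @param cells optional cell `label_map`; puncta outside any cell are
#'   discarded when `discard_outside_cells` (here "outside" means cell
#'   label 0, which only occurs for an empty partition).
#' @param scales_px Gaussian sigmas (pixels) of the LoG band; match
#'   `vesicle_radius / sqrt(2)`.
#' @param threshold_k detection threshold in robust-noise units.
#' @param min_area,max_area area gates in pixels on the reported disk.
#' @param min_distance minimum separation between detections in pixels.
#' @param discard_outside_cells drop puncta not assigned to a cell.
#' @return data.frame of vesicle records: `vesicle_id`, `cell_id`,
#'   `channel_role`, `row`, `col` (0-based integer centroid), `radius_px`,
#'   `area_px`, `response`.
#' @export
detect_puncta <- function(field, role, cells = NULL,
                          scales_px = c(1.0, 1.5, 2.0, 2.5),
                          threshold_k = 8, min_area = 3, max_area = Inf,
                          min_distance = 3, discard_outside_cells = TRUE) {
  stopifnot(inherits(field, "image_field"))
  img <- field$channels[[role]]
  if (is.null(img)) stop_config("field has no channel with role '%s'", role)
  if (length(scales_px) == 0) stop_config("empty scale band")
  nr <- nrow(img)
  nc <- ncol(img)
  best <- matrix(-Inf, nr, nc)
  best_s <- matrix(scales_px[1], nr, nc)
  for (s in scales_px) {
    g <- gaussian_blur(img, s)
    lap <- matrix(0, nr, nc)
    lap[2:(nr - 1), 2:(nc - 1)] <-
      g[1:(nr - 2), 2:(nc - 1)] + g[3:nr, 2:(nc - 1)] +
      g[2:(nr - 1), 1:(nc - 2)] + g[2:(nr - 1), 3:nc] -
      4 * g[2:(nr - 1), 2:(nc - 1)]
    resp <- -s^2 * lap  # bright blobs give positive response
    upd <- resp > best
    best[upd] <- resp[upd]
    best_s[upd] <- s
  }
  noise <- robust_scale(as.vector(best))
  if (noise == 0) noise <- sd(as.vector(best))
  if (noise == 0) {
    return(empty_vesicles(role))
  }
  peaks <- local_maxima(best, mask = best > threshold_k * noise,
                        min_distance = min_distance)
  if (nrow(peaks) == 0) return(empty_vesicles(role))
  s_at <- best_s[cbind(peaks$row + 1, peaks$col + 1)]
  radius <- sqrt(2) * s_at
  area <- pmax(1, round(pi * radius^2))
  keep <- area >= min_area & area <= max_area
  peaks <- peaks[keep, , drop = FALSE]
  radius <- radius[keep]
  area <- area[keep]
  if (nrow(peaks) == 0) return(empty_vesicles(role))
  cell_id <- if (!is.null(cells)) {
    cells$labels[cbind(peaks$row + 1, peaks$col + 1)]
  } else {
    rep(NA_integer_, nrow(peaks))
  }
  out <- data.frame(
    vesicle_id = seq_len(nrow(peaks)),
    cell_id = cell_id,
    channel_role = role,
    row = peaks$row, col = peaks$col,
    radius_px = radius, area_px = area,
    response = peaks$value
  )
  if (discard_outside_cells && !is.null(cells)) {
    out <- out[out$cell_id > 0, , drop = FALSE]
    out$vesicle_id <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}

empty_vesicles <- function(role) {
  data.frame(vesicle_id = integer(0), cell_id = integer(0),
             channel_role = character(0), row = numeric(0), col = numeric(0),
             radius_px = numeric(0), area_px = numeric(0),
             response = numeric(0))
}

# Linear indices of the disk of `radius` around 0-based (row, col).
disk_indices <- function(shape, row, col, radius) {
  r0 <- max(0, floor(row - radius))
  r1 <- min(shape[1] - 1, ceiling(row + radius))
  c0 <- max(0, floor(col - radius))
  c1 <- min(shape[2] - 1, ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1
  cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  if (nrow(inside) == 0) return(integer(0))
  (cc[inside[, 2]]) * shape[1] + rr[inside[, 1]] + 1
}

#' Measure per-channel intensities for detected objects
#'
#' For every vesicle record, the mean intensity over its disk mask is
#' computed per channel, and a background-corrected mean (floored at 0) is
#' derived by subtracting the per-cell background: the median intensity of
#' the cell's pixels that belong to no measured object. Without a cell map
#' the global non-object median is used.
#'
#' @param objects vesicle records from [detect_puncta()] (possibly several
#'   roles row-bound).
#' @param field the [image_field()].
#' @param cells optional cell `label_map` for per-cell backgrounds.
#' @return `objects` with `mean_<role>` and `corrected_<role>` columns.
#' @export
measure_objects <- function(objects, field, cells = NULL) {
  stopifnot(inherits(field, "image_field"))
  shape <- dim(field$channels[[1]])
  if (nrow(objects) == 0) {
    for (role in names(field$channels)) {
      objects[[paste0("mean_", role)]] <- numeric(0)
      objects[[paste0("corrected_", role)]] <- numeric(0)
    }
    return(objects)
  }
  masks <- lapply(seq_len(nrow(objects)), function(i) {
    disk_indices(shape, objects$row[i], objects$col[i], objects$radius_px[i])
  })
  if (any(lengths(masks) == 0)) {
    stop_config("object %d has an empty mask",
                which(lengths(masks) == 0)[1])
  }
  obj_mask <- logical(prod(shape))
  obj_mask[unlist(masks)] <- TRUE
  for (role in names(field$channels)) {
    ch <- field$channels[[role]]
    means <- vapply(masks, function(ix) mean(ch[ix]), numeric(1))
    if (!is.null(cells)) {
      bg_of_cell <- vapply(sort(unique(objects$cell_id)), function(ci) {
        pix <- cells$labels == ci & !matrix(obj_mask, shape[1], shape[2])
        if (!any(pix)) median(ch[!obj_mask]) else median(ch[pix])
      }, numeric(1))
      names(bg_of_cell) <- sort(unique(objects$cell_id))
      bg <- bg_of_cell[as.character(objects$cell_id)]
    } else {
      bg <- rep(median(ch[!obj_mask]), nrow(objects))
    }
    objects[[paste0("mean_", role)]] <- means
    objects[[paste0("corrected_", role)]] <- pmax(0, means - bg)
  }
  objects
}

#' Build per-cell records
#'
#' One row per cell with nuclear and cytoplasmic (cell minus nucleus) mean
#' intensities for every channel and an edge flag (`TRUE` when the cell's
#' nucleus touches the field border within `edge_margin` pixels); edge cells
#' are conventionally excluded from per-cell statistics.
#'
#' @param nuclei nucleus `label_map`.
#' @param cells cell `label_map` from [partition_cells()].
#' @param field the [image_field()].
#' @param edge_margin border width in pixels for the edge flag.
#' @return data.frame of cell records.
#' @export
cell_records <- function(nuclei, cells, field, edge_margin = 2) {
  stopifnot(inherits(nuclei, "label_map"), inherits(cells, "label_map"))
  n <- max(cells$labels)
  roles <- names(field$channels)
  if (n == 0) {
    out <- data.frame(cell_id = integer(0), edge = logical(0))
    for (role in roles) {
      out[[paste0("nuclear_", role)]] <- numeric(0)
      out[[paste0("cytoplasm_", role)]] <- numeric(0)
    }
    return(out)
  }
  shape <- dim(field$channels[[1]])
  out <- data.frame(cell_id = seq_len(n))
  nuc_idx <- which(nuclei$labels > 0, arr.ind = TRUE)
  nuc_lab <- nuclei$labels[nuclei$labels > 0]
  edge <- vapply(seq_len(n), function(ci) {
    pix <- nuc_idx[nuc_lab == ci, , drop = FALSE]
    nrow(pix) == 0 ||
      any(pix[, 1] <= edge_margin | pix[, 1] > shape[1] - edge_margin |
            pix[, 2] <= edge_margin | pix[, 2] > shape[2] - edge_margin)
  }, logical(1))
  out$edge <- edge
  for (role in roles) {
    ch <- field$channels[[role]]
    out[[paste0("nuclear_", role)]] <- vapply(seq_len(n), function(ci) {
      m <- nuclei$labels == ci
      if (!any(m)) NA_real_ else mean(ch[m])
    }, numeric(1))
    out[[paste0("cytoplasm_", role)]] <- vapply(seq_len(n), function(ci) {
      m <- cells$labels == ci & nuclei$labels != ci
      if (!any(m)) NA_real_ else mean(ch[m])
    }, numeric(1))
  }
  out
}
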