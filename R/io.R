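# Containers and file formats. Images travel as multi-page 16-bit TIFF with
# a JSON sidecar giving channel roles and pixel size; tables as CSV/TSV;
# ground truth and provenance as JSON; configuration as YAML.
#
# The TIFF codec below implements the uncompressed baseline subset
# (little-endian, grayscale, 8/16-bit, strip layout) because no TIFF reader
# ships with this R stack; it is deliberately minimal and round-trip tested.

#' Multi-channel image field
#'
#' @param channels named list of numeric matrices (one per channel role);
#'   all must share one shape. Canonical roles are `nucleus`, `lysosome`,
#'   `ubiquitin_FK2`, `ubiquitin_K48`, `ubiquitin_K63`, `gal3`, `poi`;
#'   additional marker roles are allowed.
#' @param pixel_size micrometers per pixel.
#' @param bit_depth sensor bit depth.
#' @return object of class `image_field`.
#' @export
image_field <- function(channels, pixel_size, bit_depth = 16L) {
  if (length(channels) == 0 || is.null(names(channels))) {
    stop_config("channels must be a non-empty named list")
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop_config("all channels must share one shape")
  if (pixel_size <= 0) stop_config("pixel_size must be > 0")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop_config("channel intensities must be >= 0")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_field> %dx%d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ---- minimal baseline TIFF ------------------------------------------------

u16 <- function(v) {
  v <- as.integer(round(v))
  ifelse(v >= 32768L, v - 65536L, v)
}

#' Write matrices as an uncompressed multi-page TIFF
#'
#' One grayscale page per matrix, 16-bit (or 8-bit) little-endian, single
#' strip per page. Values are rounded and clipped to the sample range.
#'
#' @param pages list of numeric matrices (or a single matrix).
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @export
write_tiff <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(u16(42L), con, size = 2, endian = "little")
  # first IFD comes right after the first page's pixel data
  offset <- 8L
  n_pages <- length(pages)
  writeBin(as.integer(offset + pixel_bytes(pages[[1]], bits)), con,
           size = 4, endian = "little")
  for (p in seq_len(n_pages)) {
    img <- pages[[p]]
    vmax <- 2^bits - 1
    v <- pmin(vmax, pmax(0, round(as.vector(t(img)))))  # row-major
    if (bits == 16L) {
      writeBin(u16(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.raw(v), con)
    }
    data_start <- offset
    ifd_start <- data_start + pixel_bytes(img, bits)
    entries <- list(
      c(256L, 3L, 1L, ncol(img)),            # ImageWidth
      c(257L, 3L, 1L, nrow(img)),            # ImageLength
      c(258L, 3L, 1L, bits),                 # BitsPerSample
      c(259L, 3L, 1L, 1L),                   # Compression: none
      c(262L, 3L, 1L, 1L),                   # Photometric: BlackIsZero
      c(273L, 4L, 1L, data_start),           # StripOffsets
      c(277L, 3L, 1L, 1L),                   # SamplesPerPixel
      c(278L, 3L, 1L, nrow(img)),            # RowsPerStrip
      c(279L, 4L, 1L, pixel_bytes(img, bits)),  # StripByteCounts
      c(339L, 3L, 1L, 1L)                    # SampleFormat: unsigned
    )
    writeBin(u16(length(entries)), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(u16(e[1]), con, size = 2, endian = "little")
      writeBin(u16(e[2]), con, size = 2, endian = "little")
      writeBin(as.integer(e[3]), con, size = 4, endian = "little")
      if (e[2] == 3L) {  # SHORT padded to 4 bytes
        writeBin(u16(e[4]), con, size = 2, endian = "little")
        writeBin(u16(0L), con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[4]), con, size = 4, endian = "little")
      }
    }
    ifd_end <- ifd_start + 2L + 12L * length(entries) + 4L
    if (p < n_pages) {
      next_ifd <- ifd_end + pixel_bytes(pages[[p + 1]], bits)
      writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
      offset <- ifd_end
    } else {
      writeBin(0L, con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

pixel_bytes <- function(img, bits) as.integer(length(img) * bits / 8)

#' Read an uncompressed baseline TIFF
#'
#' Supports what [write_tiff()] emits plus multi-strip layouts: grayscale,
#' 8/16-bit unsigned, little- or big-endian, no compression.
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  rd <- function(at, size, endian) {
    # unsigned reads for the 2-byte fields; 4-byte offsets stay < 2^31 here
    readBin(raw_all[(at + 1):(at + size)], "integer", size = size,
            endian = endian, signed = size == 4L)
  }
  magic <- rawToChar(raw_all[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop_config("not a TIFF file: %s", path)
  if (rd(2, 2, endian) != 42L) stop_config("bad TIFF magic in %s", path)
  ifd <- readBin(raw_all[5:8], "integer", size = 4, endian = endian)
  pages <- list()
  while (ifd != 0) {
    n_entries <- rd(ifd, 2, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      base <- ifd + 2 + (i - 1) * 12
      tag <- rd(base, 2, endian)
      type <- rd(base + 2, 2, endian)
      count <- rd(base + 4, 4, endian)
      val <- if (type == 3L && count == 1L) {
        rd(base + 8, 2, endian)
      } else if (type %in% c(3L, 4L) && count > 1L) {
        off <- rd(base + 8, 4, endian)
        sz <- if (type == 3L) 2L else 4L
        vapply(seq_len(count) - 1L,
               function(k) rd(off + k * sz, sz, endian), integer(1))
      } else {
        rd(base + 8, 4, endian)
      }
      tags[[as.character(tag)]] <- val
    }
    get_tag <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- get_tag(256); h <- get_tag(257)
    bits <- get_tag(258, 1L)
    if (get_tag(259, 1L) != 1L) stop_config("compressed TIFF not supported")
    offs <- get_tag(273); counts <- get_tag(279)
    rows_per_strip <- get_tag(278, h)
    if (!bits %in% c(8L, 16L)) stop_config("unsupported bit depth %d", bits)
    vals <- integer(0)
    for (s in seq_along(offs)) {
      nbytes <- counts[s]
      chunk <- raw_all[(offs[s] + 1):(offs[s] + nbytes)]
      v <- if (bits == 16L) {
        readBin(chunk, "integer", n = nbytes / 2, size = 2,
                endian = endian, signed = FALSE)
      } else {
        as.integer(chunk)
      }
      vals <- c(vals, v)
    }
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- rd(ifd + 2 + n_entries * 12, 4, endian)
  }
  pages
}

# ---- field + sidecar ------------------------------------------------------

#' Write an image field as TIFF + JSON sidecar
#'
#' The sidecar (same path with `.json` appended) records channel roles in
#' page order, the pixel size and bit depth.
#'
#' @param field an [image_field()].
#' @param path TIFF output path.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  write_tiff(unname(field$channels), path, bits = 16L)
  sidecar <- list(channels = names(field$channels),
                  pixel_size = field$pixel_size,
                  bit_depth = field$bit_depth)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image field written by [write_field()]
#'
#' Also accepts a plain TIFF plus an explicit channel map (YAML file with
#' `channels`, `pixel_size`).
#'
#' @param path TIFF path.
#' @param channel_map optional YAML path replacing the JSON sidecar.
#' @return an [image_field()].
#' @export
read_field <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  meta <- if (!is.null(channel_map)) {
    yaml::read_yaml(channel_map)
  } else {
    sc <- paste0(path, ".json")
    if (!file.exists(sc)) stop_config("missing sidecar %s", sc)
    jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  pages <- read_tiff(path)
  if (length(pages) != length(meta$channels)) {
    stop_config("channel map lists %d roles but TIFF has %d pages",
                length(meta$channels), length(pages))
  }
  image_field(setNames(pages, meta$channels),
              pixel_size = meta$pixel_size,
              bit_depth = meta$bit_depth %||% 16L)
}

# ---- tables and truth -----------------------------------------------------

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_config("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Write / read object tables (one row per detected object)
#'
#' @param objects data.frame with at least `vesicle_id`, `cell_id`, `row`,
#'   `col`, `area_px`.
#' @param path CSV path.
#' @export
write_objects_csv <- function(objects, path) {
  check_columns(objects, c("vesicle_id", "cell_id", "row", "col", "area_px"),
                "objects table")
  write.csv(objects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_objects_csv
#' @export
read_objects_csv <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  df <- read.csv(path)
  check_columns(df, c("vesicle_id", "cell_id", "row", "col", "area_px"),
                sprintf("objects CSV %s", path))
  df
}

#' Write / read a plate design CSV
#'
#' Schema: `well_id`, `gene`, `reagent`, `treatment`, `replicate`.
#' @param design a [plate_design()] (or compatible data.frame).
#' @param path CSV path.
#' @export
write_design_csv <- function(design, path) {
  check_columns(design, c("well_id", "gene", "reagent", "treatment",
                          "replicate"), "plate design")
  write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  df <- read.csv(path)
  check_columns(df, c("well_id", "gene", "reagent", "treatment", "replicate"),
                sprintf("design CSV %s", path))
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  class(df) <- c("plate_design", "data.frame")
  df
}

#' Write / read ground truth as JSON
#'
#' Round-trips the per-well planted fractions and the gene-effects map.
#' @param truth list with `wells`, `gene_effects`, `true_hits`.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  if (!is.null(truth$gene_effects)) {
    truth$gene_effects <- as.list(truth$gene_effects)  # keep names in JSON
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$wells)) x$wells <- as.data.frame(x$wells)
  if (!is.null(x$gene_effects)) x$gene_effects <- unlist(x$gene_effects)
  x
}

#' Read a SILAC protein-quantification table (CSV/TSV)
#'
#' Expects `protein_id`, flag columns (`contaminant`, `reverse`,
#' `site_only`) and per-replicate `heavy_k` / `light_k` intensity columns;
#' a YAML column map may rename them.
#'
#' @param path CSV or TSV file (by extension).
#' @param column_map optional YAML path with `rename: {from: to, ...}`.
#' @return data.frame.
#' @export
read_quant_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep)
  if (!is.null(column_map)) {
    cm <- yaml::read_yaml(column_map)
    for (from in names(cm$rename %||% list())) {
      names(df)[names(df) == from] <- cm$rename[[from]]
    }
  }
  check_columns(df, c("protein_id", "contaminant", "reverse", "site_only"),
                sprintf("quant table %s", path))
  if (!any(grepl("^heavy_", names(df)))) {
    stop_config("quant table %s has no heavy_<k> columns", path)
  }
  df
}
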