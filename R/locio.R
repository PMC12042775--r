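#' Localization table
#'
#' Container for single-molecule localizations: one row per detected spot
#' with its frame (1-based), coordinates (nm), localization uncertainty (nm)
#' and optional intensity (photons). Invalid rows (non-finite coordinates,
#' frame < 1, uncertainty <= 0) are rejected at construction and tallied in
#' the `validation` attribute; nothing is dropped silently.
#'
#' @param records data.frame with columns `frame`, `x`, `y`, `uncertainty`
#'   and optionally `intensity`.
#' @param meta List of metadata: `frame_rate` (frames/s), `field` (nm pair),
#'   `source` label.
#' @return Object of class `loc_table`: list with `records` and `meta`.
#' @export
loc_table <- function(records = data.frame(frame = integer(), x = numeric(),
                                           y = numeric(),
                                           uncertainty = numeric(),
                                           intensity = numeric()),
                      meta = list()) {
  required <- c("frame", "x", "y", "uncertainty")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop_format("missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (is.null(records$intensity)) records$intensity <- rep(NA_real_, nrow(records))
  records <- records[c("frame", "x", "y", "uncertainty", "intensity")]
  ok <- is.finite(records$x) & is.finite(records$y) &
    is.finite(records$frame) & records$frame >= 1 &
    is.finite(records$uncertainty) & records$uncertainty > 0
  rejected <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  rownames(records) <- NULL
  records$frame <- as.integer(records$frame)
  structure(list(records = records, meta = meta),
            validation = list(n_rejected = rejected, n_kept = nrow(records)),
            class = "loc_table")
}

#' @export
print.loc_table <- function(x, ...) {
  v <- attr(x, "validation")
  cat(sprintf("loc_table: %d localization(s)", nrow(x$records)))
  if (nrow(x$records) > 0L)
    cat(sprintf(", frames %d-%d", min(x$records$frame), max(x$records$frame)))
  if (!is.null(v) && v$n_rejected > 0L)
    cat(sprintf(" (%d row(s) rejected on validation)", v$n_rejected))
  cat("\n")
  invisible(x)
}

## Normalize a CSV header name: drop quotes, bracketed units and case, so
## `"x [nm]"`, `x..nm.` and `X` all map to `x`.
normalize_header <- function(nm) {
  nm <- gsub('"', "", nm)
  nm <- sub("\\s*\\[.*\\]\\s*$", "", nm)   # trailing [unit]
  nm <- sub("\\.\\..*$", "", nm)            # read.csv-mangled ..nm.
  tolower(trimws(gsub("\\.", " ", nm)))
}

#' Read a ThunderSTORM-style localization CSV
#'
#' Reads localization tables in the CSV dialect produced by the
#' ThunderSTORM ImageJ plugin. Column headers may carry bracketed units
#' (`"x [nm]"`); an `id` column is read and ignored if present. Rows failing
#' validation (non-finite coordinates, uncertainty <= 0, frame < 1) are
#' rejected and counted in the `validation` attribute.
#'
#' @param path CSV file path.
#' @param meta Optional metadata list stored in the table.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, meta = list()) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- normalize_header(names(df))
  required <- c("frame", "x", "y", "uncertainty")
  for (col in required) {
    if (!col %in% names(df)) stop_format("missing required column: %s", col)
  }
  if (nrow(df) == 0L) warning("empty localization file: ", path)
  tab <- loc_table(df[intersect(c(required, "intensity"), names(df))],
                   meta = meta)
  v <- attr(tab, "validation")
  if (v$n_rejected > 0L)
    message(sprintf("read_localizations: rejected %d invalid row(s)",
                    v$n_rejected))
  tab
}

fmt6 <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a localization table as ThunderSTORM-style CSV
#'
#' Header is exactly `frame,"x [nm]","y [nm]","uncertainty [nm]",
#' "intensity [photon]"`; numeric values at 6 significant digits.
#'
#' @param table A [loc_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "loc_table"))
  r <- table$records
  header <- 'frame,"x [nm]","y [nm]","uncertainty [nm]","intensity [photon]"'
  lines <- c(header,
             if (nrow(r) > 0L)
               paste(r$frame, fmt6(r$x), fmt6(r$y), fmt6(r$uncertainty),
                     fmt6(r$intensity), sep = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write track tables
#'
#' Track CSVs have columns `track_id`, `frame`, `x [nm]`, `y [nm]`,
#' `intensity`, sorted by (track_id, frame). Duplicate (track_id, frame)
#' pairs are a format error.
#'
#' @param path CSV file path.
#' @return `read_tracks`: data.frame with columns `track_id`, `frame`, `x`,
#'   `y`, `intensity`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- gsub(" ", "_", normalize_header(names(df)))
  for (col in c("track_id", "frame", "x", "y")) {
    if (!col %in% names(df)) stop_format("missing required column: %s", col)
  }
  if (is.null(df$intensity)) df$intensity <- NA_real_
  df <- df[c("track_id", "frame", "x", "y", "intensity")]
  if (anyDuplicated(df[c("track_id", "frame")]) > 0L)
    stop_format("duplicate (track_id, frame) pair(s)")
  df[order(df$track_id, df$frame), , drop = FALSE]
}

#' @rdname read_tracks
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `intensity`.
#' @export
write_tracks <- function(tracks, path) {
  for (col in c("track_id", "frame", "x", "y")) {
    if (!col %in% names(tracks)) stop_format("missing required column: %s", col)
  }
  if (anyDuplicated(tracks[c("track_id", "frame")]) > 0L)
    stop_format("duplicate (track_id, frame) pair(s)")
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  intensity <- if (is.null(tracks$intensity)) rep(NA_real_, nrow(tracks)) else tracks$intensity
  header <- 'track_id,frame,"x [nm]","y [nm]",intensity'
  lines <- c(header,
             if (nrow(tracks) > 0L)
               paste(tracks$track_id, tracks$frame, fmt6(tracks$x),
                     fmt6(tracks$y), fmt6(intensity), sep = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write rasters with a JSON sidecar
#'
#' Probability maps are written as 32-bit float TIFF, binary masks as 8-bit
#' TIFF with values {0, 255}. Pixel size and origin (nm) are semantically
#' required and live in a JSON sidecar (`<path>.json`); reading without the
#' sidecar is an error.
#'
#' @param raster A `prob_map` or `binary_mask` (or list of them for a
#'   multi-page stack).
#' @param path TIFF file path.
#' @return `read_raster`: the reconstructed object (list of objects for a
#'   multi-page file).
#' @export
write_raster <- function(raster, path) {
  single <- inherits(raster, c("prob_map", "binary_mask"))
  pages <- if (single) list(raster) else raster
  kind <- if (inherits(pages[[1]], "binary_mask")) "mask" else "prob_map"
  ## TIFF samples are stored scaled to [0, 1]; map values (tiny densities in
  ## nm^-2) are rescaled by a sidecar factor so 32-bit quantization error is
  ## negligible relative to the data.
  scale <- if (kind == "mask") 1 else max(1e-300, max(vapply(pages, function(p)
    max(p$values), numeric(1))))
  imgs <- lapply(pages, function(p) {
    m <- p$values / scale
    storage.mode(m) <- "double"
    m
  })
  if (kind == "mask") {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  }
  sidecar <- list(kind = kind,
                  pixel_nm = pages[[1]]$pixel,
                  origin_nm = as.numeric(pages[[1]]$origin),
                  n_pages = length(pages),
                  scale = scale,
                  threshold = if (kind == "mask") pages[[1]]$threshold else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop_format("sidecar missing: %s (pixel size is required)", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  out <- lapply(imgs, function(m) {
    attributes(m) <- list(dim = dim(m))
    if (sc$kind == "mask") {
      new_binary_mask(matrix(as.integer(round(m)), nrow(m), ncol(m)),
                      pixel = sc$pixel_nm, origin = sc$origin_nm,
                      threshold = if (is.null(sc$threshold)) NA_real_ else sc$threshold)
    } else {
      new_prob_map(m * sc$scale, pixel = sc$pixel_nm, origin = sc$origin_nm)
    }
  })
  if (length(out) == 1L) out[[1]] else out
}
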