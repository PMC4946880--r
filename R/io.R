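# Counts are stored as 16-bit TIFF; writeTIFF scales [0,1] by 2^16-1, so
# integer counts map to count/65535 on disk and back on read.
.counts_to_tiff <- function(counts3d, path) {
  if (any(counts3d > 65535))
    stop("counts exceed the 16-bit range", call. = FALSE)
  frames <- lapply(seq_len(dim(counts3d)[1]), function(f)
    matrix(counts3d[f, , ] / 65535, dim(counts3d)[2], dim(counts3d)[3]))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

.tiff_to_counts <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  out <- array(0L, dim = c(length(frames), d[1], d[2]))
  for (f in seq_along(frames))
    out[f, , ] <- as.integer(round(frames[[f]] * 65535))
  out
}

#' Write a raster or line-scan series to TIFF with a JSON sidecar
#'
#' Counts go to one 16-bit multi-frame TIFF per channel
#' (`<stem>_green.tif`, `<stem>_red.tif`, or `<stem>.tif` for one channel);
#' the acquisition metadata, seed and ground truth go to `<stem>.json`.
#'
#' @param series a `raster_series` or `line_scan_series`.
#' @param stem output path without extension.
#' @param seed the seed used to generate the series (recorded in the
#'   sidecar).
#' @return (invisibly) character vector of files written.
#' @export
write_scan <- function(series, stem, seed = NULL) {
  is_line <- inherits(series, "line_scan_series")
  counts <- series$counts
  as3d <- function(m) {
    if (is.matrix(m)) array(m, dim = c(1L, nrow(m), ncol(m))) else m
  }
  files <- character(0)
  if (is.list(counts)) {
    for (ch in names(counts)) {
      f <- paste0(stem, "_", ch, ".tif")
      .counts_to_tiff(as3d(if (is_line) t(counts[[ch]]) else counts[[ch]]),
                      f)
      files <- c(files, f)
    }
  } else {
    f <- paste0(stem, ".tif")
    .counts_to_tiff(as3d(if (is_line) t(counts) else counts), f)
    files <- c(files, f)
  }
  gt <- series$ground_truth
  side <- list(
    type = if (is_line) "line" else "raster",
    config = unclass(series$config),
    channels = series$channels,
    background_rate = series$background_rate,
    seed = seed,
    ground_truth = if (!is.null(gt)) list(
      species = lapply(gt$species, unclass),
      walls = gt$geometry$walls) else NULL)
  jf <- paste0(stem, ".json")
  jsonlite::write_json(side, jf, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(files, jf))
}

#' Load a raster or line scan from TIFF (+ optional sidecar)
#'
#' Reads photon counts from a 16-bit TIFF written by [write_scan()] (or any
#' TIFF of counts), merges acquisition metadata from the JSON sidecar and
#' then from explicit overrides (overrides win; conflicts are messaged).
#' Missing dwell/line-time metadata with no override is an error.
#'
#' @param path TIFF path (the sidecar is looked up by replacing the
#'   extension, or `_green`/`_red` suffixes, with `.json`).
#' @param config optional `scan_config` overriding the sidecar.
#' @param type `"auto"`, `"raster"` or `"line"`.
#' @return a `raster_series` or `line_scan_series`.
#' @export
load_scan <- function(path, config = NULL, type = "auto") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  counts <- tryCatch(.tiff_to_counts(path),
                     error = function(e) stop("unreadable TIFF '", path,
                                              "': ", conditionMessage(e),
                                              call. = FALSE))
  stem <- sub("(_green|_red)?\\.tiff?$", "", path)
  sidecar_path <- paste0(stem, ".json")
  side <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (type == "auto")
    type <- if (!is.null(side$type)) side$type else "raster"
  sc <- side$config
  if (!is.null(config)) {
    if (!is.null(sc)) {
      for (nm in names(unclass(config))) {
        if (!is.null(sc[[nm]]) &&
            !isTRUE(all.equal(sc[[nm]], config[[nm]])))
          message("sidecar/override conflict for '", nm, "': using override")
      }
    }
    cfg <- config
  } else if (!is.null(sc)) {
    cfg <- scan_config(pixel_size = sc$pixel_size,
                       pixel_dwell = sc$pixel_dwell,
                       line_time = sc$line_time,
                       frame_count = sc$frame_count,
                       image_size = sc$image_size,
                       line_length = sc$line_length,
                       n_lines = sc$n_lines)
  } else {
    stop("missing acquisition metadata (pixel_dwell, line_time): no ",
         "sidecar found and no config override given", call. = FALSE)
  }
  if (type == "line") {
    m <- t(matrix(counts[1, , ], dim(counts)[2], dim(counts)[3]))
    line_scan_series(m, cfg)
  } else {
    raster_series(counts, cfg)
  }
}

#' Save stage results as CSV/JSON files
#'
#' Writes each element of `results` into `dir`: data.frames and matrices as
#' CSV, everything else as JSON.  Files are prefixed with `prefix` and
#' stamped (in a `_manifest.json`) with the seed and a hash of the
#' configuration used.
#'
#' @param results named list of results.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default none).
#' @param seed,config recorded in the manifest.
#' @return (invisibly) the files written.
#' @export
save_results <- function(results, dir, prefix = "", seed = NULL,
                         config = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir))
      stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0)
    stop("output directory is not writable: ", dir, call. = FALSE)
  stopifnot(is.list(results))
  nm <- names(results)
  if (is.null(nm) || any(nm == ""))
    stop("results must be a fully named list", call. = FALSE)
  files <- character(0)
  for (n in nm) {
    x <- results[[n]]
    base <- file.path(dir, paste0(prefix, n))
    if (is.data.frame(x) || is.matrix(x)) {
      f <- paste0(base, ".csv")
      utils::write.csv(as.data.frame(x), f, row.names = FALSE)
    } else {
      f <- paste0(base, ".json")
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE, pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(files = basename(files), seed = seed,
                   config_hash = if (!is.null(config))
                     sum(utf8ToInt(paste(deparse(config), collapse = "")))
                   else NULL,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  mf <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(c(files, mf))
}
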