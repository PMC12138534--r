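# Readers and writers for the interchange formats: multi-page TIFF stacks
# with YAML sidecar metadata, PNG/TIFF ROI masks, deterministic CSV tables.

read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    # integer-sample TIFFs are normalized to [0, 1] by the reader; undo
    # that to recover raw camera counts. 32-bit pages are float samples
    # (the convention of write_stack_tiff) and are read verbatim.
    bits <- attr(p, "bits.per.sample") %||% 8
    if (bits < 32) p <- p * (2^bits - 1)
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of RGB pages
    as.matrix(p)
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

read_meta <- function(meta) {
  if (is.character(meta)) yaml::read_yaml(meta) else as.list(meta)
}

#' Read a raw speckle stack from multi-page TIFF plus metadata
#'
#' @param path multi-page TIFF file; page order is temporal order.
#' @param meta YAML file path or named list; must supply `exposure_T` (s)
#'   and `frame_rate` (Hz). A missing field is a named error. If the TIFF
#'   was written by [write_stack_tiff()] with a `scale` entry in the
#'   sidecar, intensities are rescaled back to their original units.
#' @return a [speckle_stack()].
#' @export
read_speckle_stack <- function(path, meta) {
  meta <- read_meta(meta)
  for (f in c("exposure_T", "frame_rate"))
    if (is.null(meta[[f]]))
      stop(sprintf("metadata field '%s' is missing", f), call. = FALSE)
  frames <- read_pages(path)
  if (!is.null(meta$scale)) frames <- frames * meta$scale
  speckle_stack(frames, exposure_T = meta$exposure_T,
                frame_rate = meta$frame_rate,
                metadata = meta[setdiff(names(meta),
                                        c("exposure_T", "frame_rate"))])
}

#' Read a confocal z-stack from multi-page TIFF plus metadata
#'
#' @param path multi-page TIFF; page order is z order.
#' @param meta YAML path or list supplying `voxel_um` as a named list/vector
#'   with entries `z`, `y`, `x` (micrometers).
#' @return a [confocal_stack()].
#' @export
read_confocal_stack <- function(path, meta) {
  meta <- read_meta(meta)
  if (is.null(meta$voxel_um))
    stop("metadata field 'voxel_um' is missing", call. = FALSE)
  v <- unlist(meta$voxel_um)
  vol <- read_pages(path)
  if (!is.null(meta$scale)) vol <- vol * meta$scale
  confocal_stack(vol, voxel_um = v[c("z", "y", "x")],
                 metadata = meta[setdiff(names(meta), "voxel_um")])
}

#' Read a binary ROI mask from PNG or TIFF
#'
#' Pixels with value > 0.5 (after the reader's own scaling) are foreground.
#'
#' @param path PNG or TIFF file.
#' @return logical matrix.
#' @export
read_roi_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write an image stack (or single map) as multi-page TIFF with sidecar
#'
#' The TIFF container stores samples in `[0, 1]`, so values are divided by
#' their maximum before writing and the scale factor is recorded in the
#' YAML sidecar (`<path>.yaml`), making the round trip lossless to 32-bit
#' float precision. Extra metadata fields are carried into the sidecar.
#'
#' @param x numeric matrix or 3-d array.
#' @param path output TIFF path.
#' @param meta named list written to the sidecar alongside `scale`.
#' @return invisibly, the sidecar path.
#' @export
write_stack_tiff <- function(x, path, meta = list()) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  mx <- max(x)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- paste0(path, ".yaml")
  yaml::write_yaml(c(meta, list(scale = scale, pages = dim(x)[3])), side)
  invisible(side)
}

#' Write a data frame as a deterministic CSV with an optional units row
#'
#' Numeric columns are formatted with the shortest round-trip decimal
#' representation, so identical inputs always produce byte-identical files
#' (the reproducibility contract for tabular outputs). If `units` is given,
#' a `# units:` comment line precedes the header.
#'
#' @param df data frame.
#' @param path output path.
#' @param units optional character vector of per-column units.
#' @return invisibly, `path`.
#' @export
write_table_csv <- function(df, path, units = NULL) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  con <- file(path, open = "wb")  # binary: fixed newlines across platforms
  on.exit(close(con))
  if (!is.null(units))
    writeLines(paste0("# units: ", paste(names(df), units, sep = "=",
                                         collapse = ", ")), con)
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Write a set of result objects with a resolved config and manifest
#'
#' Dispatches on object class: data frames become deterministic CSVs
#' ([write_table_csv()]), matrices/arrays and map-like objects
#' (`cbf_map`, contrast maps, masks) become scaled 32-bit TIFFs with YAML
#' sidecars ([write_stack_tiff()]). The fully resolved run configuration is
#' written as `config.yaml` (with package version and timestamp) and a
#' `manifest.csv` lists every written file with its MD5 checksum.
#'
#' @param results named list of objects.
#' @param out_dir output directory (created if needed).
#' @param config named list of run parameters to record.
#' @return the manifest data frame, invisibly.
#' @export
write_outputs <- function(results, out_dir, config = list()) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "cbf_map")) {
      f <- file.path(out_dir, paste0(nm, ".tif"))
      m <- x$cbf; m[!x$valid_mask] <- 0
      write_stack_tiff(m, f, meta = list(beta = x$beta,
                                         exposure_T = x$exposure_T,
                                         invalid_value = 0))
      files <- c(files, f, paste0(f, ".yaml"))
    } else if (inherits(x, "contrast_map")) {
      f <- file.path(out_dir, paste0(nm, ".tif"))
      m <- x$K; m[!x$valid_mask] <- 0
      write_stack_tiff(m, f, meta = list(n_frames_used = x$n_frames_used))
      files <- c(files, f, paste0(f, ".yaml"))
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write_table_csv(x, f, units = attr(x, "units"))
      files <- c(files, f)
    } else if (is.matrix(x) || is.array(x)) {
      f <- file.path(out_dir, paste0(nm, ".tif"))
      write_stack_tiff(x + 0, f)
      files <- c(files, f, paste0(f, ".yaml"))
    } else {
      f <- file.path(out_dir, paste0(nm, ".yaml"))
      yaml::write_yaml(x, f)
      files <- c(files, f)
    }
  }
  cfg <- c(config, list(
    tool = "speckleflow",
    version = as.character(utils::packageVersion("speckleflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files))
  write_table_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
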