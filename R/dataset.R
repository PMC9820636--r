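#' Labeled colony dataset
#'
#' An ordered collection of [colony_image()] objects with class counts that
#' are always recomputable from the item labels.
#'
#' @param items List of `colony_image` objects.
#' @param manifest_path Optional path of the manifest the dataset was read
#'   from (provenance only).
#' @return An object of class `colony_dataset`.
#' @export
colony_dataset <- function(items = list(), manifest_path = NULL) {
  stopifnot(is.list(items))
  for (it in items) stopifnot(inherits(it, "colony_image"))
  structure(list(items = items, manifest_path = manifest_path),
            class = "colony_dataset")
}

#' Labels of all items in a dataset
#' @param ds A `colony_dataset`.
#' @return Character vector of per-item labels.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$items, function(it) it$label, character(1))
}

#' Class counts of a dataset
#' @param ds A `colony_dataset`.
#' @return Named integer vector with elements `n_good` and `n_bad`.
#' @export
class_counts <- function(ds) {
  lab <- dataset_labels(ds)
  c(n_good = sum(lab == "good"), n_bad = sum(lab == "bad"))
}

#' @export
length.colony_dataset <- function(x) length(x$items)

#' @export
print.colony_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<colony_dataset> %d images (%d good, %d bad)\n",
              length(x$items), cc["n_good"], cc["n_bad"]))
  if (!is.null(x$manifest_path))
    cat("  manifest:", x$manifest_path, "\n")
  invisible(x)
}

#' Subset a dataset by item indices
#' @param ds A `colony_dataset`.
#' @param idx Integer indices into the item list.
#' @return A `colony_dataset` holding the selected items, in `idx` order.
#' @export
dataset_subset <- function(ds, idx) {
  colony_dataset(ds$items[idx], manifest_path = ds$manifest_path)
}

#' Write a dataset to disk as PNG images plus a label manifest
#'
#' Images are written as 8-bit grayscale (or RGB) PNG files named after
#' their `source_id`; labels go to `manifest.csv` (columns `path,label`)
#' with a JSON mirror `manifest.json` holding the same records plus class
#' counts. Reading the manifest back with [read_manifest()] reconstructs
#' identical labels and counts.
#'
#' @param ds A `colony_dataset`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the path of the CSV manifest.
#' @export
write_manifest <- function(ds, dir) {
  stopifnot(inherits(ds, "colony_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  n <- length(ds$items)
  paths <- character(n)
  labels <- character(n)
  for (i in seq_len(n)) {
    img <- ds$items[[i]]
    id <- if (nzchar(img$source_id)) img$source_id else sprintf("img_%05d", i)
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".png")
    px <- img$pixels
    if (identical(img$range, c(0, 255))) px <- px / 255
    px[px < 0] <- 0
    px[px > 1] <- 1
    png::writePNG(px, file.path(dir, fn))
    paths[i] <- fn
    labels[i] <- img$label
  }
  man <- data.frame(path = paths, label = labels,
                    stringsAsFactors = FALSE)
  csv <- file.path(dir, "manifest.csv")
  write.csv(man, csv, row.names = FALSE)
  cc <- class_counts(ds)
  jsonlite::write_json(
    list(items = man, n_good = unname(cc["n_good"]),
         n_bad = unname(cc["n_bad"])),
    file.path(dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE)
  invisible(csv)
}

#' Read a dataset back from a manifest
#'
#' Accepts the CSV manifest written by [write_manifest()] (columns
#' `path,label`, paths relative to the manifest's directory). Unknown label
#' strings are rejected with an error listing the offending rows.
#'
#' @param manifest Path to a `manifest.csv` file.
#' @param load_pixels If `FALSE`, items carry a 1x1 placeholder array and
#'   only labels/paths are materialized.
#' @return A `colony_dataset`.
#' @export
read_manifest <- function(manifest, load_pixels = TRUE) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(man)))
    stop("manifest must have columns `path` and `label`", call. = FALSE)
  bad <- which(!man$label %in% c("good", "bad", "unlabeled"))
  if (length(bad))
    stop("unknown label(s) in manifest rows: ",
         paste(bad, collapse = ", "), " (",
         paste(unique(man$label[bad]), collapse = ", "), ")", call. = FALSE)
  base <- dirname(manifest)
  items <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    if (load_pixels) {
      px <- read_image_file(file.path(base, man$path[i]))
    } else {
      px <- matrix(0, 1, 1)
    }
    items[[i]] <- colony_image(px, range = c(0, 1), label = man$label[i],
                               source_id = tools::file_path_sans_ext(
                                 basename(man$path[i])))
  }
  colony_dataset(items, manifest_path = manifest)
}

#' Read a PNG or TIFF image file into a plain pixel array in [0, 1]
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix or H x W x 3 array with values in `[0, 1]`;
#'   an alpha channel, if present, is dropped.
#' @export
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
    if (dim(px)[3] == 2L) px <- px[, , 1, drop = TRUE]
    if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1]
  }
  px
}
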