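# Plain-text/PNG interchange: image sets as per-class PNG directories with a
# manifest, feature matrices as TSV with a sidecar manifest, heatmaps as PNG.

#' Write an image set to a directory
#'
#' Writes PNGs into `<dir>/benign/` and `<dir>/malignant/`, lesion masks
#' into `<dir>/masks/`, and a `manifest.tsv` with columns sample_id, class,
#' path, seed.
#'
#' @param imageSet a [MammoImageSet-class].
#' @param dir output directory (created if missing).
#' @param writeMasks write lesion masks as PNGs (default TRUE).
#' @return the manifest data.frame, invisibly.
#' @export
writeImageSet <- function(imageSet, dir, writeMasks = TRUE) {
  for (d in file.path(dir, c("benign", "malignant", if (writeMasks) "masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  y <- imageLabels(imageSet)
  ids <- sprintf("s%04d", seq_len(nImages(imageSet)))
  paths <- file.path(as.character(y), paste0(ids, ".png"))
  for (i in seq_len(nImages(imageSet))) {
    im <- images(imageSet)[[i]]
    if (dim(im)[3] == 1L) im <- im[, , 1L]
    png::writePNG(im, file.path(dir, paths[i]))
    if (writeMasks && length(lesionMasks(imageSet)))
      png::writePNG(lesionMasks(imageSet)[[i]] * 1,
                    file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  manifest <- data.frame(sample_id = ids, class = as.character(y),
                         path = paths,
                         seed = imageSet@seed)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a directory-per-class image collection
#'
#' Reads PNGs from `<dir>/benign/` and `<dir>/malignant/` (any other layout
#' can be adapted by writing a `manifest.tsv`), optionally resizing to a
#' target geometry.
#'
#' @param dir directory with `benign/` and `malignant/` subdirectories of
#'   PNG files.
#' @param size optional `c(H, W)` to resize to (bilinear).
#' @return a [MammoImageSet-class] (seed `NA`, no lesion masks).
#' @export
readImageDirectory <- function(dir, size = NULL) {
  imgs <- list(); lab <- character(0)
  for (cl in c("benign", "malignant")) {
    files <- sort(list.files(file.path(dir, cl), pattern = "\\.png$",
                             full.names = TRUE))
    for (f in files) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 2L) dim(im) <- c(dim(im), 1L)
      if (dim(im)[3] > 3L) im <- im[, , 1:3, drop = FALSE]  # drop alpha
      if (!is.null(size) && !all(dim(im)[1:2] == size))
        im <- array(apply(im, 3, bilinearResize, H = size[1], W = size[2]),
                    dim = c(size[1], size[2], dim(im)[3]))
      imgs[[length(imgs) + 1L]] <- im
      lab <- c(lab, cl)
    }
  }
  stopIfNot(length(imgs) > 0L, "no PNG images found")
  new("MammoImageSet", images = imgs,
      labels = factor(lab, levels = c("benign", "malignant")),
      lesionMasks = list(), seed = NA_integer_,
      params = list(source = dir))
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has a `sample_id` first column followed by one column per
#' feature; a `<stem>_manifest.tsv` sidecar lists feature ids and their
#' column indices.
#'
#' @param F feature matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(F, path) {
  F <- asFeatureMatrix(F)
  df <- data.frame(sample_id = rownames(F), F, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "_manifest.tsv", path)
  write.table(data.frame(feature_id = colnames(F),
                         index = seq_len(ncol(F))),
              side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  F <- as.matrix(df[, -1, drop = FALSE])
  rownames(F) <- df[[1]]
  F
}

#' Write a Grad-CAM heatmap as PNG
#'
#' @param heatmap H x W matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHeatmapPNG <- function(heatmap, path) {
  png::writePNG(pmin(pmax(heatmap, 0), 1), path)
  invisible(path)
}
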