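## Reading ordered slice stacks and writing labeled volumes + object tables.
##
## Accepted inputs: a directory of lexicographically ordered PNG/TIFF
## files (one slice each) or a single multipage TIFF. PNGs are treated as
## 8-bit (values scaled back to 0..255 integers); TIFFs are read with
## their native integer values. Multichannel images use the first channel.
## Label 0 is background everywhere.

.readSliceFile <- function(f) {
  img <- tryCatch({
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      x <- png::readPNG(f)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      round(x * 255)
    } else {
      x <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      x
    }
  }, error = function(e) stop("cannot read slice file '", f, "': ",
                              conditionMessage(e)))
  storage.mode(img) <- "integer"
  img
}

#' Read an ordered slice stack from disk
#'
#' @param path directory of PNG/TIFF slice files (lexicographic order) or a
#'   single multipage TIFF.
#' @param voxelSize numeric(3) voxel edge lengths in nm.
#' @return a \linkS4class{SliceStack}.
#' @export
readStack <- function(path, voxelSize = c(2, 2, 50)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files))
      stop("no PNG/TIFF slice files found in '", path, "'")
    masks <- lapply(files, .readSliceFile)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    masks <- lapply(pages, function(x) {
      if (length(dim(x)) == 3L) x <- x[, , 1L]
      storage.mode(x) <- "integer"
      x
    })
  } else {
    stop("input path '", path, "' does not exist")
  }
  d <- vapply(masks, dim, integer(2))
  if (length(unique(d[1, ])) != 1L || length(unique(d[2, ])) != 1L)
    stop("slice dimension mismatch: found ",
         paste(unique(apply(d, 2, paste, collapse = "x")), collapse = ", "))
  SliceStack(masks, voxelSize)
}

## per-slice label images from a grouping
.labelVolume <- function(linked) {
  H <- linked@dim[1L]; W <- linked@dim[2L]
  vol <- lapply(seq_len(linked@nSlices), function(i) matrix(0L, H, W))
  segs <- linked@segments
  for (r in seq_len(nrow(segs))) {
    i <- segs$slice[r]
    vol[[i]][linked@pixels[[r]]] <- linked@labels[r]
  }
  vol
}

#' Write a labeled volume and per-object statistics to disk
#'
#' Writes one multipage TIFF in which every pixel carries the final 3D
#' label of its segment (0 = background), plus a sidecar CSV and JSON of
#' per-object records (label, segment count, voxel count, physical volume,
#' first/last slice). Labels up to 255 are stored as 8-bit, up to 65535 as
#' 16-bit; larger label values raise an error rather than being truncated.
#'
#' @param linked a \linkS4class{Linked3D}.
#' @param path output TIFF path; the sidecars replace the extension with
#'   \code{.csv} / \code{.json}.
#' @param voxelSize numeric(3) voxel edge lengths in nm.
#' @return invisibly, the object table data.frame.
#' @export
writeLabeledStack <- function(linked, path, voxelSize = c(2, 2, 50)) {
  vol <- .labelVolume(linked)
  maxLab <- if (length(linked@labels)) max(linked@labels) else 0L
  if (maxLab > 65535L)
    stop("labels exceed 16-bit capacity (max ", maxLab,
         "); compact labels before writing")
  bits <- if (maxLab > 255L) 16L else 8L
  denom <- 2^bits - 1
  tiff::writeTIFF(lapply(vol, function(m) m / denom), path,
                  bits.per.sample = bits, compression = "none")
  tab <- objectTable(linked, voxelSize)
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  utils::write.csv(tab, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(tab, paste0(base, ".json"), digits = NA)
  invisible(tab)
}

#' Write a stack as a multipage TIFF of raw mask values
#'
#' @param stack a \linkS4class{SliceStack} (values must fit 16 bits).
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path) {
  maxVal <- max(vapply(stack@masks, max, integer(1)), 0L)
  if (maxVal > 65535L) stop("mask values exceed 16-bit capacity")
  bits <- if (maxVal > 255L) 16L else 8L
  denom <- 2^bits - 1
  tiff::writeTIFF(lapply(stack@masks, function(m) m / denom), path,
                  bits.per.sample = bits, compression = "none")
  invisible(path)
}
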