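## Readers and writers for the artifact file formats: flat key-value text
## (configs, rigs), CSV tables (corners, spots, pairs, points, tracks) and
## multi-page 16-bit TIFF stacks/volumes.

#' Read a flat key-value text file
#'
#' Format: one \code{key value...} pair per line, keys may carry dotted
#' section prefixes; blank lines and lines starting with \code{#} ignored.
#' @param path file path.
#' @return named list of character values (unparsed).
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regexpr("\\s", ln)
    if (m < 0) stop("malformed key-value line: ", ln, call. = FALSE)
    key <- substr(ln, 1, m - 1)
    out[[key]] <- trimws(substr(ln, m + 1, nchar(ln)))
  }
  out
}

#' Write a flat key-value text file
#' @param kv named list; values are collapsed with spaces.
#' @param path output path.
#' @param header optional comment lines (written with a leading \code{#}).
#' @export
write_keyvalue <- function(kv, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  for (key in names(kv)) {
    v <- kv[[key]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    lines <- c(lines, paste(key, paste(v, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as CSV with a provenance header comment
#'
#' @param df data frame.
#' @param path output path.
#' @param header optional character vector of comment lines, written as
#'   \code{# ...} before the column header.
#' @export
write_table_csv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by \code{write_table_csv}
#' @param path file path.
#' @return data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a multi-page TIFF stack as an image stack
#'
#' Frames are the TIFF pages in order (time). 16-bit files are rescaled back
#' to integer counts.
#'
#' @param path TIFF path.
#' @param ... acquisition metadata passed to \code{\link{image_stack}}
#'   (frame_rate, exposure, transfer_gap, camera_id).
#' @return an \code{image_stack}.
#' @export
read_stack_tiff <- function(path, ...) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  image_stack(frames, ...)
}

#' Write an image stack (or any H x W x T array) as multi-page 16-bit TIFF
#' @param stack an \code{image_stack} or numeric array.
#' @param path output path.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  pages <- lapply(seq_len(dim(frames)[3]), function(i) {
    f <- pmin(pmax(frames[, , i], 0), 65535) / 65535
    f
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a voxel volume as multi-page TIFF (z pages) plus a sidecar header
#'
#' The sidecar (\code{<path>.txt}) records origin (mm), voxel size (um) and
#' dimensions so the volume can be re-associated with world coordinates.
#'
#' @param volume 3D array ordered (x, y, z).
#' @param grid the \code{voxel_grid} the volume was accumulated on.
#' @param path output TIFF path.
#' @export
write_volume_tiff <- function(volume, grid, path) {
  mx <- max(volume)
  scale <- if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(volume)[3]), function(k) {
    ## page = y rows, x cols
    t(volume[, , k]) * scale / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  write_keyvalue(list(origin_mm = grid$origin,
                      voxel_size_um = grid$voxel_size,
                      dims = grid$dims,
                      intensity_scale = 1 / scale),
                 paste0(path, ".txt"))
  invisible(path)
}
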