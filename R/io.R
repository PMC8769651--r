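# TIFF input/output. Images are numeric matrices [y, x]; stacks are 3D
# arrays [y, x, slice]. Values are written as 32-bit float so subpixel
# intensities survive a round trip.

#' Read / write single images and multi-page stacks as TIFF
#'
#' @param path File path.
#' @param image Numeric matrix (`[y, x]`).
#' @param stack 3D numeric array (`[y, x, slice]`).
#' @return `read_image_tiff()` a matrix, `read_stack_tiff()` a 3D array;
#'   writers return `path` invisibly.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  unclass(img)
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(normalize_unit(image), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname read_image_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @rdname read_image_tiff
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(i) normalize_unit(stack[, , i]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# tiff::writeTIFF stores float data as-is; writers expect finite values.
normalize_unit <- function(image) {
  storage.mode(image) <- "double"
  if (!all(is.finite(image))) stop_fibclem("bad_image", "image contains non-finite values")
  image
}
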