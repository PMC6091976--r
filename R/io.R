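#' Read and write multi-page TIFF stacks
#'
#' Thin wrappers around the \pkg{tiff} package working with numeric arrays
#' laid out x-by-y-by-frame. Intensities are kept in `[0, 1]`; values are
#' clamped on write.
#'
#' @param path TIFF file path.
#' @return `read_image_stack`: a numeric array (x, y, frame).
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
    error = function(e) abort(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF returns row-major matrices (y, x); transpose to (x, y)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  arr
}

#' @rdname read_image_stack
#' @param stack numeric array (x, y, frame) with values in `[0, 1]`.
#' @param bits bits per sample (8 or 16).
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    t(pmin(pmax(stack[, , k], 0), 1))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
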