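#' Read and write trace tables
#'
#' Trace tables use the tab-delimited dialect of microscope exports: first
#' column `time_s`, then `<roi>_fluo4` and `<roi>_furared` columns. CSV
#' input is also accepted by [read_trace_table()] (sniffed from the header
#' line).
#'
#' @param traces Wide trace table (e.g. from [simulate_dish()]).
#' @param path File path.
#' @return `write_trace_tsv()` returns `path` invisibly;
#'   `read_trace_table()` returns the wide tibble.
#' @export
write_trace_tsv <- function(traces, path) {
  readr::write_tsv(as_tibble(traces), path)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_table <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}

#' Extract one ROI's trace from a wide trace table
#'
#' @param traces Wide trace table (`time_s` + `<roi>_fluo4`/`<roi>_furared`).
#' @param roi ROI name (column prefix).
#' @return A `ratio_trace` tibble (`time_s`, `fluo4`, `furared`, `ratio`).
#' @export
extract_roi_trace <- function(traces, roi) {
  fc <- paste0(roi, "_fluo4")
  rc <- paste0(roi, "_furared")
  if (!all(c("time_s", fc, rc) %in% names(traces))) {
    abort(paste0("ROI columns not found: ", roi), class = "wntwave_input_error")
  }
  new_ratio_trace(traces$time_s, traces[[fc]], traces[[rc]])
}

#' Write and read synthetic image sets as TIFF
#'
#' The two intensity channels are written as a two-page 16-bit TIFF
#' (DAPI first, Cy3 second) and the nucleus labels as a separate 16-bit
#' single-page TIFF.
#'
#' @param images A `coloc_images` object (see [simulate_coloc_images()]).
#' @param image_path,mask_path Output TIFF paths.
#' @param scale Intensity scale mapped to the 16-bit maximum.
#' @return `write_coloc_tiff()` returns the paths invisibly;
#'   `read_coloc_tiff()` returns a list with `dapi`, `cy3`, `masks`.
#' @export
write_coloc_tiff <- function(images, image_path, mask_path, scale = 1024) {
  pages <- list(pmin(images$dapi / scale, 1), pmin(images$cy3 / scale, 1))
  tiff::writeTIFF(pages, image_path, bits.per.sample = 16)
  tiff::writeTIFF(images$masks / 65535, mask_path, bits.per.sample = 16)
  invisible(c(image_path, mask_path))
}

#' @rdname write_coloc_tiff
#' @export
read_coloc_tiff <- function(image_path, mask_path, scale = 1024) {
  pages <- tiff::readTIFF(image_path, all = TRUE)
  masks <- tiff::readTIFF(mask_path)
  list(
    dapi = pages[[1]] * scale,
    cy3 = pages[[2]] * scale,
    masks = matrix(as.integer(round(masks * 65535)), nrow(masks), ncol(masks))
  )
}
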