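#' Write a stack as a 16-bit multi-page TIFF with a JSON sidecar
#'
#' One page per z-slice; intensities are stored as 16-bit unsigned values
#' (clipped at 65535).  Voxel size and acquisition time go to
#' `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- pmin(round(stack$values), 65535) / 65535
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(voxel_size = stack$voxel_size, time = stack$time),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; `<path>.json` supplies voxel size and time when
#'   present.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  v <- array(0, d)
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]] * 65535
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else
    list(voxel_size = 3, time = 0)
  image_stack(round(v), meta$voxel_size, meta$time)
}

#' Write a genes/probes × samples matrix as TSV
#'
#' Header row of sample/cell IDs, first column of row IDs (column name
#' `id`).
#'
#' @param matrix Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
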