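#' Write / read the delimited methylation matrix and metadata
#'
#' The matrix is stored as tab-separated text with samples in rows (row names
#' = sample IDs) and one header row of CpG IDs; metadata as a four-column
#' table (`sample_id`, `age`, `group`, `split`).
#'
#' @param data a `methyl_dataset`.
#' @param matrix_path,meta_path file paths.
#' @return `write_dataset` returns the paths invisibly; `read_dataset`
#'   returns a `methyl_dataset`.
#' @export
write_dataset <- function(data, matrix_path, meta_path) {
  write.table(data$values, matrix_path, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(data$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(matrix_path, meta_path) {
  v <- as.matrix(read.delim(matrix_path, row.names = 1, check.names = FALSE))
  m <- read.delim(meta_path, stringsAsFactors = FALSE)
  m$age <- suppressWarnings(as.numeric(m$age))
  methyl_dataset(v, m)
}

#' Write / read a two-column CpG-to-gene annotation table
#'
#' @param annotation data.frame with columns `cpg_id`, `gene`.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation[, c("cpg_id", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
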