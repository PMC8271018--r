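# Plain-text readers/writers for the formats the pipeline exchanges:
# tidy TSV tables, dense CSV matrices, and 0-based edge lists.

#' Write a data frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a dense numeric matrix as CSV (no headers)
#' @param m matrix.
#' @param path output file.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense numeric matrix from headerless CSV
#' @param path input file.
#' @return numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a connectome as a 0-based edge-list TSV (i, j, weight)
#' @param conn a `connectome`.
#' @param path output file.
#' @export
write_edge_list <- function(conn, path) {
  ed <- connectome_edges(conn)
  ed$i <- ed$i - 1L
  ed$j <- ed$j - 1L
  write_tsv_table(ed, path)
}
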