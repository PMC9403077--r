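#' Write / read an epoch container
#'
#' Epoch arrays are stored as RDS array containers holding the data cube
#' and its axis metadata (`fs`, `t0`, labels, event types).
#'
#' @param epochs an `epoch_array`.
#' @param path file path (`.rds`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  epoch_array(x$data, fs = x$fs, t0 = x$t0, labels = x$labels,
              event_type = x$event_type)
}

#' Write a square connectivity matrix as a delimited table
#'
#' @param W square numeric matrix with region labels as dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(W, path) {
  utils::write.table(as.data.frame(W), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
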