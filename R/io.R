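## File interfaces: NIfTI volumes, tab-separated tables, YAML configs.

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param volume Numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm (recycled to 3).
#' @export
write_volume <- function(volume, path, voxel_size = 1) {
  img <- RNifti::asNifti(volume * 1, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Write a matrix as a tab-separated table with header row and column
#' @param m Matrix (ROI x ROI or similar).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(name = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as a tab-separated table
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a pipeline or synthetic configuration as YAML
#'
#' Matrices are stored with their dimnames and restored on read.
#' @param cfg A [synth_config()] or [pipeline_config()] list.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  ser <- rapply(unclass(cfg), function(x) {
    if (is.matrix(x))
      list(.matrix = TRUE, rows = rownames(x), cols = colnames(x),
           data = as.vector(x))
    else x
  }, how = "replace", classes = c("matrix", "array"))
  yaml::write_yaml(c(ser, list(.class = class(cfg))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cls <- raw$.class; raw$.class <- NULL
  restore <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = length(x$rows),
                  dimnames = list(x$rows, x$cols))
      m
    } else if (is.list(x)) lapply(x, restore) else x
  }
  out <- lapply(raw, restore)
  if (!is.null(cls)) class(out) <- cls
  out
}
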