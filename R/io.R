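#' Read and write pipeline tables as TSV
#'
#' All tabular interchange (cell records, well layouts, DE caller
#' results) uses plain tab-separated text with a header row, no quoting
#' and no row names.
#'
#' @param x a `data.frame`.
#' @param path file path.
#' @return `write_tsv_table`: `path`, invisibly. `read_tsv_table`: a
#'   `data.frame`.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Persist a detection or simulation parameter set next to its outputs
#'
#' Writes the parameter object as `key<TAB>value` lines so every run
#' records the exact configuration it used, keeping runs comparable.
#'
#' @param params a `detection_params`, `stimulus_model`, `sim_config` or
#'   `consensus_thresholds` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  flat <- vapply(unclass(params),
                 function(v) paste(format(v, digits = 15), collapse = ","),
                 character(1))
  writeLines(c(paste0("# ", class(params)[1]),
               paste(names(flat), flat, sep = "\t")), path)
  invisible(path)
}
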