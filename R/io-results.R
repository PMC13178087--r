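#' Write and read per-patient morphometry results as CSV
#'
#' One row per patient with a stable column order: `patient_id`,
#' `group_label`, `taim_pct`, `oimr_pct`, `total_index`,
#' `n_micrographs_5000x`, `n_mitochondria_15000x`. Values are written at
#' full precision, UTF-8.
#'
#' @param x Results tibble (see [compute_morphometry()]).
#' @param path Output file path.
#' @return `path` ([write_results_csv()]) or a results tibble
#'   ([read_results_csv()]).
#' @name results_io
NULL

results_cols <- c("patient_id", "group_label", "taim_pct", "oimr_pct",
                  "total_index", "n_micrographs_5000x", "n_mitochondria_15000x")

#' @rdname results_io
#' @export
write_results_csv <- function(x, path) {
  if (nrow(x) == 0L) abort("no results to write")
  missing <- setdiff(results_cols, names(x))
  if (length(missing)) {
    abort(paste0("results are missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$patient_id)) {
    abort(paste0("duplicate patient_id: ",
                 paste(unique(x$patient_id[duplicated(x$patient_id)]),
                       collapse = ", ")))
  }
  utils::write.csv(as.data.frame(x[, results_cols]), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname results_io
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  missing <- setdiff(results_cols, names(x))
  if (length(missing)) {
    abort(paste0(path, " is missing columns: ", paste(missing, collapse = ", ")))
  }
  x$patient_id <- as.character(x$patient_id)
  x
}
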