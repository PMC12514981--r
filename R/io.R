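#' Read and write per-eye cohort CSV files
#'
#' The on-disk header contract uses ASCII aliases for the ratio features
#' (`AL_over_CR`, not a slash). Required raw columns: `subject_id`,
#' `eye_id`, `gender` (0/1), `age`, `S`, `C`, `axis`, `IOP`, `AL`, `CCT`,
#' `ACD`, `LT`, `K1`, `K2`, `Km`; optional: `cyclo_S`, `cyclo_C` and any
#' derived columns. Missing cells are empty fields.
#'
#' @param path file path.
#' @param check verify the required columns are present.
#' @return `read_cohort_csv`: a data.frame of per-eye records;
#'   `write_cohort_csv`: the path, invisibly.
#' @export
read_cohort_csv <- function(path, check = TRUE) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (check) {
    need <- c("subject_id", "eye_id", "gender", "age", "S", "C", "axis",
              "IOP", "AL", "CCT", "ACD", "LT", "K1", "K2", "Km")
    miss <- setdiff(need, names(rec))
    if (length(miss))
      stop("cohort file lacks required columns: ", paste(miss, collapse = ", "))
  }
  rec
}

#' @param records a per-eye data.frame.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
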