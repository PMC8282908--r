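#' Save / load a synthetic cohort
#'
#' Cohorts are plain lists of `epoch_set`s; persistence uses R's native RDS
#' serialization (compact and lossless for numeric arrays). Model objects
#' can be saved the same way with `saveRDS` directly.
#'
#' @param cohort List of `epoch_set`s.
#' @param path File path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "epoch_set")))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  cohort <- readRDS(path)
  stopifnot(all(vapply(cohort, inherits, logical(1), "epoch_set")))
  cohort
}

#' Write an accuracy-curve result table as TSV
#'
#' @param result A `result_table` from [accuracy_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(result, path) {
  stopifnot(inherits(result, "result_table"))
  tab <- result$table
  base <- data.frame(method = "single_user", k = NA_integer_,
                     mean_accuracy = result$baseline$mean,
                     sd_accuracy = result$baseline$sd,
                     n_selections = length(result$baseline$per_subject))
  utils::write.table(rbind(tab, base), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
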