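#' Write / read a dataset as two delimited text files
#'
#' Datasets are exchanged as a features table (first column `sample_id`, one
#' column per feature, tab-separated, header row) and a phenotype table
#' (`sample_id` plus outcome columns). The round trip is lossless to full
#' double precision.
#'
#' @param data A data frame with `sample_id`, an outcome column and numeric
#'   feature columns.
#' @param features_path,phenotype_path Output file paths.
#' @param outcome Name of the outcome column.
#' @return `write_bwas_data()` returns the input invisibly;
#'   `read_bwas_data()` returns a tibble shaped like the output of
#'   [simulate_bwas_data()] (without ground-truth attributes).
#' @export
write_bwas_data <- function(data, features_path, phenotype_path,
                            outcome = "outcome") {
  parts <- bwas_xy(data, outcome = outcome)
  feats <- tibble::as_tibble(parts$x)
  feats <- tibble::add_column(feats, sample_id = parts$ids, .before = 1)
  pheno <- tibble::tibble(sample_id = parts$ids)
  pheno[[outcome]] <- parts$y
  readr::write_tsv(feats, features_path)
  readr::write_tsv(pheno, phenotype_path)
  invisible(data)
}

#' @rdname write_bwas_data
#' @export
read_bwas_data <- function(features_path, phenotype_path,
                           outcome = "outcome") {
  feats <- readr::read_tsv(features_path, show_col_types = FALSE,
                           col_types = readr::cols(sample_id = "c",
                                                   .default = "d"))
  pheno <- readr::read_tsv(phenotype_path, show_col_types = FALSE,
                           col_types = readr::cols(sample_id = "c",
                                                   .default = "d"))
  if (!outcome %in% names(pheno)) {
    abort(sprintf("phenotype table has no column `%s`.", outcome),
          class = "bwasrep_config_error")
  }
  merged <- dplyr::inner_join(pheno[, c("sample_id", outcome)], feats,
                              by = "sample_id")
  if (nrow(merged) != nrow(feats) || nrow(merged) != nrow(pheno)) {
    abort("sample ids of the two tables do not match one-to-one.",
          class = "bwasrep_config_error")
  }
  class(merged) <- c("bwas_data", class(merged))
  merged
}
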