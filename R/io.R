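# Phenotype / covariate table IO: TSV with header, columns id, trait
# value(s), age, gender.

#' Read a phenotype + covariate table
#'
#' @param path TSV with a header line and at least the columns `id`,
#'   `age`, `gender`; any other numeric column is a trait.
#' @return A data.frame with `id` as character.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "age", "gender") %in% names(tab)))
    stop("phenotype table needs columns id, age, gender")
  tab$id <- as.character(tab$id)
  tab
}

#' Write a phenotype + covariate table
#'
#' @param df data.frame including an `id` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
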