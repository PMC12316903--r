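# Plain-text table I/O. All result tables are TSV with a fixed column
# order and fixed numeric formatting so that identical inputs serialize
# byte-identically (the pipeline's reproducibility contract).

#' Read a protein quantification matrix from TSV
#'
#' First column = protein id, remaining columns = sample intensities (the
#' layout DIA search engines export at protein level).
#'
#' @param path TSV file path.
#' @return numeric matrix, proteins x samples, rownames = protein ids.
#' @export
read_quant_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("quant TSV needs an id column plus sample columns")
  if (anyDuplicated(df[[1]])) stop("duplicate protein ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite intensities in ", path)
  rownames(m) <- df[[1]]
  m
}

#' Write a protein quantification matrix to TSV
#'
#' @param mat proteins x samples matrix.
#' @param path output path.
#' @export
write_quant_tsv <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_result_tsv(df, path)
}

#' Read a sample design table from CSV
#'
#' Expected columns: `sample_id`, `condition`, `treatment` (and optionally
#' `replicate` or others).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  df
}

#' Write a result table as deterministic TSV
#'
#' Numeric columns are formatted with up to 10 significant digits,
#' trailing-zero free, so reruns with identical inputs produce
#' byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 10, scientific = FALSE,
                                       trim = TRUE)
      }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
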