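#' Read an RNA-seq sample sheet
#'
#' The sheet must assign every sample a lifestyle (`free` or `symbiotic`),
#' a temperature (28 or 34) and a replicate index.
#'
#' @param path TSV with columns `sample`, `lifestyle`, `temperature`,
#'   `replicate`.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  s <- read.delim(path, quote = "")
  validate_sample_sheet(s)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample", "lifestyle", "temperature", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  sheet$sample <- as.character(sheet$sample)
  sheet$lifestyle <- as.character(sheet$lifestyle)
  if (!all(sheet$lifestyle %in% c("free", "symbiotic")))
    stop("lifestyle must be 'free' or 'symbiotic'")
  if (!all(sheet$temperature %in% c(28, 34)))
    stop("temperature must be 28 or 34")
  if (anyDuplicated(sheet$sample)) stop("duplicate sample names in sheet")
  sheet$condition <- paste(sheet$lifestyle, sheet$temperature, sep = "_")
  sheet
}

#' Parse a gene-by-sample count matrix
#'
#' Counts must be non-negative integers; every column of the matrix must be
#' described in the sample sheet. Both violations are hard errors naming the
#' offending cell or sample.
#'
#' @param path TSV whose first column holds gene ids and whose remaining
#'   columns are samples.
#' @param samples a sample sheet data.frame (see [read_sample_sheet()]).
#' @return A list with `counts` (integer matrix) and `samples` (the sheet
#'   rows matching the matrix columns, in column order).
#' @export
parse_counts <- function(path, samples) {
  samples <- validate_sample_sheet(samples)
  raw <- read.delim(path, row.names = 1, check.names = FALSE, quote = "")
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("non-numeric count encountered")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at gene '", rownames(m)[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "'")
  missing_meta <- setdiff(colnames(m), samples$sample)
  if (length(missing_meta))
    stop("sample(s) absent from sheet: ", paste(missing_meta, collapse = ", "))
  storage.mode(m) <- "integer"
  list(counts = m, samples = samples[match(colnames(m), samples$sample), , drop = FALSE])
}
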