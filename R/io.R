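#' Read a methylation beta matrix from TSV
#'
#' The expected layout is one header row of CpG identifiers, a first column
#' `sample_id`, and one row per sample. Beta values are methylation ratios in
#' \[0, 1\]; the literal string `NA` encodes a missing (unobserved) probe.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (samples x CpGs) with sample ids as rownames and
#'   CpG ids as colnames; missing probes are `NA`.
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty beta-matrix file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("beta matrix must have a sample-id column plus at least one CpG column")
  }
  sample_ids <- as.character(df[[1]])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  cpg_ids <- colnames(df)[-1]
  if (anyDuplicated(cpg_ids)) {
    stop("duplicate CpG ids: ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  }
  num <- vapply(df[-1], is.numeric, logical(1))
  if (!all(num)) {
    stop("malformed numeric values in column(s): ",
         paste(cpg_ids[!num], collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(sample_ids, cpg_ids)
  validate_beta_matrix(m)
  m
}

#' Validate a beta matrix in place
#'
#' Checks that every non-missing value lies in \[0, 1\]; the first offending
#' cell is reported by sample and CpG id.
#'
#' @param m Numeric matrix, samples x CpGs.
#' @return The matrix, invisibly.
#' @export
validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("beta matrix must be a numeric matrix")
  bad <- which(!is.na(m) & (m < 0 | m > 1 | !is.finite(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value out of [0, 1] at sample '%s', CpG '%s' (value %s); %d offending cell(s) total",
      rownames(m)[i] %||% i, colnames(m)[j] %||% j, format(m[i, j]), nrow(bad)))
  }
  invisible(m)
}

#' Write a beta matrix as TSV
#'
#' Values are written with fixed 6-decimal precision so that a write/read
#' round trip reproduces them exactly; missing probes are written as `NA`.
#' The write is atomic (temp file plus rename).
#'
#' @param m Numeric matrix, samples x CpGs, rownames = sample ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  atomic_write(function(tmp) {
    txt <- matrix(formatC(m, format = "f", digits = 6), nrow(m), ncol(m))
    txt[is.na(m)] <- "NA"
    df <- data.frame(sample_id = rownames(m) %||% seq_len(nrow(m)),
                     txt, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("sample_id", colnames(m))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Read a MAF-like mutation call table
#'
#' Required columns: `sample_id`, `gene`, `variant`, `vaf` (variant allele
#' frequency in \[0, 1\]); additional columns are preserved. Gene symbols are
#' upper-cased. An empty table (header only) is valid and yields zero calls.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` of calls with class `mutation_table`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "gene", "variant", "vaf")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$gene <- toupper(as.character(df$gene))
  df$sample_id <- as.character(df$sample_id)
  if (nrow(df) > 0) check_unit_interval(df$vaf, "vaf", allow_na = TRUE)
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Write a mutation call table as TSV
#'
#' @param calls A `data.frame` with at least `sample_id`, `gene`, `variant`,
#'   `vaf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(calls, path) {
  required <- c("sample_id", "gene", "variant", "vaf")
  missing_cols <- setdiff(required, colnames(calls))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  atomic_write(function(tmp) {
    utils::write.table(calls, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Per-sample driver mutation flags
#'
#' Summarizes a mutation table into one row per sample with logical flags for
#' the two driver classes: H3 (K27M in H3F3A or HIST1H3B/C) and IDH
#' (any IDH1/IDH2 call).
#'
#' @param calls A mutation table (see [read_mutation_table()]).
#' @param sample_ids Optional character vector of samples to report (samples
#'   with no calls get all-FALSE flags).
#' @return A `data.frame` with columns `sample_id`, `h3_driver`, `idh_driver`.
#' @export
driver_flags <- function(calls, sample_ids = NULL) {
  ids <- sample_ids %||% unique(calls$sample_id)
  h3 <- is_h3_driver_call(calls$gene, calls$variant)
  idh <- toupper(calls$gene) %in% IDH_DRIVER_GENES
  data.frame(
    sample_id = ids,
    h3_driver = ids %in% calls$sample_id[h3],
    idh_driver = ids %in% calls$sample_id[idh],
    stringsAsFactors = FALSE
  )
}

#' Identify H3 driver calls
#'
#' K27M calls in the three histone driver genes (H3F3A, HIST1H3B, HIST1H3C);
#' a missing variant label is accepted as a gene-level call.
#'
#' @param gene,variant Character vectors of gene symbols and variant labels.
#' @return Logical vector.
#' @export
is_h3_driver_call <- function(gene, variant) {
  g <- toupper(as.character(gene)) %in% H3_DRIVER_GENES
  v <- is.na(variant) | grepl("K27M", toupper(as.character(variant)), fixed = TRUE)
  g & v
}
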