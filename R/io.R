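# TSV readers/writers for feature and proportion matrices and for dataset
# bundles. Format: tab-delimited, "." decimal, UTF-8, header row of sample
# ids with first cell "feature_id" (or "cell_type" for proportion matrices),
# numeric body at 12 significant digits.

SERIALIZE_DIGITS <- 12

parse_matrix_tsv <- function(path, first_cell) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncolumns <- length(header)
  if (ncolumns < 2) stop("header must name at least one sample", call. = FALSE)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncolumns))
    stop(sprintf("ragged table in %s: row %d has %d fields, expected %d",
                 path, which(widths != ncolumns)[1] + 1,
                 widths[widths != ncolumns][1], ncolumns), call. = FALSE)
  ids <- vapply(body, `[[`, character(1), 1)
  num <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(ncolumns - 1)))
  # vapply gives (ncol-1) x nrow when ncol > 2; normalize to rows x cols
  values <- if (is.matrix(num)) t(num) else matrix(num, ncol = 1)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    bad <- body[[idx[1]]][idx[2] + 1]
    stop(sprintf("non-numeric cell '%s' at data row %d, column '%s' in %s",
                 bad, idx[1], header[idx[2] + 1], path), call. = FALSE)
  }
  list(ids = ids, sample_ids = header[-1], values = values,
       first_cell = header[1])
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a tab-delimited table with header `feature_id<TAB>sample1...` and
#' one numeric row per feature; validates the modality's range constraints.
#'
#' @param path path to a TSV file.
#' @param modality `"rna_log2"` or `"meth_beta"`.
#' @return an [omic_matrix]; row and column order preserved from the file.
#' @export
#' @seealso [write_feature_matrix()]
read_feature_matrix <- function(path, modality = c("rna_log2", "meth_beta")) {
  modality <- match.arg(modality)
  p <- parse_matrix_tsv(path, "feature_id")
  omic_matrix(p$values, modality, feature_ids = p$ids,
              sample_ids = p$sample_ids)
}

write_matrix_tsv <- function(values, row_ids, col_ids, path, first_cell) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(first_cell, col_ids), collapse = "\t"), con)
  body <- apply(signif(values, SERIALIZE_DIGITS), 1, function(r)
    paste(format(r, digits = SERIALIZE_DIGITS, scientific = NA,
                 trim = TRUE), collapse = "\t"))
  writeLines(paste(row_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m an [omic_matrix].
#' @param path destination file path.
#' @return the path, invisibly; entries serialized at 12 significant digits
#'   so a read-back reproduces values to well below algorithmic tolerances.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "omic_matrix"))
  if (length(m$sample_ids) == 0) stop("empty sample list", call. = FALSE)
  write_matrix_tsv(m$values, m$feature_ids, m$sample_ids, path, "feature_id")
  invisible(path)
}

#' Read or write a proportion matrix as TSV
#'
#' Proportion TSVs carry the header `cell_type<TAB>sample1...`; reading
#' validates the column-stochastic invariant (renormalizing deviations up to
#' `1e-3` with a warning).
#'
#' @param path file path.
#' @param labeled whether row labels are known cell types.
#' @return `read_proportion_matrix`: a [proportion_matrix];
#'   `write_proportion_matrix`: the path, invisibly.
#' @export
read_proportion_matrix <- function(path, labeled = TRUE) {
  p <- parse_matrix_tsv(path, "cell_type")
  proportion_matrix(p$values, row_labels = p$ids, sample_ids = p$sample_ids,
                    labeled = labeled)
}

#' @rdname read_proportion_matrix
#' @param a a [proportion_matrix].
#' @export
write_proportion_matrix <- function(a, path) {
  stopifnot(inherits(a, "proportion_matrix"))
  write_matrix_tsv(a$values, a$row_labels, a$sample_ids, path, "cell_type")
  invisible(path)
}

write_reference_tsv <- function(t, path) {
  write_matrix_tsv(t$values, t$feature_ids, t$cell_type_labels, path,
                   "feature_id")
}

read_reference_tsv <- function(path, modality) {
  p <- parse_matrix_tsv(path, "feature_id")
  reference_profiles(p$values, modality, feature_ids = p$ids,
                     cell_type_labels = p$sample_ids)
}

#' Save a benchmark dataset as an on-disk bundle
#'
#' Writes `d_rna.tsv`, `d_met.tsv` and `meta.json`, plus — unless the truth is
#' hidden, as on an evaluation platform's test sets — `a_true.tsv`,
#' `t_rna.tsv` and `t_met.tsv`.
#'
#' @param ds a [benchmark_dataset].
#' @param dir destination directory (created if needed).
#' @param hide_truth omit the ground-truth files.
#' @param overwrite allow writing into a non-empty directory.
#' @return the directory path, invisibly.
#' @export
save_dataset_bundle <- function(ds, dir, hide_truth = FALSE,
                                overwrite = FALSE) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory ", dir, " is non-empty; pass overwrite = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(ds$d_rna, file.path(dir, "d_rna.tsv"))
  write_feature_matrix(ds$d_met, file.path(dir, "d_met.tsv"))
  if (!hide_truth) {
    if (!is.null(ds$a_true))
      write_proportion_matrix(ds$a_true, file.path(dir, "a_true.tsv"))
    if (!is.null(ds$t_rna))
      write_reference_tsv(ds$t_rna, file.path(dir, "t_rna.tsv"))
    if (!is.null(ds$t_met))
      write_reference_tsv(ds$t_met, file.path(dir, "t_met.tsv"))
  }
  jsonlite::write_json(ds$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a benchmark dataset bundle
#'
#' Truth files are optional: a truth-hidden bundle loads into a dataset usable
#' for method runs but not for scoring.
#'
#' @param dir bundle directory written by [save_dataset_bundle()].
#' @return a [benchmark_dataset].
#' @export
load_dataset_bundle <- function(dir) {
  need <- file.path(dir, c("d_rna.tsv", "d_met.tsv"))
  if (!all(file.exists(need)))
    stop("bundle at ", dir, " is missing d_rna.tsv/d_met.tsv", call. = FALSE)
  d_rna <- read_feature_matrix(need[1], "rna_log2")
  d_met <- read_feature_matrix(need[2], "meth_beta")
  if (!identical(d_rna$sample_ids, d_met$sample_ids))
    stop("sample-id mismatch between d_rna and d_met in bundle ", dir,
         call. = FALSE)
  meta <- if (file.exists(file.path(dir, "meta.json")))
    jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  else list()
  grab <- function(f, reader, ...) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p, ...) else NULL
  }
  benchmark_dataset(
    d_met = d_met, d_rna = d_rna,
    a_true = grab("a_true.tsv", read_proportion_matrix, labeled = TRUE),
    t_met = grab("t_met.tsv", read_reference_tsv, modality = "meth_beta"),
    t_rna = grab("t_rna.tsv", read_reference_tsv, modality = "rna_log2"),
    meta = meta)
}
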