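# Reading, writing and validating genotype matrices.

#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds minor-allele counts (0/1/2) for N individuals at
#' D variants, together with a missingness mask, unique sample and variant
#' identifiers, and (optionally) a population/superpopulation label table.
#' Allele counts are taken as given: the package never re-polarises to the
#' minor allele, so upstream exports (e.g. plink `--recode A`) define the
#' counted allele.
#'
#' @param values Integer matrix (individuals x variants); entries 0, 1, 2 or
#'   `NA` for missing genotypes.
#' @param sample_ids Character vector of unique sample identifiers (rows).
#' @param variant_ids Character vector of unique variant identifiers (columns).
#' @param labels Optional tibble with columns `sample_id`, `population`,
#'   `superpopulation` covering every sample in `values`.
#'
#' @return An object of class `genotype_matrix` with fields `values`,
#'   `missing_mask`, `sample_ids`, `variant_ids`, `labels`.
#' @export
genotype_matrix <- function(values, sample_ids, variant_ids, labels = NULL) {
  values <- as.matrix(values)
  if (length(sample_ids) != nrow(values)) {
    stop_gtmap("`sample_ids` must have one entry per row of `values`.",
               "gtmap_format_error")
  }
  if (length(variant_ids) != ncol(values)) {
    stop_gtmap("`variant_ids` must have one entry per column of `values`.",
               "gtmap_format_error")
  }
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop_gtmap(sprintf("Duplicated sample id '%s'.", dup),
               "gtmap_uniqueness_error")
  }
  if (anyDuplicated(variant_ids)) {
    dup <- variant_ids[duplicated(variant_ids)][1L]
    stop_gtmap(sprintf("Duplicated variant id '%s'.", dup),
               "gtmap_uniqueness_error")
  }
  ok <- is.na(values) | values %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_gtmap(
      sprintf("Genotype at sample '%s', variant '%s' is not 0/1/2/NA (value: %s).",
              sample_ids[bad[["row"]]], variant_ids[bad[["col"]]],
              format(values[bad[["row"]], bad[["col"]]])),
      "gtmap_value_error")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, variant_ids)
  obj <- structure(
    list(values = values,
         missing_mask = is.na(values),
         sample_ids = sample_ids,
         variant_ids = variant_ids,
         labels = NULL),
    class = "genotype_matrix")
  if (!is.null(labels)) obj <- set_labels(obj, labels)
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants, %d missing cells%s\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              if (is.null(x$labels)) "" else
                sprintf(", %d populations", dplyr::n_distinct(x$labels$population))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read a plink `.raw` additive genotype export
#'
#' Parses the whitespace-delimited text format written by
#' `plink --recode A`: six leading metadata columns
#' (`FID IID PAT MAT SEX PHENOTYPE`) followed by one column per variant with
#' allele-count cells `0`/`1`/`2` or the missing token.
#'
#' @param path Path to the `.raw` file.
#' @param missing Token marking a missing genotype (default `"NA"`).
#' @return A [genotype_matrix()]; `sample_ids` are the `IID` column and
#'   variant ids keep any allele suffix (e.g. `rs123_A`) verbatim.
#' @export
read_plink_raw <- function(path, missing = "NA") {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop_gtmap("Empty .raw file: no header line.", "gtmap_format_error")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1L]]
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6L || !identical(header[1:6], meta)) {
    stop_gtmap(
      "Malformed .raw header: expected leading columns FID IID PAT MAT SEX PHENOTYPE.",
      "gtmap_format_error")
  }
  variant_ids <- header[-(1:6)]
  body <- fields[-1L]
  body <- body[lengths(body) > 0L]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop_gtmap(sprintf("Row %d has %d fields; header has %d.",
                       which(widths != length(header))[1L],
                       widths[widths != length(header)][1L], length(header)),
               "gtmap_format_error")
  }
  iid <- vapply(body, `[[`, character(1), 2L)
  cells <- matrix(unlist(lapply(body, `[`, -(1:6))),
                  nrow = length(body), byrow = TRUE)
  parse_genotype_cells(cells, iid, variant_ids, missing)
}

parse_genotype_cells <- function(cells, sample_ids, variant_ids, missing) {
  vals <- matrix(NA_integer_, nrow(cells), ncol(cells))
  is_missing <- cells == missing
  known <- cells %in% c("0", "1", "2")
  bad <- !(is_missing | known)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_gtmap(
      sprintf("Genotype cell at sample '%s', variant '%s' is '%s'; expected 0/1/2 or '%s'.",
              sample_ids[idx[["row"]]], variant_ids[idx[["col"]]],
              cells[idx[["row"]], idx[["col"]]], missing),
      "gtmap_value_error")
  }
  vals[known] <- as.integer(cells[known])
  genotype_matrix(vals, sample_ids, variant_ids)
}

#' Read and write the TSV genotype dialect
#'
#' The TSV dialect has a `sample_id` first column, one column per variant,
#' and cells `0`/`1`/`2`/`NA`. `write_genotype_tsv()` and
#' `read_genotype_tsv()` round-trip a [genotype_matrix()] losslessly
#' (values, missingness mask and identifiers are preserved bit-exactly).
#'
#' @param path File path.
#' @param g A [genotype_matrix()].
#' @return `read_genotype_tsv()` returns a [genotype_matrix()];
#'   `write_genotype_tsv()` returns `path` invisibly.
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop_gtmap("Empty genotype TSV: no header.", "gtmap_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "sample_id") {
    stop_gtmap("Genotype TSV must have 'sample_id' as its first column.",
               "gtmap_format_error")
  }
  variant_ids <- header[-1L]
  body <- fields[-1L]
  if (length(body) == 0L) {
    return(genotype_matrix(matrix(NA_integer_, 0L, length(variant_ids)),
                           character(0), variant_ids))
  }
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop_gtmap(sprintf("Ragged TSV: row %d has %d fields, header has %d.",
                       which(widths != length(header))[1L],
                       widths[widths != length(header)][1L], length(header)),
               "gtmap_format_error")
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L)),
                  nrow = length(body), byrow = TRUE)
  parse_genotype_cells(cells, ids, variant_ids, "NA")
}

#' @rdname read_genotype_tsv
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  header <- paste(c("sample_id", g$variant_ids), collapse = "\t")
  vals <- g$values
  body <- vapply(seq_len(nrow(vals)), function(i) {
    row <- as.character(vals[i, ])
    row[is.na(row)] <- "NA"
    paste(c(g$sample_ids[i], row), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample label table
#'
#' @param path TSV with columns `sample_id`, `population`, `superpopulation`.
#' @return A tibble usable as the `labels` field of a [genotype_matrix()].
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("sample_id", "population", "superpopulation")
  if (!all(needed %in% names(tab))) {
    stop_gtmap("Labels TSV needs columns sample_id, population, superpopulation.",
               "gtmap_format_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    dup <- tab$sample_id[duplicated(tab$sample_id)][1L]
    stop_gtmap(sprintf("Duplicated sample '%s' in labels.", dup),
               "gtmap_uniqueness_error")
  }
  tibble::as_tibble(tab[needed])
}

#' Attach labels to a genotype matrix
#'
#' Labels must cover every sample in the matrix; label rows for samples not
#' present are ignored (with a message).
#'
#' @param g A [genotype_matrix()].
#' @param labels A label tibble as returned by [read_labels()].
#' @return `g` with its `labels` field set (rows ordered as `g$sample_ids`).
#' @export
set_labels <- function(g, labels) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- tibble::as_tibble(labels)
  if (anyDuplicated(labels$sample_id)) {
    stop_gtmap("Duplicated sample_id in labels.", "gtmap_uniqueness_error")
  }
  missing <- setdiff(g$sample_ids, labels$sample_id)
  if (length(missing) > 0L) {
    stop_gtmap(sprintf("Labels missing for %d sample(s), e.g. '%s'.",
                       length(missing), missing[1L]),
               "gtmap_coverage_error")
  }
  extra <- setdiff(labels$sample_id, g$sample_ids)
  if (length(extra) > 0L) {
    inform(sprintf("Ignoring %d label row(s) for samples not in the matrix.",
                   length(extra)))
  }
  g$labels <- labels[match(g$sample_ids, labels$sample_id), ]
  g
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing cell by the per-variant mean of the non-missing
#' allele counts (kept as a real number, not rounded, since downstream PCA
#' consumes real values). When imputing a test matrix, pass the training
#' `column_means` so train and test share the same imputation.
#'
#' @param g A [genotype_matrix()].
#' @param column_means Optional numeric vector of length D with the means to
#'   impute with (e.g. from a training matrix); defaults to the means of `g`.
#' @return List with `values` (dense numeric N x D matrix, no missing cells)
#'   and `column_means` (the means used).
#' @export
impute_missing <- function(g, column_means = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$values
  storage.mode(vals) <- "double"
  own_means <- colMeans(vals, na.rm = TRUE)
  if (is.null(column_means)) {
    column_means <- own_means
  } else if (length(column_means) != ncol(vals)) {
    stop_gtmap("`column_means` must have one entry per variant.",
               "gtmap_shape_error")
  }
  if (anyNA(column_means) || any(!is.finite(column_means))) {
    bad <- g$variant_ids[which(!is.finite(column_means))[1L]]
    stop_gtmap(
      sprintf("Variant '%s' is entirely missing and no imputation mean was provided.",
              bad),
      "gtmap_imputation_error")
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- column_means[idx[, "col"]]
  }
  list(values = vals, column_means = as.numeric(column_means))
}
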