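# Delimited-text I/O for genotype, phenotype, gene-map, weight and metric
# tables. Dialect (tab or comma) is auto-detected from the header line;
# files are UTF-8. Layout: one header row of column ids, first column holds
# sample ids.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L) stop(sprintf("'%s' is empty", path))
  if (grepl("\t", header)) "\t" else ","
}

read_table_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  sep <- detect_sep(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != width)
  if (length(bad) > 0L)
    stop(sprintf("malformed row in '%s': line %d has %d fields, expected %d",
                 path, bad[1L], length(fields[[bad[1L]]]), width))
  header <- fields[[1L]]
  body <- fields[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  cells <- do.call(rbind, lapply(body, `[`, -1L))
  list(col_ids = header[-1L], row_ids = ids,
       cells = matrix(as.character(cells), nrow = length(body)))
}

#' Read a genotype matrix from delimited text
#'
#' Expects a header row of SNP ids and a first column of sample ids; the
#' delimiter (tab or comma) is detected from the header. Entries must be
#' 0, 1 or 2, or `missing_code` when missingness is permitted.
#'
#' @param path path to a TSV/CSV file.
#' @param missing_code integer code marking missing genotypes (default -1).
#' @param impute if `TRUE`, missing entries are replaced by the per-SNP mode
#'   of the observed codes (ties broken towards the smaller code) and a
#'   message reports how many entries were imputed. If `FALSE`, any missing
#'   entry is an error.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, missing_code = -1L, impute = FALSE) {
  tab <- read_table_checked(path)
  suppressWarnings(vals <- matrix(as.integer(tab$cells), nrow = nrow(tab$cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-integer genotype entry '%s' for SNP '%s', sample '%s' in '%s'",
                 tab$cells[bad],
                 tab$col_ids[(bad - 1L) %/% nrow(vals) + 1L],
                 tab$row_ids[(bad - 1L) %% nrow(vals) + 1L], path))
  }
  g <- genotype_matrix(vals, snp_ids = tab$col_ids, sample_ids = tab$row_ids,
                       missing_code = missing_code, allow_missing = impute)
  if (impute && any(g == missing_code)) g <- impute_genotypes(g, missing_code)
  g
}

# Per-SNP mode imputation over the {0,1,2} alphabet; ties go to the smaller
# code so the result is deterministic.
impute_genotypes <- function(g, missing_code = -1L) {
  vals <- unclass_matrix(g)
  n_missing <- 0L
  for (j in seq_len(ncol(vals))) {
    miss <- vals[, j] == missing_code
    if (!any(miss)) next
    obs <- vals[!miss, j]
    if (length(obs) == 0L)
      stop(sprintf("SNP '%s' has no observed genotypes to impute from", colnames(vals)[j]))
    counts <- tabulate(obs + 1L, nbins = 3L)  # codes 0,1,2
    vals[miss, j] <- which.max(counts) - 1L
    n_missing <- n_missing + sum(miss)
  }
  message(sprintf("imputed %d missing genotype entries by per-SNP mode", n_missing))
  genotype_matrix(vals, gene_of = attr(g, "gene_of"), position = attr(g, "position"))
}

#' Read a phenotype matrix from delimited text
#'
#' @param path path to a TSV/CSV file with a header row of ROI ids and a
#'   first column of sample ids.
#' @return A [phenotype_matrix()].
#' @export
read_phenotypes <- function(path) {
  tab <- read_table_checked(path)
  suppressWarnings(vals <- matrix(as.numeric(tab$cells), nrow = nrow(tab$cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric phenotype entry '%s' at sample '%s', ROI '%s' in '%s'",
                 tab$cells[bad],
                 tab$row_ids[(bad - 1L) %% nrow(vals) + 1L],
                 tab$col_ids[(bad - 1L) %/% nrow(vals) + 1L], path))
  }
  phenotype_matrix(vals, roi_ids = tab$col_ids, sample_ids = tab$row_ids)
}

write_delim_matrix <- function(x, path, sep = "\t", id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a genotype matrix as delimited text
#' @param g a [genotype_matrix()].
#' @param path output file; extension `.csv` selects comma, otherwise tab.
#' @export
write_genotypes <- function(g, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write_delim_matrix(unclass_matrix(g), path, sep, id_col = "sample_id")
}

#' Write a phenotype matrix as delimited text
#' @param ph a [phenotype_matrix()].
#' @param path output file; extension `.csv` selects comma, otherwise tab.
#' @export
write_phenotypes <- function(ph, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write_delim_matrix(format(unclass_matrix(ph), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep, id_col = "sample_id")
}

#' Read a SNP-to-gene annotation map
#'
#' Two-column delimited file (snp_id, gene); returns a named character
#' vector usable as the `gene_of` argument elsewhere.
#' @param path path to the file (with header).
#' @return Named character vector mapping SNP id to gene symbol.
#' @export
read_gene_map <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop(sprintf("gene map '%s' needs two columns (snp_id, gene)", path))
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a SNP-to-gene annotation map
#' @param gene_of named character vector (names = SNP ids, values = genes).
#' @param path output file.
#' @export
write_gene_map <- function(gene_of, path) {
  utils::write.table(data.frame(snp_id = names(gene_of), gene = unname(gene_of)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a weight matrix (rows = SNP ids, columns = ROI ids)
#' @param W numeric matrix with SNP row names and ROI column names.
#' @param path output file.
#' @export
write_weights <- function(W, path) {
  write_delim_matrix(format(W, digits = 17, trim = TRUE, scientific = TRUE),
                     path, id_col = "snp_id")
}

#' Read a weight matrix written by [write_weights()]
#' @param path input file.
#' @return Numeric matrix, SNPs x ROIs.
#' @export
read_weights <- function(path) {
  tab <- read_table_checked(path)
  W <- matrix(as.numeric(tab$cells), nrow = nrow(tab$cells),
              dimnames = list(tab$row_ids, tab$col_ids))
  if (anyNA(W)) stop(sprintf("non-numeric weight entry in '%s'", path))
  W
}

#' Write a metrics report as TSV and/or JSON
#'
#' @param report a `metrics_report` from [evaluate()].
#' @param path output file; `.json` extension writes JSON, anything else a
#'   TSV with rows = ROIs plus an `aggregate` row and columns = the six
#'   error measures.
#' @export
write_metrics <- function(report, path) {
  tab <- rbind(report$per_roi, aggregate = report$aggregate)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_roi = as.data.frame(report$per_roi),
                              roi_ids = rownames(report$per_roi),
                              aggregate = as.list(report$aggregate),
                              n_features_used = report$n_features_used),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write_delim_matrix(format(tab, digits = 10, trim = TRUE), path, id_col = "roi_id")
  }
  invisible(path)
}
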