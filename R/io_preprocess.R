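#' Read a delimited genes x samples expression table
#'
#' The first row is the sample header and the first column holds gene or
#' probe identifiers.  Duplicate row identifiers are preserved (probe
#' collapse happens downstream in [collapse_probes()]); sample identifiers
#' must be unique.  Parsing is strict: ragged rows and non-numeric cells are
#' reported with their location rather than silently coerced to `NA`.
#'
#' @param path path to a delimited text file.
#' @param delimiter single-character field separator; defaults to tab for
#'   `.tsv`/`.txt` and comma for `.csv`.
#' @return numeric matrix (genes x samples) with gene rownames and sample
#'   colnames.
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) .stop("file not found: ", path)
  delimiter <- delimiter %||% .guess_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) .stop("empty file: ", path)
  if (length(lines) < 2L) .stop("no data rows in ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  n_samp <- length(header) - 1L
  if (n_samp < 1L) .stop("header has no sample columns in ", path)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) .stop("duplicate sample ids in header")
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != n_samp + 1L)
  if (length(bad))
    .stop(sprintf("ragged row: line %d has %d fields, expected %d",
                  bad[1L] + 1L, widths[bad[1L]], n_samp + 1L))
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), ncol = n_samp, byrow = TRUE)
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    .stop(sprintf("non-numeric cell '%s' at data row %d, column %d (%s)",
                  cells[idx[1L], idx[2L]], idx[1L], idx[2L],
                  sample_ids[idx[2L]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

.guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: first column `gene_id`, remaining columns
#' one per sample.  Values are printed at full double precision so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  .check_expression(x)
  header <- paste(c("gene_id", colnames(x)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a clinical table with survival annotations
#'
#' Expects columns `sample_id`, `time` (positive follow-up time in the
#' study's units) and `event` (1 = recurrence/death, 0 = censored).
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator (default guessed from the extension).
#' @return data frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path, delimiter = NULL) {
  if (!file.exists(path)) .stop("file not found: ", path)
  delimiter <- delimiter %||% .guess_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .stop("clinical table missing column(s): ",
          paste(missing_cols, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  .check_clinical(df)
  df
}

#' Read a probe-to-gene mapping table
#'
#' Two-column delimited text: probe identifier, then one or more gene
#' symbols separated by commas.  Probes mapping to several genes are kept in
#' the table (and later eliminated by [collapse_probes()]).
#'
#' @param path path to a delimited text file with a header row.
#' @param delimiter field separator between the two columns.
#' @return named list mapping each probe id to a character vector of gene
#'   symbols.
#' @export
read_probe_mapping <- function(path, delimiter = "\t") {
  if (!file.exists(path)) .stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) .stop("probe mapping needs two columns")
  if (anyDuplicated(df[[1L]])) .stop("duplicate probe ids in mapping")
  genes <- strsplit(df[[2L]], ",", fixed = TRUE)
  genes <- lapply(genes, function(g) unique(trimws(g[nzchar(trimws(g))])))
  if (any(lengths(genes) == 0L)) .stop("probe mapped to no gene symbol")
  stats::setNames(genes, df[[1L]])
}

#' Collapse probe-level rows to one row per gene by largest IQR
#'
#' Probes mapping to more than one gene symbol are eliminated.  When several
#' probes map to the same gene, the probe with the largest interquartile
#' range across samples is retained, on the grounds that it carries the most
#' variation.  Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7); IQR ties are broken by the lexicographically
#' smaller probe id so the result is deterministic.
#'
#' @param x numeric matrix keyed by probe id (rownames), samples in columns.
#' @param mapping named list from [read_probe_mapping()]: probe id ->
#'   character vector of gene symbols.
#' @return numeric matrix with one row per gene symbol (sorted), same
#'   columns as `x`.
#' @export
collapse_probes <- function(x, mapping) {
  .check_expression(x)
  probes <- rownames(x)
  unmapped <- !(probes %in% names(mapping))
  if (any(unmapped)) {
    warning(sprintf("%d probe(s) absent from mapping were dropped",
                    sum(unmapped)), call. = FALSE)
    x <- x[!unmapped, , drop = FALSE]
    probes <- rownames(x)
  }
  if (nrow(x) == 0L) .stop("no probes left after mapping filter")
  genes_per_probe <- mapping[probes]
  multi <- lengths(genes_per_probe) > 1L
  x <- x[!multi, , drop = FALSE]
  probes <- rownames(x)
  if (nrow(x) == 0L) .stop("no probes left after multi-gene elimination")
  gene <- vapply(mapping[probes], `[[`, character(1L), 1L)
  iqr <- apply(x, 1L, stats::IQR, type = 7)
  # pick, per gene, the max-IQR probe; break ties by probe id order
  ord <- order(gene, -iqr, probes, method = "radix")
  keep <- ord[!duplicated(gene[ord])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Standardize each gene to zero mean and unit variance
#'
#' The z-score transformation applied per gene row, using the sample
#' standard deviation (n - 1 denominator).  Genes that are constant across
#' samples cannot be standardized and are dropped with a warning, which also
#' keeps Euclidean distances between samples meaningful.
#'
#' @param x numeric genes x samples matrix with unique gene rownames.
#' @return matrix of the same shape (minus dropped constant genes) with each
#'   row having mean 0 and standard deviation 1.
#' @export
zscore_genes <- function(x) {
  .check_expression(x, require_unique_genes = TRUE)
  if (ncol(x) < 2L) .stop("z-scoring needs at least two samples")
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  constant <- sdv < .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(constant)) {
    warning(sprintf("%d constant gene row(s) dropped (zero variance)",
                    sum(constant)), call. = FALSE)
    x <- x[!constant, , drop = FALSE]
    mu <- mu[!constant]
    sdv <- sdv[!constant]
  }
  if (nrow(x) == 0L) .stop("no genes left after removing constant rows")
  (x - mu) / sdv
}

#' Full preprocessing: collapse probes then z-score genes
#'
#' Convenience composition of [collapse_probes()] and [zscore_genes()];
#' `mapping = NULL` skips the probe collapse for matrices already keyed by
#' gene symbol.
#'
#' @param x numeric matrix keyed by probe (or gene) id.
#' @param mapping optional probe mapping list.
#' @return z-scored genes x samples matrix.
#' @export
preprocess_expression <- function(x, mapping = NULL) {
  if (!is.null(mapping)) x <- collapse_probes(x, mapping)
  zscore_genes(x)
}
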