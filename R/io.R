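#' Construct a validated expression matrix
#'
#' The central container of the package: a numeric genes-by-samples matrix
#' with unique row (gene symbol) and column (sample/cell id) names, carrying
#' a `space` attribute that records whether values are raw counts or
#' log-normalized expression.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` and `colnames` set.
#' @param space Either `"raw_counts"` or `"log_normalized"`.
#' @return A matrix of class `ExpressionMatrix` with attribute `space`.
#' @export
expression_matrix <- function(values, space = c("log_normalized", "raw_counts")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (space == "raw_counts" && any(values < 0))
    stop("raw counts must be non-negative")
  structure(values, space = space, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (space: %s)\n",
              nrow(x), ncol(x), expr_space(x)))
  invisible(x)
}

#' Expression space of a matrix
#'
#' @param x An `ExpressionMatrix`.
#' @return `"raw_counts"` or `"log_normalized"`.
#' @export
expr_space <- function(x) {
  s <- attr(x, "space")
  if (is.null(s)) "log_normalized" else s
}

#' Construct a gene signature
#'
#' A named gene set, e.g. the circadian-rhythm-related gene (CRG) list that
#' defines the CRD score.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols; duplicates are removed.
#' @return An object of class `GeneSignature` with elements `name`, `genes`.
#' @export
gene_signature <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("signature '", name, "' has no genes")
  structure(list(name = name, genes = genes), class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a survival table
#'
#' @param sample Character vector of unique sample ids.
#' @param time Positive follow-up times in days.
#' @param event Event indicator: 1 = death observed, 0 = censored.
#' @param ... Optional covariate columns (age, sex, stage, ...), each the
#'   same length as `sample`.
#' @return A `data.frame` of class `SurvivalTable`.
#' @export
survival_table <- function(sample, time, event, ...) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stop("duplicate sample ids in survival table")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample) || length(event) != length(sample))
    stop("sample, time and event must have equal length")
  if (!all(is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and > 0")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death); got: ",
         paste(unique(setdiff(event, c(0, 1))), collapse = ", "))
  covs <- list(...)
  df <- data.frame(sample = sample, time = time, event = event,
                   stringsAsFactors = FALSE)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  class(df) <- c("SurvivalTable", "data.frame")
  df
}

#' Construct a MAF-style mutation table
#'
#' Long-format records of somatic variants: one row per (sample, gene,
#' variant classification).
#'
#' @param sample,gene,variant_classification Character vectors of equal length.
#' @return A `data.frame` of class `MAFTable`.
#' @export
maf_table <- function(sample, gene, variant_classification) {
  df <- data.frame(sample = as.character(sample),
                   gene = as.character(gene),
                   variant_classification = as.character(variant_classification),
                   stringsAsFactors = FALSE)
  class(df) <- c("MAFTable", "data.frame")
  df
}

#' Read an expression matrix from disk
#'
#' Dense TSV (gene rows, sample columns, header row of sample ids, first
#' column gene symbols) or MatrixMarket triplet format with companion
#' one-column gene and barcode name files. Duplicate gene rows are collapsed
#' by their mean with a warning; duplicate sample ids are an error.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param space Expression space of the stored values.
#' @param genes_path,barcodes_path For `mtx_triplet`: name files; default
#'   `<path>.genes.txt` / `<path>.barcodes.txt`.
#' @param transpose Set when the TSV is stored samples-in-rows.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            space = c("log_normalized", "raw_counts"),
                            genes_path = NULL, barcodes_path = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  space <- match.arg(space)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 2L) stop("malformed expression TSV header in ", path,
                               ": need a gene column plus >=1 sample column")
    # validate the raw header: data.frame subsetting would mangle duplicates
    if (anyDuplicated(hdr[-1L]))
      stop("duplicate sample ids in ", path, ": ",
           paste(unique(hdr[-1L][duplicated(hdr[-1L])]), collapse = ", "))
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    colnames(m) <- hdr[-1L]
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      ij <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric expression value at gene row %d, sample column %d in %s",
                   ij[1L], ij[2L], path))
    }
    rownames(m) <- genes
  } else {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(barcodes_path)) barcodes_path <- paste0(path, ".barcodes.txt")
    if (!file.exists(genes_path)) stop("gene name file not found: ", genes_path)
    if (!file.exists(barcodes_path)) stop("barcode file not found: ", barcodes_path)
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(barcodes_path)
    if (nrow(m) != length(rownames(m)) || ncol(m) != length(colnames(m)))
      stop("name file lengths do not match matrix dimensions")
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    warning(sprintf("collapsing %d duplicate gene row(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
    first <- unique(rownames(m))
    counts <- table(rownames(m))
    summed <- rowsum(m, group = rownames(m))  # sorted by group name
    m <- summed / as.vector(counts[rownames(summed)])
    m <- m[first, , drop = FALSE]
  }
  expression_matrix(m, space = space)
}

#' Write an expression matrix as dense TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param digits Significant digits used for formatting.
#' @export
write_expression <- function(x, path, digits = 10) {
  df <- data.frame(gene = rownames(x),
                   signif(unclass(x), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated gene symbols.
#' Duplicate genes within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_signature()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d of %s: expected >=3 tab-separated fields, got %d",
                   i, path, length(f)))
    sets[[f[1L]]] <- gene_signature(f[1L], f[-(1:2)])
  }
  sets
}

#' Write signatures as GMT
#'
#' @param sigs A `GeneSignature` or list of them.
#' @param path Output path.
#' @param description Description field written on each line.
#' @export
write_gmt <- function(sigs, path, description = "na") {
  if (inherits(sigs, "GeneSignature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Requires columns `sample`, `time` (days) and `event` (0/1). Rows with
#' non-positive or missing time are dropped with a warning reporting the
#' count; any extra columns are kept as covariates.
#'
#' @param path Path to the TSV.
#' @return A [survival_table()].
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample", "time", "event")
  if (!all(req %in% names(df)))
    stop("survival TSV must contain columns {sample, time, event}; found: ",
         paste(names(df), collapse = ", "))
  bad <- !is.finite(df$time) | df$time <= 0
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with non-positive or missing time", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  extra <- setdiff(names(df), req)
  do.call(survival_table,
          c(list(sample = df$sample, time = df$time, event = df$event),
            as.list(df[extra])))
}

#' Write a survival table as TSV
#' @param x A `SurvivalTable`.
#' @param path Output path.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a MAF-style mutation table from TSV
#'
#' Requires columns `sample`, `gene`, `variant_classification`.
#'
#' @param path Path to the TSV.
#' @return A [maf_table()].
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample", "gene", "variant_classification")
  if (!all(req %in% names(df)))
    stop("MAF TSV must contain columns {sample, gene, variant_classification}; found: ",
         paste(names(df), collapse = ", "))
  maf_table(df$sample, df$gene, df$variant_classification)
}

#' Write a MAF-style table as TSV
#' @param x A `MAFTable`.
#' @param path Output path.
#' @export
write_maf <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
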