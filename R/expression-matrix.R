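#' Construct an expression matrix with sample metadata
#'
#' The central data container of the package: a dense gene x sample grid of
#' log2 expression values together with an optional per-sample metadata table
#' (genotype, treatment, clinical fields). Values are expected to already be
#' on the log2 scale; use [log2_transform()] if they are not.
#'
#' @param values numeric matrix, rows = genes, columns = samples. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids), and
#'   contain only finite values.
#' @param metadata optional `data.frame` of per-sample attributes. Either its
#'   rownames or a `sample_id` column must identify samples; every row must
#'   refer to a sample present in `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `metadata` (a data.frame keyed by sample id,
#'   possibly empty).
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' dim(m)
#' @export
expression_matrix <- function(values, metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have gene rownames and sample colnames")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values) || !all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = character(0))
  } else {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata)) {
      rownames(metadata) <- as.character(metadata$sample_id)
      metadata$sample_id <- NULL
    }
    unknown <- setdiff(rownames(metadata), samples)
    if (length(unknown))
      stop("metadata refers to unknown sample(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(values = values, metadata = metadata),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (ncol(x$metadata))
    cat("metadata fields:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param mat an `ExpressionMatrix`
#' @return character vector of ids, in matrix order.
#' @export
genes <- function(mat) rownames(mat$values)

#' @rdname genes
#' @export
samples <- function(mat) colnames(mat$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8 TSV whose header row is `gene_id` followed by sample ids,
#' and whose first column holds gene ids. Row and column order are preserved.
#' Malformed input (duplicate ids, non-numeric or empty cells) is an error
#' with coordinates rather than silently imputed.
#'
#' @param path file path.
#' @param metadata optional per-sample metadata `data.frame` (see
#'   [expression_matrix()]) or path to a metadata TSV readable by
#'   [read_sample_metadata()].
#' @return An `ExpressionMatrix`.
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path, metadata = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "")
  if (ncol(raw) < 2)
    stop("expression file needs a gene_id column plus at least one sample")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "non-numeric or empty cell '%s' at data row %d (gene '%s'), column '%s'",
      vals[i, j], i, gene_ids[i], sample_ids[j]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  expression_matrix(num, metadata)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: header `gene_id` plus sample ids, one
#' gene per row. Round-trips losslessly at full double precision.
#'
#' @param mat an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = genes(mat), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV keyed by a `sample_id` first column; remaining columns are arbitrary
#' attributes (genotype, treatment, clinical fields).
#'
#' @param path file path.
#' @return data.frame with sample ids as rownames.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!ncol(md)) stop("empty metadata file: ", path)
  ids <- as.character(md[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  md <- md[, -1, drop = FALSE]
  rownames(md) <- ids
  md
}

#' Write a sample metadata table as TSV
#' @param metadata data.frame keyed by sample-id rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform expression values
#'
#' Replaces every value v by log2(v + pseudocount), leaving metadata
#' untouched. All shifted values must be strictly positive.
#'
#' @param mat an `ExpressionMatrix` on the linear scale.
#' @param pseudocount nonnegative offset added before taking logs.
#' @return An `ExpressionMatrix` of log2 values.
#' @export
log2_transform <- function(mat, pseudocount = 0) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("`pseudocount` must be a single nonnegative number")
  shifted <- mat$values + pseudocount
  if (any(shifted <= 0))
    stop("log2_transform: value + pseudocount <= 0 for ",
         sum(shifted <= 0), " cell(s)")
  out <- mat
  out$values <- log2(shifted)
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the same empirical distribution: the
#' per-rank mean across columns. Within-column ranks are preserved; tied
#' values receive the mean of the reference values spanning their tied ranks.
#'
#' @param mat an `ExpressionMatrix` with at least two samples.
#' @return An `ExpressionMatrix` with identical column value multisets
#'   (exactly identical when no column has ties).
#' @export
quantile_normalize <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  x <- mat$values
  if (ncol(x) < 2)
    stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort, method = "quick"))
  cs <- c(0, cumsum(ref))
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- rank(x[, j], ties.method = "min")
    hi <- rank(x[, j], ties.method = "max")
    # mean of reference values across each tied rank span
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  res <- mat
  res$values <- out
  res
}
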