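#' Feature table constructor
#'
#' A feature table is a samples x features matrix of non-negative counts
#' (taxa) or non-negative real abundances (transcripts), with unique sample
#' ids as row names and unique feature ids as column names.
#'
#' @param counts numeric matrix, samples in rows.
#' @param kind `"taxa"` (integer counts required) or `"transcripts"`.
#' @return a `feature_table`: the validated matrix with a `kind` attribute.
#' @export
feature_table <- function(counts, kind = c("taxa", "transcripts")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table needs sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate feature ids")
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    stop("feature table values must be finite numbers")
  if (any(counts < 0)) stop("feature table contains negative values")
  if (kind == "taxa") {
    if (any(counts != round(counts)))
      stop("taxa counts must be integers")
    storage.mode(counts) <- "double"
  }
  structure(counts, class = c("feature_table", "matrix", "array"), kind = kind)
}

ft_kind <- function(x) attr(x, "kind") %||% "taxa"

# plain matrix view (drops the class so matrix ops behave normally)
ft_mat <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  m
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d samples x %d features, total %s\n",
              ft_kind(x), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

.META_LEVELS <- list(
  tolerance   = c("resistant", "sensitive"),
  temperature = c("warm24", "cold12"),
  part        = c("anterior", "posterior")
)
.META_COLS <- c("sample_id", "tolerance", "temperature", "family", "part", "fish")

#' Sample metadata constructor
#'
#' Per-sample experimental factors: tolerance group (resistant/sensitive),
#' temperature arm (warm24/cold12), family, gut part (anterior/posterior)
#' and fish id. Factor levels outside the declared sets are rejected.
#'
#' @param df data.frame with columns `sample_id`, `tolerance`, `temperature`,
#'   `family`, `part`, `fish`.
#' @return validated `sample_metadata` data.frame keyed by `sample_id`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(.META_COLS, names(df))
  if (length(missing))
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[.META_COLS]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in metadata")
  for (col in names(.META_LEVELS)) {
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals), .META_LEVELS[[col]])
    if (length(bad))
      stop(sprintf("undeclared %s level(s): %s", col, paste(bad, collapse = ", ")))
    df[[col]] <- factor(vals, levels = .META_LEVELS[[col]])
  }
  df$family <- factor(as.character(df$family))
  df$fish <- as.character(df$fish)
  rownames(df) <- df$sample_id
  class(df) <- c("sample_metadata", "data.frame")
  df
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Read a feature table from TSV
#'
#' The canonical layout has samples as rows with ids in the first column;
#' `features_as_rows` reads the transposed layout. Lines starting with `#`
#' are ignored.
#'
#' @param path TSV file path.
#' @param orientation matrix layout in the file.
#' @param kind passed to [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               kind = c("taxa", "transcripts")) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("feature table TSV needs an id column plus data")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric cell(s) in ", path)
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  feature_table(m, kind = kind)
}

#' Write a feature table to TSV
#' @param table a [feature_table()] (or matrix).
#' @param path output path.
#' @param orientation layout to write.
#' @export
write_feature_table <- function(table, path,
                                orientation = c("samples_as_rows",
                                                "features_as_rows")) {
  orientation <- match.arg(orientation)
  m <- ft_mat(table)
  if (orientation == "features_as_rows") m <- t(m)
  id_col <- if (orientation == "samples_as_rows") "sample_id" else "feature_id"
  df <- data.frame(m[, 0, drop = FALSE], id = rownames(m), m,
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, tolerance, temperature, family,
#'   part, fish.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path) {
  sample_metadata(.read_tsv(path))
}

#' Write sample metadata to TSV
#' @param meta a [sample_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a normalized expression matrix (samples as rows) from TSV
#' @param path TSV path.
#' @return numeric matrix, samples x transcripts.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[-1])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("expression values must be finite numbers")
  if (any(m < 0)) stop("negative expression values")
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#' @param expr samples x transcripts matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a feature table and metadata on their shared samples
#'
#' Restricts both inputs to the intersection of sample ids in a single
#' canonical (lexicographic) order, so downstream permutation streams see the
#' same sample order regardless of input file order.
#'
#' @param table a [feature_table()] or expression matrix.
#' @param meta a [sample_metadata()].
#' @return list with `table`, `meta`, and `dropped` (ids present in only one
#'   input).
#' @export
align_tables <- function(table, meta) {
  tids <- rownames(table)
  mids <- meta$sample_id
  shared <- sort(intersect(tids, mids), method = "radix")
  if (!length(shared)) stop("no shared sample ids between table and metadata")
  dropped <- sort(c(setdiff(tids, mids), setdiff(mids, tids)), method = "radix")
  if (length(dropped))
    message("align_tables: dropped ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...")
  tab <- table[shared, , drop = FALSE]
  if (inherits(table, "feature_table"))
    tab <- feature_table(tab, kind = ft_kind(table))
  m <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(m) <- m$sample_id
  class(m) <- class(meta)
  list(table = tab, meta = m, dropped = dropped)
}
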