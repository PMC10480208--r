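#' Construct a relative-abundance table
#'
#' The central container of the package: a numeric samples x taxa matrix of
#' relative abundances (fractions). Rows are samples, columns are taxa; both
#' must carry unique identifiers. Each row must sum to 1 within `tol`.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, with
#'   rownames (sample ids) and colnames (taxon ids).
#' @param tol tolerance on the row-sum closure check.
#' @return the validated matrix with class `"abundance_table"`.
#' @export
abundance_table <- function(values, tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance table needs sample ids (rownames) and taxon ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative")
  rs <- rowSums(values)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("rows do not sum to 1 (+/- ", tol, "): ",
         paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' Coerce to an abundance table, renormalizing if requested
#'
#' @param x matrix or data.frame of non-negative values.
#' @param renormalize divide each row by its sum first (e.g. for count input).
#' @return an [abundance_table()].
#' @export
as_abundance_table <- function(x, renormalize = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (inherits(x, "abundance_table") && !renormalize) return(x)
  if (renormalize) {
    rs <- rowSums(x)
    if (any(rs <= 0)) stop("cannot renormalize: sample(s) with zero total")
    x <- sweep(x, 1, rs, "/")
  }
  abundance_table(unclass(x))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n", nrow(x), ncol(x)))
  cat("samples:", paste(utils::head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) "..." else "", "\n")
  cat("taxa:   ", paste(utils::head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) "..." else "", "\n")
  invisible(x)
}

# ---- generic delimited I/O (shared dialect: UTF-8, header row, id first) ----

#' Read a delimited table with strict dialect checks
#'
#' Shared reader for the package's TSV/CSV dialect: UTF-8, header row,
#' identifier in the first column. Ragged rows, duplicate ids and missing
#' headers raise informative errors with line numbers.
#'
#' @param path file path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @param row_ids use the first column as row names.
#' @return data.frame (with row names if `row_ids`).
#' @export
read_table <- function(path, sep = "\t", row_ids = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0) stop("empty file: ", path)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  lines <- readLines(path, n = 50, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no data rows in ", path)
  hdr <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (all(!is.na(suppressWarnings(as.numeric(hdr)))))
    stop("missing header row in ", path, " (first line is all-numeric)")
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          comment.char = "#")
  if (row_ids) {
    ids <- as.character(df[[1]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicate id(s) in ", path, ": ",
                          paste(dup, collapse = ", "))
    rownames(df) <- ids
    df[[1]] <- NULL
  }
  df
}

#' Write a table in the package dialect
#'
#' Numeric values are written at full precision (1e-15 relative) so that a
#' write/read round trip is lossless.
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param sep field separator.
#' @param id_name header name for the identifier column (row names).
#' @param provenance optional string written as a leading `#` comment line
#'   (e.g. seed and parameter hash); readers skip it.
#' @export
write_table <- function(x, path, sep = "\t", id_name = "id",
                        provenance = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  out <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                               id_name), df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17, format = "g"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' Expects samples in rows (first column `sample_id`), taxa in columns.
#'
#' @param path TSV path.
#' @param renormalize renormalize rows to sum to 1 (for count tables).
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, renormalize = FALSE) {
  df <- read_table(path, sep = "\t", row_ids = TRUE)
  as_abundance_table(as.matrix(df), renormalize = renormalize)
}

#' Write an abundance table to TSV
#' @param table an [abundance_table()].
#' @param path output path.
#' @export
write_abundance <- function(table, path) {
  write_table(unclass(table), path, id_name = "sample_id")
}

#' Read sample metadata from TSV
#'
#' First column `sample_id`; must include `pile`, `day`, `temperature`;
#' any further numeric columns are treated as nutrient covariates.
#'
#' @param path TSV path.
#' @return data.frame with sample ids as row names.
#' @export
read_metadata <- function(path) {
  df <- read_table(path, sep = "\t", row_ids = TRUE)
  need <- setdiff(c("pile", "day", "temperature"), names(df))
  if (length(need)) stop("metadata missing column(s): ", paste(need, collapse = ", "))
  if (any(!is.finite(df$temperature))) stop("non-finite temperature in metadata")
  df
}

# internal: align metadata rows to a table's samples
align_metadata <- function(table, metadata) {
  miss <- setdiff(rownames(table), rownames(metadata))
  if (length(miss))
    stop("samples absent from metadata: ", paste(utils::head(miss, 5), collapse = ", "))
  metadata[rownames(table), , drop = FALSE]
}
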