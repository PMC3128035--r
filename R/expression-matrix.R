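#' Expression matrix container
#'
#' A light-weight container for probes-by-samples expression values together
#' with the per-sample metadata needed by the two-class ranking methods:
#' sample type (A/B/C/D in the titration design), test site, and platform.
#' Values carry a scale flag so that operations defined on the natural scale
#' (duplicate-probe averaging, floor substitution) and on the log2 scale
#' (the ranking statistics) can enforce their preconditions.
#'
#' @param values numeric matrix, probes in rows, samples in columns. No
#'   missing values are permitted: loaders reject matrices with gaps rather
#'   than imputing.
#' @param probe_ids character vector of probe identifiers, one per row.
#'   Duplicates are allowed (they occur on GEH-like platforms) until
#'   [average_duplicate_probes()] is applied.
#' @param metadata data frame with one row per sample and columns
#'   `sample_id`, `type`, `site`, `platform`.
#' @param scale either `"natural"` or `"log2"`.
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              metadata = NULL, scale = c("log2", "natural")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("values must be a numeric matrix")
  if (anyNA(values))
    stop_input("expression values contain missing entries; gaps are not permitted")
  if (is.null(probe_ids))
    probe_ids <- sprintf("probe_%06d", seq_len(nrow(values)))
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) != nrow(values))
    stop_input("probe_ids length does not match row count")
  sample_ids <- colnames(values)
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample_%03d", seq_len(ncol(values)))
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sample_ids, type = NA_character_,
                           site = NA_character_, platform = NA_character_,
                           stringsAsFactors = FALSE)
  }
  required <- c("sample_id", "type", "site", "platform")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop_input("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!identical(as.character(metadata$sample_id), as.character(sample_ids)))
    stop_input("metadata sample_id must match matrix columns in order")
  if (scale == "natural" && any(values < 0))
    stop_input("natural-scale intensities must be nonnegative")
  dimnames(values) <- list(NULL, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = as.character(sample_ids),
                 metadata = metadata, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$metadata$type, useNA = "no")
  if (length(tab))
    cat("sample types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Convert a log2 matrix back to the natural scale
#'
#' Inverse of [log2_transform()]; used when duplicate-probe averaging (a
#' natural-scale operation) must be applied to data stored as log2 signals.
#'
#' @param x an `ExpressionMatrix` on the log2 scale.
#' @return the matrix on the natural scale.
#' @export
to_natural_scale <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "natural") return(x)
  x$values <- 2^x$values
  x$scale <- "natural"
  x
}

#' Read / write expression matrices as TSV
#'
#' The interchange format is a tab-separated table whose first column holds
#' probe IDs and whose remaining columns hold one sample each, plus a
#' sidecar metadata TSV with columns sample_id, type, site, platform.
#'
#' @param path expression TSV path.
#' @param metadata_path sample metadata TSV path (optional for reading).
#' @param scale scale flag of the stored values.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, metadata_path = NULL,
                                scale = c("log2", "natural")) {
  scale <- match.arg(scale)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop_input("non-numeric expression values in ", path)
  if (anyNA(values)) stop_input("missing values in ", path, "; gaps are not permitted")
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read.delim(metadata_path, stringsAsFactors = FALSE)
    metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  }
  expression_matrix(values, probe_ids, metadata, scale)
}

#' @rdname read_expression_tsv
#' @param x an `ExpressionMatrix` to write.
#' @export
write_expression_tsv <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(probe_id = x$probe_ids, x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
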