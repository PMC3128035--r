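#' Average rows that share a probe ID
#'
#' GEH-like platforms print some probes several times under one ID; their
#' signals are combined by the arithmetic mean per sample, on the natural
#' intensity scale.  Row order of the result follows first occurrence of
#' each ID.  The operation is idempotent.
#'
#' @param x an `ExpressionMatrix` on the natural scale (use
#'   [to_natural_scale()] first if needed; pass `check_scale = FALSE` to
#'   average log2 data deliberately).
#' @param check_scale enforce the natural-scale precondition.
#' @return an `ExpressionMatrix` with unique probe IDs.
#' @export
average_duplicate_probes <- function(x, check_scale = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (check_scale && x$scale != "natural")
    stop_input("duplicate-probe averaging is defined on the natural scale; ",
               "convert with to_natural_scale() or set check_scale = FALSE")
  if (!anyDuplicated(x$probe_ids)) return(x)
  f <- factor(x$probe_ids, levels = unique(x$probe_ids))
  sums <- rowsum(x$values, f, reorder = FALSE)
  counts <- as.vector(table(f))
  x$values <- sums / counts
  x$probe_ids <- levels(f)
  dimnames(x$values) <- list(NULL, x$sample_ids)
  x
}

#' Substitute a floor value for weak signals
#'
#' Every natural-scale intensity below `floor` is set to `floor` (the
#' benchmark preprocessing used 0.169 for GEH data); the replacement count
#' is reported via `message()` and attached as attribute `n_floored`.
#'
#' @param x an `ExpressionMatrix` on the natural scale.
#' @param floor positive floor intensity.
#' @param quiet suppress the log message.
#' @return the floored `ExpressionMatrix`.
#' @export
floor_values <- function(x, floor = 0.169, quiet = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) || floor <= 0)
    stop_input("floor must be a single positive number")
  if (x$scale != "natural")
    stop_input("floor substitution is defined on the natural scale")
  n <- sum(x$values < floor)
  x$values[x$values < floor] <- floor
  if (!quiet)
    message(sprintf("floor_values: replaced %d of %d signals (%.2f%%) with %.4g",
                    n, length(x$values), 100 * n / length(x$values), floor))
  attr(x, "n_floored") <- n
  x
}

#' Log2-transform a natural-scale matrix
#'
#' @param x an `ExpressionMatrix` on the natural scale with strictly
#'   positive values (apply [floor_values()] first).
#' @return the matrix on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "natural")
    stop_input("matrix is already on the log2 scale")
  if (any(x$values <= 0))
    stop_input("nonpositive values present; apply floor_values() before log2")
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Clean a probe-to-gene annotation map
#'
#' Drops rows with missing fields, removes exact duplicates, and discards
#' probes associated with more than one symbol, so that each retained probe
#' maps to exactly one gene (multi-mapping probes would double-count in
#' enrichment).
#'
#' @param map data frame whose first two columns are probe ID and gene
#'   symbol.
#' @return a cleaned two-column data frame `probe_id`, `gene`.
#' @export
clean_probe_gene_map <- function(map) {
  if (!is.data.frame(map) || ncol(map) < 2L)
    stop_input("map must be a data frame with probe and gene columns")
  map <- data.frame(probe_id = as.character(map[[1L]]),
                    gene = as.character(map[[2L]]), stringsAsFactors = FALSE)
  map <- map[!is.na(map$probe_id) & !is.na(map$gene) &
               nzchar(map$probe_id) & nzchar(map$gene), , drop = FALSE]
  map <- unique(map)
  multi <- unique(map$probe_id[duplicated(map$probe_id)])
  map <- map[!map$probe_id %in% multi, , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Collapse probe-level signals to gene level
#'
#' Averages the log2 signals of all probes mapped to the same gene symbol,
#' per sample.  Probes absent from the (cleaned) map are dropped; gene row
#' order follows the first occurrence of each gene among the retained
#' probes.
#'
#' @param x an `ExpressionMatrix` on the log2 scale with unique probe IDs.
#' @param map a probe-to-gene map (cleaned with [clean_probe_gene_map()]).
#' @param check_scale enforce the log2-scale precondition.
#' @return a gene-level `ExpressionMatrix` (row identifiers are symbols).
#' @export
collapse_probes_to_genes <- function(x, map, check_scale = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (check_scale && x$scale != "log2")
    stop_input("probe collapsing is defined on the log2 scale")
  map <- clean_probe_gene_map(map)
  if (anyDuplicated(x$probe_ids))
    stop_input("duplicate probe IDs present; run average_duplicate_probes() first")
  idx <- match(x$probe_ids, map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep))
    stop_input("no probes in the matrix are present in the annotation map")
  genes <- map$gene[idx[keep]]
  vals <- x$values[keep, , drop = FALSE]
  f <- factor(genes, levels = unique(genes))
  sums <- rowsum(vals, f, reorder = FALSE)
  counts <- as.vector(table(f))
  x$values <- sums / counts
  x$probe_ids <- levels(f)
  dimnames(x$values) <- list(NULL, x$sample_ids)
  x
}
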