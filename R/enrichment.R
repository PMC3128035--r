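#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member symbols.
#'
#' @param path file path.
#' @return for `read_gmt`, a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop_input("malformed GMT line: ", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop_input("duplicate set names in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("synthetic", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Rank-average enrichment score of one gene set
#'
#' The arithmetic mean of the ranks of the set's member genes in a
#' gene-level ranked list (average-rank tie mode): a set whose three
#' members sit at ranks 2, 8 and 14 scores (2+8+14)/3 = 8.  Small values
#' indicate enrichment.  The set is first intersected with the measured
#' genes; an empty intersection yields `NA` (an excluded set, not an
#' error).
#'
#' @param ranked a gene-level `RankedList` (after probe collapsing).
#' @param set character vector of gene symbols.
#' @return the score `E_G` in \[1, m\], or `NA` for an excluded set.
#' @export
enrichment_score <- function(ranked, set) {
  idx <- match(unique(set), ranked$probe_id)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NA_real_)
  mean(ranked$rank[idx])
}

#' Score a gene-set collection against a ranked list
#'
#' @param ranked a gene-level `RankedList`.
#' @param sets named list of gene sets.
#' @param min_size minimum post-intersection size for a set to be scored.
#' @param label list label in "Method_Comparison_Site" form.
#' @return an `EnrichmentTable` data frame (set, n_genes, e_g) with
#'   excluded sets recorded in attribute `excluded`.
#' @export
score_gene_sets <- function(ranked, sets, min_size = 1L, label = NULL) {
  if (is.null(names(sets))) stop_input("gene sets must be named")
  n_genes <- vapply(sets, function(s)
    sum(unique(s) %in% ranked$probe_id), integer(1))
  e_g <- vapply(sets, enrichment_score, numeric(1), ranked = ranked)
  keep <- n_genes >= min_size & !is.na(e_g)
  out <- data.frame(set = names(sets)[keep], n_genes = n_genes[keep],
                    e_g = e_g[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, excluded = names(sets)[!keep], label = label,
            class = c("EnrichmentTable", "data.frame"))
}

#' Rank gene sets by enrichment score
#'
#' Orders sets ascending by `E_G` with a stable set-name tie-break, and
#' attaches average-tie ranks so the set-level ranking can feed [pog()]
#' and [spearman_lists()] over the set universe.
#'
#' @param etable an `EnrichmentTable` from [score_gene_sets()].
#' @return a `RankedList` over set names, ordered most-enriched first.
#' @export
rank_gene_sets <- function(etable) {
  stopifnot(inherits(etable, "EnrichmentTable"))
  ord <- order(etable$e_g, etable$set)
  out <- data.frame(probe_id = etable$set[ord],
                    statistic = etable$e_g[ord],
                    rank = rank(etable$e_g, ties.method = "average")[ord],
                    stringsAsFactors = FALSE)
  structure(out, method = "E_G", ties = "average",
            class = c("RankedList", "data.frame"))
}

#' Intersection-union ratio of a gene set across platforms
#'
#' For one named set realized on several platforms (its membership
#' intersected with each platform's measured genes), the ratio
#' `|intersection across platforms| / |union across platforms|`: 1 for
#' identical realizations, 0 for disjoint ones.
#'
#' @param memberships list (length >= 2) of character vectors, one per
#'   platform.
#' @return ratio in \[0, 1\].
#' @export
iu_ratio <- function(memberships) {
  if (!is.list(memberships) || length(memberships) < 2L)
    stop_input("iu_ratio needs memberships from at least two platforms")
  memberships <- lapply(memberships, unique)
  u <- Reduce(union, memberships)
  if (!length(u)) stop_input("empty union across platforms")
  length(Reduce(intersect, memberships)) / length(u)
}
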