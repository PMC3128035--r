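#' Area under the ROC curve for a ranked list against a truth set
#'
#' The probability that a randomly chosen true DEG outranks a randomly
#' chosen non-DEG, with ties counted 1/2 (rank-sum formulation).
#' Evaluation is restricted to list entries matched to the truth set:
#' directly by identifier, or through a probe-to-gene map when the list is
#' probe-level and the truth is gene-level (each probe inherits its gene's
#' label).
#'
#' @param ranked a `RankedList` (average-rank tie mode recommended).
#' @param truth a `TruthSet` from [define_truth()], or any data frame with
#'   columns `gene` and `is_deg`.
#' @param map optional probe-to-gene map for label inheritance.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(ranked, truth, map = NULL) {
  label <- attr(truth, "label") %||% "truth"
  ids <- ranked$probe_id
  if (!is.null(map)) {
    map <- clean_probe_gene_map(map)
    gene_of <- map$gene[match(ids, map$probe_id)]
  } else {
    gene_of <- ids
  }
  lab <- truth$is_deg[match(gene_of, truth$gene)]
  keep <- !is.na(lab)
  if (!any(keep))
    stop_input("no list entries match truth set '", label, "'")
  lab <- lab[keep]
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L)
    stop_input("truth set '", label, "' has an empty DEG or non-DEG class ",
               "among matched entries")
  # goodness = -rank; re-rank within the matched subset with average ties
  rr <- rank(-ranked$rank[keep], ties.method = "average")
  (sum(rr[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_common_universe <- function(lists) {
  ids <- sort(lists[[1L]]$probe_id)
  for (l in lists[-1L]) {
    if (!identical(sort(l$probe_id), ids))
      stop_input("ranked lists are not over a common universe")
  }
  invisible(ids)
}

#' Percentage of overlapping genes (POG)
#'
#' `100 * |intersection of the top-X sets of all lists| / X`, the
#' reproducibility of the top of several ranked lists over a common
#' universe.  Top-X sets use the stable truncation tie rule
#' (rank, then identifier).
#'
#' @param lists a list of two or more `RankedList`s over one universe.
#' @param x top-list size X.
#' @return POG in \[0, 100\].
#' @export
pog <- function(lists, x) {
  if (!is.list(lists) || length(lists) < 2L)
    stop_input("pog needs at least two ranked lists")
  check_common_universe(lists)
  if (x > nrow(lists[[1L]])) stop_input("X exceeds the universe size")
  tops <- lapply(lists, top_x_ids, x = x)
  100 * length(Reduce(intersect, tops)) / x
}

#' Spearman correlation of two ranked lists
#'
#' The Pearson correlation of the two rank vectors (average-rank tie
#' mode), matched by identifier over a common universe.
#'
#' @param list1,list2 `RankedList`s over one universe.
#' @return correlation in \[-1, 1\].
#' @export
spearman_lists <- function(list1, list2) {
  check_common_universe(list(list1, list2))
  r1 <- list1$rank
  r2 <- list2$rank[match(list1$probe_id, list2$probe_id)]
  if (sd(r1) == 0 || sd(r2) == 0)
    stop_input("constant rank vector; Spearman correlation undefined")
  cor(r1, r2)
}

hclust_to_newick <- function(hc, digits = 6) {
  recurse <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%s", hc$labels[-node],
              format(parent_height, digits = digits, trim = TRUE))
    } else {
      h <- hc$height[node]
      kids <- vapply(hc$merge[node, ], recurse, character(1), parent_height = h)
      sprintf("(%s,%s):%s", kids[1], kids[2],
              format(max(parent_height - h, 0), digits = digits, trim = TRUE))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  kids <- vapply(hc$merge[root, ], recurse, character(1), parent_height = h)
  sprintf("(%s,%s);", kids[1], kids[2])
}

#' Average-linkage clustering of ranked lists
#'
#' Computes Spearman correlations between all pairs of lists, converts
#' them to distances `d = 1 - rho`, and agglomerates by average linkage.
#' The labels are expected in "Method_Comparison_Site" form so the merge
#' tree mirrors the reproducibility structure of the lists.
#'
#' @param lists a named list of two or more `RankedList`s over one
#'   universe.
#' @return a list with `hclust` (the stats::hclust object), `distance`
#'   (the 1 - rho matrix), `merge`, `height`, and `newick` (text
#'   rendering of the dendrogram).
#' @export
cluster_lists <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop_input("cluster_lists needs at least two ranked lists")
  if (is.null(names(lists)))
    names(lists) <- sprintf("list%d", seq_along(lists))
  check_common_universe(lists)
  k <- length(lists)
  rho <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      rho[i, j] <- rho[j, i] <- spearman_lists(lists[[i]], lists[[j]])
    }
  }
  dimnames(rho) <- list(names(lists), names(lists))
  d <- 1 - rho
  hc <- hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, distance = d, merge = hc$merge, height = hc$height,
       newick = hclust_to_newick(hc))
}
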