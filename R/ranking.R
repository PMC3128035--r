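#' Two-class design from sample metadata
#'
#' Binds a comparison label such as "A versus B" to column indices:
#' `class1` is the first-listed sample type and all statistics are oriented
#' class2 minus class1.
#'
#' @param x an `ExpressionMatrix`.
#' @param class1,class2 sample types (values of `metadata$type`).
#' @param site optional site filter; when given, only that site's samples
#'   enter the design.
#' @param min_reps minimum replicates required per class.
#' @return a `class_design` list with `idx1`, `idx2`, `n1`, `n2`,
#'   `comparison`.
#' @export
class_design <- function(x, class1, class2, site = NULL, min_reps = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  meta <- x$metadata
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(site)) keep <- meta$site == site
  idx1 <- which(keep & meta$type == class1)
  idx2 <- which(keep & meta$type == class2)
  if (length(idx1) < min_reps || length(idx2) < min_reps)
    stop_input(sprintf("class design %s vs %s needs >= %d samples per class (found %d and %d)",
                       class1, class2, min_reps, length(idx1), length(idx2)))
  structure(list(idx1 = idx1, idx2 = idx2,
                 n1 = length(idx1), n2 = length(idx2),
                 comparison = paste0(class1, class2)),
            class = "class_design")
}

new_score_table <- function(df, method, ordering) {
  stopifnot(ordering %in% c("descending_abs", "ascending"))
  if (any(!is.finite(df$statistic)))
    stop_input("non-finite statistic produced by ", method)
  structure(df, method = method, ordering = ordering,
            class = c("ScoreTable", "data.frame"))
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable: %s (%d probes, ordering %s)\n",
              attr(x, "method"), nrow(x), attr(x, "ordering")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

require_log2 <- function(x) {
  if (x$scale != "log2")
    stop_input("ranking statistics are defined on log2 data")
  invisible(x)
}

class_means <- function(x, design) {
  list(m1 = rowMeans(x$values[, design$idx1, drop = FALSE]),
       m2 = rowMeans(x$values[, design$idx2, drop = FALSE]))
}

#' Average difference (AD) statistic
#'
#' The difference of class means on the log2 scale (class2 minus class1),
#' i.e. the log fold-change of geometric means.  Genes are ranked in
#' descending order of the absolute value.
#'
#' @param x an `ExpressionMatrix` on the log2 scale.
#' @param design a [class_design()].
#' @return a `ScoreTable`.
#' @export
ad_statistic <- function(x, design) {
  require_log2(x)
  m <- class_means(x, design)
  new_score_table(data.frame(probe_id = x$probe_ids,
                             statistic = m$m2 - m$m1,
                             stringsAsFactors = FALSE),
                  "AD", "descending_abs")
}

#' Fold change (FC) statistic
#'
#' The log2 ratio of natural-scale arithmetic class means.  Distinct from
#' AD (which is the ratio of geometric means) but typically nearly
#' collinear with it; the two coincide exactly on constant replicates.
#'
#' @inheritParams ad_statistic
#' @return a `ScoreTable`.
#' @export
fc_statistic <- function(x, design) {
  require_log2(x)
  nat <- 2^x$values
  s <- log2(rowMeans(nat[, design$idx2, drop = FALSE]) /
              rowMeans(nat[, design$idx1, drop = FALSE]))
  new_score_table(data.frame(probe_id = x$probe_ids, statistic = s,
                             stringsAsFactors = FALSE),
                  "FC", "descending_abs")
}

#' Weighted average difference (WAD) statistic
#'
#' AD multiplied by a weight `w`, the relative average signal intensity:
#' the mean log2 signal of each probe over all samples of both classes,
#' min-max normalized across probes to \[0, 1\].  High-signal genes are
#' up-weighted, which suppresses the noisy low-intensity regime.
#'
#' @inheritParams ad_statistic
#' @return a `ScoreTable` with auxiliary column `weight`.
#' @export
wad_statistic <- function(x, design) {
  require_log2(x)
  if (nrow(x$values) < 2L)
    stop_input("WAD needs at least two probes for min-max normalization")
  m <- class_means(x, design)
  ad <- m$m2 - m$m1
  xbar <- rowMeans(x$values[, c(design$idx1, design$idx2), drop = FALSE])
  rng <- range(xbar)
  if (rng[1] == rng[2])
    stop_input("all probe mean intensities equal; WAD weight undefined")
  w <- (xbar - rng[1]) / (rng[2] - rng[1])
  new_score_table(data.frame(probe_id = x$probe_ids, statistic = ad * w,
                             weight = w, stringsAsFactors = FALSE),
                  "WAD", "descending_abs")
}

#' Rank products (RP) statistic
#'
#' For each of the `n1 x n2` between-class sample pairs the pairwise log2
#' difference (class2 minus class1) is ranked across genes twice: rank 1 =
#' most up-regulated for the up list, rank 1 = most down-regulated for the
#' down list.  `RP_up` and `RP_down` are the geometric means of those ranks
#' over all pairs, and the net value is their minimum; genes are ranked in
#' ascending order of the net value.
#'
#' @inheritParams ad_statistic
#' @return a `ScoreTable` (ordering `ascending`) with auxiliary columns
#'   `rp_up` and `rp_down`.
#' @export
rank_products <- function(x, design) {
  require_log2(x)
  m <- nrow(x$values)
  log_up <- numeric(m)
  log_down <- numeric(m)
  n_pairs <- design$n1 * design$n2
  for (i in design$idx1) {
    for (j in design$idx2) {
      d <- x$values[, j] - x$values[, i]
      r_up <- rank(-d, ties.method = "average")
      log_up <- log_up + log(r_up)
      log_down <- log_down + log(m + 1 - r_up)
    }
  }
  rp_up <- exp(log_up / n_pairs)
  rp_down <- exp(log_down / n_pairs)
  new_score_table(data.frame(probe_id = x$probe_ids,
                             statistic = pmin(rp_up, rp_down),
                             rp_up = rp_up, rp_down = rp_down,
                             stringsAsFactors = FALSE),
                  "RP", "ascending")
}

#' Rank a score table
#'
#' Converts statistics into ranks (1 = strongest evidence of differential
#' expression) under the table's ordering convention: descending absolute
#' value for AD/FC/WAD and the t family, ascending net value for RP.  Two
#' tie modes are provided because downstream consumers differ: average
#' ranks feed Spearman correlation and the enrichment score, while a stable
#' probe-ID tie-break gives the deterministic top-X sets needed for POG.
#'
#' @param scores a `ScoreTable`.
#' @param ties `"average"` or `"first"` (stable probe-ID order).
#' @return a `RankedList` data frame with columns `probe_id`, `statistic`,
#'   `rank`.
#' @export
rank_genes <- function(scores, ties = c("average", "first")) {
  ties <- match.arg(ties)
  stopifnot(inherits(scores, "ScoreTable"))
  key <- if (attr(scores, "ordering") == "descending_abs")
    -abs(scores$statistic) else scores$statistic
  if (ties == "average") {
    r <- rank(key, ties.method = "average")
  } else {
    ord <- order(key, scores$probe_id)
    r <- integer(length(key))
    r[ord] <- seq_along(key)
  }
  structure(data.frame(probe_id = scores$probe_id,
                       statistic = scores$statistic, rank = r,
                       stringsAsFactors = FALSE),
            method = attr(scores, "method"), ties = ties,
            class = c("RankedList", "data.frame"))
}

#' Top-X identifiers of a ranked list
#'
#' Uses the stable truncation order (rank, then probe ID) so tied
#' statistics at the boundary resolve deterministically.
#'
#' @param ranked a `RankedList`.
#' @param x number of top entries.
#' @return character vector of `x` identifiers.
#' @export
top_x_ids <- function(ranked, x) {
  if (x > nrow(ranked)) stop_input("X exceeds the list length")
  ranked$probe_id[order(ranked$rank, ranked$probe_id)][seq_len(x)]
}
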