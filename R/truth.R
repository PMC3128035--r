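#' Two-sample t-test p-values per gene
#'
#' Pooled-variance (Student) two-sided two-sample t-test, vectorized over
#' genes; Welch's unequal-variance form is available behind a flag.  When a
#' gene has zero variance in both classes the p-value is defined by the
#' zero/nonzero difference convention: 1 if the class means are equal,
#' 0 otherwise (logged via `message()`).
#'
#' @param x an `ExpressionMatrix` on the log2 scale (RT-PCR-style table).
#' @param design a [class_design()] with at least two replicates per class.
#' @param var_equal pooled Student t (default) or Welch.
#' @return numeric vector of p-values named by row identifier.
#' @export
two_sample_t_pvalues <- function(x, design, var_equal = TRUE) {
  require_log2(x)
  require_t_design(design)
  pm <- pooled_moments(x, design)
  v1 <- rowSums((pm$x1 - pm$m1)^2) / (design$n1 - 1L)
  v2 <- rowSums((pm$x2 - pm$m2)^2) / (design$n2 - 1L)
  if (var_equal) {
    se <- sqrt(pm$s2 * pm$c2)
    df <- rep(pm$df, length(se))
  } else {
    se <- sqrt(v1 / design$n1 + v2 / design$n2)
    w1 <- v1 / design$n1
    w2 <- v2 / design$n2
    df <- (w1 + w2)^2 / (w1^2 / (design$n1 - 1L) + w2^2 / (design$n2 - 1L))
  }
  p <- rep(NA_real_, length(se))
  degenerate <- se == 0
  if (any(degenerate)) {
    message(sprintf("two_sample_t_pvalues: %d gene(s) with zero variance in both classes",
                    sum(degenerate)))
    p[degenerate] <- ifelse(pm$diff[degenerate] == 0, 1, 0)
  }
  ok <- !degenerate
  p[ok] <- 2 * pt(-abs(pm$diff[ok] / se[ok]), df = df[ok])
  setNames(p, x$probe_ids)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are monotone nondecreasing in the raw p-values, each at
#' least its raw p, and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return FDR-adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_input("p-values must be numbers in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}

#' Define a "true" DEG set from RT-PCR-style data
#'
#' Three rules are supported, matching the reference-assay conventions:
#' `fdr` selects genes with Benjamini-Hochberg FDR strictly below the
#' threshold (t-test on log2 data); `ad` selects genes with absolute
#' average difference strictly above the threshold; `topx` takes the top
#' `threshold` genes by the stated key family — smallest p-value for
#' FDR-flavored truth, largest absolute AD for AD-flavored truth — with a
#' stable gene-ID tie-break.
#'
#' @param x RT-PCR-style `ExpressionMatrix` (rows are genes).
#' @param design a [class_design()].
#' @param metric `"fdr"`, `"ad"` or `"topx"`.
#' @param threshold alpha for `fdr`, cutoff for `ad`, X for `topx`.
#' @param topx_key key family for `topx`: `"fdr"` or `"ad"`.
#' @param label provenance tag; defaults to
#'   `"RTPCR_<comparison>_<METRIC>"` in the Platform_Comparison_Metric
#'   style.
#' @param var_equal passed to [two_sample_t_pvalues()].
#' @return a `TruthSet` data frame (gene, is_deg, ad, p, fdr) with
#'   attributes `label`, `metric`, `threshold`.
#' @export
define_truth <- function(x, design, metric = c("fdr", "ad", "topx"),
                         threshold, topx_key = c("fdr", "ad"),
                         label = NULL, var_equal = TRUE) {
  metric <- match.arg(metric)
  topx_key <- match.arg(topx_key)
  assert_scalar_number(threshold, "threshold", min = 0)
  genes <- x$probe_ids
  m <- class_means(x, design)
  ad <- m$m2 - m$m1
  p <- suppressMessages(two_sample_t_pvalues(x, design, var_equal = var_equal))
  fdr <- bh_adjust(p)
  is_deg <- switch(metric,
    fdr = fdr < threshold,
    ad = abs(ad) > threshold,
    topx = {
      X <- assert_count(threshold, "threshold (X)", min = 1)
      if (X > length(genes))
        stop_input("X exceeds the number of assayed genes")
      key <- if (topx_key == "fdr") p else -abs(ad)
      top <- genes[order(key, genes)][seq_len(X)]
      genes %in% top
    })
  if (is.null(label))
    label <- sprintf("RTPCR_%s_%s", design$comparison,
                     toupper(if (metric == "topx")
                       paste0("TOP", threshold) else metric))
  structure(data.frame(gene = genes, is_deg = is_deg, ad = ad, p = p,
                       fdr = fdr, row.names = NULL, stringsAsFactors = FALSE),
            label = label, metric = metric, threshold = threshold,
            class = c("TruthSet", "data.frame"))
}
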