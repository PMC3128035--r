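# Small fixture builders used across the suite.

make_em <- function(values, types, scale = "log2", site = "site1",
                    platform = "P1", probe_ids = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  stopifnot(length(types) == n)
  ids <- sprintf("%s_%s_r%d", platform, types, ave(seq_len(n), types,
                                                  FUN = seq_along))
  colnames(values) <- ids
  meta <- data.frame(sample_id = ids, type = types, site = site,
                     platform = platform, stringsAsFactors = FALSE)
  expression_matrix(values, probe_ids %||% sprintf("p%03d", seq_len(nrow(values))),
                    meta, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random two-class log2 matrix: m genes, n1 + n2 samples.
random_em <- function(m = 50, n1 = 4, n2 = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(m * (n1 + n2), mean = 8, sd = 1), m)
  make_em(vals, c(rep("A", n1), rep("B", n2)))
}

# A ranked list straight from a vector of ranks (for metric tests).
ranked_from <- function(ranks, ids = sprintf("g%03d", seq_along(ranks))) {
  structure(data.frame(probe_id = ids, statistic = -ranks, rank = ranks,
                       stringsAsFactors = FALSE),
            method = "fixture", ties = "average",
            class = c("RankedList", "data.frame"))
}
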