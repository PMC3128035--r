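# t-family statistics: all share the pooled two-sample layout with
# statistics oriented class2 - class1 and scaled by sqrt(1/n1 + 1/n2).

pooled_moments <- function(x, design) {
  v <- x$values
  x1 <- v[, design$idx1, drop = FALSE]
  x2 <- v[, design$idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  df <- design$n1 + design$n2 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  list(diff = m2 - m1, s2 = ss / df, df = df,
       c2 = 1 / design$n1 + 1 / design$n2,
       x1 = x1, x2 = x2, m1 = m1, m2 = m2)
}

require_t_design <- function(design) {
  if (design$n1 < 2L || design$n2 < 2L)
    stop_input("variance-based statistics need >= 2 replicates per class")
}

# Newton inversion of the trigamma function (used by the empirical-Bayes
# moment matching); monotone decreasing on (0, Inf), tolerance 1e-8.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# Moment matching of a scaled inverse chi-square prior on gene variances:
# z = log s^2 has mean log s0^2 + digamma(d/2) - log(d/2) shifted by the
# sampling term and variance trigamma(d0/2) + trigamma(d/2).
fit_variance_prior <- function(s2, df, covariate = NULL, span = 0.5) {
  ok <- s2 > 0
  if (!any(ok))
    stop_input("all gene variances are zero; degenerate input")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  if (is.null(covariate)) {
    emean <- rep(mean(e), length(s2))
    resid <- e - mean(e)
  } else {
    fit <- loess(e ~ covariate[ok], span = span, degree = 2,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    pred_all <- predict(fit, newdata = covariate)
    # loess with surface = "direct" extrapolates; guard residual NAs anyway
    pred_all[!is.finite(pred_all)] <- mean(e)
    emean <- pred_all
    resid <- e - emean[ok]
  }
  n <- length(z)
  evar <- sum((resid - mean(resid))^2) / max(1L, n - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: infinite prior df; the
    # pooled mean variance is the MLE of the common variance
    d0 <- Inf
    s02 <- if (is.null(covariate)) rep(mean(s2[ok]), length(s2)) else exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

squeeze_statistic <- function(pm, d0, s02) {
  s2_post <- if (is.infinite(d0)) s02
  else (d0 * s02 + pm$df * pm$s2) / (d0 + pm$df)
  pm$diff / sqrt(s2_post * pm$c2)
}

#' Moderated t statistic (modT)
#'
#' An empirical-Bayes t statistic: gene variances are shrunk toward a
#' common prior `s0^2` with `d0` prior degrees of freedom, both estimated
#' by moment matching on the distribution of `log s^2` (digamma/trigamma
#' inversion, tolerance 1e-8).  The posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` replaces the pooled variance in an
#' ordinary t.
#'
#' @param x an `ExpressionMatrix` on the log2 scale.
#' @param design a [class_design()] with at least two replicates per class.
#' @param d0 optional override of the prior degrees of freedom: `0` gives
#'   the ordinary t, `Inf` uses the prior variance alone.
#' @return a `ScoreTable` with attributes `d0` and `s02`.
#' @export
moderated_t <- function(x, design, d0 = NULL) {
  require_log2(x); require_t_design(design)
  pm <- pooled_moments(x, design)
  if (all(pm$s2 == 0))
    stop_input("zero pooled variance for every gene; degenerate input")
  if (is.null(d0)) {
    prior <- fit_variance_prior(pm$s2, pm$df)
    d0 <- prior$d0
    s02 <- prior$s02[1L]
  } else if (d0 == 0) {
    s02 <- 0
  } else {
    s02 <- fit_variance_prior(pm$s2, pm$df)$s02[1L]
  }
  s <- if (d0 == 0) pm$diff / sqrt(pm$s2 * pm$c2)
  else squeeze_statistic(pm, d0, rep(s02, length(pm$s2)))
  out <- new_score_table(data.frame(probe_id = x$probe_ids, statistic = s,
                                    stringsAsFactors = FALSE),
                         "modT", "descending_abs")
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

# SAM fudge-factor selection: candidate s0 at percentiles 0,5,...,100 of
# the per-gene standard-error term; choose the candidate minimizing the
# coefficient of variation of windowed MADs of the resulting statistics.
sam_select_s0 <- function(diff, se, n_windows = 100L) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(se, alphas, names = FALSE, type = 7)
  groups <- cut(rank(se, ties.method = "first"),
                breaks = min(n_windows, length(se)), labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- diff / (se + s0)
    mads <- tapply(d, groups, mad)
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(Inf)
    sd(mads) / m
  }, numeric(1))
  cand[which.min(cv)]
}

#' SAM t statistic (samT)
#'
#' The ordinary t with a fudge factor `s0` added to the per-gene standard
#' error: `(mean2 - mean1) / (s_g + s0)`.  `s0` is chosen over a grid of
#' candidate percentiles (0, 5, ..., 100) of the `s_g` values to minimize
#' the coefficient of variation of windowed median absolute deviations of
#' the statistic (100 windows), which stabilizes genes with near-zero
#' variance.
#'
#' @inheritParams moderated_t
#' @param s0 optional override of the fudge factor (`0` gives ordinary t).
#' @return a `ScoreTable` with attribute `s0`.
#' @export
sam_t <- function(x, design, s0 = NULL) {
  require_log2(x); require_t_design(design)
  pm <- pooled_moments(x, design)
  se <- sqrt(pm$s2 * pm$c2)
  if (all(se == 0))
    stop_input("zero pooled variance for every gene; degenerate input")
  if (is.null(s0)) s0 <- sam_select_s0(pm$diff, se)
  s <- pm$diff / (se + s0)
  out <- new_score_table(data.frame(probe_id = x$probe_ids, statistic = s,
                                    stringsAsFactors = FALSE),
                         "samT", "descending_abs")
  attr(out, "s0") <- s0
  out
}

#' Shrinkage t statistic (shrT)
#'
#' Gene variances are shrunk toward the median gene variance with an
#' analytically estimated intensity
#' `lambda* = min(1, sum_g Var-hat(v_g) / sum_g (v_g - v_median)^2)`;
#' `Var-hat(v_g)` is estimated from the spread of the squared class-centred
#' residuals.  The shrunk variance `v* = lambda* v_med + (1 - lambda*) v_g`
#' replaces the pooled variance in an ordinary t.  When all gene variances
#' are equal the intensity is 1 and the ranking coincides with AD.
#'
#' @inheritParams moderated_t
#' @param lambda optional override of the shrinkage intensity in \[0, 1\].
#' @return a `ScoreTable` with attribute `lambda`.
#' @export
shrinkage_t <- function(x, design, lambda = NULL) {
  require_log2(x); require_t_design(design)
  pm <- pooled_moments(x, design)
  if (all(pm$s2 == 0))
    stop_input("zero pooled variance for every gene; degenerate input")
  if (is.null(lambda)) {
    u <- cbind(pm$x1 - pm$m1, pm$x2 - pm$m2)^2
    n <- ncol(u)
    ubar <- rowMeans(u)
    su2 <- rowSums((u - ubar)^2) / (n - 1)
    var_v <- n * su2 / pm$df^2
    v_med <- median(pm$s2)
    denom <- sum((pm$s2 - v_med)^2)
    lambda <- if (denom == 0) 1 else min(1, sum(var_v) / denom)
  }
  assert_scalar_number(lambda, "lambda", min = 0, max = 1)
  v_star <- lambda * median(pm$s2) + (1 - lambda) * pm$s2
  s <- pm$diff / sqrt(v_star * pm$c2)
  out <- new_score_table(data.frame(probe_id = x$probe_ids, statistic = s,
                                    stringsAsFactors = FALSE),
                         "shrT", "descending_abs")
  attr(out, "lambda") <- lambda
  out
}

#' Intensity-based moderated t statistic (ibmT)
#'
#' As [moderated_t()], but the prior variance is an intensity-dependent
#' smooth fit: a local regression (loess, span 0.5) of `log s^2` on the
#' mean log2 intensity supplies `s0^2(g)`, and the prior degrees of freedom
#' are estimated from the residuals about that fit.  When the
#' variance-intensity trend is flat the statistic reduces to modT.
#'
#' @inheritParams moderated_t
#' @param span loess span of the variance-intensity fit.
#' @return a `ScoreTable` with attribute `d0`.
#' @export
ibm_t <- function(x, design, span = 0.5) {
  require_log2(x); require_t_design(design)
  pm <- pooled_moments(x, design)
  if (all(pm$s2 == 0))
    stop_input("zero pooled variance for every gene; degenerate input")
  abar <- rowMeans(x$values[, c(design$idx1, design$idx2), drop = FALSE])
  prior <- fit_variance_prior(pm$s2, pm$df, covariate = abar, span = span)
  s <- squeeze_statistic(pm, prior$d0, prior$s02)
  out <- new_score_table(data.frame(probe_id = x$probe_ids, statistic = s,
                                    stringsAsFactors = FALSE),
                         "ibmT", "descending_abs")
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Compute one of the eight ranking statistics by name
#'
#' @param method one of `"wad"`, `"ad"`, `"fc"`, `"rp"`, `"modt"`,
#'   `"samt"`, `"shrt"`, `"ibmt"`.
#' @param x an `ExpressionMatrix` on the log2 scale.
#' @param design a [class_design()].
#' @return a `ScoreTable`.
#' @export
ranking_statistic <- function(method, x, design) {
  method <- match.arg(tolower(method), ranking_methods())
  switch(method,
         wad = wad_statistic(x, design),
         ad = ad_statistic(x, design),
         fc = fc_statistic(x, design),
         rp = rank_products(x, design),
         modt = moderated_t(x, design),
         samt = sam_t(x, design),
         shrt = shrinkage_t(x, design),
         ibmt = ibm_t(x, design))
}

#' @rdname ranking_statistic
#' @export
ranking_methods <- function() c("wad", "ad", "fc", "rp", "modt", "samt",
                                "shrt", "ibmt")
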