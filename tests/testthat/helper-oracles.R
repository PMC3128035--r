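# Independent brute-force oracles: direct formula evaluation, plain loops,
# no reuse of package internals.

oracle_auc <- function(ranks, is_deg) {
  pos <- ranks[is_deg]
  neg <- ranks[!is_deg]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a < b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  r <- rank(p, ties.method = "min")
  for (i in seq_len(m)) {
    cands <- numeric(0)
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) cands <- c(cands, m * p[j] / rank(p, ties.method = "max")[j])
    }
    out[i] <- min(1, min(cands))
  }
  out
}

oracle_spearman <- function(r1, r2) {
  a <- r1 - mean(r1); b <- r2 - mean(r2)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix (merge height joining each pair of leaves).
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dd <- d
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  dm <- dd
  repeat {
    k <- sum(active)
    if (k == 1L) break
    best <- Inf; bi <- bj <- 0L
    idx <- which(active)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b && dm[idx[a], idx[b]] < best) {
        best <- dm[idx[a], idx[b]]; bi <- idx[a]; bj <- idx[b]
      }
    }
    for (x in clusters[[bi]]) for (y in clusters[[bj]]) {
      coph[x, y] <- coph[y, x] <- best
    }
    na <- length(clusters[[bi]]); nb <- length(clusters[[bj]])
    for (o in which(active)) {
      if (o != bi && o != bj) {
        dm[bi, o] <- dm[o, bi] <- (na * dm[bi, o] + nb * dm[bj, o]) / (na + nb)
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    active[bj] <- FALSE
  }
  coph
}

# --- direct-formula statistic oracles ----------------------------------

oracle_ad <- function(v, i1, i2) {
  out <- numeric(nrow(v))
  for (g in seq_len(nrow(v)))
    out[g] <- mean(v[g, i2]) - mean(v[g, i1])
  out
}

oracle_fc <- function(v, i1, i2) {
  out <- numeric(nrow(v))
  for (g in seq_len(nrow(v)))
    out[g] <- log2(mean(2^v[g, i2]) / mean(2^v[g, i1]))
  out
}

oracle_wad <- function(v, i1, i2) {
  ad <- oracle_ad(v, i1, i2)
  xbar <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) xbar[g] <- mean(v[g, c(i1, i2)])
  w <- (xbar - min(xbar)) / (max(xbar) - min(xbar))
  ad * w
}

oracle_rp <- function(v, i1, i2) {
  m <- nrow(v)
  up <- matrix(0, m, 0); down <- matrix(0, m, 0)
  for (i in i1) for (j in i2) {
    d <- v[, j] - v[, i]
    up <- cbind(up, rank(-d))
    down <- cbind(down, rank(d))
  }
  rp_up <- apply(up, 1, function(r) exp(mean(log(r))))
  rp_down <- apply(down, 1, function(r) exp(mean(log(r))))
  pmin(rp_up, rp_down)
}

oracle_t <- function(v, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  out <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) {
    s2 <- (sum((v[g, i1] - mean(v[g, i1]))^2) +
             sum((v[g, i2] - mean(v[g, i2]))^2)) / (n1 + n2 - 2)
    out[g] <- (mean(v[g, i2]) - mean(v[g, i1])) / sqrt(s2 * (1/n1 + 1/n2))
  }
  out
}

oracle_shrt <- function(v, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  n <- n1 + n2; d <- n - 2
  m <- nrow(v)
  vg <- numeric(m); varv <- numeric(m); diff <- numeric(m)
  for (g in seq_len(nrow(v))) {
    r <- c(v[g, i1] - mean(v[g, i1]), v[g, i2] - mean(v[g, i2]))
    u <- r^2
    vg[g] <- sum(u) / d
    varv[g] <- n * (sum((u - mean(u))^2) / (n - 1)) / d^2
    diff[g] <- mean(v[g, i2]) - mean(v[g, i1])
  }
  vmed <- median(vg)
  denom <- sum((vg - vmed)^2)
  lambda <- if (denom == 0) 1 else min(1, sum(varv) / denom)
  vstar <- lambda * vmed + (1 - lambda) * vg
  diff / sqrt(vstar * (1/n1 + 1/n2))
}

oracle_samt_given_s0 <- function(v, i1, i2, s0) {
  n1 <- length(i1); n2 <- length(i2)
  out <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) {
    s2 <- (sum((v[g, i1] - mean(v[g, i1]))^2) +
             sum((v[g, i2] - mean(v[g, i2]))^2)) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1/n1 + 1/n2))
    out[g] <- (mean(v[g, i2]) - mean(v[g, i1])) / (se + s0)
  }
  out
}

oracle_modt_given_prior <- function(v, i1, i2, d0, s02) {
  n1 <- length(i1); n2 <- length(i2)
  d <- n1 + n2 - 2
  out <- numeric(nrow(v))
  for (g in seq_len(nrow(v))) {
    s2 <- (sum((v[g, i1] - mean(v[g, i1]))^2) +
             sum((v[g, i2] - mean(v[g, i2]))^2)) / d
    s2post <- if (is.infinite(d0)) s02 else (d0 * s02 + d * s2) / (d0 + d)
    out[g] <- (mean(v[g, i2]) - mean(v[g, i1])) /
      sqrt(s2post * (1/n1 + 1/n2))
  }
  out
}
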