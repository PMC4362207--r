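# Numeric helpers shared across the scoring stages.

# p-values underflowing to 0 are floored so -log10 scores stay finite
.P_FLOOR <- 1e-320

.neglog10 <- function(p) -log10(pmax(p, .P_FLOOR))

# Pooled-variance two-sample t-test on scalars, NA-tolerant.
# Returns list(t, df, p) with p NA when either group is degenerate.
.pooledT <- function(x, y, one_sided = FALSE, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n0 <- length(y)
  if (n1 < 2 || n0 < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  v1 <- var(x); v0 <- var(y)
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    if (se2 <= 0) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    if (sp2 <= 0) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    df <- n1 + n0 - 2
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  }
  p <- if (one_sided) pt(tstat, df, lower.tail = FALSE) else 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# Row-wise pooled t-test of X[, grp] vs X[, !grp] for every row of X.
# NA-aware; rows with a degenerate group get p = NA.
.rowPooledT <- function(X, grp, one_sided = FALSE) {
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  g1 <- grp; g0 <- !grp
  n1 <- M[, g1, drop = FALSE] %*% rep(1, sum(g1))
  n0 <- M[, g0, drop = FALSE] %*% rep(1, sum(g0))
  s1 <- X0[, g1, drop = FALSE] %*% rep(1, sum(g1))
  s0 <- X0[, g0, drop = FALSE] %*% rep(1, sum(g0))
  q1 <- (X0[, g1, drop = FALSE]^2) %*% rep(1, sum(g1))
  q0 <- (X0[, g0, drop = FALSE]^2) %*% rep(1, sum(g0))
  m1 <- s1 / n1; m0 <- s0 / n0
  v1 <- (q1 - s1^2 / n1) / (n1 - 1)
  v0 <- (q0 - s0^2 / n0) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  df <- n1 + n0 - 2
  tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- if (one_sided) pt(tstat, df, lower.tail = FALSE) else 2 * pt(-abs(tstat), df)
  p[n1 < 2 | n0 < 2 | !is.finite(sp2) | sp2 <= 0] <- NA_real_
  as.numeric(p)
}

# Asymptotic two-sided Kolmogorov distribution tail Q(lambda).
.kolmogorovQ <- function(lambda) {
  if (lambda < 0.2) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Two-sample K-S p-value: exact (ties-aware, via stats::psmirnov) when the
# pooled sample is small, asymptotic Kolmogorov otherwise.
.ksPvalue <- function(x, y, exact_below = 30) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  pooled <- c(x, y)
  cuts <- sort(unique(pooled))
  Fx <- vapply(cuts, function(q) mean(x <= q), numeric(1))
  Fy <- vapply(cuts, function(q) mean(y <= q), numeric(1))
  D <- max(abs(Fx - Fy))
  if (n1 + n2 < exact_below) {
    p <- tryCatch(
      stats::psmirnov(D, sizes = c(n1, n2), z = pooled, two.sided = TRUE,
                      lower.tail = FALSE),
      error = function(e) .kolmogorovQ(sqrt(n1 * n2 / (n1 + n2)) * D))
  } else {
    p <- .kolmogorovQ(sqrt(n1 * n2 / (n1 + n2)) * D)
  }
  list(statistic = D, p.value = min(max(p, 0), 1))
}

# Deterministic sub-stream seeds derived from one user seed (kept < 2^31).
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
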