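# Stage-III core: Gaussian likelihoods for the five triplet models relating
# a variant v, a transcript g and an outcome p:
#   M1 (causal)      v -> g -> p            [g|v][p|g]
#   M2 (independent) v -> g, v -> p         [g|v][p|v]
#   M3 (reactive)    v -> p -> g            [p|v][g|p]
#   M4               v -> g -> p and v -> p [g|v][p|v,g]
#   M5               v -> p -> g and v -> g [p|v][g|v,p]
# Each conditional is a linear regression with Gaussian errors and MLE
# residual variance (n denominator). The broad-sense causality p-value
# scores M1 against M2 and M3 only, with empirical permutation nulls
# obtained by reshuffling the transcript across individuals.

.MODEL_FACTORS <- list(
  M1 = list(c("g", "v"), c("p", "g")),
  M2 = list(c("g", "v"), c("p", "v")),
  M3 = list(c("p", "v"), c("g", "p")),
  M4 = list(c("g", "v"), c("p", "v", "g")),
  M5 = list(c("p", "v"), c("g", "v", "p"))
)

# OLS via normal equations; singular designs fall back to a pseudo-inverse.
.ols <- function(y, X) {
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- tryCatch(solve(XtX, Xty), error = function(e) {
    warning("singular design; using pseudo-inverse fit")
    s <- svd(XtX)
    pos <- s$d > max(s$d) * 1e-12
    d_inv <- ifelse(pos, 1 / s$d, 0)
    s$v %*% (d_inv * crossprod(s$u, Xty))
  })
  resid <- y - X %*% beta
  list(coef = as.numeric(beta), rss = sum(resid^2))
}

.condLoglik <- function(rss, n) {
  sigma2 <- max(rss / n, .P_FLOOR)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Fit one triplet model by maximum likelihood
#'
#' @param modelId one of \code{"M1"}..\code{"M5"}.
#' @param v genotype vector (0/1).
#' @param g transcript vector.
#' @param p outcome (trait or second transcript) vector.
#' @return a \code{"TripletModelFit"} list: \code{model}, \code{loglik},
#'   per-conditional \code{fits} (response, predictors, coefficients with
#'   intercept first, MLE residual variance), and \code{n}.
#' @export
fitTripletModel <- function(modelId, v, g, p) {
  modelId <- match.arg(modelId, names(.MODEL_FACTORS))
  ok <- !is.na(v) & !is.na(g) & !is.na(p)
  if (sum(ok) < 5) stop("need >= 5 complete observations")
  v <- v[ok]; g <- g[ok]; p <- p[ok]
  if (length(unique(v)) < 2) stop("both alleles must be present")
  n <- length(v)
  vars <- list(v = v, g = g, p = p)
  loglik <- 0
  fits <- list()
  for (conditional in .MODEL_FACTORS[[modelId]]) {
    y <- vars[[conditional[1]]]
    X <- cbind(1, do.call(cbind, vars[conditional[-1]]))
    fit <- .ols(y, X)
    loglik <- loglik + .condLoglik(fit$rss, n)
    fits[[paste(conditional[1], "given",
                paste(conditional[-1], collapse = ","))]] <-
      list(response = conditional[1], predictors = conditional[-1],
           coef = fit$coef, sigma2 = fit$rss / n)
  }
  structure(list(model = modelId, loglik = loglik, fits = fits, n = n),
            class = "TripletModelFit")
}

#' @export
print.TripletModelFit <- function(x, ...) {
  cat(sprintf("TripletModelFit %s: loglik %.3f (n = %d)\n", x$model,
              x$loglik, x$n))
  invisible(x)
}

# Closed-form likelihood-ratio scores from centered sufficient statistics.
# RSS(y|x) = Syy - Sxy^2/Sxx for a simple regression with intercept; the
# [g|v] factor is shared by M1 and M2 so LR2 reduces to the p-conditionals.
#   LR2 = n/2 (log RSS(p|v) - log RSS(p|g))
#   LR3 = n/2 (log RSS(p|v) + log RSS(g|p) - log RSS(g|v) - log RSS(p|g))
.lrScores <- function(n, Svv, Sgg, Spp, Sgv, Sgp, Spv) {
  eps <- .P_FLOOR
  rss_p_v <- pmax(Spp - Spv^2 / Svv, eps)
  rss_p_g <- pmax(Spp - Sgp^2 / Sgg, eps)
  rss_g_v <- pmax(Sgg - Sgv^2 / Svv, eps)
  rss_g_p <- pmax(Sgg - Sgp^2 / Spp, eps)
  lr2 <- n / 2 * (log(rss_p_v) - log(rss_p_g))
  lr3 <- n / 2 * (log(rss_p_v) + log(rss_g_p) - log(rss_g_v) - log(rss_p_g))
  list(lr2 = lr2, lr3 = lr3)
}

# Each likelihood-ratio statistic is referred to an empirical null generated
# by reshuffling the transcript UNDER THE CORRESPONDING NULL MODEL:
#  - LR(M1 vs M2): g is reshuffled within genotype classes (separately among
#    the v = 0 and v = 1 individuals). This preserves the variant-transcript
#    edge and is an exact permutation null for "g independent of p given v".
#  - LR(M1 vs M3): g's residuals from its regression on p are reshuffled and
#    added back to the fitted values (Freedman-Lane), preserving the
#    transcript-outcome edge -- the null for "g independent of v given p".
# A reshuffle that ignores the null model fails structurally: LR(M1 vs M3)
# is exactly invariant to within-class reshuffles, while unconditional
# reshuffles centre its null far below both M1- and M3-typical values.

.stratifiedPermutations <- function(v, B) {
  n <- length(v)
  idx1 <- which(v == max(v)); idx0 <- setdiff(seq_len(n), idx1)
  vapply(seq_len(B), function(b) {
    out <- integer(n)
    out[idx0] <- if (length(idx0) > 1) idx0[sample.int(length(idx0))] else idx0
    out[idx1] <- if (length(idx1) > 1) idx1[sample.int(length(idx1))] else idx1
    out
  }, integer(n))
}

# Observed LRs plus the two nulls for one (v, g, p) triplet, from centered
# vectors. Within-class reshuffles leave Sgg and Sgv invariant, so each
# costs one inner product; Freedman-Lane reshuffles cost three.
.causalityEngine <- function(v, vc, gc, pc, B,
                             strat_idx = NULL, fl_idx = NULL) {
  n <- length(vc)
  Svv <- sum(vc^2); Sgg <- sum(gc^2); Spp <- sum(pc^2)
  Sgv <- sum(gc * vc); Sgp <- sum(gc * pc); Spv <- sum(pc * vc)
  obs <- .lrScores(n, Svv, Sgg, Spp, Sgv, Sgp, Spv)
  if (is.null(strat_idx)) strat_idx <- .stratifiedPermutations(v, B)
  if (is.null(fl_idx))
    fl_idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  # null for M2: within-class reshuffle of g
  Gs <- matrix(gc[strat_idx], nrow = n)
  null2 <- .lrScores(n, Svv, Sgg, Spp, Sgv,
                     as.numeric(crossprod(Gs, pc)), Spv)
  p2 <- (1 + sum(null2$lr2 >= obs$lr2)) / (1 + B)
  # null for M3: reshuffle residuals of g given p (both already centered,
  # so fitted values and residuals stay centered)
  bhat <- Sgp / Spp
  res <- gc - bhat * pc
  Rp <- matrix(res[fl_idx], nrow = n)
  SggP <- sum((bhat * pc)^2) + 2 * bhat * as.numeric(crossprod(Rp, pc)) +
    sum(res^2)
  SgvP <- bhat * Spv + as.numeric(crossprod(Rp, vc))
  SgpP <- bhat * Spp + as.numeric(crossprod(Rp, pc))
  null3 <- .lrScores(n, Svv, SggP, Spp, SgvP, SgpP, Spv)
  p3 <- (1 + sum(null3$lr3 >= obs$lr3)) / (1 + B)
  list(lr2 = obs$lr2, lr3 = obs$lr3, p2 = p2, p3 = p3)
}

#' Broad-sense causality p-value for one triplet
#'
#' Tests the causal chain v -> g -> p against the independence (M2) and
#' reactive (M3) alternatives. Each observed likelihood-ratio score is
#' compared with an empirical null obtained by reshuffling the transcript
#' values B times under the corresponding null model: within genotype
#' classes for the M2 comparison, and as residuals given the outcome for the
#' M3 comparison. P-values carry the add-one correction (1 + count)/(1 + B);
#' the causality p-value is the larger of the two, so both alternatives must
#' be rejected.
#'
#' @param v genotype vector (0/1, NA allowed).
#' @param g transcript vector.
#' @param p outcome vector.
#' @param B number of reshuffles (default 100).
#' @param seed RNG seed.
#' @return a \linkS4class{CausalityResult}.
#' @export
causalityPvalue <- function(v, g, p, B = 100, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  ok <- !is.na(v) & !is.na(g) & !is.na(p)
  if (sum(ok) < 5) stop("need >= 5 complete observations")
  v <- v[ok]; g <- g[ok]; p <- p[ok]
  if (length(unique(v)) < 2) stop("both alleles must be present")
  set.seed(seed)
  res <- .causalityEngine(v, v - mean(v), g - mean(g), p - mean(p), B)
  new("CausalityResult", lrVsM2 = res$lr2, lrVsM3 = res$lr3,
      pVsM2 = res$p2, pVsM3 = res$p3,
      causalityP = max(res$p2, res$p3),
      nPermutations = as.integer(B), seed = as.integer(seed))
}

#' Cis-mediation p-value: a transcript between an interval and a transcript
#'
#' Identical to \code{\link{causalityPvalue}} with another transcript's
#' values as the outcome; used to test whether a cis-associated gene is
#' positioned between a module's genomic interval and another module
#' transcript.
#'
#' @param v genotype vector.
#' @param gMediator candidate mediator transcript values.
#' @param gTarget downstream transcript values (the outcome).
#' @inheritParams causalityPvalue
#' @return a \linkS4class{CausalityResult}.
#' @export
mediationPvalue <- function(v, gMediator, gTarget, B = 100, seed = 1) {
  causalityPvalue(v, gMediator, gTarget, B = B, seed = seed)
}

# Causality p-values for every (transcript, trait) pair against one variant.
# Permutation index sets are drawn once per transcript and shared across
# traits, so the whole trait block costs one B x n by n x k multiply.
# Requires complete data (the per-pair scalar path handles missing values).
.causalityMatrix <- function(v, G, Tm, B, seed) {
  n <- length(v)
  stopifnot(ncol(G) == n, ncol(Tm) == n, !anyNA(v), !anyNA(G))
  vc <- v - mean(v)
  Svv <- sum(vc^2)
  out <- matrix(NA_real_, nrow(G), nrow(Tm), dimnames = list(rownames(G),
                                                             rownames(Tm)))
  set.seed(seed)
  for (i in seq_len(nrow(G))) {
    gc <- G[i, ] - mean(G[i, ])
    strat_idx <- .stratifiedPermutations(v, B)
    fl_idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    for (j in seq_len(nrow(Tm))) {
      pj <- Tm[j, ]
      okj <- !is.na(pj)
      if (!all(okj)) {                                 # fall back, NA-safe
        r <- causalityPvalue(v[okj], G[i, okj], pj[okj], B = B,
                             seed = .deriveSeed(seed, i * 7919 + j))
        out[i, j] <- r@causalityP
        next
      }
      pc <- pj - mean(pj)
      res <- .causalityEngine(v, vc, gc, pc, B,
                              strat_idx = strat_idx, fl_idx = fl_idx)
      out[i, j] <- max(res$p2, res$p3)
    }
  }
  out
}
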