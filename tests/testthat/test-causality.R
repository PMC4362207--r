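genTriplet <- function(model, n = 100, a = 0.5, l = 4, s = 0.6) {
  v <- rbinom(n, 1, 0.5)
  e <- function() rnorm(n, 0, s)
  switch(model,
    M1 = { g <- a * v + e(); p <- l * g + e() },
    M2 = { g <- a * v + e(); p <- a * v + e() },
    M3 = { p <- a * v + e(); g <- l * p + e() },
    M4 = { g <- a * v + e(); p <- a * v + l * g + e() },
    M5 = { p <- a * v + e(); g <- a * v + l * p + e() })
  list(v = v, g = g, p = p)
}

test_that("triplet model fits match lm() coefficient-by-coefficient", {
  set.seed(41)
  d <- genTriplet("M4")
  for (mod in c("M1", "M2", "M3", "M4", "M5")) {
    fit <- fitTripletModel(mod, d$v, d$g, d$p)
    ll_ref <- 0
    for (f in fit$fits) {
      ref <- lm(reformulate(f$predictors, f$response),
                data = data.frame(v = d$v, g = d$g, p = d$p))
      expect_equal(f$coef, unname(coef(ref)), tolerance = 1e-8)
      rss <- sum(resid(ref)^2)
      n <- length(d$v)
      ll_ref <- ll_ref - n / 2 * (log(2 * pi * rss / n) + 1)
    }
    expect_equal(fit$loglik, ll_ref, tolerance = 1e-8)
  }
})

test_that("nesting and noiseless-limit dominance of the generating model", {
  set.seed(42)
  d <- genTriplet("M1", s = 1e-6, l = 1)
  expect_gt(fitTripletModel("M1", d$v, d$g, d$p)$loglik,
            fitTripletModel("M2", d$v, d$g, d$p)$loglik)
  expect_gt(fitTripletModel("M1", d$v, d$g, d$p)$loglik,
            fitTripletModel("M3", d$v, d$g, d$p)$loglik)
  for (i in 1:10) {
    d <- genTriplet(sample(c("M1", "M2", "M3"), 1))
    expect_gte(fitTripletModel("M4", d$v, d$g, d$p)$loglik,
               fitTripletModel("M1", d$v, d$g, d$p)$loglik - 1e-9)
  }
})

test_that("closed-form LR scores agree with explicit model fits", {
  set.seed(43)
  for (i in 1:10) {
    d <- genTriplet(sample(paste0("M", 1:5), 1))
    r <- causalityPvalue(d$v, d$g, d$p, B = 5, seed = i)
    lr2 <- fitTripletModel("M1", d$v, d$g, d$p)$loglik -
      fitTripletModel("M2", d$v, d$g, d$p)$loglik
    lr3 <- fitTripletModel("M1", d$v, d$g, d$p)$loglik -
      fitTripletModel("M3", d$v, d$g, d$p)$loglik
    expect_equal(r@lrVsM2, lr2, tolerance = 1e-8)
    expect_equal(r@lrVsM3, lr3, tolerance = 1e-8)
  }
})

test_that("causality p-value contracts: defaults, bounds, allele swap, scaling", {
  set.seed(44)
  d <- genTriplet("M1")
  r <- causalityPvalue(d$v, d$g, d$p, seed = 3)
  expect_identical(r@nPermutations, 100L)           # default reshuffle count
  expect_gte(min(r@pVsM2, r@pVsM3), 1 / 101)
  expect_equal(r@causalityP, max(r@pVsM2, r@pVsM3))

  r_swap <- causalityPvalue(1 - d$v, d$g, d$p, seed = 3)
  expect_equal(r_swap@lrVsM2, r@lrVsM2, tolerance = 1e-9)
  expect_equal(r_swap@lrVsM3, r@lrVsM3, tolerance = 1e-9)

  r_scale <- causalityPvalue(d$v, 3.7 * d$g, 0.2 * d$p, seed = 3)
  expect_equal(r_scale@lrVsM2, r@lrVsM2, tolerance = 1e-9)
  expect_equal(r_scale@lrVsM3, r@lrVsM3, tolerance = 1e-9)
  expect_equal(r_scale@causalityP, r@causalityP)

  expect_error(causalityPvalue(d$v, d$g, d$p, B = 0), "B must be")
  expect_error(causalityPvalue(rep(1, 100), d$g, d$p), "both alleles")
})

test_that("type-I error under the independence model is near nominal", {
  set.seed(45)
  rej <- mean(replicate(200, {
    d <- genTriplet("M2")
    causalityPvalue(d$v, d$g, d$p, B = 100,
                    seed = sample.int(1e6, 1))@causalityP <= 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.09)
})

test_that("causal chains and the M4 direct-effect case are detected", {
  set.seed(46)
  p_m1 <- replicate(60, {
    d <- genTriplet("M1", l = 0.6, s = 0.3)
    causalityPvalue(d$v, d$g, d$p, B = 100, seed = sample.int(1e6, 1))@causalityP
  })
  expect_lte(median(p_m1), 0.05)
  # M4 at moderate mediated effect (lambda < 1) and low noise
  p_m4 <- replicate(60, {
    d <- genTriplet("M4", l = 0.5, s = 0.2)
    causalityPvalue(d$v, d$g, d$p, B = 100, seed = sample.int(1e6, 1))@causalityP
  })
  expect_lte(median(p_m4), 0.05)
})

test_that("mediation p-value is the same code path, bit-for-bit", {
  set.seed(47)
  n <- 80
  v <- rbinom(n, 1, 0.5)
  m <- 1.5 * v + rnorm(n, 0, 0.4)
  t2 <- 0.6 * m + rnorm(n, 0, 0.3)
  a <- causalityPvalue(v, m, t2, B = 200, seed = 9)
  b <- mediationPvalue(v, m, t2, B = 200, seed = 9)
  expect_identical(a@causalityP, b@causalityP)
  expect_identical(a@pVsM2, b@pVsM2)
  expect_lt(a@causalityP, 0.05)            # chain detected
  # fork: mediator and target independently driven by v
  set.seed(48)
  p_fork <- replicate(60, {
    v <- rbinom(n, 1, 0.5)
    mediationPvalue(v, 1.5 * v + rnorm(n, 0, 0.75),
                    1.5 * v + rnorm(n, 0, 0.75), B = 100,
                    seed = sample.int(1e6, 1))@causalityP
  })
  expect_lte(mean(p_fork <= 0.05), 0.1)
})

test_that("matrix engine matches structure and is deterministic", {
  set.seed(49)
  n <- 60
  v <- rbinom(n, 1, 0.5)
  G <- rbind(g1 = 1.5 * v + rnorm(n, 0, 0.4), g2 = rnorm(n))
  Tm <- rbind(t1 = 0.6 * G["g1", ] + rnorm(n, 0, 0.3), t2 = rnorm(n))
  pm1 <- triadnet:::.causalityMatrix(v, G, Tm, B = 500, seed = 5)
  pm2 <- triadnet:::.causalityMatrix(v, G, Tm, B = 500, seed = 5)
  expect_identical(pm1, pm2)
  expect_lt(pm1["g1", "t1"], 0.05)
  expect_gt(pm1["g2", "t2"], 0.05)
})
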