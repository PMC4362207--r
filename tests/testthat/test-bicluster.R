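# Weight fixtures use named matrices; variants are rows in genomic order.

plantedGraph <- function(nv = 8, nt = 8, blocks, bg = 0, noise = 0) {
  W <- matrix(bg, nv, nt, dimnames = list(sprintf("v%02d", seq_len(nv)),
                                          sprintf("t%02d", seq_len(nt))))
  if (noise > 0) W <- W + matrix(abs(rnorm(nv * nt, 0, noise)), nv, nt)
  for (b in blocks) W[b$v, b$t] <- b$w
  W
}

test_that("seedClusters applies a strict threshold with deterministic order", {
  W <- plantedGraph(3, 3, list(list(v = 1, t = 1, w = 200),
                               list(v = 2, t = 2, w = 200),
                               list(v = 3, t = 3, w = 180)))
  s <- seedClusters(makeGraph(W), cs = 180)
  expect_equal(nrow(s), 2)                       # 180 is not > 180
  expect_identical(s$variant, c("v01", "v02"))   # tie broken lexicographically
  expect_identical(s$trait, c("t01", "t02"))
  expect_equal(nrow(seedClusters(makeGraph(W * 0), cs = 180)), 0)
})

test_that("refineBicluster recovers a planted block and respects isolation", {
  W <- plantedGraph(8, 8, list(list(v = 3:5, t = 2:5, w = 200)))
  vt <- variantTableFor(W)
  g <- makeGraph(W)
  seeds <- seedClusters(g, 180)
  m <- refineBicluster(g, seeds[1, ], vt, cs = 180, ci = 90)
  expect_identical(m@variantIds, sprintf("v%02d", 3:5))
  expect_identical(m@traitIds, sprintf("t%02d", 2:5))
  expect_equal(m@meanWeight, 200)
  expect_equal(m@startBp, 3e6); expect_equal(m@endBp, 5e6)

  # isolated seed: neighbors all below ci -> module is the seed pair alone
  W2 <- plantedGraph(8, 8, list(list(v = 4, t = 4, w = 200)))
  m2 <- refineBicluster(makeGraph(W2), list(variant = "v04", trait = "t04"),
                        variantTableFor(W2), cs = 180, ci = 90)
  expect_identical(m2@variantIds, "v04")
  expect_identical(m2@traitIds, "t04")
})

test_that("planted block is the unique fixed point found by enumeration", {
  set.seed(21)
  W <- plantedGraph(8, 8, list(list(v = 2:4, t = c(1, 3, 6, 7), w = 150)),
                    noise = 5)
  vt <- variantTableFor(W)
  mods <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = 60)
  expect_length(mods, 1)
  # exhaustive enumeration of all consecutive-variant x trait-subset blocks
  valid <- list()
  for (a in 1:8) for (b in a:8) {
    vids <- a:b
    for (tmask in 1:255) {
      tids <- which(bitwAnd(tmask, 2^(0:7)) > 0)
      if (isValidBicluster(W, vids, tids, 60)) {
        # fixed point also requires no addable neighbor trait/variant
        addable_t <- any(vapply(setdiff(1:8, tids), function(tt)
          mean(W[vids, tt]) > 60, logical(1)))
        addable_v <- (a > 1 && mean(W[a - 1, tids]) > 60) ||
          (b < 8 && mean(W[b + 1, tids]) > 60)
        if (!addable_t && !addable_v)
          valid[[length(valid) + 1]] <- list(v = vids, t = tids)
      }
    }
  }
  # the returned module is among the enumerated fixed points and is the
  # planted one
  expect_identical(mods[[1]]@variantIds, sprintf("v%02d", 2:4))
  expect_identical(mods[[1]]@traitIds, sprintf("t%02d", c(1, 3, 6, 7)))
  hit <- any(vapply(valid, function(fp)
    identical(sprintf("v%02d", fp$v), mods[[1]]@variantIds) &&
      identical(sprintf("t%02d", fp$t), mods[[1]]@traitIds), logical(1)))
  expect_true(hit)
})

test_that("additive rescaling of weights and cutoffs leaves modules unchanged", {
  set.seed(22)
  W <- plantedGraph(8, 8, list(list(v = 3:5, t = 2:5, w = 200)), noise = 10)
  vt <- variantTableFor(W)
  m1 <- findBipartiteModules(makeGraph(W), vt, cs = 180, ci = 90)
  m2 <- findBipartiteModules(makeGraph(W + 37), vt, cs = 180 + 37, ci = 90 + 37)
  expect_equal(length(m1), length(m2))
  for (i in seq_along(m1)) {
    expect_identical(m1[[i]]@variantIds, m2[[i]]@variantIds)
    expect_identical(m1[[i]]@traitIds, m2[[i]]@traitIds)
  }
})

test_that("two disjoint planted blocks give two clean modules; empty graph none", {
  W <- plantedGraph(8, 8, list(list(v = 1:2, t = 1:3, w = 220),
                               list(v = 6:8, t = 6:8, w = 200)))
  vt <- variantTableFor(W)
  mods <- findBipartiteModules(makeGraph(W), vt, cs = 180, ci = 90)
  expect_length(mods, 2)
  expect_identical(mods[[1]]@variantIds, sprintf("v%02d", 1:2))  # heavier first
  expect_identical(mods[[1]]@traitIds, sprintf("t%02d", 1:3))
  expect_identical(mods[[2]]@variantIds, sprintf("v%02d", 6:8))
  expect_length(findBipartiteModules(makeGraph(W * 0), vt), 0)
})

test_that("returned modules satisfy membership invariants; ci is monotone", {
  set.seed(23)
  W <- plantedGraph(8, 8, list(list(v = 2:5, t = 1:5, w = 130)), noise = 30)
  vt <- variantTableFor(W)
  for (ci in c(60, 90, 110)) {
    mods <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = ci)
    for (m in mods)
      expect_true(isValidBicluster(W, m@variantIds, m@traitIds, ci))
  }
  m_lo <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = 60)
  m_hi <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = 110)
  if (length(m_lo) && length(m_hi)) {
    expect_lte(length(m_hi[[1]]@traitIds), length(m_lo[[1]]@traitIds))
    expect_lte(length(m_hi[[1]]@variantIds), length(m_lo[[1]]@variantIds))
  }
  # determinism
  a <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = 60)
  b <- findBipartiteModules(makeGraph(W), vt, cs = 120, ci = 60)
  expect_equal(a, b)
})
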