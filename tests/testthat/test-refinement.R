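# One-sub-network fixture turned into a tripartite module over a small
# aligned dataset, so refinement can be exercised end to end.

subnetModule <- function(noise = 0.5, seed = 51, k = 5, m = 3) {
  col <- simulateSubnetworks(k = k, m = m, noise = noise, nSubnetworks = 1,
                             seed = seed)
  sub <- col[[1]]
  n <- length(sub$v)
  strains <- sprintf("S%03d", seq_len(n))
  geno <- rbind(v01 = sub$v)
  colnames(geno) <- strains
  vt <- VariantTable(geno, "chr1", 1e6)
  expr <- sub$transcripts; colnames(expr) <- strains
  traits <- sub$traits; colnames(traits) <- strains
  ds <- makeDataset(vt, expr, traits)
  base <- new("BipartiteModule", variantIds = "v01",
              traitIds = rownames(traits), chromosome = "chr1",
              startBp = 1e6, endBp = 1e6, meanWeight = 100)
  tm <- new("TripartiteModule", base = base,
            candidates = rownames(expr),
            linkScores = setNames(rep(1e-4, nrow(expr)), rownames(expr)))
  list(ds = ds, module = tm, truth = sub)
}

test_that("representative variant maximizes mean association (brute force)", {
  set.seed(52)
  n <- 50
  strains <- sprintf("S%02d", seq_len(n))
  geno <- matrix(rbinom(3 * n, 1, 0.5), 3,
                 dimnames = list(c("vA", "vB", "vC"), strains))
  vt <- VariantTable(geno, rep("chr1", 3), c(1, 2, 3) * 1e6)
  expr <- matrix(rnorm(4 * n), 4,
                 dimnames = list(sprintf("g%d", 1:4), strains))
  expr["g1", ] <- expr["g1", ] + 2 * geno["vB", ]    # vB dominates
  traits <- matrix(rnorm(n), 1, dimnames = list("t1", strains))
  ds <- makeDataset(vt, expr, traits)
  base <- new("BipartiteModule", variantIds = rownames(geno)[order(rownames(geno))],
              traitIds = "t1", chromosome = "chr1", startBp = 1e6,
              endBp = 3e6, meanWeight = 1)
  tm <- new("TripartiteModule", base = base, candidates = c("g1", "g2"),
            linkScores = setNames(c(1e-4, 1e-3), c("g1", "g2")))
  A <- associationMatrix(expr, vt)
  brute <- rownames(geno)[which.max(rowMeans(A[rownames(geno), c("g1", "g2")]))]
  expect_identical(representativeVariant(tm, ds), brute)
  expect_identical(brute, "vB")
  # single-variant interval
  base1 <- new("BipartiteModule", variantIds = "vA", traitIds = "t1",
               chromosome = "chr1", startBp = 1e6, endBp = 1e6, meanWeight = 1)
  tm1 <- new("TripartiteModule", base = base1, candidates = "g1",
             linkScores = c(g1 = 1e-4))
  expect_identical(representativeVariant(tm1, ds), "vA")
})

test_that("Fisher combination matches the chi-squared oracle", {
  expect_equal(fisherTranscriptP(rep(1, 4)), 1)
  # frozen: X = -2(ln .01 + ln .04) = 15.648, df 4, survival
  # e^{-X/2}(1 + X/2) = 3.53e-3
  expect_equal(fisherTranscriptP(c(0.01, 0.04)), 0.003529618,
               tolerance = 1e-6)
  x <- 15.648
  expect_equal(fisherTranscriptP(c(0.01, 0.04)),
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-4)
  expect_error(fisherTranscriptP(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(fisherTranscriptP(numeric(0)), "at least one")
  # appending p = 1 never decreases the combined p
  set.seed(53)
  for (i in 1:25) {
    p <- runif(sample(1:6, 1))
    expect_gte(fisherTranscriptP(c(p, 1)), fisherTranscriptP(p))
  }
})

test_that("refinement dissolves a module with no causal signal", {
  fix <- subnetModule(noise = 4, seed = 54)
  # overwrite traits with pure noise so every causality p is large
  ds <- fix$ds
  ds@traits <- matrix(rnorm(length(ds@traits)), nrow(ds@traits),
                      dimnames = dimnames(ds@traits))
  expect_null(refineModule(fix$module, ds, B = 200, seed = 1))
})

test_that("refinement keeps causal traits/drivers and drops the confusables", {
  kept <- 0; total_causal <- 0; confusables <- 0; runs <- 15
  all_causal_runs <- 0
  for (i in seq_len(runs)) {
    fix <- subnetModule(noise = 0.5, seed = 100 + i)
    dm <- refineModule(fix$module, fix$ds, B = 1000, seed = i)
    causal_traits <- rownames(fix$truth$traits)[fix$truth$trait_class == "causal"]
    total_causal <- total_causal + length(causal_traits)
    if (!is.null(dm)) {
      kept <- kept + sum(causal_traits %in% dm@traitIds)
      confusables <- confusables + sum(c("pR1", "pI1") %in% dm@traitIds)
      if (all(causal_traits %in% dm@traitIds))
        all_causal_runs <- all_causal_runs + 1
    }
  }
  expect_gte(kept / total_causal, 0.85)         # per-trait causal recall
  expect_gte(all_causal_runs / runs, 0.5)       # often the full causal set
  # confusable traits appear at a low per-slot rate (one pairwise test at
  # 0.05 per retained driver can leak them occasionally)
  expect_lte(confusables / (2 * runs), 0.3)
})

test_that("driver-module invariants hold exactly and output is deterministic", {
  fix <- subnetModule(noise = 0.5, seed = 55)
  dm1 <- refineModule(fix$module, fix$ds, B = 1000, seed = 7)
  dm2 <- refineModule(fix$module, fix$ds, B = 1000, seed = 7)
  expect_false(is.null(dm1))
  expect_identical(dm1@drivers, dm2@drivers)
  expect_identical(dm1@traitIds, dm2@traitIds)
  expect_equal(dm1@causalityMatrix, dm2@causalityMatrix)
  # independent checker of the membership invariants
  for (g in dm1@drivers)
    expect_lt(fisherTranscriptP(dm1@causalityMatrix[g, ]), 0.005)
  for (tr in dm1@traitIds)
    expect_true(any(dm1@causalityMatrix[, tr] < 0.05))
  expect_true(all(dm1@drivers %in% fix$module@candidates))
  expect_true(all(dm1@traitIds %in% fix$module@base@traitIds))
})

test_that("lowering the trait cutoff never adds drivers or traits", {
  fix <- subnetModule(noise = 1, seed = 56)
  hi <- refineModule(fix$module, fix$ds, traitCutoff = 0.05, B = 1000, seed = 2)
  lo <- refineModule(fix$module, fix$ds, traitCutoff = 0.005, B = 1000, seed = 2)
  if (is.null(hi)) expect_null(lo)
  if (!is.null(lo) && !is.null(hi)) {
    expect_true(all(lo@traitIds %in% hi@traitIds))
    expect_true(all(lo@drivers %in% hi@drivers))
  }
  expect_error(refineModule(fix$module, fix$ds, transcriptCutoff = 0.005,
                            B = 50), "B too small")
})
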