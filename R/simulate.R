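# Linear-Gaussian structural-equation simulators with ground-truth labels:
# (1) causality triplets under models M1-M5, (2) co-mapped sub-networks
# (one variant, causal / reactive / independent transcripts and traits),
# (3) large composite networks embedding several sub-networks in a
# covariance-structured background. Genotypes are Bernoulli(0.5) vectors,
# mimicking homozygous recombinant-inbred panels. All generators are
# reproducible: same spec + seed gives bit-identical output.

#' Simulate causality triplets under models M1-M5
#'
#' Each triplet is (v, g, p) over \code{nIndividuals} homozygous
#' individuals, v ~ Bernoulli(0.5). Structural equations (all errors
#' N(0, sigma^2), zero intercepts):
#' \itemize{
#'   \item M1: g = alpha v + e;  p = lambda g + e
#'   \item M2: g = alpha v + e;  p = alpha v + e
#'   \item M3: p = alpha v + e;  g = lambda p + e
#'   \item M4: g = alpha v + e;  p = alpha v + lambda g + e
#'   \item M5: p = alpha v + e;  g = alpha v + lambda p + e
#' }
#' Broad-sense causal positives are M1 and M4.
#'
#' @param nIndividuals individuals per triplet (default 100).
#' @param perModelCount triplets per model (default 250, i.e. 1250 total).
#' @param alpha variant effect (default 0.5).
#' @param lambda mediated effect (default 4).
#' @param sigma error sd (default 0.6).
#' @param seed RNG seed.
#' @return list with matrices \code{v}, \code{g}, \code{p} (triplets x
#'   individuals), factor \code{model}, and logical \code{causal} (the
#'   broad-sense truth).
#' @export
simulateTriplets <- function(nIndividuals = 100, perModelCount = 250,
                             alpha = 0.5, lambda = 4, sigma = 0.6, seed = 1) {
  stopifnot(sigma > 0, perModelCount >= 1, nIndividuals >= 2)
  set.seed(seed)
  models <- c("M1", "M2", "M3", "M4", "M5")
  total <- 5 * perModelCount
  n <- nIndividuals
  V <- matrix(0, total, n); G <- matrix(0, total, n); P <- matrix(0, total, n)
  labels <- rep(models, each = perModelCount)
  e <- function() rnorm(n, 0, sigma)
  for (i in seq_len(total)) {
    v <- rbinom(n, 1, 0.5)
    switch(labels[i],
      M1 = { g <- alpha * v + e(); p <- lambda * g + e() },
      M2 = { g <- alpha * v + e(); p <- alpha * v + e() },
      M3 = { p <- alpha * v + e(); g <- lambda * p + e() },
      M4 = { g <- alpha * v + e(); p <- alpha * v + lambda * g + e() },
      M5 = { p <- alpha * v + e(); g <- alpha * v + lambda * p + e() })
    V[i, ] <- v; G[i, ] <- g; P[i, ] <- p
  }
  list(v = V, g = G, p = P, model = factor(labels, levels = models),
       causal = labels %in% c("M1", "M4"))
}

# One structural edge: child = beta * parent + N(0, (noise*beta)^2).
.edge <- function(parent, beta, noise) {
  beta * parent + rnorm(length(parent), 0, noise * beta)
}

# Build a single sub-network. Net-1 is the reference wiring:
#   v -> g1C..gmC -> p1C..pkC   (each trait sums its m incoming edges)
#   v -> p1R -> g1R             (reactive pair)
#   v -> g1I,  v -> p1I         (independent pair)
# Net-2 and Net-3 are documented variants reconstructed from sketches:
# Net-2 duplicates the confusable components (two reactive transcripts on
# p1R, the independent transcript duplicated); Net-3 chains the causal
# transcripts v -> g1C -> g2C -> ... -> gmC with only the last feeding the
# traits. Both keep k + 2 traits.
.simulateOneSubnetwork <- function(netKind, k, m, noise, betaStrong, betaWeak,
                                   n) {
  v <- rbinom(n, 1, 0.5)
  gC <- matrix(0, m, n)
  if (netKind == "net3") {
    parent <- v
    b <- betaStrong
    for (i in seq_len(m)) {
      gC[i, ] <- .edge(parent, b, noise)
      parent <- gC[i, ]
      b <- betaWeak
    }
    sources <- gC[m, , drop = FALSE]
  } else {
    for (i in seq_len(m)) gC[i, ] <- .edge(v, betaStrong, noise)
    sources <- gC
  }
  pC <- matrix(0, k, n)
  for (j in seq_len(k)) {
    acc <- 0
    for (i in seq_len(nrow(sources)))
      acc <- acc + .edge(sources[i, ], betaWeak, noise)
    pC[j, ] <- acc
  }
  pR <- .edge(v, betaStrong, noise)
  n_react <- if (netKind == "net2") 2L else 1L
  gR <- matrix(0, n_react, n)
  for (i in seq_len(n_react)) gR[i, ] <- .edge(pR, betaWeak, noise)
  n_indep <- if (netKind == "net2") 2L else 1L
  gI <- matrix(0, n_indep, n)
  for (i in seq_len(n_indep)) gI[i, ] <- .edge(v, betaStrong, noise)
  pI <- .edge(v, betaStrong, noise)
  transcripts <- rbind(gC, gR, gI)
  rownames(transcripts) <- c(paste0("gC", seq_len(m)),
                             paste0("gR", seq_len(n_react)),
                             paste0("gI", seq_len(n_indep)))
  traits <- rbind(pC, pR, pI)
  rownames(traits) <- c(paste0("pC", seq_len(k)), "pR1", "pI1")
  list(v = v, transcripts = transcripts, traits = traits,
       transcript_class = c(rep("causal", m), rep("reactive", n_react),
                            rep("independent", n_indep)),
       trait_class = c(rep("causal", k), "reactive", "independent"))
}

#' Simulate a collection of co-mapped sub-networks
#'
#' Each sub-network has one variant, m causal transcripts driving k causal
#' traits, one reactive transcript downstream of a reactive trait, and an
#' independent transcript/trait pair -- k + 2 traits in total. Every edge
#' a_i -> a_j is a_j = beta a_i + e, e ~ N(0, (noise * beta)^2), so
#' \code{noise} is the relative noise level.
#'
#' @param netKind wiring: \code{"net1"} (reference), \code{"net2"} or
#'   \code{"net3"} (documented reconstructions, see the methods vignette).
#' @param k number of causal traits (total traits = k + 2; default 5).
#' @param m number of causal transcripts (default 3).
#' @param noise relative noise level q (default 0.5).
#' @param betaStrong coefficient for v -> p and v -> g edges (default 1.5).
#' @param betaWeak coefficient for g -> p and p -> g edges (default 0.6).
#' @param nIndividuals individuals per sub-network (default 100).
#' @param nSubnetworks collection size (default 100).
#' @param seed RNG seed.
#' @return list of sub-networks, each with \code{v}, \code{transcripts},
#'   \code{traits}, and per-member truth classes.
#' @export
simulateSubnetworks <- function(netKind = c("net1", "net2", "net3"), k = 5,
                                m = 3, noise = 0.5, betaStrong = 1.5,
                                betaWeak = 0.6, nIndividuals = 100,
                                nSubnetworks = 100, seed = 1) {
  netKind <- match.arg(netKind)
  stopifnot(noise > 0, k >= 1, m >= 1)
  set.seed(seed)
  lapply(seq_len(nSubnetworks), function(s) {
    sub <- .simulateOneSubnetwork(netKind, k, m, noise, betaStrong, betaWeak,
                                  nIndividuals)
    sub$id <- sprintf("s%03d", s)
    sub
  })
}

# Synthetic PSD covariance mimicking a gene-expression correlation spectrum:
# correlated blocks plus independent noise on the diagonal.
.syntheticExpressionCov <- function(p, nBlocks = 10, rho = 0.5,
                                    diagNoise = 0.5) {
  sizes <- rep(ceiling(p / nBlocks), nBlocks)
  block_id <- rep(seq_len(nBlocks), sizes)[seq_len(p)]
  S <- outer(block_id, block_id, function(a, b) ifelse(a == b, rho, 0))
  diag(S) <- 1 + diagNoise
  S
}

#' Simulate a large composite network
#'
#' Embeds \code{nSubnetworks} co-mapped sub-networks among background
#' variants (independent Bernoulli(0.5)), background traits (standard
#' normal) and background transcripts drawn from a multivariate normal with
#' covariance \code{backgroundCov} (a synthesized block-structured PSD
#' matrix by default). Each background transcript x is then coupled to the
#' sub-networks as z = x + coupling * y, where y is a uniformly chosen
#' sub-network transcript.
#'
#' Variants are laid out on 5 chromosomes at 1 Mb spacing; each
#' sub-network's variant replaces one background variant at a seeded
#' position.
#'
#' @param nVariants,nTraits,nTranscripts,nIndividuals total network
#'   dimensions (defaults 100, 100, 200, 100).
#' @param nSubnetworks number of embedded sub-networks (default 5); 0
#'   gives a pure-noise dataset (background only).
#' @param coupling background-to-sub-network coupling constant c (default 1).
#' @param backgroundCov optional PSD covariance for the background
#'   transcripts (dimension = number of background transcripts).
#' @inheritParams simulateSubnetworks
#' @return list with \code{dataset} (a \linkS4class{TriadDataset}) and
#'   \code{truth}: per-trait and per-transcript class/sub-network labels and
#'   the sub-network variant ids.
#' @export
simulateNetwork <- function(nVariants = 100, nTraits = 100,
                            nTranscripts = 200, nSubnetworks = 5,
                            coupling = 1, backgroundCov = NULL,
                            netKind = "net1", k = 5, m = 3, noise = 0.5,
                            betaStrong = 1.5, betaWeak = 0.6,
                            nIndividuals = 100, seed = 1) {
  stopifnot(nSubnetworks >= 0, coupling >= 0)
  set.seed(seed)
  n <- nIndividuals
  subs <- lapply(seq_len(nSubnetworks), function(s)
    .simulateOneSubnetwork(netKind, k, m, noise, betaStrong, betaWeak, n))
  n_sub_trans <- nSubnetworks * (m + 2)
  n_sub_traits <- nSubnetworks * (k + 2)
  if (n_sub_trans > nTranscripts || n_sub_traits > nTraits ||
      nSubnetworks > nVariants)
    stop("network dimensions too small for the requested sub-networks")
  strain_ids <- sprintf("S%03d", seq_len(n))

  # genotypes: background variants independent; sub-network variants placed
  # at seeded distinct positions
  geno <- matrix(rbinom(nVariants * n, 1, 0.5), nVariants, n)
  vid <- sprintf("v%03d", seq_len(nVariants))
  dimnames(geno) <- list(vid, strain_ids)
  sub_pos <- if (nSubnetworks > 0) sort(sample.int(nVariants, nSubnetworks)) else integer(0)
  for (u in seq_len(nSubnetworks)) geno[sub_pos[u], ] <- subs[[u]]$v
  chrom <- rep(paste0("chr", 1:5), each = ceiling(nVariants / 5))[seq_len(nVariants)]
  pos <- unlist(lapply(table(chrom)[unique(chrom)], function(nn) seq_len(nn) * 1e6))
  vt <- VariantTable(geno, chrom, pos)

  # traits: sub-network traits first, then standard-normal background
  trait_rows <- list(); trait_class <- character(0); trait_sub <- character(0)
  for (u in seq_len(nSubnetworks)) {
    tr <- subs[[u]]$traits
    rownames(tr) <- paste0("s", u, "_", rownames(tr))
    trait_rows[[u]] <- tr
    trait_class <- c(trait_class, subs[[u]]$trait_class)
    trait_sub <- c(trait_sub, rep(paste0("s", u), nrow(tr)))
  }
  n_bg_traits <- nTraits - n_sub_traits
  bg_traits <- matrix(rnorm(n_bg_traits * n), n_bg_traits, n)
  rownames(bg_traits) <- sprintf("bg_p%03d", seq_len(n_bg_traits))
  traits <- rbind(if (nSubnetworks > 0) do.call(rbind, trait_rows), bg_traits)
  colnames(traits) <- strain_ids
  trait_class <- c(trait_class, rep("background", n_bg_traits))
  trait_sub <- c(trait_sub, rep(NA_character_, n_bg_traits))

  # transcripts: sub-network transcripts, then coupled covariance background
  trans_rows <- list(); trans_class <- character(0); trans_sub <- character(0)
  for (u in seq_len(nSubnetworks)) {
    tr <- subs[[u]]$transcripts
    rownames(tr) <- paste0("s", u, "_", rownames(tr))
    trans_rows[[u]] <- tr
    trans_class <- c(trans_class, subs[[u]]$transcript_class)
    trans_sub <- c(trans_sub, rep(paste0("s", u), nrow(tr)))
  }
  sub_trans <- if (nSubnetworks > 0) do.call(rbind, trans_rows) else
    matrix(0, 0, n)
  n_bg <- nTranscripts - n_sub_trans
  if (is.null(backgroundCov)) backgroundCov <- .syntheticExpressionCov(n_bg)
  if (!isTRUE(all.equal(dim(backgroundCov), c(n_bg, n_bg))))
    stop("backgroundCov must be ", n_bg, " x ", n_bg)
  ev <- eigen(backgroundCov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("backgroundCov is not positive semi-definite; project it to the ",
         "nearest PSD matrix (e.g. clip negative eigenvalues) first")
  X <- MASS::mvrnorm(n, mu = rep(0, n_bg), Sigma = backgroundCov)  # n x n_bg
  Z <- t(X)
  if (nSubnetworks > 0 && coupling > 0) {
    anchor <- sample.int(nrow(sub_trans), n_bg, replace = TRUE)
    Z <- Z + coupling * sub_trans[anchor, , drop = FALSE]
  }
  rownames(Z) <- sprintf("bg_g%03d", seq_len(n_bg))
  expr <- rbind(sub_trans, Z)
  colnames(expr) <- strain_ids
  trans_class <- c(trans_class, rep("background", n_bg))
  trans_sub <- c(trans_sub, rep(NA_character_, n_bg))

  ds <- new("TriadDataset", genotypes = vt, expression = expr,
            traits = traits, strains = strain_ids,
            metadata = list(generator = "simulateNetwork", seed = seed))
  truth <- list(
    traits = data.frame(trait = rownames(traits), class = trait_class,
                        subnetwork = trait_sub, stringsAsFactors = FALSE),
    transcripts = data.frame(transcript = rownames(expr), class = trans_class,
                             subnetwork = trans_sub, stringsAsFactors = FALSE),
    variants = data.frame(subnetwork = sprintf("s%d", seq_len(nSubnetworks)),
                          variant = vid[sub_pos], stringsAsFactors = FALSE))
  list(dataset = ds, truth = truth)
}
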