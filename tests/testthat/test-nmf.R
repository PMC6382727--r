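# two well-separated synthetic signatures for exact low-rank constructions
twoSigs <- function() {
  P <- matrix(0, 96, 2, dimnames = list(contextClasses(), c("g1", "g2")))
  P[1:20, 1] <- 1 / 20
  P[60:96, 2] <- 1 / 37
  P
}

test_that("NMF recovers an exact low-rank factorization", {
  P0 <- twoSigs()
  E0 <- matrix(c(100, 300, 50, 900, 250, 40, 700, 80), nrow = 2)
  M <- t(P0 %*% E0)                       # 4 samples x 96, exactly rank 2
  fit <- nmfDecompose(M, K = 2, seed = 3, nRestarts = 5, maxIter = 3000,
                      tol = 1e-10)
  P <- signatureProbs(fit)
  sim <- crossprod(P, P0) / outer(sqrt(colSums(P^2)), sqrt(colSums(P0^2)))
  # each generating signature matched by some column at cosine > 0.99
  expect_true(all(apply(sim, 2, max) > 0.99))
  expect_lt(reconstructionError(fit), 0.01 * sqrt(sum(M^2)))
})

test_that("NMF is deterministic given the seed and monotone in iterations", {
  set.seed(10)
  M <- matrix(rpois(5 * 96, 6), nrow = 5)
  f1 <- nmfDecompose(M, 2, seed = 42)
  f2 <- nmfDecompose(M, 2, seed = 42)
  expect_identical(reconstructionError(f1), reconstructionError(f2))
  expect_identical(signatureProbs(f1), signatureProbs(f2))
  # multiplicative updates never increase the objective
  errAt <- function(it) reconstructionError(
    nmfDecompose(M, 2, seed = 5, nRestarts = 1, maxIter = it, tol = 0))
  e <- vapply(c(0L, 20L, 100L, 400L), errAt, numeric(1))
  expect_true(all(diff(e) <= 1e-9))
})

test_that("signature columns are normalized and K=1 gives the global profile", {
  set.seed(11)
  M <- matrix(rpois(6 * 96, 5), nrow = 6)
  fit <- nmfDecompose(M, 3, seed = 1)
  expect_equal(colSums(signatureProbs(fit)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # exactly proportional columns: the rank-1 optimum IS the shared profile,
  # and the exposure equals each sample's total count
  p <- as.numeric(twoSigs()[, 1])
  Mp <- t(p %*% t(c(200, 800, 500)))
  f1 <- nmfDecompose(Mp, 1, seed = 2, maxIter = 3000, tol = 1e-12)
  expect_gt(cosineSimilarity(signatureProbs(f1)[, 1], p), 1 - 1e-8)
  expect_equal(as.numeric(exposures(f1)), c(200, 800, 500), tolerance = 1e-3)
  # multinomial single-signature data: approximate versions of both facts
  set.seed(12)
  Mm <- t(replicate(4, as.numeric(rmultinom(1, 5000, p))))
  fm <- nmfDecompose(Mm, 1, seed = 2)
  expect_gt(cosineSimilarity(signatureProbs(fm)[, 1], p), 0.999)
  expect_equal(as.numeric(exposures(fm)), rowSums(Mm), tolerance = 0.02)
})

test_that("extraction is equivariant under sample reordering", {
  P0 <- twoSigs()
  E0 <- matrix(c(100, 300, 50, 900, 250, 40, 700, 80), nrow = 2)
  M <- t(P0 %*% E0)
  rownames(M) <- paste0("s", 1:4)
  perm <- c(3, 1, 4, 2)
  f <- nmfDecompose(M, 2, seed = 9, maxIter = 3000, tol = 1e-12)
  fp <- nmfDecompose(M[perm, ], 2, seed = 9, maxIter = 3000, tol = 1e-12)
  # align signatures of the two runs by best cosine, then compare exposures
  S <- crossprod(signatureProbs(f), signatureProbs(fp))
  map <- apply(S, 1, which.max)
  expect_true(all(sort(map) == 1:2))
  for (k in 1:2) {
    expect_gt(cosineSimilarity(signatureProbs(f)[, k],
                               signatureProbs(fp)[, map[k]]), 0.9999)
    expect_equal(unname(exposures(f)[k, perm]),
                 unname(exposures(fp)[map[k], ]), tolerance = 0.05)
  }
})

test_that("NNLS refit reproduces exposures on noiseless exact-rank data", {
  P0 <- twoSigs()
  E0 <- matrix(c(120, 40, 310, 220, 75, 600), nrow = 2)
  M <- t(P0 %*% E0)
  sigs <- signatureSet(P0)
  E <- nnlsExposures(sigs, M)
  expect_equal(unname(E), unname(E0), tolerance = 1e-6)
})

test_that("cosine similarity obeys the closed forms", {
  v <- numeric(96)
  a <- v; a[1:2] <- 1
  b <- v; b[1] <- 1
  d <- v; d[90] <- 2
  expect_equal(cosineSimilarity(a, a), 1.0)
  expect_equal(cosineSimilarity(a, d), 0.0)
  expect_equal(cosineSimilarity(a, b), 1 / sqrt(2))
  expect_error(cosineSimilarity(a, v), "zero vector")
})

test_that("reference matching finds exact copies and breaks ties low", {
  P0 <- twoSigs()
  q <- signatureSet(P0[, 1, drop = FALSE], names = "query")
  flat <- matrix(1 / 96, 96, 1, dimnames = list(contextClasses(), NULL))
  ref <- signatureSet(cbind(flat, P0[, 1], P0[, 2], P0[, 1]),
                      names = c("R1", "R2", "R3", "R4"))
  mt <- matchToReference(q, ref)
  expect_equal(mt$best$reference, "R2")   # tie R2/R4 broken by lowest index
  expect_equal(mt$best$cosine, 1.0)
  expect_true(mt$best$tie)
  # invariance to reference order up to the tie rule
  ref2 <- signatureSet(cbind(P0[, 2], P0[, 1], flat),
                       names = c("A", "B", "C"))
  expect_equal(matchToReference(q, ref2)$best$reference, "B")
  # mismatched class ordering is fatal
  Pbad <- P0[rev(seq_len(96)), , drop = FALSE]
  qbad <- signatureSet(P0)
  methods::slot(qbad, "probs", check = FALSE) <- Pbad  # forge bad ordering
  expect_error(matchToReference(qbad, ref), "ordering")
})

test_that("complete linkage reproduces a brute-force 4-leaf example", {
  set.seed(21)
  X <- matrix(runif(96 * 4), 96, 4)
  X <- sweep(X, 2, colSums(X), "/")
  rownames(X) <- contextClasses()
  sigs <- signatureSet(X, names = paste0("q", 1:4))
  ref <- signatureSet(X[, 1:2] * 0 + matrix(runif(96 * 2), 96, 2),
                      names = c("r1", "r2"))
  mt <- matchToReference(sigs, ref)
  U <- cbind(signatureProbs(sigs), signatureProbs(ref))
  nrm <- sqrt(colSums(U^2))
  D <- 1 - crossprod(U) / outer(nrm, nrm)
  diag(D) <- 0
  expect_equal(sort(mt$tree$height), completeLinkageOracle(D),
               tolerance = 1e-12)
  expect_match(mt$newick, "^\\(.*\\);$")
})

test_that("exposure cohort comparison matches the pooled-variance closed form", {
  pr <- rbind(S1 = c(0.1, 0.2, 0.6, 0.7), S2 = c(0.9, 0.8, 0.4, 0.3))
  colnames(pr) <- paste0("s", 1:4)
  co <- data.frame(sample = paste0("s", 1:4), cohort = c("A", "A", "B", "B"))
  res <- compareExposure(pr, co, "S1", "A", "B")
  # sp^2 = 0.005, t = -0.5 / sqrt(0.005 * (1/2 + 1/2))
  expect_equal(res$t, -0.5 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(res$meanA, 0.15)
  # identical cohorts: t = 0, p = 1
  pr2 <- rbind(S1 = c(0.2, 0.4, 0.2, 0.4))
  colnames(pr2) <- paste0("s", 1:4)
  same <- compareExposure(pr2, co, "S1", "A", "B")
  expect_equal(same$t, 0)
  expect_equal(same$pValue, 1)
  expect_error(compareExposure(pr, data.frame(sample = paste0("s", 1:4),
                                              cohort = c("A", "B", "B", "B")),
                               "S1", "A", "B"), "A")
})

test_that("the cohort contrast has power at the emulated effect size", {
  # per-sample mixture weights drawn from the packaged profiles; the tested
  # contrast is the APOBEC-type proportion, 9% vs 22% cohort means. The
  # Welch variant is the right tool here: the larger cohort also has the
  # larger between-sample variance, which makes the pooled test conservative
  set.seed(31)
  bq <- bqTcProfile("exome"); tc <- tcgaTcProfile()
  co <- data.frame(sample = c(paste0("a", 1:15), paste0("b", 1:82)),
                   cohort = rep(c("BQ-TC", "TCGA-TC"), c(15, 82)))
  rej <- replicate(500, {
    a <- replicate(15, quidsig:::drawMixtureWeights(bq)["SigTCN"])
    b <- replicate(82, quidsig:::drawMixtureWeights(tc)["SigTCN"])
    pr <- matrix(c(a, b), nrow = 1, dimnames = list("SigTCN", co$sample))
    compareExposure(pr, co, "SigTCN", "BQ-TC", "TCGA-TC",
                    welch = TRUE)$pValue < 0.05
  })
  expect_gt(mean(rej), 0.8)
})
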