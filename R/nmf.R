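# De-novo mutational signature extraction.
#
# The factorization engine below is a from-scratch multiplicative-update NMF
# under the Frobenius objective ||V - P E||_F, V the transposed 96 x samples
# count matrix. Rank selection follows the bootstrap scheme used for SBS
# signature deciphering: per candidate K, Monte-Carlo resample each sample's
# 96-vector, factorize every replicate, pool the extracted signatures,
# partition them into K clusters on cosine distance and summarize cluster
# coherence (silhouette) as "signature stability" next to the mean Frobenius
# reconstruction error.

EPS <- 1e-12

frobenius <- function(A) sqrt(sum(A * A))

asCountMatrix <- function(M) {
  if (methods::is(M, "ContextMatrix")) M <- contextCounts(M)
  stopifnot2(is.matrix(M), "M must be a ContextMatrix or a samples x 96 matrix")
  stopifnot2(ncol(M) == 96L, "M must have 96 class columns")
  if (is.null(colnames(M))) colnames(M) <- contextClasses()
  stopifnot2(identical(colnames(M), contextClasses()),
             "count matrix columns must follow the canonical class order")
  if (is.null(rownames(M))) rownames(M) <- paste0("s", seq_len(nrow(M)))
  M
}

# one NMF run from a given nonnegative initialization; returns P (96 x K,
# unnormalized), E (K x S), the objective trace endpoints and iterations
nmfRun <- function(V, P, E, maxIter, tol) {
  obj0 <- frobenius(V - P %*% E)
  obj <- obj0
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    E <- E * (crossprod(P, V)) / (crossprod(P, P %*% E) + EPS)
    P <- P * (V %*% t(E)) / (P %*% E %*% t(E) + EPS)
    if (it %% 10L == 0L) {
      objNew <- frobenius(V - P %*% E)
      if (abs(obj - objNew) <= tol * max(obj, EPS)) {
        obj <- objNew
        break
      }
      obj <- objNew
    }
  }
  list(P = P, E = E, objective = frobenius(V - P %*% E),
       objectiveInit = obj0, iterations = it)
}

# normalize columns of P to probability vectors, moving the mass into E
normalizeFactors <- function(P, E) {
  cs <- colSums(P)
  cs[cs == 0] <- 1
  list(P = sweep(P, 2, cs, "/"), E = E * cs)
}

#' Nonnegative matrix factorization of a context matrix
#'
#' Minimizes the Frobenius reconstruction error \eqn{\|V - P E\|_F} by
#' multiplicative updates, where \eqn{V} is the transposed samples x 96 count
#' matrix, \eqn{P} the 96 x K signature matrix and \eqn{E} the K x samples
#' exposure matrix. The best of \code{nRestarts} random initializations (by
#' final objective) is kept; signature columns are renormalized to
#' probability vectors with the mass moved into the exposures. Deterministic
#' given \code{seed}.
#'
#' @param M a \linkS4class{ContextMatrix} or samples x 96 count matrix.
#' @param K factorization rank, \code{1 <= K <= min(96, n samples)}.
#' @param seed integer master seed for the restarts.
#' @param nRestarts random restarts (best kept).
#' @param maxIter maximum multiplicative updates per restart.
#' @param tol relative objective-change convergence tolerance (checked every
#'   10 iterations).
#' @return an \linkS4class{NmfFit}.
#' @export
nmfDecompose <- function(M, K, seed = 1L, nRestarts = 10L, maxIter = 1000L,
                         tol = 1e-6) {
  M <- asCountMatrix(M)
  stopifnot2(K >= 1L && K <= min(96L, nrow(M)),
             "K must be between 1 and min(96, number of samples)")
  stopifnot2(sum(M) > 0, "all-zero count matrix")
  stopifnot2(all(rowSums(M) > 0), "every sample must have at least one count")
  V <- t(M)  # 96 x S
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(if (is.null(seed)) NULL else seed + (r - 1L), {
      P0 <- matrix(stats::runif(96L * K, 0.1, 1), 96L, K)
      E0 <- matrix(stats::runif(K * ncol(V), 0.1, 1) * mean(V), K, ncol(V))
      nmfRun(V, P0, E0, maxIter, tol)
    })
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  nf <- normalizeFactors(best$P, best$E)
  dimnames(nf$P) <- list(colnames(M), paste0("S", seq_len(K)))
  dimnames(nf$E) <- list(paste0("S", seq_len(K)), rownames(M))
  methods::new("NmfFit",
               signatures = methods::new("SignatureSet", probs = nf$P),
               exposures = nf$E, error = best$objective,
               iterations = best$iterations)
}

# multinomial resample of each sample's 96-vector with its own total as draw
# count; all-zero rows cannot arise when the input row totals are positive
bootstrapCounts <- function(M) {
  out <- M
  for (i in seq_len(nrow(M))) {
    n <- sum(M[i, ])
    out[i, ] <- as.integer(stats::rmultinom(1L, n, M[i, ] / n))
  }
  out
}

cosineDist <- function(X) {
  # columns of X are signatures
  nrm <- sqrt(colSums(X^2))
  S <- crossprod(X) / outer(nrm, nrm)
  d <- 1 - pmin(pmax(S, -1), 1)
  diag(d) <- 0
  stats::as.dist(d)
}

# partition pooled bootstrap signatures into K clusters on cosine distance
# and summarize: consensus (normalized centroids), stability (mean
# silhouette; for K = 1 the mean cosine similarity to the medoid)
clusterSignatures <- function(pool, K) {
  d <- cosineDist(pool)
  if (K == 1L) {
    med <- which.min(colSums(as.matrix(d)))
    stab <- mean(1 - as.matrix(d)[, med])
    cl <- rep(1L, ncol(pool))
  } else {
    pm <- cluster::pam(d, k = K, diss = TRUE)
    cl <- pm$clustering
    stab <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  }
  cons <- vapply(seq_len(K), function(k) {
    v <- rowMeans(pool[, cl == k, drop = FALSE])
    v / sum(v)
  }, numeric(nrow(pool)))
  list(consensus = cons, clustering = cl, stability = stab)
}

#' Extract consensus signatures at a fixed rank
#'
#' Runs \code{\link{nmfDecompose}} on \code{nBootstrap} Monte-Carlo resampled
#' matrices (per-sample multinomial resampling of the 96-vector with its own
#' total as draw count, preserving per-sample load), pools the extracted
#' signatures, partitions the pool into K clusters on cosine distance
#' (partitioning around medoids) and returns the normalized cluster centroids
#' as consensus signatures. Exposures are refit on the original matrix by
#' nonnegative least squares against the consensus.
#'
#' @inheritParams nmfDecompose
#' @param nBootstrap bootstrap replicates (>= 2).
#' @param nRestarts restarts per replicate.
#' @return list: \code{signatures} (a \linkS4class{SignatureSet}),
#'   \code{exposures} (K x samples NNLS refit), \code{stability} (mean
#'   silhouette width of the signature clusters), \code{error} (mean
#'   Frobenius error over replicates), \code{nBootstrap}.
#' @export
extractSignatures <- function(M, K, nBootstrap = 50L, seed = 1L,
                              nRestarts = 5L, maxIter = 1000L, tol = 1e-6) {
  M <- asCountMatrix(M)
  stopifnot2(nBootstrap >= 2L, "nBootstrap must be >= 2")
  pool <- matrix(0, 96L, 0L)
  errs <- numeric(nBootstrap)
  for (b in seq_len(nBootstrap)) {
    Mb <- withSeed(if (is.null(seed)) NULL else seed + 1000L * b,
                   bootstrapCounts(M))
    fit <- nmfDecompose(Mb, K,
                        seed = if (is.null(seed)) NULL else seed + 1000L * b + 1L,
                        nRestarts = nRestarts, maxIter = maxIter, tol = tol)
    pool <- cbind(pool, signatureProbs(fit))
    errs[b] <- reconstructionError(fit)
  }
  cs <- clusterSignatures(pool, K)
  cons <- cs$consensus
  dimnames(cons) <- list(contextClasses(), paste0("S", seq_len(K)))
  sigs <- methods::new("SignatureSet", probs = cons)
  E <- nnlsExposures(sigs, M)
  list(signatures = sigs, exposures = E, stability = cs$stability,
       error = mean(errs), nBootstrap = nBootstrap)
}

#' Rank selection by bootstrap stability and reconstruction error
#'
#' For each candidate rank K the bootstrap extraction of
#' \code{\link{extractSignatures}} is run and its mean signature stability
#' (silhouette on cosine distance over the pooled bootstrap signatures) and
#' mean Frobenius reconstruction error recorded. The chosen K is the largest
#' rank in the initial run of ranks whose stability stays at or above
#' \code{threshold}: the scan stops at the first stability drop below it.
#' The full profile is always returned for manual override.
#'
#' @inheritParams extractSignatures
#' @param kRange candidate ranks (classically 1..15; capped at the number of
#'   samples).
#' @param threshold stability threshold for the decision rule.
#' @param dropTol a rank whose stability falls more than this below the
#'   previous rank's ends the scan even if it is still above
#'   \code{threshold} (this is what "before a stability drop" means
#'   operationally).
#' @return list: \code{profile} (data.frame K / stability / error),
#'   \code{K} (chosen rank).
#' @export
selectRank <- function(M, kRange = 1:15, nBootstrap = 20L, seed = 1L,
                       nRestarts = 5L, threshold = 0.80, dropTol = 0.05,
                       maxIter = 1000L, tol = 1e-6) {
  M <- asCountMatrix(M)
  kRange <- kRange[kRange >= 1L & kRange <= min(96L, nrow(M))]
  stopifnot2(length(kRange) > 0L, "no admissible ranks in kRange")
  prof <- data.frame(K = kRange, stability = NA_real_, error = NA_real_)
  for (i in seq_along(kRange)) {
    ex <- extractSignatures(M, kRange[i], nBootstrap = nBootstrap,
                            seed = if (is.null(seed)) NULL else seed + 37L * i,
                            nRestarts = nRestarts, maxIter = maxIter, tol = tol)
    prof$stability[i] <- ex$stability
    prof$error[i] <- ex$error
  }
  pass <- prof$stability >= threshold
  drop_ <- c(FALSE, -diff(prof$stability) > dropTol)
  ok <- pass & !drop_
  chosen <- if (!ok[1L]) kRange[1L] else kRange[max(which(cumsum(!ok) == 0))]
  list(profile = prof, K = chosen)
}

#' Nonnegative least-squares exposure refit
#'
#' Solves, per sample, \eqn{\min_{e \ge 0} \|v - P e\|_2} where \eqn{v} is
#' the sample's 96-count vector and \eqn{P} the signature matrix.
#'
#' @param signatures a \linkS4class{SignatureSet}.
#' @param M a \linkS4class{ContextMatrix} or samples x 96 count matrix.
#' @return K x samples exposure matrix.
#' @export
nnlsExposures <- function(signatures, M) {
  M <- asCountMatrix(M)
  P <- signatureProbs(signatures)
  E <- vapply(seq_len(nrow(M)),
              function(i) pracma::lsqnonneg(P, as.numeric(M[i, ]))$x,
              numeric(ncol(P)))
  E <- matrix(E, nrow = ncol(P), dimnames = list(colnames(P), rownames(M)))
  E
}

#' Cosine similarity between two spectra
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return \eqn{a \cdot b / (\|a\| \|b\|)}; in [0, 1] for nonnegative input.
#' @export
cosineSimilarity <- function(a, b) {
  stopifnot2(length(a) == length(b), "vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  stopifnot2(na > 0 && nb > 0, "cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Match extracted signatures to a reference panel
#'
#' Computes the full cosine-similarity matrix between the query and reference
#' signatures (both must use the canonical 96-class ordering; a mismatch is
#' fatal), reports per query the best-matching reference (ties broken by the
#' lowest reference index, flagged), and builds a complete-linkage
#' hierarchical clustering of the union of both sets on distance
#' \code{1 - cosine}, returned both as an \code{hclust} tree and in Newick.
#'
#' @param query,reference \linkS4class{SignatureSet}s.
#' @return list: \code{similarity} (query x reference matrix), \code{best}
#'   (data.frame query / reference / cosine / tie), \code{tree}
#'   (\code{hclust}), \code{newick} (character).
#' @export
matchToReference <- function(query, reference) {
  Q <- signatureProbs(query); R <- signatureProbs(reference)
  stopifnot2(identical(rownames(Q), rownames(R)),
             "query and reference must use the identical 96-class ordering")
  normQ <- sqrt(colSums(Q^2)); normR <- sqrt(colSums(R^2))
  S <- crossprod(Q, R) / outer(normQ, normR)
  best <- data.frame(query = colnames(Q),
                     reference = colnames(R)[apply(S, 1, which.max)],
                     cosine = apply(S, 1, max),
                     tie = apply(S, 1, function(r) sum(r == max(r)) > 1L),
                     stringsAsFactors = FALSE)
  U <- cbind(Q, R)
  hc <- stats::hclust(cosineDist(U), method = "complete")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(similarity = S, best = best, tree = hc, newick = nwk)
}

#' Per-sample exposure proportions
#'
#' @param E K x samples exposure matrix.
#' @return matrix of the same shape with columns summing to 1.
#' @export
exposureProportions <- function(E) {
  cs <- colSums(E)
  stopifnot2(all(cs > 0), "sample with all-zero exposures")
  sweep(E, 2, cs, "/")
}

#' Compare a signature's exposure proportion between two cohorts
#'
#' Classic unpaired two-sided t-test (pooled variance by default; Welch by
#' flag) on per-sample exposure proportions of one signature between two
#' cohorts.
#'
#' @param proportions K x samples proportion matrix
#'   (\code{\link{exposureProportions}}).
#' @param cohorts data.frame with columns \code{sample}, \code{cohort}
#'   covering every compared sample.
#' @param signature row name (or index) of the signature to compare.
#' @param cohortA,cohortB the two cohort labels.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list: \code{meanA}, \code{meanB}, \code{t}, \code{pValue},
#'   \code{nA}, \code{nB}.
#' @export
compareExposure <- function(proportions, cohorts, signature, cohortA, cohortB,
                            welch = FALSE) {
  lab <- cohorts$cohort[match(colnames(proportions), cohorts$sample)]
  a <- proportions[signature, lab == cohortA & !is.na(lab)]
  b <- proportions[signature, lab == cohortB & !is.na(lab)]
  if (length(a) < 2L) stop("cohort '", cohortA, "' has fewer than 2 samples")
  if (length(b) < 2L) stop("cohort '", cohortB, "' has fewer than 2 samples")
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(meanA = mean(a), meanB = mean(b), t = unname(tt$statistic),
       pValue = tt$p.value, nA = length(a), nB = length(b))
}
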