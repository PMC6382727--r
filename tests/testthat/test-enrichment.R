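test_that("window arithmetic follows the core/flank/buffer contract", {
  g <- flatGenome(20000)
  isl <- GenomicRanges::GRanges("1", IRanges::IRanges(10001, 10200))
  w <- buildWindows(isl, g)
  core <- as.data.frame(coreWindows(w))
  flank <- as.data.frame(flankWindows(w))
  expect_equal(c(core$start, core$end), c(9951, 10250))
  expect_equal(w@coreBp, 200 + 100)            # island length + 100
  expect_equal(flank$start, c(9001, 10701))
  expect_equal(flank$end, c(9500, 11200))
  expect_equal(w@flankBp, 1000)
})

test_that("an island at the chromosome edge is clipped, flank emptied", {
  g <- flatGenome(4000)
  isl <- GenomicRanges::GRanges("1", IRanges::IRanges(30, 129))
  w <- buildWindows(isl, g)
  core <- as.data.frame(coreWindows(w))
  expect_equal(core$start, 1)                   # left core clipped at 1
  expect_equal(core$end, 179)
  flank <- as.data.frame(flankWindows(w))
  expect_equal(nrow(flank), 1L)                 # left flank entirely gone
  expect_equal(c(flank$start, flank$end), c(630, 1129))
})

test_that("windows of clustered islands match the per-position oracle", {
  # two islands 600 nt apart: facing flanks truncated at the neighbor's core
  g <- flatGenome(30000)
  starts <- c(5001, 5901); ends <- c(5300, 6200)
  isl <- GenomicRanges::GRanges("1", IRanges::IRanges(starts, ends))
  w <- buildWindows(isl, g)
  pos <- 3500:8000
  oracle <- vapply(pos, membershipOracle, character(1),
                   islandStarts = starts, islandEnds = ends, chromLen = 30000)
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(pos, width = 1))
  got <- rep("neither", length(pos))
  got[GenomicRanges::countOverlaps(gr, coreWindows(w)) > 0] <- "core"
  got[GenomicRanges::countOverlaps(gr, flankWindows(w)) > 0] <- "flank"
  expect_identical(got, oracle)
  # disjointness and totals
  expect_length(GenomicRanges::findOverlaps(coreWindows(w), flankWindows(w)), 0L)
  expect_equal(w@coreBp, sum(GenomicRanges::width(coreWindows(w))))
})

test_that("records are assigned to the window holding their position", {
  g <- flatGenome(20000)
  isl <- GenomicRanges::GRanges("1", IRanges::IRanges(10001, 10200))
  w <- buildWindows(isl, g)
  s <- getBases(g, "1", 1, 20000)
  mkrec <- function(p) {
    r <- substring(s, p, p)
    mutationCatalog("s", "1", p, r, setdiff(c("A","C","G","T"), r)[1])
  }
  a <- quidsig:::assignWindows(mkrec(10100), w, g)   # island center
  expect_equal(a$zone, "core")
  expect_equal(quidsig:::assignWindows(mkrec(10950), w, g)$zone, "flank")
  expect_equal(quidsig:::assignWindows(mkrec(10400), w, g)$zone, "neither")
})

test_that("enrichment fold and Fisher p follow their definitions", {
  et <- enrichmentTest(100, 50, 1e6, 1.025e6)
  expect_equal(et$fold, 2.05)
  sym <- enrichmentTest(10, 10, 1000, 1000)
  expect_equal(sym$fold, 1.0)
  expect_equal(sym$pValue, 1.0)
  expect_true(enrichmentTest(3, 0, 100, 100)$infinite)
  expect_error(enrichmentTest(11, 1, 10, 100), "exceeds")
  # doubling counts and denominators keeps the fold, cannot raise the p
  a <- enrichmentTest(30, 12, 5000, 6000)
  b <- enrichmentTest(60, 24, 10000, 12000)
  expect_equal(b$fold, a$fold)
  expect_lte(b$pValue, a$pValue + 1e-12)
})

test_that("Fisher p equals the brute-force hypergeometric oracle", {
  set.seed(41)
  cases <- cbind(n1 = sample(5:250, 60, TRUE), n2 = sample(5:250, 60, TRUE))
  for (i in seq_len(nrow(cases))) {
    n1 <- cases[i, 1]; n2 <- cases[i, 2]
    k1 <- rbinom(1, n1, runif(1, 0.02, 0.5))
    k2 <- rbinom(1, n2, runif(1, 0.02, 0.5))
    expect_equal(geneFrequencyTest(k1, n1, k2, n2)$pValue,
                 fisherOracle(k1, n1, k2, n2), tolerance = 1e-9)
  }
})

test_that("per-class tallies are conserved and match a brute-force recount", {
  sim <- simulateGenome(length = 1e5, nIslands = 4, islandLength = 500,
                        seed = 51)
  w <- buildWindows(sim$islands, sim$genome)
  mix <- mixtureVector(syntheticSignatures(), c(0.5, 0.2, 0.3))
  cat <- simulateCatalog(sim$genome, sim$islands, mix, 1500,
                         islandMultiplier = 2, seed = 52)
  et <- perClassEnrichment(cat, w, sim$genome)
  allRow <- et[et$family == "all", ]
  six <- et[et$family == "six", ]
  expect_equal(sum(six$nCore), allRow$nCore)
  expect_equal(sum(six$nFlank), allRow$nFlank)
  # per-position brute-force recount of the all-class tallies
  st <- GenomicRanges::start(sim$islands); en <- GenomicRanges::end(sim$islands)
  zones <- vapply(GenomicRanges::start(mutations(cat)), membershipOracle,
                  character(1), islandStarts = st, islandEnds = en,
                  chromLen = 1e5)
  expect_equal(allRow$nCore, sum(zones == "core"))
  expect_equal(allRow$nFlank, sum(zones == "flank"))
})

test_that("elevation confined to C>T at NCG surfaces as exactly those classes", {
  sim <- simulateGenome(length = 4e5, nIslands = 8, islandLength = 800,
                        seed = 61)
  w <- buildWindows(sim$islands, sim$genome)
  # background: flat process, no island elevation
  flat <- mixtureVector(syntheticSignatures(), c(0, 0, 1))
  bg <- simulateCatalog(sim$genome, sim$islands, flat, 4000,
                        islandMultiplier = 1, sample = "s", seed = 62)
  # spike: C>T at the four NCG contexts only, strongly island-elevated
  spike <- stats::setNames(numeric(96), contextClasses())
  spike[paste0("C>T:", c("A", "C", "G", "T"), "CG")] <- 0.25
  sp <- simulateCatalog(sim$genome, sim$islands, spike, 700,
                        islandMultiplier = 8, sample = "s", seed = 63)
  et <- perClassEnrichment(combineCatalogs(list(bg, sp)), w, sim$genome)
  ct16 <- et[et$family == "sixteen", ]
  sigCls <- ct16$class[!is.na(ct16$pValue) & ct16$pValue < 0.05]
  expect_setequal(sigCls, paste0("C>T:", c("A", "C", "G", "T"), "CG"))
})

test_that("fold estimates 1 under the null and the multiplier when set", {
  # null calibration at reduced scale (the 200-seed calibration runs in the
  # end-to-end suite)
  sim <- simulateGenome(length = 2e5, nIslands = 5, islandLength = 500,
                        seed = 71)
  w <- buildWindows(sim$islands, sim$genome)
  mix <- mixtureVector(syntheticSignatures(), c(0.5, 0.1, 0.4))
  folds <- vapply(1:30, function(s) {
    cat <- simulateCatalog(sim$genome, sim$islands, mix, 2500,
                           islandMultiplier = 1, seed = 700 + s)
    et <- perClassEnrichment(cat, w, sim$genome)
    et$fold[et$family == "all"]
  }, numeric(1))
  expect_equal(mean(folds), 1, tolerance = 0.1)
  # and the multiplier is recovered when it is not 1 (larger genome so every
  # CpG-context class keeps ample eligible sites)
  sim2 <- simulateGenome(length = 5e5, nIslands = 10, islandLength = 500,
                         seed = 73)
  w2 <- buildWindows(sim2$islands, sim2$genome)
  cat2 <- simulateCatalog(sim2$genome, sim2$islands, mix, 20000,
                          islandMultiplier = 2.05, seed = 72)
  et2 <- perClassEnrichment(cat2, w2, sim2$genome)
  expect_equal(et2$fold[et2$family == "all"], 2.05, tolerance = 0.25)
})
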