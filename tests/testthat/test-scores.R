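test_that("percentile rank maps counts onto [0,1] with average-rank ties", {
  expect_equal(percentileRank(c(3, 1, 2)), c(1.0, 0.0, 0.5))
  expect_equal(percentileRank(c(5, 5, 5, 5)), rep(0.5, 4))
  expect_equal(percentileRank(c(0, 0, 7)), c(0.25, 0.25, 1.0))
  expect_error(percentileRank(3), "L >= 2")
})

test_that("CN profile spans 0 and 1 when extremes are untied", {
  sim <- randomCoupledMsa(L = 20, N = 60, nPlanted = 2, nConserved = 2,
                          gapRate = 0, seed = 61)
  aln <- sim$alignment
  mask <- applyColumnFilters(aln)
  cs <- selectCouplings(covariationMatrix(aln, mask), L = queryLength(aln))
  prof <- couplingNumber(cs)
  expect_equal(nrow(prof), 20L)
  expect_true(all(prof$CN >= 0 & prof$CN <= 1))
  expect_equal(sum(prof$couplingCount), 2L * nrow(couplingPairs(cs)))
  cnt <- prof$couplingCount
  if (sum(cnt == max(cnt)) == 1L) expect_equal(max(prof$CN), 1.0)
  if (sum(cnt == min(cnt)) == 1L) expect_equal(min(prof$CN), 0.0)
  # CN is non-decreasing in the count
  ord <- order(cnt)
  expect_true(all(diff(prof$CN[ord]) >= 0))
})

test_that("pair counts tally rows with non-gap residues at both columns", {
  aln <- pairColumnAlignment(list(c("A", "K"), c("A", "K"), c("A", "K"),
                                  c("S", "E"), c("S", "E"), c("A", "E")))
  t <- pairCounts(aln, 1, 2)
  cm <- pairCountMatrix(t)
  expect_equal(cm["A", "K"], 3L)
  expect_equal(cm["S", "E"], 2L)
  expect_equal(cm["A", "E"], 1L)
  expect_equal(sum(cm), 6L)
  expect_equal(t@N, 6L)
  # the query row guarantees n(query_i, query_j) >= 1
  expect_gte(cm["A", "K"], 1L)
})

test_that("gapped rows are excluded from pair counts", {
  aln <- toyAlignment(c(q = "AK", h1 = "A-", h2 = "-K", h3 = "SE"))
  t <- pairCounts(aln, 1, 2)
  expect_equal(t@N, 2L)
  expect_equal(pairCountMatrix(t)["A", "K"], 1L)
})

test_that("entropy differences follow the +1-smoothed log-ratio", {
  aln <- pairColumnAlignment(c(replicate(4, c("A", "K"), simplify = FALSE),
                               list(c("L", "K")),
                               replicate(5, c("S", "E"), simplify = FALSE)))
  t <- pairCounts(aln, 1, 2)
  # n(A,K) = 4, n(L,K) = 1 -> -ln(2/4) = ln 2
  expect_equal(deltaEntropy(t, "A", "K", "L"), log(2))
  # n(S,E) = 5, n(W,E) = 0 -> ln 5
  expect_equal(deltaEntropy(t, "S", "E", "W"), log(5))
  # n(gamma,beta)+1 == n(alpha,beta) -> exactly 0
  aln2 <- pairColumnAlignment(c(replicate(2, c("A", "K"), simplify = FALSE),
                                list(c("L", "K"), c("S", "E"))))
  t2 <- pairCounts(aln2, 1, 2)
  expect_equal(deltaEntropy(t2, "A", "K", "L"), 0)
  expect_error(deltaEntropy(t, "W", "K", "A"), "= 0")
  expect_error(deltaEntropy(t, "X", "K", "A"), "non-standard")
})

test_that("delta entropy equals the log-factorial entropy change", {
  # independent oracle: S = ln(N!/prod n!) via lgamma; moving one count from
  # (alpha,beta) to (gamma,beta) must change S by exactly deltaEntropy
  set.seed(71)
  for (rep in 1:200) {
    counts <- matrix(0L, 20, 20,
                     dimnames = list(coevoscore:::AA_STANDARD,
                                     coevoscore:::AA_STANDARD))
    nz <- sample(400, sample(3:12, 1))
    counts[nz] <- rpois(length(nz), 4) + 1L
    t <- new("PairCountTable", counts = counts, N = sum(counts),
             i = 1L, j = 2L)
    ab <- which(counts > 0, arr.ind = TRUE)
    pick <- ab[sample(nrow(ab), 1), ]
    alpha <- rownames(counts)[pick[1]]
    beta <- colnames(counts)[pick[2]]
    gamma <- sample(setdiff(rownames(counts), alpha), 1)
    after <- counts
    after[alpha, beta] <- after[alpha, beta] - 1L
    after[gamma, beta] <- after[gamma, beta] + 1L
    expect_equal(deltaEntropy(t, alpha, beta, gamma),
                 logFactorialEntropy(after) - logFactorialEntropy(counts),
                 tolerance = 1e-9)
  }
})

test_that("cost of coupling averages partner entropy differences", {
  sim <- randomCoupledMsa(L = 15, N = 50, nPlanted = 2, nConserved = 1,
                          gapRate = 0.05, seed = 81)
  aln <- sim$alignment
  mask <- applyColumnFilters(aln)
  cs <- selectCouplings(covariationMatrix(aln, mask, minSeqPairs = 5),
                        L = queryLength(aln))
  q <- querySeq(aln)
  pos <- which(lengths(cs@partners) > 0)[1]
  alt <- setdiff(c("A", "S", "L"), q[pos])[1]
  v <- list(position = pos, wt = q[pos], alt = alt)
  # hand oracle: explicit loop over partners
  expected <- mean(vapply(couplingPartners(cs, pos), function(j)
    deltaEntropy(pairCounts(aln, pos, j), q[pos], q[j], alt), numeric(1)))
  expect_equal(costOfCoupling(aln, cs, v), expected)
  # wild-type mismatch is an error at scoring time
  wrongWt <- setdiff(c("A", "S", "L", "G"), c(q[pos], alt))[1]
  expect_error(costOfCoupling(aln, cs,
                              list(position = pos, wt = wrongWt, alt = alt)),
               "mismatch")
})

test_that("residues without partners get CC = 0", {
  # only columns 1 and 2 covary enough to be selected with budget 1 via
  # a small multiplier; partner-free positions must cost 0
  aln <- randomAlignment(L = 8, N = 30, seed = 91, gapRate = 0)
  mask <- applyColumnFilters(aln)
  cs <- selectCouplings(covariationMatrix(aln, mask, minSeqPairs = 5),
                        L = 8, multiplier = 1 / 8)  # budget = 1 pair
  free <- which(lengths(cs@partners) == 0)[1]
  q <- querySeq(aln)
  alt <- setdiff(c("A", "S", "L"), q[free])[1]
  expect_equal(costOfCoupling(aln, cs,
                              list(position = free, wt = q[free], alt = alt)),
               0)
})

test_that("CE is the exact product of CN and CC", {
  expect_equal(ceScore(0, 5.3), 0)
  expect_equal(ceScore(0.5, 2.0), 1.0)
  expect_identical(ceScore(0.3, 1.7), 0.3 * 1.7)
  expect_error(ceScore(1.2, 1))
})

test_that("CS is the single-column entropy analog", {
  aln <- toyAlignment(setNames(
    c("A", rep("A", 9)), c("q", paste0("h", 1:9))))
  # fully conserved column of 10 A's: CS(A->gamma) = ln 10
  expect_equal(csScore(aln, list(position = 1, wt = "A", alt = "W")),
               log(10))
  # monotone: rarer alternates never score lower
  aln2 <- toyAlignment(setNames(
    c("A", "A", "A", "A", "S", "S", "W"), c("q", paste0("h", 1:6))))
  csW <- csScore(aln2, list(position = 1, wt = "A", alt = "W"))  # n=1
  csS <- csScore(aln2, list(position = 1, wt = "A", alt = "S"))  # n=2
  csL <- csScore(aln2, list(position = 1, wt = "A", alt = "L"))  # n=0
  expect_gte(csW, csS)
  expect_gte(csL, csW)
  expect_error(csScore(aln2, list(position = 1, wt = "S", alt = "A")),
               "mismatch")
})

test_that("batch scoring is pure and equals single calls", {
  sim <- randomCoupledMsa(L = 20, N = 60, nPlanted = 2, nConserved = 2,
                          gapRate = 0.05, seed = 101)
  aln <- sim$alignment
  q <- querySeq(aln)
  toks <- vapply(c(3, 7, 3), function(p)
    paste0(q[p], p, setdiff(c("A", "S", "L"), q[p])[1]), character(1))
  res <- scoreVariants(aln, toks)
  # duplicate variant scores identically
  expect_equal(res[res$position == 3, -1][1, ], res[res$position == 3, -1][2, ],
               ignore_attr = TRUE)
  # CE = CN x CC bit-exactly on every row
  expect_identical(res$CE, res$CN * res$CC)
  # batch equals per-variant single calls
  mask <- applyColumnFilters(aln)
  cs <- selectCouplings(covariationMatrix(aln, mask), L = queryLength(aln))
  for (r in seq_len(nrow(res))) {
    v <- list(position = res$position[r], wt = res$wt[r], alt = res$alt[r])
    expect_equal(res$CC[r], costOfCoupling(aln, cs, v))
    expect_equal(res$CS[r], csScore(aln, v))
  }
})

test_that("per-variant problems are flagged without aborting the batch", {
  sim <- randomCoupledMsa(L = 12, N = 40, nPlanted = 1, nConserved = 1,
                          gapRate = 0, seed = 111)
  aln <- sim$alignment
  q <- querySeq(aln)
  good <- paste0(q[2], 2, setdiff(c("A", "S"), q[2])[1])
  badWt <- paste0(setdiff(c("A", "S", "L"), q[4])[1], 4, "W")
  vars <- parseVariants(c(good, badWt, "A999S"))
  res <- scoreVariants(aln, vars)
  expect_equal(nrow(res), 3L)
  expect_equal(res$flags[2], "wt_mismatch")
  expect_equal(res$flags[3], "bad_position")
  expect_true(is.na(res$CE[2]) && is.na(res$CE[3]))
  expect_false(is.na(res$CE[1]))
})

test_that("breaking a planted pairing costs more entropy than the
           compensatory-state substitution", {
  worse <- 0L
  for (seed in 1:20) {
    sim <- generateCoupledMsa(
      L = 20, N = 120,
      plantedPairs = list(plantedPair(4, 13,
        states = list(c("A", "K"), c("S", "E")), w = 0.9)),
      gapRate = 0.05, seed = seed + 300)
    aln <- sim$alignment
    q <- querySeq(aln)
    if (q[4] != "A") next  # fix the wild-type state for a clean contrast
    t <- pairCounts(aln, 4, 13)
    breaking <- deltaEntropy(t, "A", q[13], "W")   # never-compensated residue
    comp <- deltaEntropy(t, "A", q[13], "S")       # compensatory-state residue
    if (breaking > comp) worse <- worse + 1L
    expect_gte(breaking, comp)
  }
  expect_gte(worse, 5L)  # strict inequality in most draws
})
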