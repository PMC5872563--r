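test_that("allele dissimilarity is 1 only for two differing calls", {
  expect_equal(dissimilarity(0, 1), 1L)
  expect_equal(dissimilarity(2, NA), 0L)
  expect_equal(dissimilarity(NA, 2), 0L)
  expect_equal(dissimilarity(3, 3), 0L)
  expect_equal(dissimilarity(c(0, 1, NA), c(0, 2, 1)), c(0L, 1L, 0L))
})

test_that("MEC is zero for consistent fragments and counts minimal flips", {
  set.seed(81)
  H <- HaplotypeSet(matrix(sample(0:3, 30, replace = TRUE), 3, 10))
  fr <- fragmentsFromHaps(H, readsPerHap = 3, sitesPerRead = 6)
  expect_equal(as.integer(mecScore(fr, H)), 0L)

  h2 <- HaplotypeSet(rbind(c(0L, 0L), c(1L, 1L)))
  fr2 <- FragmentSet(read = c(1, 1, 2, 2, 3, 3), site = rep(1:2, 3),
                     allele = c(0, 0, 1, 1, 0, 1))
  s <- mecScore(fr2, h2)
  expect_equal(as.integer(s), 1L)
  expect_equal(attr(s, "assignment")[1:2], c(1L, 2L))
})

test_that("MEC agrees with the brute-force triple loop on random instances", {
  set.seed(82)
  for (rep in 1:25) {
    k <- sample(2:5, 1); m <- sample(3:10, 1)
    a <- matrix(sample(c(0:3, NA), k * m, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), k, m)
    fr <- randomFragmentSet(nReads = sample(3:8, 1), nSites = m)
    expect_equal(as.integer(mecScore(fr, HaplotypeSet(a))),
                 bruteMEC(fr, HaplotypeSet(a)))
  }
})

test_that("MEC is invariant to haplotype column order and read order", {
  set.seed(83)
  H <- HaplotypeSet(matrix(sample(0:3, 24, replace = TRUE), 3, 8))
  fr <- randomFragmentSet(nReads = 6, nSites = 8)
  base <- as.integer(mecScore(fr, H))
  expect_equal(as.integer(mecScore(fr, HaplotypeSet(alleles(H)[c(3, 1, 2), ]))),
               base)
  perm <- sample(6)
  fr2 <- FragmentSet(perm[fr@read], fr@site, fr@allele, nSites = 8,
                     nReads = 6)
  expect_equal(as.integer(mecScore(fr2, H)), base)
})

test_that("CPR is permutation-invariant and scores partial mismatches", {
  truth <- HaplotypeSet(rbind(c(0L, 0L), c(1L, 1L)))
  swapped <- HaplotypeSet(rbind(c(1L, 1L), c(0L, 0L)))
  expect_equal(as.numeric(cprScore(swapped, truth)), 1)
  oneWrong <- HaplotypeSet(rbind(c(0L, 1L), c(1L, 1L)))
  expect_equal(as.numeric(cprScore(oneWrong, truth)), 0.75)
  expect_error(cprScore(HaplotypeSet(matrix(0L, 2, 3)), truth), "same")
})

test_that("CPR equals the permutation-enumeration oracle on random pairs", {
  set.seed(84)
  for (rep in 1:20) {
    k <- sample(2:4, 1); m <- sample(3:8, 1)
    est <- HaplotypeSet(matrix(sample(c(0:3, NA), k * m, replace = TRUE,
                                      prob = c(rep(0.23, 4), 0.08)), k, m))
    tru <- HaplotypeSet(matrix(sample(0:3, k * m, replace = TRUE), k, m))
    expect_equal(as.numeric(cprScore(est, tru)), bruteCPR(est, tru))
  }
})

test_that("the assignment solver matches exhaustive permutations up to k = 6", {
  set.seed(85)
  for (k in 3:6) for (rep in 1:5) {
    cost <- matrix(sample.int(30, k * k, replace = TRUE), k, k)
    ex <- tensorphase:::.lsapExhaustive(cost)
    hu <- tensorphase:::.lsapHungarian(cost)
    expect_equal(hu$cost, ex$cost)
    expect_equal(sum(cost[cbind(seq_len(k), hu$mapping)]), hu$cost)
    expect_true(all(sort(hu$mapping) == seq_len(k)))
  }
})

test_that("uncalled estimate sites count as agreement in CPR", {
  truth <- HaplotypeSet(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)))
  est <- HaplotypeSet(rbind(c(0L, NA, 0L), c(1L, NA, 1L)))
  expect_equal(as.numeric(cprScore(est, truth)), 1)
})

test_that("evaluatePhasing reports MEC, CPR percent and the best mapping", {
  truth <- HaplotypeSet(rbind(c(0L, 0L), c(1L, 1L)))
  fr <- FragmentSet(read = c(1, 1, 2, 2), site = rep(1:2, 2),
                    allele = c(0, 0, 1, 1))
  rep1 <- evaluatePhasing(fr, HaplotypeSet(rbind(c(1L, 1L), c(0L, 0L))), truth)
  expect_equal(rep1$mec, 0L)
  expect_equal(rep1$cprPercent, 100)
  expect_equal(rep1$bestMapping, c(2L, 1L))
  expect_equal(rep1$perReadAssignment, c(2L, 1L))
})
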