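makeObs <- function(frags) encodeFragments(frags)

test_that("objective is zero at a consistent factorization and counts residuals", {
  set.seed(61)
  k <- 2; m <- 6
  H <- HaplotypeSet(matrix(sample(0:3, k * m, replace = TRUE), k, m))
  fr <- fragmentsFromHaps(H, readsPerHap = 3, sitesPerRead = 4)
  obs <- makeObs(fr)
  V <- unfoldHaplotypes(H)
  expect_equal(objectiveValue(obs, attr(fr, "origins"), V), 0)

  # one covered fiber flipped to a different allele costs exactly 1
  fr2 <- fr
  fr2@allele[1] <- (fr2@allele[1] + 1L) %% 4L
  expect_equal(objectiveValue(makeObs(fr2), attr(fr, "origins"), V), 1)
})

test_that("objective agrees with a double-loop summation oracle", {
  set.seed(62)
  for (rep in 1:10) {
    fr <- randomFragmentSet(nReads = 6, nSites = 7)
    obs <- makeObs(fr)
    k <- 3
    V <- matrix(runif(4 * 7 * k), 4 * 7, k)
    origins <- sample.int(k, 6, replace = TRUE)
    expect_equal(objectiveValue(obs, origins, V),
                 bruteObjective(obs, origins, V))
  }
})

test_that("reads are assigned to the masked-distance minimizer", {
  H <- HaplotypeSet(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 2L, 2L)))
  V <- unfoldHaplotypes(H)
  fr <- FragmentSet(read = c(1, 1, 2), site = c(1, 2, 3),
                    allele = c(2, 2, 1), nSites = 3)
  expect_equal(assignReads(makeObs(fr), V), c(3L, 2L))
  # equidistant read goes to the lowest haplotype index
  H2 <- HaplotypeSet(rbind(c(0L, 0L), c(1L, 1L)))
  fr2 <- FragmentSet(read = c(1, 1), site = c(1, 2), allele = c(0, 1))
  expect_equal(assignReads(makeObs(fr2), unfoldHaplotypes(H2)), 1L)
})

test_that("assignment equals the dissimilarity-count argmin on binary V", {
  set.seed(63)
  for (rep in 1:20) {
    k <- sample(2:4, 1); m <- sample(3:8, 1)
    H <- HaplotypeSet(matrix(sample(0:3, k * m, replace = TRUE), k, m))
    fr <- randomFragmentSet(nReads = 6, nSites = m)
    got <- assignReads(makeObs(fr), unfoldHaplotypes(H))
    a <- alleles(H)
    for (i in 1:6) {
      sel <- fr@read == i
      counts <- vapply(seq_len(k), function(p)
        sum(dissimilarity(fr@allele[sel], a[p, fr@site[sel]])), numeric(1))
      expect_equal(got[i], which.min(counts))
    }
  }
})

test_that("gradient matches finite differences and masks uncovered fibers", {
  set.seed(64)
  fr <- randomFragmentSet(nReads = 5, nSites = 6)
  obs <- makeObs(fr)
  k <- 2
  V <- matrix(runif(24 * k, 0.2, 0.8), 24, k)
  origins <- sample.int(k, 5, replace = TRUE)
  G <- gradientV(obs, origins, V)
  eps <- 1e-6
  for (trial in 1:25) {
    r <- sample.int(24, 1); cc <- sample.int(k, 1)
    Vp <- V; Vp[r, cc] <- V[r, cc] + eps
    Vm <- V; Vm[r, cc] <- V[r, cc] - eps
    fd <- (objectiveValue(obs, origins, Vp) -
           objectiveValue(obs, origins, Vm)) / (2 * eps)
    expect_equal(G[r, cc], fd, tolerance = 1e-5)
  }
  # consistent factorization has zero gradient
  H <- HaplotypeSet(matrix(sample(0:3, 12, replace = TRUE), 2, 6))
  frc <- fragmentsFromHaps(H, readsPerHap = 2, sitesPerRead = 4)
  Gc <- gradientV(makeObs(frc), attr(frc, "origins"), unfoldHaplotypes(H))
  expect_equal(max(abs(Gc)), 0)
  # a site covered by no read contributes four zero rows
  fr2 <- FragmentSet(read = c(1, 2), site = c(1, 3), allele = c(0, 1),
                     nSites = 4)
  G2 <- gradientV(makeObs(fr2), c(1L, 2L), matrix(runif(32), 16, 2))
  expect_true(all(G2[c(2, 4) + rep(0:3 * 4, each = 2), ] == 0))
})

test_that("step size reduces to C/c under full observation and equal loads", {
  set.seed(65)
  k <- 2; m <- 3; cPerHap <- 4
  H <- HaplotypeSet(matrix(sample(0:3, k * m, replace = TRUE), k, m))
  fr <- fragmentsFromHaps(H, readsPerHap = cPerHap, sitesPerRead = m)
  obs <- makeObs(fr)
  origins <- attr(fr, "origins")
  V <- matrix(runif(4 * m * k), 4 * m, k)
  G <- gradientV(obs, origins, V)
  expect_equal(stepSize(G, origins, obs, C = 1), 1 / cPerHap)
  expect_equal(stepSize(G, origins, obs, C = 1.5), 1.5 / cPerHap)
  # single read, single haplotype column, full mask: alpha = C
  fr1 <- FragmentSet(read = c(1, 1, 1), site = 1:3, allele = c(0, 1, 2))
  obs1 <- makeObs(fr1)
  G1 <- gradientV(obs1, 1L, matrix(runif(12, 0.1, 0.9), 12, 1))
  expect_equal(stepSize(G1, 1L, obs1, C = 1), 1)
  # zero gradient signals convergence
  expect_true(is.na(stepSize(matrix(0, 12, 1), 1L, obs1)))
  expect_error(stepSize(G1, 1L, obs1, C = 2), "0, 2")
})

test_that("the projected update clamps entrywise into [0, 1]", {
  V <- matrix(c(0.1, 0.5, 0.9), 3, 1)
  G <- matrix(c(3, 0, -4), 3, 1)
  expect_equal(updateV(V, G, 0.1), matrix(c(0, 0.5, 1), 3, 1))
  expect_equal(updateV(V, matrix(0, 3, 1), 0.5), V)
})

test_that("spectral initialization is seeded and matches dense SVD", {
  set.seed(66)
  fr <- randomFragmentSet(nReads = 15, nSites = 10, minCov = 4, maxCov = 8)
  obs <- makeObs(fr)
  i1 <- initializeSolver(obs, 3, powerIterations = 100, seed = 7)
  i2 <- initializeSolver(obs, 3, powerIterations = 100, seed = 7)
  expect_identical(i1$V, i2$V)
  dense <- svd(as.matrix(obs@values) / i1$fiberFraction)
  expect_equal(i1$singularValues, dense$d[1:3], tolerance = 1e-6)
  expect_true(all(i1$V >= 0 & i1$V <= 1))
  expect_error(initializeSolver(obs, 100), "min")
})

test_that("full-rank noiseless observation is recovered from the spectral start", {
  set.seed(67)
  k <- 2; m <- 12
  H <- HaplotypeSet(matrix(sample(0:3, k * m, replace = TRUE), k, m))
  fr <- fragmentsFromHaps(H, readsPerHap = 6, sitesPerRead = m)  # full mask
  fit <- assembleHaplotypes(fr, k, init = "spectral", seed = 3, restarts = 2)
  expect_equal(mec(fit), 0L)
})

test_that("noiseless diploid assembly attains MEC 0 and CPR 1", {
  set.seed(68)
  m <- 50
  H <- HaplotypeSet(rbind(sample(0:1, m, replace = TRUE),
                          sample(0:1, m, replace = TRUE)))
  fr <- fragmentsFromHaps(H, readsPerHap = 10, sitesPerRead = m)
  fit <- assembleHaplotypes(fr, 2, seed = 4)
  expect_equal(mec(fit), 0L)
  expect_equal(as.numeric(cprScore(haplotypes(fit), H)), 1)
})

test_that("the hand-enumerated three-read instance reaches its optimum MEC 1", {
  fr <- FragmentSet(read = c(1, 1, 2, 2, 3, 3), site = rep(1:2, 3),
                    allele = c(0, 0, 1, 1, 0, 1))
  expect_equal(enumerateMECOptimum(fr), 1)
  fit <- assembleHaplotypes(fr, 2, seed = 1)
  expect_equal(mec(fit), 1L)
})

test_that("objective trace descends monotonically for C in (0, 2)", {
  set.seed(69)
  for (C in c(0.5, 1.0, 1.5)) {
    for (rep in 1:8) {
      k <- sample(2:3, 1)
      H <- HaplotypeSet(matrix(sample(0:3, k * 20, replace = TRUE), k, 20))
      fr <- fragmentsFromHaps(H, readsPerHap = 5, sitesPerRead = 6,
                              flipProb = 0.1)
      fit <- assembleHaplotypes(fr, k, C = C, seed = rep, restarts = 1)
      tr <- objectiveTrace(fit)
      expect_true(all(diff(tr) <= 1e-9))
    }
  }
})

test_that("iterates stay feasible and assignments stay indicators", {
  set.seed(70)
  H <- HaplotypeSet(matrix(sample(0:3, 30, replace = TRUE), 2, 15))
  fr <- fragmentsFromHaps(H, readsPerHap = 4, sitesPerRead = 5, flipProb = 0.1)
  obs <- makeObs(fr)
  V <- initializeSolver(obs, 2, seed = 1)$V
  for (t in 1:20) {
    o <- assignReads(obs, V)
    expect_true(all(o >= 1 & o <= 2))
    U <- assignmentMatrix(o, 2)
    expect_true(all(Matrix::rowSums(U) == 1))
    G <- gradientV(obs, o, V)
    a <- stepSize(G, o, obs)
    if (is.na(a)) break
    V <- updateV(V, G, a)
    expect_true(all(V >= 0 & V <= 1))
  }
})

test_that("relabeling the starting columns permutes output but not MEC", {
  set.seed(71)
  H <- HaplotypeSet(matrix(sample(0:3, 36, replace = TRUE), 3, 12))
  fr <- fragmentsFromHaps(H, readsPerHap = 5, sitesPerRead = 6)
  obs <- makeObs(fr)
  ctx <- tensorphase:::.solverContext(obs)
  V0 <- initializeSolver(obs, 3, seed = 2)$V
  run1 <- tensorphase:::.solveCore(ctx, obs, 3, 1, 200, 1e-6, V0)
  run2 <- tensorphase:::.solveCore(ctx, obs, 3, 1, 200, 1e-6, V0[, c(2, 3, 1)])
  h1 <- foldHaplotypes(run1$V, 12)
  h2 <- foldHaplotypes(run2$V, 12)
  expect_equal(as.integer(mecScore(fr, h1)), as.integer(mecScore(fr, h2)))
  expect_equal(alleles(h1)[c(2, 3, 1), ], alleles(h2))
})

test_that("seeded assembly is bit-reproducible and validates its inputs", {
  set.seed(72)
  H <- HaplotypeSet(matrix(sample(0:3, 24, replace = TRUE), 2, 12))
  fr <- fragmentsFromHaps(H, readsPerHap = 4, sitesPerRead = 5, flipProb = 0.05)
  f1 <- assembleHaplotypes(fr, 2, seed = 11)
  f2 <- assembleHaplotypes(fr, 2, seed = 11)
  expect_identical(alleles(haplotypes(f1)), alleles(haplotypes(f2)))
  expect_identical(readOrigins(f1), readOrigins(f2))
  expect_error(assembleHaplotypes(fr, 1), "ploidy")
  expect_error(assembleHaplotypes(fr, 2, C = 2.5), "0, 2")
  expect_error(assembleHaplotypes(fr, 2, tolerance = -1), "positive")
})

test_that("block splitting phases disconnected components independently", {
  # two components: sites 1-3 and sites 5-7; site 4 uncovered
  H <- HaplotypeSet(rbind(c(0L, 0L, 0L, NA, 1L, 1L, 1L),
                          c(1L, 1L, 1L, NA, 0L, 0L, 0L)))
  read <- rep(1:8, each = 3)
  site <- c(rep(1:3, 4), rep(5:7, 4))
  allele <- c(rep(c(0, 1), each = 3, times = 2), rep(c(1, 0), each = 3, times = 2))
  fr <- FragmentSet(read, site, allele, nSites = 7)
  fit <- assembleHaplotypes(fr, 2, seed = 1, splitBlocks = TRUE)
  expect_equal(mec(fit), 0L)
  a <- alleles(haplotypes(fit))
  expect_true(all(is.na(a[, 4])))
  # within each block the two haplotypes are recovered up to order
  expect_setequal(a[, 1], c(0L, 1L))
  expect_setequal(a[, 6], c(0L, 1L))
})

test_that("phase-unidentifiable sites are reported uncalled", {
  # site 3 is covered only by a single-SNP read
  fr <- FragmentSet(read = c(1, 1, 2, 2, 3), site = c(1, 2, 1, 2, 3),
                    allele = c(0, 0, 1, 1, 0), nSites = 3)
  fit <- assembleHaplotypes(fr, 2, seed = 1)
  expect_true(all(is.na(alleles(haplotypes(fit))[, 3])))
  fit2 <- assembleHaplotypes(fr, 2, seed = 1, maskUnlinked = FALSE)
  expect_false(all(is.na(alleles(haplotypes(fit2))[, 3])))
})
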