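test_that("inter-SNP gaps are geometric with the requested mean", {
  sim <- simulateHaplotypes(2, 10000, seed = 91)
  gaps <- diff(sim$positions)
  expect_lt(abs(mean(gaps) - 300) / 300, 0.05)
})

test_that("biallelic sites carry exactly two alleles, polyallelic at least two", {
  sim <- simulateHaplotypes(4, 500, mode = "biallelic", seed = 92)
  nAll <- apply(alleles(sim$haplotypes), 2, function(x) length(unique(x)))
  expect_true(all(nAll == 2))
  simP <- simulateHaplotypes(3, 500, mode = "polyallelic", seed = 93)
  nAllP <- apply(alleles(simP$haplotypes), 2, function(x) length(unique(x)))
  expect_true(all(nAllP >= 2))
  expect_gt(max(nAllP), 2)   # genuinely polyallelic somewhere
})

test_that("haplotype and read simulation are deterministic under a seed", {
  s1 <- simulateHaplotypes(3, 200, seed = 94)
  s2 <- simulateHaplotypes(3, 200, seed = 94)
  expect_identical(alleles(s1$haplotypes), alleles(s2$haplotypes))
  expect_identical(s1$positions, s2$positions)
  p1 <- simulateReads(s1$haplotypes, s1$positions, coverage = 5, seed = 95)
  p2 <- simulateReads(s1$haplotypes, s1$positions, coverage = 5, seed = 95)
  expect_identical(fragments(p1)@allele, fragments(p2)@allele)
  expect_identical(readOrigins(p1), readOrigins(p2))
  expect_identical(plantedErrors(p1), plantedErrors(p2))
})

test_that("noiseless reads are consistent with the truth", {
  sim <- simulateHaplotypes(3, 300, seed = 96)
  ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 8,
                      errorRate = 0, seed = 97)
  expect_equal(nrow(plantedErrors(ps)), 0L)
  expect_equal(as.integer(mecScore(fragments(ps), truthHaplotypes(ps))), 0L)
  # every read matches its recorded origin exactly
  fr <- fragments(ps)
  a <- alleles(truthHaplotypes(ps))
  expect_true(all(fr@allele == a[cbind(readOrigins(ps)[fr@read], fr@site)]))
})

test_that("the substitution model flips at rate p_e, uniformly over alternatives", {
  sim <- simulateHaplotypes(2, 2000, seed = 98)
  pe <- 0.05
  ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 30,
                      errorRate = pe, seed = 99)
  fr <- fragments(ps)
  nAlleles <- length(fr@allele)
  expect_gt(nAlleles, 1e5)
  nFlips <- nrow(plantedErrors(ps))
  sdBin <- sqrt(nAlleles * pe * (1 - pe))
  expect_lt(abs(nFlips - nAlleles * pe), 3 * sdBin)
  # flipped alleles are uniform over the three alternatives: the offset
  # (observed - true) mod 4 should be uniform over {1,2,3}
  a <- alleles(truthHaplotypes(ps))
  keyAll <- paste(fr@read, fr@site)
  keyErr <- paste(plantedErrors(ps)[, "read"], plantedErrors(ps)[, "site"])
  idx <- match(keyErr, keyAll)
  offs <- (fr@allele[idx] -
           a[cbind(readOrigins(ps)[fr@read[idx]], fr@site[idx])]) %% 4
  expect_true(all(offs %in% 1:3))
  expect_gt(chisq.test(tabulate(offs, 3))$p.value, 0.01)
})

test_that("realized coverage matches the target in both accounting modes", {
  sim <- simulateHaplotypes(3, 600, seed = 100)
  ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 8, seed = 101)
  pairs <- length(fragments(ps)@site)
  expect_lt(abs(pairs / (600 * 3) - 8) / 8, 0.1)
  psT <- simulateReads(sim$haplotypes, sim$positions, coverage = 8,
                       coverageMode = "total", seed = 102)
  expect_lt(abs(length(fragments(psT)@site) / 600 - 8) / 8, 0.1)
})

test_that("long-insert fragment sets are connected at coverage 10", {
  connected <- 0L
  for (s in 1:10) {
    sim <- simulateHaplotypes(2, 300, seed = 200 + s)
    ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 10,
                        seed = 300 + s)
    comp <- tensorphase:::.readComponents(fragments(ps))
    connected <- connected + as.integer(max(comp) == 1L)
  }
  expect_gte(connected, 9L)
})

test_that("simulated fragment sets round-trip through the file dialect", {
  sim <- simulateHaplotypes(3, 150, seed = 103)
  ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 4, seed = 104)
  fr <- fragments(ps)
  f <- withr::local_tempfile()
  writeFragmentFile(fr, f)
  back <- readFragmentFile(f, nSites = nSites(fr))
  expect_equal(back@read, fr@read)
  expect_equal(back@site, fr@site)
  expect_equal(back@allele, fr@allele)
})

test_that("degenerate simulator inputs are rejected", {
  sim <- simulateHaplotypes(2, 10, seed = 105)
  expect_error(simulateReads(sim$haplotypes, sim$positions[1:3], coverage = 5),
               "one entry per SNP")
  expect_error(simulateReads(sim$haplotypes, sim$positions, coverage = 0))
  expect_error(simulateHaplotypes(1, 10), "k >= 2")
})
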