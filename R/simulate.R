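# Synthetic haplotypes and paired-end SNP fragments.
#
# The generator emulates whole-genome paired-end sequencing of a k-ploid
# organism restricted to its SNP sites: SNPs are placed along the genome with
# geometric inter-SNP gaps (SNP rate 1/300 by default), each read pair samples
# one haplotype uniformly at random, and each covered allele call is, with
# probability p_e, replaced by one of the other three alleles chosen
# uniformly. Long inserts make the resulting fragment blocks nearly fully
# connected, the regime long-range phasing targets.

#' Simulate ground-truth haplotypes
#'
#' Places m SNPs along a genome with inter-SNP gaps drawn as
#' `geometric(snpRate) + 1` (mean `1/snpRate`), then draws alleles per site.
#' In biallelic mode each site receives two distinct allele codes from 0..3
#' and every haplotype carries one of the two; with `polymorphicOnly` (the
#' default) assignments are redrawn until at least two haplotypes differ at
#' every site, so all sites are genuine SNPs. In polyallelic mode each
#' haplotype's allele is drawn uniformly from the four codes, redrawing
#' monomorphic sites.
#'
#' @param ploidy number of haplotypes k (>= 2)
#' @param nSites number of SNP sites m
#' @param mode `"biallelic"` or `"polyallelic"`
#' @param snpRate per-base SNP probability (default 1/300)
#' @param polymorphicOnly redraw sites where all haplotypes agree
#' @param seed optional integer seed
#' @return a list with `haplotypes` (a [HaplotypeSet-class]) and `positions`
#'   (integer genomic coordinates of the m SNPs, in bp)
#' @examples
#' sim <- simulateHaplotypes(3, 100, seed = 1)
#' ploidy(sim$haplotypes)
#' @export
simulateHaplotypes <- function(ploidy, nSites,
                               mode = c("biallelic", "polyallelic"),
                               snpRate = 1 / 300, polymorphicOnly = TRUE,
                               seed = NULL) {
  mode <- match.arg(mode)
  k <- as.integer(ploidy); m <- as.integer(nSites)
  stopifnot(k >= 2L, m >= 1L, snpRate > 0, snpRate < 1)
  gen <- function() {
    positions <- cumsum(stats::rgeom(m, snpRate) + 1L)
    a <- matrix(NA_integer_, k, m)
    if (mode == "biallelic") {
      a1 <- sample(0:3, m, replace = TRUE)
      a2 <- (a1 + sample(1:3, m, replace = TRUE)) %% 4L
      pick <- matrix(sample(c(TRUE, FALSE), k * m, replace = TRUE), k, m)
      if (polymorphicOnly) {
        mono <- which(colSums(pick) %in% c(0L, k))
        while (length(mono)) {
          pick[, mono] <- sample(c(TRUE, FALSE), k * length(mono), replace = TRUE)
          mono <- mono[colSums(pick[, mono, drop = FALSE]) %in% c(0L, k)]
        }
      }
      a[] <- ifelse(pick, rep(a1, each = k), rep(a2, each = k))
    } else {
      a[] <- sample(0:3, k * m, replace = TRUE)
      mono <- which(apply(a, 2L, function(x) length(unique(x))) == 1L)
      while (length(mono)) {
        a[, mono] <- sample(0:3, k * length(mono), replace = TRUE)
        mono <- mono[vapply(mono, function(j) length(unique(a[, j])) == 1L,
                            logical(1))]
      }
    }
    list(haplotypes = HaplotypeSet(a), positions = as.integer(positions))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Simulate erroneous paired-end SNP fragments
#'
#' Generates read pairs until the realized SNP coverage reaches the target:
#' each pair picks a haplotype uniformly at random and a start uniform over
#' the genome; both mates span `readLength` bases and are separated by a gap
#' drawn from `Normal(insertMean, insertSdFraction * insertMean)` truncated
#' at zero. A pair's fragment consists of the SNP positions falling inside
#' either mate; pairs covering no SNP are discarded and do not count toward
#' the read total. Each covered allele is then flipped, independently with
#' probability `errorRate`, to one of the other three allele codes chosen
#' uniformly.
#'
#' Coverage accounting: with `coverageMode = "per-haplotype"` (default) the
#' generator stops once the mean number of covering reads per (site,
#' haplotype) pair reaches `coverage`, i.e. total covered pairs reach
#' `coverage * k * m`; with `"total"` the target is `coverage * m` summed
#' over all haplotypes.
#'
#' @param haplotypes ground-truth [HaplotypeSet-class]
#' @param positions genomic SNP coordinates from [simulateHaplotypes()]
#' @param coverage target sequencing coverage over SNP positions
#' @param errorRate per-allele substitution probability p_e in `[0, 1)`
#' @param readLength bases per mate (default 250, i.e. 2 x 250 pairs)
#' @param insertMean mean gap between mates in bp (default 10000)
#' @param insertSdFraction gap standard deviation as a fraction of the mean
#' @param coverageMode `"per-haplotype"` or `"total"` (see above)
#' @param seed optional integer seed
#' @return a [PhasingSimulation-class]
#' @examples
#' sim <- simulateHaplotypes(2, 60, seed = 1)
#' ps <- simulateReads(sim$haplotypes, sim$positions, coverage = 8,
#'                     errorRate = 0, seed = 1)
#' mecScore(fragments(ps), truthHaplotypes(ps))  # 0: noiseless
#' @export
simulateReads <- function(haplotypes, positions, coverage, errorRate = 0.002,
                          readLength = 250L, insertMean = 10000,
                          insertSdFraction = 0.1,
                          coverageMode = c("per-haplotype", "total"),
                          seed = NULL) {
  coverageMode <- match.arg(coverageMode)
  stopifnot(is(haplotypes, "HaplotypeSet"),
            errorRate >= 0, errorRate < 1, coverage > 0,
            insertSdFraction >= 0, readLength >= 1)
  a <- haplotypes@alleles
  k <- nrow(a); m <- ncol(a)
  if (length(positions) != m) stop("positions must have one entry per SNP site")
  if (m == 0L) stop("no SNPs in genome")
  positions <- as.numeric(positions)
  L <- as.numeric(readLength)
  target <- ceiling(coverage * m * if (coverageMode == "per-haplotype") k else 1)

  gen <- function() {
    span <- 2 * L + insertMean * (1 + 4 * insertSdFraction)
    lo <- positions[1L] - span
    hi <- positions[m]
    readSite <- readAllele <- readIdx <- vector("list", 0L)
    origins <- integer(0)
    errRead <- errSite <- integer(0)
    got <- 0L
    nkept <- 0L
    snpPerRead <- max(2 * L * m / (hi - lo + span), 0.05)
    while (got < target) {
      B <- max(500L, ceiling(1.3 * (target - got) / snpPerRead))
      s1 <- floor(stats::runif(B, lo, hi + 1))
      gap <- pmax(0, round(stats::rnorm(B, insertMean, insertSdFraction * insertMean)))
      s2 <- s1 + L + gap
      lo1 <- findInterval(s1 - 1, positions) + 1L
      hi1 <- findInterval(s1 + L - 1, positions)
      lo2 <- findInterval(s2 - 1, positions) + 1L
      hi2 <- findInterval(s2 + L - 1, positions)
      n1 <- pmax(hi1 - lo1 + 1L, 0L)
      n2 <- pmax(hi2 - lo2 + 1L, 0L)
      cnt <- n1 + n2
      keep <- which(cnt > 0L)
      if (length(keep) == 0L) next
      # truncate the batch where the coverage target is crossed
      cum <- cumsum(cnt[keep])
      stopAt <- which(got + cum >= target)
      if (length(stopAt)) keep <- keep[seq_len(stopAt[1L])]
      nv <- as.vector(rbind(n1[keep], n2[keep]))
      fr <- as.vector(rbind(lo1[keep], lo2[keep]))
      sites <- sequence(nvec = nv, from = ifelse(nv > 0L, fr, 1L))
      rdsLocal <- rep(seq_along(keep), times = cnt[keep])
      rds <- nkept + rdsLocal
      org <- sample.int(k, length(keep), replace = TRUE)
      alle <- a[cbind(org[rdsLocal], sites)]
      flip <- stats::runif(length(alle)) < errorRate
      if (any(flip)) {
        alle[flip] <- (alle[flip] + sample.int(3L, sum(flip), replace = TRUE)) %% 4L
        errRead <- c(errRead, rds[flip])
        errSite <- c(errSite, sites[flip])
      }
      readIdx[[length(readIdx) + 1L]] <- rds
      readSite[[length(readSite) + 1L]] <- sites
      readAllele[[length(readAllele) + 1L]] <- alle
      origins <- c(origins, org)
      nkept <- nkept + length(keep)
      got <- got + length(alle)
    }
    frags <- FragmentSet(unlist(readIdx), unlist(readSite), unlist(readAllele),
                         nSites = m, nReads = nkept)
    pe <- if (length(errRead)) cbind(read = as.integer(errRead),
                                     site = as.integer(errSite))
          else matrix(integer(), 0L, 2L, dimnames = list(NULL, c("read", "site")))
    new("PhasingSimulation",
      fragments = frags, truth = haplotypes,
      positions = as.integer(positions), readOrigins = origins,
      plantedErrors = pe,
      config = list(coverage = coverage, coverageMode = coverageMode,
                    errorRate = errorRate, readLength = readLength,
                    insertMean = insertMean,
                    insertSdFraction = insertSdFraction, seed = seed)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
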