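# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized code paths: plain double loops over reads, sites
# and haplotypes.

# random sparse FragmentSet; alleles uniform over 0..3
randomFragmentSet <- function(nReads = 8, nSites = 12, minCov = 1,
                              maxCov = NULL) {
  if (is.null(maxCov)) maxCov <- nSites
  read <- integer(0); site <- integer(0); allele <- integer(0)
  for (i in seq_len(nReads)) {
    nc <- sample(seq.int(minCov, maxCov), 1)
    ss <- sort(sample.int(nSites, nc))
    read <- c(read, rep(i, nc))
    site <- c(site, ss)
    allele <- c(allele, sample(0:3, nc, replace = TRUE))
  }
  FragmentSet(read, site, allele, nSites = nSites, nReads = nReads)
}

# FragmentSet drawn noiselessly (or with flips) from a HaplotypeSet
fragmentsFromHaps <- function(haps, readsPerHap = 4, sitesPerRead = NULL,
                              flipProb = 0) {
  a <- alleles(haps)
  k <- nrow(a); m <- ncol(a)
  if (is.null(sitesPerRead)) sitesPerRead <- m
  read <- integer(0); site <- integer(0); allele <- integer(0)
  origins <- integer(0)
  i <- 0
  for (p in seq_len(k)) for (r in seq_len(readsPerHap)) {
    i <- i + 1
    ss <- sort(sample.int(m, min(sitesPerRead, m)))
    al <- a[p, ss]
    flip <- runif(length(al)) < flipProb
    al[flip] <- (al[flip] + sample(1:3, sum(flip), replace = TRUE)) %% 4
    read <- c(read, rep(i, length(ss)))
    site <- c(site, ss)
    allele <- c(allele, al)
    origins <- c(origins, p)
  }
  structure(FragmentSet(read, site, allele, nSites = m, nReads = i),
            origins = origins)
}

# plain triple-loop MEC
bruteMEC <- function(frags, haps) {
  a <- alleles(haps)
  total <- 0
  for (i in seq_len(nReads(frags))) {
    sel <- frags@read == i
    ss <- frags@site[sel]; al <- frags@allele[sel]
    best <- Inf
    for (p in seq_len(nrow(a))) {
      d <- 0
      for (t in seq_along(ss)) {
        hv <- a[p, ss[t]]
        if (!is.na(hv) && hv != al[t]) d <- d + 1
      }
      if (d < best) best <- d
    }
    total <- total + best
  }
  total
}

# exhaustive MEC optimum over all binary diploid haplotype pairs (k = 2,
# alleles restricted to {0,1}), for tiny m
enumerateMECOptimum <- function(frags) {
  m <- nSites(frags)
  best <- Inf
  for (code1 in 0:(2^m - 1)) for (code2 in 0:(2^m - 1)) {
    h <- rbind(as.integer(intToBits(code1))[seq_len(m)],
               as.integer(intToBits(code2))[seq_len(m)])
    best <- min(best, bruteMEC(frags, HaplotypeSet(h)))
  }
  best
}

# CPR by direct permutation enumeration with scalar dissimilarity
bruteCPR <- function(est, truth) {
  ae <- alleles(est); at <- alleles(truth)
  k <- nrow(ae); m <- ncol(ae)
  d1 <- function(x, y) as.integer(!is.na(x) && !is.na(y) && x != y)
  allPerms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (pp in allPerms(seq_len(k))) {
    cost <- 0
    for (p in seq_len(k)) for (j in seq_len(m))
      cost <- cost + d1(ae[pp[p], j], at[p, j])
    best <- min(best, cost)
  }
  1 - best / (m * k)
}

# half the summed squared masked residuals, by explicit loops
bruteObjective <- function(obs, origins, V) {
  vals <- as.matrix(obs@values); msk <- as.matrix(obs@mask)
  total <- 0
  for (i in seq_len(nrow(vals))) for (cc in seq_len(ncol(vals))) {
    if (msk[i, cc] != 0) total <- total + (vals[i, cc] - V[cc, origins[i]])^2
  }
  total / 2
}
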