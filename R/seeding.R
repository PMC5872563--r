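# Guided combinatorial seeding for the alternating solver.
#
# The relaxed-objective alternation converges to whichever basin its starting
# point selects, and with short fragments (a handful of SNPs per read) the
# landscape is riddled with near-degenerate optima that differ from the truth
# by per-site column relabelings. The guided seed builds a label-consistent
# starting haplotype estimate directly from the reads:
#
#   1. per-site genotype: the allele multiplicity vector maximizing a
#      multinomial likelihood with a small substitution-error floor;
#   2. phase: sites are decided one at a time in Prim order (always the
#      undecided site with the strongest read-linkage into the decided
#      region), choosing the multiset-to-column assignment that minimizes the
#      accumulated per-read mismatch under each read's best column;
#   3. polish: site-wise ICM sweeps (re-deciding each site's column
#      permutation, and its multiplicities where the count likelihood is
#      ambiguous), a suffix-permutation pass that repairs switch errors, and
#      a segment-relabeling local search that removes short switched blocks.
#
# The result seeds the projected-gradient alternation, which refines allele
# calls freely (it carries no genotype constraint).

# all vectors of `nall` non-negative integers summing to k
.compositions <- function(k, nall) {
  if (nall == 1L) return(list(k))
  out <- list()
  for (i in 0:k) for (rest in .compositions(k - i, nall - 1L))
    out[[length(out) + 1L]] <- c(i, rest)
  out
}

# ML allele multiplicity vector at one site; eps is a robustness floor for
# sequencing errors so that rarely-observed alleles can be dropped
.mlMultiset <- function(cnt, k, margin = 3, eps = 0.02) {
  obs <- which(cnt > 0L)
  comps <- .compositions(k, length(obs))
  ll <- vapply(comps, function(co) {
    pr <- (co / k) * (1 - eps) + ((k - co) / k) * (eps / 3)
    sum(cnt[obs] * log(pr))
  }, numeric(1))
  o <- order(ll, decreasing = TRUE)
  mult <- integer(4L)
  mult[obs] <- comps[[o[1L]]]
  list(mult = mult,
       ambiguous = length(o) > 1L && (ll[o[1L]] - ll[o[2L]]) < margin)
}

# neighbouring multiplicity vectors: move one copy between observed alleles
.multisetShifts <- function(mult, obsAlleles) {
  out <- list(mult)
  for (a in which(mult > 0L)) for (b in obsAlleles + 1L) if (a != b) {
    mm <- mult
    mm[a] <- mm[a] - 1L
    mm[b] <- mm[b] + 1L
    out[[length(out) + 1L]] <- mm
  }
  unique(out)
}

# distinct column assignments (permutations) of a multiplicity vector
.multisetCands <- function(mult, perms) {
  ms <- rep(0:3, mult)
  unique(lapply(perms, function(p) ms[p]))
}

# MEC-greedy score of assigning alleles (rows of a candidate list) at one
# site, given accumulated per-read mismatch counts `base` and the site's
# read alleles `a2`; compiled kernel
.candScore <- function(cc, base, a2) {
  candScores(base, as.integer(a2), do.call(rbind, cc))
}

# Prim-ordered greedy phase seeding (stage 1 + 2); returns the k x m matrix
# plus per-site data reused by the polish passes
.primSeed <- function(frags, k) {
  m <- frags@nSites
  n <- frags@nReads
  perms <- .permutations(k)
  rr <- frags@read; ss <- frags@site; aa <- frags@allele
  bySite <- split(seq_along(ss), ss)
  ord <- as.integer(names(bySite))
  hap <- matrix(NA_integer_, k, m)
  cands <- vector("list", m)
  obsAll <- vector("list", m)
  ambig <- logical(m)
  for (ii in seq_along(bySite)) {
    idx <- bySite[[ii]]; j <- ord[ii]
    cnt <- tabulate(aa[idx] + 1L, 4L)
    mlr <- .mlMultiset(cnt, k)
    obsAll[[j]] <- which(cnt > 0L) - 1L
    ambig[j] <- mlr$ambiguous
    cands[[j]] <- .multisetCands(mlr$mult, perms)
  }
  readSites <- split(seq_along(ss), rr)
  dist <- matrix(0L, n, k)
  anchored <- logical(n)
  decided <- logical(m)
  linkSupport <- integer(m)
  covFull <- integer(m)
  covFull[ord] <- lengths(bySite)
  todo <- ord
  while (length(todo)) {
    # random jitter (< 1) only breaks ties among equal integer supports
    if (!any(decided) || max(linkSupport[todo]) == 0L) {
      j <- todo[which.max(covFull[todo] + stats::runif(length(todo)))]
    } else {
      j <- todo[which.max(linkSupport[todo] + stats::runif(length(todo)))]
    }
    idx <- bySite[[match(j, ord)]]
    r2 <- rr[idx]; a2 <- aa[idx]
    cc <- cands[[j]]
    if (length(cc) > 1L && any(anchored[r2])) {
      sel <- anchored[r2]
      sc <- .candScore(cc, dist[r2[sel], , drop = FALSE], a2[sel])
      g <- cc[[which.min(sc)]]
    } else {
      g <- cc[[1L]]
    }
    hap[, j] <- g
    dist[r2, ] <- dist[r2, , drop = FALSE] + outer(a2, g, "!=")
    decided[j] <- TRUE
    todo <- todo[todo != j]
    for (t in idx) {
      osites <- ss[readSites[[rr[t]]]]
      und <- osites[!decided[osites]]
      linkSupport[und] <- linkSupport[und] + 1L
    }
    anchored[r2] <- TRUE
  }
  list(hap = hap, ambig = ambig, obsAll = obsAll)
}

# site-wise ICM polish; when `shift` is TRUE, sites flagged genotype-ambiguous
# may also move allele multiplicities
.icmPass <- function(hap, frags, k, sweeps = 4L, shift = FALSE,
                     ambig = NULL, obsAll = NULL) {
  m <- frags@nSites; n <- frags@nReads
  perms <- .permutations(k)
  rr <- frags@read; ss <- frags@site; aa <- frags@allele
  bySite <- split(seq_along(ss), ss)
  ord <- as.integer(names(bySite))
  dist <- matrix(0L, n, k)
  for (p in seq_len(k)) {
    dist[, p] <- as.integer(rowsum(as.integer(hap[p, ss] != aa), rr)[, 1L])
  }
  for (sw in seq_len(sweeps)) {
    changed <- 0L
    for (ii in seq_along(bySite)) {
      j <- ord[ii]; idx <- bySite[[ii]]
      r2 <- rr[idx]; a2 <- aa[idx]
      g0 <- hap[, j]
      if (shift && isTRUE(ambig[j])) {
        msets <- .multisetShifts(tabulate(g0 + 1L, 4L), obsAll[[j]])
        cc <- unique(unlist(lapply(msets, .multisetCands, perms = perms),
                            recursive = FALSE))
      } else {
        cc <- .multisetCands(tabulate(g0 + 1L, 4L), perms)
      }
      if (length(cc) < 2L) next
      base <- dist[r2, , drop = FALSE] - outer(a2, g0, "!=")
      sc <- .candScore(cc, base, a2)
      g <- cc[[which.min(sc)]]
      if (!identical(g, g0)) {
        changed <- changed + 1L
        hap[, j] <- g
        dist[r2, ] <- base + outer(a2, g, "!=")
      }
    }
    if (changed == 0L) break
  }
  hap
}

# greedy left-to-right suffix-permutation (switch-error) repair
.switchPass <- function(hap, frags, k) {
  m <- frags@nSites; n <- frags@nReads
  perms <- .permutations(k)
  idp <- which(vapply(perms, function(pp) all(pp == seq_len(k)), logical(1)))
  permsMat <- do.call(rbind, perms)
  rr <- frags@read; ss <- frags@site; aa <- frags@allele
  bySite <- split(seq_along(ss), ss)
  ord <- as.integer(names(bySite))
  readLo <- tapply(ss, rr, min)
  readHi <- tapply(ss, rr, max)
  dist <- matrix(0L, n, k)
  for (p in seq_len(k)) {
    dist[, p] <- as.integer(rowsum(as.integer(hap[p, ss] != aa), rr)[, 1L])
  }
  dl <- matrix(0L, n, k)
  dr <- dist
  for (ii in seq_along(ord)) {
    j <- ord[ii]
    if (ii > 1L) {
      act <- which(readLo < j & readHi >= j)
      if (length(act)) {
        sc <- rowMinSumPerm(dl[act, , drop = FALSE], dr[act, , drop = FALSE],
                            permsMat)
        b <- which.min(sc)
        if (b != idp && sc[b] < sc[idp]) {
          pp <- perms[[b]]
          tail <- ord[ii:length(ord)]
          hap[, tail] <- hap[pp, tail, drop = FALSE]
          dr <- dr[, pp, drop = FALSE]
        }
      }
    }
    idx <- bySite[[ii]]
    mm <- outer(aa[idx], hap[, j], "!=")
    dl[rr[idx], ] <- dl[rr[idx], , drop = FALSE] + mm
    dr[rr[idx], ] <- dr[rr[idx], , drop = FALSE] - mm
  }
  hap
}

# segment-relabeling local search: permute the columns of one contiguous run
# of sites when that lowers the MEC; candidate run starts are sites touched by
# at least two currently-mismatching reads, and the windowed sweep over run
# ends is a compiled kernel
.segmentPass <- function(hap, frags, k, window = 80L, maxPasses = 3L) {
  perms <- .permutations(k)
  idp <- which(vapply(perms, function(pp) all(pp == seq_len(k)), logical(1)))
  perms <- perms[-idp]
  if (length(perms) == 0L) return(hap)
  permsMat <- do.call(rbind, perms)
  m <- frags@nSites; n <- frags@nReads
  rr <- frags@read; ss <- frags@site; aa <- frags@allele
  np <- length(ss)
  ord <- sort(unique(ss))
  nOrd <- length(ord)
  pos <- integer(m); pos[ord] <- seq_len(nOrd)
  pairPos <- pos[ss]
  pairMism <- function(idx) {
    t(hap[, ss[idx], drop = FALSE] != rep(aa[idx], each = k)) + 0L
  }
  mismAll <- pairMism(seq_len(np))
  dtot <- rowsum(mismAll, rr)
  for (pass in seq_len(maxPasses)) {
    minNow <- dtot[cbind(seq_len(n), max.col(-dtot, ties.method = "first"))]
    tb <- table(ss[rr %in% which(minNow > 0L)])
    tb <- tb[tb >= 2L]
    # work cap: examine the most conflicted run starts first
    if (length(tb) > 150L) tb <- sort(tb, decreasing = TRUE)[seq_len(150L)]
    confSites <- sort(as.integer(names(tb)))
    improved <- FALSE
    for (j1 in confSites) {
      i1 <- pos[j1]
      hi <- min(nOrd, i1 + window - 1L)
      segIdx <- which(pairPos >= i1 & pairPos <= hi)
      if (length(segIdx) == 0L) next
      segIdx <- segIdx[order(pairPos[segIdx])]
      touched <- unique(rr[segIdx])
      lookup <- integer(n); lookup[touched] <- seq_along(touched)
      res <- segWindowBest(dtot[touched, , drop = FALSE], pairPos[segIdx],
                           lookup[rr[segIdx]], mismAll[segIdx, , drop = FALSE],
                           permsMat)
      if (res[3L] > 0) {
        pp <- perms[[res[3L]]]
        segApply <- ord[seq.int(i1, res[2L])]
        hap[, segApply] <- hap[pp, segApply, drop = FALSE]
        updIdx <- segIdx[pairPos[segIdx] <= res[2L]]
        old <- mismAll[updIdx, , drop = FALSE]
        mismAll[updIdx, ] <- pairMism(updIdx)
        upd <- rowsum(mismAll[updIdx, , drop = FALSE] - old, rr[updIdx])
        ur <- as.integer(rownames(upd))
        dtot[ur, ] <- dtot[ur, , drop = FALSE] + upd
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  hap
}

#' Combinatorial seed for the alternating solver
#'
#' Builds a haplotype estimate directly from the reads: per-site genotypes
#' by maximum-likelihood allele multiplicities, phase by Prim-ordered greedy
#' assignment (each site is decided when its read-linkage into the already
#' decided region is strongest), then switch-error and segment-relabeling
#' repairs with site-wise ICM sweeps. Used by [assembleHaplotypes()] as the
#' default starting point of the projected-gradient alternation; exposed so
#' the seed quality can be inspected on its own.
#'
#' @param frags a [FragmentSet-class]
#' @param ploidy number of haplotypes k (>= 2)
#' @param seed optional integer seed (tie-breaking among equally-linked
#'   sites is randomized)
#' @param polish run the segment-relabeling local search (slower but more
#'   accurate); [assembleHaplotypes()] polishes only its best restart
#' @return a [HaplotypeSet-class]; sites covered by no read are uncalled
#' @export
seedHaplotypes <- function(frags, ploidy, seed = NULL, polish = TRUE) {
  stopifnot(is(frags, "FragmentSet"))
  k <- as.integer(ploidy)
  hap <- .lightSeed(frags, k, seed = seed)
  if (polish) hap <- .polishSeed(hap, frags, k)
  HaplotypeSet(hap)
}

.lightSeed <- function(frags, k, seed = NULL) {
  run <- function() {
    ps <- .primSeed(frags, k)
    hap <- .icmPass(ps$hap, frags, k, sweeps = 4L, shift = TRUE,
                    ambig = ps$ambig, obsAll = ps$obsAll)
    hap <- .switchPass(hap, frags, k)
    .icmPass(hap, frags, k, sweeps = 2L)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

.polishSeed <- function(hap, frags, k) {
  hap <- .segmentPass(hap, frags, k)
  .icmPass(hap, frags, k, sweeps = 2L)
}
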