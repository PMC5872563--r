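# MEC and CPR: the two standard haplotype assembly quality metrics.

#' Allele dissimilarity
#'
#' The indicator used throughout MEC and CPR: two allele calls disagree (1)
#' iff both are called (non-NA) and differ; any comparison involving an
#' uncalled allele counts as agreement (0).
#'
#' @param a1,a2 allele codes (0..3) or NA; vectors are compared elementwise
#' @return integer vector of 0/1 dissimilarities
#' @examples
#' dissimilarity(0, 1)   # 1
#' dissimilarity(2, NA)  # 0
#' @export
dissimilarity <- function(a1, a2) {
  as.integer(!is.na(a1) & !is.na(a2) & a1 != a2)
}

# n x k matrix of per-read mismatch counts against each haplotype
.readHapMismatches <- function(frags, haps) {
  a <- haps@alleles
  if (ncol(a) != frags@nSites)
    stop("fragments and haplotypes disagree on the number of SNP sites")
  k <- nrow(a)
  n <- frags@nReads
  d <- matrix(0L, n, k)
  for (p in seq_len(k)) {
    hp <- a[p, frags@site]
    mis <- !is.na(hp) & hp != frags@allele
    d[, p] <- as.integer(rowsum(as.integer(mis), frags@read,
                                reorder = TRUE)[, 1L])
  }
  d
}

#' Minimum error correction score
#'
#' The MEC score of a haplotype estimate against a fragment set: the total,
#' over reads, of the smallest number of allele calls in the read that would
#' have to change for the read to be consistent with one of the k haplotypes.
#' Uncalled haplotype sites never count as mismatches.
#'
#' @param frags a [FragmentSet-class]
#' @param haps a [HaplotypeSet-class] over the same m sites
#' @return integer MEC score, with attribute `"assignment"` giving each
#'   read's minimizing haplotype index (ties to the lowest index)
#' @examples
#' h <- HaplotypeSet(rbind(c(0, 0), c(1, 1)))
#' fr <- FragmentSet(read = c(1, 1, 2, 2, 3, 3), site = c(1, 2, 1, 2, 1, 2),
#'                   allele = c(0, 0, 1, 1, 0, 1))
#' mecScore(fr, h)  # 1: read 3 is one flip away from either haplotype
#' @export
mecScore <- function(frags, haps) {
  d <- .readHapMismatches(frags, haps)
  per <- max.col(-d, ties.method = "first")
  out <- sum(d[cbind(seq_len(nrow(d)), per)])
  structure(as.integer(out), assignment = per)
}

#' Correct phasing rate
#'
#' CPR (reconstruction rate) of a haplotype estimate against the truth:
#' `1 - mincost / (m*k)`, where mincost is the total allele dissimilarity
#' under the best one-to-one mapping between estimated and true haplotypes.
#' The mapping is found by exhaustive enumeration of the k! permutations for
#' k <= 8 and by solving the k x k linear sum assignment problem on the
#' pairwise mismatch-cost table otherwise. Because uncalled estimate sites
#' count as agreement, CPR is an optimistic measure when coverage is
#' incomplete.
#'
#' @param estimate,truth [HaplotypeSet-class] objects of equal ploidy and
#'   length
#' @return CPR in `[0, 1]`, with attribute `"mapping"`: entry p is the truth
#'   haplotype matched to estimate haplotype p
#' @examples
#' truth <- HaplotypeSet(rbind(c(0, 0), c(1, 1)))
#' cprScore(HaplotypeSet(rbind(c(1, 1), c(0, 0))), truth)  # 1: column swap
#' @export
cprScore <- function(estimate, truth) {
  ae <- estimate@alleles; at <- truth@alleles
  if (!identical(dim(ae), dim(at)))
    stop("estimate and truth must have the same ploidy and number of sites")
  k <- nrow(ae); m <- ncol(ae)
  cost <- matrix(0L, k, k)  # cost[p, q]: estimate p vs truth q
  for (p in seq_len(k)) for (q in seq_len(k))
    cost[p, q] <- sum(dissimilarity(ae[p, ], at[q, ]))
  sol <- if (k <= 8L) .lsapExhaustive(cost) else .lsapHungarian(cost)
  structure(1 - sol$cost / (m * k), mapping = sol$mapping)
}

# exhaustive minimum-cost bijection (k! enumeration)
.lsapExhaustive <- function(cost) {
  k <- nrow(cost)
  best <- Inf; bestp <- seq_len(k)
  for (p in .permutations(k)) {
    cc <- sum(cost[cbind(seq_len(k), p)])
    if (cc < best) { best <- cc; bestp <- p }
  }
  list(cost = best, mapping = bestp)
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(k)) {
    i <- i + 1L
    out[[i]] <- append(p, k, after = pos - 1L)
  }
  out
}

# O(k^3) shortest-augmenting-path assignment (Jonker-Volgenant style) for
# larger k; duals v, per-column matched row in way/matched bookkeeping.
.lsapHungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        jj <- j + 1L
        if (!used[jj]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(n + 1L)) {
        if (used[jj]) { u[p[jj]] <- u[p[jj]] + delta; v[jj] <- v[jj] - delta }
        else minv[jj] <- minv[jj] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  mapping <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) mapping[p[j + 1L]] <- j
  list(cost = sum(cost[cbind(seq_len(n), mapping)]), mapping = mapping)
}

#' Evaluate a phasing against fragments and (optionally) the truth
#'
#' Convenience wrapper producing a full evaluation report: the MEC score with
#' its per-read assignment, and, when the truth is supplied, the CPR and the
#' best haplotype mapping.
#'
#' @param frags a [FragmentSet-class]
#' @param estimate the assembled [HaplotypeSet-class]
#' @param truth optional ground-truth [HaplotypeSet-class]
#' @return a list with elements `mec`, `perReadAssignment`, and (given truth)
#'   `cpr`, `cprPercent` and `bestMapping`
#' @export
evaluatePhasing <- function(frags, estimate, truth = NULL) {
  mec <- mecScore(frags, estimate)
  out <- list(mec = as.integer(mec),
              perReadAssignment = attr(mec, "assignment"))
  if (!is.null(truth)) {
    cpr <- cprScore(estimate, truth)
    out$cpr <- as.numeric(cpr)
    out$cprPercent <- 100 * as.numeric(cpr)
    out$bestMapping <- attr(cpr, "mapping")
  }
  out
}
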