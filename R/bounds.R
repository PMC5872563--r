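# Evaluators for the theoretical performance guarantees: the incoherence and
# condition number of the signal matrix, the sufficient coverage condition,
# and the resulting bounds on the factorization error, expected MEC and
# expected CPR. The two numerical constants (C0, C1) appearing in the theory
# are not instantiated anywhere in the analysis; they default to 1 here and
# the evaluated bounds are diagnostics on concrete instances, not certified
# guarantees.

.topkSVD <- function(M, k, iterations = 200L, seed = 1L) {
  .powerSVD(M, k, iterations = iterations, seed = seed)
}

#' Incoherence parameter of a matrix
#'
#' For a rank-k matrix with compact SVD `M = U S V'`, returns the smallest
#' `mu` such that every row energy of U is at most `mu*k/n` and every row
#' energy of V is at most `mu*k/m`:
#' `mu = max(n/k * max_i sum_l U[i,l]^2, m/k * max_j sum_l V[j,l]^2)`.
#' Spread-out singular vectors give `mu` near 1 (easy completion); spiky
#' ones push `mu` toward `max(n, m)/k`.
#'
#' @param M a numeric (possibly sparse) matrix, or an [ObservedMatrix-class]
#'   whose zero-filled value matrix is then used
#' @param k target rank (the ploidy, for the phasing signal matrix)
#' @param iterations power-iteration sweeps used for the top-k SVD
#' @return the incoherence parameter `mu >= 1`
#' @examples
#' incoherence(matrix(1, 8, 5), k = 1)  # uniform singular vectors: mu = 1
#' @export
incoherence <- function(M, k, iterations = 200L) {
  if (is(M, "ObservedMatrix")) M <- M@values
  k <- as.integer(k)
  n <- nrow(M); m <- ncol(M)
  if (k < 1L || k > min(n, m)) stop("k must lie in [1, min(dim(M))]")
  sv <- .topkSVD(M, k, iterations = iterations)
  if (sv$d[k] <= 1e-9 * max(sv$d[1L], 1))
    stop("matrix rank is below k; incoherence undefined")
  max(n / k * max(rowSums(sv$u^2)), m / k * max(rowSums(sv$v^2)))
}

#' Condition number of the rank-k signal
#'
#' Ratio `sigma_1 / sigma_k` of the first to the k-th singular value.
#'
#' @inheritParams incoherence
#' @return condition number `kappa >= 1`
#' @examples
#' conditionNumber(diag(c(2, 1)), k = 2)  # 2
#' @export
conditionNumber <- function(M, k, iterations = 200L) {
  if (is(M, "ObservedMatrix")) M <- M@values
  k <- as.integer(k)
  if (k < 1L || k > min(dim(M))) stop("k must lie in [1, min(dim(M))]")
  sv <- .topkSVD(M, k, iterations = iterations)
  if (sv$d[k] <= 1e-9 * max(sv$d[1L], 1))
    stop("matrix is rank-deficient below k")
  sv$d[1L] / sv$d[k]
}

#' Sufficient coverage condition for recovery
#'
#' Evaluates the condition
#' `C_snp > max( C0 * (mu^4 k^14 kappa^12 C_seq)^(1/3),
#'               p_e k^2 kappa^6 / (2 C1) )`
#' under which (for suitable constants) the alternating scheme provably
#' recovers the signal matrix up to the noise-driven error. The inequality is
#' strict: `C_snp` equal to the threshold does not satisfy it.
#'
#' @param cSnp expected number of SNPs covered per read (`m * p`)
#' @param cSeq expected coverage per haplotype sequence (`n * p`)
#' @param pe data error rate
#' @param k ploidy
#' @param mu incoherence parameter (>= 1)
#' @param kappa condition number (>= 1)
#' @param C0,C1 the theory's numerical constants; defaults of 1 are
#'   placeholders, not calibrated values
#' @return list with `satisfied` (logical), `threshold` (the max of the two
#'   arms) and `margin` (`cSnp / threshold`)
#' @examples
#' coverageCondition(cSnp = 60, cSeq = 10, pe = 0, k = 2)
#' @export
coverageCondition <- function(cSnp, cSeq, pe, k, mu = 1, kappa = 1,
                              C0 = 1, C1 = 1) {
  stopifnot(cSnp > 0, cSeq > 0, pe >= 0, k >= 1, mu >= 1, kappa >= 1,
            C0 > 0, C1 > 0)
  thr <- max(C0 * (mu^4 * k^14 * kappa^12 * cSeq)^(1 / 3),
             pe * k^2 * kappa^6 / (2 * C1))
  list(satisfied = cSnp > thr, threshold = thr, margin = cSnp / thr)
}

#' Bound on the expected MEC score
#'
#' `E[MEC] <= 2 * pe * (cSeq * m + kappa^4 * C1 * k)`: the expected MEC of
#' the recovered haplotypes grows linearly with the error rate, the haplotype
#' length and the coverage.
#'
#' @inheritParams coverageCondition
#' @param m haplotype length (number of SNP sites)
#' @return the bound value (>= 0)
#' @examples
#' mecBound(pe = 0.01, cSeq = 10, m = 100, k = 2)  # 20.04
#' @export
mecBound <- function(pe, cSeq, m, k, kappa = 1, C1 = 1) {
  stopifnot(pe >= 0, cSeq > 0, m >= 1, k >= 1, kappa >= 1, C1 > 0)
  2 * pe * (cSeq * m + kappa^4 * C1 * k)
}

#' Bound on the expected correct phasing rate
#'
#' `E[CPR] >= 1 - C1 * kappa^4 * pe * k / (n * cSnp)`, clamped into `[0, 1]`:
#' the achievable CPR improves with more reads and denser SNP coverage per
#' read, and degrades with the error rate and the ploidy.
#'
#' @inheritParams coverageCondition
#' @param n number of reads
#' @return the bound value in `[0, 1]`
#' @examples
#' cprBound(pe = 0.01, k = 2, n = 100, cSnp = 5)  # 0.99996
#' @export
cprBound <- function(pe, k, n, cSnp, kappa = 1, C1 = 1) {
  stopifnot(pe >= 0, k >= 1, n >= 1, cSnp > 0, kappa >= 1, C1 > 0)
  min(max(1 - C1 * kappa^4 * pe * k / (n * cSnp), 0), 1)
}

#' Bound on the squared factorization error
#'
#' `||Mbar - U* V*'||_F^2 <= C1 * kappa^4 * pe * k * m / (2 * cSnp)`: the
#' residual of the recovered factorization against the noiseless signal,
#' driven entirely by the sequencing error rate.
#'
#' @inheritParams mecBound
#' @return the bound value (>= 0)
#' @examples
#' errorBound(pe = 0.01, k = 3, m = 1000, cSnp = 10)  # 1.5
#' @export
errorBound <- function(pe, k, m, cSnp, kappa = 1, C1 = 1) {
  stopifnot(pe >= 0, k >= 1, m >= 1, cSnp > 0, kappa >= 1, C1 > 0)
  C1 * kappa^4 * pe * k * m / (2 * cSnp)
}
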