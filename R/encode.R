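# One-hot tensor encoding and mode-1 unfoldings.
#
# Allele codes 0..3 map to the four standard basis vectors of R^4; a missing
# call maps to the all-zero vector. After mode-1 unfolding, channel c of site j
# sits in column (c-1)*m + j, i.e. the tensor's four frontal slices become four
# contiguous column blocks.

#' One-hot encode a FragmentSet into its observed unfolding
#'
#' Builds the n x 4m mode-1 unfolding of the one-hot fragment tensor together
#' with its observation mask. For a covered pair (read i, site j) with allele
#' code a, the value matrix has a single 1 at column `a*m + j` (1-based with
#' `a` in 0..3), and the mask marks all four channel columns
#' `{j, m+j, 2m+j, 3m+j}` of row i; everything outside the mask is zero.
#'
#' @param frags a [FragmentSet-class]
#' @return an [ObservedMatrix-class]
#' @examples
#' fr <- FragmentSet(read = 1, site = 1, allele = 2, nSites = 5)
#' obs <- encodeFragments(fr)
#' which(as.matrix(obs@values)[1, ] == 1)  # column 11 = 2*5 + 1
#' @export
encodeFragments <- function(frags) {
  stopifnot(is(frags, "FragmentSet"))
  n <- frags@nReads
  m <- frags@nSites
  vals <- Matrix::sparseMatrix(
    i = frags@read, j = frags@allele * m + frags@site,
    x = 1, dims = c(n, 4L * m)
  )
  np <- length(frags@site)
  mask <- Matrix::sparseMatrix(
    i = rep(frags@read, 4L),
    j = rep.int(0:3, rep(np, 4L)) * m + rep(frags@site, 4L),
    x = 1, dims = c(n, 4L * m)
  )
  new("ObservedMatrix", values = vals, mask = mask, nSites = m,
      readIDs = frags@readIDs)
}

#' Decode an observed unfolding back into fragments
#'
#' Inverse of [encodeFragments()]: recovers the covered (read, site, allele)
#' triplets from the one-hot value matrix and mask.
#'
#' @param obs an [ObservedMatrix-class]
#' @return a [FragmentSet-class]
#' @export
decodeObserved <- function(obs) {
  stopifnot(is(obs, "ObservedMatrix"))
  m <- obs@nSites
  tv <- as(obs@values, "TsparseMatrix")
  keep <- tv@x != 0
  col <- tv@j[keep] + 1L     # Tsparse indices are 0-based
  FragmentSet(
    read = tv@i[keep] + 1L,
    site = (col - 1L) %% m + 1L,
    allele = (col - 1L) %/% m,
    nSites = m, nReads = nrow(obs@values), readIDs = obs@readIDs
  )
}

#' Unfold a HaplotypeSet into its 4m x k one-hot matrix
#'
#' Column p holds the one-hot encoding of haplotype p: rows
#' `{j, m+j, 2m+j, 3m+j}` are the four channel indicators of site j, and an
#' uncalled (NA) site encodes to four zeros.
#'
#' @param haps a [HaplotypeSet-class]
#' @return a dense 4m x k 0/1 matrix
#' @examples
#' unfoldHaplotypes(HaplotypeSet(matrix(0L, 1, 1)))  # c(1,0,0,0)
#' @export
unfoldHaplotypes <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"))
  a <- haps@alleles
  k <- nrow(a); m <- ncol(a)
  V <- matrix(0, 4L * m, k)
  for (p in seq_len(k)) {
    j <- which(!is.na(a[p, ]))
    V[a[p, j] * m + j, p] <- 1
  }
  V
}

#' Round a relaxed haplotype unfolding to allele calls
#'
#' Maps a (possibly fractional) 4m x k matrix with entries in [0, 1] back to a
#' [HaplotypeSet-class]: for each site and haplotype the allele is the argmax
#' over the four channel values, with ties broken toward the lowest channel
#' index; a site whose four channels are all exactly zero is left uncalled
#' (NA). This is how the solver's relaxed solution is turned into haplotypes.
#'
#' @param V numeric 4m x k matrix with entries in `[0, 1]` (a tolerance of
#'   1e-9 is allowed before an error is raised)
#' @param m number of SNP sites
#' @return a [HaplotypeSet-class] with k = `ncol(V)` haplotypes
#' @examples
#' foldHaplotypes(matrix(c(0.1, 0.7, 0.1, 0.1), 4, 1), m = 1)  # allele 1
#' @export
foldHaplotypes <- function(V, m) {
  V <- as.matrix(V)
  m <- as.integer(m)
  if (nrow(V) != 4L * m) stop("V must have 4*m rows")
  if (any(V < -1e-9) || any(V > 1 + 1e-9))
    stop("entries of V must lie in [0, 1]")
  k <- ncol(V)
  a <- matrix(NA_integer_, k, m)
  for (p in seq_len(k)) {
    ch <- matrix(V[, p], m, 4L)        # site j, channel c at ch[j, c]
    best <- max.col(ch, ties.method = "first")
    called <- ch[cbind(seq_len(m), best)] != 0
    a[p, called] <- best[called] - 1L
  }
  HaplotypeSet(a)
}
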