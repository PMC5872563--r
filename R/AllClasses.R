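#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t rowSums colSums
NULL

MISSING_CHAR <- "-"

#' FragmentSet: SNP fragments of sequencing reads
#'
#' A `FragmentSet` stores, for each sequencing read, the SNP sites it covers
#' and the allele observed at each covered site. Alleles are coded as integers
#' 0--3 (one code per nucleotide; the mapping to bases is an arbitrary but
#' fixed convention). Internally the covered (read, site, allele) triplets are
#' held in coordinate form, sorted by read and then site, so that very sparse
#' fragment matrices (each read typically covers a handful of the m SNP sites)
#' stay cheap to store and to encode.
#'
#' @slot read integer vector, 1-based read index of each covered pair
#' @slot site integer vector, 1-based SNP site index of each covered pair
#' @slot allele integer vector, allele code in 0..3 of each covered pair
#' @slot nReads number of reads n
#' @slot nSites number of SNP sites m (haplotype length)
#' @slot readIDs character vector of read identifiers, length n
#'
#' @seealso [FragmentSet()] to construct one, [readFragmentFile()] to parse
#'   the fragment file format, [encodeFragments()] for the one-hot encoding.
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(
    read = "integer", site = "integer", allele = "integer",
    nReads = "integer", nSites = "integer", readIDs = "character"
  )
)

setValidity("FragmentSet", function(object) {
  msg <- character()
  np <- length(object@read)
  if (length(object@site) != np || length(object@allele) != np)
    msg <- c(msg, "read, site and allele slots must have equal length")
  if (np == 0L) msg <- c(msg, "a FragmentSet must contain at least one covered site")
  n <- object@nReads; m <- object@nSites
  if (length(n) != 1L || is.na(n) || n < 1L) msg <- c(msg, "nReads must be a positive count")
  if (length(m) != 1L || is.na(m) || m < 1L) msg <- c(msg, "nSites must be a positive count")
  if (length(msg)) return(msg)
  if (any(object@read < 1L) || any(object@read > n))
    msg <- c(msg, "read indices out of range")
  if (any(object@site < 1L) || any(object@site > m))
    msg <- c(msg, sprintf("site indices must lie in [1, %d]", m))
  if (any(is.na(object@allele)) || any(object@allele < 0L) || any(object@allele > 3L))
    msg <- c(msg, "allele codes must be in 0..3 (no missing alleles inside a read)")
  if (length(object@readIDs) != n)
    msg <- c(msg, "readIDs must have one entry per read")
  # sorted by read, strictly increasing sites within a read; every read non-empty
  if (is.unsorted(object@read)) msg <- c(msg, "triplets must be sorted by read index")
  if (length(msg) == 0L) {
    same <- object@read[-1L] == object@read[-np]
    if (np > 1L && any(same & diff(object@site) <= 0L))
      msg <- c(msg, "site indices within a read must be strictly increasing")
    if (length(unique(object@read)) != n)
      msg <- c(msg, "every read must cover at least one site")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#'
#' @param read integer vector of 1-based read indices, one per covered
#'   (read, site) pair
#' @param site integer vector of 1-based SNP site indices, parallel to `read`
#' @param allele integer vector of allele codes (0..3), parallel to `read`
#' @param nSites number of SNP sites m; defaults to `max(site)`
#' @param nReads number of reads n; defaults to `max(read)`
#' @param readIDs optional character read identifiers (default `"r1".."rn"`)
#'
#' @return a [FragmentSet-class] object (triplets are re-sorted by read, site)
#' @examples
#' fr <- FragmentSet(read = c(1, 1, 2), site = c(1, 3, 2), allele = c(0, 1, 2))
#' nReads(fr)
#' @export
FragmentSet <- function(read, site, allele, nSites = max(site),
                        nReads = max(read), readIDs = NULL) {
  read <- as.integer(read); site <- as.integer(site); allele <- as.integer(allele)
  o <- order(read, site)
  if (is.null(readIDs)) readIDs <- paste0("r", seq_len(nReads))
  new("FragmentSet",
    read = read[o], site = site[o], allele = allele[o],
    nReads = as.integer(nReads), nSites = as.integer(nSites),
    readIDs = as.character(readIDs)
  )
}

#' HaplotypeSet: k haplotype sequences over coded alleles
#'
#' Holds the k haplotype sequences of a k-ploid organism as a k x m integer
#' matrix of allele codes 0--3, with `NA` marking sites a haplotype leaves
#' uncalled (e.g. sites never covered by any read in an assembly).
#'
#' @slot alleles integer matrix, k rows (haplotypes) by m columns (SNP sites)
#' @exportClass HaplotypeSet
setClass("HaplotypeSet", representation(alleles = "matrix"))

setValidity("HaplotypeSet", function(object) {
  a <- object@alleles
  if (!is.numeric(a) && !all(is.na(a))) return("alleles must be an integer matrix")
  if (nrow(a) < 1L || ncol(a) < 1L) return("alleles must have at least one row and column")
  vals <- a[!is.na(a)]
  if (length(vals) && (any(vals != as.integer(vals)) || any(vals < 0) || any(vals > 3)))
    return("allele codes must be integers in 0..3 or NA")
  TRUE
})

#' Construct a HaplotypeSet
#'
#' @param alleles k x m matrix of allele codes (0..3, NA for uncalled sites),
#'   or anything coercible to one
#' @return a [HaplotypeSet-class]
#' @examples
#' HaplotypeSet(rbind(c(0, 1, 0), c(1, 0, 1)))
#' @export
HaplotypeSet <- function(alleles) {
  a <- as.matrix(alleles)
  storage.mode(a) <- "integer"
  new("HaplotypeSet", alleles = a)
}

#' ObservedMatrix: one-hot unfolded SNP fragment tensor
#'
#' The mode-1 unfolding of the one-hot encoded fragment tensor: an n x 4m
#' sparse 0/1 matrix of observed values together with the n x 4m observation
#' mask. Column `(c-1)*m + j` holds channel c (allele code c-1) of site j, so
#' the four channels of one site occupy columns `{j, m+j, 2m+j, 3m+j}`; a
#' covered (read, site) pair has all four of its channel columns masked and
#' exactly one of them equal to 1, and everything outside the mask is
#' zero-filled.
#'
#' @slot values n x 4m sparse numeric matrix of 0/1 observations
#' @slot mask n x 4m sparse numeric matrix, 1 on observed entries
#' @slot nSites number of SNP sites m
#' @slot readIDs read identifiers carried through from the FragmentSet
#' @seealso [encodeFragments()], [decodeObserved()]
#' @exportClass ObservedMatrix
setClass("ObservedMatrix",
  representation(
    values = "Matrix", mask = "Matrix",
    nSites = "integer", readIDs = "character"
  )
)

setValidity("ObservedMatrix", function(object) {
  m <- object@nSites
  if (ncol(object@values) != 4L * m) return("values must have 4*nSites columns")
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  v <- object@values@x
  if (length(v) && any(v != 0 & v != 1)) return("observed values must be 0/1")
  TRUE
})

#' HaplotypeAssembly: result of a phasing run
#'
#' Returned by [assembleHaplotypes()]. Bundles the called haplotypes, the
#' final read-origin assignment, the objective trace of the alternating
#' minimization, and the MEC score of the solution.
#'
#' @slot haplotypes the assembled [HaplotypeSet-class]
#' @slot origins integer vector, assigned haplotype index (1..k) per read
#' @slot objectiveTrace numeric vector of objective values, one per iteration
#' @slot iterations number of alternating iterations performed
#' @slot converged logical, TRUE if the relative-decrease tolerance was met
#' @slot mec minimum error correction score of the returned haplotypes
#' @exportClass HaplotypeAssembly
setClass("HaplotypeAssembly",
  representation(
    haplotypes = "HaplotypeSet", origins = "integer",
    objectiveTrace = "numeric", iterations = "integer",
    converged = "logical", mec = "integer"
  )
)

#' PhasingSimulation: simulated reads plus ground truth
#'
#' Returned by [simulateReads()]. Carries the generated [FragmentSet-class]
#' together with everything needed to validate an assembly against the truth:
#' the true haplotypes, the genomic SNP coordinates, each read's true origin,
#' and the (read, site) pairs whose alleles were flipped by the error model.
#'
#' @slot fragments simulated [FragmentSet-class]
#' @slot truth ground-truth [HaplotypeSet-class]
#' @slot positions integer vector of genomic SNP coordinates (bp)
#' @slot readOrigins integer vector, true haplotype of each retained read
#' @slot plantedErrors two-column integer matrix of (read, site) flips
#' @slot config list of the resolved simulation parameters
#' @exportClass PhasingSimulation
setClass("PhasingSimulation",
  representation(
    fragments = "FragmentSet", truth = "HaplotypeSet",
    positions = "integer", readOrigins = "integer",
    plantedErrors = "matrix", config = "list"
  )
)

setValidity("PhasingSimulation", function(object) {
  k <- nrow(object@truth@alleles)
  if (length(object@readOrigins) != object@fragments@nReads)
    return("readOrigins must have one entry per read")
  if (any(object@readOrigins < 1L | object@readOrigins > k))
    return("readOrigins must lie in 1..ploidy")
  if (ncol(object@plantedErrors) != 2L)
    return("plantedErrors must be a (read, site) two-column matrix")
  TRUE
})
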