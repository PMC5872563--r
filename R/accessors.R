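#' Accessors for tensorphase objects
#'
#' Small, read-only views into [FragmentSet-class], [HaplotypeSet-class],
#' [ObservedMatrix-class], [HaplotypeAssembly-class] and
#' [PhasingSimulation-class] objects; prefer these over `@` slot access.
#'
#' @param x an object of one of the classes above
#' @return the requested component: counts (`nReads`, `nSites`, `ploidy`,
#'   `mec`), the allele matrix (`alleles`), identifiers (`readIDs`), embedded
#'   objects (`haplotypes`, `fragments`, `truthHaplotypes`), or per-read /
#'   per-iteration vectors (`readOrigins`, `objectiveTrace`, `snpPositions`,
#'   `plantedErrors`, `converged`)
#' @name accessors
#' @examples
#' fr <- FragmentSet(read = c(1, 2), site = c(1, 2), allele = c(0, 1))
#' nReads(fr); nSites(fr)
NULL

#' @rdname accessors
setMethod("nReads", "FragmentSet", function(x) x@nReads)
#' @rdname accessors
setMethod("nReads", "ObservedMatrix", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nSites", "FragmentSet", function(x) x@nSites)
#' @rdname accessors
setMethod("nSites", "HaplotypeSet", function(x) ncol(x@alleles))
#' @rdname accessors
setMethod("nSites", "ObservedMatrix", function(x) x@nSites)
#' @rdname accessors
setMethod("ploidy", "HaplotypeSet", function(x) nrow(x@alleles))
#' @rdname accessors
setMethod("ploidy", "HaplotypeAssembly", function(x) nrow(x@haplotypes@alleles))
#' @rdname accessors
setMethod("alleles", "HaplotypeSet", function(x) x@alleles)
#' @rdname accessors
setMethod("readIDs", "FragmentSet", function(x) x@readIDs)
#' @rdname accessors
setMethod("readIDs", "ObservedMatrix", function(x) x@readIDs)
#' @rdname accessors
setMethod("haplotypes", "HaplotypeAssembly", function(x) x@haplotypes)
#' @rdname accessors
setMethod("readOrigins", "HaplotypeAssembly", function(x) x@origins)
#' @rdname accessors
setMethod("readOrigins", "PhasingSimulation", function(x) x@readOrigins)
#' @rdname accessors
setMethod("objectiveTrace", "HaplotypeAssembly", function(x) x@objectiveTrace)
#' @rdname accessors
setMethod("converged", "HaplotypeAssembly", function(x) x@converged)
#' @rdname accessors
setMethod("mec", "HaplotypeAssembly", function(x) x@mec)
#' @rdname accessors
setMethod("fragments", "PhasingSimulation", function(x) x@fragments)
#' @rdname accessors
setMethod("truthHaplotypes", "PhasingSimulation", function(x) x@truth)
#' @rdname accessors
setMethod("snpPositions", "PhasingSimulation", function(x) x@positions)
#' @rdname accessors
setMethod("plantedErrors", "PhasingSimulation", function(x) x@plantedErrors)

#' Read-origin indicator matrix
#'
#' Expands a per-read haplotype assignment into the n x k binary indicator
#' matrix U whose i-th row is the standard basis vector of the haplotype read
#' i is assigned to.
#'
#' @param x a [HaplotypeAssembly-class], a [PhasingSimulation-class] (true
#'   origins), or an integer vector of 1-based origins
#' @param k ploidy (needed only for the integer-vector method; defaults to
#'   `max(x)`)
#' @param ... passed between methods
#' @return a sparse n x k 0/1 `Matrix` with exactly one 1 per row
#' @examples
#' assignmentMatrix(c(1L, 2L, 1L), k = 2)
#' @name assignmentMatrix
NULL

#' @rdname assignmentMatrix
setMethod("assignmentMatrix", "integer", function(x, k = max(x), ...) {
  Matrix::sparseMatrix(i = seq_along(x), j = x, x = 1, dims = c(length(x), k))
})
#' @rdname assignmentMatrix
setMethod("assignmentMatrix", "numeric", function(x, k = max(x), ...) {
  assignmentMatrix(as.integer(x), k = as.integer(k))
})
#' @rdname assignmentMatrix
setMethod("assignmentMatrix", "HaplotypeAssembly", function(x, ...) {
  assignmentMatrix(x@origins, k = ploidy(x))
})
#' @rdname assignmentMatrix
setMethod("assignmentMatrix", "PhasingSimulation", function(x, ...) {
  assignmentMatrix(x@readOrigins, k = nrow(x@truth@alleles))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf(
    "FragmentSet: %d reads over %d SNP sites (%d covered pairs, mean %.2f per read)\n",
    object@nReads, object@nSites, length(object@site),
    length(object@site) / object@nReads
  ))
})

setMethod("show", "HaplotypeSet", function(object) {
  a <- object@alleles
  cat(sprintf("HaplotypeSet: ploidy %d, %d SNP sites", nrow(a), ncol(a)))
  nmiss <- sum(is.na(a))
  if (nmiss) cat(sprintf(" (%d uncalled entries)", nmiss))
  cat("\n")
  shown <- min(ncol(a), 40L)
  for (p in seq_len(nrow(a))) {
    s <- ifelse(is.na(a[p, seq_len(shown)]), "-", a[p, seq_len(shown)])
    cat(sprintf("  h%d: %s%s\n", p, paste(s, collapse = ""),
                if (shown < ncol(a)) "..." else ""))
  }
})

setMethod("show", "ObservedMatrix", function(object) {
  cat(sprintf(
    "ObservedMatrix: %d x %d one-hot unfolding (%d sites, %.3f%% of fibers observed)\n",
    nrow(object@values), ncol(object@values), object@nSites,
    100 * length(object@mask@x) / (4 * prod(dim(object@values)) / 4)
  ))
})

setMethod("show", "HaplotypeAssembly", function(object) {
  tr <- object@objectiveTrace
  cat(sprintf(
    "HaplotypeAssembly: ploidy %d, %d sites | MEC %d | %d iterations (%s), objective %.4g\n",
    ploidy(object), nSites(object@haplotypes), object@mec, object@iterations,
    if (object@converged) "converged" else "max iterations reached",
    if (length(tr)) tr[length(tr)] else NA_real_
  ))
})

setMethod("show", "PhasingSimulation", function(object) {
  cat(sprintf(
    "PhasingSimulation: ploidy %d, %d SNPs, %d reads, %d planted errors\n",
    nrow(object@truth@alleles), ncol(object@truth@alleles),
    object@fragments@nReads, nrow(object@plantedErrors)
  ))
})
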