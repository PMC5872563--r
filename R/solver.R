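# Alternating minimization of the relaxed MEC objective
#
#   f(U, V) = 1/2 || P_Omega( Rbar - U V' ) ||_F^2 ,  V in [0,1]^{4m x k},
#   rows of U standard basis vectors,
#
# alternating (i) exact per-read re-assignment of U (argmin over the k basis
# vectors) with (ii) a projected gradient step on V with the adaptive step
# size  alpha = C ||G||_F^2 / ||P_Omega(U G')||_F^2 ,  C in (0, 2), which
# guarantees monotone descent. Because U has indicator rows, every masked
# entry of U V' is just V[c, origin(i)], so the solver only ever touches the
# observed triplets and sparse Matrix products; the dense n x 4m matrix is
# never formed.

.originsOf <- function(U, n = NULL) {
  if (is.numeric(U) && is.null(dim(U))) return(as.integer(U))
  U <- as(U, "CsparseMatrix")
  o <- as.integer(as.matrix(U %*% seq_len(ncol(U))))
  o
}

# precomputed solver context for one ObservedMatrix
.solverContext <- function(obs) {
  tv <- as(obs@mask, "TsparseMatrix")
  list(
    values = obs@values, mask = obs@mask,
    n = nrow(obs@values), m = obs@nSites,
    covPerRead = Matrix::rowSums(obs@values),
    mi = tv@i + 1L, mc = tv@j + 1L,                 # mask triplets
    mv = as.numeric(obs@values[cbind(tv@i + 1L, tv@j + 1L)])
  )
}

.objectiveCore <- function(ctx, origins, V) {
  pred <- V[cbind(ctx$mc, origins[ctx$mi])]
  0.5 * sum((ctx$mv - pred)^2)
}

.assignCore <- function(ctx, V) {
  B <- as.matrix(ctx$values %*% V)
  D <- as.matrix(ctx$mask %*% (V * V))
  dist <- ctx$covPerRead - 2 * B + D
  max.col(-dist, ties.method = "first")
}

.gradientCore <- function(ctx, origins, V) {
  Uind <- assignmentMatrix(origins, k = ncol(V))
  S <- as.matrix(Matrix::crossprod(ctx$values, Uind))
  counts <- as.matrix(Matrix::crossprod(ctx$mask, Uind))
  list(G = -(S - V * counts), counts = counts)
}

#' Relaxed MEC objective value
#'
#' Evaluates `f(U, V) = 0.5 * ||P_Omega(Rbar - U V')||_F^2`: half the sum of
#' squared residuals between the observed one-hot entries and the assigned
#' haplotype columns, over the observation mask only.
#'
#' @param obs an [ObservedMatrix-class]
#' @param U read assignment: an integer vector of 1-based haplotype origins
#'   or an n x k indicator matrix
#' @param V numeric 4m x k haplotype unfolding with entries in `[0, 1]`
#' @return the objective value (>= 0); equals the MEC score when `V` is the
#'   one-hot unfolding of a haplotype set without uncalled sites
#' @export
objectiveValue <- function(obs, U, V) {
  V <- as.matrix(V)
  if (nrow(V) != 4L * obs@nSites) stop("V must have 4*nSites rows")
  o <- .originsOf(U)
  if (length(o) != nrow(obs@values)) stop("U must assign every read")
  .objectiveCore(.solverContext(obs), o, V)
}

#' Assign each read to its closest haplotype column
#'
#' Independently for every read, picks the haplotype column p minimizing the
#' masked squared distance between the read's observed row and `V e_p`
#' restricted to the read's covered fibers; ties go to the lowest haplotype
#' index. This is the exact U-update of the alternating scheme.
#'
#' @param obs an [ObservedMatrix-class]
#' @param V numeric 4m x k matrix with entries in `[0, 1]`
#' @return integer vector of 1-based origins, one per read (expand with
#'   [assignmentMatrix()] if the indicator matrix form is needed)
#' @export
assignReads <- function(obs, V) {
  V <- as.matrix(V)
  .assignCore(.solverContext(obs), V)
}

#' Gradient of the relaxed objective with respect to V
#'
#' Returns `-(P_Omega(Rbar - U V'))' U`, the partial derivative of the
#' objective at the current assignment. Rows belonging to fibers never
#' covered by any read of a haplotype are exactly zero.
#'
#' @inheritParams objectiveValue
#' @return a 4m x k numeric matrix
#' @export
gradientV <- function(obs, U, V) {
  V <- as.matrix(V)
  o <- .originsOf(U)
  .gradientCore(.solverContext(obs), o, V)$G
}

#' Adaptive step size for the projected gradient step
#'
#' Computes `alpha = C * ||G||_F^2 / ||P_Omega(U G')||_F^2`. With `C` in
#' (0, 2) this step length makes the projected gradient update decrease the
#' objective. Because U has indicator rows, the denominator reduces to
#' `sum(counts * G^2)` where `counts[c, p]` is the number of masked entries
#' in column c among reads assigned to haplotype p.
#'
#' @param grad gradient matrix as returned by [gradientV()]
#' @param U read assignment (origins vector or indicator matrix)
#' @param obs the [ObservedMatrix-class] supplying the mask
#' @param C step constant in (0, 2); default 1
#' @return the step size (> 0), or `NA_real_` when the gradient is zero,
#'   which signals convergence (no step should be taken)
#' @export
stepSize <- function(grad, U, obs, C = 1) {
  if (C <= 0 || C >= 2) stop("C must lie in (0, 2)")
  o <- .originsOf(U)
  Uind <- assignmentMatrix(o, k = ncol(grad))
  counts <- as.matrix(Matrix::crossprod(obs@mask, Uind))
  g2 <- sum(grad^2)
  if (g2 == 0) return(NA_real_)
  C * g2 / sum(counts * grad^2)
}

#' Projected gradient update of V
#'
#' Takes the gradient step and clamps every entry back into `[0, 1]`.
#'
#' @param V current 4m x k matrix
#' @param grad gradient matrix
#' @param alpha step size (> 0)
#' @return the updated matrix, entrywise in `[0, 1]`
#' @export
updateV <- function(V, grad, alpha) {
  stopifnot(alpha > 0)
  pmin(pmax(V - alpha * grad, 0), 1)
}

# power subspace iteration for the top-k singular triplets of a (sparse)
# matrix; finishes with an exact SVD of the k-dimensional projection
.powerSVD <- function(M, k, iterations = 30L, seed = NULL) {
  run <- function() {
    X <- matrix(stats::rnorm(ncol(M) * k), ncol(M), k)
    X <- qr.Q(qr(X))
    for (it in seq_len(iterations)) {
      X <- as.matrix(Matrix::crossprod(M, M %*% X))
      X <- qr.Q(qr(X))
    }
    Y <- as.matrix(M %*% X)
    sv <- svd(Y, nu = k, nv = k)
    u <- sv$u
    v <- X %*% sv$v
    # canonical sign: make each right singular vector sum positive, so the
    # clamp onto [0,1] downstream does not annihilate mostly-negative columns
    flip <- colSums(v) < 0
    u[, flip] <- -u[, flip]
    v[, flip] <- -v[, flip]
    list(u = u, d = sv$d[seq_len(k)], v = v)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Spectral initialization of the solver
#'
#' Computes the rank-k SVD (by seeded power iteration) of the zero-filled
#' observed matrix rescaled by the inverse observed-fiber fraction, and sets
#' `V0 = clamp(W_k * sqrt(Sigma_k))` from the top-k right singular vectors,
#' then `U0 = assignReads(obs, V0)`. Starting the alternating scheme from
#' this point places it, with high probability, inside the basin where the
#' relaxed objective is well behaved.
#'
#' @param obs an [ObservedMatrix-class]
#' @param k ploidy (>= 2)
#' @param powerIterations number of power-iteration sweeps
#' @param seed optional integer seed for the random subspace start
#' @return a list with elements `V` (4m x k initial matrix in `[0,1]`),
#'   `origins` (initial assignment), `singularValues` (top-k singular values
#'   of the rescaled matrix) and `fiberFraction` (the estimate of the
#'   observation probability p)
#' @export
initializeSolver <- function(obs, k, powerIterations = 30L, seed = NULL) {
  n <- nrow(obs@values); m <- obs@nSites
  k <- as.integer(k)
  if (k < 1L || k > min(n, 4L * m)) stop("k must lie in [1, min(n, 4m)]")
  phat <- (length(obs@mask@x) / 4) / (as.numeric(n) * m)
  if (phat == 0) stop("observed matrix has no covered fibers")
  sv <- .powerSVD(obs@values / phat, k, iterations = powerIterations, seed = seed)
  V0 <- sv$v %*% diag(sqrt(sv$d), k)
  V0 <- pmin(pmax(V0, 0), 1)
  list(V = V0, origins = .assignCore(.solverContext(obs), V0),
       singularValues = sv$d, fiberFraction = phat)
}

# single-start alternating run on one context, from a given V0
.solveCore <- function(ctx, obs, k, C, maxIterations, tolerance, V0,
                       verbose = FALSE) {
  V <- V0
  trace <- numeric(0)
  converged <- FALSE
  origins <- integer(ctx$n)
  for (t in seq_len(maxIterations)) {
    origins <- .assignCore(ctx, V)
    gr <- .gradientCore(ctx, origins, V)
    g2 <- sum(gr$G^2)
    if (g2 <= .Machine$double.eps) {
      trace <- c(trace, .objectiveCore(ctx, origins, V))
      converged <- TRUE
      break
    }
    alpha <- C * g2 / sum(gr$counts * gr$G^2)
    V <- pmin(pmax(V - alpha * gr$G, 0), 1)
    f <- .objectiveCore(ctx, origins, V)
    trace <- c(trace, f)
    if (verbose) message(sprintf("  iter %4d  objective %.6g", t, f))
    if (t > 1L && (trace[t - 1L] - f) / max(trace[t - 1L], 1) < tolerance) {
      converged <- TRUE
      break
    }
  }
  origins <- .assignCore(ctx, V)
  list(V = V, origins = origins, trace = trace, converged = converged,
       iterations = length(trace))
}

#' Assemble haplotypes from SNP fragments
#'
#' The full pipeline: one-hot encode the fragments, build a starting point,
#' then alternate exact read reassignment with projected gradient steps on
#' the haplotype matrix until the relative objective decrease drops below
#' `tolerance` or `maxIterations` is hit. The relaxed solution is rounded to
#' allele calls per site (sites covered by no read are reported uncalled),
#' and the MEC score of the result is attached.
#'
#' Two starting points are available. `init = "guided"` (default) seeds the
#' alternation with the combinatorial estimate of [seedHaplotypes()], which
#' resolves the per-site column-relabeling degeneracy that short fragments
#' leave in the relaxed objective; `init = "spectral"` uses the clamped
#' rank-k SVD start of [initializeSolver()] alone. With `restarts > 1` the
#' pipeline is run from several seeded starts and the solution with the
#' lowest MEC is kept.
#'
#' @param frags a [FragmentSet-class]
#' @param ploidy number of haplotypes k (>= 2)
#' @param C step constant in (0, 2); the midpoint 1 is the default
#' @param maxIterations iteration cap (default 500)
#' @param tolerance relative objective-decrease stopping threshold
#' @param powerIterations power-iteration sweeps for the spectral start
#' @param seed optional integer seed; fixes all random tie-breaking, so runs
#'   with the same seed are bit-identical
#' @param restarts number of seeded starts (default 2);
#'   the solution with the lowest MEC is kept
#' @param init `"guided"` or `"spectral"` (see Details)
#' @param maskUnlinked report sites whose phase is unidentifiable (covered
#'   only by single-SNP reads, hence never linked to any other site) as
#'   uncalled rather than emitting an arbitrary column order (default TRUE)
#' @param splitBlocks if TRUE, partition reads into connectivity components
#'   (reads sharing a SNP site) and assemble each block independently; the
#'   haplotype column order is arbitrary per block
#' @param verbose print per-iteration objective values
#' @return a [HaplotypeAssembly-class]
#' @examples
#' truth <- HaplotypeSet(rbind(c(0, 0, 0), c(1, 1, 1)))
#' fr <- FragmentSet(read = rep(1:6, each = 3), site = rep(1:3, 6),
#'                   allele = rep(c(0, 1), each = 3, times = 3))
#' fit <- assembleHaplotypes(fr, ploidy = 2, seed = 1)
#' mec(fit)
#' @export
assembleHaplotypes <- function(frags, ploidy, C = 1, maxIterations = 500L,
                               tolerance = 1e-6, powerIterations = 30L,
                               seed = NULL, restarts = 2L,
                               init = c("guided", "spectral"),
                               maskUnlinked = TRUE,
                               splitBlocks = FALSE, verbose = FALSE) {
  stopifnot(is(frags, "FragmentSet"))
  init <- match.arg(init)
  k <- as.integer(ploidy)
  if (k < 2L) stop("ploidy must be at least 2")
  if (C <= 0 || C >= 2) stop("C must lie in (0, 2)")
  if (tolerance <= 0) stop("tolerance must be positive")

  if (splitBlocks) {
    comp <- .readComponents(frags)
    if (max(comp) > 1L)
      return(.assembleByBlocks(frags, comp, k, C, maxIterations, tolerance,
                               powerIterations, seed, restarts, init,
                               maskUnlinked, verbose))
  }

  obs <- encodeFragments(frags)
  ctx <- .solverContext(obs)
  best <- NULL
  for (r in seq_len(max(1L, as.integer(restarts)))) {
    s <- if (is.null(seed)) NULL else as.integer(seed) + (r - 1L) * 131L
    if (init == "guided") {
      # light seeds per restart; the expensive segment polish and the
      # gradient refinement run once, on the best light seed
      hap <- .lightSeed(frags, k, seed = s)
      sm <- as.integer(mecScore(frags, HaplotypeSet(hap)))
      if (is.null(best) || sm < best$mec) best <- list(hap = hap, mec = sm)
    } else {
      V0 <- initializeSolver(obs, k, powerIterations = powerIterations,
                             seed = s)$V
      run <- .solveCore(ctx, obs, k, C, maxIterations, tolerance, V0, verbose)
      haps <- foldHaplotypes(run$V, frags@nSites)
      run$mec <- as.integer(mecScore(frags, haps))
      run$haps <- haps
      if (is.null(best) || run$mec < best$mec) best <- run
    }
  }
  if (init == "guided") {
    hap <- .polishSeed(best$hap, frags, k)
    V0 <- unfoldHaplotypes(HaplotypeSet(hap))
    run <- .solveCore(ctx, obs, k, C, maxIterations, tolerance, V0, verbose)
    haps <- foldHaplotypes(run$V, frags@nSites)
    run$mec <- as.integer(mecScore(frags, haps))
    run$haps <- haps
    best <- run
  }
  haps <- best$haps
  if (maskUnlinked) {
    un <- .unlinkedSites(frags)
    if (length(un)) {
      a <- haps@alleles
      a[, un] <- NA_integer_
      haps <- HaplotypeSet(a)
      best$mec <- as.integer(mecScore(frags, haps))
    }
  }
  unassigned <- setdiff(seq_len(k), unique(best$origins))
  if (length(unassigned) && verbose)
    message("unanchored haplotype column(s): ", paste(unassigned, collapse = ", "))
  new("HaplotypeAssembly",
    haplotypes = haps, origins = best$origins,
    objectiveTrace = best$trace, iterations = as.integer(best$iterations),
    converged = best$converged, mec = best$mec
  )
}

# sites covered exclusively by single-SNP reads: no read links them to any
# other site, so their column order is unidentifiable
.unlinkedSites <- function(frags) {
  multi <- which(tabulate(frags@read, frags@nReads) >= 2L)
  linked <- unique(frags@site[frags@read %in% multi])
  covered <- unique(frags@site)
  setdiff(covered, linked)
}

# union-find over sites; a read joins all its sites into one component
.readComponents <- function(frags) {
  m <- frags@nSites
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  sites <- split(frags@site, frags@read)
  for (s in sites) {
    r0 <- find(s[1L])
    for (x in s[-1L]) {
      r1 <- find(x)
      if (r1 != r0) parent[r1] <- r0
    }
  }
  firstSite <- vapply(sites, `[`, integer(1), 1L)
  roots <- vapply(firstSite, find, integer(1))
  as.integer(factor(roots))
}

.assembleByBlocks <- function(frags, comp, k, C, maxIterations, tolerance,
                              powerIterations, seed, restarts, init,
                              maskUnlinked, verbose) {
  m <- frags@nSites
  allAlleles <- matrix(NA_integer_, k, m)
  origins <- integer(frags@nReads)
  trace <- numeric(0)
  conv <- TRUE
  iters <- 0L
  for (b in sort(unique(comp))) {
    rid <- which(comp == b)
    sel <- frags@read %in% rid
    sub <- FragmentSet(
      read = match(frags@read[sel], rid), site = frags@site[sel],
      allele = frags@allele[sel], nSites = m, nReads = length(rid),
      readIDs = frags@readIDs[rid]
    )
    fit <- assembleHaplotypes(sub, k, C = C, maxIterations = maxIterations,
                              tolerance = tolerance,
                              powerIterations = powerIterations,
                              seed = if (is.null(seed)) NULL else seed + b,
                              restarts = restarts, init = init,
                              maskUnlinked = maskUnlinked, verbose = verbose)
    a <- fit@haplotypes@alleles
    covered <- colSums(!is.na(a)) > 0L
    allAlleles[, covered] <- a[, covered]
    origins[rid] <- fit@origins
    trace <- c(trace, fit@objectiveTrace[length(fit@objectiveTrace)])
    conv <- conv && fit@converged
    iters <- max(iters, fit@iterations)
  }
  haps <- HaplotypeSet(allAlleles)
  new("HaplotypeAssembly",
    haplotypes = haps, origins = origins, objectiveTrace = trace,
    iterations = iters, converged = conv,
    mec = as.integer(mecScore(frags, haps))
  )
}
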