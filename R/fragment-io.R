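# Fragment and haplotype file I/O.
#
# Fragment dialect (the de-facto community format consumed by HapCUT-family
# tools, extended with allele characters '2' and '3' for polyallelic data):
# one read per line,
#   block_count read_id (start_1based alleles)*block_count quality
# with whitespace separation. Quality strings are parsed (their length is
# validated against the allele count) but ignored: the assembly model has a
# single global error rate, not per-base qualities.

#' Read a SNP fragment file
#'
#' Parses the whitespace-separated fragment dialect described above into a
#' [FragmentSet-class]. Starts are 1-based in the file and kept 1-based
#' internally; allele characters must be in `'0'..'3'`.
#'
#' @param path file to read
#' @param nSites optional explicit number of SNP sites m; by default m is
#'   inferred as the largest covered site, so trailing sites covered by no
#'   read must be declared explicitly
#' @return a [FragmentSet-class]
#' @examples
#' f <- tempfile()
#' writeLines("2 r1 3 01 7 2 ###", f)
#' readFragmentFile(f)  # r1 covers sites 3,4,7 with alleles 0,1,2
#' @export
readFragmentFile <- function(path, nSites = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no reads in fragment file '", path, "'")
  read <- site <- allele <- vector("list", length(lines))
  ids <- character(length(lines))
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "[ \t]+")[[1]]
    bad <- function(why) stop(sprintf("line %d of '%s': %s", ln, path, why))
    if (length(tok) < 4L) bad("expected at least 4 fields")
    nb <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(nb) || nb < 1L) bad("block count must be a positive integer")
    if (length(tok) != 2L * nb + 3L)
      bad(sprintf("expected %d fields for %d block(s), found %d",
                  2L * nb + 3L, nb, length(tok)))
    ids[ln] <- tok[2L]
    starts <- suppressWarnings(as.integer(tok[seq(3L, by = 2L, length.out = nb)]))
    alls <- tok[seq(4L, by = 2L, length.out = nb)]
    qual <- tok[length(tok)]
    if (any(is.na(starts)) || any(starts < 1L)) bad("block starts must be positive integers")
    if (is.unsorted(starts, strictly = TRUE)) bad("block starts must be strictly increasing")
    chars <- strsplit(alls, "")
    if (any(!unlist(chars) %in% c("0", "1", "2", "3")))
      bad("allele characters must be in '0'..'3'")
    sites <- unlist(mapply(function(s, a) s + seq_along(a) - 1L, starts, chars,
                           SIMPLIFY = FALSE))
    if (length(sites) != nchar(qual))
      bad("quality string length must equal the number of allele calls")
    if (anyDuplicated(sites) || is.unsorted(sites, strictly = TRUE))
      bad("blocks must not overlap")
    read[[ln]] <- rep.int(ln, length(sites))
    site[[ln]] <- sites
    allele[[ln]] <- as.integer(unlist(chars))
  }
  site <- unlist(site)
  m <- if (is.null(nSites)) max(site) else as.integer(nSites)
  if (m < max(site)) stop("nSites is smaller than the largest covered site")
  FragmentSet(unlist(read), site, unlist(allele),
              nSites = m, nReads = length(lines), readIDs = ids)
}

#' Write a SNP fragment file
#'
#' Emits the fragment dialect read by [readFragmentFile()]. Runs of
#' consecutively covered sites become blocks; quality strings are written as
#' `'#'` repeats since no quality model is attached.
#'
#' @param frags a [FragmentSet-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeFragmentFile <- function(frags, path) {
  stopifnot(is(frags, "FragmentSet"))
  per <- split(data.frame(site = frags@site, allele = frags@allele), frags@read)
  ridx <- as.integer(names(per))
  lines <- vapply(seq_along(per), function(i) {
    d <- per[[i]]
    blk <- cumsum(c(1L, diff(d$site) != 1L))
    starts <- tapply(d$site, blk, `[`, 1L)
    alls <- tapply(as.character(d$allele), blk, paste, collapse = "")
    paste(length(starts), frags@readIDs[ridx[i]],
          paste(rbind(starts, alls), collapse = " "),
          strrep("#", nrow(d)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense fragment matrix
#'
#' Parses a whitespace-separated table with one row per read and one column
#' per SNP site; entries are allele characters `'0'..'3'` or `'-'` for an
#' uncovered site.
#'
#' @param path file to read
#' @return a [FragmentSet-class] with m equal to the column count
#' @export
readDenseMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no reads in dense fragment file '", path, "'")
  rows <- strsplit(trimws(lines), "[ \t]+")
  m <- length(rows[[1L]])
  read <- site <- allele <- vector("list", length(rows))
  for (ln in seq_along(rows)) {
    r <- rows[[ln]]
    if (length(r) != m)
      stop(sprintf("line %d of '%s': expected %d columns, found %d",
                   ln, path, m, length(r)))
    if (any(!r %in% c("0", "1", "2", "3", "-")))
      stop(sprintf("line %d of '%s': entries must be '0'..'3' or '-'", ln, path))
    cov <- which(r != "-")
    if (length(cov) == 0L)
      stop(sprintf("line %d of '%s': empty read (no covered site)", ln, path))
    read[[ln]] <- rep.int(ln, length(cov))
    site[[ln]] <- cov
    allele[[ln]] <- as.integer(r[cov])
  }
  FragmentSet(unlist(read), unlist(site), unlist(allele),
              nSites = m, nReads = length(rows))
}

#' Write haplotypes to a text file
#'
#' Header line `#k m`, then k lines of m characters over `'0'..'3'` with `'-'`
#' for uncalled sites.
#'
#' @param haps a [HaplotypeSet-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeHaplotypes <- function(haps, path) {
  stopifnot(is(haps, "HaplotypeSet"))
  a <- haps@alleles
  body <- apply(a, 1L, function(r) paste(ifelse(is.na(r), "-", r), collapse = ""))
  writeLines(c(sprintf("#%d %d", nrow(a), ncol(a)), body), path)
  invisible(path)
}

#' Read haplotypes written by [writeHaplotypes()]
#'
#' @param path file to read
#' @return a [HaplotypeSet-class]
#' @export
readHaplotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#"))
    stop("malformed haplotype file '", path, "': missing '#k m' header")
  hdr <- as.integer(strsplit(sub("^#", "", lines[1L]), "[ \t]+")[[1L]])
  k <- hdr[1L]; m <- hdr[2L]
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != k) stop("expected ", k, " haplotype lines")
  a <- matrix(NA_integer_, k, m)
  for (p in seq_len(k)) {
    ch <- strsplit(body[p], "")[[1L]]
    if (length(ch) != m) stop("haplotype line ", p, " has wrong length")
    if (any(!ch %in% c("0", "1", "2", "3", "-")))
      stop("haplotype characters must be '0'..'3' or '-'")
    a[p, ch != "-"] <- as.integer(ch[ch != "-"])
  }
  HaplotypeSet(a)
}
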