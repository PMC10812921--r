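#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that returns records
#' in file order with upper-cased sequences.  For FASTQ input the per-base
#' qualities (Sanger encoding) are kept in the element metadata column
#' `qualities`.
#'
#' @param path file path.
#' @param format "fasta", "fastq", or "auto" to infer from the extension.
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ATGCAAAT", ">r2", "acgtacgt"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      fa = , fasta = , fna = "fasta",
      fq = , fastq = "fastq",
      stop("cannot infer sequence format from extension '", ext,
           "'; pass format explicitly"))
  }
  res <- tryCatch({
    if (format == "fastq") {
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    } else {
      x <- Biostrings::readDNAStringSet(path, format = "fasta")
    }
    x
  }, error = function(e) {
    stop("malformed ", format, " file '", path, "': ", conditionMessage(e))
  })
  if (format == "fastq") {
    # a truncated quality line leaves corrupt bytes behind the claimed width
    qw <- tryCatch(nchar(as.character(S4Vectors::mcols(res)$qualities)),
                   error = function(e) NULL)
    if (is.null(qw) || any(qw != Biostrings::width(res)))
      stop("malformed fastq file '", path,
           "': quality length differs from sequence length")
  }
  res
}

#' Trim raw SELEX reads to fixed-length inserts
#'
#' Locates the terminal `anchorLength` bases of the 5' flank and the leading
#' `anchorLength` bases of the 3' flank in each read (up to
#' `maxAnchorMismatches` mismatches per anchor) and extracts the enclosed
#' insert.  The leftmost 5' anchor hit is used; among 3' hits the one
#' consistent with `requiredInsertLength` is preferred (a random insert can
#' contain an anchor-like subsequence), falling back to the leftmost.  A read
#' is accepted only if both anchors are found, the insert has exactly
#' `requiredInsertLength` bases, and it contains no ambiguity codes;
#' everything else is counted as rejected, so `accepted + rejected` always
#' equals the number of input reads.
#'
#' @param reads `DNAStringSet` or character vector of raw reads.
#' @param policy a [TrimPolicy-class] (default [TrimPolicy()]).
#' @param condition,factorName,bob1,band metadata for the returned
#'   [SelexReadSet-class].
#' @return list with elements `readset` (accepted inserts as a
#'   [SelexReadSet-class]) and `rejected` (integer count).
#' @examples
#' pol <- TrimPolicy()
#' raw <- paste0(pol@flank5, strrep("A", 35), pol@flank3)
#' trimReads(raw, pol)$readset
#' @export
trimReads <- function(reads, policy = TrimPolicy(), condition = "sample",
                      factorName = "POU1", bob1 = FALSE, band = "monomer") {
  methods::validObject(policy)
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(as.character(reads)))
  n <- length(reads)
  aL <- policy@anchorLength
  anchor5 <- substr(policy@flank5, nchar(policy@flank5) - aL + 1L,
                    nchar(policy@flank5))
  anchor3 <- substr(policy@flank3, 1L, aL)
  inserts <- character(0)
  if (n > 0L) {
    m5 <- Biostrings::vmatchPattern(anchor5, reads,
                                    max.mismatch = policy@maxAnchorMismatches)
    m3 <- Biostrings::vmatchPattern(anchor3, reads,
                                    max.mismatch = policy@maxAnchorMismatches)
    e5 <- Biostrings::endIndex(m5)   # list of ends per read, NULL if none
    s3 <- Biostrings::startIndex(m3)
    seqs <- as.character(reads)
    inserts <- vapply(seq_len(n), function(i) {
      ends5 <- e5[[i]]
      if (is.null(ends5) || !length(ends5)) return(NA_character_)
      insStart <- min(ends5) + 1L
      starts3 <- s3[[i]]
      starts3 <- starts3[starts3 >= insStart]
      if (!length(starts3)) return(NA_character_)
      # a random insert can contain an anchor-like subsequence; prefer the 3'
      # hit consistent with the designed geometry when one exists
      expected <- insStart + policy@requiredInsertLength
      hit3 <- if (expected %in% starts3) expected else min(starts3)
      insEnd <- hit3 - 1L
      if (insEnd < insStart) return("")
      substr(seqs[i], insStart, insEnd)
    }, character(1))
  }
  ok <- !is.na(inserts) &
    nchar(inserts) == policy@requiredInsertLength &
    !grepl("[^ACGT]", inserts)
  accepted <- inserts[ok]
  readset <- SelexReadSet(accepted, condition = condition,
                          factorName = factorName, bob1 = bob1, band = band,
                          insertLength = policy@requiredInsertLength)
  list(readset = readset, rejected = as.integer(n - sum(ok)))
}

#' Write / read a tab-separated table
#'
#' Deterministic TSV serialisation used for all tabular outputs: header row,
#' no quoting, no row names.  `readTSV()` round-trips what `writeTSV()`
#' wrote.  S4 results ([FrequencyTable-class], [PositionalComposition-class])
#' are coerced through their `as.data.frame` methods first.
#'
#' @param x data.frame (or coercible object) to write.
#' @param path file path.
#' @return `writeTSV` returns `path` invisibly; `readTSV` returns a
#'   data.frame.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeTSV(data.frame(word = "ATGCAAAT", count = 3L), p)
#' readTSV(p)
#' @export
writeTSV <- function(x, path) {
  x <- as.data.frame(x)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write table: directory does not exist: ", dir)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
  if (!file.exists(path)) stop("table file does not exist: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
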