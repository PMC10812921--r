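#' Accessors for bandSELEX classes
#'
#' Small accessor generics so that slots never need to be touched directly:
#' `inserts()` returns the DNAStringSet of a read set, `condition()` its
#' label, `band()` the excised band class, `patternWord()` the IUPAC word of
#' a pattern or frequency table, `wordCounts()`/`relFreq()` the census
#' counts/percentages, `matchedReads()`/`totalReads()` the bookkeeping
#' counts, `composition()` the positional base-percentage matrix and
#' `psamAffinities()` the affinity matrix of a Psam.
#'
#' @param x object to access.
#' @return The slot value (see details per generic).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("inserts", function(x) standardGeneric("inserts"))
#' @rdname accessors
#' @export
setMethod("inserts", "SelexReadSet", function(x) x@inserts)

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setMethod("condition", "SelexReadSet", function(x) x@condition)

#' @rdname accessors
#' @export
setGeneric("band", function(x) standardGeneric("band"))
#' @rdname accessors
#' @export
setMethod("band", "SelexReadSet", function(x) x@band)

#' @rdname accessors
#' @export
setGeneric("patternWord", function(x) standardGeneric("patternWord"))
#' @rdname accessors
#' @export
setMethod("patternWord", "DegeneratePattern", function(x) x@word)
#' @rdname accessors
#' @export
setMethod("patternWord", "FrequencyTable", function(x) x@pattern@word)

#' @rdname accessors
#' @export
setGeneric("wordCounts", function(x) standardGeneric("wordCounts"))
#' @rdname accessors
#' @export
setMethod("wordCounts", "FrequencyTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("relFreq", function(x) standardGeneric("relFreq"))
#' @rdname accessors
#' @export
setMethod("relFreq", "FrequencyTable", function(x) x@relFreq)

#' @rdname accessors
#' @export
setGeneric("matchedReads", function(x) standardGeneric("matchedReads"))
#' @rdname accessors
#' @export
setMethod("matchedReads", "FrequencyTable", function(x) x@matchedReads)

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setMethod("totalReads", "FrequencyTable", function(x) x@totalReads)

#' @rdname accessors
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))
#' @rdname accessors
#' @export
setMethod("composition", "PositionalComposition", function(x) x@composition)

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setMethod("nSites", "PositionalComposition", function(x) x@nSites)

#' @rdname accessors
#' @export
setGeneric("psamAffinities", function(x) standardGeneric("psamAffinities"))
#' @rdname accessors
#' @export
setMethod("psamAffinities", "Psam", function(x) x@affinities)

#' Number of concrete words matching a degenerate pattern
#'
#' @param pattern a [DegeneratePattern-class].
#' @return integer product of per-position degeneracies.
#' @examples
#' patternCardinality(DegeneratePattern("ANNNNAAN"))  # 1024
#' @export
patternCardinality <- function(pattern) {
  letters <- strsplit(pattern@word, "")[[1]]
  prod(vapply(letters,
              function(l) nchar(Biostrings::IUPAC_CODE_MAP[[l]]), numeric(1)))
}

#' Coerce census results to data frames
#'
#' `FrequencyTable` becomes (word, count, rel_freq_percent), ordered by
#' descending count with lexicographic tie-break; `PositionalComposition`
#' becomes (position, A, C, G, T).
#'
#' @param x object to coerce.
#' @param row.names,optional ignored (S3 compatibility).
#' @param ... ignored.
#' @return A data.frame.
#' @export
as.data.frame.FrequencyTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  o <- order(-x@counts, names(x@counts))
  data.frame(word = names(x@counts)[o],
             count = unname(x@counts[o]),
             rel_freq_percent = unname(x@relFreq[o]),
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.FrequencyTable
#' @export
as.data.frame.PositionalComposition <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  if (x@nSites == 0L)
    return(data.frame(position = integer(0), A = numeric(0), C = numeric(0),
                      G = numeric(0), T = numeric(0)))
  data.frame(position = seq_len(nrow(x@composition)), x@composition,
             stringsAsFactors = FALSE)
}
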