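#' Reverse complement of a DNA string
#'
#' @param x character scalar over the DNA alphabet (ambiguity codes allowed).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence (i.i.d. uniform over A/C/G/T)
#' @param n length in bp.
#' @return character scalar of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Introduce random substitutions into a DNA string
#'
#' Each position mutates independently with probability `rate`; a mutated
#' base is replaced by one of the three other bases, uniformly.
#'
#' @param x DNA string.
#' @param rate per-base substitution probability in \[0, 1).
#' @return mutated string of the same length.
#' @keywords internal
mutate_dna <- function(x, rate) {
  n <- nchar(x)
  if (rate <= 0 || n == 0L) return(x)
  mutate_dna_count(x, stats::rbinom(1L, n, rate))
}

# Substitute exactly k distinct positions; bounds the realized divergence,
# which matters where a divergence ceiling is part of the construction.
mutate_dna_count <- function(x, k) {
  n <- nchar(x)
  if (k == 0L) return(x)
  pos <- sample.int(n, k)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- bases[bases != chars[p]]
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

# Union-find with path compression; used for ambiguity components.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}

# Merge a set of 0-based half-open intervals into their union.
# Returns a data.frame(start, end) sorted, non-overlapping.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Total number of bases covered by the union of 0-based half-open intervals.
covered_bases <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
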