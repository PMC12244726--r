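# Synthetic fixture for the comparison module: reference scaffolds with an
# assembly constructed as full-length matches, split arm pairs (cut at a
# central repeat), or shredded multi-contig matches, emitted directly as the
# hit tables a whole-genome aligner would produce, plus self-alignment hit
# tables with a planted repeat-dense region.

#' Simulate a reference-versus-assembly comparison fixture
#'
#' For each reference scaffold a relationship class is drawn (or given):
#' `one_to_one` references are tiled by one query contig over ~96% of their
#' length; `arm_pair` references by two queries covering the two terminal
#' arms with an uncovered central satellite gap; `complex` references by
#' five interleaved queries. Hit tables carry realistic hit-level
#' fragmentation (50-200 kb hits separated by 1-5 kb gaps). Self-alignment
#' tables are produced for one contig with a dense off-diagonal repeat
#' region (a planted candidate centromere) and one repeat-free contig with
#' no off-diagonal hits.
#'
#' @param seed integer seed.
#' @param n_refs number of reference scaffolds.
#' @param ref_length reference scaffold length (bp).
#' @param classes optional character vector of planted classes, recycled.
#' @param dense_span planted repeat-dense span as a fraction pair of the
#'   self-alignment contig.
#' @return list with `reference_lengths`, `hits`, `truth` (data.frame:
#'   `reference_id`, `class`), `self_hits`, `self_contig_lengths`,
#'   `centromere_truth`.
#' @export
simulate_comparison_fixture <- function(seed = 1L, n_refs = 6L,
                                        ref_length = 2e6,
                                        classes = c("one_to_one", "arm_pair",
                                                    "complex"),
                                        dense_span = c(0.40, 0.55)) {
  set.seed(seed)
  classes <- rep_len(classes, n_refs)
  ref_ids <- sprintf("ref%02d", seq_len(n_refs))
  hits <- list()
  emit <- function(ref, query, span_start, span_end) {
    # Tile [span_start, span_end) with 50-200 kb hits and 1-5 kb gaps.
    pos <- span_start
    while (pos < span_end - 1000) {
      len <- min(round(stats::runif(1, 5e4, 2e5)), span_end - pos)
      hits[[length(hits) + 1L]] <<- data.frame(
        query_id = query, target_id = ref,
        query_start = pos - span_start, query_end = pos - span_start + len,
        target_start = pos, target_end = pos + len,
        strand = "+", percent_identity = round(stats::runif(1, 98, 100), 2),
        alignment_length = len, score = len, source_tag = "other",
        stringsAsFactors = FALSE)
      pos <- pos + len + round(stats::runif(1, 1e3, 5e3))
    }
  }
  for (i in seq_len(n_refs)) {
    ref <- ref_ids[i]
    if (classes[i] == "one_to_one") {
      emit(ref, paste0(ref, "_q1"), 0, ref_length)
    } else if (classes[i] == "arm_pair") {
      cut1 <- round(ref_length * stats::runif(1, 0.40, 0.47))
      cut2 <- round(ref_length * stats::runif(1, 0.53, 0.60))
      emit(ref, paste0(ref, "_armL"), 0, cut1)
      emit(ref, paste0(ref, "_armR"), cut2, ref_length)
    } else {
      # Five interleaved pieces, none terminal-dominant.
      cuts <- round(ref_length * seq(0, 1, length.out = 6L))
      for (k in 1:5) {
        emit(ref, sprintf("%s_piece%d", ref, k), cuts[k], cuts[k + 1L])
      }
    }
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL
  reference_lengths <- stats::setNames(rep(ref_length, n_refs), ref_ids)

  # Self-alignment fixture: one contig with 50 interspersed mutual repeats
  # inside the dense span, one clean contig with no off-diagonal hits.
  L <- ref_length
  dense <- round(L * dense_span)
  self_hits <- list()
  for (k in 1:50) {
    a_len <- round(stats::runif(1, 2e3, 1e4))
    b_len <- round(stats::runif(1, 2e3, 1e4))
    a <- round(stats::runif(1, dense[1], dense[2] - a_len))
    b <- round(stats::runif(1, dense[1], dense[2] - b_len))
    self_hits[[k]] <- data.frame(
      query_id = "selfA", target_id = "selfA",
      query_start = a, query_end = a + a_len,
      target_start = b, target_end = b + b_len,
      strand = sample(c("+", "-"), 1L),
      percent_identity = round(stats::runif(1, 85, 99), 2),
      alignment_length = b_len, score = b_len, source_tag = "self",
      stringsAsFactors = FALSE)
  }
  self_hits <- do.call(rbind, self_hits)
  # The trivial full-length diagonal every self-alignment reports.
  diagonal <- data.frame(
    query_id = c("selfA", "selfB"), target_id = c("selfA", "selfB"),
    query_start = 0, query_end = L, target_start = 0, target_end = L,
    strand = "+", percent_identity = 100, alignment_length = L, score = L,
    source_tag = "self", stringsAsFactors = FALSE)
  self_hits <- rbind(self_hits, diagonal)
  list(reference_lengths = reference_lengths, hits = hits,
       truth = data.frame(reference_id = ref_ids, class = classes,
                          stringsAsFactors = FALSE),
       self_hits = self_hits,
       self_contig_lengths = c(selfA = L, selfB = L),
       centromere_truth = data.frame(contig_id = "selfA",
                                     start = dense[1], end = dense[2]))
}
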