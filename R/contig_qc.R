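# Assembly curation screens: k-mer Shannon entropy for low-complexity
# contigs, per-contig read depth with organelle-homology confirmation for
# organelle-derived contigs, and telomere motif scanning.

#' Normalized k-mer Shannon entropy of a sequence
#'
#' `H = -sum p_i log2 p_i` over the observed k-mer frequencies, normalized by
#' `log2(min(4^k, number of k-mer positions))` so the result lies in
#' `[0, 1]`: 0 for a single repeated k-mer, ~1 for uniform random sequence.
#' k-mers containing `N` are excluded from counting.
#'
#' @param sequence DNA string.
#' @param k k-mer size (`1 <= k <= nchar(sequence)`).
#' @return normalized entropy in `[0, 1]`.
#' @export
shannon_entropy <- function(sequence, k = 21L) {
  n <- nchar(sequence)
  if (k < 1L) stop("k must be >= 1")
  if (n < k) stop("sequence shorter than k")
  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) <= 1L) return(0)
  p <- tabulate(factor(kmers)) / length(kmers)
  H <- -sum(p * log2(p))
  denom <- log2(min(4^k, length(kmers)))
  min(1, max(0, H / denom))
}

#' Flag low-complexity contigs by normalized k-mer entropy
#'
#' A contig is flagged `low_complexity` when its normalized `k`-mer entropy
#' falls below `threshold`; contigs made only of short tandem repeats score
#' far below random sequence at the default `k = 21`.
#'
#' @param contigs named character vector of contig sequences.
#' @param k k-mer size.
#' @param threshold entropy cutoff in `[0, 1]`.
#' @return data.frame with `contig_id`, `flag` (`low_complexity`/`pass`),
#'   `entropy`, `k`, `threshold`.
#' @export
flag_low_complexity_contigs <- function(contigs, k = 21L, threshold = 0.5) {
  stopifnot(length(contigs) > 0, !is.null(names(contigs)))
  ent <- vapply(contigs, shannon_entropy, numeric(1), k = k)
  data.frame(contig_id = names(contigs),
             flag = ifelse(ent < threshold, "low_complexity", "pass"),
             entropy = unname(ent), k = k, threshold = threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean read depth per contig
#'
#' Depth is total aligned bases divided by contig length. Multi-mapping reads
#' contribute only their best-scoring alignment (ties: first after a stable
#' sort). Contigs without alignments are reported at depth 0.
#'
#' @param read_alignments read-to-contig hit table ([read_alignments()] /
#'   [reads_to_alignments()]).
#' @param contig_lengths named numeric vector of contig lengths.
#' @return data.frame with `contig_id`, `length`, `aligned_bases`,
#'   `mean_depth`.
#' @export
per_contig_depth <- function(read_alignments, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  h <- read_alignments
  unknown <- setdiff(unique(h$target_id), names(contig_lengths))
  if (length(unknown)) {
    stop("alignment references unknown contig ", unknown[[1L]])
  }
  if (nrow(h)) {
    score <- ifelse(is.na(h$score), h$alignment_length, h$score)
    o <- order(h$query_id, -score)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
    bases <- tapply(h$target_end - h$target_start, h$target_id, sum)
  } else {
    bases <- numeric(0)
  }
  ab <- rep(0, length(contig_lengths))
  names(ab) <- names(contig_lengths)
  ab[names(bases)] <- bases
  data.frame(contig_id = names(contig_lengths),
             length = unname(contig_lengths),
             aligned_bases = unname(ab),
             mean_depth = unname(ab / contig_lengths),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag organelle-derived contigs by depth and organelle homology
#'
#' A contig is flagged `organelle_depth` only when both conditions hold:
#' its mean depth exceeds `fold` times the median depth over all contigs,
#' and at least `min_organelle_fraction` of its length is covered by hits
#' from the organelle genomes. The homology requirement mirrors the manual
#' confirmation step that a depth-only screen needs, since high depth alone
#' can also reflect collapsed nuclear repeats.
#'
#' @param depths result of [per_contig_depth()].
#' @param organelle_hits organelle-to-assembly hit table (targets are
#'   contigs).
#' @param fold depth multiple of the median required.
#' @param min_organelle_fraction minimum covered fraction.
#' @return data.frame with `contig_id`, `flag` (`organelle_depth`/`pass`),
#'   `mean_depth`, `fold_over_median`, `organelle_fraction`.
#' @export
flag_depth_outliers <- function(depths, organelle_hits, fold = 5,
                                min_organelle_fraction = 0.5) {
  if (nrow(depths) < 3L) stop("need >= 3 contigs for a median depth")
  med <- stats::median(depths$mean_depth)
  frac <- vapply(seq_len(nrow(depths)), function(i) {
    h <- organelle_hits[organelle_hits$target_id == depths$contig_id[i], ,
                        drop = FALSE]
    if (nrow(h) == 0L) return(0)
    covered_bases(h$target_start, h$target_end) / depths$length[i]
  }, numeric(1))
  deep <- depths$mean_depth > fold * med
  data.frame(contig_id = depths$contig_id,
             flag = ifelse(deep & frac >= min_organelle_fraction,
                           "organelle_depth", "pass"),
             mean_depth = depths$mean_depth,
             fold_over_median = depths$mean_depth / med,
             organelle_fraction = frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

count_motif <- function(s, motif) {
  m <- gregexpr(motif, s, fixed = TRUE)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) 0L else length(m)
}

#' Scan a contig for telomere motif repeats
#'
#' Counts non-overlapping exact motif matches per non-overlapping window;
#' the forward motif and its reverse complement are both counted, and each
#' terminal count is the larger of the two (plant telomeres read `TTTAGGG`
#' on the 5' strand and `CCCTAAA` at the 3' end).
#'
#' @param contig contig sequence (character scalar).
#' @param contig_id contig name for the report.
#' @param motif telomere motif, default the plant heptamer `TTTAGGG`.
#' @param window terminal/window size in bp; clipped to the contig length.
#' @return list of class `telomere_scan`: `contig_id`, `motif`, `window`,
#'   `left_count`, `right_count`, `per_window_counts` (data.frame).
#' @export
telomere_scan <- function(contig, contig_id = "contig", motif = "TTTAGGG",
                          window = 10000L) {
  stopifnot(nchar(motif) >= 3L)
  n <- nchar(contig)
  rc <- revcomp(motif)
  if (n < nchar(motif)) {
    warning("contig ", contig_id, " shorter than motif; counts are 0")
    pw <- data.frame(window_start = 0L, window_end = n,
                     forward = 0L, reverse = 0L)
    return(structure(list(contig_id = contig_id, motif = motif,
                          window = min(window, n), left_count = 0L,
                          right_count = 0L, per_window_counts = pw),
                     class = "telomere_scan"))
  }
  window <- min(window, n)
  starts <- seq.int(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  fwd <- integer(length(starts)); rev <- integer(length(starts))
  for (i in seq_along(starts)) {
    w <- substr(contig, starts[i] + 1L, ends[i])
    fwd[i] <- count_motif(w, motif)
    rev[i] <- count_motif(w, rc)
  }
  # The last window is re-anchored to the contig end so a terminal tract is
  # never split across window boundaries.
  last <- substr(contig, n - window + 1L, n)
  right_f <- count_motif(last, motif); right_r <- count_motif(last, rc)
  structure(list(
    contig_id = contig_id, motif = motif, window = window,
    left_count = max(fwd[1L], rev[1L]),
    right_count = max(right_f, right_r),
    per_window_counts = data.frame(window_start = starts, window_end = ends,
                                   forward = fwd, reverse = rev)),
    class = "telomere_scan")
}

#' Classify telomere-to-telomere completeness of a contig
#'
#' A terminus is telomere-positive when its terminal-window motif count
#' reaches `min_copies`.
#'
#' @param scan a [telomere_scan()] result.
#' @param min_copies motif copies required to call a telomere.
#' @return one of `both_telomeres`, `left_only`, `right_only`, `none`.
#' @export
classify_contig_completeness <- function(scan, min_copies = 25L) {
  left <- scan$left_count >= min_copies
  right <- scan$right_count >= min_copies
  if (left && right) "both_telomeres"
  else if (left) "left_only"
  else if (right) "right_only"
  else "none"
}

#' Run all contig QC screens
#'
#' Convenience wrapper: entropy screen, depth screen (when read alignments
#' are given) and telomere classification for every contig.
#'
#' @param contigs named character vector of contig sequences.
#' @param read_alignments optional read-to-contig hit table.
#' @param organelle_hits optional organelle-to-contig hit table (required
#'   with `read_alignments` for the organelle-depth screen).
#' @param k,entropy_threshold entropy screen parameters.
#' @param fold,min_organelle_fraction depth screen parameters.
#' @param motif,window,min_copies telomere screen parameters.
#' @return list with `flags` (one row per contig per screen), `depth`,
#'   `telomeres` data.frames.
#' @export
run_contig_qc <- function(contigs, read_alignments = NULL,
                          organelle_hits = NULL, k = 21L,
                          entropy_threshold = 0.5, fold = 5,
                          min_organelle_fraction = 0.5, motif = "TTTAGGG",
                          window = 10000L, min_copies = 25L) {
  lc <- flag_low_complexity_contigs(contigs, k = k,
                                    threshold = entropy_threshold)
  depth <- NULL
  od <- NULL
  if (!is.null(read_alignments)) {
    stopifnot(!is.null(organelle_hits))
    depth <- per_contig_depth(read_alignments, nchar(contigs))
    od <- flag_depth_outliers(depth, organelle_hits, fold = fold,
                              min_organelle_fraction = min_organelle_fraction)
  }
  tel <- do.call(rbind, lapply(names(contigs), function(id) {
    sc <- telomere_scan(contigs[[id]], id, motif = motif, window = window)
    data.frame(contig_id = id, left_count = sc$left_count,
               right_count = sc$right_count,
               completeness = classify_contig_completeness(sc, min_copies),
               stringsAsFactors = FALSE)
  }))
  flags <- rbind(
    data.frame(contig_id = lc$contig_id, screen = "entropy", flag = lc$flag,
               stringsAsFactors = FALSE),
    if (!is.null(od)) data.frame(contig_id = od$contig_id, screen = "depth",
                                 flag = od$flag, stringsAsFactors = FALSE))
  list(flags = flags, entropy = lc, depth = od, telomeres = tel)
}
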