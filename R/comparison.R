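# Contig-to-reference relationship classification from alignment coverage,
# and windowed self-alignment density screening for candidate centromeres
# (the dense off-diagonal "dot plot rectangle" made quantitative).

#' Per-reference alignment coverage profile
#'
#' For every (reference, query) pair, hits whose reference footprint is at
#' least `min_hit_length` are unioned into merged intervals; the covered
#' fraction is covered bases over reference length.
#'
#' @param hits normalized hit table, queries are assembly contigs and
#'   targets the reference scaffolds.
#' @param reference_lengths named numeric vector.
#' @param min_hit_length minimum reference span of a contributing hit (bp).
#' @return list with `summary` (data.frame: `reference_id`, `query_id`,
#'   `covered_bases`, `fraction`) and `intervals` (merged covered intervals
#'   per pair).
#' @export
coverage_profile <- function(hits, reference_lengths, min_hit_length = 1000L) {
  stopifnot(!is.null(names(reference_lengths)))
  unknown <- setdiff(unique(hits$target_id), names(reference_lengths))
  if (length(unknown)) stop("unknown reference id ", unknown[[1L]])
  hits <- hits[hits$target_end - hits$target_start >= min_hit_length, ,
               drop = FALSE]
  key <- paste(hits$target_id, hits$query_id, sep = "\r")
  summaries <- list(); intervals <- list()
  for (kk in unique(key)) {
    h <- hits[key == kk, , drop = FALSE]
    m <- merge_intervals(h$target_start, h$target_end)
    ref <- h$target_id[[1L]]
    intervals[[length(intervals) + 1L]] <- data.frame(
      reference_id = ref, query_id = h$query_id[[1L]],
      start = m$start, end = m$end, stringsAsFactors = FALSE)
    summaries[[length(summaries) + 1L]] <- data.frame(
      reference_id = ref, query_id = h$query_id[[1L]],
      covered_bases = sum(m$end - m$start),
      fraction = sum(m$end - m$start) / reference_lengths[[ref]],
      stringsAsFactors = FALSE)
  }
  summary <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(reference_id = character(0), query_id = character(0),
               covered_bases = numeric(0), fraction = numeric(0))
  ints <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(reference_id = character(0), query_id = character(0),
               start = numeric(0), end = numeric(0))
  o <- order(summary$reference_id, -summary$fraction, summary$query_id)
  list(summary = summary[o, , drop = FALSE], intervals = ints,
       reference_lengths = reference_lengths)
}

#' Classify contig-to-reference relationships
#'
#' Per reference scaffold: `one_to_one` when the best single query alone
#' covers at least `min_total_cov`; `arm_pair` when the two best queries
#' each cover at least `min_arm_cov`, occupy disjoint terminal footprints
#' (one anchored in the first, one in the last tenth of the reference),
#' are separated by an uncovered central gap of at least `min_mid_gap_frac`
#' of the reference, and jointly cover at least `min_total_cov` of the
#' non-gap length — the signature of two chromosome arms split at an
#' unassembled central repeat; `complex` when `min_total_cov` is reached
#' only by three or more queries; otherwise `none`.
#'
#' @param profile result of [coverage_profile()].
#' @param min_total_cov,min_arm_cov,min_mid_gap_frac thresholds (fractions).
#' @return data.frame per reference: `reference_id`, `class`, `queries`
#'   (comma-separated), `best_fraction`, `mid_gap_start`, `mid_gap_end`.
#' @export
classify_relationship <- function(profile, min_total_cov = 0.8,
                                  min_arm_cov = 0.25,
                                  min_mid_gap_frac = 0.05) {
  refs <- names(profile$reference_lengths)
  out <- lapply(refs, function(ref) {
    L <- profile$reference_lengths[[ref]]
    s <- profile$summary[profile$summary$reference_id == ref, , drop = FALSE]
    res <- data.frame(reference_id = ref, class = "none", queries = "",
                      best_fraction = 0, mid_gap_start = NA_real_,
                      mid_gap_end = NA_real_, stringsAsFactors = FALSE)
    if (nrow(s) == 0L) return(res)
    res$best_fraction <- s$fraction[[1L]]
    if (s$fraction[[1L]] >= min_total_cov) {
      res$class <- "one_to_one"
      res$queries <- s$query_id[[1L]]
      return(res)
    }
    if (nrow(s) >= 2L && all(s$fraction[1:2] >= min_arm_cov)) {
      q1 <- s$query_id[[1L]]; q2 <- s$query_id[[2L]]
      fp <- function(q) {
        iv <- profile$intervals
        iv <- iv[iv$reference_id == ref & iv$query_id == q, , drop = FALSE]
        c(min(iv$start), max(iv$end))
      }
      f1 <- fp(q1); f2 <- fp(q2)
      if (f1[1] > f2[1]) { tmp <- f1; f1 <- f2; f2 <- tmp
                           tmp <- q1; q1 <- q2; q2 <- tmp }
      gap <- f2[1] - f1[2]
      terminal <- f1[1] <= 0.1 * L && f2[2] >= 0.9 * L
      joint <- sum(s$covered_bases[1:2]) / (L - max(gap, 0))
      if (gap >= min_mid_gap_frac * L && terminal && joint >= min_total_cov) {
        res$class <- "arm_pair"
        res$queries <- paste(q1, q2, sep = ",")
        res$mid_gap_start <- f1[2]
        res$mid_gap_end <- f2[1]
        return(res)
      }
    }
    # Cumulative union coverage, adding queries by decreasing fraction.
    iv <- profile$intervals
    iv <- iv[iv$reference_id == ref, , drop = FALSE]
    acc <- data.frame(start = numeric(0), end = numeric(0))
    for (i in seq_len(nrow(s))) {
      q <- s$query_id[[i]]
      acc <- rbind(acc, iv[iv$query_id == q, c("start", "end")])
      cov <- covered_bases(acc$start, acc$end) / L
      if (cov >= min_total_cov) {
        res$class <- if (i >= 3L) "complex" else "none"
        res$queries <- paste(s$query_id[seq_len(i)], collapse = ",")
        return(res)
      }
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windowed off-diagonal self-alignment density
#'
#' Splits each contig into non-overlapping windows and computes the fraction
#' of each window covered by off-diagonal self-alignment target intervals
#' (the trivial full-length self-match — identical query and target interval
#' on the same sequence — is excluded). Window densities are standardized
#' per contig; windows with z-score above `zscore_threshold` are flagged and
#' adjacent flagged windows merge into one candidate region. Contigs whose
#' windows all share one density (e.g. all zero) yield no candidates.
#'
#' @param self_hits normalized self-alignment hit table.
#' @param contig_lengths named numeric vector.
#' @param window window size in bp; a window longer than the contig is
#'   clipped to one whole-contig window with a warning.
#' @param zscore_threshold flagging threshold.
#' @return data.frame: `contig_id`, `start`, `end`, `mean_density`,
#'   `max_zscore`.
#' @export
self_alignment_density <- function(self_hits, contig_lengths,
                                   window = 100000L, zscore_threshold = 2) {
  stopifnot(!is.null(names(contig_lengths)))
  diag <- self_hits$query_id == self_hits$target_id &
    self_hits$query_start == self_hits$target_start &
    self_hits$query_end == self_hits$target_end
  h <- self_hits[!diag, , drop = FALSE]
  out <- list()
  for (contig in names(contig_lengths)) {
    L <- contig_lengths[[contig]]
    w <- window
    if (w > L) {
      warning("window exceeds length of ", contig,
              "; using one whole-contig window")
      w <- L
    }
    starts <- seq.int(0L, L - 1L, by = w)
    ends <- pmin(starts + w, L)
    hc <- h[h$target_id == contig, , drop = FALSE]
    cov <- merge_intervals(hc$target_start, hc$target_end)
    dens <- vapply(seq_along(starts), function(i) {
      if (nrow(cov) == 0L) return(0)
      inter <- pmin(cov$end, ends[i]) - pmax(cov$start, starts[i])
      sum(pmax(inter, 0)) / (ends[i] - starts[i])
    }, numeric(1))
    sdv <- stats::sd(dens)
    if (length(dens) < 2L || is.na(sdv) || sdv == 0) next
    z <- (dens - mean(dens)) / sdv
    flag <- z > zscore_threshold
    if (!any(flag)) next
    r <- rle(flag)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      win <- seq.int(idx_start[j], idx_end[j])
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig, start = starts[win[1L]],
        end = ends[win[length(win)]],
        mean_density = mean(dens[win]), max_zscore = max(z[win]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0), mean_density = numeric(0),
                      max_zscore = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
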