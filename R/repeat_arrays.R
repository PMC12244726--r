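# Tandem/satellite run detection and rDNA array profiling: cluster rRNA gene
# hits into arrays, estimate repeat-unit lengths and copy numbers, and call
# the 5S/35S linkage arrangement.

#' Detect exact tandem repeat runs
#'
#' Scans for maximal runs in which position `i` matches position `i + p`
#' (exact matching), for periods `min_period..max_period`, and reports each
#' run with the smallest qualifying period. Overlapping runs with different
#' periods are resolved in favour of more copies, then smaller period. This
#' is an exact-match detector for short periods; divergent satellites are
#' the province of Tandem Repeats Finder via [read_trf_dat()].
#'
#' @param sequence DNA string.
#' @param contig_id name used in the report.
#' @param min_period,max_period period range in bp.
#' @param min_copies minimum copy number of a reported run.
#' @return data.frame: `contig_id`, `start`, `end` (0-based half-open),
#'   `period`, `copy_number`, `consensus` (first unit of the run).
#' @export
detect_tandem_runs <- function(sequence, contig_id = "contig",
                               min_period = 1L, max_period = 500L,
                               min_copies = 5L) {
  n <- nchar(sequence)
  stopifnot(min_period >= 1L, max_period >= min_period, min_copies >= 2L)
  max_period <- min(max_period, n %/% min_copies)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  cand <- list()
  for (p in seq.int(min_period, max_period)) {
    if (p > n - p) break
    eq <- chars[seq_len(n - p)] == chars[seq.int(p + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    need <- p * (min_copies - 1L)
    hit <- which(r$values & r$lengths >= need)
    for (i in hit) {
      run_start <- starts[i]            # 1-based on the match vector
      run_len <- r$lengths[i] + p       # total bases in the tandem region
      cand[[length(cand) + 1L]] <- data.frame(
        contig_id = contig_id,
        start = run_start - 1L, end = run_start - 1L + run_len,
        period = p, copy_number = run_len / p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0), period = numeric(0),
                      copy_number = numeric(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  # Greedy selection: more copies first, then smaller period, then position.
  cand <- cand[order(-cand$copy_number, cand$period, cand$start), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  sel <- data.frame(start = numeric(0), end = numeric(0))
  for (i in seq_len(nrow(cand))) {
    if (nrow(sel) == 0L ||
          all(cand$end[i] <= sel$start | cand$start[i] >= sel$end)) {
      keep[i] <- TRUE
      sel <- rbind(sel, data.frame(start = cand$start[i], end = cand$end[i]))
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$consensus <- substring(sequence, out$start + 1L, out$start + out$period)
  rownames(out) <- NULL
  out
}

#' Cluster rRNA gene hits into candidate arrays
#'
#' Hits on the same contig are joined into one array when consecutive hits
#' (by start) are separated by less than `max_gap`. An array with fewer than
#' two full-unit equivalents (occurrences of its most frequent gene label)
#' is labelled a `cluster` rather than an `array`: scattered rRNA gene
#' copies and fragments are common outside true tandem operon repeats.
#'
#' @param gene_hits data.frame with `contig_id`, `start`, `end`, `gene`
#'   (e.g. `18S`, `5.8S`, `26S`, `5S`) and optionally `strand`, `identity`.
#' @param max_gap maximum start-to-end gap within an array (bp).
#' @return list with `arrays` (data.frame: `array_id`, `contig_id`, `start`,
#'   `end`, `n_hits`, `kind`) and `hits` (input plus `array_id`).
#' @export
cluster_gene_hits_into_arrays <- function(gene_hits, max_gap = 20000L) {
  if (is.null(gene_hits) || nrow(gene_hits) == 0L) {
    arrays <- data.frame(array_id = character(0), contig_id = character(0),
                         start = numeric(0), end = numeric(0),
                         n_hits = integer(0), kind = character(0),
                         stringsAsFactors = FALSE)
    return(list(arrays = arrays, hits = gene_hits))
  }
  gene_hits <- gene_hits[order(gene_hits$contig_id, gene_hits$start), ,
                         drop = FALSE]
  new_contig <- c(TRUE, gene_hits$contig_id[-1L] !=
                    gene_hits$contig_id[-nrow(gene_hits)])
  gap <- c(Inf, gene_hits$start[-1L] - gene_hits$end[-nrow(gene_hits)])
  aid <- cumsum(new_contig | gap >= max_gap)
  gene_hits$array_id <- sprintf("array%03d", aid)
  arrays <- do.call(rbind, lapply(split(gene_hits, gene_hits$array_id),
                                  function(h) {
    units <- max(table(h$gene))
    data.frame(array_id = h$array_id[[1L]], contig_id = h$contig_id[[1L]],
               start = min(h$start), end = max(h$end), n_hits = nrow(h),
               kind = if (units >= 2L) "array" else "cluster",
               stringsAsFactors = FALSE)
  }))
  rownames(arrays) <- NULL
  list(arrays = arrays, hits = gene_hits)
}

#' Estimate repeat-unit length of an rDNA array
#'
#' Unit-length samples are the successive start-to-start distances of the
#' array's most frequent gene label (each full unit carries each gene once).
#' Modes are the local maxima of a 100 bp-binned histogram that reach at
#' least 20% of the global maximum; each mode is reported as the median of
#' the samples in its bin, which keeps the estimate on the data rather than
#' on bin centres.
#'
#' @param array_hits hit rows of one array.
#' @param bin_width histogram bin width in bp.
#' @param prominence minimum fraction of the tallest bin for a local
#'   maximum to count as a mode.
#' @return list with `gene` (the delimiting label), `samples` (numeric),
#'   `modes` (numeric, possibly length 0 when < 2 same-gene hits).
#' @export
estimate_unit_length <- function(array_hits, bin_width = 100L,
                                 prominence = 0.2) {
  tab <- table(array_hits$gene)
  gene <- names(tab)[which.max(tab)]
  starts <- sort(array_hits$start[array_hits$gene == gene])
  if (length(starts) < 2L) {
    return(list(gene = gene, samples = numeric(0), modes = numeric(0)))
  }
  samples <- diff(starts)
  bins <- floor(samples / bin_width)
  rng <- seq.int(min(bins), max(bins))
  counts <- tabulate(factor(bins, levels = rng), nbins = length(rng))
  peak <- max(counts)
  is_mode <- vapply(seq_along(rng), function(i) {
    left <- if (i == 1L) 0L else counts[i - 1L]
    right <- if (i == length(rng)) 0L else counts[i + 1L]
    counts[i] >= left && counts[i] >= right && counts[i] >= prominence * peak &&
      counts[i] > 0L
  }, logical(1))
  # Collapse plateaus of equal adjacent modal bins into one mode.
  mode_bins <- rng[is_mode]
  if (length(mode_bins) > 1L) {
    drop <- c(FALSE, diff(mode_bins) == 1L &
                counts[match(mode_bins[-1L], rng)] ==
                  counts[match(mode_bins[-length(mode_bins)], rng)])
    mode_bins <- mode_bins[!drop]
  }
  modes <- vapply(mode_bins, function(b)
    stats::median(samples[bins == b]), numeric(1))
  list(gene = gene, samples = samples, modes = sort(modes))
}

#' Count repeat units in an rDNA array
#'
#' The headline copy count is the occurrence count of the most frequent gene
#' label; per-gene counts with their min/max are reported alongside, since
#' unit fragments can carry one gene of a unit but not the others.
#'
#' @param array_hits hit rows of one array.
#' @return list with `copy_count`, `per_gene` (named integer vector),
#'   `min_count`, `max_count`.
#' @export
count_units <- function(array_hits) {
  if (is.null(array_hits) || nrow(array_hits) == 0L) {
    stop("cannot count units of an empty array")
  }
  tab <- table(array_hits$gene)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  list(copy_count = max(counts), per_gene = counts,
       min_count = min(counts), max_count = max(counts))
}

#' Classify 5S/35S rDNA arrangement
#'
#' A 35S array is L-type (linked) when at least half of its units have a 5S
#' hit within `linkage_distance` of the unit interval; unit intervals run
#' start-to-start of the delimiting gene, the last unit extending by the
#' median unit length. The genome-level call is `S_type` when no array is
#' linked, `L_type` when all are, otherwise `mixed` (`na` without arrays).
#'
#' @param arrays_35S result of [cluster_gene_hits_into_arrays()] on the 35S
#'   gene hits (18S/5.8S/26S).
#' @param hits_5S data.frame of 5S hits with `contig_id`, `start`, `end`.
#' @param linkage_distance maximum distance in bp for a 5S hit to count as
#'   linked to a unit.
#' @return list with `per_array` (data.frame: `array_id`, `linked_fraction`,
#'   `arrangement`) and `genome_call`.
#' @export
classify_rdna_arrangement <- function(arrays_35S, hits_5S,
                                      linkage_distance = 5000L) {
  arrays <- arrays_35S$arrays
  arrays <- arrays[arrays$kind == "array", , drop = FALSE]
  if (nrow(arrays) == 0L) {
    return(list(per_array = data.frame(array_id = character(0),
                                       linked_fraction = numeric(0),
                                       arrangement = character(0)),
                genome_call = "na"))
  }
  per <- lapply(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    h <- arrays_35S$hits[arrays_35S$hits$array_id == a$array_id, ,
                         drop = FALSE]
    gene <- names(which.max(table(h$gene)))
    starts <- sort(h$start[h$gene == gene])
    unit_len <- if (length(starts) > 1L) stats::median(diff(starts))
                else a$end - a$start
    u_start <- starts
    u_end <- c(starts[-1L], starts[length(starts)] + unit_len)
    s5 <- hits_5S[hits_5S$contig_id == a$contig_id, , drop = FALSE]
    linked <- vapply(seq_along(u_start), function(j) {
      if (nrow(s5) == 0L) return(FALSE)
      d <- pmax(0, pmax(u_start[j] - s5$end, s5$start - u_end[j]))
      any(d <= linkage_distance)
    }, logical(1))
    frac <- mean(linked)
    data.frame(array_id = a$array_id, linked_fraction = frac,
               arrangement = if (frac >= 0.5) "L_type" else "S_type",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  call <- if (all(per$arrangement == "L_type")) "L_type"
          else if (all(per$arrangement == "S_type")) "S_type"
          else "mixed"
  list(per_array = per, genome_call = call)
}

#' Derive rRNA gene hits from a planted rDNA array truth row
#'
#' The synthetic generator records the rDNA array interval together with the
#' gene offsets inside the repeat unit; this helper expands that payload
#' into the per-copy gene-hit table that a homology search over the array
#' would produce (the units are exact copies).
#'
#' @param truth_row one `rdna_array` row of the generator's truth table.
#' @return gene-hit data.frame for [cluster_gene_hits_into_arrays()].
#' @export
rdna_truth_to_hits <- function(truth_row) {
  stopifnot(truth_row$feature_type == "rdna_array")
  kv <- strsplit(strsplit(truth_row$payload, ";", fixed = TRUE)[[1L]], "=",
                 fixed = TRUE)
  vals <- vapply(kv, `[[`, "", 2L)
  names(vals) <- vapply(kv, `[[`, "", 1L)
  unit_len <- as.integer(vals[["unit_length"]])
  copies <- as.integer(vals[["copies"]])
  offs <- vals[grepl("^offset_", names(vals))]
  genes <- sub("^offset_", "", names(offs))
  out <- list()
  for (g in seq_along(genes)) {
    se <- as.integer(strsplit(offs[[g]], "-", fixed = TRUE)[[1L]])
    for (cp in seq_len(copies) - 1L) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = truth_row$contig_id,
        start = truth_row$start + cp * unit_len + se[1L],
        end = truth_row$start + cp * unit_len + se[2L],
        strand = "+", gene = genes[g], identity = 100,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
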