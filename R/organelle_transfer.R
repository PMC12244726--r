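# Organelle-to-nuclear transfer detection: filter organelle-vs-nuclear hits,
# collapse them into source segments, merge nearby segments into regions,
# classify regions as NUMT / NUPT / NUM_PT / NUMPT, and validate insertion
# junctions with spanning long-read alignments.

#' Thresholds of the transfer pipeline
#'
#' Boundary semantics follow the rule wording literally: alignment length
#' strictly greater than `min_hit_length`; identity at least `min_identity`;
#' segments merged when the gap is strictly less than `max_merge_gap`;
#' a junction is validated by a read covering at least `min_junction_span`
#' bp on each side.
#'
#' @param min_hit_length minimum alignment length in bp (exclusive).
#' @param min_identity minimum percent identity (inclusive).
#' @param max_merge_gap maximum gap between merged segments in bp
#'   (exclusive).
#' @param min_junction_span bases a read must cover on each side of an
#'   insertion boundary (inclusive).
#' @param ambiguity_reciprocal_overlap reciprocal overlap
#'   (intersection / shorter length) at or above which a mitochondrial and a
#'   plastid segment are replaced by one ambiguous segment.
#' @return a `transfer_config` list.
#' @export
transfer_config <- function(min_hit_length = 100,
                            min_identity = 85,
                            max_merge_gap = 300,
                            min_junction_span = 50,
                            ambiguity_reciprocal_overlap = 0.5) {
  stopifnot(min_hit_length >= 0, min_identity >= 0, max_merge_gap >= 0,
            min_junction_span >= 0,
            ambiguity_reciprocal_overlap > 0,
            ambiguity_reciprocal_overlap <= 1)
  structure(as.list(environment()), class = "transfer_config")
}

#' Filter organelle-vs-nuclear hits on length and identity
#'
#' Keeps hits with `alignment_length > min_hit_length` and
#' `percent_identity >= min_identity`; input order is preserved.
#'
#' @param hits normalized hit table.
#' @param config a [transfer_config()].
#' @return the surviving rows of `hits`.
#' @export
filter_hits <- function(hits, config = transfer_config()) {
  keep <- hits$alignment_length > config$min_hit_length &
    hits$percent_identity >= config$min_identity
  hits[keep, , drop = FALSE]
}

empty_segments <- function() {
  data.frame(contig_id = character(0), start = numeric(0), end = numeric(0),
             source = character(0), best_identity = numeric(0),
             stringsAsFactors = FALSE)
}

# Collapse hits of one source on one contig into union segments, carrying
# the best identity of the supporting hits.
collapse_source_hits <- function(hits, source) {
  if (nrow(hits) == 0L) return(empty_segments())
  out <- lapply(split(hits, hits$target_id), function(h) {
    ir <- IRanges::IRanges(start = h$target_start + 1L, end = h$target_end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    best <- tapply(h$percent_identity[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov), max)
    data.frame(contig_id = h$target_id[[1L]],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               source = source,
               best_identity = as.numeric(best[as.character(seq_along(red))]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collapse mito and plastid hits into source-labelled segments
#'
#' Hits from each source are unioned per contig into `M` (mitochondrial) and
#' `P` (plastid) segments. Where an `M` and a `P` segment overlap
#' reciprocally (intersection over the shorter segment) at or above
#' `ambiguity_reciprocal_overlap`, the organelle of origin cannot be
#' distinguished — for example a transferred gene present in both organelle
#' genomes — and the overlapping segments are replaced by a single ambiguous
#' `A` segment spanning their union.
#'
#' @param mito_hits,plastid_hits filtered, normalized hit tables whose
#'   targets are nuclear contigs.
#' @param config a [transfer_config()].
#' @return data.frame of segments: `contig_id`, `start`, `end`, `source`
#'   (`M`, `P` or `A`), `best_identity`, sorted by contig and start.
#' @export
assign_segment_sources <- function(mito_hits, plastid_hits,
                                   config = transfer_config()) {
  segs <- rbind(collapse_source_hits(mito_hits, "M"),
                collapse_source_hits(plastid_hits, "P"))
  if (nrow(segs) == 0L) return(empty_segments())
  thr <- config$ambiguity_reciprocal_overlap
  out <- lapply(split(segs, segs$contig_id), function(s) {
    m <- which(s$source == "M"); p <- which(s$source == "P")
    parent <- uf_new(nrow(s))
    for (i in m) for (j in p) {
      inter <- min(s$end[i], s$end[j]) - max(s$start[i], s$start[j])
      if (inter <= 0) next
      if (inter / min(s$end[i] - s$start[i], s$end[j] - s$start[j]) >= thr) {
        parent <- uf_union(parent, i, j)
      }
    }
    comp <- vapply(seq_len(nrow(s)), function(i) uf_find(parent, i),
                   numeric(1))
    merged <- lapply(split(seq_len(nrow(s)), comp), function(idx) {
      data.frame(contig_id = s$contig_id[[1L]],
                 start = min(s$start[idx]), end = max(s$end[idx]),
                 source = if (length(unique(s$source[idx])) > 1L) "A"
                          else s$source[idx][[1L]],
                 best_identity = max(s$best_identity[idx]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, merged)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby segments into transfer regions
#'
#' Segments on the same contig are concatenated into a single region when
#' the gap between consecutive segments is strictly less than
#' `max_merge_gap`; overlapping and nested segments are absorbed. Sources
#' may differ across a merged region — a tandem mito + plastid merge is what
#' produces a NUMPT candidate.
#'
#' @param segments segment table from [assign_segment_sources()].
#' @param config a [transfer_config()].
#' @return list with `regions` (data.frame: `region_id`, `contig_id`,
#'   `start`, `end`) and `segments` (the input plus a `region_id` column).
#' @export
merge_segments_into_regions <- function(segments,
                                        config = transfer_config()) {
  if (nrow(segments) == 0L) {
    return(list(regions = data.frame(region_id = character(0),
                                     contig_id = character(0),
                                     start = numeric(0), end = numeric(0),
                                     stringsAsFactors = FALSE),
                segments = cbind(segments, region_id = character(0))))
  }
  segments <- segments[order(segments$contig_id, segments$start,
                             segments$end), , drop = FALSE]
  gap_new <- c(TRUE, segments$contig_id[-1L] !=
                 segments$contig_id[-nrow(segments)])
  region_idx <- integer(nrow(segments))
  cur_end <- -Inf
  rid <- 0L
  for (i in seq_len(nrow(segments))) {
    if (gap_new[i] || segments$start[i] - cur_end >= config$max_merge_gap) {
      rid <- rid + 1L
      cur_end <- segments$end[i]
    } else {
      cur_end <- max(cur_end, segments$end[i])
    }
    region_idx[i] <- rid
  }
  regions <- do.call(rbind, lapply(split(seq_len(nrow(segments)), region_idx),
                                   function(idx) {
    data.frame(contig_id = segments$contig_id[idx[1L]],
               start = min(segments$start[idx]),
               end = max(segments$end[idx]), stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$contig_id, regions$start), , drop = FALSE]
  regions$region_id <- sprintf("region%05d", seq_len(nrow(regions)))
  regions <- regions[, c("region_id", "contig_id", "start", "end")]
  rownames(regions) <- NULL
  # Map segments onto the (re-ordered) regions by containment.
  seg_region <- vapply(seq_len(nrow(segments)), function(i) {
    j <- which(regions$contig_id == segments$contig_id[i] &
                 regions$start <= segments$start[i] &
                 regions$end >= segments$end[i])
    regions$region_id[j[1L]]
  }, character(1))
  segments$region_id <- seg_region
  rownames(segments) <- NULL
  list(regions = regions, segments = segments)
}

#' Classify a transfer region from its segment sources
#'
#' Let `S` be the set of segment sources excluding ambiguous `A` segments:
#' `S = {M}` is a NUMT, `S = {P}` a NUPT, `S = {M, P}` a NUMPT (mitochondrial
#' and plastid sequence in tandem), and an all-ambiguous region (`S` empty)
#' a NUM_PT.
#'
#' @param sources character vector of segment sources (`M`, `P`, `A`).
#' @return one of `"NUMT"`, `"NUPT"`, `"NUMPT"`, `"NUM_PT"`.
#' @export
classify_region <- function(sources) {
  if (length(sources) == 0L) stop("region without segments")
  s <- setdiff(unique(sources), "A")
  if (length(s) == 0L) "NUM_PT"
  else if (setequal(s, "M")) "NUMT"
  else if (setequal(s, "P")) "NUPT"
  else "NUMPT"
}

#' Classify all merged regions
#'
#' @param merged result of [merge_segments_into_regions()].
#' @return the `regions` data.frame with added `category`, `n_segments`,
#'   `sources` and `best_identity` columns.
#' @export
classify_regions <- function(merged) {
  regions <- merged$regions
  segs <- merged$segments
  if (nrow(regions) == 0L) {
    regions$category <- character(0)
    regions$n_segments <- integer(0)
    regions$sources <- character(0)
    regions$best_identity <- numeric(0)
    return(regions)
  }
  by_region <- split(segs, segs$region_id)
  regions$category <- vapply(regions$region_id, function(id)
    classify_region(by_region[[id]]$source), character(1))
  regions$n_segments <- vapply(regions$region_id, function(id)
    nrow(by_region[[id]]), integer(1))
  regions$sources <- vapply(regions$region_id, function(id)
    paste(by_region[[id]]$source, collapse = ","), character(1))
  regions$best_identity <- vapply(regions$region_id, function(id)
    max(by_region[[id]]$best_identity), numeric(1))
  regions
}

#' Validate insertion junctions with long-read alignments
#'
#' For each region boundary `b`, the junction is `yes` (validated) when at
#' least one read alignment spans `[b - min_junction_span,
#' b + min_junction_span)` entirely, `untested` when no read alignment
#' overlaps that interval at all, and `no` otherwise. Regions whose
#' boundaries all validate are unlikely to be assembly chimeras.
#'
#' @param regions classified region table.
#' @param read_hits read-to-contig hit table.
#' @param config a [transfer_config()].
#' @return `regions` with `left_validated` and `right_validated` columns.
#' @export
validate_junctions <- function(regions, read_hits,
                               config = transfer_config()) {
  span <- config$min_junction_span
  check <- function(contig, b) {
    h <- read_hits[read_hits$target_id == contig, , drop = FALSE]
    ov <- h$target_start < b + span & h$target_end > b - span
    if (!any(ov)) return("untested")
    spans <- h$target_start <= b - span & h$target_end >= b + span
    if (any(spans)) "yes" else "no"
  }
  regions$left_validated <- vapply(seq_len(nrow(regions)), function(i)
    check(regions$contig_id[i], regions$start[i]), character(1))
  regions$right_validated <- vapply(seq_len(nrow(regions)), function(i)
    check(regions$contig_id[i], regions$end[i]), character(1))
  regions
}

#' Summarize transfer regions per category
#'
#' @param regions classified region table.
#' @param config a [transfer_config()] recorded in the summary.
#' @return data.frame with one row per category (`NUMT`, `NUPT`, `NUM_PT`,
#'   `NUMPT`): region `count` and summed `total_length` in bp.
#' @export
summarize_transfers <- function(regions, config = transfer_config()) {
  cats <- c("NUMT", "NUPT", "NUM_PT", "NUMPT")
  df <- data.frame(
    category = cats,
    count = vapply(cats, function(cc) sum(regions$category == cc),
                   numeric(1)),
    total_length = vapply(cats, function(cc)
      sum(regions$end[regions$category == cc] -
            regions$start[regions$category == cc]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "thresholds") <- unclass(config)
  df
}

#' Run an external blastn and return the outfmt-6 table path
#'
#' Builds a nucleotide BLAST database for the subject and runs
#' `blastn -task blastn -outfmt 6`. Requires NCBI BLAST+ on the PATH; the
#' alignment step is pluggable, so any precomputed 12-column table can be
#' supplied to [run_transfer_pipeline()] instead.
#'
#' @param query_fasta,subject_fasta input FASTA paths.
#' @param out_tsv output table path.
#' @param evalue E-value cutoff.
#' @param task blastn task.
#' @return `out_tsv`, invisibly.
#' @export
run_blastn <- function(query_fasta, subject_fasta, out_tsv,
                       evalue = 1e-5, task = "blastn") {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "") {
    stop("NCBI BLAST+ (blastn/makeblastdb) not found on PATH; supply a ",
         "precomputed alignment table instead")
  }
  db <- file.path(tempfile("blastdb"), "db")
  dir.create(dirname(db))
  status <- system2("makeblastdb",
                    c("-in", shQuote(subject_fasta), "-dbtype", "nucl",
                      "-out", shQuote(db)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed on ", subject_fasta)
  status <- system2("blastn",
                    c("-task", task, "-query", shQuote(query_fasta),
                      "-db", shQuote(db), "-outfmt", "6",
                      "-evalue", format(evalue, scientific = TRUE),
                      "-out", shQuote(out_tsv)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn failed")
  invisible(out_tsv)
}

#' Run the full organelle-transfer pipeline
#'
#' Filter hits, collapse into source segments, merge into regions, classify
#' into the four categories, optionally validate junctions with read
#' alignments, and write a GFF3 annotation plus a per-category summary.
#'
#' @param mito_hits,plastid_hits normalized organelle-to-nuclear hit tables;
#'   alternatively give `nuclear_fasta` + `mito_fasta` / `plastid_fasta` and
#'   the tables are produced with [run_blastn()].
#' @param nuclear_fasta,mito_fasta,plastid_fasta FASTA paths, used only when
#'   the respective hit table is NULL.
#' @param read_hits optional read-to-contig hit table for junction
#'   validation.
#' @param config a [transfer_config()].
#' @param out_dir if non-NULL, write `transfers.gff3` and `summary.tsv`
#'   there.
#' @param contig_lengths optional named vector for GFF3 bounds checking.
#' @return list with `regions`, `segments`, `summary`.
#' @export
run_transfer_pipeline <- function(mito_hits = NULL, plastid_hits = NULL,
                                  nuclear_fasta = NULL, mito_fasta = NULL,
                                  plastid_fasta = NULL, read_hits = NULL,
                                  config = transfer_config(),
                                  out_dir = NULL, contig_lengths = NULL) {
  if (is.null(mito_hits)) {
    stopifnot(!is.null(nuclear_fasta), !is.null(mito_fasta))
    tsv <- tempfile(fileext = ".tsv")
    run_blastn(mito_fasta, nuclear_fasta, tsv)
    mito_hits <- read_alignments(tsv, "blast_tab", source_tag = "mito")
  }
  if (is.null(plastid_hits)) {
    stopifnot(!is.null(nuclear_fasta), !is.null(plastid_fasta))
    tsv <- tempfile(fileext = ".tsv")
    run_blastn(plastid_fasta, nuclear_fasta, tsv)
    plastid_hits <- read_alignments(tsv, "blast_tab", source_tag = "plastid")
  }
  mito_f <- filter_hits(normalize_hits(mito_hits), config)
  plastid_f <- filter_hits(normalize_hits(plastid_hits), config)
  segs <- assign_segment_sources(mito_f, plastid_f, config)
  merged <- merge_segments_into_regions(segs, config)
  regions <- classify_regions(merged)
  if (!is.null(read_hits)) {
    regions <- validate_junctions(regions, read_hits, config)
  } else if (nrow(regions)) {
    regions$left_validated <- "untested"
    regions$right_validated <- "untested"
  } else {
    regions$left_validated <- character(0)
    regions$right_validated <- character(0)
  }
  summary <- summarize_transfers(regions, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gff <- data.frame(
      contig_id = regions$contig_id, start = regions$start,
      end = regions$end, type = rep("transfer", nrow(regions)),
      attributes = sprintf(
        "ID=%s;Category=%s;sources=%s;best_identity=%s;left_validated=%s;right_validated=%s",
        regions$region_id, regions$category,
        gff3_escape(gsub(",", "|", regions$sources)),
        signif(regions$best_identity, 5),
        regions$left_validated, regions$right_validated),
      stringsAsFactors = FALSE)
    write_gff3(gff, file.path(out_dir, "transfers.gff3"),
               contig_lengths = contig_lengths)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(regions = regions, segments = merged$segments, summary = summary)
}
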