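#' Read a FASTA file into a named vector of cleaned DNA sequences
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` (IUPAC
#' ambiguity codes and the like) is coerced to `N`; the number of coerced
#' characters is reported with a message. All internal coordinates in this
#' package are 0-based half-open on these sequences.
#'
#' @param path FASTA file (plain or line-wrapped).
#' @return named character vector; names are record ids, values sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]], " in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  n_coerced <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  clean <- if (n_coerced > 0) gsub("[^ACGTN]", "N", seqs) else seqs
  if (n_coerced > 0) {
    message(n_coerced, " non-ACGTN character(s) coerced to N in ", path)
  }
  names(clean) <- ids
  clean
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (qualities ignored)
#' @inheritParams read_fasta
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

# Column layout of the tabular BLAST dialect (outfmt 6 default columns).
BLAST_TAB_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read pairwise alignments into the internal hit table
#'
#' Supports the 12-column tabular BLAST dialect (`blast_tab`; 1-based
#' inclusive coordinates, subject coordinates reversed on minus-strand hits)
#' and PAF (`paf`; already 0-based half-open, percent identity derived as
#' `100 * matches / alignment block length`). Hits are normalized so that
#' target coordinates ascend; the original orientation is kept in `strand`.
#'
#' @param path alignment file.
#' @param dialect `"blast_tab"` or `"paf"`.
#' @param source_tag provenance label stored per hit, one of
#'   `mito`, `plastid`, `read`, `self`, `other`.
#' @return data.frame with columns `query_id`, `target_id`, `query_start`,
#'   `query_end`, `target_start`, `target_end` (0-based half-open, target
#'   ascending), `strand`, `percent_identity`, `alignment_length`, `score`,
#'   `source_tag`.
#' @export
read_alignments <- function(path, dialect = c("blast_tab", "paf"),
                            source_tag = "other") {
  dialect <- match.arg(dialect)
  source_tag <- match.arg(source_tag,
                          c("mito", "plastid", "read", "self", "other"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits(source_tag))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  min_cols <- if (dialect == "blast_tab") 12L else 12L
  bad <- which(ncols < min_cols)
  if (length(bad)) {
    stop("malformed ", dialect, " row at line ", bad[[1L]], " of ", path,
         " (", ncols[bad[[1L]]], " columns)")
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v)) {
      stop("malformed ", dialect, " row at line ", which(is.na(v))[[1L]],
           " of ", path, ": non-numeric ", what)
    }
    v
  }
  chr <- function(col) vapply(fields, `[[`, "", col)

  if (dialect == "blast_tab") {
    qstart <- num(7L, "qstart"); qend <- num(8L, "qend")
    sstart <- num(9L, "sstart"); send <- num(10L, "send")
    if (any(c(qstart, qend, sstart, send) < 1)) {
      stop("negative or zero coordinate in blast_tab file ", path)
    }
    hits <- data.frame(
      query_id = chr(1L), target_id = chr(2L),
      query_start = pmin(qstart, qend) - 1, query_end = pmax(qstart, qend),
      target_start = pmin(sstart, send) - 1, target_end = pmax(sstart, send),
      strand = ifelse(sstart <= send, "+", "-"),
      percent_identity = num(3L, "pident"),
      alignment_length = num(4L, "length"),
      score = num(12L, "bitscore"),
      source_tag = source_tag,
      stringsAsFactors = FALSE
    )
  } else {
    qstart <- num(3L, "qstart"); qend <- num(4L, "qend")
    tstart <- num(8L, "tstart"); tend <- num(9L, "tend")
    matches <- num(10L, "matches"); blocklen <- num(11L, "block length")
    if (any(c(qstart, tstart) < 0) || any(c(qend, tend) < 1)) {
      stop("negative coordinate in PAF file ", path)
    }
    hits <- data.frame(
      query_id = chr(1L), target_id = chr(6L),
      query_start = qstart, query_end = qend,
      target_start = tstart, target_end = tend,
      strand = chr(5L),
      percent_identity = 100 * matches / pmax(blocklen, 1),
      alignment_length = blocklen,
      score = matches,
      source_tag = source_tag,
      stringsAsFactors = FALSE
    )
  }
  normalize_hits(hits)
}

empty_hits <- function(source_tag = "other") {
  data.frame(query_id = character(0), target_id = character(0),
             query_start = numeric(0), query_end = numeric(0),
             target_start = numeric(0), target_end = numeric(0),
             strand = character(0), percent_identity = numeric(0),
             alignment_length = numeric(0), score = numeric(0),
             source_tag = character(0),
             stringsAsFactors = FALSE)
}

#' Normalize a hit table onto ascending target coordinates
#'
#' Idempotent; flips any hit with `target_start > target_end` and records the
#' flip in `strand`.
#'
#' @param hits hit table as produced by [read_alignments()].
#' @return normalized hit table.
#' @export
normalize_hits <- function(hits) {
  flip <- hits$target_start > hits$target_end
  if (any(flip)) {
    tmp <- hits$target_start[flip]
    hits$target_start[flip] <- hits$target_end[flip]
    hits$target_end[flip] <- tmp
    hits$strand[flip] <- ifelse(hits$strand[flip] == "+", "-", "+")
  }
  stopifnot(all(hits$target_end - hits$target_start >= 1 | nrow(hits) == 0))
  hits
}

#' Parse Tandem Repeats Finder .dat output
#'
#' Understands the `Sequence: <id>` headers followed by whitespace-separated
#' repeat rows (start, end, period, copy number, ... , consensus). TRF's
#' 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path a TRF `.dat` file.
#' @return data.frame with `contig_id`, `start`, `end`, `period`,
#'   `copy_number`, `consensus`.
#' @export
read_trf_dat <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NA_character_
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      current <- sub("^Sequence:\\s+(\\S+).*$", "\\1", ln)
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 14L) next
    start <- suppressWarnings(as.numeric(f[[1L]]))
    end <- suppressWarnings(as.numeric(f[[2L]]))
    if (is.na(start) || is.na(end)) next
    if (is.na(current)) stop("TRF data row before any Sequence: header")
    if (end <= start - 1) {
      warning("skipping TRF row with end <= start on ", current)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      contig_id = current,
      start = start - 1, end = end,
      period = as.numeric(f[[3L]]),
      copy_number = as.numeric(f[[4L]]),
      consensus = f[[14L]],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0), period = numeric(0),
                      copy_number = numeric(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Percent-encode characters reserved in GFF3 attribute values.
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open intervals are converted to GFF3's 1-based
#' inclusive convention at this boundary. Rows are written in deterministic
#' `(contig, start, end, type)` order.
#'
#' @param features data.frame with columns `contig_id`, `start`, `end`,
#'   `type`, and optionally `strand`, `score`, `attributes` (a pre-built
#'   `key=value;...` string whose values must already be escaped with
#'   [gff3_escape()]).
#' @param path output file.
#' @param source value of the GFF3 source column.
#' @param contig_lengths optional named vector; when given, intervals
#'   exceeding their contig length are an error.
#' @export
write_gff3 <- function(features, path, source = "orgweave",
                       contig_lengths = NULL) {
  stopifnot(all(c("contig_id", "start", "end", "type") %in% names(features)))
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[features$contig_id]
    if (anyNA(len)) stop("feature on unknown contig")
    if (any(features$end > len)) {
      stop("feature interval exceeds contig length on ",
           features$contig_id[which(features$end > len)[1L]])
    }
  }
  o <- order(features$contig_id, features$start, features$end, features$type)
  features <- features[o, , drop = FALSE]
  strand <- features$strand %||% rep(".", nrow(features))
  strand[is.na(strand)] <- "."
  score <- features$score %||% rep(".", nrow(features))
  attrs <- features$attributes %||% sprintf("ID=feature%06d", seq_len(nrow(features)))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   features$contig_id, source, features$type,
                   as.integer(features$start) + 1L,
                   as.integer(features$end),
                   as.character(score), strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with `contig_id`, `start`, `end` and an optional
#'   `name` column.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  nm <- df$name %||% rep(".", nrow(df))
  o <- order(df$contig_id, df$start, df$end)
  writeLines(sprintf("%s\t%d\t%d\t%s", df$contig_id[o],
                     as.integer(df$start[o]), as.integer(df$end[o]), nm[o]),
             path)
  invisible(path)
}

#' Read a BED file
#' @param path BED file.
#' @return data.frame with `contig_id`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig_id", "start", "end", "name")[
                            seq_len(max(count.fields(path, sep = "\t")))])
  if (is.null(df$name)) df$name <- "."
  df
}
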