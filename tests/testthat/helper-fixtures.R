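# Shared fixtures, built once per test run and cached in-process.

.fixture_cache <- new.env(parent = emptyenv())

# Small configuration for fast unit tests (not the default study conditions).
small_config <- function(seed = 7L, ...) {
  args <- list(
    seed = seed, n_contigs = 3L, contig_length = 60000L,
    plastome_length = 20000L, mitome_length = 30000L,
    n_numt = 3L, n_nupt = 3L, n_numpt = 2L, n_numpt_ambiguous = 2L,
    shared_gene_blocks = 2L, shared_block_length = 1500L,
    insert_length_range = c(200L, 1500L),
    telomere_copies = 60L, n_satellite_arrays = 1L, satellite_copies = 100L,
    rdna_copies = 0L, n_repeat_only_contigs = 1L,
    repeat_contig_length = 20000L, nuclear_depth = 5, organelle_depth = 60,
    read_length_mean = 5000L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# The default-condition fixture (seed 42): full generator run plus blastn
# organelle-vs-assembly hit tables and simulated read alignments. Expensive,
# so cached; used by the acceptance suite.
default_fixture <- function() {
  if (!exists("fx42", envir = .fixture_cache)) {
    cfg <- simulation_config(seed = 42L)
    org <- make_organelle_genomes(cfg)
    asm <- make_nuclear_assembly(cfg, org)
    dir <- tempfile("fx42_")
    dir.create(dir)
    write_fasta(asm$contigs, file.path(dir, "genomes.fasta"))
    write_fasta(org$plastome, file.path(dir, "plastome.fasta"))
    write_fasta(org$mitome, file.path(dir, "mitome.fasta"))
    run_blastn(file.path(dir, "mitome.fasta"),
               file.path(dir, "genomes.fasta"), file.path(dir, "mito.tsv"))
    run_blastn(file.path(dir, "plastome.fasta"),
               file.path(dir, "genomes.fasta"), file.path(dir, "plastid.tsv"))
    mito_hits <- read_alignments(file.path(dir, "mito.tsv"), "blast_tab",
                                 source_tag = "mito")
    plastid_hits <- read_alignments(file.path(dir, "plastid.tsv"),
                                    "blast_tab", source_tag = "plastid")
    reads <- simulate_long_reads(asm$contigs, org$plastome, org$mitome, cfg)
    assign("fx42", list(cfg = cfg, org = org, contigs = asm$contigs,
                        truth = asm$truth, mito_hits = mito_hits,
                        plastid_hits = plastid_hits, reads = reads,
                        read_aln = reads_to_alignments(reads)),
           envir = .fixture_cache)
  }
  get("fx42", envir = .fixture_cache)
}

SATELLITE_UNIT_36_test <- function() orgweave:::SATELLITE_UNIT_36

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random hit table generator for property tests.
random_hits <- function(n, contigs = c("c1", "c2"), max_pos = 10000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(500L, n, replace = TRUE)
  fwd <- sample(c(TRUE, FALSE), n, replace = TRUE)
  data.frame(
    query_id = sprintf("q%03d", seq_len(n)),
    target_id = sample(contigs, n, replace = TRUE),
    query_start = 0, query_end = len,
    target_start = ifelse(fwd, start, start + len),
    target_end = ifelse(fwd, start + len, start),
    strand = "+",
    percent_identity = round(stats::runif(n, 70, 100), 2),
    alignment_length = len,
    score = len, source_tag = "other", stringsAsFactors = FALSE)
}

# Independent O(n^2) transitive-closure oracle for the segment-merge rule:
# two segments are related when they lie on the same contig and the gap
# between them (negative when overlapping) is strictly below `gap`; regions
# are the connected components under the closure of that relation.
oracle_merge_regions <- function(segs, gap = 300) {
  n <- nrow(segs)
  if (n == 0L) {
    return(data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (segs$contig_id[i] == segs$contig_id[j]) {
      g <- max(segs$start[i], segs$start[j]) - min(segs$end[i], segs$end[j])
      if (g < gap) adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cc <- cc + 1L
    queue <- i
    comp[i] <- cc
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cc
      queue <- c(queue, nb)
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(contig_id = segs$contig_id[idx[1L]],
               start = min(segs$start[idx]), end = max(segs$end[idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random segment set for merge-rule property tests.
random_segments <- function(n, contigs = c("c1", "c2"), max_pos = 20000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(1000L, n, replace = TRUE)
  data.frame(contig_id = sample(contigs, n, replace = TRUE),
             start = start, end = start + len,
             source = sample(c("M", "P"), n, replace = TRUE),
             best_identity = 90, stringsAsFactors = FALSE)
}

# Planted-truth transfer rows (the acceptance surface of the generator).
transfer_truth <- function(truth) {
  truth[truth$feature_type %in% c("NUMT", "NUPT", "NUMPT", "NUM_PT"), ,
        drop = FALSE]
}

# Match recovered regions to planted transfer intervals; returns per-truth-row
# maximum boundary offset (NA when nothing overlaps).
boundary_offsets <- function(regions, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    cand <- regions[regions$contig_id == truth$contig_id[i] &
                      regions$start < truth$end[i] &
                      regions$end > truth$start[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_real_)
    max(abs(min(cand$start) - truth$start[i]),
        abs(max(cand$end) - truth$end[i]))
  }, numeric(1))
}
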