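# Synthetic genomes with planted organelle transfers, telomeres, satellite
# and rDNA arrays, plus long reads at category-specific depths. Everything is
# deterministic under config$seed: the organelle stage seeds with `seed`, the
# nuclear stage with `seed + 1`, the read stage with `seed + 2`, each consuming
# one R random stream in documented order.

# Fixed 36 bp satellite unit used by default for planted satellite arrays and
# repeat-only contigs (centromeric satellite monomers in plants are commonly
# tens to hundreds of bp).
SATELLITE_UNIT_36 <- "ACGGTTCAGATCCTAGGCTTAACGTGGATCAAGTCC"

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the study conditions the pipeline targets: ~27x nuclear
#' long-read depth with organelle sequence present at 10-100 fold higher
#' depth, Mb-scale nuclear contigs carrying organelle insertions of 200-5000
#' bp at ~5% divergence, exact `TTTAGGG` telomere tracts, a fixed 36 bp
#' satellite unit, and multi-kb rDNA-like units in long tandem arrays.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output.
#' @param n_contigs number of nuclear background contigs.
#' @param contig_length length of each nuclear contig (bp).
#' @param plastome_length,mitome_length organelle genome lengths (bp).
#' @param n_numt,n_nupt,n_numpt,n_numpt_ambiguous planted counts of NUMTs,
#'   NUPTs, complex tandem NUMPTs, and ambiguous NUM/PTs.
#' @param n_broken_numpt tandem mito+plastid insertions separated by a gap of
#'   300-800 bp, i.e. wider than the merge rule; plants the negative case in
#'   which the pair must be reported as separate NUMT + NUPT.
#' @param insert_length_range min/max insert length (bp).
#' @param insert_divergence substitution rate applied to inserted organelle
#'   segments, in `[0, 0.5)`.
#' @param shared_gene_blocks number of plastome segments copied (at <= 1%
#'   divergence) into the mitogenome, emulating plastid genes residing in the
#'   mitome; these create the NUM/PT ambiguity.
#' @param shared_block_length length of each shared block (bp).
#' @param telomere_plan character vector recycled over contigs, values in
#'   `both`, `left`, `right`, `none`.
#' @param telomere_copies exact `TTTAGGG` copies per planted tract.
#' @param satellite_unit satellite monomer sequence.
#' @param n_satellite_arrays planted interstitial satellite arrays.
#' @param satellite_copies monomer copies per planted array.
#' @param rdna_unit_length,rdna_copies rDNA-like repeat unit length and copy
#'   number of the planted array (one array, on the last nuclear contig
#'   chosen at random).
#' @param n_repeat_only_contigs extra contigs consisting purely of tandem
#'   satellite monomers.
#' @param repeat_contig_length length of each repeat-only contig (bp).
#' @param include_organelle_contigs add verbatim copies of the plastome and
#'   mitogenome to the assembly as contigs `orgP` / `orgM` (the organelle
#'   contigs a real assembly retains until depth screening removes them).
#' @param nuclear_depth,organelle_depth sequencing depths (x).
#' @param read_length_mean mean long-read length (bp).
#' @param read_error_rate per-base substitution error rate of simulated reads.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 10L,
                              contig_length = 500000L,
                              plastome_length = 150000L,
                              mitome_length = 300000L,
                              n_numt = 40L,
                              n_nupt = 30L,
                              n_numpt = 10L,
                              n_numpt_ambiguous = 10L,
                              n_broken_numpt = 0L,
                              insert_length_range = c(200L, 5000L),
                              insert_divergence = 0.05,
                              shared_gene_blocks = 5L,
                              shared_block_length = 2000L,
                              telomere_plan = c("both", "left", "right", "none"),
                              telomere_copies = 120L,
                              satellite_unit = SATELLITE_UNIT_36,
                              n_satellite_arrays = 2L,
                              satellite_copies = 300L,
                              rdna_unit_length = 11400L,
                              rdna_copies = 30L,
                              n_repeat_only_contigs = 2L,
                              repeat_contig_length = 50000L,
                              include_organelle_contigs = TRUE,
                              nuclear_depth = 27,
                              organelle_depth = 500,
                              read_length_mean = 15000L,
                              read_error_rate = 0.002) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_contigs, cfg$n_numt, cfg$n_nupt, cfg$n_numpt,
              cfg$n_numpt_ambiguous, cfg$n_broken_numpt,
              cfg$shared_gene_blocks, cfg$n_satellite_arrays,
              cfg$n_repeat_only_contigs, cfg$rdna_copies)
  stopifnot(all(counts >= 0),
            cfg$insert_divergence >= 0, cfg$insert_divergence < 0.5,
            length(cfg$insert_length_range) == 2L,
            cfg$insert_length_range[1] <= cfg$insert_length_range[2],
            all(cfg$telomere_plan %in% c("both", "left", "right", "none")))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate toy plastome and mitogenome with shared gene blocks
#'
#' Both genomes are i.i.d. random DNA; `shared_gene_blocks` plastome
#' intervals are copied into the mitogenome with at most 1% divergence, so a
#' nuclear insertion of such a block cannot be attributed to either organelle
#' (the NUM/PT case). Deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `plastome`, `mitome` (named character scalars) and
#'   `shared_blocks`, a data.frame of paired 0-based half-open coordinates on
#'   both genomes.
#' @export
make_organelle_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$plastome_length >= 10000, config$mitome_length >= 10000)
  if (config$shared_gene_blocks * config$shared_block_length >
        config$plastome_length) {
    stop("shared gene blocks do not fit in the plastome")
  }
  set.seed(config$seed)
  plastome <- random_dna(config$plastome_length)
  mitome <- random_dna(config$mitome_length)

  nb <- config$shared_gene_blocks
  bl <- config$shared_block_length
  blocks <- data.frame(block_id = integer(0), plastome_start = integer(0),
                       plastome_end = integer(0), mitome_start = integer(0),
                       mitome_end = integer(0))
  if (nb > 0) {
    p_starts <- sample_disjoint_starts(config$plastome_length, rep(bl, nb),
                                       min_sep = 500L)
    m_starts <- sample_disjoint_starts(config$mitome_length, rep(bl, nb),
                                       min_sep = 500L)
    for (i in seq_len(nb)) {
      block <- substr(plastome, p_starts[i] + 1L, p_starts[i] + bl)
      # exactly 1% substitutions so the block pair stays at >= 99% identity
      substr(mitome, m_starts[i] + 1L, m_starts[i] + bl) <-
        mutate_dna_count(block, floor(0.01 * bl))
    }
    blocks <- data.frame(block_id = seq_len(nb),
                         plastome_start = p_starts, plastome_end = p_starts + bl,
                         mitome_start = m_starts, mitome_end = m_starts + bl)
  }
  list(plastome = c(plastome = plastome), mitome = c(mitome = mitome),
       shared_blocks = blocks)
}

# Sample non-overlapping 0-based start positions for segments of the given
# lengths, with at least `min_sep` bp between segments and to both ends.
sample_disjoint_starts <- function(total_length, lengths, min_sep = 400L,
                                   max_tries = 2000L, label = "sequence") {
  starts <- integer(0)
  occupied <- data.frame(start = numeric(0), end = numeric(0))
  for (len in lengths) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(total_length - len - 2L * min_sep, 1L) + min_sep
      if (nrow(occupied) == 0L ||
            all(s + len + min_sep <= occupied$start |
                  s >= occupied$end + min_sep)) {
        occupied <- rbind(occupied, data.frame(start = s, end = s + len))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place segment of ", len, " bp on ", label,
                      " after ", max_tries, " tries (congested)")
  }
  starts
}

# Sample a source interval of length len avoiding the given intervals
# (expanded by margin). Returns the 0-based start.
sample_source_start <- function(total_length, len, avoid, margin = 300L) {
  for (t in 1:2000) {
    s <- sample.int(total_length - len, 1L) - 1L
    if (nrow(avoid) == 0L ||
          all(s + len + margin <= avoid$start | s >= avoid$end + margin)) {
      return(s)
    }
  }
  stop("could not sample a source interval avoiding shared blocks")
}

#' Build a nuclear assembly with planted features and its truth table
#'
#' Plants, onto i.i.d. random background contigs: NUMTs (mitome-only
#' segments), NUPTs (plastome-only segments), NUM/PTs (copies of shared
#' plastome/mitome blocks), NUMPTs (a mito-only and a plastid-only segment in
#' tandem, separated by a gap drawn uniformly from 0-299 bp so the merge rule
#' joins them), optional "broken" NUMPT pairs with gaps of 300-800 bp,
#' telomere tracts, satellite arrays, one rDNA-like tandem array, pure-repeat
#' contigs and verbatim organelle contigs. Inserted organelle segments are
#' mutated at `insert_divergence`. Features never overlap and keep >= 400 bp
#' of background between them. Deterministic under `config$seed + 1`.
#'
#' @param config a [simulation_config()].
#' @param organelles result of [make_organelle_genomes()].
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame: `feature_type`, `contig_id`, `start`, `end`, `payload`).
#' @export
make_nuclear_assembly <- function(config, organelles) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  plastome <- unname(organelles$plastome)
  mitome <- unname(organelles$mitome)
  blocks <- organelles$shared_blocks
  avoid_p <- data.frame(start = blocks$plastome_start, end = blocks$plastome_end)
  avoid_m <- data.frame(start = blocks$mitome_start, end = blocks$mitome_end)

  n <- config$n_contigs
  contigs <- vapply(seq_len(n), function(i) random_dna(config$contig_length),
                    character(1))
  names(contigs) <- sprintf("ctg%02d", seq_len(n))
  truth <- list()
  add_truth <- function(type, contig, start, end, payload = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_type = type, contig_id = contig,
      start = as.integer(start), end = as.integer(end),
      payload = payload, stringsAsFactors = FALSE)
  }

  tel_len <- config$telomere_copies * 7L
  plan <- rep_len(config$telomere_plan, n)
  # Reserve telomere zones plus a margin so transfers never touch them.
  occupied <- lapply(seq_len(n), function(i) {
    data.frame(start = c(0, config$contig_length - tel_len - 400),
               end = c(tel_len + 400, config$contig_length))
  })
  names(occupied) <- names(contigs)

  place <- function(contig_idx, len, min_sep = 400L) {
    occ <- occupied[[contig_idx]]
    for (t in 1:2000) {
      s <- sample.int(config$contig_length - len, 1L) - 1L
      if (all(s + len + min_sep <= occ$start | s >= occ$end + min_sep)) {
        occupied[[contig_idx]] <<- rbind(occ, data.frame(start = s, end = s + len))
        return(s)
      }
    }
    stop("feature placement failed on congested contig ",
         names(contigs)[contig_idx])
  }
  overwrite <- function(contig_idx, start, segment) {
    substr(contigs[[contig_idx]], start + 1L, start + nchar(segment)) <<- segment
  }
  draw_len <- function() {
    r <- config$insert_length_range
    sample(seq.int(r[1], r[2]), 1L)
  }

  # rDNA array first (largest feature; placed on the last contig).
  if (config$rdna_copies > 0) {
    stopifnot(config$rdna_unit_length >= 7000)
    unit <- random_dna(config$rdna_unit_length)
    array_seq <- strrep(unit, config$rdna_copies)
    array_len <- nchar(array_seq)
    if (array_len + 2 * (tel_len + 800) > config$contig_length) {
      stop("rDNA array does not fit on a contig")
    }
    ci <- n
    s <- place(ci, array_len)
    overwrite(ci, s, array_seq)
    # Fixed gene offsets inside the unit: 18S, 5.8S, 26S.
    add_truth("rdna_array", names(contigs)[ci], s, s + array_len,
              sprintf("unit_length=%d;copies=%d;offset_18S=500-2300;offset_5.8S=2500-2660;offset_26S=2900-6300",
                      config$rdna_unit_length, config$rdna_copies))
  }

  plant_transfer <- function(type) {
    ci <- sample.int(n, 1L)
    if (type == "NUMT") {
      len <- draw_len()
      src <- sample_source_start(config$mitome_length, len, avoid_m)
      seg <- mutate_dna(substr(mitome, src + 1L, src + len),
                        config$insert_divergence)
      s <- place(ci, len)
      overwrite(ci, s, seg)
      add_truth("NUMT", names(contigs)[ci], s, s + len,
                sprintf("source=mito;src_start=%d;src_end=%d", src, src + len))
    } else if (type == "NUPT") {
      len <- draw_len()
      src <- sample_source_start(config$plastome_length, len, avoid_p)
      seg <- mutate_dna(substr(plastome, src + 1L, src + len),
                        config$insert_divergence)
      s <- place(ci, len)
      overwrite(ci, s, seg)
      add_truth("NUPT", names(contigs)[ci], s, s + len,
                sprintf("source=plastid;src_start=%d;src_end=%d", src, src + len))
    } else if (type == "NUM_PT") {
      b <- blocks[sample.int(nrow(blocks), 1L), ]
      max_len <- min(config$insert_length_range[2], config$shared_block_length)
      len <- sample(seq.int(config$insert_length_range[1], max_len), 1L)
      off <- sample.int(config$shared_block_length - len + 1L, 1L) - 1L
      src <- b$plastome_start + off
      seg <- mutate_dna(substr(plastome, src + 1L, src + len),
                        config$insert_divergence)
      s <- place(ci, len)
      overwrite(ci, s, seg)
      add_truth("NUM_PT", names(contigs)[ci], s, s + len,
                sprintf("source=shared;block_id=%d;src_start=%d;src_end=%d",
                        b$block_id, src, src + len))
    } else { # NUMPT / broken NUMPT
      broken <- type == "broken_NUMPT"
      len_m <- draw_len(); len_p <- draw_len()
      gap <- if (broken) sample(300:800, 1L) else sample(0:299, 1L)
      total <- len_m + gap + len_p
      src_m <- sample_source_start(config$mitome_length, len_m, avoid_m)
      src_p <- sample_source_start(config$plastome_length, len_p, avoid_p)
      seg_m <- mutate_dna(substr(mitome, src_m + 1L, src_m + len_m),
                          config$insert_divergence)
      seg_p <- mutate_dna(substr(plastome, src_p + 1L, src_p + len_p),
                          config$insert_divergence)
      s <- place(ci, total)
      overwrite(ci, s, seg_m)
      overwrite(ci, s + len_m + gap, seg_p)
      add_truth(if (broken) "broken_NUMPT" else "NUMPT",
                names(contigs)[ci], s, s + total,
                sprintf("gap=%d;mito=%d-%d;plastid=%d-%d;src_m=%d-%d;src_p=%d-%d",
                        gap, s, s + len_m, s + len_m + gap, s + total,
                        src_m, src_m + len_m, src_p, src_p + len_p))
    }
  }

  if (config$n_numpt_ambiguous > 0 && nrow(blocks) == 0) {
    stop("cannot plant NUM/PTs without shared gene blocks")
  }
  for (i in seq_len(config$n_numt)) plant_transfer("NUMT")
  for (i in seq_len(config$n_nupt)) plant_transfer("NUPT")
  for (i in seq_len(config$n_numpt)) plant_transfer("NUMPT")
  for (i in seq_len(config$n_numpt_ambiguous)) plant_transfer("NUM_PT")
  for (i in seq_len(config$n_broken_numpt)) plant_transfer("broken_NUMPT")

  # Satellite arrays.
  sat_len <- nchar(config$satellite_unit) * config$satellite_copies
  for (i in seq_len(config$n_satellite_arrays)) {
    ci <- sample.int(n, 1L)
    s <- place(ci, sat_len)
    overwrite(ci, s, strrep(config$satellite_unit, config$satellite_copies))
    add_truth("satellite_array", names(contigs)[ci], s, s + sat_len,
              sprintf("unit=%s;copies=%d", config$satellite_unit,
                      config$satellite_copies))
  }

  # Telomeres (exact tracts written last so nothing can overwrite them).
  for (i in seq_len(n)) {
    id <- names(contigs)[i]
    if (plan[i] %in% c("both", "left")) {
      overwrite(i, 0L, strrep("TTTAGGG", config$telomere_copies))
      add_truth("telomere_left", id, 0L, tel_len,
                sprintf("copies=%d", config$telomere_copies))
    }
    if (plan[i] %in% c("both", "right")) {
      overwrite(i, config$contig_length - tel_len,
                strrep("CCCTAAA", config$telomere_copies))
      add_truth("telomere_right", id, config$contig_length - tel_len,
                config$contig_length,
                sprintf("copies=%d", config$telomere_copies))
    }
  }

  # Repeat-only contigs: pure tandem repetition of the satellite unit.
  if (config$n_repeat_only_contigs > 0) {
    for (i in seq_len(config$n_repeat_only_contigs)) {
      id <- sprintf("rep%02d", i)
      copies <- ceiling(config$repeat_contig_length /
                          nchar(config$satellite_unit))
      seq <- substr(strrep(config$satellite_unit, copies), 1L,
                    config$repeat_contig_length)
      contigs[[id]] <- seq
      add_truth("repeat_only_contig", id, 0L, config$repeat_contig_length,
                sprintf("unit=%s", config$satellite_unit))
    }
  }

  # Organelle-derived contigs retained in the raw assembly.
  if (config$include_organelle_contigs) {
    contigs[["orgP"]] <- plastome
    add_truth("organelle_contig", "orgP", 0L, nchar(plastome), "source=plastid")
    contigs[["orgM"]] <- mitome
    add_truth("organelle_contig", "orgM", 0L, nchar(mitome), "source=mito")
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth)
}

#' Simulate long reads at category-specific depths
#'
#' Reads are sampled uniformly from each source until the configured depth in
#' bases is reached: nuclear contigs at `nuclear_depth`, the plastome and
#' mitogenome at `organelle_depth`. Read lengths are normal around
#' `read_length_mean` (sd 10%, floor 500 bp, capped at the source length with
#' a warning). Substitution errors occur at `read_error_rate`. Read names
#' encode source and coordinates. Deterministic under `config$seed + 2`.
#'
#' Sequence materialisation is optional: the returned metadata (source,
#' 0-based half-open coordinates, strand, error count) fully describes every
#' read, and [reads_to_alignments()] turns it into an idealised perfectly
#' mapped hit table without the cost of building and re-mapping multi-hundred
#' megabase FASTQ files.
#'
#' @param contigs named character vector of nuclear contigs; contigs named in
#'   `organelle_contig_ids` are skipped (they receive their coverage from the
#'   organelle genome reads).
#' @param plastome,mitome organelle genome sequences (character scalars).
#' @param config a [simulation_config()].
#' @param fastq_path if non-NULL, write the reads as FASTQ here (constant
#'   quality).
#' @param keep_sequences return read sequences in the result (implied when
#'   `fastq_path` is set and error injection is requested).
#' @param organelle_contig_ids assembly contigs that are verbatim organelle
#'   copies (default `orgP`/`orgM` when present).
#' @return data.frame: `read_id`, `source_id`, `start`, `end`, `strand`,
#'   `length`, `n_errors`, plus `sequence` when requested.
#' @export
simulate_long_reads <- function(contigs, plastome, mitome, config,
                                fastq_path = NULL, keep_sequences = FALSE,
                                organelle_contig_ids =
                                  intersect(c("orgP", "orgM"), names(contigs))) {
  stopifnot(inherits(config, "sim_config"),
            config$nuclear_depth > 0, config$organelle_depth > 0)
  set.seed(config$seed + 2L)
  sources <- c(as.list(contigs[setdiff(names(contigs), organelle_contig_ids)]),
               list(plastome = unname(plastome), mitome = unname(mitome)))
  depths <- c(rep(config$nuclear_depth,
                  length(sources) - 2L), config$organelle_depth,
              config$organelle_depth)
  need_seq <- keep_sequences || !is.null(fastq_path)

  out <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    src_id <- names(sources)[i]
    L <- nchar(src)
    rl_mean <- config$read_length_mean
    if (rl_mean > L) {
      warning("read length mean exceeds length of ", src_id,
              "; reads truncated")
      rl_mean <- L
    }
    target <- depths[i] * L
    n_est <- ceiling(target / rl_mean * 1.3) + 5L
    lens <- pmin(L, pmax(500L, round(stats::rnorm(n_est, rl_mean,
                                                  0.1 * rl_mean))))
    n_reads <- which(cumsum(lens) >= target)[1]
    if (is.na(n_reads)) n_reads <- n_est
    lens <- lens[seq_len(n_reads)]
    starts <- vapply(L - lens, function(m) sample.int(m + 1L, 1L) - 1L,
                     numeric(1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    nerr <- stats::rbinom(n_reads, lens, config$read_error_rate)
    df <- data.frame(
      read_id = sprintf("%s_read%05d", src_id, seq_len(n_reads)),
      source_id = src_id, start = starts, end = starts + lens,
      strand = strands, length = lens, n_errors = nerr,
      stringsAsFactors = FALSE)
    if (need_seq) {
      seqs <- substring(src, starts + 1L, starts + lens)
      flip <- strands == "-"
      if (any(flip)) {
        seqs[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[flip])))
      }
      err <- nerr > 0
      if (any(err)) seqs[err] <- mapply(inject_errors, seqs[err], nerr[err])
      df$sequence <- seqs
    }
    out[[i]] <- df
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (!is.null(fastq_path)) {
    con <- file(fastq_path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$read_id, " ", reads$source_id, ":",
                      reads$start, "-", reads$end, "(", reads$strand, ")\n",
                      reads$sequence, "\n+\n",
                      strrep("~", reads$length)), con)
  }
  if (!keep_sequences) reads$sequence <- NULL
  reads
}

# Place exactly k substitutions at distinct random positions.
inject_errors <- function(seq, k) {
  n <- nchar(seq)
  pos <- sort(sample.int(n, min(k, n)))
  pieces <- substring(seq, c(1L, pos + 1L), c(pos - 1L, n))
  orig <- substring(seq, pos, pos)
  bases <- c("A", "C", "G", "T")
  repl <- vapply(orig, function(b) {
    alt <- bases[bases != b]
    if (length(alt) == 0L) "N" else alt[sample.int(length(alt), 1L)]
  }, character(1))
  out <- character(2L * length(pos) + 1L)
  out[seq(1L, by = 2L, length.out = length(pos) + 1L)] <- pieces
  out[seq(2L, by = 2L, length.out = length(pos))] <- repl
  paste(out, collapse = "")
}

#' Convert simulated read metadata to an idealised read-alignment table
#'
#' Every read maps exactly once at its true coordinates; reads drawn from the
#' organelle genomes are mapped onto the corresponding organelle contigs of
#' the assembly when those are present. Percent identity reflects the
#' injected error count.
#'
#' @param reads result of [simulate_long_reads()].
#' @param organelle_map named character vector mapping read source ids
#'   (`plastome`, `mitome`) to assembly contig ids; sources absent from the
#'   map keep their own id as target.
#' @return hit table in the [read_alignments()] convention, `source_tag`
#'   `"read"`.
#' @export
reads_to_alignments <- function(reads,
                                organelle_map = c(plastome = "orgP",
                                                  mitome = "orgM")) {
  target <- reads$source_id
  hit <- target %in% names(organelle_map)
  target[hit] <- organelle_map[target[hit]]
  data.frame(
    query_id = reads$read_id, target_id = target,
    query_start = 0, query_end = reads$length,
    target_start = reads$start, target_end = reads$end,
    strand = reads$strand,
    percent_identity = 100 * (1 - reads$n_errors / reads$length),
    alignment_length = reads$length, score = reads$length - reads$n_errors,
    source_tag = "read", stringsAsFactors = FALSE)
}

#' Write the truth table as BED + TSV
#'
#' @param truth truth table from [make_nuclear_assembly()].
#' @param bed_path,tsv_path output files.
#' @return invisibly, the two paths.
#' @export
write_truth <- function(truth, bed_path, tsv_path) {
  o <- order(truth$contig_id, truth$start, truth$end, truth$feature_type)
  truth <- truth[o, , drop = FALSE]
  write_bed(data.frame(contig_id = truth$contig_id, start = truth$start,
                       end = truth$end, name = truth$feature_type), bed_path)
  utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed_path, tsv_path))
}

#' Run the whole generator and write a fixture directory
#'
#' Emits `genomes.fasta` (the assembly), `plastome.fasta`, `mitome.fasta`,
#' `truth.bed`, `truth.tsv`, `reads.tsv` (read metadata), optionally
#' `reads.fastq`, and `config.tsv` with the resolved configuration.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created).
#' @param write_fastq materialise read sequences as FASTQ.
#' @return invisibly, a list with `contigs`, `truth`, `organelles`, `reads`.
#' @export
simulate_genome_set <- function(config, outdir, write_fastq = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  org <- make_organelle_genomes(config)
  asm <- make_nuclear_assembly(config, org)
  reads <- simulate_long_reads(asm$contigs, org$plastome, org$mitome, config,
                               fastq_path = if (write_fastq)
                                 file.path(outdir, "reads.fastq") else NULL)
  write_fasta(asm$contigs, file.path(outdir, "genomes.fasta"))
  write_fasta(org$plastome, file.path(outdir, "plastome.fasta"))
  write_fasta(org$mitome, file.path(outdir, "mitome.fasta"))
  write_truth(asm$truth, file.path(outdir, "truth.bed"),
              file.path(outdir, "truth.tsv"))
  utils::write.table(reads, file.path(outdir, "reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- data.frame(key = names(config),
                    value = vapply(config, function(x)
                      paste(as.character(x), collapse = ","), character(1)))
  utils::write.table(cfg, file.path(outdir, "config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(contigs = asm$contigs, truth = asm$truth,
                 organelles = org, reads = reads))
}
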