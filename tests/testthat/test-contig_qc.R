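test_that("normalized Shannon entropy matches hand-computed values", {
  expect_equal(shannon_entropy("AAAAAAAAAA", k = 1L), 0)
  # perfect 4-periodic sequence, k = 4: four (near-)uniform 4-mers give
  # ~2 bits over a log2(256) = 8-bit ceiling
  s <- strrep("ACGT", 100L)
  expect_equal(shannon_entropy(s, k = 4L), 0.25, tolerance = 1e-3)
  expect_error(shannon_entropy("ACG", k = 4L), "shorter")
  set.seed(99)
  r <- random_dna_test(100000L)
  expect_gt(shannon_entropy(r, k = 21L), 0.95)
})

test_that("entropy at k=1 is invariant under reversal and complementation", {
  set.seed(12)
  s <- random_dna_test(4000L)
  rev <- paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  expect_equal(shannon_entropy(s, 1L), shannon_entropy(rev, 1L))
  expect_equal(shannon_entropy(s, 1L), shannon_entropy(revcomp(s), 1L),
               tolerance = 1e-12)
})

test_that("entropy decreases with repetitiveness", {
  set.seed(44)
  unit <- random_dna_test(36L)
  pure <- strrep(unit, 400L)
  rand <- random_dna_test(nchar(pure))
  mixed <- paste0(substr(rand, 1L, nchar(pure) / 2),
                  substr(pure, 1L, nchar(pure) / 2))
  e <- vapply(c(pure, mixed, rand), shannon_entropy, numeric(1), k = 21L)
  expect_true(e[[1L]] < e[[2L]] && e[[2L]] < e[[3L]])
})

test_that("low-complexity screen flags tandem-repeat contigs only", {
  set.seed(21)
  contigs <- c(sat = strrep(SATELLITE_UNIT_36_test(), 1000L),
               rand = random_dna_test(50000L))
  fl <- flag_low_complexity_contigs(contigs)
  expect_identical(fl$flag, c("low_complexity", "pass"))
  fl0 <- flag_low_complexity_contigs(contigs, threshold = 0)
  expect_true(all(fl0$flag == "pass"))
})

test_that("per-contig depth follows the aligned-base definition", {
  lens <- c(c1 = 10000, c2 = 5000)
  h <- data.frame(query_id = "r1", target_id = "c1", query_start = 0,
                  query_end = 1000, target_start = 2000, target_end = 3000,
                  strand = "+", percent_identity = 99,
                  alignment_length = 1000, score = 1000,
                  source_tag = "read", stringsAsFactors = FALSE)
  d <- per_contig_depth(h, lens)
  expect_equal(d$mean_depth[d$contig_id == "c1"], 0.1)
  expect_equal(d$mean_depth[d$contig_id == "c2"], 0)
  expect_equal(per_contig_depth(h[0, ], lens)$mean_depth, c(0, 0))
  h_bad <- h; h_bad$target_id <- "nope"
  expect_error(per_contig_depth(h_bad, lens), "unknown contig")
})

test_that("multi-mapping reads count only their best alignment", {
  lens <- c(c1 = 1000, c2 = 1000)
  h <- data.frame(query_id = "r1", target_id = c("c1", "c2"),
                  query_start = 0, query_end = 500,
                  target_start = 0, target_end = c(500, 400), strand = "+",
                  percent_identity = 99, alignment_length = c(500, 400),
                  score = c(500, 400), source_tag = "read",
                  stringsAsFactors = FALSE)
  d <- per_contig_depth(h, lens)
  expect_equal(d$aligned_bases, c(500, 0))
})

test_that("depth conservation: sum(depth x length) equals aligned bases", {
  set.seed(77)
  h <- normalize_hits(random_hits(200))
  h$query_id <- sprintf("r%03d", seq_len(nrow(h)))  # all primary
  lens <- c(c1 = 20000, c2 = 20000)
  d <- per_contig_depth(h, lens)
  expect_equal(sum(d$mean_depth * d$length),
               sum(h$target_end - h$target_start))
})

test_that("organelle-depth flag needs both depth and homology", {
  depths <- data.frame(contig_id = c("a", "b", "c", "d"),
                       length = 1000, aligned_bases = 0,
                       mean_depth = c(27, 27, 27, 500),
                       stringsAsFactors = FALSE)
  org <- data.frame(query_id = "mito", target_id = "d", query_start = 0,
                    query_end = 900, target_start = 0, target_end = 900,
                    strand = "+", percent_identity = 95,
                    alignment_length = 900, score = 900,
                    source_tag = "mito", stringsAsFactors = FALSE)
  fl <- flag_depth_outliers(depths, org)
  expect_identical(fl$flag, c("pass", "pass", "pass", "organelle_depth"))
  fl2 <- flag_depth_outliers(depths, org[0, ])
  expect_true(all(fl2$flag == "pass"))  # depth alone is not sufficient
  expect_error(flag_depth_outliers(depths[1:2, ], org), ">= 3 contigs")
})

test_that("telomere scan counts terminal motif tracts on both strands", {
  set.seed(6)
  left <- paste0(strrep("TTTAGGG", 100L), random_dna_test(50000L))
  sc <- telomere_scan(left, "L")
  expect_gte(sc$left_count, 100L)
  expect_lte(sc$right_count, 5L)

  right <- paste0(random_dna_test(50000L), strrep("CCCTAAA", 100L))
  sc2 <- telomere_scan(right, "R")
  expect_gte(sc2$right_count, 100L)

  rand <- random_dna_test(100000L)
  sc3 <- telomere_scan(rand, "rand")
  expect_true(all(sc3$per_window_counts$forward <= 5L))
  expect_true(all(sc3$per_window_counts$reverse <= 5L))

  expect_warning(tiny <- telomere_scan("ACG", "tiny"), "shorter than motif")
  expect_identical(tiny$left_count, 0L)
})

test_that("completeness classification applies the copy threshold", {
  mk <- function(l, r) structure(list(left_count = l, right_count = r),
                                 class = "telomere_scan")
  expect_identical(classify_contig_completeness(mk(120, 130)),
                   "both_telomeres")
  expect_identical(classify_contig_completeness(mk(120, 3)), "left_only")
  expect_identical(classify_contig_completeness(mk(3, 120)), "right_only")
  expect_identical(classify_contig_completeness(mk(24, 24)), "none")
  expect_identical(classify_contig_completeness(mk(25, 3)), "left_only")
})

test_that("QC screens recover the planted truth on a small assembly", {
  cfg <- small_config(seed = 17L)
  org <- make_organelle_genomes(cfg)
  asm <- make_nuclear_assembly(cfg, org)
  reads <- simulate_long_reads(asm$contigs, org$plastome, org$mitome, cfg)
  # organelle homology hits constructed from the organelle contigs' identity
  org_hits <- data.frame(
    query_id = c("plastome", "mitome"), target_id = c("orgP", "orgM"),
    query_start = 0, query_end = c(cfg$plastome_length, cfg$mitome_length),
    target_start = 0, target_end = c(cfg$plastome_length, cfg$mitome_length),
    strand = "+", percent_identity = 100,
    alignment_length = c(cfg$plastome_length, cfg$mitome_length),
    score = 1, source_tag = c("plastid", "mito"), stringsAsFactors = FALSE)
  qc <- run_contig_qc(asm$contigs, reads_to_alignments(reads), org_hits)
  truth <- asm$truth
  rep_ids <- truth$contig_id[truth$feature_type == "repeat_only_contig"]
  org_ids <- truth$contig_id[truth$feature_type == "organelle_contig"]
  lc <- qc$entropy
  expect_setequal(lc$contig_id[lc$flag == "low_complexity"], rep_ids)
  dp <- qc$depth
  expect_setequal(dp$contig_id[dp$flag == "organelle_depth"], org_ids)
  # telomere classes match the plan for the regular nuclear contigs
  plan <- rep_len(cfg$telomere_plan, cfg$n_contigs)
  want <- c(both = "both_telomeres", left = "left_only",
            right = "right_only", none = "none")[plan]
  got <- qc$telomeres$completeness[match(sprintf("ctg%02d",
                                                 seq_len(cfg$n_contigs)),
                                         qc$telomeres$contig_id)]
  expect_identical(unname(got), unname(want))
})
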