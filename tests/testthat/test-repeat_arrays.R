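# Independent brute-force tandem-run scanner: for every period, walk the
# sequence position by position, extend exact matches, and record maximal
# runs. Quadratic and only for short oracle sequences.
brute_tandem <- function(seq, min_period = 1L, max_period = 50L,
                         min_copies = 5L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  runs <- list()
  for (p in min_period:min(max_period, n %/% min_copies)) {
    i <- 1L
    while (i + p <= n) {
      if (ch[i] == ch[i + p]) {
        j <- i
        while (j + p <= n && ch[j] == ch[j + p]) j <- j + 1L
        total <- (j - i) + p
        if (total / p >= min_copies) {
          runs[[length(runs) + 1L]] <- c(start = i - 1L, end = i - 1L + total,
                                         period = p)
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(runs)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      period = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, runs))
  df[order(df$period, df$start), ]
}

test_that("tandem detector finds planted runs with smallest period", {
  set.seed(101)
  s <- paste0(random_dna_test(200L), strrep("ACG", 10L),
              random_dna_test(200L))
  runs <- detect_tandem_runs(s, min_period = 3L, max_period = 50L,
                             min_copies = 6L)
  main <- runs[which.max(runs$copy_number), ]
  expect_equal(main$period, 3)
  expect_lt(abs(main$copy_number - 10), 1)

  homo <- detect_tandem_runs(strrep("A", 50L))
  expect_equal(homo$period, 1)
  expect_equal(homo$copy_number, 50)
})

test_that("random sequence yields no long-period high-copy runs", {
  set.seed(8)
  s <- random_dna_test(10000L)
  runs <- detect_tandem_runs(s, min_period = 1L, max_period = 500L,
                             min_copies = 5L)
  expect_false(any(runs$period >= 10 & runs$copy_number >= 5))
})

test_that("detector covers the same runs as the brute-force scanner", {
  set.seed(64)
  for (trial in 1:5) {
    s <- paste0(random_dna_test(400L), strrep(random_dna_test(7L), 12L),
                random_dna_test(400L), strrep("AT", 20L),
                random_dna_test(300L))
    got <- detect_tandem_runs(s, min_period = 1L, max_period = 40L,
                              min_copies = 5L)
    want <- brute_tandem(s, 1L, 40L, 5L)
    # every selected run is a maximal brute-force run at its period...
    for (i in seq_len(nrow(got))) {
      hit <- want[want$period == got$period[i] &
                    want$start == got$start[i] & want$end == got$end[i], ]
      expect_identical(nrow(hit), 1L)
    }
    # ...and every brute-force region is covered by some selected run
    for (i in seq_len(nrow(want))) {
      cover <- got[got$start < want$end[i] & got$end > want$start[i], ]
      expect_gte(nrow(cover), 1L)
    }
  }
})

mk_rdna_hits <- function(unit_lens, contig = "c1", origin = 0L,
                         genes = c("18S", "5.8S", "26S"),
                         offsets = list(c(500, 2300), c(2500, 2660),
                                        c(2900, 6300))) {
  starts <- origin + cumsum(c(0, utils::head(unit_lens, -1L)))
  do.call(rbind, lapply(seq_along(genes), function(g) {
    data.frame(contig_id = contig, start = starts + offsets[[g]][1L],
               end = starts + offsets[[g]][2L], strand = "+",
               gene = genes[[g]], identity = 100, stringsAsFactors = FALSE)
  }))
}

test_that("gene hits cluster into arrays split at large gaps", {
  h1 <- mk_rdna_hits(rep(11400L, 30L))
  cl <- cluster_gene_hits_into_arrays(h1)
  expect_identical(nrow(cl$arrays), 1L)
  expect_identical(cl$arrays$n_hits, 90L)
  expect_identical(cl$arrays$kind, "array")

  h2 <- rbind(h1, mk_rdna_hits(rep(11400L, 5L), origin = 2e6))
  cl2 <- cluster_gene_hits_into_arrays(h2)
  expect_identical(nrow(cl2$arrays), 2L)

  cl0 <- cluster_gene_hits_into_arrays(h1[0, ])
  expect_identical(nrow(cl0$arrays), 0L)

  # a lone gene fragment is a cluster, not an array
  cl1 <- cluster_gene_hits_into_arrays(h1[1, ])
  expect_identical(cl1$arrays$kind, "cluster")
})

test_that("clustering is permutation-invariant and idempotent", {
  set.seed(2)
  h <- mk_rdna_hits(sample(c(11400L, 13700L), 20L, replace = TRUE))
  a <- cluster_gene_hits_into_arrays(h)
  b <- cluster_gene_hits_into_arrays(h[sample.int(nrow(h)), ])
  expect_equal(a$arrays, b$arrays)
  again <- cluster_gene_hits_into_arrays(a$hits[, names(h)])
  expect_equal(again$arrays, a$arrays)
})

test_that("unit-length estimation recovers planted unit modes", {
  uni <- mk_rdna_hits(rep(11400L, 30L))
  est <- estimate_unit_length(uni)
  expect_identical(length(est$modes), 1L)
  expect_lt(abs(est$modes - 11400), 100)

  set.seed(30)
  lens <- sample(rep(c(11400L, 13700L), each = 15L))
  bim <- mk_rdna_hits(lens)
  est2 <- estimate_unit_length(bim)
  expect_identical(length(est2$modes), 2L)
  expect_lt(abs(est2$modes[1] - 11400), 100)
  expect_lt(abs(est2$modes[2] - 13700), 100)

  two <- mk_rdna_hits(c(11400L, 11400L))[c(1, 2), ]  # two 18S hits only
  est3 <- estimate_unit_length(two)
  expect_identical(length(est3$samples), 1L)
  expect_equal(est3$modes, 11400)

  one <- mk_rdna_hits(11400L)
  expect_identical(length(estimate_unit_length(one)$modes), 0L)
})

test_that("unit estimation hits planted lengths across many seeded arrays", {
  for (seed in 1:50) {
    set.seed(seed)
    true_len <- sample(8000:15000, 1L)
    copies <- sample(5:40, 1L)
    est <- estimate_unit_length(mk_rdna_hits(rep(true_len, copies)))
    expect_lte(abs(est$modes[[1L]] - true_len), 100)
  }
})

test_that("unit counting reports per-gene counts with min and max", {
  h <- mk_rdna_hits(rep(11400L, 30L))
  cu <- count_units(h)
  expect_identical(cu$copy_count, 30L)
  # one extra 18S fragment without its 26S partner
  h2 <- rbind(h, data.frame(contig_id = "c1", start = 400000, end = 401800,
                            strand = "+", gene = "18S", identity = 100))
  cu2 <- count_units(h2)
  expect_identical(cu2$copy_count, 31L)
  expect_identical(unname(cu2$per_gene[["18S"]]), 31L)
  expect_identical(unname(cu2$per_gene[["26S"]]), 30L)
  expect_identical(cu2$min_count, 30L)
  expect_identical(cu2$max_count, 31L)
  expect_error(count_units(h[0, ]), "empty")
})

test_that("5S/35S arrangement classification covers S, L and mixed", {
  arr <- cluster_gene_hits_into_arrays(mk_rdna_hits(rep(11400L, 10L)))
  far <- data.frame(contig_id = "c9", start = 0, end = 120)
  expect_identical(classify_rdna_arrangement(arr, far)$genome_call, "S_type")

  starts_18s <- sort(arr$hits$start[arr$hits$gene == "18S"])
  near <- data.frame(contig_id = "c1", start = starts_18s + 7000,
                     end = starts_18s + 7120)
  expect_identical(classify_rdna_arrangement(arr, near)$genome_call,
                   "L_type")

  two <- cluster_gene_hits_into_arrays(
    rbind(mk_rdna_hits(rep(11400L, 10L)),
          mk_rdna_hits(rep(11400L, 10L), contig = "c2")))
  near1 <- near  # linked on c1 only
  out <- classify_rdna_arrangement(two, near1)
  expect_identical(out$genome_call, "mixed")

  none <- cluster_gene_hits_into_arrays(mk_rdna_hits(rep(11400L, 1L)))
  expect_identical(classify_rdna_arrangement(none, far)$genome_call, "na")
})

test_that("planted rDNA truth rows expand to the expected gene hits", {
  cfg <- small_config(seed = 3L, rdna_copies = 8L, rdna_unit_length = 7000L,
                      contig_length = 80000L)
  asm <- make_nuclear_assembly(cfg, make_organelle_genomes(cfg))
  row <- asm$truth[asm$truth$feature_type == "rdna_array", ]
  hits <- rdna_truth_to_hits(row)
  expect_identical(nrow(hits), 8L * 3L)
  expect_true(all(hits$start >= row$start & hits$end <= row$end))
  cl <- cluster_gene_hits_into_arrays(hits)
  expect_identical(count_units(cl$hits)$copy_count, 8L)
})
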