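cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(n_per_class = 3, seed = 11, depth_scale = 0.6)
      bl <- build_loci(co$alignments, co$contig_lengths, min_cov = 18,
                       merge_window = 500)
      cache <<- list(co = co, bl = bl)
    }
    cache
  }
})

test_that("piRNA selection needs length over 1 kb plus a ping-pong pair", {
  fx <- cohort_fixture()
  co <- fx$co; bl <- fx$bl
  sel <- select_pirna_loci(bl$loci, co$alignments, bl$assignment)
  matched <- match_truth(sel, co$truth)
  cls <- co$truth$class[match(matched, co$truth$locus_id)]
  # every ping-pong locus qualifies; miRNA loci are far too short
  pp_ids <- co$truth$locus_id[co$truth$class == "pingpong_piRNA"]
  expect_true(all(pp_ids %in% matched))
  expect_false(any(cls == "miRNA"))
  expect_true(all(sel$end - sel$start > 1000))
  expect_true(all(sel$pp_pair_count >= 1))
  # the optional z threshold removes chance-overlap (debris) loci
  sel_z <- select_pirna_loci(bl$loci, co$alignments, bl$assignment,
                             min_pp_z = 2)
  cls_z <- co$truth$class[match(match_truth(sel_z, co$truth),
                                co$truth$locus_id)]
  expect_false(any(cls_z == "debris"))
  expect_true(all(pp_ids %in% match_truth(sel_z, co$truth)))
})

test_that("short or pair-less loci are rejected by the selection rule", {
  g <- make_genome(1, 2e4, 0.4, 40)
  # 800-nt ping-pong locus: has o=10 pairs but is too short
  sim <- simulate_pingpong_locus(g, "contig_1", 2000, span_len = 1000,
                                 depth = 400, seed = 100)
  loci <- data.frame(contig = "contig_1", start = 2100L, end = 2900L,
                     locus_id = "locus_0001", stringsAsFactors = FALSE)
  aln <- sim$alignments[sim$alignments$start >= 2100 &
                          sim$alignments$end <= 2900, ]
  expect_equal(nrow(select_pirna_loci(loci, aln,
                                      rep("locus_0001", nrow(aln)))), 0L)
  # long debris locus without any exact 10-nt overlap pair
  de <- simulate_debris(g, "contig_1", 10000, span_len = 5000,
                        depth = 80, seed = 101)
  h <- overlap_histogram(de$alignments)
  loci2 <- data.frame(contig = "contig_1", start = 10000L, end = 15000L,
                      locus_id = "locus_0002", stringsAsFactors = FALSE)
  got <- select_pirna_loci(loci2, de$alignments,
                           rep("locus_0002", nrow(de$alignments)))
  expect_equal(nrow(got), as.integer(h$counts["10"] >= 1))
})

test_that("strand classes split at 5x and 10x ratios", {
  expect_equal(strand_class(100, 30)$strand_class, "no_bias")
  expect_equal(strand_class(700, 100)$strand_class, "strand_bias")
  expect_equal(strand_class(1000, 0)$strand_class, "unistrand")
  # boundary ratios belong to strand_bias
  expect_equal(strand_class(500, 100)$strand_class, "strand_bias")
  expect_equal(strand_class(1000, 100)$strand_class, "strand_bias")
  expect_equal(strand_class(1001, 100)$strand_class, "unistrand")
  expect_equal(strand_class(499, 100)$strand_class, "no_bias")
  expect_error(strand_class(0, 0), "reads")
})

test_that("genomic context distinguishes intergenic, genic and intronic", {
  ann <- list(
    genes = data.frame(contig = "c", start = 1000L, end = 9000L,
                       strand = "+", gene_id = "g1"),
    exons = data.frame(contig = "c", start = c(1000L, 6000L),
                       end = c(4000L, 9000L), strand = "+",
                       gene_id = "g1"),
    introns = data.frame(contig = "c", start = 4000L, end = 6000L,
                         strand = "+", gene_id = "g1")
  )
  loci <- data.frame(contig = "c",
                     start = c(4500L, 3900L, 20000L, 1500L),
                     end = c(5500L, 4500L, 21000L, 8500L))
  expect_equal(genomic_context(loci, ann),
               c("intronic", "genic", "intergenic", "genic"))
})

test_that("taxonomy separates repeat peaks from dispersed piRNA loci", {
  g <- make_genome(1, 3e4, 0.4, 41)
  rp <- simulate_repeat_peak_locus(g, "contig_1", 2000, n_peaks = 5,
                                   peak_depth = 100, seed = 110)
  llen <- rp$truth$end - rp$truth$start
  tx <- taxonomy(rp$alignments, llen)
  expect_equal(tx$taxonomy, "non_arthropod")
  expect_equal(tx$pci, 1.0)

  pp <- simulate_pingpong_locus(g, "contig_1", 10000, span_len = 3000,
                                depth = 600, seed = 111)
  tx2 <- taxonomy(pp$alignments, 3000)
  expect_equal(tx2$taxonomy, "arthropod_like")
  expect_lt(tx2$pci, 0.8)

  # low-depth loci default to arthropod_like with a flag
  tx3 <- taxonomy(pp$alignments[1:10, ], 3000)
  expect_true(tx3$low_depth)
  expect_equal(tx3$taxonomy, "arthropod_like")
})

test_that("repeat typing reads sequence identity and strandedness", {
  g <- make_genome(1, 3e4, 0.4, 42)
  rp <- simulate_repeat_peak_locus(g, "contig_1", 2000, n_peaks = 5,
                                   peak_depth = 100, seed = 120)
  rt <- repeat_typing(rp$alignments, "non_arthropod")
  expect_equal(rt$repeat_type, "single_read_repeat")
  expect_equal(rt$repeat_strandedness, "single_strand")

  # five peaks with five distinct sequences on both strands
  starts <- c(100L, 400L, 700L, 1000L, 1300L)
  aln <- alignment_table("c", rep(starts, each = 20),
                         rep(starts, each = 20) + 28L,
                         rep(c("+", "-"), 50),
                         rep(vapply(1:5, function(i) paste(
                           rep(c("A", "C", "G", "T", "A")[i], 28),
                           collapse = ""), character(1)), each = 20),
                         1L, 1L)
  rt2 <- repeat_typing(aln, "non_arthropod")
  expect_equal(rt2$repeat_type, "multi_read_motif")
  expect_equal(rt2$repeat_strandedness, "dual_strand")

  expect_equal(repeat_typing(aln, "arthropod_like"),
               list(repeat_type = "none", repeat_strandedness = "na"))
})

test_that("size class and unique-hit support use strict boundaries", {
  expect_equal(size_class(c(2551, 2550, 100)),
               c("gt_2550", "le_2550", "le_2550"))
  aln <- alignment_table("c", c(0L, 30L), c(20L, 50L), "+", NA,
                         c(2L, 3L), 1L)
  expect_false(has_unique_hits(aln))
  aln$n_hits[1] <- 1L
  expect_true(has_unique_hits(aln))
})

test_that("the piRNA report fills every categorical axis exactly once", {
  fx <- cohort_fixture()
  co <- fx$co; bl <- fx$bl
  rep_df <- classify_pirna_loci(bl$loci, co$alignments, bl$assignment,
                                co$annotations)
  with_reads <- rep_df[!is.na(rep_df$taxonomy), ]
  expect_gt(nrow(with_reads), 0)
  expect_true(all(with_reads$taxonomy %in%
                    c("arthropod_like", "non_arthropod")))
  expect_true(all(with_reads$strand_class %in%
                    c("no_bias", "strand_bias", "unistrand")))
  expect_true(all(with_reads$context %in%
                    c("intergenic", "genic", "intronic")))
  expect_true(all(with_reads$size_class %in% c("gt_2550", "le_2550")))
  expect_true(all(with_reads$repeat_type %in%
                    c("single_read_repeat", "multi_read_motif", "none")))
  # expected labels recovered on this small cohort
  matched <- match_truth(with_reads, co$truth)
  tr <- co$truth[match(matched, co$truth$locus_id), ]
  big <- !is.na(matched) & (with_reads$end - with_reads$start) > 1000
  expect_true(mean(with_reads$strand_class[big] ==
                     tr$expected_strand_class[big]) >= 0.9)
  expect_true(all(with_reads$context[big] == tr$expected_context[big]))
})

test_that("perfect re-mapping of repeat reads preserves non-arthropod calls", {
  g <- make_genome(1, 3e4, 0.4, 43)
  rp <- simulate_repeat_peak_locus(g, "contig_1", 2000, n_peaks = 6,
                                   peak_depth = 80, seed = 130)
  aln <- rp$alignments
  # enforce 0-mismatch re-mapping: keep reads equal to the genome slice
  ref <- as.character(Biostrings::extractAt(
    rp$genome[[1]], IRanges::IRanges(aln$start + 1L, aln$end)))
  minus <- aln$strand == "-"
  ref[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ref[minus])))
  keep <- aln$seq == ref
  expect_true(all(keep))                      # generator is error-free
  tx <- taxonomy(aln[keep, ], rp$truth$end - rp$truth$start)
  expect_equal(tx$taxonomy, "non_arthropod")
})
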