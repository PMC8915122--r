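test_that("genome generation is seeded and honors GC content", {
  g1 <- make_genome(1, 1e5, 0.4, 7)
  g2 <- make_genome(1, 1e5, 0.4, 7)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  comp <- Biostrings::alphabetFrequency(g1[[1]], baseOnly = TRUE)
  gc <- (comp["C"] + comp["G"]) / sum(comp)
  expect_lt(abs(gc - 0.4), 0.01)          # binomial bound at n = 1e5

  gall <- make_genome(1, 1e4, 1.0, 3)
  compall <- Biostrings::alphabetFrequency(gall[[1]], baseOnly = TRUE)
  expect_equal(unname(compall["A"] + compall["T"]), 0)
})

test_that("simulators are deterministic given a seed", {
  g <- make_genome(1, 2e4, 0.4, 1)
  a <- simulate_pingpong_locus(g, "contig_1", 2000, seed = 9)
  b <- simulate_pingpong_locus(g, "contig_1", 2000, seed = 9)
  expect_identical(a$alignments, b$alignments)
  expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
  d <- simulate_pingpong_locus(g, "contig_1", 2000, seed = 10)
  expect_false(identical(a$alignments, d$alignments))
})

test_that("miRNA simulator builds a 2-nt-overhang hairpin with precise 5' ends", {
  g <- make_genome(1, 2e4, 0.4, 2)
  sim <- simulate_mirna_locus(g, "contig_1", 5000, arm_len = 22,
                              precision_5p = 1.0, depth = 100, seed = 4)
  tr <- sim$truth
  mature <- sim$alignments[sim$alignments$start >= tr$mature_start - 1 &
                             sim$alignments$start < tr$mature_end, ]
  mat_only <- sim$alignments[five_prime(sim$alignments) == tr$mature_start, ]
  expect_equal(nrow(mat_only), 100L)      # precision 1 -> single 5' base
  ov <- duplex_overhangs(c(tr$mature_start, tr$mature_end),
                         c(tr$star_start, tr$star_end),
                         c(tr$start, tr$end), tr$strand)
  expect_equal(unname(ov), c(2, 2))
  # read sequences equal the genome slice
  i <- which(sim$alignments$strand == "+")[1]
  expect_equal(sim$alignments$seq[i], as.character(Biostrings::extractAt(
    sim$genome[[1]],
    IRanges::IRanges(sim$alignments$start[i] + 1L, sim$alignments$end[i]))))
})

test_that("short-loop hairpins written by the miRNA simulator are detectable", {
  g <- make_genome(1, 2e4, 0.4, 21)
  sim <- simulate_mirna_locus(g, "contig_1", 5000, arm_len = 22,
                              loop_len = 4, seed = 31)
  tr <- sim$truth
  prec <- as.character(Biostrings::extractAt(
    sim$genome[[1]], IRanges::IRanges(tr$start + 1L, tr$end)))
  hits <- short_loop_scan(prec, min_stem = 22, loop_sizes = c(3, 4))
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$loop_len == 4 & hits$stem_len >= 22))
})

test_that("ping-pong simulator gives every pair an exact 10-nt overlap", {
  g <- make_genome(1, 2e4, 0.4, 5)
  sim <- simulate_pingpong_locus(g, "contig_1", 2000, span_len = 5000,
                                 depth = 200, pingpong_fraction = 1.0,
                                 seed = 6)
  aln <- sim$alignments
  plus <- aln[aln$strand == "+", ]
  minus <- aln[aln$strand == "-", ]
  # every plus read has a partner whose 5' end overlaps by exactly 10
  expect_true(all(plus$start %in% (minus$end - 10L)))
  expect_true(all((minus$end - 10L) %in% plus$start))
})

test_that("ping-pong fraction zero leaves only uniform background", {
  g <- make_genome(1, 2e4, 0.4, 5)
  sim <- simulate_pingpong_locus(g, "contig_1", 2000, span_len = 5000,
                                 depth = 500, pingpong_fraction = 0,
                                 seed = 7)
  h <- overlap_histogram(sim$alignments)
  expect_lt(h$z["10"], 3)
})

test_that("phased simulator lays head-to-tail trains with the requested gap", {
  g <- make_genome(1, 2e4, 0.4, 8)
  sim <- simulate_phased_locus(g, "contig_1", 2000, span_len = 3000,
                               depth = 800, read_len = 30, gap = 1,
                               u1_bias = 0.9, seed = 12)
  fp <- sort(unique(five_prime(sim$alignments)))
  # gap 1 = next read starts at the following base: 5' starts step by 30
  expect_true(all(diff(fp) == 30L))
  # the U draw is per train position, so score one read per position
  pos_reads <- sim$alignments[!duplicated(five_prime(sim$alignments)), ]
  u1 <- first_base_bias(pos_reads)
  half <- 1.96 * sqrt(0.9 * 0.1 / nrow(pos_reads))
  expect_lt(abs(u1 - 0.9), half + 1e-9)

  gap3 <- simulate_phased_locus(g, "contig_1", 8000, span_len = 3000,
                                depth = 500, read_len = 28, gap = 3,
                                seed = 13)
  fp3 <- sort(unique(five_prime(gap3$alignments)))
  expect_true(all(diff(fp3) == 30L))             # read_len + gap - 1
})

test_that("phased U profile peaks again at the next read's first base", {
  g <- make_genome(1, 3e4, 0.4, 9)
  sim <- simulate_phased_locus(g, "contig_1", 2000, span_len = 6000,
                               depth = 2000, read_len = 30, gap = 1,
                               u1_bias = 0.8, seed = 14)
  ph <- phasing_stats(sim$alignments, genome = sim$genome, window = 35)
  expect_equal(unname(which.max(ph$u_profile[2:35])) + 1L, 31L)
  expect_gte(ph$u_profile[1], 0.75)
})

test_that("repeat-peak simulator stacks reads at n identical positions", {
  g <- make_genome(1, 2e4, 0.4, 10)
  sim <- simulate_repeat_peak_locus(g, "contig_1", 2000, n_peaks = 5,
                                    peak_depth = 100, seed = 15)
  aln <- sim$alignments
  expect_equal(length(unique(five_prime(aln))), 5L)
  expect_equal(length(unique(aln$seq)), 1L)      # tandem units identical
  tx <- taxonomy(aln, sim$truth$end - sim$truth$start)
  expect_equal(tx$pci, 1.0)
  # peaks are spaced a full unit apart: no phasing signal at small d
  ph <- phasing_stats(aln)
  expect_true(all(is.na(ph$z)) || max(ph$z, na.rm = TRUE) < 2)
})

test_that("debris reads are short and unstructured", {
  g <- make_genome(1, 2e4, 0.4, 11)
  sim <- simulate_debris(g, "contig_1", 2000, depth = 800, seed = 16)
  expect_true(all(read_length(sim$alignments) <= 20L))
  # 1U tracks the genome T frequency (~30% at GC 0.4)
  u1 <- first_base_bias(sim$alignments)
  expect_lt(abs(u1 - 0.3), 0.06)
})

test_that("siRNA ladder geometry is phased duplexes with 2-nt overhangs", {
  g <- make_genome(1, 2e4, 0.4, 12)
  sim <- simulate_sirna_ladder(g, "contig_1", 2000, n_duplexes = 10,
                               read_len = 21, depth_per_duplex = 5,
                               seed = 17)
  aln <- sim$alignments
  plus_fp <- sort(unique(five_prime(aln[aln$strand == "+", ])))
  minus_fp <- sort(unique(five_prime(aln[aln$strand == "-", ])))
  expect_true(all(diff(plus_fp) == 21L))
  expect_equal(minus_fp - plus_fp, rep(18L, 10))  # o = 19 => fp gap 18
})

test_that("cohort loci are separated, labeled, and annotated consistently", {
  co <- simulate_cohort(n_per_class = 2, seed = 5, depth_scale = 0.3)
  tr <- co$truth
  ord <- order(tr$start)
  gaps <- tr$start[ord][-1] - tr$end[ord][-nrow(tr)]
  expect_true(all(gaps > 500))
  expect_equal(sort(unique(tr$class)),
               sort(c("miRNA", "pingpong_piRNA", "phased_piRNA",
                      "repeat_peak_piRNA", "debris")))
  # GFF3 round trip reproduces the gene models and introns
  gff <- tempfile(fileext = ".gff3")
  write_annotations_gff3(co$annotations, gff)
  back <- load_annotations(gff)
  expect_equal(back$genes[, c("start", "end")],
               co$annotations$genes[, c("start", "end")],
               ignore_attr = TRUE)
  expect_equal(nrow(back$introns), nrow(co$annotations$introns))
  # intronic-context loci sit inside an intron of the paired gene
  itr <- tr[tr$expected_context == "intronic", ]
  for (i in seq_len(nrow(itr))) {
    expect_true(any(back$introns$start <= itr$start[i] &
                      back$introns$end >= itr$end[i]))
  }
})
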