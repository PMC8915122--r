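test_that("duplex overhangs follow the antiparallel pairing geometry", {
  # mature [100,122), star [140,162) in precursor [98,162): 2-nt overhangs
  expect_equal(unname(duplex_overhangs(c(100, 122), c(140, 162),
                                       c(98, 162))), c(2, 2))
  # blunt duplex: arms flush with the pairing register
  expect_equal(unname(duplex_overhangs(c(100, 122), c(140, 162),
                                       c(100, 162))), c(0, 0))
  # asymmetric: mature shifted one base inward
  expect_equal(unname(duplex_overhangs(c(101, 123), c(140, 162),
                                       c(98, 162))), c(3, 3))
  # strand flip leaves the generator geometry intact
  g <- make_genome(1, 2e4, 0.4, 30)
  sim <- simulate_mirna_locus(g, "contig_1", 3000, strand = "-", seed = 60)
  tr <- sim$truth
  expect_equal(unname(duplex_overhangs(
    c(tr$mature_start, tr$mature_end), c(tr$star_start, tr$star_end),
    c(tr$start, tr$end), "-")), c(2, 2))
  expect_error(duplex_overhangs(c(100, 130), c(120, 150), c(90, 160)),
               "overlap")
})

test_that("five_prime_precision is the modal 5' share", {
  expect_equal(five_prime_precision(c(`100` = 95, `101` = 5)), 0.95)
  expect_equal(five_prime_precision(rep(25, 4)), 0.25)
  expect_true(is.na(five_prime_precision(numeric(0))))
})

test_that("simulated 5' precision is recovered within a binomial bound", {
  g <- make_genome(1, 2e4, 0.4, 31)
  sim <- simulate_mirna_locus(g, "contig_1", 3000, precision_5p = 0.95,
                              depth = 400, seed = 61)
  tr <- sim$truth
  pile <- arm_pileup(sim$alignments, tr$contig, tr$mature_start,
                     tr$mature_end, tr$strand, slop = 2L)
  est <- five_prime_precision(pile)
  expect_lt(abs(est - 0.95), 1.96 * sqrt(0.95 * 0.05 / 400) + 1e-9)
})

test_that("classify_mirna reproduces the triage rule at all boundaries", {
  cases <- expand.grid(oh = c(2, 1), prec = c(0.90, 0.901),
                       star = c(8, 9))
  expected <- function(oh_ok, p_ok, star) {
    if (oh_ok && p_ok) {
      if (star >= 9) "confident" else "candidate"
    } else if (oh_ok || p_ok) "candidate" else "false_positive"
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    v <- classify_mirna(c(cs$oh, 2), cs$prec, cs$star)
    expect_equal(v$label,
                 expected(cs$oh == 2, cs$prec > 0.90, cs$star),
                 info = paste(cs, collapse = "/"))
  }
  # precision threshold is strict, star threshold means "exceed eight"
  expect_equal(classify_mirna(c(2, 2), 0.95, 20)$label, "confident")
  expect_equal(classify_mirna(c(2, 2), 0.95, 5)$label, "candidate")
  expect_equal(classify_mirna(c(1, 3), 0.4, 50)$label, "false_positive")
  expect_error(classify_mirna(c(2, 2), NA, 10), "pileup")
})

test_that("curate_hairpins recovers labels on simulated hairpins", {
  g <- make_genome(1, 1e5, 0.4, 32)
  cand <- list(); aln <- list(); want <- character()
  specs <- list(
    list(precision = 0.97, star_frac = 0.2, label = "confident"),
    list(precision = 0.97, star_frac = 0.01, label = "candidate"),
    list(precision = 0.5, star_frac = 0.2, label = "candidate"),
    list(precision = 0.97, star_frac = 0.2, label = "confident"),
    list(precision = 0.5, star_frac = 0.2, label = "candidate")
  )
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    sim <- simulate_mirna_locus(g, "contig_1", 3000 + i * 2000,
                                precision_5p = s$precision, depth = 400,
                                star_frac = s$star_frac, seed = 70 + i)
    g <- sim$genome
    tr <- sim$truth
    cand[[i]] <- data.frame(
      contig = tr$contig, precursor_start = tr$start,
      precursor_end = tr$end, strand = tr$strand,
      mature_start = tr$mature_start, mature_end = tr$mature_end,
      star_start = tr$star_start, star_end = tr$star_end,
      stringsAsFactors = FALSE)
    aln[[i]] <- sim$alignments
    want[i] <- s$label
  }
  verdicts <- curate_hairpins(do.call(rbind, cand), do.call(rbind, aln))
  expect_equal(verdicts$label, want)
  expect_true(all(verdicts$overhang_5p == 2 & verdicts$overhang_3p == 2))
})

test_that("a shifted star annotation breaks the overhang criterion", {
  g <- make_genome(1, 2e4, 0.4, 33)
  sim <- simulate_mirna_locus(g, "contig_1", 3000, precision_5p = 0.5,
                              depth = 200, seed = 80)
  tr <- sim$truth
  cand <- data.frame(contig = tr$contig, precursor_start = tr$start,
                     precursor_end = tr$end, strand = tr$strand,
                     mature_start = tr$mature_start,
                     mature_end = tr$mature_end,
                     star_start = tr$star_start - 1,
                     star_end = tr$star_end - 1, stringsAsFactors = FALSE)
  v <- curate_hairpins(cand, sim$alignments)
  expect_false(v$overhang_ok)          # overhangs shift to (1, 1)
  expect_equal(v$label, "false_positive")
})

test_that("short_loop_scan finds exact constructed hairpins", {
  set.seed(90)
  S <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(S)))
  seq <- paste0(S, "GAAA", rc)
  hits <- short_loop_scan(seq, min_stem = 22)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$loop_len, 4L)
  expect_gte(hits$stem_len, 22L)
  # one stem mismatch kills a full-length hit
  broken <- seq
  substr(broken, 5, 5) <- chartr("ACGT", "GTAC", substr(seq, 5, 5))
  expect_equal(nrow(short_loop_scan(broken, min_stem = 22)), 0L)
  # U input and three-base loops work
  sequ <- chartr("T", "U", paste0(S, "GAA", rc))
  expect_equal(short_loop_scan(sequ, min_stem = 22)$loop_len, 3L)
})

test_that("short_loop_scan matches the exhaustive oracle on random sequence", {
  set.seed(91)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    expect_equal(short_loop_scan(seq, min_stem = 3),
                 oracle_short_loops(seq, min_stem = 3),
                 ignore_attr = TRUE)
  }
})

test_that("miRNA quantification normalizes per library", {
  g <- make_genome(1, 2e4, 0.4, 34)
  sim <- simulate_mirna_locus(g, "contig_1", 3000, depth = 300, seed = 95)
  tr <- sim$truth
  cand <- data.frame(contig = tr$contig, precursor_start = tr$start,
                     precursor_end = tr$end, strand = tr$strand,
                     mature_start = tr$mature_start,
                     mature_end = tr$mature_end,
                     star_start = tr$star_start, star_end = tr$star_end,
                     stringsAsFactors = FALSE)
  libs <- list(a = sim$alignments, b = sim$alignments[0, ])
  q <- quantify_mirna(cand, libs, mapped_totals = c(a = 1e6, b = 1e6))
  expect_equal(unname(q$rpm[1, "a"]), sum(arm_pileup(
    sim$alignments, tr$contig, tr$mature_start, tr$mature_end,
    tr$strand)))
  expect_equal(unname(q$log2_rpm[1, "b"]), 0)
  expect_lte(sum(q$rpm[, "a"]), 1e6)
})
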