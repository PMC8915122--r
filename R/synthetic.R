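#' @title Synthetic small RNA data generator
#' @description
#' Deterministic simulators for every locus class the analysis handles:
#' miRNA hairpins with precise 5' ends and 2-nt 3'-overhang duplexes,
#' ping-pong piRNA loci (exact 10-nt 5'-5' opposite-strand overlaps),
#' phased piRNA trains (head-to-tail 1U reads), repeat-peak loci where all
#' reads stack at a few identical positions, processively diced siRNA
#' ladders, and degradation debris. Each simulator writes the required
#' sequence features into the genome, emits an alignment table whose
#' sequences match the (edited) genome, and records its generative
#' parameters in a truth row so downstream tests can assert recovery
#' without hard-coded constants.
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random genome
#'
#' Bases are i.i.d. with the requested GC content; identical seeds give
#' byte-identical sequences.
#'
#' @param n_contigs number of contigs (`contig_1` ...).
#' @param contig_len length of each contig in nt (>= 10000).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A [Biostrings::DNAStringSet] of `n_contigs` sequences.
#' @export
make_genome <- function(n_contigs = 1L, contig_len = 1e5, gc = 0.4,
                        seed = 1L) {
  stopifnot(contig_len >= 10000, gc >= 0, gc <= 1)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) rand_dna(contig_len, gc),
                   character(1))
    gen <- Biostrings::DNAStringSet(seqs)
    names(gen) <- paste0("contig_", seq_len(n_contigs))
    gen
  })
}

#' Write a genome to FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# replace genome[contig][start, start+nchar(s)) (0-based) with s
edit_genome <- function(genome, contig, start, s) {
  x <- genome[[contig]]
  Biostrings::subseq(x, start + 1L, start + nchar(s)) <- Biostrings::DNAString(s)
  genome[[contig]] <- x
  genome
}

genome_base <- function(genome, contig, pos) {
  as.character(Biostrings::extractAt(
    genome[[contig]], IRanges::IRanges(pos + 1L, pos + 1L)))
}

# set single bases at 0-based positions to `base` with probability p, else
# to a random base different from `base`; duplicate positions keep the
# first draw
edit_biased_base <- function(genome, contig, pos, base, p) {
  hit <- stats::runif(length(pos)) < p
  others <- setdiff(c("A", "C", "G", "T"), base)
  new <- ifelse(hit, base, sample(others, length(pos), replace = TRUE))
  keep <- !duplicated(pos)
  pos <- pos[keep]; new <- new[keep]
  x <- genome[[contig]]
  genome[[contig]] <- Biostrings::replaceAt(
    x, IRanges::IRanges(pos + 1L, pos + 1L), Biostrings::DNAStringSet(new))
  genome
}

# build alignment rows with sequences extracted from the genome
reads_from_genome <- function(genome, contig, start, end, strand,
                              n_hits = 1L, count = 1L) {
  seqs <- as.character(Biostrings::extractAt(
    genome[[contig]], IRanges::IRanges(start + 1L, end)))
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  alignment_table(contig = contig, start = start, end = end, strand = strand,
                  seq = seqs, n_hits = n_hits, count = count)
}

truth_row <- function(class, contig, start, end, strand, depth, seed, ...) {
  extra <- list(...)
  base <- data.frame(
    locus_id = NA_character_, class = class, contig = contig,
    start = start, end = end, strand = strand, depth = depth,
    seed = seed, stringsAsFactors = FALSE
  )
  fields <- c("read_len", "read_len_min", "read_len_max", "u1_bias",
              "a10_bias", "pingpong_fraction", "phase_gap", "n_peaks",
              "peak_depth", "precision_5p", "star_frac", "arm_len",
              "loop_len", "mature_start", "mature_end", "star_start",
              "star_end", "n_duplexes", "pp_echo_frac",
              "expected_strand_class", "expected_context",
              "expected_taxonomy")
  for (f in fields) {
    base[[f]] <- if (!is.null(extra[[f]])) extra[[f]] else NA
  }
  base
}

#' Simulate a miRNA hairpin locus
#'
#' Writes a perfect inverted repeat (stem `arm_len + 2` nt, loop `loop_len`
#' nt with non-pairing terminal loop bases) into the genome at `at`, then
#' emits mature-arm reads whose 5' ends agree with probability
#' `precision_5p` (off-target 5' ends shifted by one) and star-arm reads
#' positioned so the mature:star duplex carries exactly 2-nt 3' overhangs on
#' both ends. In transcript coordinates within the precursor `[0, Lp)`, the
#' mature arm sits at `[2, 2 + arm_len)` and the star arm at
#' `[Lp - arm_len, Lp)`, so with the stem pairing base `x` to
#' `Lp - 1 - x` both duplex 3' overhangs equal 2.
#'
#' @param genome [Biostrings::DNAStringSet], modified copy returned.
#' @param contig contig to write into.
#' @param at 0-based genomic start for the precursor.
#' @param arm_len mature/star arm length in nt (18-25).
#' @param loop_len loop length in nt (>= 3).
#' @param depth number of mature-arm reads.
#' @param precision_5p probability that a mature read starts at the
#'   annotated 5' base.
#' @param star_frac star-arm depth as a fraction of `depth`.
#' @param strand precursor strand.
#' @param seed RNG seed.
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_mirna_locus <- function(genome, contig, at, arm_len = 22L,
                                 loop_len = 8L, depth = 200L,
                                 precision_5p = 0.95, star_frac = 0.2,
                                 strand = "+", seed = 1L) {
  stopifnot(loop_len >= 3L, arm_len >= 18L, arm_len <= 25L)
  with_seed(seed, {
    stem_len <- arm_len + 2L
    lp <- 2L * stem_len + loop_len
    stem <- rand_dna(stem_len)
    loop <- rand_dna(loop_len)
    # pin terminal loop bases to A so the loop cannot extend the stem
    substr(loop, 1L, 1L) <- "A"
    substr(loop, loop_len, loop_len) <- "A"
    hairpin <- paste0(stem, loop, revcomp(stem))
    genome <- edit_genome(genome, contig, at, hairpin)

    rel_to_genome <- function(rs, re) {
      if (strand == "+") c(at + rs, at + re) else c(at + lp - re, at + lp - rs)
    }
    mat <- rel_to_genome(2L, 2L + arm_len)
    star <- rel_to_genome(lp - arm_len, lp)

    off <- ifelse(stats::runif(depth) < precision_5p, 0L,
                  sample(c(-1L, 1L), depth, replace = TRUE))
    n_star <- max(0L, round(star_frac * depth))
    if (strand == "+") {
      m_start <- mat[1] + off
      s_start <- rep(star[1], n_star)
    } else {
      m_start <- mat[1] - off        # 5' end of a minus read is `end - 1`
      s_start <- rep(star[1], n_star)
    }
    starts <- c(m_start, s_start)
    aln <- reads_from_genome(genome, contig, starts, starts + arm_len,
                             rep(strand, length(starts)))
    truth <- truth_row("miRNA", contig, at, at + lp, strand, depth, seed,
                       arm_len = arm_len, loop_len = loop_len,
                       precision_5p = precision_5p, star_frac = star_frac,
                       read_len = arm_len,
                       mature_start = mat[1], mature_end = mat[2],
                       star_start = star[1], star_end = star[2],
                       expected_strand_class = "unistrand",
                       expected_taxonomy = NA_character_)
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate a ping-pong piRNA locus
#'
#' A fraction `pingpong_fraction` of reads is emitted as opposite-strand
#' pairs whose 5' ends overlap by exactly 10 nt; the plus-strand partner
#' starts with U with probability `u1_bias` and carries A at position 10
#' with probability `a10_bias` (which simultaneously makes the minus
#' partner 1U, as in the ping-pong amplification geometry). Remaining reads
#' are placed uniformly on both strands. Read lengths are drawn from
#' `read_lens` (default 26-32 nt).
#'
#' @inheritParams simulate_mirna_locus
#' @param span_len locus span in nt (>= 1000).
#' @param pingpong_fraction fraction of reads in exact-overlap pairs.
#' @param u1_bias probability of 5' U on the initiating partner.
#' @param a10_bias probability of A at position 10 of the initiating partner.
#' @param read_lens integer vector of read lengths to draw from.
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_pingpong_locus <- function(genome, contig, at, span_len = 5000L,
                                    depth = 500L, pingpong_fraction = 0.5,
                                    u1_bias = 0.7, a10_bias = 0.7,
                                    read_lens = 26:32, seed = 1L) {
  stopifnot(span_len >= 1000L)
  with_seed(seed, {
    n_pairs <- floor(depth * pingpong_fraction / 2)
    n_bg <- depth - 2L * n_pairs
    lmax <- max(read_lens)
    if (span_len < 2L * lmax + 20L) stop("span too small for read placement")

    p <- at + sample.int(span_len - 2L * lmax, n_pairs, replace = TRUE) + lmax
    lp <- sample(read_lens, n_pairs, replace = TRUE)
    lm <- sample(read_lens, n_pairs, replace = TRUE)
    genome <- edit_biased_base(genome, contig, p, "T", u1_bias)
    genome <- edit_biased_base(genome, contig, p + 9L, "A", a10_bias)

    bg_len <- sample(read_lens, n_bg, replace = TRUE)
    bg_start <- at + sample.int(span_len - lmax, n_bg, replace = TRUE) - 1L
    bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)

    starts <- c(p, p + 10L - lm, bg_start)
    ends <- c(p + lp, p + 10L, bg_start + bg_len)
    strands <- c(rep("+", n_pairs), rep("-", n_pairs), bg_strand)
    aln <- reads_from_genome(genome, contig, starts, ends, strands)
    truth <- truth_row("pingpong_piRNA", contig, at, at + span_len, "*",
                       depth, seed, pingpong_fraction = pingpong_fraction,
                       u1_bias = u1_bias, a10_bias = a10_bias,
                       read_len_min = min(read_lens),
                       read_len_max = max(read_lens),
                       expected_strand_class = "no_bias",
                       expected_taxonomy = "arthropod_like")
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate a phased (Zucchini-processed) piRNA locus
#'
#' Emits head-to-tail trains of same-strand reads in which the distance from
#' an upstream read's 3' end to the next read's 5' end equals `gap`
#' (`gap = 1` means the next read starts at the very next nucleotide, the
#' tightest proximity). Each train position's 5' base is U with probability
#' `u1_bias`, so the positional U profile shows a second peak at offset
#' `read_len + gap` — the first nucleotide of the next read.
#'
#' @inheritParams simulate_pingpong_locus
#' @param read_len read length in nt.
#' @param gap 3'-to-next-5' distance, in `{1, 2, 3}`.
#' @param strand strand of the train.
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_phased_locus <- function(genome, contig, at, span_len = 3000L,
                                  depth = 1000L, read_len = 30L, gap = 1L,
                                  u1_bias = 0.7, strand = "+", seed = 1L) {
  stopifnot(gap %in% 1:3)
  with_seed(seed, {
    step <- read_len + gap - 1L
    k <- (span_len - read_len) %/% step + 1L
    if (strand == "+") {
      fp <- at + (seq_len(k) - 1L) * step
      u_pos <- fp
      starts <- fp
    } else {
      fp <- at + span_len - 1L - (seq_len(k) - 1L) * step
      u_pos <- fp
      starts <- fp - read_len + 1L
    }
    u_base <- if (strand == "+") "T" else "A"
    genome <- edit_biased_base(genome, contig, u_pos, u_base, u1_bias)
    idx <- sample.int(k, depth, replace = TRUE)
    aln <- reads_from_genome(genome, contig, starts[idx],
                             starts[idx] + read_len,
                             rep(strand, depth))
    truth <- truth_row("phased_piRNA", contig, at, at + span_len, strand,
                       depth, seed, phase_gap = gap, u1_bias = u1_bias,
                       read_len = read_len,
                       expected_strand_class = "unistrand",
                       expected_taxonomy = "arthropod_like")
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate a repeat-peak ("non-arthropod") locus
#'
#' Writes a tandem repeat of `n_peaks` identical units and stacks reads at
#' exactly one 5' position per unit, so every peak carries the identical
#' sequence. By default all reads are on one strand; `pp_echo_frac` adds a
#' minority of opposite-strand partners at exact 10-nt 5'-5' overlap,
#' mimicking the partial ping-pong signal such loci retain.
#'
#' @inheritParams simulate_pingpong_locus
#' @param n_peaks number of repeat units / read stacks (>= 3).
#' @param peak_depth reads per peak.
#' @param unit_len repeat unit length in nt.
#' @param read_len read length in nt.
#' @param pp_echo_frac fraction of each peak's reads echoed as
#'   opposite-strand 10-nt-overlap partners (0 = strictly single strand).
#' @param strand majority strand.
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_repeat_peak_locus <- function(genome, contig, at, n_peaks = 5L,
                                       peak_depth = 100L, unit_len = 200L,
                                       read_len = 28L, pp_echo_frac = 0,
                                       strand = "+", seed = 1L) {
  stopifnot(n_peaks >= 3L, unit_len > read_len + 20L)
  with_seed(seed, {
    unit <- rand_dna(unit_len)
    genome <- edit_genome(genome, contig, at,
                          paste(rep(unit, n_peaks), collapse = ""))
    offset <- 10L
    peak_fp <- at + (seq_len(n_peaks) - 1L) * unit_len + offset
    n_echo <- round(pp_echo_frac * peak_depth)
    n_main <- peak_depth - n_echo
    starts <- rep(peak_fp, each = n_main)
    strands <- rep(strand, length(starts))
    ends <- starts + read_len
    if (n_echo > 0L) {
      # opposite-strand partner: 5' at peak_fp + 9 (10-nt 5'-5' overlap)
      e_start <- rep(peak_fp + 10L - read_len, each = n_echo)
      starts <- c(starts, e_start)
      ends <- c(ends, e_start + read_len)
      strands <- c(strands, rep(if (strand == "+") "-" else "+",
                                n_echo * n_peaks))
    }
    aln <- reads_from_genome(genome, contig, starts, ends, strands)
    truth <- truth_row("repeat_peak_piRNA", contig, at,
                       at + n_peaks * unit_len, strand,
                       n_peaks * peak_depth, seed, n_peaks = n_peaks,
                       peak_depth = peak_depth, read_len = read_len,
                       pp_echo_frac = pp_echo_frac,
                       expected_strand_class =
                         if (pp_echo_frac < 0.09) "unistrand" else "strand_bias",
                       expected_taxonomy = "non_arthropod")
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate degradation debris
#'
#' Short (default 15-20 nt) reads at uniform random positions, strands and
#' lengths; no engineered biogenesis signature.
#'
#' @inheritParams simulate_pingpong_locus
#' @param len_range integer vector of read lengths to draw from.
#' @param strand_prob probability that a read falls on the plus strand
#'   (0.5 = balanced; values near 1 emulate one-strand degradation).
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_debris <- function(genome, contig, at, span_len = 2000L,
                            depth = 500L, len_range = 15:20,
                            strand_prob = 0.5, seed = 1L) {
  with_seed(seed, {
    len <- sample(len_range, depth, replace = TRUE)
    start <- at + sample.int(span_len - max(len_range), depth,
                             replace = TRUE) - 1L
    strand <- sample(c("+", "-"), depth, replace = TRUE,
                     prob = c(strand_prob, 1 - strand_prob))
    aln <- reads_from_genome(genome, contig, start, start + len, strand)
    truth <- truth_row("debris", contig, at, at + span_len, "*", depth,
                       seed, read_len_min = min(len_range),
                       read_len_max = max(len_range),
                       expected_strand_class = "no_bias",
                       expected_taxonomy = NA_character_)
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate a processively diced siRNA ladder
#'
#' Head-to-tail 21-mers (or `read_len`-mers) on both strands arranged as
#' consecutive duplexes with 2-nt 3' overhangs: plus-strand 5' ends are
#' spaced exactly `read_len` apart and each minus partner's 5' end overlaps
#' its plus partner by `read_len - 2` nt. This is the positive-control
#' geometry the siRNA scan must detect.
#'
#' @inheritParams simulate_pingpong_locus
#' @param n_duplexes number of consecutive duplexes (>= 2).
#' @param read_len duplex strand length in nt.
#' @param depth_per_duplex reads per strand per duplex position.
#' @return `list(genome, alignments, truth)`.
#' @export
simulate_sirna_ladder <- function(genome, contig, at, n_duplexes = 10L,
                                  read_len = 21L, depth_per_duplex = 20L,
                                  seed = 1L) {
  stopifnot(n_duplexes >= 2L)
  with_seed(seed, {
    plus_fp <- at + (seq_len(n_duplexes) - 1L) * read_len
    minus_fp <- plus_fp + read_len - 3L      # 5'-5' overlap = read_len - 2
    p_start <- rep(plus_fp, each = depth_per_duplex)
    m_fp <- rep(minus_fp, each = depth_per_duplex)
    starts <- c(p_start, m_fp - read_len + 1L)
    ends <- starts + read_len
    strands <- rep(c("+", "-"), each = n_duplexes * depth_per_duplex)
    aln <- reads_from_genome(genome, contig, starts, ends, strands)
    truth <- truth_row("sirna_ladder", contig, at,
                       at + n_duplexes * read_len + 2L, "*",
                       2L * n_duplexes * depth_per_duplex, seed,
                       n_duplexes = n_duplexes, read_len = read_len,
                       expected_strand_class = "no_bias",
                       expected_taxonomy = "arthropod_like")
    list(genome = genome, alignments = aln, truth = truth)
  })
}

#' Simulate a multi-locus cohort with annotations and truth labels
#'
#' Places `n_per_class` loci of each requested class on one genome,
#' separated by more than the locus-merging window, and builds a matching
#' gene annotation so that each locus has a known genomic context
#' (rotating intergenic / genic / intronic). Everything is reproducible
#' from `seed`.
#'
#' @param n_per_class loci per class.
#' @param classes subset of `c("miRNA", "pingpong_piRNA", "phased_piRNA",
#'   "repeat_peak_piRNA", "debris", "sirna_ladder")`.
#' @param spacing gap between consecutive locus spans in nt (> merge
#'   window).
#' @param seed RNG seed; per-locus seeds are derived from it.
#' @param depth_scale multiplier on default per-class depths.
#' @return A list with `genome` ([Biostrings::DNAStringSet]),
#'   `alignments` (alignment table), `truth` (one row per locus with
#'   generative parameters and expected labels), `annotations`
#'   (list of `genes`/`exons`/`introns` data.frames), and
#'   `contig_lengths`.
#' @export
simulate_cohort <- function(n_per_class = 20L,
                            classes = c("miRNA", "pingpong_piRNA",
                                        "phased_piRNA",
                                        "repeat_peak_piRNA", "debris"),
                            spacing = 2000L, seed = 1L,
                            depth_scale = 1) {
  spans <- c(miRNA = 60L, pingpong_piRNA = 1500L, phased_piRNA = 1560L,
             repeat_peak_piRNA = 1500L, debris = 1500L,
             sirna_ladder = 220L)
  plan <- data.frame(class = rep(classes, each = n_per_class),
                     stringsAsFactors = FALSE)
  plan <- with_seed(seed, plan[sample.int(nrow(plan)), , drop = FALSE])
  plan$span <- spans[plan$class]
  plan$at <- cumsum(c(spacing, utils::head(plan$span, -1) + spacing))
  glen <- plan$at[nrow(plan)] + plan$span[nrow(plan)] + spacing
  glen <- max(glen, 10000L)
  genome <- make_genome(1L, glen, gc = 0.4, seed = seed)
  contig <- names(genome)[1]
  contexts <- rep(c("intergenic", "genic", "intronic"),
                  length.out = nrow(plan))

  aln_list <- vector("list", nrow(plan))
  truth_list <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    lseed <- (seed * 1009L + i * 7L) %% .Machine$integer.max
    cls <- plan$class[i]
    at <- plan$at[i]
    sim <- switch(
      cls,
      miRNA = simulate_mirna_locus(genome, contig, at,
                                   depth = round(200 * depth_scale),
                                   seed = lseed),
      pingpong_piRNA = simulate_pingpong_locus(
        genome, contig, at, span_len = plan$span[i],
        depth = round(2600 * depth_scale), pingpong_fraction = 0.5,
        seed = lseed),
      phased_piRNA = simulate_phased_locus(
        genome, contig, at, span_len = plan$span[i],
        depth = round(2600 * depth_scale), read_len = 30L, gap = 1L,
        seed = lseed),
      repeat_peak_piRNA = simulate_repeat_peak_locus(
        genome, contig, at, n_peaks = 6L,
        peak_depth = round(150 * depth_scale), unit_len = 250L,
        pp_echo_frac = 0.08, seed = lseed),
      debris = simulate_debris(genome, contig, at,
                               span_len = plan$span[i],
                               depth = round(2500 * depth_scale),
                               seed = lseed),
      sirna_ladder = simulate_sirna_ladder(
        genome, contig, at, n_duplexes = 10L,
        depth_per_duplex = round(20 * depth_scale), seed = lseed),
      stop("unknown class: ", cls)
    )
    genome <- sim$genome
    tr <- sim$truth
    tr$locus_id <- sprintf("truth_%03d", i)
    tr$expected_context <- contexts[i]
    aln_list[[i]] <- sim$alignments
    truth_list[[i]] <- tr
  }
  truth <- do.call(rbind, truth_list)
  aln <- do.call(rbind, aln_list)
  aln <- sort_records(aln)
  rownames(aln) <- NULL
  ann <- cohort_annotations(truth, contig, glen)
  list(genome = genome, alignments = aln, truth = truth,
       annotations = ann, contig_lengths = stats::setNames(glen, contig))
}

# gene models realizing each truth locus's expected context
cohort_annotations <- function(truth, contig, glen) {
  genes <- list(); exons <- list()
  for (i in seq_len(nrow(truth))) {
    ctx <- truth$expected_context[i]
    if (is.na(ctx) || ctx == "intergenic") next
    ls <- truth$start[i]; le <- truth$end[i]
    gid <- paste0("gene_", truth$locus_id[i])
    if (ctx == "genic") {
      gs <- max(0L, ls - 100L); ge <- min(glen, le + 100L)
      ex <- data.frame(start = c(gs, le - 20L), end = c(ls + 50L, ge))
    } else {                      # intronic: exons flank the locus
      gs <- max(0L, ls - 400L); ge <- min(glen, le + 400L)
      ex <- data.frame(start = c(gs, le + 300L), end = c(ls - 300L, ge))
    }
    genes[[gid]] <- data.frame(contig = contig, start = gs, end = ge,
                               strand = "+", gene_id = gid,
                               stringsAsFactors = FALSE)
    exons[[gid]] <- data.frame(contig = contig, start = ex$start,
                               end = ex$end, strand = "+", gene_id = gid,
                               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  if (is.null(genes)) {
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        gene_id = character(), stringsAsFactors = FALSE)
    return(list(genes = empty, exons = empty, introns = empty))
  }
  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    g <- genes[genes$gene_id == ex$gene_id[1], ]
    gaps <- interval_complement(ex$start, ex$end, g$start, g$end)
    if (nrow(gaps) == 0L) return(NULL)
    data.frame(contig = g$contig, start = gaps$start, end = gaps$end,
               strand = g$strand, gene_id = g$gene_id,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- rownames(exons) <- NULL
  if (!is.null(introns)) rownames(introns) <- NULL
  list(genes = genes, exons = exons,
       introns = if (is.null(introns)) genes[0, ] else introns)
}

#' Write an annotation set as GFF3
#'
#' @param annotations list with `genes` and `exons` data.frames
#'   (0-based half-open), as produced by [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  g <- annotations$genes
  e <- annotations$exons
  lines <- "##gff-version 3"
  if (!is.null(g) && nrow(g)) {
    gl <- paste(g$contig, "srnasig", "gene", g$start + 1L, g$end, ".",
                g$strand, ".", paste0("ID=", g$gene_id), sep = "\t")
    el <- paste(e$contig, "srnasig", "exon", e$start + 1L, e$end, ".",
                e$strand, ".",
                paste0("ID=", e$gene_id, ".e", stats::ave(
                  seq_len(nrow(e)), e$gene_id, FUN = seq_along),
                  ";Parent=", e$gene_id),
                sep = "\t")
    lines <- c(lines, gl, el)
  }
  writeLines(lines, path)
  invisible(path)
}
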