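#' Find candidate siRNA loci
#'
#' Coverage islands of 20-23 nt reads with per-base depth strictly greater
#' than `min_cov`, minus any island intersecting the miRNA exclusion set.
#' Islands are not merged by default: the scan looks at compact
#' Dicer-product stacks, not broad clusters.
#'
#' @param aln alignment table (all lengths; 20-23 nt reads are selected
#'   here).
#' @param contig_lengths named integer vector of contig lengths.
#' @param min_cov exclusive depth threshold.
#' @param exclude optional `data.frame` with `contig`, `start`, `end` of
#'   miRNA loci to drop.
#' @param merge_window island merge gap in nt (0 = never merge).
#' @return Locus table (`contig`, `start`, `end`, `locus_id`).
#' @export
find_sirna_loci <- function(aln, contig_lengths = NULL, min_cov = 30,
                            exclude = NULL, merge_window = 0L) {
  len <- aln$end - aln$start
  short <- aln[len >= 20L & len <= 23L, , drop = FALSE]
  track <- coverage_track(short, contig_lengths)
  loci <- find_loci(track, min_cov = min_cov, merge_window = merge_window,
                    strict = TRUE)
  if (!is.null(exclude) && nrow(loci)) {
    drop <- overlaps_any(loci$contig, loci$start, loci$end, exclude)
    loci <- loci[!drop, , drop = FALSE]
    rownames(loci) <- NULL
  }
  loci
}

#' Strand-ratio bin of an siRNA candidate locus
#'
#' `r = max / max(min, 1)` over the two strand counts. `equal` for
#' `r <= 1.1`, `mixed` for `1.1 < r <= 1.9`, `bias` for `r > 1.9` (the
#' nominal bins are 1-1.1, 1.2-1.9 and >= 2; ratio values in the gaps
#' 1.1-1.2 and 1.9-2.0 are assigned to `mixed` and `bias` respectively,
#' and the raw ratio is always returned for re-binning).
#'
#' @param plus_count,minus_count per-strand 20-23 nt read counts
#'   (vectorized).
#' @return `data.frame` with `ratio` and `bin`.
#' @export
strand_bin <- function(plus_count, minus_count) {
  hi <- pmax(plus_count, minus_count)
  lo <- pmax(pmin(plus_count, minus_count), 1)
  r <- hi / lo
  bin <- ifelse(r <= 1.1, "equal", ifelse(r <= 1.9, "mixed", "bias"))
  data.frame(ratio = r, bin = bin, stringsAsFactors = FALSE)
}

#' Per-size overlap z-score matrix
#'
#' For each read length `L` in `sizes`, the same-length overlap histogram
#' z-scores over `o = o_min..L`. Row `L`, column `o`; `NA` where a length
#' class has fewer than two reads or `o` exceeds `L`. The ping-pong
#' position is `o = 10`, the Dicer position `o = L - 2`.
#'
#' @param reads alignment table of one locus.
#' @param sizes read lengths profiled.
#' @param o_min smallest overlap scored.
#' @return Numeric matrix `length(sizes)` x `max(sizes) - o_min + 1`.
#' @export
per_size_overlap_matrix <- function(reads, sizes = 20:23, o_min = 4L) {
  o_cols <- seq.int(o_min, max(sizes))
  z <- matrix(NA_real_, length(sizes), length(o_cols),
              dimnames = list(sizes, o_cols))
  len <- reads$end - reads$start
  for (L in sizes) {
    sub <- reads[len == L, , drop = FALSE]
    if (nrow(sub) < 2L) next
    h <- overlap_histogram(sub, o_max = L, query_len = L, o_min = o_min)
    z[as.character(L), as.character(o_min:L)] <- h$z[o_min:L]
  }
  z
}

#' Count 21/21-nt read pairs overlapping by 19 nt
#'
#' The duplex configuration processive Dicer cleavage leaves: both reads
#' `L` nt, opposite strands, 5'-5' overlap exactly `L - 2`. Counted both
#' per alignment (multiplicity-weighted) and per species (distinct
#' sequences).
#'
#' @param reads alignment table of one locus.
#' @param L read length in nt.
#' @return List with `per_alignment` and `per_species` pair counts.
#' @export
count_2121_pairs <- function(reads, L = 21L) {
  len <- reads$end - reads$start
  sub <- reads[len == L, , drop = FALSE]
  if (nrow(sub) < 2L) {
    return(list(per_alignment = 0, per_species = 0))
  }
  ha <- overlap_histogram(sub, o_max = L, query_len = L)
  hs <- overlap_histogram(sub, o_max = L, query_len = L,
                          mode = "per_species")
  list(per_alignment = unname(ha$counts[as.character(L - 2L)]),
       per_species = unname(hs$counts[as.character(L - 2L)]))
}

#' Short-to-long read log ratio
#'
#' `log2((n_short + 1) / (n_long + 1))` with short = 20-23 nt and long =
#' 26-32 nt: positive values mark loci dominated by Dicer-sized reads,
#' negative values piRNA-sized reads.
#'
#' @param reads alignment table of one locus.
#' @param short_range,long_range integer length ranges.
#' @return A single number.
#' @export
short_long_ratio <- function(reads, short_range = 20:23,
                             long_range = 26:32) {
  len <- reads$end - reads$start
  n_short <- sum(reads$count[len %in% short_range])
  n_long <- sum(reads$count[len %in% long_range])
  log2((n_short + 1) / (n_long + 1))
}

#' Phased siRNA runs
#'
#' Chains of three or more same-strand `L`-mers whose consecutive distinct
#' 5' positions are spaced exactly `L` nt apart — the head-to-tail register
#' left on each strand by processive dicing of a long duplex. Opposite-
#' strand `L`/`L` duplexes (overlap `L - 2`) whose partners both fall
#' outside any run are reported as distributive pairs.
#'
#' @param reads alignment table of one locus.
#' @param L read length in nt.
#' @return List with `run_count`, `runs` (list of 5' position vectors),
#'   `distributive_pairs`.
#' @export
phased_runs <- function(reads, L = 21L) {
  len <- reads$end - reads$start
  sub <- reads[len == L, , drop = FALSE]
  runs <- list()
  run_pos <- list("+" = integer(), "-" = integer())
  for (str in c("+", "-")) {
    ss <- sub[sub$strand == str, , drop = FALSE]
    if (nrow(ss) == 0L) next
    for (ctg in unique(ss$contig)) {
      fp <- sort(unique(five_prime(ss[ss$contig == ctg, , drop = FALSE])))
      if (length(fp) < 2L) next
      brk <- cumsum(c(0L, as.integer(diff(fp) != L)))
      for (chain in split(fp, brk)) {
        if (length(chain) >= 3L) {
          runs[[length(runs) + 1L]] <- chain
          run_pos[[str]] <- c(run_pos[[str]], chain)
        }
      }
    }
  }
  # distributive duplexes: plus 5' p pairs minus 5' p + L - 3 (o = L - 2)
  plus_fp <- unique(five_prime(sub[sub$strand == "+", , drop = FALSE]))
  minus_fp <- unique(five_prime(sub[sub$strand == "-", , drop = FALSE]))
  duplex_p <- plus_fp[(plus_fp + L - 3L) %in% minus_fp]
  distributive <- sum(!(duplex_p %in% run_pos[["+"]]) &
                        !((duplex_p + L - 3L) %in% run_pos[["-"]]))
  list(run_count = length(runs), runs = runs,
       distributive_pairs = distributive)
}

#' Per-locus siRNA scan report
#'
#' For every candidate locus from [find_sirna_loci()]: the strand-ratio
#' bin, ping-pong z-score, per-length Dicer z-scores (20-23 nt), the
#' 21/21 19-nt-overlap duplex count, the short:long read log ratio, RPKM
#' and the phased-run count.
#'
#' @param loci locus table from [find_sirna_loci()].
#' @param aln alignment table (all read lengths, for the short:long
#'   ratio).
#' @param mapped_total library mapped-read total for RPKM.
#' @return One row per locus.
#' @export
sirna_report <- function(loci, aln, mapped_total = sum(aln$count)) {
  assignment <- assign_reads(aln, loci)
  n <- nrow(loci)
  out <- loci
  out$ratio <- out$z_pingpong <- out$z_dicer_20 <- out$z_dicer_21 <-
    out$z_dicer_22 <- out$z_dicer_23 <- out$short_long_log_ratio <-
    out$rpkm <- NA_real_
  out$strand_bin <- NA_character_
  out$n_2121_pairs <- out$n_2121_species <- out$phased_run_count <-
    out$distributive_pairs <- NA_real_
  len <- aln$end - aln$start
  for (i in seq_len(n)) {
    rd <- aln[!is.na(assignment) & assignment == loci$locus_id[i], ,
              drop = FALSE]
    if (nrow(rd) == 0L) next
    short <- rd[(rd$end - rd$start) >= 20L & (rd$end - rd$start) <= 23L, ,
                drop = FALSE]
    sb <- strand_bin(sum(short$count[short$strand == "+"]),
                     sum(short$count[short$strand == "-"]))
    out$strand_bin[i] <- sb$bin
    out$ratio[i] <- sb$ratio
    out$z_pingpong[i] <- pingpong_z(short)
    for (L in 20:23) {
      out[[paste0("z_dicer_", L)]][i] <- dicer_z(short, L)
    }
    pp <- count_2121_pairs(short)
    out$n_2121_pairs[i] <- pp$per_alignment
    out$n_2121_species[i] <- pp$per_species
    out$short_long_log_ratio[i] <- short_long_ratio(rd)
    llen <- loci$end[i] - loci$start[i]
    out$rpkm[i] <- sum(rd$count) * 1e9 / (llen * mapped_total)
    pr <- phased_runs(short)
    out$phased_run_count[i] <- pr$run_count
    out$distributive_pairs[i] <- pr$distributive_pairs
  }
  out
}

#' Test for enrichment of Dicer signatures at dual-strand loci
#'
#' Compares the rate of mixed/equal strand bins among loci with a positive
#' 21-nt Dicer z-score against the rate among loci with a non-positive
#' one (one-sided two-proportion test). Loci whose 21-nt Dicer z-score is
#' undefined (too few 21-mers on one strand) carry no information about
#' the Dicer signature and are excluded. In a cohort without genuine
#' siRNA loci the Dicer-positive set shows no excess of mixed/equal loci
#' — the absence signature.
#'
#' @param report output of [sirna_report()].
#' @return List with `frac_mixed_equal_dicer_pos`, `base_rate` (the
#'   mixed/equal rate among scored loci), `p_value` and the contingency
#'   counts.
#' @export
dicer_strand_enrichment <- function(report) {
  report <- report[!is.na(report$z_dicer_21), , drop = FALSE]
  me <- report$strand_bin %in% c("mixed", "equal")
  pos <- report$z_dicer_21 > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  x <- c(sum(me & pos), sum(me & !pos))
  nn <- c(n_pos, n_neg)
  p <- if (all(nn > 0)) {
    suppressWarnings(stats::prop.test(x, nn, alternative = "greater")$p.value)
  } else NA_real_
  list(frac_mixed_equal_dicer_pos = if (n_pos > 0) x[1] / n_pos else
    NA_real_,
    base_rate = mean(me), p_value = p,
    counts = stats::setNames(c(x, nn), c("me_pos", "me_neg", "n_pos",
                                         "n_neg")))
}
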