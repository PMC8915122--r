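#' Select piRNA loci
#'
#' A locus qualifies as a piRNA locus when it is longer than `min_len` nt
#' and its 15-31 nt reads contain at least one opposite-strand pair with an
#' exact 10-nt 5'-5' overlap (evidence of ping-pong processing).
#'
#' @param loci locus table (from [build_loci()] or [find_loci()]).
#' @param aln alignment table.
#' @param assignment per-read locus ids from [assign_reads()].
#' @param min_len exclusive locus length threshold in nt.
#' @param min_pp_z optional additional requirement on the ping-pong
#'   z-score (`NULL` = any exact-overlap pair qualifies).
#' @return Subset of `loci` with an added `pp_pair_count` column.
#' @export
select_pirna_loci <- function(loci, aln, assignment, min_len = 1000L,
                              min_pp_z = NULL) {
  keep <- logical(nrow(loci))
  ppn <- numeric(nrow(loci))
  len_ok <- (loci$end - loci$start) > min_len
  rlen <- aln$end - aln$start
  for (i in which(len_ok)) {
    rd <- aln[!is.na(assignment) & assignment == loci$locus_id[i] &
                rlen >= 15L & rlen <= 31L, , drop = FALSE]
    if (nrow(rd) < 2L) next
    h <- overlap_histogram(rd, o_max = 30L)
    ppn[i] <- h$counts["10"]
    keep[i] <- ppn[i] >= 1 &&
      (is.null(min_pp_z) || (!is.na(h$z["10"]) && h$z["10"] >= min_pp_z))
  }
  out <- loci[keep, , drop = FALSE]
  out$pp_pair_count <- ppn[keep]
  out
}

#' Strand-bias class of a piRNA locus
#'
#' `r = max(plus, minus) / max(min(plus, minus), 1)` (one pseudocount on
#' the minority strand keeps the ratio finite): `no_bias` when `r < 5`,
#' `strand_bias` when `5 <= r <= 10`, `unistrand` when `r > 10`
#' (all-one-strand loci are unistrand by construction).
#'
#' @param plus_count,minus_count per-strand read counts (vectorized).
#' @return `data.frame` with `ratio` and `strand_class`.
#' @export
strand_class <- function(plus_count, minus_count) {
  if (any(plus_count + minus_count == 0)) stop("locus without reads")
  hi <- pmax(plus_count, minus_count)
  lo <- pmax(pmin(plus_count, minus_count), 1)
  r <- hi / lo
  cls <- ifelse(r < 5, "no_bias", ifelse(r <= 10, "strand_bias",
                                         "unistrand"))
  data.frame(ratio = r, strand_class = cls, stringsAsFactors = FALSE)
}

within_any <- function(contig, start, end, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(iv$contig == contig[i] & iv$start <= start[i] & iv$end >= end[i])
  }, logical(1))
}

overlaps_any <- function(contig, start, end, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(iv$contig == contig[i] & iv$start < end[i] & iv$end > start[i])
  }, logical(1))
}

#' Genomic context of loci
#'
#' `intronic` when a locus lies entirely within a single intron; `genic`
#' when it overlaps a gene in any other way (an exon boundary, exon plus
#' intron); `intergenic` when it overlaps no gene. Genic takes precedence
#' over intronic when a locus touches both exon and intron sequence.
#'
#' @param loci locus table with `contig`, `start`, `end`.
#' @param annotations annotation set from [load_annotations()] or
#'   [simulate_cohort()] (`genes`/`exons`/`introns` data.frames).
#' @return Character vector in `{intergenic, genic, intronic}`.
#' @export
genomic_context <- function(loci, annotations) {
  in_gene <- overlaps_any(loci$contig, loci$start, loci$end,
                          annotations$genes)
  in_intron <- within_any(loci$contig, loci$start, loci$end,
                          annotations$introns)
  ifelse(!in_gene, "intergenic", ifelse(in_intron, "intronic", "genic"))
}

#' Repeat-peak taxonomy of a piRNA locus
#'
#' Arthropod-type piRNA loci accumulate reads at effectively random
#' positions; the atypical class presents as cluster-like repeating sites
#' where all reads stack on a few positions. The call is operationalized
#' through the peak concentration index (PCI): the share of reads whose
#' (strand, 5' position) is among the locus's top-`k` positions. A locus is
#' `non_arthropod` when `PCI >= pci_min` and its number of distinct 5'
#' positions is at most `density_max` per nt of locus length; loci with
#' fewer than `min_reads` reads default to `arthropod_like` and are
#' flagged low-depth. Raw metrics are returned so calls are auditable.
#'
#' @param reads alignment table of the locus.
#' @param locus_len locus length in nt.
#' @param k number of top positions in the PCI.
#' @param pci_min PCI threshold.
#' @param density_max maximum distinct 5' positions per nt.
#' @param min_reads depth below which no call is attempted.
#' @return List with `taxonomy`, `pci`, `n_positions`, `low_depth`.
#' @export
taxonomy <- function(reads, locus_len, k = 10L, pci_min = 0.8,
                     density_max = 0.05, min_reads = 50L) {
  total <- sum(reads$count)
  if (total < min_reads) {
    return(list(taxonomy = "arthropod_like", pci = NA_real_,
                n_positions = NA_integer_, low_depth = TRUE))
  }
  key <- paste(reads$strand, five_prime(reads), sep = "\1")
  per_pos <- rowsum(as.numeric(reads$count), key)
  npos <- nrow(per_pos)
  pci <- sum(utils::head(sort(per_pos[, 1], decreasing = TRUE), k)) / total
  call <- if (pci >= pci_min && npos <= density_max * locus_len) {
    "non_arthropod"
  } else "arthropod_like"
  list(taxonomy = call, pci = pci, n_positions = npos, low_depth = FALSE)
}

#' Repeat typing of a non-arthropod locus
#'
#' `single_read_repeat` when one distinct read sequence accounts for at
#' least half of the locus's reads, otherwise `multi_read_motif`;
#' strandedness is `dual_strand` when the minority strand holds at least
#' 10% of reads, else `single_strand`. Loci not called `non_arthropod`
#' return `(none, na)`.
#'
#' @param reads alignment table of the locus.
#' @param taxonomy_call the locus's taxonomy (see [taxonomy()]).
#' @return List with `repeat_type` and `repeat_strandedness`.
#' @export
repeat_typing <- function(reads, taxonomy_call) {
  if (!identical(taxonomy_call, "non_arthropod")) {
    return(list(repeat_type = "none", repeat_strandedness = "na"))
  }
  total <- sum(reads$count)
  seq_key <- ifelse(is.na(reads$seq),
                    paste(reads$start, reads$end, reads$strand),
                    reads$seq)
  top_seq <- max(rowsum(as.numeric(reads$count), seq_key))
  rtype <- if (top_seq / total >= 0.5) "single_read_repeat" else
    "multi_read_motif"
  minority <- min(sum(reads$count[reads$strand == "+"]),
                  sum(reads$count[reads$strand == "-"]))
  strd <- if (minority / total >= 0.10) "dual_strand" else "single_strand"
  list(repeat_type = rtype, repeat_strandedness = strd)
}

#' Size class of loci
#'
#' @param locus_len locus lengths in nt (vectorized).
#' @param threshold split point in nt (default 2.55 kb).
#' @return `"gt_2550"` for lengths strictly above the threshold, else
#'   `"le_2550"`.
#' @export
size_class <- function(locus_len, threshold = 2550L) {
  ifelse(locus_len > threshold, "gt_2550", "le_2550")
}

#' Unique-mapping support
#'
#' @param reads alignment table of a locus.
#' @return `TRUE` when any read maps to a single genomic position
#'   (`n_hits == 1`).
#' @export
has_unique_hits <- function(reads) {
  any(reads$n_hits == 1L)
}

#' Full per-locus piRNA report
#'
#' Runs the piRNA selection and every classification axis over a locus
#' table: biogenesis signatures (ping-pong z, phasing z at distances 1-3,
#' 1U fraction), taxonomy with PCI, strand class with raw ratio, genomic
#' context, size class, unique-hit support and repeat typing. All loci are
#' reported; `is_pirna` records which pass the selection rule.
#'
#' @param loci locus table from [build_loci()].
#' @param aln alignment table.
#' @param assignment per-read locus ids.
#' @param annotations annotation set (or `NULL` to skip context calls).
#' @param min_len piRNA locus length threshold.
#' @return One row per locus with all metrics and categorical calls.
#' @export
classify_pirna_loci <- function(loci, aln, assignment, annotations = NULL,
                                min_len = 1000L) {
  sel <- select_pirna_loci(loci, aln, assignment, min_len = min_len)
  n <- nrow(loci)
  rep_df <- loci
  rep_df$is_pirna <- loci$locus_id %in% sel$locus_id
  rep_df$pingpong_z <- rep_df$phasing_z <- rep_df$u1_fraction <-
    rep_df$pci <- rep_df$strand_ratio <- NA_real_
  rep_df$taxonomy <- rep_df$strand_class <- rep_df$context <-
    rep_df$repeat_type <- rep_df$repeat_strandedness <- NA_character_
  for (i in seq_len(n)) {
    rd <- aln[!is.na(assignment) & assignment == loci$locus_id[i], ,
              drop = FALSE]
    if (nrow(rd) == 0L) next
    llen <- loci$end[i] - loci$start[i]
    rep_df$pingpong_z[i] <- pingpong_z(rd)
    ph <- phasing_stats(rd)
    if (!is.null(ph$z)) {
      rep_df$phasing_z[i] <- suppressWarnings(
        max(ph$z[as.character(1:3)], na.rm = TRUE))
      if (!is.finite(rep_df$phasing_z[i])) rep_df$phasing_z[i] <- NA_real_
    }
    rep_df$u1_fraction[i] <- first_base_bias(rd)
    tx <- taxonomy(rd, llen)
    rep_df$taxonomy[i] <- tx$taxonomy
    rep_df$pci[i] <- tx$pci
    sc <- strand_class(sum(rd$count[rd$strand == "+"]),
                       sum(rd$count[rd$strand == "-"]))
    rep_df$strand_class[i] <- sc$strand_class
    rep_df$strand_ratio[i] <- sc$ratio
    rt <- repeat_typing(rd, tx$taxonomy)
    rep_df$repeat_type[i] <- rt$repeat_type
    rep_df$repeat_strandedness[i] <- rt$repeat_strandedness
  }
  rep_df$size_class <- size_class(loci$end - loci$start)
  rep_df$has_unique_hits <- vapply(seq_len(n), function(i) {
    rd <- aln[!is.na(assignment) & assignment == loci$locus_id[i], ,
              drop = FALSE]
    nrow(rd) > 0L && has_unique_hits(rd)
  }, logical(1))
  if (!is.null(annotations)) {
    rep_df$context <- genomic_context(loci, annotations)
  }
  rep_df
}
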