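#' Per-contig read coverage track
#'
#' Depth at base `b` is the number of alignments covering `b`, strands
#' combined, with multiplicity from the `count` field. In `by_hits` mode
#' each alignment contributes `count / n_hits` instead, spreading
#' multimapped reads across their placements.
#'
#' @param aln alignment table (length-filtered upstream).
#' @param contig_lengths named integer vector; defaults to the maximum
#'   alignment end per contig.
#' @param weight_mode `"per_alignment"` (weight = `count`) or `"by_hits"`
#'   (weight = `count / n_hits`).
#' @return Named list of numeric vectors; element `i` of a vector is the
#'   depth at 0-based position `i - 1`.
#' @export
coverage_track <- function(aln, contig_lengths = NULL,
                           weight_mode = c("per_alignment", "by_hits")) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(contig_lengths)) {
    if (nrow(aln) == 0L) return(list())
    contig_lengths <- tapply(aln$end, aln$contig, max)
  }
  w <- if (weight_mode == "by_hits") aln$count / aln$n_hits else
    as.numeric(aln$count)
  track <- lapply(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    sel <- aln$contig == ctg
    if (!any(sel)) return(numeric(len))
    # difference array: +w at start, -w at end, then cumulative sum
    d <- numeric(len + 1L)
    s <- pmax(aln$start[sel], 0L) + 1L
    e <- pmin(aln$end[sel], len) + 1L
    add_s <- rowsum(w[sel], s)
    add_e <- rowsum(w[sel], e)
    d[as.integer(rownames(add_s))] <- d[as.integer(rownames(add_s))] + add_s
    d[as.integer(rownames(add_e))] <- d[as.integer(rownames(add_e))] - add_e
    cumsum(d)[seq_len(len)]
  })
  names(track) <- names(contig_lengths)
  track
}

#' Find small RNA loci as coverage islands
#'
#' Maximal runs of bases with depth at or above `min_cov` (strictly above
#' with `strict = TRUE`) are extracted per contig; runs separated by a gap
#' shorter than `merge_window` are merged into one locus. The gap
#' comparison is strict: a gap of exactly `merge_window` nt keeps two loci.
#'
#' @param track coverage track from [coverage_track()].
#' @param min_cov per-base depth threshold.
#' @param merge_window merge gap in nt.
#' @param strict if `TRUE`, require depth strictly greater than `min_cov`.
#' @return `data.frame` with `contig`, `start`, `end`, `locus_id`
#'   (0-based half-open), sorted by contig and start.
#' @export
find_loci <- function(track, min_cov = 200, merge_window = 500L,
                      strict = FALSE) {
  stopifnot(min_cov >= 1)
  out <- lapply(names(track), function(ctg) {
    v <- track[[ctg]]
    pass <- if (strict) v > min_cov else v >= min_cov
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    s <- starts[keep]; e <- ends[keep]
    if (length(s) > 1L) {
      gap <- s[-1L] - e[-length(e)]
      brk <- cumsum(c(0L, as.integer(gap >= merge_window)))
      s <- as.vector(tapply(s, brk, min))
      e <- as.vector(tapply(e, brk, max))
    }
    data.frame(contig = ctg, start = s, end = e, stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, out)
  if (is.null(loci)) {
    loci <- data.frame(contig = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  loci$locus_id <- if (nrow(loci)) sprintf("locus_%04d", seq_len(nrow(loci)))
    else character()
  rownames(loci) <- NULL
  loci
}

#' Assign reads to loci by overlap
#'
#' A read belongs to a locus if its span intersects the locus interval; a
#' read overlapping several loci is assigned to the earliest (leftmost)
#' one.
#'
#' @param aln alignment table.
#' @param loci locus table from [find_loci()].
#' @return Character vector of `locus_id` (or `NA`) per alignment row.
#' @export
assign_reads <- function(aln, loci) {
  res <- rep(NA_character_, nrow(aln))
  for (ctg in unique(aln$contig)) {
    lc <- loci[loci$contig == ctg, , drop = FALSE]
    sel <- which(aln$contig == ctg)
    if (nrow(lc) == 0L || length(sel) == 0L) next
    q <- IRanges::IRanges(aln$start[sel] + 1L, aln$end[sel])
    s <- IRanges::IRanges(lc$start + 1L, lc$end)
    hit <- IRanges::findOverlaps(q, s, select = "first")
    res[sel] <- lc$locus_id[hit]
  }
  res
}

#' Read-length profile of a locus
#'
#' Counts assigned reads by length over 15-32 nt (weighted by `count`),
#' with row-normalized fractions.
#'
#' @param reads alignment table for one locus (>= 1 read).
#' @param len_range integer vector of profiled lengths.
#' @return List with `counts` and `fractions`, both named by length.
#' @export
size_profile <- function(reads, len_range = 15:32) {
  stopifnot(nrow(reads) >= 1L)
  len <- reads$end - reads$start
  counts <- stats::setNames(numeric(length(len_range)), len_range)
  inr <- len %in% len_range
  if (any(inr)) {
    acc <- rowsum(as.numeric(reads$count[inr]), len[inr])
    counts[rownames(acc)] <- as.vector(acc)
  }
  tot <- sum(counts)
  list(counts = counts,
       fractions = if (tot > 0) counts / tot else counts)
}

#' Discover loci and profile them in one pass
#'
#' Convenience wrapper: coverage track, island finding, read assignment and
#' per-locus summary statistics (max depth, total read count, strand
#' counts, modal read length) plus the matrix of normalized size profiles.
#'
#' @inheritParams coverage_track
#' @inheritParams find_loci
#' @return List with `loci` (stats-augmented locus table), `assignment`
#'   (per-read locus id), `profiles` (loci x 18 matrix of length
#'   fractions) and `track`.
#' @export
build_loci <- function(aln, contig_lengths = NULL, min_cov = 200,
                       merge_window = 500L,
                       weight_mode = c("per_alignment", "by_hits"),
                       strict = FALSE) {
  weight_mode <- match.arg(weight_mode)
  track <- coverage_track(aln, contig_lengths, weight_mode)
  loci <- find_loci(track, min_cov, merge_window, strict)
  assignment <- assign_reads(aln, loci)
  len_range <- 15:32
  profiles <- matrix(0, nrow(loci), length(len_range),
                     dimnames = list(loci$locus_id, len_range))
  loci$depth <- loci$total_count <- loci$plus_count <- loci$minus_count <-
    loci$mean_read_len <- NA_real_
  for (i in seq_len(nrow(loci))) {
    rd <- aln[!is.na(assignment) & assignment == loci$locus_id[i], ,
              drop = FALSE]
    v <- track[[loci$contig[i]]]
    loci$depth[i] <- max(v[(loci$start[i] + 1L):loci$end[i]])
    loci$total_count[i] <- sum(rd$count)
    loci$plus_count[i] <- sum(rd$count[rd$strand == "+"])
    loci$minus_count[i] <- sum(rd$count[rd$strand == "-"])
    len <- rd$end - rd$start
    loci$mean_read_len[i] <- sum(len * rd$count) / sum(rd$count)
    profiles[i, ] <- size_profile(rd)$fractions
  }
  list(loci = loci, assignment = assignment, profiles = profiles,
       track = track)
}

#' Cluster loci by read-length profile
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances) of
#' row-normalized size profiles, cut at `k` clusters. Cluster indices are
#' relabeled in order of decreasing mean read length so that labels are
#' stable across runs: cluster 1 holds the longest-read loci.
#'
#' @param profiles numeric matrix, loci x lengths, rows summing to 1
#'   (column names are read lengths in nt).
#' @param k number of clusters.
#' @return List with `cluster` (named integer vector), `mean_profiles`
#'   (k x lengths matrix) and `mean_read_len` (per cluster).
#' @export
cluster_loci <- function(profiles, k = 9L) {
  if (nrow(profiles) < k) stop("fewer loci than clusters requested")
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  lens <- as.numeric(colnames(profiles))
  mrl <- vapply(seq_len(k), function(g) {
    p <- colMeans(profiles[raw == g, , drop = FALSE])
    sum(p * lens) / sum(p)
  }, numeric(1))
  relabel <- match(seq_len(k), order(mrl, decreasing = TRUE))
  cluster <- stats::setNames(relabel[raw], rownames(profiles))
  mean_profiles <- t(vapply(seq_len(k), function(g) {
    colMeans(profiles[cluster == g, , drop = FALSE])
  }, numeric(ncol(profiles))))
  dimnames(mean_profiles) <- list(seq_len(k), colnames(profiles))
  list(cluster = cluster, mean_profiles = mean_profiles,
       mean_read_len = sort(mrl, decreasing = TRUE))
}

#' Positional nucleotide bias of a read set
#'
#' Per-position A/C/G/T frequencies over the first `positions` bases of
#' every read (count-weighted), plus the information content per position
#' in bits, `2 + sum(f * log2(f))` — the seqlogo statistic. Reads with an
#' N at any scored position (or without sequence, or shorter than the
#' window) are excluded.
#'
#' @param reads alignment table with sequences.
#' @param positions number of 5' positions scored.
#' @return List with `freq` (4 x positions matrix) and `ic` (bits per
#'   position).
#' @export
cluster_base_bias <- function(reads, positions = 10L) {
  keep <- !is.na(reads$seq) & nchar(reads$seq) >= positions
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) stop("no scorable reads")
  mat <- matrix(unlist(strsplit(substr(reads$seq, 1L, positions), "")),
                ncol = positions, byrow = TRUE)
  clean <- rowSums(matrix(mat %in% c("A", "C", "G", "T"),
                          nrow = nrow(mat))) == positions
  mat <- mat[clean, , drop = FALSE]
  w <- reads$count[clean]
  if (nrow(mat) == 0L) stop("no reads without N at scored positions")
  freq <- vapply(seq_len(positions), function(j) {
    f <- vapply(c("A", "C", "G", "T"),
                function(b) sum(w[mat[, j] == b]), numeric(1))
    f / sum(f)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  ic <- apply(freq, 2L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  list(freq = freq, ic = ic)
}

#' Library-size normalization
#'
#' Reads-per-million-mapped and the heatmap-ready `log2(RPM + 1)`
#' transform.
#'
#' @param counts numeric vector of locus read counts.
#' @param library_mapped_total total mapped reads in the library (> 0).
#' @return `data.frame` with `count`, `rpm`, `log2_rpm`.
#' @export
normalize_expression <- function(counts, library_mapped_total) {
  stopifnot(library_mapped_total > 0)
  rpm <- counts * 1e6 / library_mapped_total
  data.frame(count = counts, rpm = rpm, log2_rpm = log2(rpm + 1))
}
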