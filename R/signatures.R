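#' 5'-5' overlap length of an opposite-strand read pair
#'
#' For a plus-strand read and a minus-strand read on the same contig, the
#' overlap is `o = five_prime(minus) - five_prime(plus) + 1`, defined only
#' when `o >= 1` and each read's 5' end lies within the partner's span
#' (equivalently `o <= min(length_plus, length_minus)`). A 10-nt overlap is
#' the ping-pong signature; `length - 2` for a same-length pair is the
#' Dicer signature (2-nt 3' overhangs on both ends).
#'
#' @param plus_read,minus_read one-row alignment tables (or equal-length
#'   tables, paired row-wise).
#' @return Integer vector of overlaps; `NA` where the pair does not overlap
#'   in the 5'-5' sense.
#' @export
overlap_len <- function(plus_read, minus_read) {
  if (any(plus_read$strand != "+") || any(minus_read$strand != "-")) {
    stop("overlap_len expects a plus-strand and a minus-strand read")
  }
  o <- minus_read$end - plus_read$start
  len_p <- plus_read$end - plus_read$start
  len_m <- minus_read$end - minus_read$start
  ok <- plus_read$contig == minus_read$contig & o >= 1L & o <= len_p &
    o <= len_m
  ifelse(ok, o, NA_integer_)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

zscores <- function(counts, window) {
  z <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  x <- counts[window]
  s <- pop_sd(x)
  if (is.finite(s) && s > 0) z[window] <- (counts[window] - mean(x)) / s
  z
}

collapse_species <- function(aln) {
  key <- paste(aln$contig, aln$start, aln$end, aln$strand, aln$seq,
               sep = "\1")
  aln <- aln[!duplicated(key), , drop = FALSE]
  aln$count <- 1L
  aln
}

# group alignments of one strand into distinct (contig, five_prime, length)
# classes with summed weights
fp_groups <- function(aln, weights) {
  fp <- five_prime(aln)
  len <- aln$end - aln$start
  key <- paste(aln$contig, fp, len, sep = "\1")
  first <- !duplicated(key)
  w <- as.vector(rowsum(weights, key))        # rowsum sorts by key
  ord <- sort(key[first])
  g <- data.frame(contig = aln$contig[first], fp = fp[first],
                  len = len[first], key = key[first],
                  stringsAsFactors = FALSE)
  g$w <- w[match(g$key, ord)]
  g
}

#' Histogram of 5'-5' overlaps between opposite-strand reads
#'
#' Counts every plus/minus read pair by [overlap_len()] using a
#' position-indexed sweep (exactly equal to the quadratic all-pairs count),
#' and converts counts to z-scores over the window `o = o_min..o_max` using
#' the population standard deviation; the signal bin is part of the
#' background. In `per_alignment` mode each aligned pair contributes the
#' product of the two reads' `count` fields; `per_species` mode first
#' collapses identical (contig, span, strand, sequence) reads to one
#' species each.
#'
#' @param reads alignment table with both strands.
#' @param o_max largest overlap scored.
#' @param same_length_only if `TRUE`, only pairs of equal read length are
#'   counted.
#' @param query_len if not `NULL`, restrict to reads of exactly this length.
#' @param mode pair-counting mode, `"per_alignment"` or `"per_species"`.
#' @param o_min smallest overlap in the z-score window.
#' @return An object of class `overlap_histogram`: list with `counts`
#'   (named vector over `1..o_max`), `z` (same shape; `NA` outside the
#'   window or when the window sd is 0), `n_pairs`, and the call
#'   parameters.
#' @export
overlap_histogram <- function(reads, o_max = 30L, same_length_only = FALSE,
                              query_len = NULL,
                              mode = c("per_alignment", "per_species"),
                              o_min = 1L) {
  mode <- match.arg(mode)
  if (!is.null(query_len)) {
    reads <- reads[reads$end - reads$start == query_len, , drop = FALSE]
    same_length_only <- TRUE
  }
  if (mode == "per_species") reads <- collapse_species(reads)
  counts <- stats::setNames(numeric(o_max), seq_len(o_max))
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  if (nrow(plus) && nrow(minus)) {
    pg <- fp_groups(plus, plus$count)
    mg <- fp_groups(minus, minus$count)
    lmax <- 50L
    # per-(contig, fp) minus weights, by exact length and cumulative (>= o)
    mkey <- paste(mg$contig, mg$fp, sep = "\1")
    upos <- !duplicated(mkey)
    ukey <- mkey[upos]
    m_by_len <- matrix(0, nrow = length(ukey), ncol = lmax)
    idx <- cbind(match(mkey, ukey), mg$len)
    m_by_len[idx] <- m_by_len[idx] + mg$w
    m_cum <- t(apply(m_by_len, 1L, function(r) rev(cumsum(rev(r)))))
    if (length(ukey) == 1L) m_cum <- matrix(m_cum, nrow = 1L)

    np <- nrow(pg)
    ip <- rep(seq_len(np), each = o_max)
    o <- rep(seq_len(o_max), np)
    keep <- o <= pg$len[ip]
    ip <- ip[keep]; o <- o[keep]
    tkey <- paste(pg$contig[ip], pg$fp[ip] + o - 1L, sep = "\1")
    m <- match(tkey, ukey)
    hit <- !is.na(m)
    ip <- ip[hit]; o <- o[hit]; m <- m[hit]
    if (length(o)) {
      wm <- if (same_length_only) {
        m_by_len[cbind(m, pg$len[ip])]   # o <= len_p (== len_m) already holds
      } else {
        m_cum[cbind(m, o)]               # total minus weight with len >= o
      }
      wprod <- pg$w[ip] * wm
      acc <- rowsum(wprod, group = o)
      counts[rownames(acc)] <- as.vector(acc)
    }
  }
  window <- seq.int(o_min, o_max)
  structure(list(counts = counts, z = zscores(counts, window),
                 n_pairs = sum(counts), o_min = o_min, o_max = o_max,
                 same_length_only = same_length_only,
                 query_len = query_len, mode = mode),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat("overlap histogram (", x$mode,
      if (x$same_length_only) ", same-length pairs" else "",
      "): ", x$n_pairs, " pairs over o = 1..", x$o_max, "\n", sep = "")
  top <- order(x$counts, decreasing = TRUE)[1:3]
  cat("top overlaps:", paste0("o=", top, " (n=", round(x$counts[top], 2),
                              ", z=", round(x$z[top], 2), ")",
                              collapse = "; "), "\n")
  invisible(x)
}

#' Ping-pong z-score
#'
#' z-score of the 10-nt 5'-5' overlap bin, the hallmark of ping-pong piRNA
#' amplification.
#'
#' @inheritParams overlap_histogram
#' @param ... passed to [overlap_histogram()].
#' @return A single number, or `NA` when fewer than two reads are present
#'   or the histogram is degenerate.
#' @export
pingpong_z <- function(reads, o_max = 30L, ...) {
  if (nrow(reads) < 2L) return(NA_real_)
  h <- overlap_histogram(reads, o_max = o_max, ...)
  unname(h$z["10"])
}

#' Dicer z-score for length-L reads
#'
#' Restricts the overlap histogram to pairs in which both reads have length
#' `L` and returns the z-score at `o = L - 2`, the 2-nt 3' overhang
#' configuration RNase III cleavage leaves. The z window runs to the
#' structural maximum overlap `L`.
#'
#' @param reads alignment table.
#' @param L read length in nt (typically 20-23).
#' @param o_min smallest overlap in the z window.
#' @param mode pair-counting mode.
#' @return z-score at `L - 2`, or `NA` when fewer than two length-`L` reads
#'   exist or the histogram is degenerate.
#' @export
dicer_z <- function(reads, L = 21L, o_min = 1L,
                    mode = c("per_alignment", "per_species")) {
  mode <- match.arg(mode)
  sub <- reads[reads$end - reads$start == L, , drop = FALSE]
  if (nrow(sub) < 2L) return(NA_real_)
  h <- overlap_histogram(sub, o_max = L, query_len = L, mode = mode,
                         o_min = o_min)
  unname(h$z[as.character(L - 2L)])
}

#' First-nucleotide bias
#'
#' Fraction of reads (weighted by `count`) whose first base is `base`;
#' reads with `N` (or no sequence) at the first position are excluded from
#' the denominator. With `base = "T"` this is the 1U bias diagnostic of
#' PIWI loading.
#'
#' @param reads alignment table with sequences.
#' @param base the nucleotide tested (DNA alphabet; U is stored as T).
#' @return Fraction in `[0, 1]`, or `NA` when no read has a scorable first
#'   base.
#' @export
first_base_bias <- function(reads, base = "T") {
  first <- substr(reads$seq, 1L, 1L)
  ok <- !is.na(first) & first %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(reads$count[ok & first == base]) / sum(reads$count[ok])
}

modal_value <- function(x, w) {
  agg <- rowsum(w, x)
  as.integer(rownames(agg)[which.max(agg)])
}

#' Phasing (Zucchini) statistics
#'
#' For each strand separately, reads are reduced to their distinct 5'
#' positions (multiplicity ignored: phasing is positional). Walking the
#' positions in transcript order, the distance from the upstream position's
#' representative 3' end (modal read end at that 5' position) to the next
#' 5' end is recorded: immediately adjacent head-to-tail reads give
#' `d = 1`, the tightest Zucchini register. Distances from both strands are
#' pooled into a histogram over `d = 0..d_max` with z-scores (population
#' sd, signal included in background).
#'
#' When `genome` is supplied, a positional U profile is also computed: each
#' read's 5' end anchors a window and the genome base identity (on the read
#' strand) is recorded at offsets `1..window`; a phased locus shows a
#' second U peak at `read_len + gap`, the first base of the next read.
#'
#' @param reads alignment table.
#' @param genome optional [Biostrings::DNAStringSet] for the U profile.
#' @param d_max largest distance scored.
#' @param window U-profile width in nt.
#' @return Object of class `phasing_profile`: list with `counts`, `z`
#'   (over `d = 0..d_max`), `n_intervals`, and `u_profile` (length
#'   `window`, or `NULL` without a genome). `NA` fields when fewer than two
#'   distinct 5' positions exist on every strand.
#' @export
phasing_stats <- function(reads, genome = NULL, d_max = 30L, window = 35L) {
  dists <- integer()
  n_pos <- 0L
  for (str in c("+", "-")) {
    sub <- reads[reads$strand == str, , drop = FALSE]
    if (nrow(sub) == 0L) next
    fp <- five_prime(sub)
    tp <- three_prime(sub)
    for (ctg in unique(sub$contig)) {
      sel <- sub$contig == ctg
      f <- fp[sel]; t3 <- tp[sel]; w <- sub$count[sel]
      upos <- sort(unique(f), decreasing = (str == "-"))
      n_pos <- n_pos + length(upos)
      if (length(upos) < 2L) next
      rep3 <- vapply(upos, function(p) modal_value(t3[f == p], w[f == p]),
                     integer(1))
      d <- if (str == "+") {
        upos[-1L] - rep3[-length(rep3)]
      } else {
        rep3[-length(rep3)] - upos[-1L]
      }
      dists <- c(dists, d)
    }
  }
  if (length(dists) == 0L) {
    return(structure(list(counts = NULL, z = NULL, n_intervals = 0L,
                          n_positions = n_pos, u_profile = NULL,
                          d_max = d_max),
                     class = "phasing_profile"))
  }
  counts <- stats::setNames(numeric(d_max + 1L), 0:d_max)
  tab <- table(dists[dists >= 0L & dists <= d_max])
  counts[names(tab)] <- as.numeric(tab)
  z <- zscores(counts, seq_along(counts))
  u_profile <- if (!is.null(genome)) u_profile_5p(reads, genome, window)
  structure(list(counts = counts, z = z, n_intervals = length(dists),
                 n_positions = n_pos, u_profile = u_profile, d_max = d_max),
            class = "phasing_profile")
}

#' @export
print.phasing_profile <- function(x, ...) {
  if (is.null(x$counts)) {
    cat("phasing profile: not available (<2 distinct 5' positions)\n")
    return(invisible(x))
  }
  top <- names(x$counts)[which.max(x$counts)]
  cat("phasing profile:", x$n_intervals, "consecutive-position intervals;",
      "modal distance d =", top, "(z =",
      round(x$z[top], 2), ")\n")
  invisible(x)
}

# fraction of reads (count-weighted) whose genome base at 5'-anchored
# offset k (1..window, read strand) is T
u_profile_5p <- function(reads, genome, window = 35L) {
  num <- numeric(window)
  den <- numeric(window)
  for (str in c("+", "-")) {
    sub <- reads[reads$strand == str, , drop = FALSE]
    if (nrow(sub) == 0L) next
    fp <- five_prime(sub)
    for (ctg in unique(sub$contig)) {
      sel <- sub$contig == ctg
      f <- fp[sel]; w <- sub$count[sel]
      clen <- length(genome[[ctg]])
      if (str == "+") {
        ok <- f + window <= clen
        rng <- IRanges::IRanges(f[ok] + 1L, f[ok] + window)
      } else {
        ok <- f - window + 1L >= 0L
        rng <- IRanges::IRanges(f[ok] - window + 2L, f[ok] + 1L)
      }
      if (!any(ok)) next
      seqs <- Biostrings::extractAt(genome[[ctg]], rng)
      if (str == "-") seqs <- Biostrings::reverseComplement(seqs)
      mat <- matrix(unlist(strsplit(as.character(seqs), "")),
                    ncol = window, byrow = TRUE)
      wt <- w[ok]
      num <- num + colSums((mat == "T") * wt)
      den <- den + sum(wt)
    }
  }
  ifelse(den > 0, num / den, NA_real_)
}
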