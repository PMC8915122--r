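# Independent brute-force reference implementations used to validate the
# package's indexed algorithms, plus small fixture builders.

# all-pairs 5'-5' overlap count via dense outer products
oracle_overlap_counts <- function(aln, o_max = 30L, same_length_only = FALSE,
                                  query_len = NULL,
                                  mode = "per_alignment") {
  if (!is.null(query_len)) {
    aln <- aln[aln$end - aln$start == query_len, , drop = FALSE]
    same_length_only <- TRUE
  }
  if (mode == "per_species") {
    key <- paste(aln$contig, aln$start, aln$end, aln$strand, aln$seq)
    aln <- aln[!duplicated(key), , drop = FALSE]
    aln$count <- 1L
  }
  p <- aln[aln$strand == "+", , drop = FALSE]
  m <- aln[aln$strand == "-", , drop = FALSE]
  counts <- stats::setNames(numeric(o_max), seq_len(o_max))
  if (nrow(p) == 0L || nrow(m) == 0L) return(counts)
  O <- outer(m$end, p$start, "-")                     # minus rows x plus cols
  len_p <- p$end - p$start
  len_m <- m$end - m$start
  valid <- outer(m$contig, p$contig, "==") & O >= 1L &
    sweep(O, 2L, len_p, "<=") & (O <= len_m)
  if (same_length_only) valid <- valid & outer(len_m, len_p, "==")
  w <- outer(m$count, p$count)
  for (o in seq_len(o_max)) {
    counts[o] <- sum(w[valid & O == o])
  }
  counts
}

# consecutive-distinct-5'-position distances, naive per-strand walk
oracle_phasing_counts <- function(aln, d_max = 30L) {
  counts <- stats::setNames(numeric(d_max + 1L), 0:d_max)
  for (str in c("+", "-")) {
    sub <- aln[aln$strand == str, , drop = FALSE]
    for (ctg in unique(sub$contig)) {
      s <- sub[sub$contig == ctg, , drop = FALSE]
      fp <- if (str == "+") s$start else s$end - 1L
      tp <- if (str == "+") s$end - 1L else s$start
      ord <- unique(sort(fp, decreasing = (str == "-")))
      if (length(ord) < 2L) next
      for (i in seq_len(length(ord) - 1L)) {
        here <- fp == ord[i]
        # modal 3' end at this 5' position, count-weighted
        tb <- tapply(s$count[here], tp[here], sum)
        t3 <- as.integer(names(tb)[which.max(tb)])
        d <- if (str == "+") ord[i + 1L] - t3 else t3 - ord[i + 1L]
        if (d >= 0L && d <= d_max) counts[d + 1L] <- counts[d + 1L] + 1
      }
    }
  }
  counts
}

# per-base threshold scan with explicit gap merging
oracle_find_loci <- function(track, min_cov, merge_window, strict = FALSE) {
  res <- list()
  for (ctg in names(track)) {
    v <- track[[ctg]]
    pass <- if (strict) v > min_cov else v >= min_cov
    islands <- list()
    i <- 1L
    while (i <= length(v)) {
      if (pass[i]) {
        j <- i
        while (j < length(v) && pass[j + 1L]) j <- j + 1L
        islands[[length(islands) + 1L]] <- c(i - 1L, j)   # 0-based [s, e)
        i <- j + 1L
      } else i <- i + 1L
    }
    if (length(islands) == 0L) next
    merged <- islands[1]
    for (k in seq_along(islands)[-1]) {
      last <- merged[[length(merged)]]
      gap <- islands[[k]][1] - last[2]
      if (gap < merge_window) {
        merged[[length(merged)]] <- c(last[1], islands[[k]][2])
      } else {
        merged[[length(merged) + 1L]] <- islands[[k]]
      }
    }
    res[[ctg]] <- data.frame(
      contig = ctg,
      start = vapply(merged, `[`, numeric(1), 1),
      end = vapply(merged, `[`, numeric(1), 2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer())
  }
  rownames(out) <- NULL
  out
}

# exhaustive short-loop inverted-repeat search over all loop placements
oracle_short_loops <- function(seq, min_stem, loop_sizes = c(3L, 4L),
                               gu = FALSE) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  pair <- function(a, b) {
    ok <- (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
    if (gu) ok <- ok | (a == "G" & b == "T") | (a == "T" & b == "G")
    ok
  }
  hits <- list()
  for (l in loop_sizes) {
    for (i in seq_len(max(0L, n - l + 1L))) {
      if (i + l - 1L > n) next
      if (pair(s[i], s[i + l - 1L])) next
      k <- 0L
      repeat {
        a <- i - 1L - k
        b <- i + l + k
        if (a < 1L || b > n || !pair(s[a], s[b])) break
        k <- k + 1L
      }
      if (k >= min_stem) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = i - 1L - k, end = i + l + k - 1L, stem_len = k,
          loop_len = l)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$loop_len), , drop = FALSE]
}

# random alignment table (no sequences) for oracle comparisons
random_alignments <- function(n, span = 2000L, origin = 0L,
                              lens = 15:32, contigs = "contig_1",
                              max_count = 1L) {
  len <- sample(lens, n, replace = TRUE)
  start <- origin + sample.int(span - max(lens), n, replace = TRUE) - 1L
  alignment_table(
    contig = sample(contigs, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    seq = NA_character_,
    n_hits = sample(1:3, n, replace = TRUE),
    count = sample.int(max_count, n, replace = TRUE)
  )
}

# pair each discovered locus with the truth locus it overlaps most
match_truth <- function(loci, truth) {
  vapply(seq_len(nrow(loci)), function(i) {
    ov <- pmin(loci$end[i], truth$end) - pmax(loci$start[i], truth$start)
    ov[truth$contig != loci$contig[i]] <- -1L
    if (max(ov) <= 0) NA_character_ else truth$locus_id[which.max(ov)]
  }, character(1))
}
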