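#' 3' overhangs of a mature:star miRNA duplex
#'
#' The two arms of a hairpin pair antiparallel within the precursor. With
#' the precursor spanning `[h1, h2)` and the stem pairing register
#' reflecting around the precursor (transcript position `x` pairs with
#' `Lp - 1 - x`, `Lp = h2 - h1`), the 3' overhang at each duplex end is
#' determined by the arm coordinates alone. In transcript-relative
#' coordinates with upstream arm `[p1, p2)` and downstream arm `[q1, q2)`:
#' the overhang at the precursor-5' end (downstream arm's 3' overhang) is
#' `q2 + p1 - Lp` and the loop-proximal overhang (upstream arm's 3') is
#' `p2 + q1 - Lp`. RNase III cleavage leaves both equal to 2.
#'
#' @param mature,star length-2 numeric vectors, 0-based half-open genomic
#'   arm intervals (mature may be the 5p or the 3p arm).
#' @param precursor length-2 numeric vector, precursor interval containing
#'   both arms.
#' @param strand precursor strand.
#' @return Named numeric vector `c(overhang_5p_side, overhang_3p_side)`;
#'   the first element is the overhang at the duplex end nearest the
#'   precursor 5' end, the second at the loop-proximal end.
#' @export
duplex_overhangs <- function(mature, star, precursor, strand = "+") {
  iv <- rbind(mature, star)
  if (any(iv[, 1] < precursor[1]) || any(iv[, 2] > precursor[2])) {
    stop("arms must lie within the precursor")
  }
  if (max(mature[1], star[1]) < min(mature[2], star[2])) {
    stop("mature and star arms overlap")
  }
  lp <- precursor[2] - precursor[1]
  rel <- if (strand == "+") {
    iv - precursor[1]
  } else {
    cbind(precursor[2] - iv[, 2], precursor[2] - iv[, 1])
  }
  up <- rel[which.min(rel[, 1]), ]
  dn <- rel[which.max(rel[, 1]), ]
  c(overhang_5p_side = unname(dn[2] + up[1] - lp),
    overhang_3p_side = unname(up[2] + dn[1] - lp))
}

#' 5' processing precision of an arm pileup
#'
#' Fraction of an arm's reads sharing the single most common 5' position —
#' the statistic behind the ">90% of reads share a 5' base" curation rule.
#'
#' @param arm_pileup named numeric vector, 5' position -> read count.
#' @return Fraction in `(0, 1]`, or `NA` for an empty pileup.
#' @export
five_prime_precision <- function(arm_pileup) {
  if (length(arm_pileup) == 0L || sum(arm_pileup) == 0) return(NA_real_)
  max(arm_pileup) / sum(arm_pileup)
}

#' Pile up read 5' ends on a hairpin arm
#'
#' @param aln alignment table.
#' @param contig,start,end,strand arm location (0-based half-open).
#' @param slop tolerance in nt around the arm for the 5' end.
#' @return Named numeric vector, 5' position -> summed count.
#' @export
arm_pileup <- function(aln, contig, start, end, strand, slop = 0L) {
  fp <- five_prime(aln)
  sel <- aln$contig == contig & aln$strand == strand &
    fp >= start - slop & fp < end + slop
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  acc <- rowsum(as.numeric(aln$count[sel]), fp[sel])
  stats::setNames(as.vector(acc), rownames(acc))
}

#' Triage a miRNA candidate
#'
#' Pure decision rule over the three curation measurements:
#' `overhang_ok` — both duplex 3' overhangs equal 2 nt (RNase III
#' geometry); `precision_ok` — mature-arm 5' precision strictly above
#' `precision_min`; star support — star-arm coverage of at least
#' `star_min` reads ("exceeding a coverage of eight"). A candidate passing
#' both structural criteria with star support is `confident`; passing both
#' without star support, or exactly one of the two, makes it `candidate`;
#' failing both makes it a `false_positive`.
#'
#' @param overhangs length-2 numeric vector from [duplex_overhangs()].
#' @param precision mature-arm 5' precision from [five_prime_precision()].
#' @param star_coverage star-arm read count.
#' @param precision_min exclusive precision threshold.
#' @param star_min minimum star coverage for a confident call.
#' @return List with `overhang_ok`, `precision_ok`, `star_coverage`,
#'   `label` and `reasons`.
#' @export
classify_mirna <- function(overhangs, precision, star_coverage,
                           precision_min = 0.90, star_min = 9L) {
  if (is.na(precision)) stop("mature arm pileup is required")
  overhang_ok <- !anyNA(overhangs) && all(overhangs == 2)
  precision_ok <- precision > precision_min
  star_ok <- star_coverage >= star_min
  label <- if (overhang_ok && precision_ok) {
    if (star_ok) "confident" else "candidate"
  } else if (overhang_ok || precision_ok) {
    "candidate"
  } else {
    "false_positive"
  }
  reasons <- c(
    if (!overhang_ok) "duplex 3' overhangs not (2,2)",
    if (!precision_ok) sprintf("5' precision %.3f <= %.2f", precision,
                               precision_min),
    if (overhang_ok && precision_ok && !star_ok)
      sprintf("star coverage %d < %d", star_coverage, star_min)
  )
  list(overhang_ok = overhang_ok, precision_ok = precision_ok,
       star_coverage = star_coverage, label = label,
       reasons = if (is.null(reasons)) character() else reasons)
}

#' Curate a table of miRNA hairpin candidates against alignments
#'
#' For each candidate (precursor plus mature/star arm coordinates),
#' measures the duplex overhangs, the mature-arm 5' precision and the
#' star-arm coverage (reads whose 5' end falls within `star_slop` nt of
#' the annotated star 5' end), then applies [classify_mirna()].
#'
#' @param candidates `data.frame` with columns `contig`,
#'   `precursor_start`, `precursor_end`, `strand`, `mature_start`,
#'   `mature_end`, `star_start`, `star_end` (0-based half-open).
#' @param aln alignment table.
#' @param precision_min,star_min rule thresholds, see [classify_mirna()].
#' @param star_slop tolerance in nt for star 5' ends.
#' @param mature_slop tolerance in nt around the mature arm when piling up
#'   5' ends: reads processed a base or two off the annotated arm still
#'   belong to the arm's pileup and must count against its precision.
#' @return `candidates` augmented with `overhang_5p`, `overhang_3p`,
#'   `overhang_ok`, `precision`, `precision_ok`, `star_coverage`, `label`,
#'   `reasons`.
#' @export
curate_hairpins <- function(candidates, aln, precision_min = 0.90,
                            star_min = 9L, star_slop = 2L,
                            mature_slop = 2L) {
  n <- nrow(candidates)
  out <- candidates
  out$overhang_5p <- out$overhang_3p <- NA_real_
  out$overhang_ok <- out$precision_ok <- NA
  out$precision <- NA_real_
  out$star_coverage <- NA_real_
  out$label <- NA_character_
  out$reasons <- NA_character_
  for (i in seq_len(n)) {
    cc <- candidates[i, ]
    ov <- duplex_overhangs(c(cc$mature_start, cc$mature_end),
                           c(cc$star_start, cc$star_end),
                           c(cc$precursor_start, cc$precursor_end),
                           cc$strand)
    mat_pile <- arm_pileup(aln, cc$contig, cc$mature_start, cc$mature_end,
                           cc$strand, slop = mature_slop)
    star_5p <- if (cc$strand == "+") cc$star_start else cc$star_end - 1L
    star_pile <- arm_pileup(aln, cc$contig, star_5p, star_5p + 1L,
                            cc$strand, slop = star_slop)
    prec <- five_prime_precision(mat_pile)
    v <- classify_mirna(ov, prec, sum(star_pile), precision_min, star_min)
    out$overhang_5p[i] <- ov[1]; out$overhang_3p[i] <- ov[2]
    out$overhang_ok[i] <- v$overhang_ok
    out$precision[i] <- prec; out$precision_ok[i] <- v$precision_ok
    out$star_coverage[i] <- v$star_coverage
    out$label[i] <- v$label
    out$reasons[i] <- paste(v$reasons, collapse = "; ")
  }
  out
}

wc_pairs <- function(a, b, gu = FALSE) {
  p <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (gu) p <- p | (a == "G" & b == "T") | (a == "T" & b == "G")
  p
}

#' Scan a precursor for short-loop perfect-stem hairpins
#'
#' Finds maximal perfect inverted repeats (Watson-Crick pairing only by
#' default; no mismatches or bulges) whose loop is exactly one of
#' `loop_sizes` nt and whose stem reaches at least `min_stem` bp. Loops
#' are exact: a hit is reported only when the outermost loop bases do not
#' themselves pair, so the same stem is not also a hit at a smaller loop
#' size.
#'
#' @param precursor_seq character, DNA sequence (U accepted, stored as T).
#' @param min_stem minimum stem length in bp.
#' @param loop_sizes loop lengths searched.
#' @param gu if `TRUE`, allow G:U wobble pairs in the stem.
#' @return `data.frame` with `start` (0-based, outermost paired base),
#'   `end` (exclusive), `stem_len`, `loop_len`; zero rows when nothing is
#'   found.
#' @export
short_loop_scan <- function(precursor_seq, min_stem = 18L,
                            loop_sizes = c(3L, 4L), gu = FALSE) {
  s <- strsplit(toupper(chartr("Uu", "Tt", precursor_seq)), "")[[1]]
  n <- length(s)
  hits <- list()
  for (l in loop_sizes) {
    if (n < 2L * min_stem + l) next
    for (i in seq_len(n - l + 1L)) {          # loop occupies s[i .. i+l-1]
      if (wc_pairs(s[i], s[i + l - 1L], gu)) next   # loop would shrink
      k <- 0L
      while (i - 1L - k >= 1L && i + l + k <= n &&
             wc_pairs(s[i - 1L - k], s[i + l + k], gu)) {
        k <- k + 1L
      }
      if (k >= min_stem) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = i - 1L - k, end = i + l + k - 1L,
          stem_len = k, loop_len = l)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$loop_len), , drop = FALSE]
}

#' Per-library miRNA expression matrix
#'
#' Mature-arm read counts per library, normalized to reads per million
#' mapped ([normalize_expression()]) and log2(RPM + 1) transformed.
#'
#' @param candidates candidate table as in [curate_hairpins()].
#' @param libraries named list of alignment tables, one per library.
#' @param mapped_totals optional named numeric vector of per-library
#'   mapped totals; defaults to each library's summed `count`.
#' @return List of candidates x libraries matrices: `counts`, `rpm`,
#'   `log2_rpm`.
#' @export
quantify_mirna <- function(candidates, libraries, mapped_totals = NULL) {
  if (is.null(mapped_totals)) {
    mapped_totals <- vapply(libraries, function(a) sum(a$count), numeric(1))
  }
  counts <- vapply(names(libraries), function(lib) {
    a <- libraries[[lib]]
    vapply(seq_len(nrow(candidates)), function(i) {
      cc <- candidates[i, ]
      sum(arm_pileup(a, cc$contig, cc$mature_start, cc$mature_end,
                     cc$strand))
    }, numeric(1))
  }, numeric(nrow(candidates)))
  counts <- matrix(counts, nrow = nrow(candidates),
                   dimnames = list(rownames(candidates), names(libraries)))
  rpm <- sweep(counts, 2L, mapped_totals, function(x, tot) x * 1e6 / tot)
  list(counts = counts, rpm = rpm, log2_rpm = log2(rpm + 1))
}
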