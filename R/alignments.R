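#' Build an alignment table
#'
#' The internal currency of the package: one row per mapped read (alignment),
#' in 0-based half-open genomic coordinates. Conversions from the 1-based
#' conventions of SAM and GFF3 happen only at format boundaries
#' ([load_alignments()], [load_annotations()]); everything downstream assumes
#' this convention.
#'
#' @param contig character, reference sequence name.
#' @param start integer, 0-based inclusive start.
#' @param end integer, exclusive end; `end - start` is the read length in nt.
#' @param strand character, `"+"` or `"-"`.
#' @param seq character or `NA`, read bases 5'->3' in read orientation
#'   (for minus-strand alignments this is the reverse complement of the
#'   reference slice). Alphabet ACGTN; U is stored as T.
#' @param n_hits positive integer, number of genome alignments of the read
#'   (bowtie report count / SAM `NH` tag).
#' @param count positive integer, collapsed read multiplicity.
#'
#' @return A `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `seq`, `n_hits`, `count`.
#' @export
alignment_table <- function(contig = character(), start = integer(),
                            end = integer(), strand = character(),
                            seq = NA_character_, n_hits = 1L, count = 1L) {
  n <- length(start)
  aln <- data.frame(
    contig = rep_len(as.character(contig), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    seq = rep_len(as.character(seq), n),
    n_hits = rep_len(as.integer(n_hits), n),
    count = rep_len(as.integer(count), n),
    stringsAsFactors = FALSE
  )
  validate_alignments(aln)
  aln
}

validate_alignments <- function(aln) {
  stopifnot(is.data.frame(aln))
  need <- c("contig", "start", "end", "strand", "seq", "n_hits", "count")
  missing_cols <- setdiff(need, names(aln))
  if (length(missing_cols)) {
    stop("alignment table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(aln) == 0L) return(invisible(aln))
  len <- aln$end - aln$start
  if (any(len < 1L) || any(len > 50L)) {
    stop("alignment lengths must lie in [1, 50] nt")
  }
  if (!all(aln$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  has_seq <- !is.na(aln$seq)
  if (any(nchar(aln$seq[has_seq]) != len[has_seq])) {
    stop("sequence length must equal end - start")
  }
  if (any(aln$n_hits < 1L) || any(aln$count < 1L)) {
    stop("n_hits and count must be positive")
  }
  invisible(aln)
}

#' 5' and 3' genomic positions of alignments
#'
#' Strand-aware ends: on `+` the 5' end is `start` and the 3' end is
#' `end - 1`; on `-` the 5' end is `end - 1` and the 3' end is `start`.
#' Both are 0-based positions of the terminal nucleotide itself, so
#' `abs(five_prime(a) - three_prime(a)) == length - 1` always holds.
#'
#' @param aln alignment table (see [alignment_table()]).
#' @return Integer vector of genomic positions, one per alignment.
#' @export
five_prime <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$end - 1L)
}

#' @rdname five_prime
#' @export
three_prime <- function(aln) {
  ifelse(aln$strand == "+", aln$end - 1L, aln$start)
}

#' Read length of each alignment in nt
#' @param aln alignment table.
#' @return Integer vector.
#' @export
read_length <- function(aln) aln$end - aln$start

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Load small RNA alignments from SAM/BAM or the BED read dialect
#'
#' Normalizes records into the internal alignment table: 0-based half-open
#' coordinates, read sequences in read orientation, and a length /
#' multimapping filter applied up front. Highly redundant reads are excluded
#' by `max_hits` (the study convention drops reads reported at more than 100
#' genomic positions).
#'
#' SAM/BAM input (`.sam`, `.bam`) is parsed with Rsamtools; the `NH` tag
#' supplies `n_hits` (missing tag = 1, noted once per file). SAM stores the
#' minus-strand SEQ field in reference orientation, so it is
#' reverse-complemented back into read orientation here.
#'
#' The BED dialect is six tab-separated columns:
#' contig, start, end, name = read sequence (or "." for none),
#' score = n_hits, strand; an optional seventh column carries `count`.
#'
#' @param path file path; format chosen by extension (`.sam`, `.bam`, else
#'   BED dialect).
#' @param min_len,max_len read length bounds in nt, inclusive.
#' @param max_hits maximum number of genome alignments per read.
#' @return Alignment table (see [alignment_table()]).
#' @export
load_alignments <- function(path, min_len = 15L, max_len = 32L,
                            max_hits = 100L) {
  stopifnot(min_len <= max_len, max_hits >= 1L)
  ext <- tolower(tools::file_ext(path))
  aln <- if (ext %in% c("sam", "bam")) {
    read_sam_alignments(path)
  } else {
    read_bed_alignments(path)
  }
  len <- aln$end - aln$start
  aln <- aln[len >= min_len & len <= max_len & aln$n_hits <= max_hits, ,
             drop = FALSE]
  rownames(aln) <- NULL
  validate_alignments(aln)
  aln
}

read_sam_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam),
                     overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "seq", "qwidth"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$pos)
  if (n == 0L) return(alignment_table())
  nh <- rec$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  if (anyNA(nh)) {
    message("load_alignments: NH tag absent for some records in ", path,
            "; treating n_hits as 1")
    nh[is.na(nh)] <- 1L
  }
  seq <- as.character(rec$seq)
  minus <- as.character(rec$strand) == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  seq[seq == ""] <- NA_character_
  data.frame(
    contig = as.character(rec$rname),
    start = rec$pos - 1L,                 # SAM POS is 1-based
    end = rec$pos - 1L + rec$qwidth,
    strand = as.character(rec$strand),
    seq = seq,
    n_hits = as.integer(nh),
    count = 1L,
    stringsAsFactors = FALSE
  )
}

read_bed_alignments <- function(path) {
  bed <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("unparseable BED dialect file ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(bed) < 6L) {
    stop("BED read dialect needs >= 6 columns, got ", ncol(bed))
  }
  start <- suppressWarnings(as.integer(bed[[2]]))
  end <- suppressWarnings(as.integer(bed[[3]]))
  nh <- suppressWarnings(as.integer(bed[[5]]))
  bad <- which(is.na(start) | is.na(end) | is.na(nh))
  if (length(bad)) {
    stop("unparseable BED dialect record at line ", bad[1], " of ", path)
  }
  seq <- toupper(chartr("Uu", "Tt", bed[[4]]))
  seq[seq == "." | seq == ""] <- NA_character_
  count <- if (ncol(bed) >= 7L) as.integer(bed[[7]]) else 1L
  data.frame(
    contig = bed[[1]], start = start, end = end, strand = bed[[6]],
    seq = seq, n_hits = nh, count = count, stringsAsFactors = FALSE
  )
}

#' Load gene/exon annotations from GFF3 and derive introns
#'
#' Introns are computed per gene as the gene span minus the union of its
#' exons. GFF3 1-based closed coordinates are converted to the internal
#' 0-based half-open convention. Exons falling outside their parent gene are
#' clipped with a warning.
#'
#' @param gff3_path path to a GFF3 file with `gene` and `exon` features
#'   (exons carry a `Parent` attribute).
#' @return A list with elements `genes`, `exons`, `introns`, each a
#'   `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `gene_id` (0-based half-open).
#' @export
load_annotations <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  gene_id <- as.character(genes$ID)
  if (anyNA(gene_id)) gene_id[is.na(gene_id)] <- paste0("gene_", which(is.na(gene_id)))
  parent <- as.character(S4Vectors::unstrsplit(exons$Parent, sep = ","))

  as_df <- function(g, ids) {
    data.frame(contig = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               strand = as.character(GenomicRanges::strand(g)),
               gene_id = ids, stringsAsFactors = FALSE)
  }
  genes_df <- as_df(genes, gene_id)
  exons_df <- as_df(exons, parent)

  introns <- lapply(seq_len(nrow(genes_df)), function(i) {
    g <- genes_df[i, ]
    ex <- exons_df[exons_df$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex) == 0L) return(NULL)
    if (any(ex$start < g$start | ex$end > g$end)) {
      warning("exon outside parent gene ", g$gene_id, "; clipping")
      ex$start <- pmax(ex$start, g$start)
      ex$end <- pmin(ex$end, g$end)
    }
    gaps <- interval_complement(ex$start, ex$end, g$start, g$end)
    if (nrow(gaps) == 0L) return(NULL)
    data.frame(contig = g$contig, start = gaps$start, end = gaps$end,
               strand = g$strand, gene_id = g$gene_id,
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, introns)
  if (is.null(introns)) {
    introns <- genes_df[0, , drop = FALSE]
  }
  list(genes = genes_df, exons = exons_df, introns = introns)
}

# complement of union of [starts, ends) within [lo, hi)
interval_complement <- function(starts, ends, lo, hi) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  gaps_s <- integer(); gaps_e <- integer()
  cur <- lo
  for (i in seq_along(starts)) {
    if (starts[i] > cur) {
      gaps_s <- c(gaps_s, cur); gaps_e <- c(gaps_e, starts[i])
    }
    cur <- max(cur, ends[i])
  }
  if (cur < hi) {
    gaps_s <- c(gaps_s, cur); gaps_e <- c(gaps_e, hi)
  }
  data.frame(start = gaps_s, end = gaps_e)
}

sort_records <- function(df) {
  sorted <- !is.unsorted(order(df$contig, df$start))
  df[order(df$contig, df$start), , drop = FALSE]
}

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         format(x, scientific = FALSE, trim = TRUE),
         signif(x, 6))
}

#' Write intervals as BED6
#'
#' @param records data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (defaults `locus_<i>`, `.`, `+`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  if (nrow(records) && is.unsorted(order(records$contig, records$start))) {
    message("write_bed: sorting records by contig, start")
    records <- sort_records(records)
  }
  name <- if ("name" %in% names(records)) records$name else
    paste0("locus_", seq_len(nrow(records)))
  score <- if ("score" %in% names(records)) fmt_num(records$score) else "."
  strand <- if ("strand" %in% names(records)) records$strand else "+"
  lines <- if (nrow(records) == 0L) character() else
    paste(records$contig, records$start, records$end, name, score, strand,
          sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments in the BED read dialect
#'
#' Columns: contig, start, end, sequence (`.` if absent), n_hits, strand,
#' count. Readable back with [load_alignments()].
#'
#' @param aln alignment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(aln, path) {
  if (nrow(aln) && is.unsorted(order(aln$contig, aln$start))) {
    aln <- sort_records(aln)
  }
  seq <- ifelse(is.na(aln$seq), ".", aln$seq)
  lines <- if (nrow(aln) == 0L) character() else
    paste(aln$contig, aln$start, aln$end, seq, aln$n_hits, aln$strand,
          aln$count, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedgraph
#'
#' Adjacent bases with equal depth are merged into one interval line;
#' zero-depth runs are omitted.
#'
#' @param track named list of per-contig numeric depth vectors (element `i`
#'   is the depth at 0-based position `i - 1`), as from [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character()
  for (contig in names(track)) {
    v <- track[[contig]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- c(lines, paste(contig, starts[keep], ends[keep],
                            fmt_num(r$values[keep]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a tab-separated table
#'
#' Deterministic column order and fixed 6-significant-digit float formatting.
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write alignments as a SAM file
#'
#' Emits an unsorted SAM with `@SQ` headers taken from `contig_lengths`, a
#' 100% match CIGAR per read, and the `NH` tag carrying `n_hits`. Sequences
#' of minus-strand reads are stored in reference orientation, per the SAM
#' convention. Collapsed multiplicity is expanded so that `count` copies of
#' a row become `count` records.
#'
#' @param aln alignment table.
#' @param path output path ending in `.sam`.
#' @param contig_lengths named integer vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(contig_lengths),
                  "\tLN:", as.integer(contig_lengths)))
  aln <- sort_records(aln)
  aln <- aln[rep(seq_len(nrow(aln)), aln$count), , drop = FALSE]
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    len <- aln$end - aln$start
    seq <- ifelse(is.na(aln$seq), "*", aln$seq)
    minus <- aln$strand == "-" & !is.na(aln$seq)
    if (any(minus)) seq[minus] <- revcomp(seq[minus])
    body <- paste(paste0("r", seq_len(nrow(aln))), flag, aln$contig,
                  aln$start + 1L, 255L, paste0(len, "M"), "*", 0L, 0L,
                  seq, "*", paste0("NH:i:", aln$n_hits), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
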