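#' Identify Alu-derived internal exons
#'
#' An internal (neither first nor last) exon is called Alu-derived when a
#' single repeat copy covers at least `min_overlap_bp` of the exon and more
#' than `min_overlap_frac` of its length (strict inequality). When several
#' copies overlap an exon, the one with the largest intersection is taken
#' and the thresholds apply to that copy alone.
#'
#' @param transcripts a `transcript_model_list`.
#' @param repeats data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name` (subfamily, e.g. "AluSx"), `family`.
#' @param min_overlap_bp,min_overlap_frac the 25 bp / 50% thresholds.
#' @return data.frame of class `alu_exon_records`, one row per
#'   (exon, transcript) pair: exon coordinates, `exon_id`
#'   ("chrom:start-end:strand"), host ids, exon length and index, overlap
#'   statistics and repeat subfamily/family.
#' @export
find_alu_exons <- function(transcripts, repeats,
                           min_overlap_bp = 25L, min_overlap_frac = 0.5) {
  stopifnot(inherits(transcripts, "transcript_model_list"))
  check_repeats(repeats)
  tx_chroms <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  rp_chroms <- unique(repeats$chrom)
  if (length(tx_chroms) && nrow(repeats) &&
      length(intersect(tx_chroms, rp_chroms)) == 0) {
    stop(sprintf(
      "inconsistent chromosome names: transcripts use {%s}, repeats use {%s}",
      paste(tx_chroms, collapse = ","), paste(rp_chroms, collapse = ",")))
  }

  ## internal exons of every transcript
  rows <- list()
  for (tx in transcripts) {
    n <- nrow(tx$exons)
    if (n < 3) next
    for (i in 2:(n - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = tx$exons[i, "start"],
        end = tx$exons[i, "end"], strand = tx$strand,
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        exon_index = i, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(
    exon_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), transcript_id = character(0),
    gene_id = character(0), exon_index = integer(0), length = integer(0),
    overlap_bp = integer(0), overlap_frac = numeric(0),
    subfamily = character(0), family = character(0),
    stringsAsFactors = FALSE)
  class(empty) <- c("alu_exon_records", "data.frame")
  if (length(rows) == 0 || nrow(repeats) == 0) return(empty)
  ex <- do.call(rbind, rows)

  ex_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  rp_gr <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end))
  hits <- GenomicRanges::findOverlaps(ex_gr, rp_gr, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(ex_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(rp_gr)[S4Vectors::subjectHits(hits)]))

  ## best single repeat per exon row
  q <- S4Vectors::queryHits(hits)
  best <- tapply(seq_along(q), q, function(ii) ii[which.max(ov[ii])])
  qi <- as.integer(names(best))
  si <- S4Vectors::subjectHits(hits)[unlist(best)]
  ob <- ov[unlist(best)]
  len <- ex$end[qi] - ex$start[qi]
  frac <- ob / len
  keep <- ob >= min_overlap_bp & frac > min_overlap_frac
  if (!any(keep)) return(empty)
  qi <- qi[keep]; si <- si[keep]; ob <- ob[keep]
  len <- len[keep]; frac <- frac[keep]

  out <- data.frame(
    exon_id = sprintf("%s:%d-%d:%s", ex$chrom[qi], ex$start[qi], ex$end[qi],
                      ex$strand[qi]),
    chrom = ex$chrom[qi], start = ex$start[qi], end = ex$end[qi],
    strand = ex$strand[qi], transcript_id = ex$transcript_id[qi],
    gene_id = ex$gene_id[qi], exon_index = ex$exon_index[qi],
    length = len, overlap_bp = as.integer(ob), overlap_frac = frac,
    subfamily = repeats$name[si], family = repeats$family[si],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("alu_exon_records", "data.frame")
  out
}

check_repeats <- function(repeats) {
  need <- c("chrom", "start", "end", "strand", "name", "family")
  if (!all(need %in% names(repeats))) {
    stop("repeats must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(repeats) &&
      (any(repeats$end <= repeats$start) || any(!nzchar(repeats$family)))) {
    stop("repeat intervals must satisfy start < end with non-empty family")
  }
  invisible(TRUE)
}

#' Classify an exon's position relative to the CDS
#'
#' FIVE_UTR if the exon lies entirely 5' of the CDS start, THREE_UTR if
#' entirely 3' of the stop; CDS if it overlaps the CDS span by >= 1 bp
#' (exons straddling a UTR/CDS boundary are classified CDS).
#'
#' @param exon length-2 vector `c(start, end)` (0-based half-open).
#' @param transcript host `transcript_model` with CDS annotation; a
#'   transcript without CDS raises a `noncoding_transcript` condition.
#' @return one of "FIVE_UTR", "CDS", "THREE_UTR".
#' @export
classify_exon_region <- function(exon, transcript) {
  transcript_orf_start(transcript)  # raises noncoding_transcript if no CDS
  cs <- transcript$cds_start
  ce <- transcript$cds_end
  if (exon[2] > cs && exon[1] < ce) return("CDS")
  upstream <- exon[2] <= cs
  if (transcript$strand == "+") {
    if (upstream) "FIVE_UTR" else "THREE_UTR"
  } else {
    if (upstream) "THREE_UTR" else "FIVE_UTR"
  }
}

#' Reconstruct the exon-inclusion ORF of a transcript
#'
#' Splices the candidate exon between its flanking annotated exons, rebuilds
#' the mature mRNA on the sense strand, and translates from the annotated
#' start codon to the first in-frame stop. An exon whose length is not a
#' multiple of 3 shifts the downstream reading frame; if no stop codon is
#' reached the result is flagged `stop_lost` rather than dropped.
#'
#' @param transcript host `transcript_model` (skipping isoform) with an
#'   annotated start codon.
#' @param alu_exon length-2 vector `c(start, end)` inside one intron.
#' @param genome named DNAStringSet.
#' @return object of class `inclusion_orf`: the mature `mrna`, `orf_nt`,
#'   `protein`, mRNA coordinates of the ORF start and stop codon, the exon's
#'   mRNA interval and amino-acid span (codon-partial boundaries assigned to
#'   the exon), the last exon-exon junction position, and flags
#'   (`stop_lost`, `frameshift`).
#' @export
build_inclusion_orf <- function(transcript, alu_exon, genome) {
  orf_g <- transcript_orf_start(transcript)
  tx2 <- insert_exon(transcript, alu_exon)
  mrna <- splice_mrna(tx2$exons, tx2$strand, tx2$chrom, genome)
  orf_start <- genomic_to_mrna(tx2$exons, tx2$strand, orf_g)
  tr <- translate_from(mrna, orf_start)

  ## exon interval in mRNA coordinates
  ex_len <- alu_exon[2] - alu_exon[1]
  first_sense <- if (tx2$strand == "+") alu_exon[1] else alu_exon[2] - 1L
  ex_s <- genomic_to_mrna(tx2$exons, tx2$strand, first_sense)
  ex_e <- ex_s + ex_len

  n_ex <- nrow(tx2$exons)
  order53 <- if (tx2$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  last_len <- diff(tx2$exons[order53[n_ex], c("start", "end")])
  last_junction <- nchar(mrna) - as.integer(last_len)

  prot_len <- nchar(tr$protein)
  orf_end <- if (tr$stop_lost) nchar(mrna) else tr$stop_end
  aa_start <- max(0L, as.integer(floor((ex_s - orf_start) / 3)))
  aa_end <- min(prot_len, as.integer(ceiling((ex_e - orf_start) / 3)))
  structure(list(
    transcript_id = transcript$transcript_id,
    exon_id = sprintf("%s:%d-%d:%s", transcript$chrom, alu_exon[1],
                      alu_exon[2], transcript$strand),
    mrna = mrna,
    orf_nt = substr(mrna, orf_start + 1, orf_end),
    protein = tr$protein,
    orf_start = orf_start,
    stop_start = tr$stop_start, stop_end = tr$stop_end,
    stop_lost = tr$stop_lost,
    exon_mrna = c(ex_s, ex_e),
    aa_span = c(aa_start, aa_end),
    last_junction = last_junction,
    frameshift = (ex_len %% 3L) != 0L
  ), class = "inclusion_orf")
}

#' @export
print.inclusion_orf <- function(x, ...) {
  cat(sprintf(
    "<inclusion_orf> %s in %s: %d nt mRNA, %d aa%s%s, exon aa span [%d,%d)\n",
    x$exon_id, x$transcript_id, nchar(x$mrna), nchar(x$protein),
    if (x$frameshift) ", frameshift" else "",
    if (x$stop_lost) ", stop-lost" else "", x$aa_span[1], x$aa_span[2]))
  invisible(x)
}

#' Apply the 50-nt premature-termination-codon rule
#'
#' A stop codon located more than 50 nt upstream of the last exon-exon
#' junction of the mature mRNA predicts degradation by nonsense-mediated
#' decay. Stop-lost ORFs are classified NON_PTC with a warning attribute.
#'
#' @param orf an `inclusion_orf`.
#' @return "PTC" or "NON_PTC", with attributes `distance` (last junction
#'   minus stop-codon end, in nt) and `stop_lost`.
#' @export
classify_ptc <- function(orf) {
  stopifnot(inherits(orf, "inclusion_orf"))
  if (orf$stop_lost) {
    out <- "NON_PTC"
    attr(out, "distance") <- NA_integer_
    attr(out, "stop_lost") <- TRUE
    warning("stop-lost ORF classified NON_PTC")
    return(out)
  }
  dist <- orf$last_junction - orf$stop_end
  out <- if (dist > 50L) "PTC" else "NON_PTC"
  attr(out, "distance") <- dist
  attr(out, "stop_lost") <- FALSE
  out
}

#' Compare divisibility-by-3 of exon lengths between two exon sets
#'
#' Tests whether putative protein-coding exons are enriched for lengths that
#' preserve the downstream reading frame relative to NMD-inducing exons.
#'
#' @param coding_lengths,nmd_lengths integer exon lengths (or data frames
#'   with a `length` column).
#' @return list with the 2x2 `table` (rows coding/nmd, columns
#'   divisible/not), per-set `fractions`, and the two-sided Fisher exact `p`.
#' @export
frame_divisibility_test <- function(coding_lengths, nmd_lengths) {
  get_len <- function(x) {
    if (is.data.frame(x)) x <- x$length
    as.integer(x)
  }
  a <- get_len(coding_lengths)
  b <- get_len(nmd_lengths)
  if (length(a) == 0 || length(b) == 0) stop("both exon sets must be non-empty")
  tab <- matrix(c(sum(a %% 3 == 0), sum(a %% 3 != 0),
                  sum(b %% 3 == 0), sum(b %% 3 != 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("coding", "nmd"),
                                c("divisible", "not_divisible")))
  list(table = tab,
       fractions = tab[, 1] / rowSums(tab),
       p = fisher_exact_2x2(tab)$p)
}

#' Count and fraction of records from one repeat subfamily
#'
#' @param records `alu_exon_records` (or any data.frame with a `subfamily`
#'   column).
#' @param subfamily subfamily name, e.g. "AluY".
#' @return list with `count`, `total` and `fraction`.
#' @export
subfamily_fraction <- function(records, subfamily) {
  if (nrow(records) == 0) stop("empty record set")
  n <- sum(records$subfamily == subfamily)
  list(count = n, total = nrow(records), fraction = n / nrow(records))
}
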