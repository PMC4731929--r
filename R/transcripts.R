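#' Construct a transcript model
#'
#' Coordinates are 0-based half-open throughout the package; GTF input is
#' converted at the reader boundary.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix/data.frame of exon `start`,`end`
#'   (0-based half-open), in ascending genomic order, non-overlapping.
#' @param cds_start,cds_end genomic CDS span (0-based half-open, including
#'   the stop codon) or `NA` for non-coding transcripts.
#' @param biotype transcript biotype string.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             biotype = "protein_coding") {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2 || nrow(exons) < 1) {
    stop("exons must be a matrix with columns start, end and >= 1 row")
  }
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("exon end must exceed exon start")
  }
  if (is.unsorted(exons[, "start"], strictly = TRUE) ||
      any(diff(as.vector(t(exons))) < 0)) {
    stop("exons must be sorted, non-overlapping intervals")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.na(cds_start) &&
      (cds_start < exons[1, "start"] || cds_end > exons[nrow(exons), "end"] ||
       cds_end <= cds_start)) {
    stop("CDS boundaries must fall inside the exon span")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         biotype = biotype),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "no CDS" else {
    sprintf("CDS [%d, %d)", x$cds_start, x$cds_end)
  }
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d exon(s), %s, %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), cds, x$biotype))
  invisible(x)
}

#' Bundle transcript models into a collection
#'
#' @param models list of `transcript_model` objects.
#' @return named list of class `transcript_model_list`.
#' @export
transcript_model_list <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1), "transcript_model")))
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  structure(models, class = "transcript_model_list")
}

#' @export
print.transcript_model_list <- function(x, ...) {
  cat(sprintf("<transcript_model_list> %d transcript(s)\n", length(x)))
  invisible(x)
}

#' Fetch genomic sequence
#'
#' @param genome named [Biostrings::DNAStringSet] keyed by chromosome.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand "+" returns the forward sequence, "-" its reverse
#'   complement.
#' @return character scalar of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' absent from the genome", chrom))
  }
  if (start < 0 || end > length(genome[[chrom]]) || end < start) {
    stop("interval outside chromosome bounds")
  }
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## Genomic 0-based positions of the mature mRNA in 5'->3' order.
mrna_positions <- function(exons, strand) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq.int(exons[i, "start"], exons[i, "end"] - 1L)
  }), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

## mRNA offset (0-based) of a genomic position.
genomic_to_mrna <- function(exons, strand, gpos) {
  pos <- mrna_positions(exons, strand)
  idx <- match(gpos, pos)
  if (any(is.na(idx))) stop("genomic position not exonic")
  idx - 1L
}

## Spliced mature mRNA sequence (sense strand).
splice_mrna <- function(exons, strand, chrom, genome) {
  parts <- vapply(seq_len(nrow(exons)), function(i) {
    fetch_sequence(genome, chrom, exons[i, "start"], exons[i, "end"], "+")
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

## Insert an extra exon interval into the intron of a transcript model.
insert_exon <- function(transcript, exon) {
  exon <- as.integer(exon)
  ex <- transcript$exons
  fits <- which(exon[1] >= ex[-nrow(ex), "end"] &
                  exon[2] <= ex[-1, "start"])
  if (length(fits) != 1) {
    stop("exon does not splice between two annotated exons of the transcript")
  }
  new_ex <- rbind(ex[seq_len(fits), , drop = FALSE],
                  matrix(exon, 1, 2, dimnames = list(NULL, c("start", "end"))),
                  ex[(fits + 1):nrow(ex), , drop = FALSE])
  out <- transcript
  out$exons <- new_ex
  out
}

#' Remove one exon from a transcript model
#'
#' Used to derive the skipping isoform from an annotation that carries the
#' Alu exon.
#'
#' @param transcript a `transcript_model`.
#' @param exon length-2 vector `c(start, end)` matching one annotated exon.
#' @return the transcript without that exon.
#' @export
drop_exon <- function(transcript, exon) {
  ex <- transcript$exons
  hit <- which(ex[, "start"] == exon[1] & ex[, "end"] == exon[2])
  if (length(hit) != 1) stop("exon interval not found in the transcript")
  if (nrow(ex) < 3 || hit == 1 || hit == nrow(ex)) {
    stop("only internal exons can be dropped")
  }
  out <- transcript
  out$exons <- ex[-hit, , drop = FALSE]
  out
}

## Translate a sense-strand nucleotide string from position `from` (0-based)
## until the first stop codon. Returns protein, stop coords, stop_lost flag.
translate_from <- function(mrna, from) {
  n <- nchar(mrna)
  aas <- character(0)
  k <- from
  while (k + 3 <= n) {
    codon <- substr(mrna, k + 1, k + 3)
    aa <- unname(Biostrings::GENETIC_CODE[codon])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") {
      return(list(protein = paste(aas, collapse = ""),
                  stop_start = k, stop_end = k + 3L, stop_lost = FALSE))
    }
    aas <- c(aas, aa)
    k <- k + 3L
  }
  list(protein = paste(aas, collapse = ""), stop_start = NA_integer_,
       stop_end = NA_integer_, stop_lost = TRUE)
}

#' Translate the annotated ORF of a transcript
#'
#' @param transcript a `transcript_model` with CDS annotation.
#' @param genome named DNAStringSet.
#' @return protein string (no stop character).
#' @export
translate_transcript <- function(transcript, genome) {
  orf <- transcript_orf_start(transcript)
  mrna <- splice_mrna(transcript$exons, transcript$strand,
                      transcript$chrom, genome)
  start_m <- genomic_to_mrna(transcript$exons, transcript$strand, orf)
  translate_from(mrna, start_m)$protein
}

## Genomic position (0-based) of the first base of the start codon.
transcript_orf_start <- function(transcript) {
  if (is.na(transcript$cds_start)) {
    stop(structure(class = c("noncoding_transcript", "error", "condition"),
                   list(message = sprintf(
                     "transcript %s has no CDS annotation",
                     transcript$transcript_id), call = NULL)))
  }
  if (transcript$strand == "+") transcript$cds_start else
    transcript$cds_end - 1L
}
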