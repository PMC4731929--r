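#' Read transcript models from a GTF file (Ensembl dialect)
#'
#' Exon and CDS features are assembled per `transcript_id`; 1-based closed
#' GTF coordinates are converted to the package's 0-based half-open
#' convention. CDS boundaries are taken as the min/max over a transcript's
#' CDS features.
#'
#' @param path GTF file path.
#' @return a `transcript_model_list`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0) return(transcript_model_list(list()))
  if (any(is.na(df$transcript_id))) {
    stop(sprintf("missing transcript_id attribute on %d exon/CDS feature(s)",
                 sum(is.na(df$transcript_id))))
  }
  models <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    biotype <- if ("gene_biotype" %in% names(d) && !is.na(d$gene_biotype[1])) {
      d$gene_biotype[1]
    } else "protein_coding"
    transcript_model(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      exons = cbind(start = ex$start - 1L, end = ex$end),
      cds_start = if (nrow(cds)) min(cds$start) - 1L else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
      biotype = biotype)
  })
  transcript_model_list(unname(models))
}

#' Write transcript models to a GTF file
#'
#' @param transcripts a `transcript_model_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     tx$gene_id, tx$transcript_id, tx$biotype)
    feat <- function(type, s0, e0) {
      sprintf("%s\taluexon\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom, type, s0 + 1L, e0, tx$strand, attrs)
    }
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, feat("exon", tx$exons[i, "start"], tx$exons[i, "end"]))
      if (!is.na(tx$cds_start)) {
        cs <- max(tx$exons[i, "start"], tx$cds_start)
        ce <- min(tx$exons[i, "end"], tx$cds_end)
        if (ce > cs) lines <- c(lines, feat("CDS", cs, ce))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat annotations from a RepeatMasker .out file
#'
#' Standard whitespace-delimited layout with a 3-line header; 1-based
#' inclusive coordinates are converted to 0-based half-open. Short lines are
#' skipped and tallied in the `n_skipped` attribute.
#'
#' @param path .out file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `name`,
#'   `family`.
#' @export
read_repeatmasker_out <- function(path) {
  raw <- readLines(path)
  if (length(raw) > 3) raw <- raw[-(1:3)] else raw <- character(0)
  raw <- raw[nzchar(trimws(raw))]
  fields <- strsplit(trimws(raw), "[[:space:]]+")
  short <- vapply(fields, length, integer(1)) < 11
  fields <- fields[!short]
  out <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 5),
    start = as.integer(vapply(fields, `[[`, character(1), 6)) - 1L,
    end = as.integer(vapply(fields, `[[`, character(1), 7)),
    strand = ifelse(vapply(fields, `[[`, character(1), 9) == "C", "-", "+"),
    name = vapply(fields, `[[`, character(1), 10),
    family = vapply(fields, `[[`, character(1), 11),
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(short)
  out
}

#' Write repeat annotations as a RepeatMasker .out file
#'
#' @param repeats repeat data.frame (see [read_repeatmasker_out()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  header <- c(
    "   SW  perc perc perc  query     position in query    matching repeat      position in repeat",
    "score  div. del. ins.  sequence  begin    end (left)  repeat class/family  begin  end (left)",
    "")
  body <- sprintf(
    "  225   1.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  %s  1  300  (0)  %d",
    repeats$chrom, repeats$start + 1L, repeats$end,
    ifelse(repeats$strand == "-", "C", "+"),
    repeats$name, repeats$family, seq_len(nrow(repeats)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read repeat annotations from a BED6 file
#'
#' @param path BED file path.
#' @param family repeat family recorded on every interval (BED carries no
#'   family column).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `name`,
#'   `family` (0-based half-open).
#' @export
read_repeat_bed <- function(path, family = "SINE/Alu") {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    family = family, stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` and a name column.
#' @param path output path.
#' @param name_col column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path, name_col = "name") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, df$start, df$end,
                   df[[name_col]], 0L, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA into a named DNAStringSet
#'
#' @param path FASTA path.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- vapply(strsplit(names(g), "[[:space:]]+"), `[[`, character(1), 1)
  g
}

#' Write a genome FASTA
#'
#' @param genome named DNAStringSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a junction library as FASTA
#'
#' Headers encode `exon_id|role|boundary`.
#'
#' @param library a `junction_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library$seq)
  names(seqs) <- sprintf("%s|%s|%d", library$exon_id, library$role,
                         library$boundary)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write and read tab-separated stage hand-off tables
#'
#' Headered UTF-8 TSV with "." for missing values.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Read editing counts and a library manifest from TSV files
#'
#' The counts table has columns `chrom`, `pos`, `strand`, then `e_<lib>` and
#' `u_<lib>` pairs for each library in the manifest.
#'
#' @param counts_path,manifest_path TSV paths.
#' @return an `editing_counts` object.
#' @export
read_editing_counts <- function(counts_path, manifest_path) {
  tab <- read_tsv(counts_path)
  manifest <- read_tsv(manifest_path)
  libs <- manifest$library
  e <- as.matrix(tab[, paste0("e_", libs), drop = FALSE])
  u <- as.matrix(tab[, paste0("u_", libs), drop = FALSE])
  colnames(e) <- colnames(u) <- libs
  editing_counts(tab[, c("chrom", "pos", "strand")], e, u, manifest)
}

#' Write editing counts and manifest as TSV files
#'
#' @param x an `editing_counts` object.
#' @param counts_path,manifest_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_editing_counts <- function(x, counts_path, manifest_path) {
  e <- x$e; u <- x$u
  colnames(e) <- paste0("e_", colnames(e))
  colnames(u) <- paste0("u_", colnames(u))
  tab <- cbind(x$sites[, c("chrom", "pos", "strand")],
               as.data.frame(e), as.data.frame(u))
  write_tsv(tab, counts_path)
  write_tsv(x$manifest, manifest_path)
  invisible(counts_path)
}

#' Read a peptide library (one peptide per line)
#'
#' @param path text file path.
#' @return character vector of peptides.
#' @export
read_peptide_list <- function(path) {
  out <- trimws(readLines(path))
  out[nzchar(out)]
}
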