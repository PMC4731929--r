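#' Classify Alu exon records by mRNA region and NMD fate
#'
#' For each (exon, transcript) record the host transcript is reduced to its
#' skipping isoform, the inclusion ORF rebuilt, and the exon classified by
#' region (5'UTR/CDS/3'UTR) and by the 50-nt PTC rule. Records on
#' transcripts without CDS annotation are marked region `NA` and excluded
#' from coding analysis.
#'
#' @param records `alu_exon_records` from [find_alu_exons()]; the host
#'   transcript is expected to carry the exon.
#' @param transcripts the `transcript_model_list` the records came from.
#' @param genome named DNAStringSet.
#' @return the records with added columns `region`, `ptc`, `len_mod3`,
#'   `stop_lost`; attribute `orfs` holds the `inclusion_orf` objects keyed
#'   by exon id.
#' @export
classify_alu_exons <- function(records, transcripts, genome) {
  region <- character(nrow(records))
  ptc <- rep(NA_character_, nrow(records))
  stop_lost <- rep(NA, nrow(records))
  orfs <- list()
  for (i in seq_len(nrow(records))) {
    tx <- transcripts[[records$transcript_id[i]]]
    exon <- c(records$start[i], records$end[i])
    region[i] <- tryCatch(
      classify_exon_region(exon, tx),
      noncoding_transcript = function(e) NA_character_)
    if (is.na(region[i]) || region[i] != "CDS") next
    skip <- drop_exon(tx, exon)
    orf <- build_inclusion_orf(skip, exon, genome)
    orfs[[records$exon_id[i]]] <- orf
    ptc[i] <- suppressWarnings(classify_ptc(orf))
    stop_lost[i] <- orf$stop_lost
  }
  out <- as.data.frame(records)
  out$region <- region
  out$ptc <- ptc
  out$len_mod3 <- out$length %% 3L
  out$stop_lost <- stop_lost
  attr(out, "orfs") <- orfs
  class(out) <- c("alu_exon_records", "data.frame")
  out
}

#' Pipeline funnel report
#'
#' Runs the discovery funnel on classified records and RNA-seq junction
#' counts: Alu-derived internal exons found, those in the CDS, the non-PTC
#' (putative protein-coding) subset, the high-inclusion and
#' differentially-spliced exon lists among them, and their union.
#'
#' @param classified output of [classify_alu_exons()].
#' @param rna_counts `junction_counts` over >= 2 samples.
#' @param psi_threshold high-inclusion cutoff (default 0.33).
#' @param delta_threshold,fdr_threshold differential-splicing cutoffs.
#' @param min_max_junction junction coverage gate (default 10 reads).
#' @return list of class `alu_funnel` with counts `n_found`, `n_cds`,
#'   `n_non_ptc`, `n_high_inclusion`, `n_differential`, `n_combined` and
#'   the underlying exon id vectors.
#' @export
alu_exon_report <- function(classified, rna_counts, psi_threshold = 0.33,
                            delta_threshold = 0.10, fdr_threshold = 0.10,
                            min_max_junction = 10L) {
  cds <- classified[!is.na(classified$region) & classified$region == "CDS", ]
  non_ptc <- cds[!is.na(cds$ptc) & cds$ptc == "NON_PTC", ]
  candidate_ids <- unique(non_ptc$exon_id)
  counts <- rna_counts[rna_counts$exon_id %in% candidate_ids, , drop = FALSE]
  psis <- compute_psi(counts, min_max_junction)
  high <- select_high_inclusion(psis, psi_threshold)
  diff <- differential_splicing(counts, delta_threshold = delta_threshold,
                                fdr_threshold = fdr_threshold,
                                min_max_junction = min_max_junction)
  combined <- combine_exon_lists(high, diff$called)
  structure(list(
    n_found = length(unique(classified$exon_id)),
    n_cds = length(unique(cds$exon_id)),
    n_non_ptc = length(candidate_ids),
    n_high_inclusion = length(high),
    n_differential = length(diff$called),
    n_combined = length(combined),
    high_inclusion = high, differential = diff$called, combined = combined,
    candidates = candidate_ids), class = "alu_funnel")
}

#' @export
print.alu_funnel <- function(x, ...) {
  cat("Alu exon discovery funnel\n")
  cat(sprintf("  Alu-derived internal exons : %d\n", x$n_found))
  cat(sprintf("  located in the CDS         : %d\n", x$n_cds))
  cat(sprintf("  non-PTC (putative coding)  : %d\n", x$n_non_ptc))
  cat(sprintf("  high inclusion (psi gate)  : %d\n", x$n_high_inclusion))
  cat(sprintf("  differentially spliced     : %d\n", x$n_differential))
  cat(sprintf("  combined list              : %d\n", x$n_combined))
  invisible(x)
}
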