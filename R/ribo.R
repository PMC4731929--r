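#' Trim reads to a fixed-length prefix
#'
#' Ribosome footprints are mapped with their first `n` nucleotides only
#' (default 30, for 36-nt sequencing reads); shorter reads are dropped and
#' tallied.
#'
#' @param reads character vector of nucleotide strings.
#' @param n prefix length; must be positive.
#' @return trimmed reads with attribute `n_dropped`.
#' @export
trim_to_prefix <- function(reads, n = 30L) {
  if (n <= 0) stop("prefix length must be positive")
  short <- nchar(reads) < n
  out <- substr(reads[!short], 1L, n)
  attr(out, "n_dropped") <- sum(short)
  out
}

#' Compare Ribo-seq and RNA-seq inclusion levels per exon
#'
#' Computes psi in each assay over the same junction library and flags
#' translational evidence. Only exons with at least `min_max_junction` reads
#' on one of the three junctions in *both* assays are evaluated; the rest
#' are returned in the `excluded` attribute with a reason.
#'
#' @param ribo_counts,rna_counts `junction_counts` tables (one sample each)
#'   over the same exon universe; a mismatch raises an error listing the
#'   difference.
#' @param strong_threshold Ribo-seq psi for the strong-translation flag
#'   (default 0.15, inclusive).
#' @param min_max_junction dual coverage gate (default 10 reads).
#' @return data.frame of class `translation_evidence` with `exon_id`,
#'   `psi_ribo`, `psi_rna` and logical flags `nonzero_ribo`, `strong_ribo`,
#'   `higher_in_ribo`.
#' @export
compare_ribo_rna <- function(ribo_counts, rna_counts,
                             strong_threshold = 0.15,
                             min_max_junction = 10L) {
  only_ribo <- setdiff(ribo_counts$exon_id, rna_counts$exon_id)
  only_rna <- setdiff(rna_counts$exon_id, ribo_counts$exon_id)
  if (length(only_ribo) || length(only_rna)) {
    stop(sprintf(
      "mismatched exon universes; only in ribo: {%s}; only in rna: {%s}",
      paste(only_ribo, collapse = ","), paste(only_rna, collapse = ",")))
  }
  pr <- compute_psi(ribo_counts, min_max_junction)
  pn <- compute_psi(rna_counts, min_max_junction)
  m <- merge(pr[, c("exon_id", "psi", "covered")],
             pn[, c("exon_id", "psi", "covered")],
             by = "exon_id", suffixes = c("_ribo", "_rna"))
  gate <- m$covered_ribo & m$covered_rna & !is.na(m$psi_ribo) &
    !is.na(m$psi_rna)
  excluded <- data.frame(
    exon_id = m$exon_id[!gate],
    reason = ifelse(!m$covered_ribo[!gate], "ribo coverage < gate",
                    ifelse(!m$covered_rna[!gate], "rna coverage < gate",
                           "psi undefined")),
    stringsAsFactors = FALSE)
  out <- data.frame(
    exon_id = m$exon_id[gate],
    psi_ribo = m$psi_ribo[gate], psi_rna = m$psi_rna[gate],
    stringsAsFactors = FALSE)
  out$nonzero_ribo <- out$psi_ribo > 0
  out$strong_ribo <- out$psi_ribo >= strong_threshold
  out$higher_in_ribo <- out$psi_ribo > out$psi_rna
  attr(out, "excluded") <- excluded
  class(out) <- c("translation_evidence", "data.frame")
  out
}

#' Enrichment of strong Ribo-seq signal in the coding exon set
#'
#' One-sided (greater) Fisher exact test for over-representation of
#' strongly translated exons among putative protein-coding exons relative
#' to a control set (e.g. NMD-inducing exons).
#'
#' @param coding_hits,coding_total strong-translation count and set size for
#'   the coding exons.
#' @param control_hits,control_total likewise for the control set.
#' @return list with `odds_ratio` and `p`.
#' @examples
#' ribo_enrichment_test(17, 76, 24, 180)$p  # ~0.056
#' @export
ribo_enrichment_test <- function(coding_hits, coding_total,
                                 control_hits, control_total) {
  if (coding_hits > coding_total || control_hits > control_total) {
    stop("hits cannot exceed totals")
  }
  fisher_exact_2x2(a = coding_hits, b = coding_total - coding_hits,
                   c = control_hits, d = control_total - control_hits,
                   alternative = "greater")
}
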