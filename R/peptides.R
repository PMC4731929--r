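#' Build the protein search space for peptide mapping
#'
#' The space contains the background proteome (annotated ORF translations,
#' i.e. the exon-skipping isoforms plus all other genes) and one inclusion
#' isoform per candidate exon, each annotated with the exon's amino-acid
#' span (codon-partial boundaries assigned to the exon, inclusive).
#'
#' @param background named character vector of background protein sequences.
#' @param inclusion_orfs list of `inclusion_orf` objects; untranslatable
#'   entries (empty protein) are skipped with a tally.
#' @return data.frame of class `protein_space` with columns `protein_id`,
#'   `type` ("background"/"inclusion"), `exon_id`, `seq`, `aa_start`,
#'   `aa_end` (NA for background).
#' @export
build_protein_space <- function(background, inclusion_orfs = list()) {
  bg <- data.frame(
    protein_id = names(background), type = "background",
    exon_id = NA_character_, seq = unname(unlist(background)),
    aa_start = NA_integer_, aa_end = NA_integer_,
    stringsAsFactors = FALSE)
  skipped <- 0L
  inc <- lapply(inclusion_orfs, function(o) {
    stopifnot(inherits(o, "inclusion_orf"))
    if (nchar(o$protein) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    data.frame(
      protein_id = paste0(o$transcript_id, "|", o$exon_id, "|inclusion"),
      type = "inclusion", exon_id = o$exon_id, seq = o$protein,
      aa_start = o$aa_span[1], aa_end = o$aa_span[2],
      stringsAsFactors = FALSE)
  })
  out <- rbind(bg, do.call(rbind, inc))
  rownames(out) <- NULL
  if (anyDuplicated(out$protein_id)) stop("duplicate protein ids in space")
  attr(out, "n_untranslatable") <- skipped
  class(out) <- c("protein_space", "data.frame")
  out
}

## All (possibly overlapping) 1-based start positions of `pat` in `s`.
find_all_occurrences <- function(pat, s) {
  starts <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (m < 0) break
    starts <- c(starts, from + as.integer(m) - 1L)
    from <- from + as.integer(m)
  }
  starts
}

#' Map a peptide library onto the protein space
#'
#' Peptides shorter than `min_length` amino acids are dropped, as are
#' peptides with non-amino-acid characters and peptides occurring at more
#' than one location anywhere in the space (the uniqueness rule). A unique
#' match becomes a hit only when it overlaps an inclusion isoform's exon
#' amino-acid span; hits are located as exon-body or junction-spanning
#' (>= 1 aa strictly on each side of the junction).
#'
#' @param peptides character vector of uppercase amino-acid strings.
#' @param space a `protein_space`.
#' @param min_length minimum peptide length (default 6).
#' @return data.frame of class `peptide_hits`: `peptide`, `exon_id`,
#'   `protein_id`, `aa_match_start`, `aa_match_end` (0-based half-open
#'   protein coordinates) and `location` in
#'   {EXON_BODY, UPSTREAM_JUNCTION, DOWNSTREAM_JUNCTION}. The `rejected`
#'   attribute tabulates dropped peptides with reasons.
#' @export
map_peptides <- function(peptides, space, min_length = 6L) {
  stopifnot(inherits(space, "protein_space"))
  ok_chars <- sprintf("^[%s]+$", .AMINO_ACIDS)
  rejected <- list()
  hits <- list()
  for (pep in unique(peptides)) {
    if (!grepl(ok_chars, pep)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(peptide = pep, reason = "invalid characters")
      next
    }
    if (nchar(pep) < min_length) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(peptide = pep, reason = "below minimum length")
      next
    }
    locs <- lapply(seq_len(nrow(space)), function(i) {
      st <- find_all_occurrences(pep, space$seq[i])
      if (length(st)) cbind(row = i, start = st) else NULL
    })
    locs <- do.call(rbind, locs)
    if (is.null(locs)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(peptide = pep, reason = "no match")
      next
    }
    if (nrow(locs) > 1) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(peptide = pep, reason = "multiple locations")
      next
    }
    i <- locs[1, "row"]
    s0 <- locs[1, "start"] - 1L          # 0-based match start
    e0 <- s0 + nchar(pep)
    if (space$type[i] != "inclusion") next  # unique background match, no hit
    a <- space$aa_start[i]; b <- space$aa_end[i]
    if (e0 <= a || s0 >= b) next            # unique but outside the exon span
    location <- if (s0 < a && e0 > a) {
      "UPSTREAM_JUNCTION"
    } else if (s0 < b && e0 > b) {
      "DOWNSTREAM_JUNCTION"
    } else "EXON_BODY"
    hits[[length(hits) + 1L]] <- data.frame(
      peptide = pep, exon_id = space$exon_id[i],
      protein_id = space$protein_id[i],
      aa_match_start = s0, aa_match_end = e0, location = location,
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    peptide = character(0), exon_id = character(0),
    protein_id = character(0), aa_match_start = integer(0),
    aa_match_end = integer(0), location = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(rejected)) {
    do.call(rbind, rejected)
  } else data.frame(peptide = character(0), reason = character(0))
  class(out) <- c("peptide_hits", "data.frame")
  out
}

#' Summarize peptide hits per exon
#'
#' @param hits a `peptide_hits` data.frame.
#' @return data.frame with one row per exon: `exon_id`, `n_hits`,
#'   `has_hit`, `has_junction_spanning_hit`.
#' @export
classify_hits <- function(hits) {
  exons <- unique(hits$exon_id)
  data.frame(
    exon_id = exons,
    n_hits = vapply(exons, function(e) sum(hits$exon_id == e), integer(1)),
    has_hit = TRUE,
    has_junction_spanning_hit = vapply(exons, function(e) {
      any(hits$exon_id == e &
            hits$location %in% c("UPSTREAM_JUNCTION", "DOWNSTREAM_JUNCTION"))
    }, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Negative-control upper bound on the peptide-search FDR
#'
#' The background hit rate observed in a negative-control exon set (e.g.
#' NMD-inducing exons, assumed all true negatives) is extrapolated to the
#' candidate set: expected false positives = round(n_candidates x rate,
#' half-up), and the FDR upper bound is that count over the observed
#' candidate hits.
#'
#' @param n_candidates,candidate_hits candidate set size and observed hits.
#' @param n_control,control_hits control set size and hits.
#' @return list with `background_rate`, `expected_false_positives` and
#'   `fdr_upper_bound` (NA with a warning when `candidate_hits` is 0).
#' @examples
#' negative_control_fdr(262, 85, 649, 47)  # 19 expected FP, 22% bound
#' @export
negative_control_fdr <- function(n_candidates, candidate_hits,
                                 n_control, control_hits) {
  counts <- c(n_candidates, candidate_hits, n_control, control_hits)
  if (any(counts < 0) || candidate_hits > n_candidates ||
      control_hits > n_control) {
    stop("counts must be non-negative with hits <= totals")
  }
  rate <- control_hits / n_control
  efp <- round_half_up(n_candidates * rate)
  if (candidate_hits == 0) {
    warning("no candidate hits: FDR upper bound undefined")
    fdr <- NA_real_
  } else {
    fdr <- efp / candidate_hits
  }
  list(background_rate = rate, expected_false_positives = efp,
       fdr_upper_bound = fdr)
}

#' Compare peptide hit rates between candidate and control exon sets
#'
#' @param candidate_hits,candidate_total,control_hits,control_total counts.
#' @return list with `odds_ratio` and two-sided Fisher exact `p`.
#' @examples
#' hit_rate_enrichment(85, 262, 47, 649)$p  # ~1.8e-20
#' @export
hit_rate_enrichment <- function(candidate_hits, candidate_total,
                                control_hits, control_total) {
  if (candidate_hits > candidate_total || control_hits > control_total) {
    stop("hits cannot exceed totals")
  }
  fisher_exact_2x2(a = candidate_hits, b = candidate_total - candidate_hits,
                   c = control_hits, d = control_total - control_hits)
}
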