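#' Build the three splice-junction sequences of a cassette exon
#'
#' Each junction is the concatenation of the last `flank` nt of the 5' exon
#' and the first `flank` nt of the 3' exon, on the transcript (sense)
#' strand; with the default `flank = 27` junctions are 54 bp. Segments are
#' truncated (and flagged) when an exon is shorter than `flank`.
#'
#' @param transcript host `transcript_model` (skipping isoform).
#' @param alu_exon length-2 vector `c(start, end)` inside one intron.
#' @param genome named DNAStringSet.
#' @param flank segment length per side (default 27).
#' @return data.frame of class `junction_library` with columns `exon_id`,
#'   `role` (UPSTREAM/DOWNSTREAM/SKIPPING), `seq`, `boundary` (offset of the
#'   splice boundary within `seq`) and `truncated`.
#' @export
build_junction_library <- function(transcript, alu_exon, genome, flank = 27L) {
  tx2 <- insert_exon(transcript, alu_exon)  # errors if not intronic/internal
  ex <- tx2$exons
  i <- which(ex[, "start"] == alu_exon[1] & ex[, "end"] == alu_exon[2])
  up_i <- if (tx2$strand == "+") i - 1L else i + 1L
  dn_i <- if (tx2$strand == "+") i + 1L else i - 1L

  sense_seq <- function(j) {
    fetch_sequence(genome, tx2$chrom, ex[j, "start"], ex[j, "end"],
                   tx2$strand)
  }
  up <- sense_seq(up_i); mid <- sense_seq(i); dn <- sense_seq(dn_i)
  tail_seg <- function(s) substr(s, max(1L, nchar(s) - flank + 1L), nchar(s))
  head_seg <- function(s) substr(s, 1L, min(flank, nchar(s)))

  mk <- function(role, left, right) {
    data.frame(
      exon_id = sprintf("%s:%d-%d:%s", tx2$chrom, alu_exon[1], alu_exon[2],
                        tx2$strand),
      role = role, seq = paste0(left, right),
      boundary = nchar(left),
      truncated = nchar(left) < flank || nchar(right) < flank,
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk("UPSTREAM", tail_seg(up), head_seg(mid)),
               mk("DOWNSTREAM", tail_seg(mid), head_seg(dn)),
               mk("SKIPPING", tail_seg(up), head_seg(dn)))
  class(out) <- c("junction_library", "data.frame")
  out
}

#' Combine junction libraries of several exons
#'
#' @param ... `junction_library` data frames.
#' @return a single `junction_library`.
#' @export
combine_junction_libraries <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(out[, c("exon_id", "role")])) {
    stop("duplicate (exon, role) keys in the combined library")
  }
  class(out) <- c("junction_library", "data.frame")
  out
}

## Minimum ungapped mismatch count of `read` against `jseq`, over offsets
## whose alignment covers the splice boundary with >= 1 nt on each side.
## Returns +Inf when no valid offset exists.
best_mismatch <- function(read_chars, jseq_chars, boundary) {
  rl <- length(read_chars); jl <- length(jseq_chars)
  if (rl > jl) return(Inf)
  offs <- 0:(jl - rl)
  offs <- offs[offs < boundary & offs + rl > boundary]
  if (length(offs) == 0) return(Inf)
  min(vapply(offs, function(o) {
    sum(read_chars != jseq_chars[(o + 1):(o + rl)])
  }, numeric(1)))
}

#' Match reads to a splice-junction library
#'
#' Reads are trimmed to `read_prefix_length`, then aligned ungapped at every
#' offset of every junction that covers the splice boundary with at least
#' one nucleotide on each side. A read is counted for a junction iff its
#' minimal mismatch count is `<= max_mismatches` and exactly one junction in
#' the whole library attains that minimum (ties are discarded as
#' multi-mapped).
#'
#' @param reads character vector of nucleotide strings.
#' @param library a `junction_library` (possibly combined over exons).
#' @param read_prefix_length reads are truncated to this length before
#'   matching (50 for the RNA-seq contract, 30 for Ribo-seq); shorter reads
#'   are skipped and tallied.
#' @param max_mismatches mismatch cap (default 2).
#' @param sample sample label recorded in the output.
#' @return `junction_counts` data.frame: `exon_id`, `sample`, `UJC`, `DJC`,
#'   `SJC`; attributes `n_short`, `n_unmapped`, `n_multi` tally dropped
#'   reads.
#' @export
match_reads <- function(reads, library, read_prefix_length = 50L,
                        max_mismatches = 2L, sample = "sample1") {
  stopifnot(read_prefix_length > 0)
  n_short <- sum(nchar(reads) < read_prefix_length)
  reads <- reads[nchar(reads) >= read_prefix_length]
  reads <- substr(reads, 1L, read_prefix_length)

  jchars <- strsplit(library$seq, "", fixed = TRUE)
  counts <- integer(nrow(library))
  n_unmapped <- 0L; n_multi <- 0L
  for (r in reads) {
    rc <- strsplit(r, "", fixed = TRUE)[[1]]
    mm <- vapply(seq_len(nrow(library)), function(j) {
      best_mismatch(rc, jchars[[j]], library$boundary[j])
    }, numeric(1))
    m <- min(mm)
    if (!is.finite(m) || m > max_mismatches) {
      n_unmapped <- n_unmapped + 1L
    } else if (sum(mm == m) > 1L) {
      n_multi <- n_multi + 1L
    } else {
      counts[which.min(mm)] <- counts[which.min(mm)] + 1L
    }
  }
  exons <- unique(library$exon_id)
  get <- function(ex, role) {
    i <- which(library$exon_id == ex & library$role == role)
    if (length(i)) counts[i] else 0L
  }
  out <- data.frame(
    exon_id = exons, sample = sample,
    UJC = vapply(exons, get, integer(1), "UPSTREAM"),
    DJC = vapply(exons, get, integer(1), "DOWNSTREAM"),
    SJC = vapply(exons, get, integer(1), "SKIPPING"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_short") <- n_short
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_multi") <- n_multi
  class(out) <- c("junction_counts", "data.frame")
  out
}

#' Percent-spliced-in from junction read counts
#'
#' psi = I / (I + S) with inclusion support I = (UJC + DJC) / 2 (the average
#' of the two inclusion junctions, correcting the two-junction versus
#' one-junction count imbalance) and skipping support S = SJC. psi is `NA`
#' (undefined) when I + S = 0. The coverage flag requires
#' `max(UJC, DJC, SJC) >= min_max_junction` reads.
#'
#' @param counts `junction_counts` data.frame with columns `exon_id`,
#'   `sample`, `UJC`, `DJC`, `SJC`.
#' @param min_max_junction coverage gate (default 10 reads).
#' @return the input with added columns `I`, `S`, `psi`, `max_jc`,
#'   `covered`; class `psi_estimates`.
#' @export
compute_psi <- function(counts, min_max_junction = 10L) {
  need <- c("exon_id", "sample", "UJC", "DJC", "SJC")
  stopifnot(all(need %in% names(counts)))
  cts <- as.matrix(counts[, c("UJC", "DJC", "SJC")])
  if (any(is.na(cts)) || any(cts < 0)) stop("counts must be non-negative")
  out <- as.data.frame(counts)
  out$I <- (out$UJC + out$DJC) / 2
  out$S <- out$SJC
  tot <- out$I + out$S
  out$psi <- ifelse(tot > 0, out$I / tot, NA_real_)
  out$max_jc <- pmax(out$UJC, out$DJC, out$SJC)
  out$covered <- out$max_jc >= min_max_junction
  class(out) <- c("psi_estimates", "data.frame")
  out
}

#' Exons with moderate-to-high inclusion in at least one sample
#'
#' Selects exons whose inclusion level reaches `threshold` in at least one
#' sample that also passes the 10-read junction coverage gate.
#'
#' @param psis a `psi_estimates` data.frame from [compute_psi()].
#' @param threshold minimum psi (default 0.33, inclusive).
#' @return character vector of exon ids.
#' @export
select_high_inclusion <- function(psis, threshold = 0.33) {
  keep <- !is.na(psis$psi) & psis$covered & psis$psi >= threshold
  sort(unique(psis$exon_id[keep]))
}

#' Differential splicing between sample pairs (Fisher-exact stand-in)
#'
#' A deliberately simple substitute for likelihood-based differential
#' splicing models: per (exon, sample pair) with both samples passing the
#' coverage gate, a two-sided Fisher exact test on the 2x2 table of rounded
#' inclusion support I (half-up) versus skipping count S, BH-corrected over
#' all tested hypotheses jointly. An exon is called when some pair has
#' `|dPsi| >= delta_threshold` and `q < fdr_threshold`.
#'
#' @param counts `junction_counts` over >= 2 samples.
#' @param sample_pairs optional 2-column matrix/data.frame of sample name
#'   pairs; default all unordered pairs.
#' @param delta_threshold minimum |dPsi| (default 0.10).
#' @param fdr_threshold BH q cutoff (default 0.10, strict).
#' @param min_max_junction coverage gate passed to [compute_psi()].
#' @return list with `tests` (exon, sample_a, sample_b, psi_a, psi_b,
#'   delta_psi, p, q) and `called` (character vector of exon ids).
#' @export
differential_splicing <- function(counts, sample_pairs = NULL,
                                  delta_threshold = 0.10,
                                  fdr_threshold = 0.10,
                                  min_max_junction = 10L) {
  psis <- compute_psi(counts, min_max_junction)
  samples <- unique(psis$sample)
  if (length(samples) < 2) stop("differential splicing needs >= 2 samples")
  if (is.null(sample_pairs)) {
    sample_pairs <- t(utils::combn(samples, 2))
  }
  sample_pairs <- as.matrix(sample_pairs)

  rows <- list()
  for (k in seq_len(nrow(sample_pairs))) {
    sa <- sample_pairs[k, 1]; sb <- sample_pairs[k, 2]
    pa <- psis[psis$sample == sa, ]
    pb <- psis[psis$sample == sb, ]
    common <- intersect(pa$exon_id, pb$exon_id)
    for (ex in common) {
      ra <- pa[pa$exon_id == ex, ][1, ]
      rb <- pb[pb$exon_id == ex, ][1, ]
      if (!isTRUE(ra$covered) || !isTRUE(rb$covered)) next
      if (is.na(ra$psi) || is.na(rb$psi)) next
      tab <- matrix(c(round_half_up(ra$I), ra$S,
                      round_half_up(rb$I), rb$S), 2, byrow = TRUE)
      p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else {
        fisher_exact_2x2(tab)$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = ex, sample_a = sa, sample_b = sb,
        psi_a = ra$psi, psi_b = rb$psi, delta_psi = ra$psi - rb$psi,
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(list(tests = data.frame(), called = character(0)))
  }
  tests <- do.call(rbind, rows)
  tests$q <- bh_fdr(tests$p)
  hit <- abs(tests$delta_psi) >= delta_threshold & tests$q < fdr_threshold
  list(tests = tests, called = sort(unique(tests$exon_id[hit])))
}

round_half_up <- function(x) floor(x + 0.5)

#' Union of two exon lists
#'
#' @param high_inclusion,differential character vectors of exon ids.
#' @return deduplicated sorted union.
#' @export
combine_exon_lists <- function(high_inclusion, differential) {
  sort(union(high_inclusion, differential))
}
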