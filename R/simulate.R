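## Fixed synthetic 300-nt Alu-like consensus bundled with the package.
## Subfamily labels attached to simulated copies are simulation metadata,
## not sequence-derived.
ALU_CONSENSUS <- paste0(
  "GAGGCGAGTCACAGTGACGAATAAAGCAAGCGGGCGGCCTGTTCACAACCTCAAAGGAGC",
  "CGGCGTCGGGTGGACTCACGACGTGCTGGGGGATACCCGGGTAGACTGGGTGAACTGAGC",
  "CGTTCGAACGAAATATATCTGAGGTTTCATGGAACCCCCGACGATCCTACGTCACACGTC",
  "TATCCCTTAGAAGCGAAACGCTACAAGCCACCCGTTGTATGCGGTCGAGCGCTGGTCTGG",
  "GAAACAAATGAGGCGGGACTAGTCTAGGAATCAGCTGTCACCAAGCTGATACATCTAGGA")

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by every generator:
#' multi-exon genes with intronic Alu-like insertions, a subset exonized
#' with known region/frame/PTC status and true per-tissue inclusion levels,
#' junction read counts for RNA-seq and Ribo-seq, planted peptide libraries,
#' and 3x3-replicate editing count tables.
#'
#' @param seed integer seed; fully determines every output.
#' @param n_genes number of genes.
#' @param n_tissues number of tissues with independent true psi.
#' @param exons_per_gene,exon_length,intron_length inclusive integer ranges.
#' @param p_insert probability a gene's intron carries an Alu insertion.
#' @param p_exonize probability an inserted copy is exonized.
#' @param subfamily_probs named probabilities of subfamily labels.
#' @param mutation_rate per-base substitution rate applied to each inserted
#'   copy.
#' @param ptc_fraction fraction of exonized events planted with an in-frame
#'   premature stop codon (PTC events); the rest are frame-preserving with
#'   a clean reading frame (NON_PTC).
#' @param psi_shape length-2 Beta parameters for true per-tissue psi.
#' @param ptc_translation_factor Ribo-seq translation factor of PTC events
#'   (NON_PTC events have factor 1).
#' @param editing list of editing-simulation parameters: `n_sites`,
#'   fractions `frac_null`, `frac_common`, `frac_short`, `frac_long`,
#'   `baseline_shape` (Beta), `delta` (logit-scale effect), `coverage_mean`,
#'   `coverage_size` (negative binomial), `n_replicates`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 40L, n_tissues = 4L,
                       exons_per_gene = c(5L, 8L),
                       exon_length = c(90L, 180L),
                       intron_length = c(700L, 1200L),
                       p_insert = 0.7, p_exonize = 0.6,
                       subfamily_probs = c(AluSx = 0.6, AluJb = 0.25,
                                           AluY = 0.15),
                       mutation_rate = 0.02,
                       ptc_fraction = 0.5,
                       psi_shape = c(2, 2),
                       ptc_translation_factor = 0.3,
                       editing = list()) {
  ed <- utils::modifyList(list(
    n_sites = 300L, frac_null = 0.5, frac_common = 0.25,
    frac_short = 0.125, frac_long = 0.125,
    baseline_shape = c(2, 6), delta = 1.5,
    coverage_mean = 100, coverage_size = 10, n_replicates = 3L), editing)
  probs <- c(p_insert, p_exonize, ptc_fraction, mutation_rate,
             ed$frac_null, ed$frac_common, ed$frac_short, ed$frac_long)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(subfamily_probs) - 1) > 1e-8) {
    stop("subfamily probabilities must sum to 1")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues), exons_per_gene = exons_per_gene,
    exon_length = exon_length, intron_length = intron_length,
    p_insert = p_insert, p_exonize = p_exonize,
    subfamily_probs = subfamily_probs, mutation_rate = mutation_rate,
    ptc_fraction = ptc_fraction, psi_shape = psi_shape,
    ptc_translation_factor = ptc_translation_factor, editing = ed),
    class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

random_dna <- function(n) sample(.BASES, n, replace = TRUE)

mutate_seq <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1)
  chars
}

## Write sense-strand bases at mRNA offsets of a transcript layout.
## pos: genomic 0-based positions in 5'->3' mRNA order.
write_sense <- function(chrom_vec, pos, strand, offsets, bases) {
  g <- pos[offsets + 1L]
  chrom_vec[g + 1L] <- if (strand == "-") {
    unname(.COMPLEMENT[bases])
  } else bases
  chrom_vec
}

read_sense <- function(chrom_vec, pos, strand, offsets) {
  b <- chrom_vec[pos[offsets + 1L] + 1L]
  if (strand == "-") unname(.COMPLEMENT[b]) else b
}

## Replace premature stop codons in [orf_start, limit) (mRNA offsets,
## codon-aligned at orf_start). Returns list(chrom_vec, n_edits).
sanitize_frame <- function(chrom_vec, pos, strand, orf_start, limit) {
  n_edits <- 0L
  k <- orf_start
  while (k + 3L <= limit) {
    codon <- paste(read_sense(chrom_vec, pos, strand, k:(k + 2L)),
                   collapse = "")
    if (codon %in% .STOP_CODONS) {
      chrom_vec <- write_sense(chrom_vec, pos, strand, k + 2L, "T")
      n_edits <- n_edits + 1L
    }
    k <- k + 3L
  }
  list(chrom_vec = chrom_vec, n_edits = n_edits)
}

#' Simulate a toy genome with planted Alu exonization events
#'
#' Generates multi-exon genes on a single chromosome; a subset of introns
#' receive a (mutated) copy of the bundled Alu-like consensus, and a subset
#' of those copies are exonized: an internal exon carved out of the copy is
#' added to the gene's annotated transcript, with canonical AG/GT
#' dinucleotides at its splice sites. NON_PTC events preserve the reading
#' frame (length divisible by 3, no internal in-frame stop); PTC events
#' carry an in-frame stop inside the exon, more than 50 nt upstream of the
#' last junction. All coding frames are sanitized so the annotated stop
#' codon is the first in-frame stop of each isoform.
#'
#' @param config a [sim_config()].
#' @return list of class `alu_simulation`: `genome` (DNAStringSet),
#'   `transcripts` (inclusion-isoform annotation, one transcript per gene),
#'   `repeats` (all inserted copies), `truth` (per-event data.frame with
#'   coordinates, subfamily, region class, frame, PTC status, true psi per
#'   tissue and translation factor), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom <- "chrS"
  chrom_vec <- character(0)
  models <- list()
  repeat_rows <- list()
  truth_rows <- list()
  gap <- 300L

  for (g in seq_len(config$n_genes)) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                     replace = TRUE)
    in_len <- sample(config$intron_length[1]:config$intron_length[2],
                     n_ex - 1, replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    gseq <- random_dna(glen)
    offset <- length(chrom_vec) + gap
    starts <- offset + cumsum(c(0L, head(ex_len + c(in_len, 0L), -1)))
    exons <- cbind(start = as.integer(starts),
                   end = as.integer(starts + ex_len))

    inserted <- stats::runif(1) < config$p_insert
    exonized <- inserted && stats::runif(1) < config$p_exonize
    alu_exon <- NULL
    subfam <- NA_character_
    ptc <- NA
    if (inserted) {
      j <- sample(seq_len(n_ex - 1), 1)
      alu_chars <- mutate_seq(strsplit(ALU_CONSENSUS, "")[[1]],
                              config$mutation_rate)
      alu_len <- length(alu_chars)
      intron_start_local <- starts[j] + ex_len[j] - offset
      d <- sample(100:(in_len[j] - alu_len - 100L), 1)
      alu_start <- starts[j] + ex_len[j] + d          # genomic
      gseq[(intron_start_local + d + 1L):(intron_start_local + d + alu_len)] <-
        alu_chars
      subfam <- sample(names(config$subfamily_probs), 1,
                       prob = config$subfamily_probs)
      repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
        chrom = chrom, start = alu_start, end = alu_start + alu_len,
        strand = sample(c("+", "-"), 1), name = subfam,
        family = "SINE/Alu", stringsAsFactors = FALSE)
      if (exonized) {
        ptc <- stats::runif(1) < config$ptc_fraction
        e_len <- if (ptc) {
          sample(85:150, 1)
        } else sample(seq(84L, 144L, by = 3L), 1)
        a_off <- sample(0:(alu_len - e_len), 1)
        alu_exon <- c(alu_start + a_off, alu_start + a_off + e_len)
      }
    }
    chrom_vec <- c(chrom_vec, random_dna(gap), gseq)

    incl_exons <- exons
    if (!is.null(alu_exon)) {
      k <- findInterval(alu_exon[1], exons[, "start"])
      incl_exons <- rbind(exons[seq_len(k), , drop = FALSE],
                          matrix(as.integer(alu_exon), 1, 2,
                                 dimnames = list(NULL, c("start", "end"))),
                          exons[(k + 1):n_ex, , drop = FALSE])
      ## canonical splice dinucleotides on the sense strand
      ss <- if (strand == "+") {
        list(c(alu_exon[1] - 2L, alu_exon[1] - 1L, "A", "G"),
             c(alu_exon[2], alu_exon[2] + 1L, "G", "T"))
      } else {
        list(c(alu_exon[2] + 1L, alu_exon[2], "A", "G"),
             c(alu_exon[1] - 1L, alu_exon[1] - 2L, "G", "T"))
      }
      for (s in ss) {
        gpos <- as.integer(s[1:2])
        bases <- s[3:4]
        if (strand == "-") bases <- unname(.COMPLEMENT[bases])
        chrom_vec[gpos + 1L] <- bases
      }
    }

    models[[g]] <- list(
      gene = g, strand = strand, exons = exons, incl_exons = incl_exons,
      alu_exon = alu_exon, subfam = subfam, ptc = ptc)
  }

  ## define CDS per gene, plant start/stop codons and sanitize frames
  for (g in seq_len(config$n_genes)) {
    m <- models[[g]]
    pos_skip <- mrna_positions(m$exons, m$strand)
    orf_start <- 30L
    skip_len <- length(pos_skip)
    last_len <- m$exons[if (m$strand == "+") nrow(m$exons) else 1L, ]
    last_len <- last_len["end"] - last_len["start"]
    target <- skip_len - as.integer(last_len) + 15L
    stop_start <- orf_start + 3L * as.integer(ceiling((target - orf_start) / 3))
    chrom_vec <- write_sense(chrom_vec, pos_skip, m$strand,
                             orf_start:(orf_start + 2L), c("A", "T", "G"))
    chrom_vec <- write_sense(chrom_vec, pos_skip, m$strand,
                             stop_start:(stop_start + 2L), c("T", "A", "A"))

    pstop_start <- NA_integer_
    if (!is.null(m$alu_exon)) {
      pos_incl <- mrna_positions(m$incl_exons, m$strand)
      e_len <- m$alu_exon[2] - m$alu_exon[1]
      first_sense <- if (m$strand == "+") m$alu_exon[1] else m$alu_exon[2] - 1L
      ex_s <- match(first_sense, pos_incl) - 1L
      stop_incl <- stop_start + e_len
      if (m$ptc) {
        k0 <- as.integer(ceiling((ex_s + 3L - orf_start) / 3))
        pstop_start <- orf_start + 3L * k0
        chrom_vec <- write_sense(chrom_vec, pos_incl, m$strand,
                                 pstop_start:(pstop_start + 2L),
                                 c("T", "A", "A"))
      }
      limit_incl <- if (m$ptc) pstop_start else stop_incl
      for (iter in 1:20) {
        s1 <- sanitize_frame(chrom_vec, pos_skip, m$strand, orf_start,
                             stop_start)
        s2 <- sanitize_frame(s1$chrom_vec, pos_incl, m$strand, orf_start,
                             limit_incl)
        chrom_vec <- s2$chrom_vec
        if (s1$n_edits + s2$n_edits == 0L) break
        if (iter == 20L) stop("frame sanitation did not converge")
      }
    } else {
      for (iter in 1:20) {
        s1 <- sanitize_frame(chrom_vec, pos_skip, m$strand, orf_start,
                             stop_start)
        chrom_vec <- s1$chrom_vec
        if (s1$n_edits == 0L) break
      }
    }
    cds_g <- pos_skip[(orf_start + 1L):(stop_start + 3L)]
    models[[g]]$cds <- c(min(cds_g), max(cds_g) + 1L)
    models[[g]]$frame_offset <- if (!is.null(m$alu_exon)) {
      pos_incl <- mrna_positions(m$incl_exons, m$strand)
      first_sense <- if (m$strand == "+") m$alu_exon[1] else m$alu_exon[2] - 1L
      (match(first_sense, pos_incl) - 1L - orf_start) %% 3L
    } else NA_integer_
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chrom_vec, collapse = ""), chrom))

  tx_models <- list()
  for (g in seq_len(config$n_genes)) {
    m <- models[[g]]
    tx_models[[g]] <- transcript_model(
      transcript_id = sprintf("TX%03d", g), gene_id = sprintf("G%03d", g),
      chrom = chrom, strand = m$strand, exons = m$incl_exons,
      cds_start = m$cds[1], cds_end = m$cds[2])
    if (!is.null(m$alu_exon)) {
      psi <- stats::rbeta(config$n_tissues, config$psi_shape[1],
                          config$psi_shape[2])
      row <- data.frame(
        exon_id = sprintf("%s:%d-%d:%s", chrom, m$alu_exon[1], m$alu_exon[2],
                          m$strand),
        gene_id = sprintf("G%03d", g), transcript_id = sprintf("TX%03d", g),
        chrom = chrom, start = m$alu_exon[1], end = m$alu_exon[2],
        strand = m$strand, length = m$alu_exon[2] - m$alu_exon[1],
        subfamily = m$subfam, region = "CDS",
        frame_offset = m$frame_offset,
        len_mod3 = (m$alu_exon[2] - m$alu_exon[1]) %% 3L,
        ptc = m$ptc,
        translation_factor = if (m$ptc) config$ptc_translation_factor else 1,
        stop_before_downstream_junction = m$ptc,
        stringsAsFactors = FALSE)
      for (t in seq_len(config$n_tissues)) {
        row[[sprintf("psi_tissue%d", t)]] <- psi[t]
      }
      truth_rows[[length(truth_rows) + 1L]] <- row
    }
  }

  structure(list(
    genome = genome,
    transcripts = transcript_model_list(tx_models),
    repeats = if (length(repeat_rows)) {
      do.call(rbind, repeat_rows)
    } else data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), family = character(0)),
    truth = if (length(truth_rows)) {
      do.call(rbind, truth_rows)
    } else NULL,
    config = config), class = "alu_simulation")
}

#' @export
print.alu_simulation <- function(x, ...) {
  cat(sprintf(
    "<alu_simulation> %d gene(s), %d Alu insertion(s), %d exonized, seed %d\n",
    length(x$transcripts), nrow(x$repeats),
    if (is.null(x$truth)) 0L else nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Junction library for every planted exon of a simulation
#'
#' @param sim an `alu_simulation`.
#' @param flank junction segment length per side.
#' @return combined `junction_library`.
#' @export
sim_junction_library <- function(sim, flank = 27L) {
  libs <- lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    tx <- sim$transcripts[[tr$transcript_id]]
    skip <- drop_exon(tx, c(tr$start, tr$end))
    build_junction_library(skip, c(tr$start, tr$end), sim$genome, flank)
  })
  do.call(combine_junction_libraries, libs)
}

#' Simulate junction read counts from planted inclusion levels
#'
#' A junction read originates from the inclusion isoform (which carries two
#' inclusion junctions) with probability `2a / (2a + b)`, where
#' `a = psi * t` (t = translation factor for Ribo-seq, 1 for RNA-seq) and
#' `b = 1 - psi`; inclusion reads split evenly between the upstream and
#' downstream junctions, the rest are skipping reads. Under this model the
#' averaged-junction estimator of [compute_psi()] is consistent for psi.
#' For Ribo-seq, no footprints are generated downstream of an isoform's
#' stop codon: events whose premature stop precedes the downstream junction
#' get DJC = 0.
#'
#' @param sim an `alu_simulation`.
#' @param depth reads per exon and sample; must be positive.
#' @param assay "rna" (all tissues) or "ribo" (one cell-line sample whose
#'   true psi is tissue 1's).
#' @param seed integer seed.
#' @param exact logical; if TRUE, expected counts (rounded) replace
#'   binomial sampling — the noiseless limit.
#' @return a `junction_counts` data.frame.
#' @export
simulate_junction_counts <- function(sim, depth = 2000L,
                                     assay = c("rna", "ribo"),
                                     seed = sim$config$seed, exact = FALSE) {
  assay <- match.arg(assay)
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  truth <- sim$truth
  samples <- if (assay == "rna") {
    sprintf("tissue%d", seq_len(sim$config$n_tissues))
  } else "ribo"
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (s in samples) {
      psi <- if (assay == "rna") {
        truth[[paste0("psi_", s)]][i]
      } else truth$psi_tissue1[i]
      t_fac <- if (assay == "ribo") truth$translation_factor[i] else 1
      a <- psi * t_fac
      b <- 1 - psi
      p_inc <- if (2 * a + b > 0) 2 * a / (2 * a + b) else 0
      if (exact) {
        inc <- round_half_up(depth * p_inc)
        u <- round_half_up(inc / 2)
      } else {
        inc <- stats::rbinom(1, depth, p_inc)
        u <- stats::rbinom(1, inc, 0.5)
      }
      d <- inc - u
      if (assay == "ribo" && truth$stop_before_downstream_junction[i]) {
        d <- 0L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = truth$exon_id[i], sample = s,
        UJC = as.integer(u), DJC = as.integer(d),
        SJC = as.integer(depth - inc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("junction_counts", "data.frame")
  out
}

#' Materialize junction counts as read sequences
#'
#' Emits, for each (exon, junction, sample) count, that many error-free
#' reads drawn from the junction sequence at uniformly sampled offsets
#' covering the splice boundary.
#'
#' @param counts a `junction_counts` table.
#' @param library the `junction_library` the counts refer to.
#' @param read_length read length (<= junction length).
#' @param seed integer seed.
#' @return named list (one element per sample) of character read vectors.
#' @export
simulate_junction_reads <- function(counts, library, read_length = 50L,
                                    seed = 1L) {
  set.seed(seed)
  out <- list()
  roles <- c(UJC = "UPSTREAM", DJC = "DOWNSTREAM", SJC = "SKIPPING")
  for (s in unique(counts$sample)) {
    reads <- character(0)
    cs <- counts[counts$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(cs))) {
      for (col in names(roles)) {
        n <- cs[[col]][i]
        if (n == 0) next
        j <- which(library$exon_id == cs$exon_id[i] &
                     library$role == roles[[col]])
        jseq <- library$seq[j]
        bnd <- library$boundary[j]
        offs <- 0:(nchar(jseq) - read_length)
        offs <- offs[offs < bnd & offs + read_length > bnd]
        if (length(offs) == 0) stop("read length incompatible with junction")
        o <- sample(rep(offs, length.out = max(n, length(offs))), n)
        reads <- c(reads, substr(rep(jseq, n), o + 1L, o + read_length))
      }
    }
    out[[s]] <- sample(reads)
  }
  out
}

#' Protein space of a simulation
#'
#' Background = every gene's skipping-isoform translation; inclusion
#' isoforms for each planted exon.
#'
#' @param sim an `alu_simulation`.
#' @return list with `space` (a `protein_space`) and `orfs` (named list of
#'   `inclusion_orf` keyed by exon id).
#' @export
sim_protein_space <- function(sim) {
  truth <- sim$truth
  exonized <- if (is.null(truth)) character(0) else truth$transcript_id
  background <- character(0)
  for (tx in sim$transcripts) {
    model <- tx
    if (tx$transcript_id %in% exonized) {
      tr <- truth[truth$transcript_id == tx$transcript_id, ]
      model <- drop_exon(tx, c(tr$start, tr$end))
    }
    background[[tx$transcript_id]] <- translate_transcript(model, sim$genome)
  }
  orfs <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    tx <- sim$transcripts[[tr$transcript_id]]
    skip <- drop_exon(tx, c(tr$start, tr$end))
    orfs[[tr$exon_id]] <- build_inclusion_orf(skip, c(tr$start, tr$end),
                                              sim$genome)
  }
  list(space = build_protein_space(background, orfs), orfs = orfs)
}

## Try peptide windows around `anchor` until one with the required
## occurrence count in the space is found; NA if none.
pick_peptide <- function(space, protein, from0, len, want_unique = TRUE) {
  pep <- substr(protein, from0 + 1L, from0 + len)
  if (nchar(pep) < len) return(NA_character_)
  n <- sum(vapply(space$seq, function(s) {
    length(find_all_occurrences(pep, s))
  }, integer(1)))
  if ((want_unique && n == 1) || (!want_unique && n > 1)) pep else
    NA_character_
}

#' Plant a peptide library with known intended classifications
#'
#' For each planted exon emits (where geometry permits) a unique exon-body
#' peptide, unique upstream/downstream junction-spanning peptides (3 aa on
#' the flank side), a multi-mapping decoy (flank-only sequence present in
#' both the inclusion isoform and the background skipping protein), and a
#' 5-aa sub-length peptide; plus unique background-only peptides from
#' non-exonized genes. Peptides whose planted class cannot be realized
#' (e.g. a repeat-derived body peptide that is not unique) are skipped.
#'
#' @param sim an `alu_simulation`.
#' @param space_info result of [sim_protein_space()].
#' @param n_background number of background-only peptides.
#' @param body_length planted peptide length (default 9).
#' @return list with `peptides` and `labels` (data.frame of `peptide`,
#'   `exon_id`, `intended`).
#' @export
simulate_peptides <- function(sim, space_info = sim_protein_space(sim),
                              n_background = 5L, body_length = 9L) {
  space <- space_info$space
  labels <- list()
  add <- function(pep, exon_id, intended) {
    labels[[length(labels) + 1L]] <<- data.frame(
      peptide = pep, exon_id = exon_id, intended = intended,
      stringsAsFactors = FALSE)
  }
  inc <- space[space$type == "inclusion", , drop = FALSE]
  for (i in seq_len(nrow(inc))) {
    a <- inc$aa_start[i]; b <- inc$aa_end[i]
    prot <- inc$seq[i]
    ex <- inc$exon_id[i]
    if (b - a >= body_length + 2L) {
      mid <- a + ((b - a) - body_length) %/% 2L
      for (f in c(mid, a + 1L, b - body_length - 1L)) {
        pep <- pick_peptide(space, prot, f, body_length)
        if (!is.na(pep)) { add(pep, ex, "EXON_BODY"); break }
      }
    }
    if (a >= 3L && b - a >= body_length - 3L) {
      pep <- pick_peptide(space, prot, a - 3L, body_length)
      if (!is.na(pep)) add(pep, ex, "UPSTREAM_JUNCTION")
    }
    if (nchar(prot) - b >= 3L && b - a >= body_length - 3L) {
      pep <- pick_peptide(space, prot, b - (body_length - 3L), body_length)
      if (!is.na(pep)) add(pep, ex, "DOWNSTREAM_JUNCTION")
    }
    if (a >= body_length + 4L) {
      pep <- pick_peptide(space, prot, a - body_length - 4L, body_length,
                          want_unique = FALSE)
      if (!is.na(pep)) add(pep, ex, "MULTI_MAPPING")
    }
    if (b - a >= 5L) add(substr(prot, a + 1L, a + 5L), ex, "TOO_SHORT")
  }
  bg <- space[space$type == "background" &
                !space$protein_id %in% sim$truth$transcript_id, ,
              drop = FALSE]
  n_added <- 0L
  for (i in seq_len(nrow(bg))) {
    if (n_added >= n_background) break
    prot <- bg$seq[i]
    if (nchar(prot) < body_length + 20L) next
    pep <- pick_peptide(space, prot, nchar(prot) %/% 2L, body_length)
    if (!is.na(pep)) { add(pep, NA_character_, "BACKGROUND"); n_added <- n_added + 1L }
  }
  labels <- do.call(rbind, labels)
  list(peptides = labels$peptide, labels = labels)
}

#' Simulate replicated A-to-I editing count tables
#'
#' Per site, a baseline editing level is drawn from a Beta distribution;
#' group levels are `plogis(qlogis(baseline) + delta_group)` with
#' `delta_EV = 0`. Null sites have zero delta in all groups; effect sites
#' shift SHORT, LONG or both by `delta`. Per replicate, coverage is
#' negative binomial and edited counts binomial at the group level.
#'
#' @param config a [sim_config()] (its `editing` element is used).
#' @param seed integer seed.
#' @return list with `counts` (an `editing_counts`) and `truth` (site
#'   class and true per-group levels).
#' @export
simulate_editing_counts <- function(config, seed = config$seed) {
  ed <- config$editing
  set.seed(seed)
  n <- ed$n_sites
  fr <- c(null = ed$frac_null, common = ed$frac_common,
          short_specific = ed$frac_short, long_specific = ed$frac_long)
  if (abs(sum(fr) - 1) > 1e-8) stop("editing class fractions must sum to 1")
  classes <- sample(names(fr), n, replace = TRUE, prob = fr)
  baseline <- stats::rbeta(n, ed$baseline_shape[1], ed$baseline_shape[2])
  delta_short <- ifelse(classes %in% c("common", "short_specific"),
                        ed$delta, 0)
  delta_long <- ifelse(classes %in% c("common", "long_specific"),
                       ed$delta, 0)
  lv <- cbind(EV = baseline,
              SHORT = stats::plogis(stats::qlogis(baseline) + delta_short),
              LONG = stats::plogis(stats::qlogis(baseline) + delta_long))
  groups <- rep(c("EV", "SHORT", "LONG"), each = ed$n_replicates)
  reps <- rep(seq_len(ed$n_replicates), times = 3)
  libs <- sprintf("%s%d", groups, reps)
  e <- u <- matrix(0L, n, length(libs), dimnames = list(NULL, libs))
  for (j in seq_along(libs)) {
    cov <- stats::rnbinom(n, mu = ed$coverage_mean, size = ed$coverage_size)
    ej <- stats::rbinom(n, cov, lv[, groups[j]])
    e[, j] <- ej
    u[, j] <- cov - ej
  }
  sites <- data.frame(chrom = "chrS", pos = seq_len(n) * 1000L,
                      strand = "+", stringsAsFactors = FALSE)
  counts <- editing_counts(sites, e, u, data.frame(
    library = libs, group = groups, replicate = reps,
    stringsAsFactors = FALSE))
  truth <- data.frame(
    site_id = sprintf("%s:%d:%s", sites$chrom, sites$pos, sites$strand),
    class = classes, baseline = baseline,
    level_ev = lv[, "EV"], level_short = lv[, "SHORT"],
    level_long = lv[, "LONG"], stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
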