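# In-code fixtures: toy genomes and transcripts built deterministically.

toy_genome <- function(seqs) {
  Biostrings::DNAStringSet(unlist(seqs))
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Three-exon plus-strand gene on a deterministic 600-nt chromosome, CDS from
# the start of exon 1 to the end of exon 3. Exons [0,60), [160,220),
# [460,520); the middle exon is internal.
toy_three_exon_tx <- function(chrom = "chrA") {
  transcript_model("txA", "gA", chrom, "+",
                   exons = cbind(start = c(0L, 160L, 460L),
                                 end = c(60L, 220L, 520L)),
                   cds_start = 0L, cds_end = 520L)
}

toy_three_exon_genome <- function(chrom = "chrA") {
  toy_genome(setNames(list(random_seq(600, 421)), chrom))
}

# A minimal toy coding gene: skipping mRNA "ATGGCA" + "GCATAA"
# (exons [10,16) and [100,106)), candidate exon "GCAGCA" at [50,56).
# Inclusion mRNA = ATG GCA GCA GCA GCA TAA -> protein "MAAAA".
toy_coding_fixture <- function() {
  pre <- strrep("C", 10)
  seq <- paste0(pre, "ATGGCA",                      # exon 1 [10,16)
                strrep("T", 34), "GCAGCA",          # alu exon [50,56)
                strrep("T", 44), "GCATAA",          # exon 3 [100,106)
                strrep("C", 20))
  genome <- toy_genome(list(chrB = seq))
  tx <- transcript_model("txB", "gB", "chrB", "+",
                         exons = cbind(start = c(10L, 100L),
                                       end = c(16L, 106L)),
                         cds_start = 10L, cds_end = 106L)
  list(genome = genome, tx = tx, alu_exon = c(50L, 56L))
}

# Junction count row constructor.
jc_row <- function(exon_id, sample, u, d, s) {
  out <- data.frame(exon_id = exon_id, sample = sample, UJC = u, DJC = d,
                    SJC = s, stringsAsFactors = FALSE)
  class(out) <- c("junction_counts", "data.frame")
  out
}

jc_table <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("junction_counts", "data.frame")
  out
}

# Small editing counts object with explicit matrices.
toy_editing_counts <- function(e, u) {
  libs <- c(paste0("EV", 1:3), paste0("SHORT", 1:3), paste0("LONG", 1:3))
  colnames(e) <- colnames(u) <- libs
  sites <- data.frame(chrom = "chrZ", pos = seq_len(nrow(e)) * 10L,
                      strand = "+", stringsAsFactors = FALSE)
  manifest <- data.frame(library = libs,
                         group = rep(c("EV", "SHORT", "LONG"), each = 3),
                         replicate = rep(1:3, times = 3),
                         stringsAsFactors = FALSE)
  editing_counts(sites, e, u, manifest)
}

# Shared small simulation for cross-module tests (built once per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_genome(sim_config(seed = 7))
    cache
  }
})
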