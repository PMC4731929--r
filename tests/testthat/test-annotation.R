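alu_repeat <- function(chrom, start, end, name = "AluSx") {
  data.frame(chrom = chrom, start = start, end = end, strand = "+",
             name = name, family = "SINE/Alu", stringsAsFactors = FALSE)
}

test_that("find_alu_exons enforces the 25 bp and >50% overlap thresholds", {
  tx <- toy_three_exon_tx()                     # internal exon [160,220), 60 bp
  txs <- transcript_model_list(list(tx))
  # 40 of 60 bp covered: both thresholds met
  expect_equal(nrow(find_alu_exons(txs, alu_repeat("chrA", 180, 260))), 1)
  # exactly 50%: 30 of 60 is not > 50%
  expect_equal(nrow(find_alu_exons(txs, alu_repeat("chrA", 190, 260))), 0)
  # fraction 1 but internal exon never considered: first/last exons skipped
  expect_equal(nrow(find_alu_exons(txs, alu_repeat("chrA", 0, 60))), 0)
  expect_equal(nrow(find_alu_exons(txs, alu_repeat("chrA", 460, 520))), 0)
  # 24 bp < 25 bp even at fraction 0.6 (40-bp internal exon)
  tx40 <- transcript_model("tx40", "g40", "chrA", "+",
                           cbind(start = c(0L, 160L, 460L),
                                 end = c(60L, 200L, 520L)),
                           cds_start = 0L, cds_end = 520L)
  expect_equal(nrow(find_alu_exons(transcript_model_list(list(tx40)),
                                   alu_repeat("chrA", 176, 200))), 0)
})

test_that("find_alu_exons takes the single best-overlapping repeat", {
  tx <- toy_three_exon_tx()
  reps <- rbind(alu_repeat("chrA", 150, 185, "AluJb"),   # 25 bp overlap
                alu_repeat("chrA", 170, 230, "AluY"))    # 50 bp overlap
  rec <- find_alu_exons(transcript_model_list(list(tx)), reps)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$subfamily, "AluY")
  expect_equal(rec$overlap_bp, 50L)
  expect_equal(rec$overlap_frac, 50 / 60)
})

test_that("find_alu_exons rejects disjoint chromosome naming", {
  tx <- toy_three_exon_tx()
  expect_error(
    find_alu_exons(transcript_model_list(list(tx)),
                   alu_repeat("1", 170, 230)),
    "inconsistent chromosome names")
})

test_that("find_alu_exons matches a brute-force intersection oracle on
           random layouts", {
  set.seed(55)
  for (case in 1:25) {
    n_ex <- sample(3:6, 1)
    starts <- cumsum(sample(50:200, n_ex * 2))[seq(1, n_ex * 2, 2)]
    ends <- starts + sample(30:90, n_ex, replace = TRUE)
    tx <- transcript_model("t", "g", "chrR",
                           sample(c("+", "-"), 1),
                           cbind(start = as.integer(starts),
                                 end = as.integer(ends)),
                           cds_start = as.integer(starts[1]),
                           cds_end = as.integer(ends[n_ex]))
    reps <- do.call(rbind, lapply(1:4, function(i) {
      s <- sample(0:max(ends), 1)
      alu_repeat("chrR", s, s + sample(40:300, 1),
                 sample(c("AluSx", "AluY"), 1))
    }))
    rec <- find_alu_exons(transcript_model_list(list(tx)), reps)
    for (i in 2:(n_ex - 1)) {
      exon <- c(starts[i], ends[i])
      best <- oracle_best_overlap(exon, reps)
      expected <- best >= 25 && best > 0.5 * (exon[2] - exon[1])
      got <- any(rec$start == exon[1] & rec$end == exon[2])
      expect_equal(got, expected,
                   info = sprintf("case %d exon %d", case, i))
      if (got) {
        r <- rec[rec$start == exon[1], ]
        expect_equal(r$overlap_bp, best)
        expect_true(r$overlap_bp >= 25 && r$overlap_frac > 0.5)
      }
    }
  }
})

test_that("classify_exon_region places exons relative to the CDS", {
  tx <- transcript_model("t", "g", "chrA", "+",
                         cbind(start = c(0L, 100L, 200L, 300L, 400L),
                               end = c(50L, 150L, 250L, 350L, 450L)),
                         cds_start = 120L, cds_end = 340L)
  expect_equal(classify_exon_region(c(200L, 250L), tx), "CDS")
  expect_equal(classify_exon_region(c(0L, 50L), tx), "FIVE_UTR")
  expect_equal(classify_exon_region(c(400L, 450L), tx), "THREE_UTR")
  # any overlap with the CDS, even 10 bp across the start codon, is CDS
  expect_equal(classify_exon_region(c(100L, 130L), tx), "CDS")
  expect_equal(classify_exon_region(c(100L, 120L), tx), "FIVE_UTR")
  # minus strand: genomically-upstream exons are 3'UTR
  txm <- transcript_model("tm", "g", "chrA", "-", tx$exons,
                          cds_start = 120L, cds_end = 340L)
  expect_equal(classify_exon_region(c(0L, 50L), txm), "THREE_UTR")
  expect_equal(classify_exon_region(c(400L, 450L), txm), "FIVE_UTR")
  # non-coding transcript raises a typed condition
  txnc <- transcript_model("tn", "g", "chrA", "+", tx$exons)
  expect_error(classify_exon_region(c(200L, 250L), txnc),
               class = "noncoding_transcript")
})

test_that("build_inclusion_orf translates the toy inclusion isoform", {
  fx <- toy_coding_fixture()
  orf <- build_inclusion_orf(fx$tx, fx$alu_exon, fx$genome)
  expect_equal(orf$mrna, "ATGGCAGCAGCAGCATAA")
  expect_equal(orf$protein, "MAAAA")
  expect_false(orf$frameshift)
  expect_false(orf$stop_lost)
  # exon occupies nucleotides [6,12) of the mRNA -> amino acids [2,4)
  expect_equal(orf$exon_mrna, c(6L, 12L))
  expect_equal(orf$aa_span, c(2L, 4L))
})

test_that("frame-preserving insertion leaves the downstream protein intact;
           frame-shifting insertion changes it", {
  sim <- shared_sim()
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    tx <- sim$transcripts[[truth$transcript_id[i]]]
    exon <- c(truth$start[i], truth$end[i])
    skip <- drop_exon(tx, exon)
    orf <- build_inclusion_orf(skip, exon, sim$genome)
    skip_prot <- translate_transcript(skip, sim$genome)
    a <- orf$aa_span[1]
    expect_equal(substr(orf$protein, 1, a), substr(skip_prot, 1, a))
    if (truth$len_mod3[i] == 0 && !truth$ptc[i]) {
      ins <- truth$length[i] / 3
      expect_equal(nchar(orf$protein), nchar(skip_prot) + ins)
      # identical downstream of the insertion (junction-straddling codon,
      # when present, may differ on both sides; skip one codon)
      expect_equal(substr(orf$protein, a + ins + 2, nchar(orf$protein)),
                   substr(skip_prot, a + 2, nchar(skip_prot)))
    }
  }
})

test_that("stop-lost inclusion transcripts are flagged, not dropped", {
  # exon introduces a frameshift and no stop is reachable before mRNA end
  seqs <- paste0(strrep("C", 10), "ATGGCA", strrep("T", 34), "GCAG",
                 strrep("T", 46), "GCAGCC", strrep("C", 20))
  genome <- toy_genome(list(chrB = seqs))
  tx <- transcript_model("t", "g", "chrB", "+",
                         cbind(start = c(10L, 100L), end = c(16L, 106L)),
                         cds_start = 10L, cds_end = 106L)
  orf <- build_inclusion_orf(tx, c(50L, 54L), genome)
  expect_true(orf$stop_lost)
  expect_warning(cls <- classify_ptc(orf), "stop-lost")
  expect_equal(as.character(cls), "NON_PTC")
})

test_that("classify_ptc applies the strict 50-nt rule", {
  mk <- function(dist) {
    structure(list(stop_lost = FALSE, stop_end = 100L,
                   last_junction = 100L + dist), class = "inclusion_orf")
  }
  expect_equal(as.character(classify_ptc(mk(51L))), "PTC")
  expect_equal(as.character(classify_ptc(mk(50L))), "NON_PTC")
  # stop inside the last exon: junction upstream of the stop
  expect_equal(as.character(classify_ptc(mk(-20L))), "NON_PTC")
})

test_that("classify_ptc is invariant to extra 5'UTR exons", {
  fx <- toy_coding_fixture()
  orf1 <- build_inclusion_orf(fx$tx, fx$alu_exon, fx$genome)
  # prepend a UTR exon at [0,6): pure 5'UTR, CDS unchanged
  tx2 <- transcript_model("txB2", "gB", "chrB", "+",
                          cbind(start = c(0L, 10L, 100L),
                                end = c(6L, 16L, 106L)),
                          cds_start = 10L, cds_end = 106L)
  orf2 <- build_inclusion_orf(tx2, fx$alu_exon, fx$genome)
  expect_equal(as.character(classify_ptc(orf1)),
               as.character(classify_ptc(orf2)))
  expect_equal(orf1$last_junction - orf1$stop_end,
               orf2$last_junction - orf2$stop_end)
})

test_that("frame_divisibility_test counts and Fisher p", {
  # proportional table -> p = 1
  r <- frame_divisibility_test(c(3, 3, 4), c(3, 3, 3, 3, 4, 4))
  expect_equal(unname(r$fractions), c(2 / 3, 2 / 3))
  expect_equal(r$p, 1)
  # all divisible vs none, 10 vs 10, against the enumeration oracle
  r2 <- frame_divisibility_test(rep(9, 10), rep(10, 10))
  expect_equal(r2$p, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  expect_error(frame_divisibility_test(numeric(0), c(3)), "non-empty")
})

test_that("subfamily_fraction counts and errors", {
  rec <- data.frame(subfamily = c("AluY", "AluSx", "AluY", "AluJb",
                                  "AluSx", "AluSx"))
  r <- subfamily_fraction(rec, "AluY")
  expect_equal(r$count, 2L)
  expect_equal(r$fraction, 1 / 3)
  expect_equal(subfamily_fraction(rec, "AluYk12")$fraction, 0)
  expect_error(subfamily_fraction(rec[0, , drop = FALSE], "AluY"), "empty")
})

test_that("region classes partition classified exons; PTC splits the CDS set", {
  sim <- shared_sim()
  rec <- find_alu_exons(sim$transcripts, sim$repeats)
  cls <- classify_alu_exons(rec, sim$transcripts, sim$genome)
  expect_true(all(cls$region %in% c("FIVE_UTR", "CDS", "THREE_UTR")))
  cds <- cls[cls$region == "CDS", ]
  expect_equal(sum(cds$ptc == "PTC") + sum(cds$ptc == "NON_PTC"), nrow(cds))
})
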